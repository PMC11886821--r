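# mscosine

Batched greedy and modified cosine similarity for tandem mass spectrometry
(MS/MS) spectral library matching.

Comparing an unknown compound's MS/MS fragmentation spectrum against a
library of reference spectra is the core step of compound identification in
untargeted metabolomics, and of molecular networking and analogue search.
The standard similarity is the cosine between matched peak-weight vectors —
but because measured fragment m/z values carry error, peaks must first be
paired within an m/z tolerance, each peak used at most once. `mscosine`
implements the field's standard **greedy** solution of this assignment
problem and its **modified** variant for analogue molecules, as an exact,
match-limit-aware, block-tiled engine:

* every reference/query pair yields a triple **(score, match count,
  overflow flag)** — the overflow flag marks scores computed from a
  truncated candidate-pair list (the `match_limit` budget) and therefore
  not to be trusted;
* spectra are packed into zero-padded batches with per-spectrum metadata
  (peak counts, cosine norms, precursor m/z); the R×Q grid is tiled into
  independent B×B blocks, and results are bit-identical for every batch
  size and block order;
* the compiled kernel is templated on float64/float32, so single-precision
  behaviour (including tolerance-boundary effects) can be measured, not
  guessed;
* output is dense (three R×Q planes) or a sparse coordinate list filtered
  at a score threshold, with overflowed entries always retained for audit.

The score for accepted pair set *A*, with peak weights
*w = mz^p_mz · intensity^p_int* (defaults 0 and 1), is

    S = sum_{(i,j) in A} w_ref[i] * w_qry[j] / (||w_ref|| * ||w_qry||)

Greedy collects tolerance-feasible pairs, sorts by descending weight
product (ties pinned to ascending index order for reproducibility), and
accepts pairs whose peaks are both unused. Modified cosine adds a second
collection pass after shifting each fragment by its spectrum's precursor
m/z, which recovers fragments displaced by the precursor mass difference
between structurally related molecules.

The package also ships MGF/MSP readers and an MGF writer, a plain
brute-force reference scorer (`oracle_greedy()`), an optimal-assignment
bound for small instances (`oracle_optimal()`), a synthetic
spectral-library generator with exact planted-match truth
(`generate_library()`), a single-vs-double precision agreement experiment
(`verify_agreement()`), and a command-line interface
(`inst/cli/mscosine-cli` with `score`, `synth`, `verify` subcommands).

## Worked example

```r
library(mscosine)

# four paired reference/query spectra: 80% shared peaks, small m/z jitter
lib <- generate_library(synth_config(4, peak_count_range = c(6L, 10L),
                                     shared_fraction = 0.8, seed = 42))
m <- score_all(lib$references, lib$queries, kernel_config(batch_size = 2L))
m
#> <score_matrix> dense greedy cosine, 4 references x 4 queries
#>   score range [0.0000, 0.9991], 0.00% cells overflowed
round(m$score, 3)
#>       [,1]  [,2]  [,3]  [,4]
#> [1,] 0.895 0.000 0.000 0.000
#> [2,] 0.000 0.999 0.000 0.000
#> [3,] 0.000 0.000 0.902 0.000
#> [4,] 0.000 0.000 0.000 0.282
diag(m$matches)
#> [1] 6 6 7 6
lib$truth   # planted shared peaks that landed within tolerance
#> [1] 6 6 7 6
```

Each query matches only its paired reference (off-diagonal scores are 0
because decoy peaks are kept away from anything matchable), the diagonal
match counts recover the planted truth exactly, and diagonal scores fall
below 1 only because each query carries a few unshared decoy peaks. A
single pair gives the same triple directly:

```r
greedy_cosine(lib$references[[1]], lib$queries[[1]])
#> $score
#> [1] 0.8948837
#> $matches
#> [1] 6
#> $overflow
#> [1] FALSE
```

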