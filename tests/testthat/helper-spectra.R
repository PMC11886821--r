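# Shared fixtures, all built in code.

# A small random spectrum with reproducible peaks; m/z drawn off-grid so
# nothing lines up by accident.
random_spectrum <- function(n, seed, mz_range = c(50, 500),
                            precursor = TRUE, id = paste0("s", seed)) {
  set.seed(seed)
  mz <- sort(runif(n, mz_range[1], mz_range[2]))
  spectrum(mz, 10^runif(n, 0, 3),
           precursor_mz = if (precursor) max(mz) + 1.00728 else NULL,
           identifier = id)
}

# Deterministic handful of spectra for IO and batch tests.
toy_library <- function(n = 5, peaks = 8, seed = 100) {
  lapply(seq_len(n), function(k)
    random_spectrum(peaks, seed + k, id = sprintf("toy_%02d", k)))
}

expect_triple_equal <- function(a, b) {
  expect_identical(a$score, b$score)
  expect_identical(as.integer(a$matches), as.integer(b$matches))
  expect_identical(as.logical(a$overflow), as.logical(b$overflow))
}

# Exhaustive maximum-weight matching by recursion — only for tiny instances;
# independent check on both the greedy rule and the igraph-backed optimum.
exhaustive_optimal <- function(ref, query, cfg) {
  d <- abs(outer(ref$mz, query$mz, "-")) <= cfg$tolerance
  rw <- ref$mz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- query$mz^cfg$mz_power * query$intensity^cfg$intensity_power
  best <- 0
  recurse <- function(i, used_q, acc) {
    if (acc > best) best <<- acc
    if (i > length(ref$mz)) return()
    recurse(i + 1L, used_q, acc)  # leave ref peak i unmatched
    for (j in which(d[i, ])) {
      if (!used_q[j]) {
        used_q[j] <- TRUE
        recurse(i + 1L, used_q, acc + rw[i] * qw[j])
        used_q[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(query$mz)), 0)
  best / (spectrum_norm(ref, cfg) * spectrum_norm(query, cfg))
}
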