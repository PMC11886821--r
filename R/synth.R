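#' Configuration for the synthetic spectral-library generator
#'
#' The generator emulates, at desk scale, the structure that makes spectral
#' library matching non-trivial: variable peak counts, a controlled fraction
#' of query peaks shared with a paired reference, sub-tolerance m/z jitter
#' on the shared peaks, and an optional precursor-mass offset that turns
#' each pair into an analogue pair (all shared fragments displaced by the
#' precursor difference, recoverable by modified cosine only).
#'
#' m/z values are built on an integer grid (`mz_grid` spacing) before jitter
#' is applied, so that libraries are bit-identical across platforms under a
#' fixed seed and the planted-match truth is computable exactly from the
#' jitter draws. Jitter is uniform on `[-jitter_sd, +jitter_sd]`, which
#' makes "within tolerance" decidable from the draw itself. Intensities are
#' log-uniform over `intensity_shape` decades, reproducing the
#' few-dominant-peaks character of real fragmentation spectra.
#'
#' @param n_spectra number of reference/query pairs to generate.
#' @param peak_count_range integer `(min, max)` peaks per spectrum.
#' @param mz_range `(min, max)` fragment m/z window (Th).
#' @param shared_fraction fraction of each query's peaks copied from its
#'   paired reference (in `[0, 1]`).
#' @param jitter_sd half-width (Th) of the uniform m/z perturbation applied
#'   to shared peaks.
#' @param precursor_offset precursor mass difference (Th) injected between
#'   paired spectra; shared fragments are displaced by the same offset.
#' @param intensity_shape decades spanned by the log-uniform intensity
#'   distribution.
#' @param tolerance m/z tolerance (Th) used for the planted-match truth
#'   accounting and for the strict decoy-placement rule.
#' @param mz_grid grid spacing (Th) of the pre-jitter m/z construction.
#' @param strict_truth if TRUE, decoy (non-shared) peaks are rejection
#'   sampled to stay at least `2 * tolerance` away from every peak that
#'   could legitimately match, so kernel match counts on diagonal pairs
#'   equal the planted counts exactly. Requires
#'   `mz_grid >= 2 * (tolerance + jitter_sd)`.
#' @param seed RNG seed; a fixed seed gives a bit-identical library.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_spectra, peak_count_range = c(5L, 60L),
                         mz_range = c(50, 1000), shared_fraction = 0.8,
                         jitter_sd = 0.01, precursor_offset = 0,
                         intensity_shape = 3, tolerance = 0.1,
                         mz_grid = 1, strict_truth = TRUE, seed = 1L) {
  n_spectra <- as.integer(n_spectra)
  if (is.na(n_spectra) || n_spectra < 1L)
    stop("n_spectra must be a positive integer", call. = FALSE)
  peak_count_range <- as.integer(peak_count_range)
  if (length(peak_count_range) != 2L || any(peak_count_range < 1L) ||
      peak_count_range[1] > peak_count_range[2])
    stop("peak_count_range must be an increasing pair of positive integers",
         call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  if (jitter_sd < 0) stop("jitter_sd must be >= 0", call. = FALSE)
  if (strict_truth && mz_grid < 2 * (tolerance + jitter_sd))
    stop("strict_truth requires mz_grid >= 2 * (tolerance + jitter_sd); ",
         "use strict_truth = FALSE for dense-overlap libraries",
         call. = FALSE)
  n_grid <- floor(mz_range[2] / mz_grid) - ceiling(mz_range[1] / mz_grid) + 1
  if (n_grid < peak_count_range[2])
    stop("mz_range/mz_grid admits fewer grid points than max peak count",
         call. = FALSE)
  structure(list(n_spectra = n_spectra,
                 peak_count_range = peak_count_range,
                 mz_range = as.double(mz_range),
                 shared_fraction = shared_fraction,
                 jitter_sd = jitter_sd,
                 precursor_offset = as.double(precursor_offset),
                 intensity_shape = as.double(intensity_shape),
                 tolerance = as.double(tolerance),
                 mz_grid = as.double(mz_grid),
                 strict_truth = isTRUE(strict_truth),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Sample `n` distinct grid points (values, ascending) subject to the strict
# constraints: pairwise unshifted separation is guaranteed by the grid
# spacing (distinct points differ by >= mz_grid); with a nonzero precursor
# offset, additionally forbid point pairs whose separation is within
# 2*(tol + jitter) of |offset| (those would create spurious unshifted
# matches between a reference and its offset analogue). `forbid_near` lists
# existing peak positions new points must stay clear of (decoy placement).
sample_grid_mz <- function(n, sc, forbid_near = numeric(0)) {
  lo <- ceiling(sc$mz_range[1] / sc$mz_grid)
  hi <- floor(sc$mz_range[2] / sc$mz_grid)
  guard <- 2 * sc$tolerance + 2 * sc$jitter_sd
  need_offset_check <- sc$strict_truth && sc$precursor_offset != 0 &&
    sc$shared_fraction > 0
  if (!need_offset_check && !length(forbid_near))
    return(sort(sample(seq.int(lo, hi), n) * sc$mz_grid))
  pool <- seq.int(lo, hi) * sc$mz_grid
  if (length(forbid_near)) {
    ok <- vapply(pool, function(v) min(abs(forbid_near - v)) >= guard,
                 logical(1))
    pool <- pool[ok]
  }
  if (!need_offset_check) {
    if (length(pool) < n)
      stop("rejection sampling failed; loosen the synthetic configuration",
           call. = FALSE)
    return(sort(sample(pool, n)))
  }
  pts <- numeric(0)
  tries <- 0L
  while (length(pts) < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("rejection sampling failed; loosen the synthetic configuration",
           call. = FALSE)
    for (v in sample(pool, min(n, length(pool)))) {
      if (length(pts) >= n) break
      if (length(pts) && min(abs(pts - v)) < sc$mz_grid / 2) next
      if (length(pts) &&
          any(abs(abs(pts - v) - abs(sc$precursor_offset)) < guard)) next
      pts <- c(pts, v)
    }
  }
  sort(pts)
}

rand_intensity <- function(n, sc) 10^stats::runif(n, 0, sc$intensity_shape)

#' Generate a paired synthetic spectral library
#'
#' Produces `n_spectra` reference/query pairs under a [synth_config()].
#' Query k copies a `shared_fraction` of its peaks from reference k
#' (intensities included), displaces them by `precursor_offset` plus a
#' uniform jitter, and fills the remainder with decoy peaks; its precursor
#' m/z is the reference's plus `precursor_offset`. With
#' `shared_fraction = 1` the query is an exact analogue copy (same peak
#' count, every peak planted), so that offset-free, jitter-free settings
#' give diagonal scores of exactly 1. The returned `truth` vector holds,
#' per pair, the number of planted shared peaks whose jitter landed within
#' the configured tolerance — a lower bound on (and, under
#' `strict_truth`, exactly) the kernel's diagonal match count.
#'
#' @param sc a [synth_config()].
#' @return A list with `references` and `queries` (lists of
#'   [spectrum()] objects) and `truth` (integer vector).
#' @export
generate_library <- function(sc) {
  stopifnot(inherits(sc, "synth_config"))
  set.seed(sc$seed)
  refs <- vector("list", sc$n_spectra)
  qrys <- vector("list", sc$n_spectra)
  truth <- integer(sc$n_spectra)
  pr <- sc$peak_count_range
  for (k in seq_len(sc$n_spectra)) {
    n_r <- if (pr[1] == pr[2]) pr[1] else sample(pr[1]:pr[2], 1L)
    # shared_fraction 1 means the query IS an analogue copy of the
    # reference (same peak count, every peak planted); otherwise the query
    # count is drawn independently
    n_q <- if (sc$shared_fraction == 1) n_r
           else if (pr[1] == pr[2]) pr[1] else sample(pr[1]:pr[2], 1L)
    rmz <- sample_grid_mz(n_r, sc)
    rint <- rand_intensity(n_r, sc)
    rprec <- max(rmz) + 1.00728  # protonated-molecule style precursor
    n_shared <- min(round(sc$shared_fraction * n_q), n_r)
    sel <- if (n_shared > 0) sort(sample.int(n_r, n_shared)) else integer(0)
    jitter <- stats::runif(n_shared, -sc$jitter_sd, sc$jitter_sd)
    planted_mz <- rmz[sel] + sc$precursor_offset + jitter
    planted_int <- rint[sel]
    n_decoy <- n_q - n_shared
    if (n_decoy > 0) {
      forbid <- if (sc$strict_truth)
        c(rmz, rmz + sc$precursor_offset) else numeric(0)
      dmz <- sample_grid_mz(n_decoy, sc, forbid_near = forbid)
      dint <- rand_intensity(n_decoy, sc)
    } else {
      dmz <- numeric(0)
      dint <- numeric(0)
    }
    qmz <- c(planted_mz, dmz)
    qint <- c(planted_int, dint)
    o <- order(qmz)
    refs[[k]] <- new_spectrum(rmz, rint, rprec,
                              sprintf("ref_%05d", k))
    qrys[[k]] <- new_spectrum(qmz[o], qint[o], rprec + sc$precursor_offset,
                              sprintf("query_%05d", k))
    truth[k] <- sum(abs(jitter) <= sc$tolerance)
  }
  list(references = refs, queries = qrys, truth = truth)
}
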