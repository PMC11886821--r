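#' Construct an MS/MS spectrum
#'
#' A spectrum is a set of fragment peaks (m/z in Thomson plus a non-negative
#' intensity each), optionally carrying the precursor ion m/z and free-form
#' metadata. On construction peaks are sorted by ascending m/z, zero-intensity
#' peaks are dropped (they cannot contribute to any cosine score and would
#' waste match-limit slots), and peaks with identical m/z are merged by
#' summing their intensities so the m/z grid is strictly ascending.
#'
#' @param mz numeric vector of fragment m/z values (Th).
#' @param intensity numeric vector of non-negative intensities, same length
#'   as `mz`.
#' @param precursor_mz optional positive scalar, the precursor ion m/z (Th).
#'   Required for modified-cosine scoring.
#' @param identifier opaque identifier string (e.g. an MGF TITLE).
#' @param metadata named list of additional key/value metadata.
#' @return An object of class `ms_spectrum`: a list with elements `mz`,
#'   `intensity`, `precursor_mz`, `identifier`, `metadata`.
#' @examples
#' s <- spectrum(c(100, 50, 100), c(1, 2, 3), precursor_mz = 305.1)
#' s$mz        # 50, 100 (duplicates merged)
#' s$intensity # 2, 4
#' @export
spectrum <- function(mz, intensity, precursor_mz = NULL, identifier = "",
                     metadata = list()) {
  mz <- as.double(mz)
  intensity <- as.double(intensity)
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (any(!is.finite(mz)) || any(!is.finite(intensity)))
    stop("mz and intensity must be finite", call. = FALSE)
  if (any(intensity < 0))
    stop("intensities must be non-negative", call. = FALSE)
  keep <- intensity > 0
  mz <- mz[keep]
  intensity <- intensity[keep]
  if (length(mz)) {
    o <- order(mz)
    mz <- mz[o]
    intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      grp <- cumsum(!duplicated(mz))
      intensity <- as.double(rowsum(intensity, grp))
      mz <- mz[!duplicated(mz)]
    }
  }
  if (!is.null(precursor_mz)) {
    precursor_mz <- as.double(precursor_mz)
    if (length(precursor_mz) != 1L || !is.finite(precursor_mz) ||
        precursor_mz <= 0)
      stop("precursor_mz must be a single positive number", call. = FALSE)
  }
  new_spectrum(mz, intensity, precursor_mz, as.character(identifier), metadata)
}

# Fast internal constructor: assumes mz strictly ascending, intensities > 0.
# Used by the synthetic generator where invariants hold by construction.
new_spectrum <- function(mz, intensity, precursor_mz = NULL, identifier = "",
                         metadata = list()) {
  structure(
    list(mz = mz, intensity = intensity, precursor_mz = precursor_mz,
         identifier = identifier, metadata = metadata),
    class = "ms_spectrum"
  )
}

#' Number of peaks in a spectrum
#' @param s an `ms_spectrum`.
#' @return integer peak count.
#' @export
n_peaks <- function(s) length(s$mz)

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s: %d peaks",
              if (nzchar(x$identifier)) x$identifier else "(unnamed)",
              length(x$mz)))
  if (!is.null(x$precursor_mz))
    cat(sprintf(", precursor m/z %.4f", x$precursor_mz))
  if (length(x$mz))
    cat(sprintf(", m/z range [%.4f, %.4f]", min(x$mz), max(x$mz)))
  cat("\n")
  invisible(x)
}

#' Kernel configuration
#'
#' Bundles every tunable of the scoring kernel. Defaults follow the greedy
#' cosine conventions of the wider MS/MS matching ecosystem: a 0.1 Th
#' fragment tolerance, intensity-only peak weighting, and generous match and
#' peak caps.
#'
#' @param tolerance maximum |Delta m/z| (Th) for two fragments to be
#'   considered the same ion; the comparison is inclusive (`<=`).
#' @param mz_power exponent applied to m/z in the peak weight
#'   `mz^mz_power * intensity^intensity_power`.
#' @param intensity_power exponent applied to intensity in the peak weight.
#' @param match_limit maximum number of candidate peak pairs collected per
#'   comparison pass; exceeding it raises the overflow flag and truncates
#'   collection. Modified cosine runs two passes of this size.
#' @param max_peaks per-spectrum peak cap applied before batching; spectra
#'   with more peaks keep their `max_peaks` most intense ones.
#' @param precision `"double"` or `"single"`; the kernel performs all m/z
#'   comparisons and score arithmetic in this precision.
#' @param batch_size number of spectra packed per batch (the block edge B of
#'   the tiled score matrix).
#' @param sparse_threshold score cutoff in `[0, 1)` below which entries are
#'   dropped from sparse output.
#' @return An object of class `kernel_config`.
#' @export
kernel_config <- function(tolerance = 0.1, mz_power = 0,
                          intensity_power = 1, match_limit = 1024L,
                          max_peaks = 1024L, precision = c("double", "single"),
                          batch_size = 512L, sparse_threshold = 0) {
  precision <- match.arg(precision)
  tolerance <- as.double(tolerance)
  if (length(tolerance) != 1L || !is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be a single positive number", call. = FALSE)
  match_limit <- as.integer(match_limit)
  if (is.na(match_limit) || match_limit < 1L)
    stop("match_limit must be a positive integer", call. = FALSE)
  max_peaks <- as.integer(max_peaks)
  if (is.na(max_peaks) || max_peaks < 1L)
    stop("max_peaks must be a positive integer", call. = FALSE)
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L)
    stop("batch_size must be a positive integer", call. = FALSE)
  sparse_threshold <- as.double(sparse_threshold)
  if (length(sparse_threshold) != 1L || is.na(sparse_threshold) ||
      sparse_threshold < 0 || sparse_threshold >= 1)
    stop("sparse_threshold must lie in [0, 1)", call. = FALSE)
  structure(
    list(tolerance = tolerance, mz_power = as.double(mz_power),
         intensity_power = as.double(intensity_power),
         match_limit = match_limit, max_peaks = max_peaks,
         precision = precision, batch_size = batch_size,
         sparse_threshold = sparse_threshold),
    class = "kernel_config"
  )
}

#' @export
print.kernel_config <- function(x, ...) {
  cat("<kernel_config>\n")
  cat(sprintf("  tolerance       %g Th\n", x$tolerance))
  cat(sprintf("  weighting       mz^%g * intensity^%g\n", x$mz_power,
              x$intensity_power))
  cat(sprintf("  match_limit     %d\n", x$match_limit))
  cat(sprintf("  max_peaks       %d\n", x$max_peaks))
  cat(sprintf("  precision       %s\n", x$precision))
  cat(sprintf("  batch_size      %d\n", x$batch_size))
  cat(sprintf("  sparse_threshold %g\n", x$sparse_threshold))
  invisible(x)
}

#' Keep only the most intense peaks of a spectrum
#'
#' If the spectrum has more than `max_peaks` peaks, the `max_peaks` most
#' intense ones are retained (intensity ties broken in favour of lower m/z)
#' and the result is re-sorted by ascending m/z. Shorter spectra are returned
#' unchanged.
#'
#' @param s an `ms_spectrum`.
#' @param max_peaks positive integer peak cap.
#' @return An `ms_spectrum` with at most `max_peaks` peaks.
#' @export
truncate_peaks <- function(s, max_peaks) {
  max_peaks <- as.integer(max_peaks)
  if (is.na(max_peaks) || max_peaks < 1L)
    stop("max_peaks must be a positive integer", call. = FALSE)
  n <- length(s$mz)
  if (n <= max_peaks) return(s)
  keep <- order(-s$intensity, s$mz)[seq_len(max_peaks)]
  keep <- sort(keep)  # restore ascending m/z order
  new_spectrum(s$mz[keep], s$intensity[keep], s$precursor_mz, s$identifier,
               s$metadata)
}

#' Peak weights under the configured exponents
#'
#' The weight of peak i is `mz_i^mz_power * intensity_i^intensity_power`.
#' With the default exponents (0, 1) weights are the raw intensities.
#'
#' @param s an `ms_spectrum`.
#' @param mz_power,intensity_power weighting exponents.
#' @return A data.frame with columns `mz` and `weight`.
#' @export
weighted_peaks <- function(s, mz_power = 0, intensity_power = 1) {
  data.frame(mz = s$mz,
             weight = s$mz^mz_power * s$intensity^intensity_power)
}

#' Cosine norm of a spectrum
#'
#' Euclidean norm of the weight vector under `cfg`'s exponents:
#' `sqrt(sum(weight^2))`. This is the per-spectrum normalising factor carried
#' in batch metadata; the kernel divides the accumulated products by the
#' product of the two norms.
#'
#' @param s an `ms_spectrum`.
#' @param cfg a [kernel_config()].
#' @return A non-negative scalar.
#' @export
spectrum_norm <- function(s, cfg = kernel_config()) {
  w <- s$mz^cfg$mz_power * s$intensity^cfg$intensity_power
  sqrt(sum(w * w))
}
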