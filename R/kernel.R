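#' Collect candidate peak pairs within tolerance
#'
#' Enumerates all peak index pairs (i, j) with
#' `|ref_mz[i] - (query_mz[j] + shift)| <= tolerance`, in reference-major
#' order (i ascending, then j ascending), stopping once `cfg$match_limit`
#' pairs have been collected. Encountering one more feasible pair past the
#' limit raises the overflow flag and ends the pass early, mirroring the
#' fixed-size pair buffer of the batched kernel.
#'
#' @param ref,query `ms_spectrum` objects.
#' @param cfg a [kernel_config()]; supplies tolerance, weighting exponents,
#'   match limit and working precision.
#' @param shift m/z shift (Th) added to query peaks before comparison, or
#'   `"precursor"` to use `ref$precursor_mz - query$precursor_mz` (the
#'   modified-cosine shifted pass). Default 0 (unshifted pass).
#' @return A data.frame with columns `ref_index`, `query_index`, `product`
#'   (weight product of the paired peaks) and attribute `overflow` (logical).
#' @export
collect_pairs <- function(ref, query, cfg = kernel_config(), shift = 0) {
  if (identical(shift, "precursor")) {
    for (nm in c("ref", "query")) {
      s <- if (nm == "ref") ref else query
      if (is.null(s$precursor_mz))
        stop(sprintf("precursor shift requested but the %s spectrum '%s' has no precursor_mz",
                     nm, s$identifier), call. = FALSE)
    }
    shift <- ref$precursor_mz - query$precursor_mz
  }
  rw <- ref$mz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- query$mz^cfg$mz_power * query$intensity^cfg$intensity_power
  res <- cpp_collect_pairs(ref$mz, rw, query$mz, qw, cfg$tolerance,
                           cfg$match_limit, as.double(shift),
                           cfg$precision == "single")
  out <- data.frame(ref_index = res$ref_index,
                    query_index = res$query_index,
                    product = res$product)
  attr(out, "overflow") <- res$overflow
  out
}

#' Greedy reduction of candidate pairs
#'
#' Sorts candidate pairs by descending weight product (ties broken by
#' ascending `(ref_index, query_index)` — a fixed, hardware-independent
#' order) and accepts each pair whose two peaks are both still unused.
#' Accepted products are accumulated into the unnormalised score; each
#' accepted pair marks both of its peaks as used.
#'
#' @param pairs data.frame as returned by [collect_pairs()].
#' @param ref_len,query_len peak counts of the two spectra.
#' @param cfg a [kernel_config()] (only `precision` is used).
#' @return A list with `score` (unnormalised, i.e. the sum of accepted
#'   products) and `matches` (number of accepted pairs).
#' @export
greedy_reduce <- function(pairs, ref_len, query_len, cfg = kernel_config()) {
  cpp_greedy_reduce(as.integer(pairs$ref_index),
                    as.integer(pairs$query_index),
                    as.double(pairs$product),
                    as.integer(ref_len), as.integer(query_len),
                    cfg$precision == "single")
}

score_triple <- function(score, matches, overflow) {
  list(score = score, matches = matches, overflow = overflow)
}

#' Greedy cosine similarity between two spectra
#'
#' The greedy approximation to the peak-assignment cosine: candidate pairs
#' within the m/z tolerance are collected (up to the match limit), sorted by
#' descending weight product, and greedily accepted so that each peak is used
#' at most once. The accumulated product sum is divided by the product of the
#' two spectrum norms.
#'
#' A spectrum with zero norm (no positive-weight peaks) scores 0 with no
#' error, so batch runs never abort on a degenerate record.
#'
#' @param ref,query `ms_spectrum` objects.
#' @param cfg a [kernel_config()].
#' @return A list with elements `score` (in `[0, 1]` up to floating
#'   rounding), `matches` (accepted pair count) and `overflow` (TRUE when
#'   pair collection was truncated at the match limit).
#' @examples
#' a <- spectrum(c(100, 150, 200), c(0.7, 0.2, 0.1))
#' greedy_cosine(a, a)$score  # 1
#' @export
greedy_cosine <- function(ref, query, cfg = kernel_config()) {
  rw <- ref$mz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- query$mz^cfg$mz_power * query$intensity^cfg$intensity_power
  res <- cpp_score_pair(ref$mz, rw, spectrum_norm(ref, cfg),
                        query$mz, qw, spectrum_norm(query, cfg),
                        cfg$tolerance, cfg$match_limit, FALSE, 0, 0,
                        cfg$precision == "single")
  score_triple(res$score, res$matches, res$overflow)
}

#' Modified cosine similarity between two spectra
#'
#' Extends [greedy_cosine()] with a second pair-collection pass run after
#' shifting every fragment by its spectrum's precursor m/z: peaks match in
#' the shifted pass when
#' `|(ref_mz - ref_precursor) - (query_mz - query_precursor)| <= tolerance`.
#' This recovers fragment matches between analogue molecules whose spectra
#' are offset by the precursor mass difference. Each pass may collect up to
#' `cfg$match_limit` pairs (2x the greedy budget in total); a pair found by
#' both passes is kept once, with the unshifted copy winning. The union is
#' reduced and normalised exactly as in [greedy_cosine()]; overflow is
#' reported when either pass overflowed.
#'
#' @param ref,query `ms_spectrum` objects; both must carry `precursor_mz`.
#' @param cfg a [kernel_config()].
#' @return A list with `score`, `matches`, `overflow` as in
#'   [greedy_cosine()].
#' @export
modified_cosine <- function(ref, query, cfg = kernel_config()) {
  if (is.null(ref$precursor_mz))
    stop(sprintf("modified cosine requires a precursor m/z: reference '%s' has none",
                 ref$identifier), call. = FALSE)
  if (is.null(query$precursor_mz))
    stop(sprintf("modified cosine requires a precursor m/z: query '%s' has none",
                 query$identifier), call. = FALSE)
  rw <- ref$mz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- query$mz^cfg$mz_power * query$intensity^cfg$intensity_power
  res <- cpp_score_pair(ref$mz, rw, spectrum_norm(ref, cfg),
                        query$mz, qw, spectrum_norm(query, cfg),
                        cfg$tolerance, cfg$match_limit, TRUE,
                        ref$precursor_mz, query$precursor_mz,
                        cfg$precision == "single")
  score_triple(res$score, res$matches, res$overflow)
}
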