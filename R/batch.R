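#' Pack spectra into padded batches
#'
#' Groups consecutive spectra into batches of `cfg$batch_size`. Within a
#' batch, spectra are truncated to `cfg$max_peaks` most intense peaks,
#' weighted under `cfg`'s exponents, and laid out as two `M x B` matrices
#' (m/z and weight; one column per spectrum slot) where `M` is the longest
#' true peak count in the batch. Entries past each spectrum's length are
#' exactly zero. The final batch is padded with empty slots up to `B`;
#' padding slots have length 0 and are excluded from scoring.
#'
#' Per-slot metadata travels with the batch: true peak counts, cosine norms
#' (see [spectrum_norm()]) and, when `with_precursor = TRUE`, precursor m/z
#' values.
#'
#' @param spectra list of `ms_spectrum` objects.
#' @param cfg a [kernel_config()].
#' @param with_precursor if TRUE, record precursor m/z per slot (required
#'   for modified-cosine scoring); an error names the first spectrum lacking
#'   one.
#' @return A list of `spectrum_batch` objects.
#' @export
pack_batches <- function(spectra, cfg = kernel_config(),
                         with_precursor = FALSE) {
  if (!length(spectra)) stop("no spectra to pack", call. = FALSE)
  B <- cfg$batch_size
  n <- length(spectra)
  n_batches <- ceiling(n / B)
  out <- vector("list", n_batches)
  for (b in seq_len(n_batches)) {
    lo <- (b - 1L) * B + 1L
    hi <- min(b * B, n)
    sl <- lapply(spectra[lo:hi], truncate_peaks, max_peaks = cfg$max_peaks)
    n_real <- length(sl)
    lens <- vapply(sl, n_peaks, integer(1))
    M <- max(1L, lens)
    mz <- matrix(0, nrow = M, ncol = B)
    wt <- matrix(0, nrow = M, ncol = B)
    norms <- numeric(B)
    precs <- numeric(B)
    ids <- character(B)
    for (k in seq_len(n_real)) {
      s <- sl[[k]]
      if (lens[k] > 0L) {
        mz[seq_len(lens[k]), k] <- s$mz
        wt[seq_len(lens[k]), k] <-
          s$mz^cfg$mz_power * s$intensity^cfg$intensity_power
      }
      norms[k] <- spectrum_norm(s, cfg)
      ids[k] <- s$identifier
      if (with_precursor) {
        if (is.null(s$precursor_mz))
          stop(sprintf("spectrum '%s' (slot %d) has no precursor_mz but modified cosine was requested",
                       s$identifier, lo + k - 1L), call. = FALSE)
        precs[k] <- s$precursor_mz
      }
    }
    out[[b]] <- structure(
      list(mz = mz, weight = wt,
           lengths = c(lens, integer(B - n_real)),
           norms = norms,
           precursors = if (with_precursor) precs else NULL,
           ids = ids, n_real = n_real, batch_size = B, pad_width = M,
           packed_with = cfg[c("tolerance", "mz_power", "intensity_power",
                               "match_limit", "max_peaks", "precision")]),
      class = "spectrum_batch")
  }
  out
}

#' @export
print.spectrum_batch <- function(x, ...) {
  cat(sprintf("<spectrum_batch> %d/%d slots filled, pad width %d\n",
              x$n_real, x$batch_size, x$pad_width))
  invisible(x)
}

#' Unpack a batch back into spectra-like peak lists
#'
#' Inverse of the packing layout: recovers each real slot's (mz, weight)
#' sequence, dropping the zero padding.
#'
#' @param batch a `spectrum_batch`.
#' @return A list with one `data.frame(mz, weight)` per real slot.
#' @export
unpack_batch <- function(batch) {
  lapply(seq_len(batch$n_real), function(k) {
    len <- batch$lengths[k]
    data.frame(mz = batch$mz[seq_len(len), k],
               weight = batch$weight[seq_len(len), k])
  })
}

check_cfg_match <- function(batch, cfg) {
  want <- cfg[c("tolerance", "mz_power", "intensity_power", "match_limit",
                "max_peaks", "precision")]
  if (!identical(batch$packed_with, want))
    stop("batch was packed with a different kernel configuration",
         call. = FALSE)
}

#' Score one block of the similarity matrix
#'
#' Computes the full `B x B` block of (score, matches, overflow) triples
#' between a reference batch and a query batch. Cell (i, j) equals the
#' unbatched pair kernel applied to reference i and query j; every cell is
#' independent of every other, so cells may be computed in any order (the
#' contract that makes the block embarrassingly parallel). Cells touching a
#' padding slot carry (0, 0, FALSE) and are flagged invalid.
#'
#' @param ref_batch,query_batch `spectrum_batch` objects packed with `cfg`.
#' @param cfg the same [kernel_config()] used for packing.
#' @param kind `"greedy"` or `"modified"`.
#' @return A list with matrices `score`, `matches`, `overflow` (all
#'   `B x B`, rows = reference slots) and logical vectors `valid_ref`,
#'   `valid_query` marking real (non-padding) slots.
#' @export
score_block <- function(ref_batch, query_batch, cfg = kernel_config(),
                        kind = c("greedy", "modified")) {
  kind <- match.arg(kind)
  check_cfg_match(ref_batch, cfg)
  check_cfg_match(query_batch, cfg)
  modified <- kind == "modified"
  if (modified &&
      (is.null(ref_batch$precursors) || is.null(query_batch$precursors)))
    stop("modified cosine requires batches packed with with_precursor = TRUE",
         call. = FALSE)
  res <- cpp_score_block(
    ref_batch$mz, ref_batch$weight, ref_batch$lengths, ref_batch$norms,
    if (modified) ref_batch$precursors else numeric(0),
    query_batch$mz, query_batch$weight, query_batch$lengths,
    query_batch$norms,
    if (modified) query_batch$precursors else numeric(0),
    cfg$tolerance, cfg$match_limit, modified, cfg$precision == "single")
  list(score = res$score, matches = res$matches, overflow = res$overflow,
       valid_ref = seq_len(ref_batch$batch_size) <= ref_batch$n_real,
       valid_query = seq_len(query_batch$batch_size) <= query_batch$n_real)
}

#' Score every reference against every query
#'
#' Tiles the `R x Q` similarity grid into `ceil(R/B) x ceil(Q/B)`
#' non-overlapping blocks, scores each block with [score_block()], and
#' assembles the results. Block traversal order does not affect the result,
#' and neither does the batch size `B` (bit-identical output for any
#' `B >= 1` at a fixed precision).
#'
#' Dense output stores three `R x Q` planes (score, matches, overflow).
#' Sparse output keeps a coordinate list of entries with
#' `score >= cfg$sparse_threshold`; entries whose overflow flag is set are
#' retained regardless of score so that truncated (hence untrustworthy)
#' comparisons remain auditable.
#'
#' @param references,queries non-empty lists of `ms_spectrum` objects.
#' @param cfg a [kernel_config()].
#' @param kind `"greedy"` or `"modified"`.
#' @param output `"dense"` or `"sparse"`.
#' @param max_dense_cells refuse dense output beyond this many cells
#'   (default 1e8); use sparse output for larger problems.
#' @return A `score_matrix` object; see Details.
#' @details A dense `score_matrix` has elements `score`, `matches`,
#'   `overflow` (R x Q matrices). A sparse one has `entries`, a data.frame
#'   with columns `ref`, `query` (1-based indices), `ref_id`, `query_id`,
#'   `score`, `matches`, `overflow`, plus the `threshold` used. Both carry
#'   `shape`, `ref_ids`, `query_ids`, `kind`, `storage`.
#' @examples
#' lib <- lapply(1:3, function(k)
#'   spectrum(c(100, 200) + k, c(1, 2), identifier = paste0("s", k)))
#' m <- score_all(lib, lib, kernel_config(batch_size = 2L))
#' diag(m$score)  # all 1: each spectrum against itself
#' @export
score_all <- function(references, queries, cfg = kernel_config(),
                      kind = c("greedy", "modified"),
                      output = c("dense", "sparse"),
                      max_dense_cells = 1e8) {
  kind <- match.arg(kind)
  output <- match.arg(output)
  if (!length(references)) stop("no reference spectra", call. = FALSE)
  if (!length(queries)) stop("no query spectra", call. = FALSE)
  R <- length(references)
  Q <- length(queries)
  if (output == "dense" && as.double(R) * Q > max_dense_cells)
    stop(sprintf("dense output of %d x %d = %.3g cells exceeds max_dense_cells = %.3g; use output = \"sparse\"",
                 R, Q, as.double(R) * Q, max_dense_cells), call. = FALSE)
  with_prec <- kind == "modified"
  rb <- pack_batches(references, cfg, with_precursor = with_prec)
  qb <- pack_batches(queries, cfg, with_precursor = with_prec)
  ref_ids <- vapply(references, function(s) s$identifier, character(1))
  query_ids <- vapply(queries, function(s) s$identifier, character(1))
  B <- cfg$batch_size

  if (output == "dense") {
    score <- matrix(0, R, Q)
    matches <- matrix(0L, R, Q)
    overflow <- matrix(FALSE, R, Q)
    for (i in seq_along(rb)) {
      ri <- seq_len(rb[[i]]$n_real) + (i - 1L) * B
      for (j in seq_along(qb)) {
        qi <- seq_len(qb[[j]]$n_real) + (j - 1L) * B
        blk <- score_block(rb[[i]], qb[[j]], cfg, kind)
        score[ri, qi] <- blk$score[blk$valid_ref, blk$valid_query]
        matches[ri, qi] <- blk$matches[blk$valid_ref, blk$valid_query]
        overflow[ri, qi] <- blk$overflow[blk$valid_ref, blk$valid_query]
      }
    }
    structure(list(storage = "dense", kind = kind, shape = c(R, Q),
                   ref_ids = ref_ids, query_ids = query_ids,
                   score = score, matches = matches, overflow = overflow,
                   cfg = cfg),
              class = "score_matrix")
  } else {
    thr <- cfg$sparse_threshold
    parts <- list()
    for (i in seq_along(rb)) {
      for (j in seq_along(qb)) {
        blk <- score_block(rb[[i]], qb[[j]], cfg, kind)
        nr <- rb[[i]]$n_real
        nq <- qb[[j]]$n_real
        sc <- blk$score[seq_len(nr), seq_len(nq), drop = FALSE]
        mt <- blk$matches[seq_len(nr), seq_len(nq), drop = FALSE]
        ov <- blk$overflow[seq_len(nr), seq_len(nq), drop = FALSE]
        keep <- which(sc >= thr | ov)
        if (!length(keep)) next
        r_loc <- (keep - 1L) %% nr + 1L
        q_loc <- (keep - 1L) %/% nr + 1L
        parts[[length(parts) + 1L]] <- data.frame(
          ref = r_loc + (i - 1L) * B,
          query = q_loc + (j - 1L) * B,
          score = sc[keep], matches = mt[keep], overflow = ov[keep])
      }
    }
    entries <- if (length(parts)) do.call(rbind, parts) else
      data.frame(ref = integer(), query = integer(), score = numeric(),
                 matches = integer(), overflow = logical())
    entries <- entries[order(entries$ref, entries$query), , drop = FALSE]
    rownames(entries) <- NULL
    entries$ref_id <- ref_ids[entries$ref]
    entries$query_id <- query_ids[entries$query]
    entries <- entries[, c("ref", "query", "ref_id", "query_id", "score",
                           "matches", "overflow")]
    structure(list(storage = "sparse", kind = kind, shape = c(R, Q),
                   ref_ids = ref_ids, query_ids = query_ids,
                   entries = entries, threshold = thr, cfg = cfg),
              class = "score_matrix")
  }
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s %s cosine, %d references x %d queries\n",
              x$storage, x$kind, x$shape[1], x$shape[2]))
  if (x$storage == "sparse") {
    cat(sprintf("  %d entries retained at threshold %g\n",
                nrow(x$entries), x$threshold))
  } else {
    cat(sprintf("  score range [%.4f, %.4f], %.2f%% cells overflowed\n",
                min(x$score), max(x$score), 100 * mean(x$overflow)))
  }
  invisible(x)
}

#' Flatten a score matrix to a data.frame of triples
#'
#' Dense matrices expand to all `R x Q` cells; sparse ones return the
#' retained entries. Rows are in reference-major order (all queries for
#' reference 1, then reference 2, ...).
#'
#' @param x a `score_matrix`.
#' @param ... unused.
#' @return data.frame with columns `ref`, `query`, `ref_id`, `query_id`,
#'   `score`, `matches`, `overflow`.
#' @export
as.data.frame.score_matrix <- function(x, ...) {
  if (x$storage == "sparse") return(x$entries)
  R <- x$shape[1]
  Q <- x$shape[2]
  ref <- rep(seq_len(R), each = Q)
  query <- rep(seq_len(Q), times = R)
  data.frame(ref = ref, query = query,
             ref_id = x$ref_ids[ref], query_id = x$query_ids[query],
             score = x$score[cbind(ref, query)],
             matches = x$matches[cbind(ref, query)],
             overflow = x$overflow[cbind(ref, query)])
}
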