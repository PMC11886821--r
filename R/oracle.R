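#' Brute-force reference scorer (greedy rule, unbatched)
#'
#' A deliberately plain re-implementation of the greedy / modified cosine
#' used as the independent reference in tests: full pair enumeration with
#' base-R vector operations, no batching, no compiled code, and no match
#' limit unless one is explicitly requested. When `apply_limit = TRUE` and
#' `cfg$match_limit` is at least the feasible pair count, the oracle and the
#' compiled kernel follow the identical sort-and-deduplicate rule and agree
#' bitwise at double precision.
#'
#' @param ref,query `ms_spectrum` objects.
#' @param cfg a [kernel_config()]; the oracle always computes in double
#'   precision regardless of `cfg$precision`.
#' @param shift_kind `"none"` for greedy cosine, `"precursor"` for modified
#'   cosine (adds the precursor-shifted collection pass).
#' @param apply_limit if TRUE, truncate each collection pass at
#'   `cfg$match_limit` pairs and report overflow, as the kernel does.
#' @return A list with `score`, `matches`, `overflow`.
#' @export
oracle_greedy <- function(ref, query, cfg = kernel_config(),
                          shift_kind = c("none", "precursor"),
                          apply_limit = FALSE) {
  shift_kind <- match.arg(shift_kind)
  rmz <- ref$mz
  qmz <- query$mz
  rw <- rmz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- qmz^cfg$mz_power * query$intensity^cfg$intensity_power
  nr <- spectrum_norm(ref, cfg)
  nq <- spectrum_norm(query, cfg)
  if (!length(rmz) || !length(qmz) || !(nr > 0) || !(nq > 0))
    return(list(score = 0, matches = 0L, overflow = FALSE))
  limit <- if (apply_limit) cfg$match_limit else Inf
  qn <- length(qmz)

  # one collection pass: feasible (i, j) in i-major order, truncated at
  # `limit` NEW pairs (keys in `skip` are ignored and cost no budget)
  enum_pass <- function(shift, skip_keys = integer(0)) {
    feas <- t(abs(outer(rmz, qmz + shift, "-")) <= cfg$tolerance)
    idx <- which(feas)  # column-major on t() => reference-major order
    i <- (idx - 1L) %/% qn + 1L
    j <- (idx - 1L) %% qn + 1L
    keys <- (i - 1L) * qn + j
    fresh <- !(keys %in% skip_keys)
    i <- i[fresh]
    j <- j[fresh]
    keys <- keys[fresh]
    overflow <- length(i) > limit
    if (overflow) {
      i <- i[seq_len(limit)]
      j <- j[seq_len(limit)]
      keys <- keys[seq_len(limit)]
    }
    list(i = i, j = j, keys = keys, overflow = overflow)
  }

  p1 <- enum_pass(0)
  i <- p1$i
  j <- p1$j
  overflow <- p1$overflow
  if (shift_kind == "precursor") {
    if (is.null(ref$precursor_mz) || is.null(query$precursor_mz))
      stop("precursor shift requested but a precursor m/z is missing",
           call. = FALSE)
    p2 <- enum_pass(ref$precursor_mz - query$precursor_mz, p1$keys)
    i <- c(i, p2$i)
    j <- c(j, p2$j)
    overflow <- overflow || p2$overflow
  }
  if (!length(i))
    return(list(score = 0, matches = 0L, overflow = overflow))

  p <- rw[i] * qw[j]
  ord <- order(p, i, j, method = "radix",
               decreasing = c(TRUE, FALSE, FALSE))
  rused <- logical(length(rmz))
  qused <- logical(qn)
  acc <- 0
  m <- 0L
  for (k in ord) {
    ik <- i[k]
    jk <- j[k]
    if (!rused[ik] && !qused[jk]) {
      rused[ik] <- TRUE
      qused[jk] <- TRUE
      acc <- acc + p[k]
      m <- m + 1L
    }
  }
  if (m == 0L) return(list(score = 0, matches = 0L, overflow = overflow))
  list(score = acc / (nr * nq), matches = m, overflow = overflow)
}

#' Optimal-assignment (Hungarian) cosine on small instances
#'
#' Exact counterpart of the greedy score: the maximum-weight matching over
#' all tolerance-feasible peak pairs, normalised by the same product of
#' spectrum norms. Exponential-free but still far too slow for production
#' use, it exists to bound the greedy heuristic from above in tests
#' (greedy <= optimal always). The matching itself is delegated to
#' igraph's maximum-weight bipartite matching.
#'
#' @param ref,query `ms_spectrum` objects (intended for <= ~50 peaks each).
#' @param cfg a [kernel_config()].
#' @return The optimal cosine score (scalar).
#' @export
oracle_optimal <- function(ref, query, cfg = kernel_config()) {
  rmz <- ref$mz
  qmz <- query$mz
  rw <- rmz^cfg$mz_power * ref$intensity^cfg$intensity_power
  qw <- qmz^cfg$mz_power * query$intensity^cfg$intensity_power
  nr <- spectrum_norm(ref, cfg)
  nq <- spectrum_norm(query, cfg)
  if (!length(rmz) || !length(qmz) || !(nr > 0) || !(nq > 0)) return(0)
  feas <- which(abs(outer(rmz, qmz, "-")) <= cfg$tolerance, arr.ind = TRUE)
  if (!nrow(feas)) return(0)
  rn <- length(rmz)
  qn <- length(qmz)
  g <- igraph::make_empty_graph(n = rn + qn, directed = FALSE)
  g <- igraph::add_edges(g, rbind(feas[, 1], rn + feas[, 2]))
  igraph::V(g)$type <- c(rep(FALSE, rn), rep(TRUE, qn))
  w <- rw[feas[, 1]] * qw[feas[, 2]]
  m <- igraph::max_bipartite_match(g, weights = w)
  m$matching_weight / (nr * nq)
}
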