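#' Write a score matrix to disk
#'
#' Three formats are supported:
#' \describe{
#'   \item{`tsv`}{Tab-separated rows `ref_id, query_id, score, matches,
#'     overflow` in reference-major order; every cell for dense input, the
#'     retained entries for sparse. Scores are printed with 6 decimals.}
#'   \item{`coo`}{Coordinate-list text: as `tsv` plus leading `ref`/`query`
#'     integer index columns and a `# shape: R Q` header comment, so a
#'     sparse matrix can be reconstructed with its full shape.}
#'   \item{`dense`}{A binary container (RDS serialisation of the
#'     `score_matrix` object); exact round trip.}
#' }
#'
#' @param x a `score_matrix` from [score_all()].
#' @param path output path.
#' @param format one of `"tsv"`, `"coo"`, `"dense"`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(x, path, format = c("tsv", "coo", "dense")) {
  format <- match.arg(format)
  if (format == "dense") {
    saveRDS(x, path)
    return(invisible(path))
  }
  df <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "coo") {
    writeLines(sprintf("# shape: %d %d", x$shape[1], x$shape[2]), con)
    writeLines(sprintf("# storage: %s threshold: %g", x$storage,
                       if (x$storage == "sparse") x$threshold else 0), con)
    writeLines("ref\tquery\tref_id\tquery_id\tscore\tmatches\toverflow", con)
    writeLines(sprintf("%d\t%d\t%s\t%s\t%.6f\t%d\t%d",
                       df$ref, df$query, df$ref_id, df$query_id,
                       df$score, df$matches, as.integer(df$overflow)), con)
  } else {
    writeLines("ref_id\tquery_id\tscore\tmatches\toverflow", con)
    writeLines(sprintf("%s\t%s\t%.6f\t%d\t%d",
                       df$ref_id, df$query_id,
                       df$score, df$matches, as.integer(df$overflow)), con)
  }
  invisible(path)
}

#' Read scores written by [write_scores()]
#'
#' @param path input path.
#' @param format the format the file was written in.
#' @return For `"dense"`, the original `score_matrix`. For `"tsv"` and
#'   `"coo"`, a data.frame of triples (scores at the 6-decimal precision of
#'   the text format).
#' @export
read_scores <- function(path, format = c("tsv", "coo", "dense")) {
  format <- match.arg(format)
  if (format == "dense") return(readRDS(path))
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  df$overflow <- as.logical(df$overflow)
  df
}
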