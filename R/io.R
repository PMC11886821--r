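#' Read spectra from an MGF file
#'
#' Parses the Mascot generic format: `BEGIN IONS`/`END IONS` blocks with
#' `KEY=VALUE` header lines followed by whitespace-separated peak lines.
#' `PEPMASS` (first field) maps to `precursor_mz`, `TITLE` to `identifier`;
#' other headers (`CHARGE`, `RTINSECONDS`, ...) are kept as string metadata.
#' Peaks are sorted by ascending m/z on load and zero-intensity peaks are
#' dropped, as in [spectrum()].
#'
#' @param path path to an MGF file. An empty file yields an empty list.
#' @return A list of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_start <- 0L
  mz <- numeric()
  int <- numeric()
  title <- ""
  pep <- NULL
  meta <- list()
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (!in_block) {
      if (toupper(ln) == "BEGIN IONS") {
        in_block <- TRUE
        block_start <- k
        mz <- numeric()
        int <- numeric()
        title <- ""
        pep <- NULL
        meta <- list()
      }
      # stray content outside blocks is tolerated and ignored
      next
    }
    if (toupper(ln) == "END IONS") {
      spectra[[length(spectra) + 1L]] <-
        spectrum(mz, int, precursor_mz = pep, identifier = title,
                 metadata = meta)
      in_block <- FALSE
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0L && !grepl("^[0-9.+-]", ln)) {
      key <- toupper(substr(ln, 1L, eq - 1L))
      val <- substr(ln, eq + 1L, nchar(ln))
      if (key == "PEPMASS") {
        first <- strsplit(trimws(val), "[ \t]+")[[1]][1]
        pep <- suppressWarnings(as.double(first))
        if (is.na(pep))
          stop(sprintf("malformed PEPMASS at line %d of %s", k, path),
               call. = FALSE)
      } else if (key == "TITLE") {
        title <- val
      } else {
        meta[[key]] <- val
      }
      next
    }
    fields <- strsplit(ln, "[ \t]+")[[1]]
    vals <- suppressWarnings(as.double(fields[1:2]))
    if (length(fields) < 2L || anyNA(vals))
      stop(sprintf("malformed peak line %d of %s: '%s'", k, path, ln),
           call. = FALSE)
    mz <- c(mz, vals[1])
    int <- c(int, vals[2])
  }
  if (in_block)
    stop(sprintf("unterminated BEGIN IONS block starting at line %d of %s",
                 block_start, path), call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' Peak values are printed with 17 significant digits so that a
#' write/read cycle round-trips m/z and intensity to full double precision.
#'
#' @param spectra list of [spectrum()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    if (nzchar(s$identifier))
      writeLines(paste0("TITLE=", s$identifier), con)
    if (!is.null(s$precursor_mz))
      writeLines(sprintf("PEPMASS=%.17g", s$precursor_mz), con)
    for (key in names(s$metadata))
      writeLines(paste0(key, "=", s$metadata[[key]]), con)
    if (length(s$mz))
      writeLines(sprintf("%.17g %.17g", s$mz, s$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Read spectra from an NIST MSP file
#'
#' Parses text records of the NIST MSP dialect: a `Name:` line, optional
#' `PrecursorMZ:` (or `PRECURSORMZ:`) line, a mandatory `Num Peaks:` line,
#' and then peak lines (`mz intensity`, whitespace- or semicolon-separated,
#' possibly several pairs per line). The declared peak count is validated
#' against the number of peaks parsed.
#'
#' @param path path to an MSP file.
#' @return A list of [spectrum()] objects.
#' @export
read_msp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  k <- 1L
  n <- length(lines)
  while (k <= n) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) {
      k <- k + 1L
      next
    }
    if (!grepl("^name[ \t]*:", ln, ignore.case = TRUE))
      stop(sprintf("expected 'Name:' at line %d of %s", k, path),
           call. = FALSE)
    name <- trimws(sub("^[^:]*:", "", ln))
    pep <- NULL
    npk <- NA_integer_
    meta <- list()
    k <- k + 1L
    # header lines until Num Peaks
    while (k <= n) {
      ln <- trimws(lines[k])
      if (!nzchar(ln))
        stop(sprintf("record '%s' has no 'Num Peaks:' line (%s)", name, path),
             call. = FALSE)
      if (grepl("^num[ \t]*peaks[ \t]*:", ln, ignore.case = TRUE)) {
        npk <- suppressWarnings(as.integer(trimws(sub("^[^:]*:", "", ln))))
        if (is.na(npk))
          stop(sprintf("malformed 'Num Peaks' at line %d of %s", k, path),
               call. = FALSE)
        k <- k + 1L
        break
      }
      colon <- regexpr(":", ln, fixed = TRUE)
      if (colon < 0L) {
        if (grepl("^[0-9.+-]", ln))
          stop(sprintf("record '%s' has no 'Num Peaks:' line before its peaks (%s)",
                       name, path), call. = FALSE)
        stop(sprintf("malformed header at line %d of %s: '%s'", k, path, ln),
             call. = FALSE)
      }
      key <- trimws(substr(ln, 1L, colon - 1L))
      val <- trimws(substr(ln, colon + 1L, nchar(ln)))
      if (toupper(gsub("[ _]", "", key)) == "PRECURSORMZ") {
        pep <- suppressWarnings(as.double(val))
        if (is.na(pep))
          stop(sprintf("malformed precursor m/z at line %d of %s", k, path),
               call. = FALSE)
      } else {
        meta[[key]] <- val
      }
      k <- k + 1L
    }
    if (is.na(npk))
      stop(sprintf("record '%s' has no 'Num Peaks:' line (%s)", name, path),
           call. = FALSE)
    mz <- numeric()
    int <- numeric()
    while (k <= n && length(mz) < npk) {
      ln <- trimws(lines[k])
      if (!nzchar(ln)) break
      fields <- strsplit(gsub(";", " ", ln), "[ \t]+")[[1]]
      vals <- suppressWarnings(as.double(fields))
      if (anyNA(vals) || length(vals) %% 2L != 0L)
        stop(sprintf("malformed peak line %d of %s: '%s'", k, path, ln),
             call. = FALSE)
      mz <- c(mz, vals[seq(1L, length(vals), by = 2L)])
      int <- c(int, vals[seq(2L, length(vals), by = 2L)])
      k <- k + 1L
    }
    if (length(mz) != npk)
      stop(sprintf(
        "record '%s' declares %d peaks but %d were parsed (%s)",
        name, npk, length(mz), path), call. = FALSE)
    spectra[[length(spectra) + 1L]] <-
      spectrum(mz, int, precursor_mz = pep, identifier = name,
               metadata = meta)
  }
  spectra
}
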