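cfg <- kernel_config(batch_size = 4L)

test_that("pack_batches pads the leftover batch and zeroes beyond lengths", {
  sp <- toy_library(10)
  batches <- pack_batches(sp, cfg)
  expect_length(batches, 3)
  expect_equal(vapply(batches, function(b) b$n_real, integer(1)),
               c(4L, 4L, 2L))
  last <- batches[[3]]
  expect_equal(last$lengths, c(8L, 8L, 0L, 0L))  # two padding slots

  # mixed peak counts: pad width is the longest in the batch
  mixed <- list(random_spectrum(3, 1), random_spectrum(7, 2),
                random_spectrum(5, 3))
  b <- pack_batches(mixed, cfg)[[1]]
  expect_equal(b$pad_width, 7)
  for (k in 1:3) {
    len <- b$lengths[k]
    if (len < b$pad_width) {
      expect_true(all(b$mz[(len + 1):b$pad_width, k] == 0))
      expect_true(all(b$weight[(len + 1):b$pad_width, k] == 0))
    }
  }
})

test_that("packing then unpacking recovers every (mz, weight) sequence", {
  sp <- lapply(1:9, function(k) random_spectrum(3 + k, 400 + k))
  for (b in pack_batches(sp, cfg)) {
    recovered <- unpack_batch(b)
    offset <- match(recovered[[1]]$mz[1],
                    vapply(sp, function(s) s$mz[1], numeric(1)))
    for (k in seq_along(recovered)) {
      s <- sp[[offset + k - 1]]
      expect_identical(recovered[[k]]$mz, s$mz)
      expect_identical(recovered[[k]]$weight, s$intensity)  # default weights
    }
  }
})

test_that("packing for modified cosine requires precursors and names offenders", {
  sp <- toy_library(3)
  sp[[2]] <- spectrum(c(100, 200), c(1, 2), identifier = "lost_precursor")
  expect_error(pack_batches(sp, cfg, with_precursor = TRUE),
               "lost_precursor")
  expect_silent(pack_batches(sp, cfg, with_precursor = FALSE))
})

test_that("score_block matches the per-pair kernel on every valid cell", {
  refs <- lapply(1:4, function(k) random_spectrum(10 + k, 600 + k))
  qrys <- lapply(1:3, function(k) random_spectrum(12 + k, 700 + k))
  rb <- pack_batches(refs, cfg)[[1]]
  qb <- pack_batches(qrys, cfg)[[1]]
  for (kind in c("greedy", "modified")) {
    rb2 <- pack_batches(refs, cfg, with_precursor = kind == "modified")[[1]]
    qb2 <- pack_batches(qrys, cfg, with_precursor = kind == "modified")[[1]]
    blk <- score_block(rb2, qb2, cfg, kind)
    expect_equal(blk$valid_query, c(TRUE, TRUE, TRUE, FALSE))
    for (i in 1:4) for (j in 1:3) {
      direct <- if (kind == "greedy")
        greedy_cosine(refs[[i]], qrys[[j]], cfg)
      else modified_cosine(refs[[i]], qrys[[j]], cfg)
      expect_identical(blk$score[i, j], direct$score)
      expect_identical(blk$matches[i, j], direct$matches)
      expect_identical(blk$overflow[i, j], direct$overflow)
    }
    # padding cells carry the neutral triple
    expect_true(all(blk$score[, 4] == 0))
    expect_true(all(blk$matches[, 4] == 0L))
  }
})

test_that("score_block rejects batches packed under a different config", {
  sp <- toy_library(3)
  b1 <- pack_batches(sp, cfg)[[1]]
  other <- kernel_config(batch_size = 4L, tolerance = 0.5)
  expect_error(score_block(b1, b1, other), "different kernel configuration")
  expect_error(score_block(b1, b1, cfg, "modified"), "with_precursor")
})

test_that("score_all: identity diagonal, batch-size invariance, block independence", {
  lib <- generate_library(synth_config(12, peak_count_range = c(6L, 20L),
                                       seed = 5))
  refs <- lib$references
  m <- score_all(refs, refs, kernel_config(batch_size = 5L))
  expect_equal(dim(m$score), c(12, 12))
  expect_equal(diag(m$score), rep(1, 12), tolerance = 1e-12)
  expect_equal(diag(m$matches),
               vapply(refs, n_peaks, integer(1)))

  # identical output for any batch size, bitwise
  qrys <- lib$queries
  runs <- lapply(c(1L, 3L, 16L), function(B)
    score_all(refs, qrys, kernel_config(batch_size = B)))
  expect_identical(runs[[1]]$score, runs[[2]]$score)
  expect_identical(runs[[2]]$score, runs[[3]]$score)
  expect_identical(runs[[1]]$matches, runs[[3]]$matches)
  expect_identical(runs[[1]]$overflow, runs[[3]]$overflow)
})

test_that("appending padding-like empty spectra does not disturb valid cells", {
  lib <- generate_library(synth_config(6, peak_count_range = c(5L, 12L),
                                       seed = 9))
  base <- score_all(lib$references, lib$queries,
                    kernel_config(batch_size = 4L))
  extended <- c(lib$references,
                list(spectrum(numeric(0), numeric(0), identifier = "empty")))
  ext <- score_all(extended, lib$queries, kernel_config(batch_size = 4L))
  expect_identical(ext$score[1:6, ], base$score)
  expect_true(all(ext$score[7, ] == 0))
})

test_that("sparse output equals dense output filtered at the threshold", {
  lib <- generate_library(synth_config(15, peak_count_range = c(5L, 25L),
                                       shared_fraction = 0.9, seed = 21))
  for (thr in c(0, 0.4, 0.9)) {
    cfg_t <- kernel_config(batch_size = 6L, sparse_threshold = thr)
    dense <- score_all(lib$references, lib$queries, cfg_t, output = "dense")
    sparse <- score_all(lib$references, lib$queries, cfg_t,
                        output = "sparse")
    keep <- which(dense$score >= thr, arr.ind = TRUE)
    keep <- keep[order(keep[, 1], keep[, 2]), , drop = FALSE]
    expect_equal(nrow(sparse$entries), nrow(keep))
    expect_equal(sparse$entries$ref, unname(keep[, 1]))
    expect_equal(sparse$entries$query, unname(keep[, 2]))
    expect_identical(sparse$entries$score, dense$score[keep])
    expect_identical(sparse$entries$matches, dense$matches[keep])
  }
})

test_that("sparse output retains overflowed entries regardless of score", {
  set.seed(31)
  mk <- function(seed) {
    set.seed(seed)
    spectrum(sort(runif(40, 100, 100.3)), runif(40, 1, 2),
             identifier = paste0("dense", seed))
  }
  refs <- lapply(1:3, mk)
  qrys <- lapply(4:6, mk)
  cfg_o <- kernel_config(match_limit = 4L, sparse_threshold = 0.99,
                         batch_size = 2L)
  dense <- score_all(refs, qrys, cfg_o, output = "dense")
  sparse <- score_all(refs, qrys, cfg_o, output = "sparse")
  expect_true(any(dense$overflow))
  audit <- which(dense$overflow & dense$score < 0.99, arr.ind = TRUE)
  for (r in seq_len(nrow(audit)))
    expect_true(any(sparse$entries$ref == audit[r, 1] &
                    sparse$entries$query == audit[r, 2]))
})

test_that("dense output is refused beyond the cell budget", {
  sp <- toy_library(4)
  expect_error(score_all(sp, sp, cfg, max_dense_cells = 9), "sparse")
  expect_error(score_all(list(), sp, cfg), "no reference")
  expect_error(score_all(sp, list(), cfg), "no query")
})

test_that("score files round-trip through tsv, coo and the dense container", {
  lib <- generate_library(synth_config(5, peak_count_range = c(5L, 10L),
                                       seed = 44))
  m <- score_all(lib$references, lib$queries, kernel_config(batch_size = 3L))
  df <- as.data.frame(m)
  expect_equal(nrow(df), 25)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_scores(m, tsv, "tsv")
  back <- read_scores(tsv, "tsv")
  expect_equal(nrow(back), 25)
  expect_lt(max(abs(back$score - df$score)), 1e-6)  # 6-decimal text format
  expect_identical(back$matches, df$matches)
  expect_identical(back$overflow, df$overflow)
  expect_identical(back$ref_id, df$ref_id)

  sp_cfg <- kernel_config(batch_size = 3L, sparse_threshold = 0.5)
  ms <- score_all(lib$references, lib$queries, sp_cfg, output = "sparse")
  coo <- withr::local_tempfile(fileext = ".tsv")
  write_scores(ms, coo, "coo")
  back2 <- read_scores(coo, "coo")
  expect_equal(nrow(back2), nrow(ms$entries))
  expect_lt(max(abs(back2$score - ms$entries$score)), 1e-6)
  expect_identical(back2$ref, ms$entries$ref)

  bin <- withr::local_tempfile(fileext = ".rds")
  write_scores(m, bin, "dense")
  expect_identical(read_scores(bin, "dense")$score, m$score)
})
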