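cfg0 <- kernel_config()  # tolerance 0.1, weights = intensity, double

test_that("collect_pairs respects the tolerance window and match limit", {
  r <- spectrum(100.0, 1)
  expect_equal(nrow(collect_pairs(r, spectrum(100.05, 1), cfg0)), 1)
  expect_false(attr(collect_pairs(r, spectrum(100.05, 1), cfg0), "overflow"))
  expect_equal(nrow(collect_pairs(r, spectrum(100.2, 1), cfg0)), 0)
  # boundary is inclusive
  expect_equal(nrow(collect_pairs(r, spectrum(100.1, 1), cfg0)), 1)

  # 100 x 100 mutually-feasible peaks against a limit of 64
  set.seed(1)
  a <- spectrum(sort(runif(100, 100, 100.05)), runif(100, 1, 2))
  b <- spectrum(sort(runif(100, 100, 100.05)), runif(100, 1, 2))
  p <- collect_pairs(a, b, kernel_config(match_limit = 64L))
  expect_equal(nrow(p), 64)
  expect_true(attr(p, "overflow"))
  # reference-major enumeration order
  expect_true(all(diff(p$ref_index) >= 0))
})

test_that("greedy_reduce applies the sort-and-mark rule", {
  one <- data.frame(ref_index = 1L, query_index = 1L, product = 6.0)
  expect_equal(greedy_reduce(one, 1, 1, cfg0),
               list(score = 6.0, matches = 1L))

  # the middle pair is blocked by the first pick
  pr <- data.frame(ref_index = c(1L, 1L, 2L), query_index = c(1L, 2L, 2L),
                   product = c(6, 5, 4))
  expect_equal(greedy_reduce(pr, 2, 2, cfg0),
               list(score = 10.0, matches = 2L))

  empty <- data.frame(ref_index = integer(), query_index = integer(),
                      product = numeric())
  expect_equal(greedy_reduce(empty, 3, 3, cfg0),
               list(score = 0.0, matches = 0L))
})

test_that("staged collect/reduce/normalise equals greedy_cosine", {
  for (seed in 1:10) {
    a <- random_spectrum(20, seed)
    b <- random_spectrum(25, seed + 50)
    p <- collect_pairs(a, b, cfg0)
    red <- greedy_reduce(p, n_peaks(a), n_peaks(b), cfg0)
    staged <- red$score / (spectrum_norm(a, cfg0) * spectrum_norm(b, cfg0))
    direct <- greedy_cosine(a, b, cfg0)
    if (red$matches > 0) expect_identical(staged, direct$score)
    expect_identical(red$matches, direct$matches)
  }
})

test_that("greedy cosine: self-similarity, disjoint spectra, spec example vs oracle", {
  s <- random_spectrum(40, seed = 3)
  self <- greedy_cosine(s, s, cfg0)
  expect_equal(self$score, 1, tolerance = 1e-12)
  expect_equal(self$matches, 40L)
  expect_false(self$overflow)

  far <- greedy_cosine(spectrum(c(100, 110), c(1, 1)),
                       spectrum(c(300, 310), c(1, 1)), cfg0)
  expect_equal(far, list(score = 0, matches = 0L, overflow = FALSE))

  ref <- spectrum(c(100, 150, 200), c(0.7, 0.2, 0.1))
  qry <- spectrum(c(100.05, 150.05, 300), c(0.7, 0.2, 0.1))
  k <- greedy_cosine(ref, qry, cfg0)
  o <- oracle_greedy(ref, qry, cfg0)
  expect_identical(k$score, o$score)
  expect_identical(k$matches, o$matches)
  expect_equal(k$matches, 2L)
})

test_that("zero-norm (empty after filtering) spectra score 0 without error", {
  z <- spectrum(c(100, 200), c(0, 0))  # all peaks dropped at load
  s <- random_spectrum(5, seed = 2)
  expect_equal(greedy_cosine(z, s, cfg0),
               list(score = 0, matches = 0L, overflow = FALSE))
  expect_equal(greedy_cosine(s, z, cfg0)$score, 0)
})

test_that("modified cosine recovers precursor-shifted fragments", {
  s <- random_spectrum(20, seed = 5)
  expect_equal(modified_cosine(s, s, cfg0)$score, 1, tolerance = 1e-12)
  expect_equal(modified_cosine(s, s, cfg0)$matches, 20L)

  # no unshifted match; shifted pass aligns 100 - 500 = 118 - 518
  ref <- spectrum(100, 1, precursor_mz = 500)
  qry <- spectrum(118, 1, precursor_mz = 518)
  m <- modified_cosine(ref, qry, cfg0)
  expect_equal(m$score, 1)
  expect_equal(m$matches, 1L)
  expect_equal(greedy_cosine(ref, qry, cfg0)$score, 0)

  # precursor difference with no shifted-frame alignment: equals greedy
  a <- spectrum(c(100, 200, 300), c(1, 2, 3), precursor_mz = 400)
  b <- spectrum(c(100, 200, 300), c(1, 2, 3), precursor_mz = 450)
  m2 <- modified_cosine(a, b, cfg0)
  g2 <- greedy_cosine(a, b, cfg0)
  o2 <- oracle_greedy(a, b, cfg0, shift_kind = "precursor")
  expect_identical(m2$score, g2$score)
  expect_identical(m2$score, o2$score)

  expect_error(modified_cosine(spectrum(100, 1), s, cfg0), "precursor")
  expect_error(
    modified_cosine(s, spectrum(100, 1, identifier = "noprec"), cfg0),
    "noprec")
})

test_that("greedy score is symmetric and scale invariant", {
  for (seed in 1:20) {
    a <- random_spectrum(15, seed, mz_range = c(100, 200))
    b <- random_spectrum(18, seed + 100, mz_range = c(100, 200))
    ab <- greedy_cosine(a, b, cfg0)
    ba <- greedy_cosine(b, a, cfg0)
    expect_identical(ab$score, ba$score)
    expect_identical(ab$matches, ba$matches)

    scaled <- spectrum(b$mz, 7.3 * b$intensity, b$precursor_mz)
    sc <- greedy_cosine(a, scaled, cfg0)
    expect_equal(sc$score, ab$score, tolerance = 1e-12)
    expect_identical(sc$matches, ab$matches)
  }
})

test_that("scores are bounded and matches capped by the smaller spectrum", {
  for (seed in 1:25) {
    n1 <- 5 + seed
    n2 <- 35 - seed
    a <- random_spectrum(n1, seed, mz_range = c(100, 120))
    b <- random_spectrum(n2, seed + 200, mz_range = c(100, 120))
    g <- greedy_cosine(a, b, cfg0)
    expect_lte(g$score, 1 + 4 * .Machine$double.eps * max(n1, n2))
    expect_gte(g$score, 0)
    expect_lte(g$matches, min(n1, n2))
  }
})

test_that("overflow is monotone in match_limit and vanishes above the feasible count", {
  set.seed(8)
  a <- spectrum(sort(runif(60, 100, 100.4)), runif(60, 1, 10))
  b <- spectrum(sort(runif(60, 100, 100.4)), runif(60, 1, 10))
  limits <- c(4L, 16L, 64L, 256L, 1024L, 8192L)
  ovf <- vapply(limits, function(l)
    greedy_cosine(a, b, kernel_config(match_limit = l))$overflow,
    logical(1))
  expect_true(all(diff(as.integer(ovf)) <= 0))  # never FALSE -> TRUE
  # once the limit covers all feasible pairs, equals the no-limit oracle
  full <- greedy_cosine(a, b, kernel_config(match_limit = 8192L))
  expect_false(full$overflow)
  expect_triple_equal(full, oracle_greedy(a, b, cfg0))
})

test_that("feasible-pair count is non-decreasing in tolerance", {
  a <- random_spectrum(30, seed = 4, mz_range = c(100, 110))
  b <- random_spectrum(30, seed = 104, mz_range = c(100, 110))
  counts <- vapply(c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 2),
                   function(tol) nrow(collect_pairs(a, b,
                     kernel_config(tolerance = tol, match_limit = 100000L))),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("single-precision kernel tracks the double-precision result", {
  cfg_s <- kernel_config(precision = "single")
  n_close <- 0
  for (seed in 1:100) {
    a <- random_spectrum(25, seed, mz_range = c(50, 800))
    b <- random_spectrum(25, seed + 1000, mz_range = c(50, 800))
    d <- greedy_cosine(a, b, cfg0)$score
    s <- greedy_cosine(a, b, cfg_s)$score
    n_close <- n_close + (abs(d - s) <= 1e-3)
  }
  expect_gte(n_close, 99)
})
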