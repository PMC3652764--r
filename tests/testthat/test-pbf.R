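test_that("position sequences reproduce the worked example", {
  expect_equal(ss_positions(TOY, "C"), c(1, 2, 12, 13, 14, 15, 16))
  expect_equal(ss_positions(TOY, "E"), c(7, 8, 9, 10, 11))
  expect_equal(ss_positions("HHH", "E"), integer(0))
})

test_that("interval distances are successive position differences", {
  expect_equal(interval_distances(ss_positions(TOY, "C")),
               c(1, 10, 1, 1, 1, 1))
  # two-block position fixture: unit gaps within blocks, 8 across
  expect_equal(interval_distances(c(3, 4, 5, 6, 14, 15, 16, 17, 18, 19)),
               c(1, 1, 1, 8, 1, 1, 1, 1, 1))
  expect_equal(interval_distances(c(5)), integer(0))
  expect_error(interval_distances(c(3, 3)), "strictly increasing")
})

test_that("distance counts relate to positions by length and span", {
  set.seed(21)
  for (i in 1:100) {
    s <- random_ss(sample(1:80, 1))
    for (e in c("H", "E", "C")) {
      po <- ss_positions(s, e)
      nd <- interval_distances(po)
      expect_length(nd, max(0L, length(po) - 1L))
      if (length(po) >= 2)
        expect_equal(sum(nd), max(po) - min(po))
    }
  }
})

test_that("distance distributions are proper probability tables", {
  expect_equal(distance_distribution(c(1, 10, 1, 1, 1, 1)),
               c("1" = 5 / 6, "10" = 1 / 6))
  expect_equal(distance_distribution(c(1, 1, 1, 1)), c("1" = 1))
  expect_length(distance_distribution(integer(0)), 0L)
  set.seed(23)
  for (i in 1:50) {
    d <- distance_distribution(sample(1:12, sample(1:30, 1), replace = TRUE))
    expect_equal(sum(d), 1)
    expect_true(all(d > 0))
  }
})

test_that("semi-moments match a brute-force multiset oracle", {
  dc <- c(1, 10, 1, 1, 1, 1)
  d <- distance_distribution(dc)
  expect_equal(semi_mean(d, 5), 5 / 6, tolerance = 1e-12)
  expect_equal(semi_variance(d, 5), 5 / 6 - 25 / 36, tolerance = 1e-12)
  expect_equal(semi_mean(d, Inf), 2.5, tolerance = 1e-12)
  expect_equal(semi_variance(d, Inf), 11.25, tolerance = 1e-12)
  expect_equal(semi_mean(c("1" = 1), 3), 1)
  expect_equal(semi_variance(c("1" = 1), 3), 0)
  set.seed(29)
  for (i in 1:100) {
    dists <- sample(1:15, sample(2:40, 1), replace = TRUE)
    d <- distance_distribution(dists)
    for (k in c(1, 3, 7, Inf)) {
      o <- semi_oracle(dists, k)
      expect_equal(semi_mean(d, k), o$E, tolerance = 1e-12)
      expect_equal(semi_variance(d, k), o$D, tolerance = 1e-12)
    }
    # untruncated semi-mean is the ordinary mean of the multiset
    expect_equal(semi_mean(d, Inf), mean(dists), tolerance = 1e-12)
    # semi-mean is non-decreasing in k
    sm <- vapply(1:15, function(k) semi_mean(d, k), numeric(1))
    expect_true(all(diff(sm) >= -1e-15))
  }
})

test_that("reciprocal CV matches closed forms and handles degeneracy", {
  d <- distance_distribution(c(1, 10, 1, 1, 1, 1))
  expect_equal(c_k(d, 5), sqrt(5), tolerance = 1e-12)
  expect_equal(c_k(d, Inf), 2.5 / sqrt(11.25), tolerance = 1e-12)
  expect_equal(c_k(d, Inf, variant = "variance-ratio"), 2.5 / 11.25,
               tolerance = 1e-12)
  # zero variance and empty distribution give the degenerate value
  expect_equal(c_k(c("1" = 1), 5), 0)
  expect_equal(c_k(c("1" = 1), 5, degenerate = -1), -1)
  expect_equal(c_k(distance_distribution(integer(0))), 0)
  # two-point distribution {1:p, m:1-p}: algebraic mean/sd
  set.seed(31)
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.95)
    m <- sample(2:30, 1)
    d2 <- stats::setNames(c(p, 1 - p), c("1", as.character(m)))
    mu <- p + m * (1 - p)
    va <- p + m^2 * (1 - p) - mu^2
    expect_equal(c_k(d2, Inf), mu / sqrt(va), tolerance = 1e-12)
  }
})

test_that("truncation at or past the largest distance recovers C_F", {
  set.seed(37)
  for (i in 1:100) {
    s <- random_ss(sample(5:80, 1))
    for (e in c("H", "E", "C")) {
      d <- distance_distribution(interval_distances(ss_positions(s, e)))
      if (length(d) == 0) next
      kmax <- max(as.numeric(names(d)))
      expect_identical(c_k(d, kmax), c_k(d, Inf))
      expect_identical(c_k(d, kmax + 3), c_k(d, Inf))
    }
  }
})

test_that("position-based feature rows are complete in fixed order", {
  v <- pbf_vector(TOY)
  expect_named(v, c("CF_C", "CF_H", "CF_E"))
  expect_equal(unname(v["CF_C"]), 2.5 / sqrt(11.25), tolerance = 1e-12)
  expect_equal(unname(v["CF_E"]), 0)  # constant distances: degenerate
  v5 <- pbf_vector(TOY, k = 5)
  expect_named(v5, c("C5_C", "C5_H", "C5_E"))
  expect_equal(unname(v5["C5_C"]), sqrt(5), tolerance = 1e-12)
  expect_equal(unname(pbf_vector("CCCC")), c(0, 0, 0))
})
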