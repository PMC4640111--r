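test_that("fsNML estimates match direct evaluation of the estimator", {
  expect_equal(fsnml_estimate(c(0, 0, 0, 0)), rep(0.25, 4))
  # e(1) = 2, numerator 2 * 2 = 4, denominator 4 + 3
  expect_equal(fsnml_estimate(c(1, 0, 0, 0)), c(4, 1, 1, 1) / 7)
  for (k in c(1, 5, 100)) {
    expect_equal(fsnml_estimate(rep(k, 4)), rep(0.25, 4))
  }
  expect_error(fsnml_estimate(c(-1, 0, 0, 0)), "non-negative")
})

test_that("fsNML outputs are strictly positive and normalized for huge counts", {
  set.seed(2)
  for (i in 1:50) {
    cnt <- sample(0:1e6, 4, replace = TRUE)
    th <- fsnml_estimate(cnt)
    expect_true(all(th > 0))
    expect_equal(sum(th), 1, tolerance = 1e-12)
  }
})

test_that("position fits concentrate where the data do", {
  sites <- paste0(rep("A", 300), sample(c("C", "G"), 300, replace = TRUE))
  f <- fit_position(sites, position = 1, depth = 1)
  expect_true(all(f$theta[, "A"] > 0.99))
  expect_error(fit_position(character(0), 1, 1), "empty")
})

test_that("a deterministic copy of the previous column selects a split", {
  set.seed(9)
  col1 <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  sites <- paste0(col1, col1)  # column 2 copies column 1
  f <- fit_position(sites, position = 2, depth = 1)
  expect_gt(nrow(f$theta), 1)  # structure separates the copied symbol
  # each context's mass sits on the copied symbol
  for (ci in seq_len(nrow(f$theta))) {
    expect_gt(max(f$theta[ci, ]), 0.9)
  }
})

test_that("motif fitting: d = 0 equals a PWM with fsNML columns", {
  sites <- random_sites(60, 5, seed = 13)
  m0 <- fit_motif(sites, order = 0)
  expect_equal(motif_log_likelihood(m0, sites), pwm_loglik_oracle(sites),
               tolerance = 1e-9)
  # all-minimal higher-order model assigns the same likelihoods as the PWM
  m2 <- fit_motif(sites, order = 2)
  min_all <- all(vapply(m2$positions, function(p) nrow(p$theta) == 1L, TRUE))
  if (min_all) {
    expect_equal(motif_log_likelihood(m2, sites),
                 motif_log_likelihood(m0, sites), tolerance = 1e-9)
  }
})

test_that("structure score is non-decreasing in the maximal order", {
  sites <- random_sites(80, 4, seed = 17)
  sc <- vapply(0:2, function(d) fit_motif(sites, d)$score, 0)
  expect_true(all(diff(sc) >= -1e-9))
})

test_that("structure score ignores the order of the sites", {
  sites <- random_sites(50, 4, seed = 19)
  expect_equal(fit_motif(sites, 2)$score,
               fit_motif(rev(sites), 2)$score, tolerance = 1e-12)
})

test_that("motif likelihood handles edge cases and width mismatches", {
  m <- pwm_motif(matrix(c(1, 0, 0, 0), nrow = 1))
  expect_equal(motif_log_likelihood(m, "A"), 0)  # log 1
  u <- pwm_motif(matrix(0.25, nrow = 2, ncol = 4))
  expect_equal(motif_log_likelihood(u, "AC"), 2 * log(1 / 4))
  expect_error(motif_log_likelihood(u, "ACG"), "width")
})

test_that("model JSON round-trips structures and parameters", {
  sites <- random_sites(100, 4, seed = 23)
  m <- fit_motif(sites, order = 2)
  f <- withr::local_tempfile(fileext = ".json")
  pmm_write(m, f)
  m2 <- pmm_read(f)
  expect_equal(m2$width, m$width)
  expect_equal(m2$order, m$order)
  for (l in seq_len(m$width)) {
    expect_equal(m2$positions[[l]]$pct$root, m$positions[[l]]$pct$root)
    expect_equal(unname(m2$positions[[l]]$theta),
                 unname(m$positions[[l]]$theta), tolerance = 1e-12)
  }
  test_sites <- random_sites(20, 4, seed = 29)
  expect_equal(motif_log_likelihood(m2, test_sites),
               motif_log_likelihood(m, test_sites), tolerance = 1e-9)
})

test_that("tidy and glance expose the fitted motif", {
  sites <- random_sites(40, 3, seed = 31)
  m <- fit_motif(sites, order = 1)
  td <- tidy(m)
  expect_true(all(c("position", "context", "symbol", "prob") %in% names(td)))
  sums <- tapply(td$prob, paste(td$position, td$context), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  g <- glance(m)
  expect_equal(g$width, 3L)
  expect_equal(g$score, m$score)
})
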