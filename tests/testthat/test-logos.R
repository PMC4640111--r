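test_that("information content follows the logo definition", {
  lm <- logo_matrix(c("AA", "AC"))
  # position 1: all A -> 2 bits; position 2: half A half C -> 1 bit
  expect_equal(unique(lm$ic[lm$position == 1]), 2)
  expect_equal(unique(lm$ic[lm$position == 2]), 1)
  expect_equal(sum(lm$height[lm$position == 1]), 2)

  u <- logo_matrix(c("A", "C", "G", "T"))
  expect_equal(unique(u$ic), 0)
  expect_error(logo_matrix(character(0)), "empty")
})

test_that("logo frequencies converge to the generating PWM profile", {
  prob <- rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25),
                c(0.05, 0.05, 0.45, 0.45))
  sites <- sample_motif_sites(pwm_motif(prob), 10000, seed = 10)
  lm <- logo_matrix(sites)
  ic_true <- apply(prob, 1, function(p) 2 + sum(ifelse(p > 0, p * log2(p), 0)))
  ic_obs <- unique(lm[, c("position", "ic")])$ic
  expect_equal(ic_obs, ic_true, tolerance = 0.05)
})

test_that("conditional logos expose contexts with coverage-based widths", {
  # column 2 copies column 1; context coverages follow column-1 frequencies
  set.seed(12)
  col1 <- sample(c("A", "C", "G", "T"), 800, replace = TRUE,
                 prob = c(0.6, 0.3, 0.06, 0.04))
  sites <- paste0(col1, col1)
  m <- fit_motif(sites, order = 1)
  cl <- conditional_logo(m, sites, position = 2)
  cov <- unique(cl[, c("context", "coverage", "width_class")])
  expect_equal(sum(cov$coverage), 1)
  expect_true(all(cl$width_class %in% c(1, 0.5, 0.25)))
  # a context covering > 50% gets full width, 5-50% half, < 5% quarter
  expect_equal(cov$width_class[which.max(cov$coverage)][cov$coverage[which.max(cov$coverage)] > 0.5],
               rep(1, sum(max(cov$coverage) > 0.5)))

  # minimal PCT: one context of full coverage and width 1
  m0 <- fit_motif(random_sites(30, 3, seed = 5), order = 0)
  cl0 <- conditional_logo(m0, random_sites(30, 3, seed = 5), 2)
  expect_equal(unique(cl0$coverage), 1)
  expect_equal(unique(cl0$width_class), 1)
})

test_that("width classes map coverage bands with inclusive boundaries", {
  # hand-built order-1 model with a fully split PCT at position 2, applied
  # to sites with exact context coverages 0.60 / 0.30 / 0.05 / 0.05
  sites <- paste0(rep(c("A", "C", "G", "T"), c(60, 30, 5, 5)), "A")
  m <- fit_motif(sites, order = 1)
  m$positions[[2]]$pct <- pct_maximal(1)
  m$positions[[2]]$leaf_map <- parsimotif:::pct_leaf_map(pct_maximal(1))
  m$positions[[2]]$theta <- matrix(0.25, 4, 4)
  m$positions[[2]]$deff <- 1L
  cl <- conditional_logo(m, sites, 2)
  cov <- unique(as.data.frame(cl[, c("members", "coverage", "width_class")]))
  expect_equal(cov$width_class[cov$members == "A"], 1)     # 0.60 > 50 %
  expect_equal(cov$width_class[cov$members == "C"], 0.5)   # 30 %
  expect_equal(cov$width_class[cov$members == "G"], 0.5)   # 5 % boundary
  expect_equal(cov$width_class[cov$members == "T"], 0.5)   # 5 % boundary
})

test_that("autoplot builds ggplot objects for both logo types", {
  sites <- random_sites(50, 4, seed = 8)
  expect_s3_class(ggplot2::autoplot(logo_matrix(sites)), "ggplot")
  m <- fit_motif(sites, order = 1)
  expect_s3_class(ggplot2::autoplot(conditional_logo(m, sites, 2)), "ggplot")
})
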