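test_that("flanking fits concentrate on repeated symbols and stay proper", {
  fm <- fit_flanking(seq_set(rep(strrep("A", 50), 4)), order = 0)
  expect_gt(fm$cond[1, "A"], 0.97)  # add-one smoothed count ratio
  expect_equal(rowSums(fm$cond), 1, ignore_attr = TRUE)

  # near-uniform synthetic data gives near-uniform order-0 estimates
  set.seed(3)
  fm_u <- fit_flanking(seq_set(random_sites(30, 80)), order = 0)
  expect_true(all(abs(fm_u$cond - 0.25) < 0.03))

  # a single short sequence still trains (lower-order prefixes only)
  fm_s <- fit_flanking(seq_set("AC"), order = 2)
  expect_equal(rowSums(fm_s$cond), rep(1, 16), ignore_attr = TRUE)
  expect_error(fit_flanking(seq_set("ACGT")[0, ], 2), "empty")
})

test_that("flanking segment scores follow the fresh-start factorization", {
  fm <- uniform_flanking(0)
  expect_equal(flanking_log_prob(fm, ""), 0)
  expect_equal(flanking_log_prob(fm, "ACG"), 3 * log(1 / 4))

  # hand-built order-1 model: P(A) = 0.5, P(C|A) = 0.9
  fm1 <- uniform_flanking(1)
  fm1$init[[1]] <- matrix(c(0.5, 0.3, 0.1, 0.1), nrow = 1)
  fm1$cond <- matrix(0.1 / 3, nrow = 4, ncol = 4)
  fm1$cond[1, ] <- c(0.05, 0.9, 0.025, 0.025)
  fm1$log_init <- lapply(fm1$init, log)
  fm1$log_cond <- log(fm1$cond)
  expect_equal(flanking_log_prob(fm1, "AC"), log(0.5 * 0.9))
})

test_that("conditional likelihood is additive in motif and flank factors", {
  data <- seq_set(c("ACGTACG", "TTGACCA"))
  fm <- fit_flanking(data, order = 2)
  motif <- fit_motif(c("CGT", "GAC", "ACG", "TTG"), order = 1)
  om <- oops_model(motif, fm)
  for (i in 1:2) {
    for (v in c(1, 3, 5)) {
      s <- data$seq[i]
      expect_equal(
        conditional_log_likelihood(om, s, v, "F"),
        flanking_log_prob(fm, substr(s, 1, v - 1)) +
          flanking_log_prob(fm, substr(s, v + 3, 7)) +
          motif_log_likelihood(motif, substr(s, v, v + 2)),
        tolerance = 1e-12
      )
      expect_equal(
        conditional_log_likelihood(om, s, v, "R"),
        flanking_log_prob(fm, substr(s, 1, v - 1)) +
          flanking_log_prob(fm, substr(s, v + 3, 7)) +
          motif_log_likelihood(motif, reverse_complement(substr(s, v, v + 2))),
        tolerance = 1e-12
      )
    }
  }
})

test_that("when the motif spans the sequence only the motif term remains", {
  fm <- uniform_flanking(2)
  motif <- fit_motif(c("ACGT", "ACGA", "TCGT"), order = 0)
  om <- oops_model(motif, fm)
  expect_equal(conditional_log_likelihood(om, "ACGT", 1, "F"),
               motif_log_likelihood(motif, "ACGT"))
})

test_that("reverse-strand scoring of a palindromic window equals forward", {
  fm <- uniform_flanking(0)
  motif <- fit_motif(c("ACGT", "AAGT", "ACTT"), order = 1)
  om <- oops_model(motif, fm)
  # GAATTC-style palindrome: rc("ACGT") == "ACGT"
  expect_equal(conditional_log_likelihood(om, "GACGTG", 2, "R"),
               conditional_log_likelihood(om, "GACGTG", 2, "F"))
})

test_that("joint likelihood mixes strands under uniform priors", {
  motif <- pwm_motif(matrix(c(0.7, 0.1, 0.1, 0.1), nrow = 1))
  om <- oops_model(motif, uniform_flanking(0))
  # W = 1, seq "A": rc is "T", so log(1 * 1/2 * (0.7 + 0.1)) = log 0.4
  expect_equal(joint_log_likelihood(om, "A", 1), log(0.4))
  # equal strand terms collapse to one term plus the position prior
  pal <- fit_motif(c("AT", "TA", "GC"), order = 0)
  om2 <- oops_model(pal, uniform_flanking(0))
  j <- joint_log_likelihood(om2, "CATC", 2)
  condF <- conditional_log_likelihood(om2, "CATC", 2, "F")
  expect_equal(j, condF + log(1 / 3), tolerance = 1e-12)
})

test_that("the OOPS marginal is a proper distribution over sequences", {
  # brute force over all 4^L sequences with order-0 flanks
  fm <- fit_flanking(seq_set(c("ACGTAC", "GGTCAT")), order = 0)
  motif <- fit_motif(c("AC", "AG", "GT", "AA"), order = 1)
  om <- oops_model(motif, fm)
  for (L in c(3, 5)) {
    allseq <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), L)),
                    1, paste, collapse = "")
    total <- sum(vapply(allseq, function(s) {
      exp(parsimotif:::oops_marginal(om, parsimotif:::encode_seq(s)))
    }, 0))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})
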