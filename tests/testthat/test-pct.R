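test_that("contexts of the five-context worked example and the extreme trees", {
  tree <- fig_tree()
  ctx <- pct_contexts(tree)
  expect_length(ctx, 5)
  expect_setequal(
    vapply(ctx, paste, "", collapse = ","),
    c("AA,AG,AT,CA,CG,CT", "GA,GG,GT,TA,TG,TT", "AC,GC", "CC", "TC")
  )
  all_seqs <- sort(unlist(ctx))
  expect_equal(length(all_seqs), 16)
  expect_false(anyDuplicated(all_seqs) > 0)

  expect_length(pct_contexts(pct_minimal(2))[[1]], 16)
  expect_length(pct_contexts(pct_maximal(1)), 4)
})

test_that("contexts form a partition for every enumerated structure", {
  for (p in enumerate_pcts(2, 3)) {
    ctx <- pct_contexts(p)
    seqs <- unlist(ctx)
    expect_equal(sort(seqs), sort(unique(seqs)))
    expect_equal(length(seqs), 9)
  }
})

test_that("count aggregation respects the context partition", {
  raw <- matrix(1:64, nrow = 16, ncol = 4)
  # minimal: single context = column sums
  expect_equal(as.vector(aggregate_counts(raw, pct_minimal(2))),
               colSums(raw))
  # maximal: identity
  expect_equal(unname(aggregate_counts(raw, pct_maximal(2))), unname(raw))
  # worked-example tree: hand aggregation over listed members
  tree <- fig_tree()
  agg <- aggregate_counts(raw, tree)
  expect_equal(nrow(agg), 5)
  expect_equal(colSums(agg), colSums(raw))
  # the {CC} singleton context: code of "CC" is distal C (digit 1) and
  # proximal C (digit 0) -> (2-1)*4 + (2-1) = 5 -> row 6
  ctx <- pct_contexts(tree)
  cc_leaf <- which(vapply(ctx, identical, TRUE, "CC"))
  expect_equal(agg[cc_leaf, ], raw[6, ])
  expect_error(aggregate_counts(raw, pct_minimal(1)), "depth")
})

test_that("BIC score evaluates the penalized log-likelihood with natural logs", {
  raw <- matrix(c(3, 1, 0, 0), nrow = 1)
  expect_equal(bic_score(pct_minimal(0), raw, 4),
               3 * log(3 / 4) + log(1 / 4) - 1.5 * log(4),
               tolerance = 1e-12)
  raw_u <- matrix(c(1, 1, 1, 1), nrow = 1)
  expect_equal(bic_score(pct_minimal(0), raw_u, 4),
               4 * log(1 / 4) - 1.5 * log(4), tolerance = 1e-12)
  expect_error(bic_score(pct_minimal(0), matrix(0, 1, 4), 0), "sample size")
})

test_that("minimal PCTs of any depth score like the depth-0 tree", {
  set.seed(5)
  sites <- random_sites(40, 4)
  for (l in 2:4) {
    raw0 <- context_counts(sites, l, 0)
    sc0 <- bic_score(pct_minimal(0), raw0, 40)
    for (d in seq_len(min(2, l - 1))) {
      rawd <- context_counts(sites, l, d)
      expect_equal(bic_score(pct_minimal(d), rawd, 40), sc0,
                   tolerance = 1e-9)
    }
  }
})

test_that("DP maximization agrees with brute-force enumeration", {
  set.seed(11)
  for (i in 1:25) {
    raw <- random_count_table(1, 4)
    n <- sum(raw)
    if (n == 0) next
    expect_equal(maximize_bic(raw, 1, n)$score,
                 brute_force_best(raw, 1, n, 4), tolerance = 1e-9)
  }
  for (i in 1:25) {
    raw <- random_count_table(2, 2)
    n <- sum(raw)
    if (n == 0) next
    expect_equal(maximize_bic(raw, 2, n, m = 2)$score,
                 brute_force_best(raw, 2, n, 2), tolerance = 1e-9)
  }
  for (i in 1:10) {
    raw <- random_count_table(2, 3)
    n <- sum(raw)
    if (n == 0) next
    expect_equal(maximize_bic(raw, 2, n, m = 3)$score,
                 brute_force_best(raw, 2, n, 3), tolerance = 1e-9)
  }
})

test_that("maximization is exact at depth 0 and monotone in depth", {
  raw <- matrix(c(5, 2, 1, 0), nrow = 1)
  opt <- maximize_bic(raw, 0, 8)
  expect_equal(opt$pct$depth, 0L)
  expect_equal(opt$score, bic_score(pct_minimal(0), raw, 8))

  set.seed(23)
  sites <- random_sites(100, 5)
  for (l in 3:5) {
    sc <- vapply(0:2, function(d) {
      maximize_bic(context_counts(sites, l, d), d, 100)$score
    }, 0)
    expect_true(all(diff(sc) >= -1e-9))
  }
})

test_that("structure enumeration yields the expected counts", {
  expect_length(enumerate_pcts(1, 4), 15)  # Bell number of a 4-set
  expect_length(enumerate_pcts(2, 2), 6)   # 2 + 2 * 2 by hand
  expect_length(enumerate_pcts(0, 4), 1)
  expect_error(enumerate_pcts(3, 4), "refusing")
})

test_that("string and JSON-style serialization round-trip", {
  trees <- c(list(fig_tree(), pct_minimal(2), pct_maximal(2), pct_minimal(0)),
             enumerate_pcts(1, 4))
  for (p in trees) {
    expect_equal(pct_from_string(pct_to_string(p), m = p$m)$root, p$root)
    expect_equal(parsimotif:::pct_from_list(parsimotif:::pct_to_list(p))$root,
                 p$root)
  }
})

test_that("invalid trees are rejected", {
  bad <- list(list(label = c("A", "C"), children = NULL))
  expect_error(pct_from_spec(1, bad), "partition")
})
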