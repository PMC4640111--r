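# shared fixtures and independent oracles, built in code at test time

# the five-context depth-2 tree used as a worked example throughout
fig_tree <- function() {
  pct_from_spec(2, list(
    list(label = c("A", "G", "T"), children = list(
      list(label = c("A", "C")),
      list(label = c("G", "T"))
    )),
    list(label = "C", children = list(
      list(label = c("A", "G")),
      list(label = "C"),
      list(label = "T")
    ))
  ))
}

# independent PWM log-likelihood: per-column fsNML estimates, no PCT code
pwm_loglik_oracle <- function(sites) {
  M <- matrix(match(unlist(strsplit(sites, "")), c("A", "C", "G", "T")),
              ncol = nchar(sites[1]), byrow = TRUE)
  ll <- 0
  for (l in seq_len(ncol(M))) {
    th <- fsnml_estimate(tabulate(M[, l], nbins = 4))
    ll <- ll + sum(log(th)[M[, l]])
  }
  ll
}

# brute-force AUC: explicit pairwise wins with half credit for ties
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

random_count_table <- function(depth, m, lambda = 3) {
  matrix(stats::rpois(m^depth * m, lambda), nrow = m^depth, ncol = m)
}

# brute-force BIC maximization over every structure
brute_force_best <- function(raw, depth, n, m) {
  max(vapply(enumerate_pcts(depth, m),
             function(p) bic_score(p, raw, n), 0))
}

random_sites <- function(n, width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = "")
  }, "")
}
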