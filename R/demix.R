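#' Fit a two-component PWM mixture to aligned sites
#'
#' Standard EM for a mixture of two product-multinomial (PWM) components,
#' used to test whether a predicted site set is better explained by two
#' distinct motifs. Responsibilities are initialized at random; the best of
#' `restarts` runs by final log-likelihood is returned. M-steps add a small
#' pseudocount to every cell so no column degenerates to zero.
#'
#' @param sites Character vector of aligned sites (>= 2).
#' @param restarts Number of random restarts (default 20).
#' @param tol Stop when the log-likelihood gain falls below this (default
#'   `1e-6`).
#' @param pseudocount Added to each weighted count in the M-step (default
#'   0.1).
#' @param max_iter Iteration cap per restart.
#' @param seed Optional integer seed.
#' @return A `pwm_mixture`: `weights` (length 2), `components` (list of two
#'   W x 4 probability matrices), `loglik`, `n_iter`.
#' @export
fit_two_pwm_mixture <- function(sites, restarts = 20L, tol = 1e-6,
                                pseudocount = 0.1, max_iter = 500L,
                                seed = NULL) {
  if (length(sites) < 2) abort("need at least two sites to fit a mixture")
  if (!is.null(seed)) set.seed(seed)
  M <- site_matrix(sites)
  n <- nrow(M)
  W <- ncol(M)
  # indicator matrices per symbol for fast weighted counts
  ind <- lapply(1:4, function(a) M == a)

  comp_loglik <- function(logp) {
    # n-vector of log P(site | component) for W x 4 log-prob matrix
    ll <- numeric(n)
    for (l in seq_len(W)) ll <- ll + logp[l, ][M[, l]]
    ll
  }

  run_em <- function() {
    r1 <- stats::runif(n)
    ll_old <- -Inf
    it <- 0L
    repeat {
      it <- it + 1L
      r <- cbind(r1, 1 - r1)
      w <- unname(colMeans(r))
      comps <- lapply(1:2, function(k) {
        p <- vapply(1:4, function(a) colSums(r[, k] * ind[[a]]), numeric(W))
        p <- p + pseudocount
        p / rowSums(p)
      })
      lw <- log(w)
      l1 <- lw[1] + comp_loglik(log(comps[[1]]))
      l2 <- lw[2] + comp_loglik(log(comps[[2]]))
      mx <- pmax(l1, l2)
      ll <- sum(mx + log(exp(l1 - mx) + exp(l2 - mx)))
      r1 <- exp(l1 - mx) / (exp(l1 - mx) + exp(l2 - mx))
      if (it >= max_iter || (is.finite(ll_old) && ll - ll_old < tol)) {
        return(list(weights = w, components = comps, loglik = ll, n_iter = it))
      }
      ll_old <- ll
    }
  }

  best <- NULL
  for (rs in seq_len(restarts)) {
    fit <- run_em()
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  best$components <- lapply(best$components, function(p) {
    colnames(p) <- DNA
    p
  })
  structure(best, class = "pwm_mixture")
}

#' @export
print.pwm_mixture <- function(x, ...) {
  cat("<pwm_mixture> weights", format(x$weights, digits = 4),
      "loglik", format(x$loglik, digits = 8), "\n")
  invisible(x)
}

#' Kullback-Leibler divergence (natural log)
#'
#' `sum_i p_i ln(p_i / q_i)`; terms with `p_i = 0` contribute zero. Errors
#' when `q` lacks support where `p` has mass.
#'
#' @param p,q Probability vectors of equal length.
#' @return Non-negative divergence.
#' @export
kld <- function(p, q) {
  if (length(p) != length(q)) abort("p and q must have equal length")
  nz <- p > 0
  if (any(q[nz] == 0)) abort("KLD undefined: q has zero mass where p > 0")
  sum(p[nz] * log(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence of one PWM column pair
#'
#' `w1 KLD(p1 || pbar) + w2 KLD(p2 || pbar)` with the mixture column
#' `pbar = w1 p1 + w2 p2`; bounded by `ln 2`.
#'
#' @param p1,p2 Probability vectors (one PWM column each).
#' @param w1,w2 Mixture weights (sum to 1).
#' @return Column divergence in `[0, ln 2]`.
#' @export
column_jsd <- function(p1, p2, w1, w2) {
  if (abs(w1 + w2 - 1) > 1e-8 || w1 < 0 || w2 < 0) {
    abort("weights must be non-negative and sum to 1")
  }
  pbar <- w1 * p1 + w2 * p2
  d <- 0
  if (w1 > 0) d <- d + w1 * kld(p1, pbar)
  if (w2 > 0) d <- d + w2 * kld(p2, pbar)
  d
}

#' Aggregated Jensen-Shannon divergence of a two-PWM mixture fit
#'
#' Sum of the per-column divergences over all motif positions; large values
#' indicate that the site set mixes two distinct motifs.
#'
#' @param fit A `pwm_mixture`.
#' @return Non-negative total divergence.
#' @export
motif_jsd <- function(fit) {
  W <- nrow(fit$components[[1]])
  sum(vapply(seq_len(W), function(j) {
    column_jsd(fit$components[[1]][j, ], fit$components[[2]][j, ],
               fit$weights[1], fit$weights[2])
  }, 0))
}

#' Categorize a data set by averaged motif divergence
#'
#' Averages the divergences obtained from predictions of several model
#' orders (typically 1 to 4) and assigns category "A" (single motif) when
#' the mean is strictly below the threshold, otherwise "B" (putative
#' mixture of motifs). The boundary value goes to "B".
#'
#' @param jsd_values Numeric vector of divergences (one per model order).
#' @param threshold Decision threshold (default 0.18).
#' @return `"A"` or `"B"`.
#' @export
categorize <- function(jsd_values, threshold = 0.18) {
  if (length(jsd_values) == 0) abort("need at least one divergence value")
  if (mean(jsd_values) < threshold) "A" else "B"
}
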