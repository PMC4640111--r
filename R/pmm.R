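#' fsNML conditional probability estimate
#'
#' The factorized sequential normalized maximum likelihood estimator for a
#' multinomial from counts `N_a`:
#' `theta_a = e(N_a) (N_a + 1) / sum_b e(N_b) (N_b + 1)` with
#' `e(N) = ((N + 1) / N)^N` and `e(0) = 1`. Hyperparameter-free, strictly
#' positive, and equal to the uniform distribution for all-zero counts.
#' `e(N)` is evaluated in log space so large counts do not overflow.
#'
#' @param counts Non-negative numeric vector of symbol counts.
#' @return Probability vector of the same length (sums to 1).
#' @examples
#' fsnml_estimate(c(1, 0, 0, 0))  # (4/7, 1/7, 1/7, 1/7)
#' @export
fsnml_estimate <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  le <- ifelse(counts > 0, counts * log1p(1 / counts), 0)
  lw <- le + log(counts + 1)
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Fit one motif position: PCT by BIC, parameters by fsNML
#'
#' Selects the exact BIC-optimal parsimonious context tree for the given
#' position from the context counts of the aligned sites, then estimates
#' one fsNML conditional probability vector per context. The effective
#' context depth at position `position` is `min(depth, position - 1)`.
#'
#' @param sites Character vector of aligned sites.
#' @param position Motif position (1-based).
#' @param depth Maximal context depth d.
#' @return List with `pct`, `theta` (contexts x 4 matrix), `score` (BIC),
#'   and `counts` (aggregated per-context counts).
#' @export
fit_position <- function(sites, position, depth) {
  if (length(sites) < 1) abort("cannot fit a motif position from an empty site set")
  M <- site_matrix(sites)
  fit_position_mat(M, position, depth)
}

fit_position_mat <- function(M, position, depth) {
  raw <- context_counts_mat(M, position, depth)
  deff <- min(depth, position - 1L)
  n <- nrow(M)
  opt <- maximize_bic(raw, deff, n, m = 4L)
  agg <- aggregate_counts(raw, opt$pct)
  theta <- t(apply(agg, 1, fsnml_estimate))
  colnames(theta) <- DNA
  list(pct = opt$pct, theta = theta, score = opt$score, counts = agg)
}

#' Fit a parsimonious Markov motif model from aligned sites
#'
#' One PCT and fsNML parameter set per position; the structure score is the
#' sum over positions of the per-position BIC scores (natural log). At
#' maximal depth 0 this reduces to a classical PWM with fsNML-smoothed
#' columns.
#'
#' @param sites Character vector of aligned sites (equal width).
#' @param order Maximal context depth d (0 = PWM).
#' @return A `pmm` object: fields `width`, `order`, `positions` (per
#'   position: `pct`, `theta`, `leaf_map`, `deff`, `score`), `score`
#'   (summed structure score) and `n` (number of training sites).
#' @export
fit_motif <- function(sites, order) {
  if (length(sites) < 1) abort("cannot fit a motif from an empty site set")
  M <- site_matrix(sites)
  fit_motif_mat(M, order)
}

fit_motif_mat <- function(M, order) {
  W <- ncol(M)
  positions <- lapply(seq_len(W), function(l) {
    f <- fit_position_mat(M, l, order)
    list(pct = f$pct, theta = f$theta, log_theta = log(f$theta),
         leaf_map = pct_leaf_map(f$pct),
         deff = f$pct$depth, score = f$score)
  })
  structure(
    list(width = W, order = as.integer(order), positions = positions,
         score = sum(vapply(positions, `[[`, 0, "score")), n = nrow(M)),
    class = "pmm"
  )
}

#' Construct a PWM motif model from a probability matrix
#'
#' Builds an order-0 `pmm` directly from given per-position nucleotide
#' probabilities (rows = positions, columns = A, C, G, T). Useful for
#' defining synthetic generating motifs.
#'
#' @param prob Numeric matrix, W x 4, rows summing to 1.
#' @return A `pmm` of order 0.
#' @export
pwm_motif <- function(prob) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 4) abort("a PWM needs 4 columns (A, C, G, T)")
  if (any(prob < 0) || any(abs(rowSums(prob) - 1) > 1e-8)) {
    abort("PWM rows must be probability vectors")
  }
  positions <- lapply(seq_len(nrow(prob)), function(l) {
    th <- matrix(prob[l, ], nrow = 1, dimnames = list(NULL, DNA))
    list(pct = pct_minimal(0L), theta = th, log_theta = log(th),
         leaf_map = 1L, deff = 0L, score = NA_real_)
  })
  structure(list(width = nrow(prob), order = 0L, positions = positions,
                 score = NA_real_, n = NA_integer_),
            class = "pmm")
}

# per-position maximal-context theta lookup helpers ------------------------

# context code of row i at position l from site matrix M (0 when deff = 0)
pos_codes <- function(M, l, deff) {
  if (deff == 0) return(rep(0L, nrow(M)))
  ctx_code(lapply(seq_len(deff), function(j) M[, l - j]))
}

#' Log-likelihood of sites under a motif model
#'
#' The PMM likelihood: per site, the sum over positions of
#' `log theta_{l, c(site), site_l}` where `c(site)` is the context of the
#' preceding symbols; for a set of sites, by default the total over members.
#'
#' @param model A `pmm` object.
#' @param sites Character vector of sites of width `model$width`.
#' @param per_site If `TRUE`, return one value per site instead of the sum.
#' @return Log-likelihood (natural log), scalar or vector.
#' @export
motif_log_likelihood <- function(model, sites, per_site = FALSE) {
  M <- site_matrix(sites)
  if (ncol(M) != model$width) abort("site width does not match model width")
  ll <- numeric(nrow(M))
  for (l in seq_len(model$width)) {
    p <- model$positions[[l]]
    code <- pos_codes(M, l, p$deff)
    leaf <- p$leaf_map[code + 1L]
    ll <- ll + p$log_theta[cbind(leaf, M[, l])]
  }
  if (per_site) ll else sum(ll)
}

# vectorized motif log-likelihood of every width-W window of an encoded
# sequence (forward orientation)
window_motif_scores <- function(model, x) {
  W <- model$width
  nv <- length(x) - W + 1L
  if (nv < 1) abort("sequence shorter than motif width")
  sc <- numeric(nv)
  for (l in seq_len(W)) {
    p <- model$positions[[l]]
    sym <- x[l:(l + nv - 1L)]
    if (p$deff == 0) {
      leaf <- rep.int(1L, nv)
    } else {
      code <- ctx_code(lapply(seq_len(p$deff), function(j) {
        x[(l - j):(l - j + nv - 1L)]
      }))
      leaf <- p$leaf_map[code + 1L]
    }
    sc <- sc + p$log_theta[cbind(leaf, sym)]
  }
  sc
}

#' Save / load a motif model as version-tagged JSON
#'
#' Persists width, order, every PCT and every conditional probability
#' vector; `pmm_read()` restores an equivalent model.
#'
#' @param model A `pmm` object.
#' @param path File path.
#' @return `path` invisibly (write); a `pmm` (read).
#' @export
pmm_write <- function(model, path) {
  obj <- list(
    format = "parsimotif-pmm", version = 1L,
    width = model$width, order = model$order,
    n = model$n, score = model$score,
    positions = lapply(model$positions, function(p) {
      list(pct = pct_to_list(p$pct), theta = unname(p$theta))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pmm_write
#' @export
pmm_read <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "parsimotif-pmm")) abort("not a parsimotif model file")
  positions <- lapply(obj$positions, function(p) {
    pct <- pct_from_list(p$pct)
    th <- if (is.matrix(p$theta)) p$theta
          else do.call(rbind, lapply(p$theta, unlist))
    colnames(th) <- DNA
    list(pct = pct, theta = th, log_theta = log(th),
         leaf_map = pct_leaf_map(pct), deff = pct$depth, score = NA_real_)
  })
  structure(list(width = as.integer(obj$width), order = as.integer(obj$order),
                 positions = positions,
                 score = if (is.null(obj$score)) NA_real_ else obj$score,
                 n = if (is.null(obj$n)) NA_integer_ else as.integer(obj$n)),
            class = "pmm")
}

#' @export
print.pmm <- function(x, ...) {
  cat("<pmm> width", x$width, "order", x$order)
  if (!is.na(x$score)) cat(" structure score", format(x$score, digits = 6))
  cat("\n")
  invisible(x)
}
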