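#' Fit a homogeneous flanking Markov model
#'
#' Estimates a homogeneous Markov model of the given order from pooled
#' counts over all sequences: conditional probabilities from all order-`h`
#' transition counts, and initial distributions (orders 0 .. h-1, used for
#' the first symbols of a segment) from pooled prefix counts. All counts get
#' add-one smoothing so short inputs yield proper distributions.
#'
#' @param data Sequence-set tibble.
#' @param order Markov order h >= 0 (default 2).
#' @return A `flanking_model`: fields `order`, `init` (list of `4^j x 4`
#'   probability matrices for j = 0 .. h-1) and `cond` (`4^h x 4`).
#' @export
fit_flanking <- function(data, order = 2L) {
  if (nrow(data) < 1) abort("cannot fit a flanking model from an empty sequence set")
  h <- as.integer(order)
  if (h < 0) abort("order must be >= 0")
  xs <- lapply(data$seq, encode_seq)

  count_level <- function(j, prefix_only) {
    # counts of symbol at a position given the j previous symbols
    cnt <- matrix(0L, nrow = 4L^j, ncol = 4L)
    for (x in xs) {
      L <- length(x)
      us <- if (prefix_only) {
        if (L >= j + 1L) j + 1L else integer(0)
      } else {
        if (L >= j + 1L) (j + 1L):L else integer(0)
      }
      for (u in us) {
        code <- if (j == 0) 0L else ctx_code(as.list(x[u - seq_len(j)]))
        cnt[code + 1L, x[u]] <- cnt[code + 1L, x[u]] + 1L
      }
    }
    cnt
  }

  init <- lapply(seq_len(h) - 1L, function(j) {
    cnt <- count_level(j, prefix_only = TRUE) + 1L  # add-one smoothing
    p <- cnt / rowSums(cnt)
    colnames(p) <- DNA
    p
  })
  cond_cnt <- count_level(h, prefix_only = FALSE) + 1L
  cond <- cond_cnt / rowSums(cond_cnt)
  colnames(cond) <- DNA
  structure(list(order = h, init = init, cond = cond,
                 log_init = lapply(init, log), log_cond = log(cond)),
            class = "flanking_model")
}

#' Build a uniform flanking model
#'
#' All conditional and initial distributions uniform over A, C, G, T;
#' convenient as the simplest synthetic background.
#'
#' @param order Markov order h.
#' @return A `flanking_model`.
#' @export
uniform_flanking <- function(order = 2L) {
  h <- as.integer(order)
  u <- function(nr) matrix(0.25, nrow = nr, ncol = 4L,
                           dimnames = list(NULL, DNA))
  init <- lapply(seq_len(h) - 1L, function(j) u(4L^j))
  cond <- u(4L^h)
  structure(list(order = h, init = init, cond = cond,
                 log_init = lapply(init, log), log_cond = log(cond)),
            class = "flanking_model")
}

# log-probability terms of an encoded segment scored from a fresh start
flank_terms <- function(fm, x) {
  L <- length(x)
  if (L == 0) return(numeric(0))
  h <- fm$order
  t <- numeric(L)
  for (u in seq_len(min(h, L))) {
    j <- u - 1L
    code <- if (j == 0) 0L else ctx_code(as.list(x[u - seq_len(j)]))
    t[u] <- fm$log_init[[j + 1L]][code + 1L, x[u]]
  }
  if (L >= h + 1L) {
    us <- (h + 1L):L
    code <- if (h == 0) rep(0L, length(us))
            else ctx_code(lapply(seq_len(h), function(j) x[us - j]))
    t[us] <- fm$log_cond[cbind(code + 1L, x[us])]
  }
  t
}

#' Log-probability of a segment under the flanking model
#'
#' Each segment is scored from a fresh start: its first `min(order, length)`
#' symbols use the initial distributions, later symbols the order-`h`
#' conditionals. The empty segment has probability 1 (log 0).
#'
#' @param model A `flanking_model`.
#' @param segment DNA string (may be empty).
#' @return Log-probability (natural log).
#' @export
flanking_log_prob <- function(model, segment) {
  if (nchar(segment) == 0) return(0)
  sum(flank_terms(model, encode_seq(segment)))
}

#' Combine motif and flanking models into an OOPS model
#'
#' The one-occurrence-per-sequence (OOPS) model: each sequence carries
#' exactly one motif instance of width W at an unknown start position and
#' strand; the remainder is generated by the homogeneous flanking model.
#'
#' @param motif A `pmm`.
#' @param flanking A `flanking_model`.
#' @return An `oops_model`.
#' @export
oops_model <- function(motif, flanking) {
  stopifnot(inherits(motif, "pmm"), inherits(flanking, "flanking_model"))
  structure(list(motif = motif, flanking = flanking, width = motif$width),
            class = "oops_model")
}

# per-sequence scan: all conditional and joint log-likelihoods ------------

# suffix fresh-start scores S[t] = log P_f(x[t..L]) for t = 1..L+1
suffix_flank_scores <- function(fm, x) {
  L <- length(x)
  h <- fm$order
  S <- numeric(L + 1L)  # S[L+1] = 0
  if (L == 0) return(S)
  # conditional term g[u] for u >= h+1 (full order-h context), suffix-summed
  if (L >= h + 1L) {
    us <- (h + 1L):L
    code <- if (h == 0) rep(0L, length(us))
            else ctx_code(lapply(seq_len(h), function(j) x[us - j]))
    g <- fm$log_cond[cbind(code + 1L, x[us])]
    G <- rev(cumsum(rev(g)))  # G[t] = sum over u >= t + h, t = 1..L-h
    S[seq_len(L - h)] <- G
  }
  # initial-distribution terms: the j-th symbol of the segment starting at t
  # (j = 0 .. h-1) is scored with the order-j initial distribution
  for (j in seq_len(h) - 1L) {
    ts <- seq_len(L - j)  # segments long enough to contain symbol t + j
    us <- ts + j
    code <- if (j == 0) rep(0L, length(us))
            else ctx_code(lapply(seq_len(j), function(jj) x[us - jj]))
    S[ts] <- S[ts] + fm$log_init[[j + 1L]][cbind(code + 1L, x[us])]
  }
  S
}

# prefix scores P[v] = log P_f(x[1..v-1]) for v = 1..L+1
prefix_flank_scores <- function(fm, x) {
  c(0, cumsum(flank_terms(fm, x)))
}

# For one encoded sequence: matrices of conditional log-likelihoods per
# (start, strand) plus the joint log-likelihood per start (OOPS model with
# uniform position and strand priors).
scan_sequence <- function(model, x, flank_cache = NULL) {
  W <- model$width
  L <- length(x)
  if (L < W) abort("sequence shorter than motif width")
  nv <- L - W + 1L
  if (is.null(flank_cache)) {
    fm <- model$flanking
    P <- prefix_flank_scores(fm, x)     # P[v] = prefix up to v-1
    S <- suffix_flank_scores(fm, x)     # S[t] = suffix from t
    flank <- P[seq_len(nv)] + S[seq_len(nv) + W]
  } else {
    flank <- flank_cache
  }
  mF <- window_motif_scores(model$motif, x)
  mR <- rev(window_motif_scores(model$motif, int_revcomp(x)))
  condF <- flank + mF
  condR <- flank + mR
  mx <- pmax(condF, condR)
  joint <- -log(nv) - log(2) + mx + log(exp(condF - mx) + exp(condR - mx))
  list(condF = condF, condR = condR, joint = joint, n_windows = nv)
}

#' Conditional log-likelihood of a sequence given latent variables
#'
#' The factorized OOPS conditional: flanking score of the prefix before the
#' motif window, flanking score of the suffix after it (each from a fresh
#' start), and the motif score of the window (reverse-complemented first for
#' strand "R").
#'
#' @param model An `oops_model`.
#' @param seq DNA string.
#' @param start Motif start position v (1-based).
#' @param strand `"F"` or `"R"`.
#' @return Log-likelihood (natural log).
#' @export
conditional_log_likelihood <- function(model, seq, start, strand) {
  x <- encode_seq(seq)
  W <- model$width
  L <- length(x)
  if (L < W) abort("sequence shorter than motif width")
  if (start < 1 || start > L - W + 1) abort("start position out of range")
  sc <- scan_sequence(model, x)
  if (identical(strand, "F")) sc$condF[start]
  else if (identical(strand, "R")) sc$condR[start]
  else abort("strand must be 'F' or 'R'")
}

#' Joint log-likelihood of a sequence and a motif start position
#'
#' Sums the two strand terms, each weighted by the uniform strand prior 1/2,
#' and multiplies by the uniform position prior 1/(L - W + 1); computed
#' stably in log space.
#'
#' @inheritParams conditional_log_likelihood
#' @return Log of `P(x, v = start)` under the OOPS model.
#' @export
joint_log_likelihood <- function(model, seq, start) {
  x <- encode_seq(seq)
  sc <- scan_sequence(model, x)
  if (start < 1 || start > sc$n_windows) abort("start position out of range")
  sc$joint[start]
}

# OOPS marginal log P(x) = logsumexp over starts of the joint
oops_marginal <- function(model, x) {
  logsumexp(scan_sequence(model, x)$joint)
}

# full-sequence log-probability under the flanking model alone
flank_sequence_loglik <- function(fm, x) {
  sum(flank_terms(fm, x))
}
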