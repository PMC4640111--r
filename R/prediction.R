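#' Scan sequences with a fitted OOPS model
#'
#' Computes the joint log-likelihood `log P(x_i, v = j)` (strand terms
#' summed, uniform position and strand priors) for every valid start
#' position of every sequence.
#'
#' @param model An `oops_model`.
#' @param data Sequence-set tibble.
#' @return Tibble with columns `id`, `start`, `loglik`; one row per valid
#'   window.
#' @export
likelihood_scan <- function(model, data) {
  res <- lapply(seq_len(nrow(data)), function(i) {
    sc <- scan_sequence(model, encode_seq(data$seq[i]))
    tibble(id = data$id[i], start = seq_len(sc$n_windows), loglik = sc$joint)
  })
  dplyr::bind_rows(res)
}

#' Significance threshold from negative-data likelihoods
#'
#' Derives the prediction threshold Z from the empirical distribution of
#' window log-likelihoods on motif-free (negative) sequences. Under the
#' default upper-tail reading, Z is the smallest observed value such that
#' the fraction of values strictly greater than Z is at most `alpha`, so on
#' the negatives themselves at most a fraction `alpha` of windows would be
#' predicted. The literal lower-quantile reading (`tail = "lower"`) is kept
#' as a switch for completeness; it admits nearly every window and is not
#' the default.
#'
#' @param values Numeric vector of window log-likelihoods (nonempty).
#' @param alpha Tail mass (default `1e-4`).
#' @param tail `"upper"` (default) or `"lower"`.
#' @return The threshold Z on the log scale.
#' @export
threshold_from_negatives <- function(values, alpha = 1e-4,
                                     tail = c("upper", "lower")) {
  if (length(values) == 0) abort("cannot derive a threshold from an empty list")
  tail <- match.arg(tail)
  n <- length(values)
  u <- sort(unique(values))
  if (tail == "lower") {
    # smallest value with at most alpha mass strictly below it
    below <- c(0, cumsum(tabulate(match(sort(values), u), nbins = length(u))))
    ok <- which(below[seq_along(u)] / n <= alpha)
    return(u[max(ok)])
  }
  cnt <- tabulate(match(values, u), nbins = length(u))
  greater <- rev(cumsum(rev(cnt))) - cnt  # strictly greater than u[k]
  ok <- which(greater / n <= alpha)
  u[min(ok)]
}

#' Predict binding sites above a threshold
#'
#' Reports every window of the positive sequences whose joint
#' log-likelihood exceeds `threshold`. The strand of each record is the one
#' whose conditional term dominates, and reverse-strand windows are
#' reverse-complemented so the returned `site` column is an aligned site
#' set. Overlapping windows are all reported.
#'
#' @param model An `oops_model`.
#' @param data Sequence-set tibble (positives).
#' @param threshold Log-scale threshold Z (from
#'   [threshold_from_negatives()]).
#' @return Tibble `id`, `start`, `strand`, `site`, `loglik`, sorted by
#'   sequence and start.
#' @export
predict_sites <- function(model, data, threshold) {
  if (is.na(threshold) || isTRUE(threshold == Inf)) {
    abort("threshold must be a number or -Inf")
  }
  W <- model$width
  res <- lapply(seq_len(nrow(data)), function(i) {
    x <- encode_seq(data$seq[i])
    sc <- scan_sequence(model, x)
    keep <- which(sc$joint > threshold)
    if (length(keep) == 0) return(NULL)
    strand <- ifelse(sc$condF[keep] >= sc$condR[keep], "F", "R")
    site <- substr(rep(data$seq[i], length(keep)), keep, keep + W - 1L)
    rev_idx <- strand == "R"
    if (any(rev_idx)) site[rev_idx] <- reverse_complement(site[rev_idx])
    tibble(id = data$id[i], start = keep, strand = strand,
           site = site, loglik = sc$joint[keep])
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), start = integer(), strand = character(),
                  site = character(), loglik = numeric())
  }
  out
}
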