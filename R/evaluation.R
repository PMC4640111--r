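#' Classification improvement score
#'
#' `psi(auc0, aucd) = log2((1 - auc0) / (1 - aucd))`: the base-2 log of the
#' ratio of distances to perfect classification between the order-0 (PWM)
#' model and the order-d model. A value of 1 means the dependency model
#' halves the distance to a perfect classifier; antisymmetric in its
#' arguments.
#'
#' @param auc0 AUC of the order-0 model, in `[0, 1)`.
#' @param aucd AUC of the order-d model, in `[0, 1)`.
#' @return The improvement score (positive iff `aucd > auc0`).
#' @examples
#' psi(0.9, 0.95)  # 1: distance to perfect classification halved
#' @export
psi <- function(auc0, aucd) {
  if (any(auc0 < 0 | auc0 >= 1) || any(aucd < 0 | aucd >= 1)) {
    abort("AUC values must lie in [0, 1); an AUC of 1 gives an infinite score")
  }
  log2((1 - auc0) / (1 - aucd))
}

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney form: the fraction of (positive, negative) score pairs won
#' by the positive, ties counting one half.
#'
#' @param pos_scores,neg_scores Numeric score vectors (both nonempty).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  np <- length(pos_scores)
  nn <- length(neg_scores)
  if (np == 0 || nn == 0) abort("both classes need at least one score")
  r <- rank(c(pos_scores, neg_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Assign sequences to cross-validation folds
#'
#' Positives and negatives are split independently into `k` near-equal
#' folds by a seeded shuffle; every sequence lands in exactly one test
#' fold.
#'
#' @param pos,neg Sequence-set tibbles.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed.
#' @return Tibble with columns `id`, `class` ("pos"/"neg") and `fold`.
#' @export
cv_split <- function(pos, neg, k = 10L, seed = NULL) {
  if (nrow(pos) < k || nrow(neg) < k) {
    abort("need at least k sequences per class for k folds")
  }
  if (!is.null(seed)) set.seed(seed)
  assign_folds <- function(n) sample(rep_len(seq_len(k), n))
  dplyr::bind_rows(
    tibble(id = pos$id, class = "pos", fold = assign_folds(nrow(pos))),
    tibble(id = neg$id, class = "neg", fold = assign_folds(nrow(neg)))
  )
}

#' Fragment-based classification of positives vs negatives
#'
#' Evaluates motif models of several maximal orders by how well a
#' generative two-class classifier separates motif-containing from
#' background sequences, with k-fold cross-validation. Per fold: the
#' flanking model is fitted on the union of the training positives and
#' negatives; a de novo motif discovery is run on the training positives
#' for each order (flanking model held fixed); each test sequence is scored
#' by the log-likelihood ratio of the OOPS model (motif marginalized over
#' start and strand, or maximized with `site_aggregation = "max"`) to the
#' homogeneous flanking-only model. AUC is computed per fold and order, and
#' the improvement score `psi` relative to order 0 when order 0 is present.
#'
#' @param pos,neg Sequence-set tibbles.
#' @param orders Integer vector of maximal model orders (e.g. `c(0, 2)`).
#' @param width Motif width W.
#' @param k Number of folds.
#' @param flank_order Flanking model order (default 2).
#' @param restarts,min_iter,patience Discovery control parameters per fold.
#' @param site_aggregation `"sum"` (marginalize over windows; default) or
#'   `"max"`.
#' @param seed Integer master seed for folds and discoveries.
#' @return Tibble with columns `fold`, `order`, `auc`, `psi`.
#' @export
fragment_classify <- function(pos, neg, orders, width, k = 10L,
                              flank_order = 2L, restarts = 3L,
                              min_iter = 20L, patience = 5L,
                              site_aggregation = c("sum", "max"),
                              seed = NULL) {
  site_aggregation <- match.arg(site_aggregation)
  if (!is.null(seed)) set.seed(seed)
  folds <- cv_split(pos, neg, k = k)
  run_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                 k * length(orders)), nrow = k)

  score_set <- function(model, fm, data) {
    vapply(data$seq, function(s) {
      x <- encode_seq(s)
      cls <- if (site_aggregation == "sum") oops_marginal(model, x)
             else max(scan_sequence(model, x)$joint)
      cls - flank_sequence_loglik(fm, x)
    }, 0, USE.NAMES = FALSE)
  }

  rows <- list()
  for (f in seq_len(k)) {
    pos_test <- pos[pos$id %in% folds$id[folds$class == "pos" & folds$fold == f], ]
    neg_test <- neg[neg$id %in% folds$id[folds$class == "neg" & folds$fold == f], ]
    pos_train <- pos[!pos$id %in% pos_test$id, ]
    neg_train <- neg[!neg$id %in% neg_test$id, ]
    fm <- fit_flanking(dplyr::bind_rows(pos_train, neg_train),
                       order = flank_order)
    for (oi in seq_along(orders)) {
      disc <- discover(pos_train, width = width, order = orders[oi],
                       flanking = fm, restarts = restarts,
                       min_iter = min_iter, patience = patience,
                       seed = run_seeds[f, oi])
      a <- auc(score_set(disc$model, fm, pos_test),
               score_set(disc$model, fm, neg_test))
      rows[[length(rows) + 1L]] <- tibble(fold = f, order = orders[oi], auc = a)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (0 %in% orders) {
    base <- out[out$order == 0, c("fold", "auc")]
    names(base)[2] <- "auc0"
    out <- dplyr::left_join(out, base, by = "fold")
    out$psi <- ifelse(out$auc < 1 & out$auc0 < 1, psi(out$auc0, out$auc), NA_real_)
    out$auc0 <- NULL
  } else {
    out$psi <- NA_real_
  }
  out
}

#' Pairwise Wilcoxon signed-rank comparison of model orders
#'
#' Delegates to [stats::wilcox.test()] (paired, two-sided, exact null for
#' small fold counts) on the per-fold AUC vectors of every pair of orders.
#'
#' @param auc_tbl Tibble with columns `fold`, `order`, `auc` (as returned
#'   by [fragment_classify()]), or a named list of equal-length AUC
#'   vectors.
#' @return Tibble `order1`, `order2`, `mean_diff` (mean AUC of `order1`
#'   minus `order2`) and `p_value`.
#' @export
compare_orders <- function(auc_tbl) {
  if (is.data.frame(auc_tbl)) {
    lst <- split(auc_tbl$auc[order(auc_tbl$fold)],
                 auc_tbl$order[order(auc_tbl$fold)])
  } else {
    lst <- auc_tbl
  }
  if (length(unique(lengths(lst))) != 1) {
    abort("AUC vectors must have equal length (paired folds)")
  }
  nm <- names(lst)
  rows <- list()
  for (i in seq_along(lst)) {
    for (j in seq_along(lst)) {
      if (i >= j) next
      d <- lst[[i]] - lst[[j]]
      p <- if (all(d == 0)) 1 else
        suppressWarnings(stats::wilcox.test(lst[[i]], lst[[j]],
                                            paired = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- tibble(
        order1 = nm[i], order2 = nm[j],
        mean_diff = mean(d), p_value = p
      )
    }
  }
  dplyr::bind_rows(rows)
}
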