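#' Sequence logo matrix from aligned sites
#'
#' Per position: nucleotide relative frequencies, the information content
#' `IC = 2 + sum_a p_a log2 p_a` in bits (0 log 0 = 0), and the stack
#' height `p_a * IC` of each letter. No small-sample correction is applied.
#'
#' @param sites Character vector of aligned sites (nonempty).
#' @return A tibble of class `logo_matrix` with columns `position`,
#'   `symbol`, `freq`, `ic`, `height` (long format; 4 rows per position).
#' @export
logo_matrix <- function(sites) {
  if (length(sites) == 0) abort("cannot compute a logo from an empty site set")
  M <- site_matrix(sites)
  W <- ncol(M)
  rows <- lapply(seq_len(W), function(l) {
    p <- tabulate(M[, l], nbins = 4L) / nrow(M)
    ic <- 2 + sum(ifelse(p > 0, p * log2(p), 0))
    tibble(position = l, symbol = DNA, freq = p, ic = ic, height = p * ic)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("logo_matrix", class(out))
  out
}

#' Conditional sequence logo at one motif position
#'
#' For each context of the fitted PCT at `position`: the conditional
#' nucleotide frequencies of the sites whose preceding symbols fall in that
#' context, the fraction of sites it covers, and a display width class.
#' Contexts covering more than 50 % of the sites get full width (1),
#' contexts covering 5 % to 50 % half width (0.5), and rare contexts below
#' 5 % quarter width (0.25); the boundaries map to the middle class.
#'
#' @param model A fitted `pmm`.
#' @param sites Aligned sites the model was fitted on (or compatible).
#' @param position Motif position (1-based).
#' @return A tibble of class `conditional_logo` with columns `context`
#'   (index), `members` (context sequences, comma-joined), `coverage`,
#'   `width_class`, `symbol`, `freq`.
#' @export
conditional_logo <- function(model, sites, position) {
  if (position < 1 || position > model$width) abort("position out of range")
  M <- site_matrix(sites)
  if (ncol(M) != model$width) abort("site width does not match model width")
  p <- model$positions[[position]]
  code <- pos_codes(M, position, p$deff)
  leaf <- p$leaf_map[code + 1L]
  n_ctx <- nrow(p$theta)
  members <- vapply(pct_contexts(p$pct), paste, "", collapse = ",")
  rows <- lapply(seq_len(n_ctx), function(ci) {
    idx <- leaf == ci
    cov <- mean(idx)
    freq <- if (any(idx)) tabulate(M[idx, position], nbins = 4L) / sum(idx)
            else rep(0, 4)
    wc <- if (cov > 0.5) 1 else if (cov >= 0.05) 0.5 else 0.25
    tibble(context = ci, members = members[ci], coverage = cov,
           width_class = wc, symbol = DNA, freq = freq)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("conditional_logo", class(out))
  out
}

#' Plot a sequence logo
#'
#' Letters are drawn as stacked text scaled by `height` (information
#' content times frequency), the standard logo layout.
#'
#' @param object A `logo_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.logo_matrix <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$position, .data$freq)
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$position),
    ymax = cumsum(.data$height), ymin = .data$ymax - .data$height
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_text(
      ggplot2::aes(x = .data$position, y = (.data$ymin + .data$ymax) / 2,
                   label = .data$symbol, colour = .data$symbol,
                   size = .data$height),
      fontface = "bold", show.legend = FALSE
    ) +
    ggplot2::scale_size_continuous(range = c(0, 8)) +
    ggplot2::scale_colour_manual(values = c(A = "#109648", C = "#255C99",
                                            G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = unique(df$position)) +
    ggplot2::labs(x = "position", y = "bits") +
    ggplot2::ylim(0, 2) +
    ggplot2::theme_minimal()
}

#' Plot a conditional sequence logo
#'
#' One nucleotide stack per context, with bar width scaled by the context's
#' width class (1, 1/2 or 1/4 of full width by coverage).
#'
#' @param object A `conditional_logo`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conditional_logo <- function(object, ...) {
  df <- dplyr::arrange(as_tibble(object), .data$context, .data$freq)
  df <- dplyr::mutate(
    dplyr::group_by(df, .data$context),
    ymax = cumsum(.data$freq), ymin = .data$ymax - .data$freq
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(xmin = .data$context - 0.45 * .data$width_class,
                   xmax = .data$context + 0.45 * .data$width_class,
                   ymin = .data$ymin, ymax = .data$ymax,
                   fill = .data$symbol),
      colour = "grey30", linewidth = 0.2
    ) +
    ggplot2::scale_fill_manual(values = c(A = "#109648", C = "#255C99",
                                          G = "#F7B32B", T = "#D62839")) +
    ggplot2::scale_x_continuous(breaks = unique(df$context),
                                labels = unique(df$members)) +
    ggplot2::labs(x = "context", y = "conditional frequency") +
    ggplot2::theme_minimal()
}
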