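#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a parsimonious Markov motif model
#'
#' One row per (position, context, symbol) with the fsNML conditional
#' probability; `context` lists the context sequences of the leaf,
#' comma-joined ("" at effective depth 0).
#'
#' @param x A `pmm`.
#' @param ... Unused.
#' @return A tibble with columns `position`, `context`, `symbol`, `prob`.
#' @export
tidy.pmm <- function(x, ...) {
  rows <- lapply(seq_len(x$width), function(l) {
    p <- x$positions[[l]]
    members <- vapply(pct_contexts(p$pct), paste, "", collapse = ",")
    tibble(
      position = l,
      context = rep(members, each = 4L),
      symbol = rep(DNA, times = length(members)),
      prob = as.vector(t(p$theta))
    )
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.pmm
#' @export
glance.pmm <- function(x, ...) {
  n_params <- sum(vapply(x$positions, function(p) 3L * nrow(p$theta), 0L))
  tibble(width = x$width, order = x$order, score = x$score,
         n_contexts = sum(vapply(x$positions, function(p) nrow(p$theta), 0L)),
         n_params = n_params, n_sites = x$n)
}

#' Tidy a motif discovery result
#'
#' Returns the best latent configuration (one row per sequence).
#'
#' @param x A `motif_discovery`.
#' @param ... Unused.
#' @return Tibble `id`, `start`, `strand`.
#' @export
tidy.motif_discovery <- function(x, ...) x$latents

#' @rdname tidy.motif_discovery
#' @export
glance.motif_discovery <- function(x, ...) {
  tibble(width = x$width, order = x$order, score = x$score,
         restart = x$restart, iteration = x$iteration,
         n_restarts = length(x$restart_scores))
}

#' Tidy a two-PWM mixture fit
#'
#' @param x A `pwm_mixture`.
#' @param ... Unused.
#' @return Tibble `component`, `weight`, `position`, `symbol`, `prob`.
#' @export
tidy.pwm_mixture <- function(x, ...) {
  rows <- lapply(1:2, function(k) {
    p <- x$components[[k]]
    tibble(component = k, weight = x$weights[k],
           position = rep(seq_len(nrow(p)), each = 4L),
           symbol = rep(DNA, times = nrow(p)),
           prob = as.vector(t(p)))
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy.pwm_mixture
#' @export
glance.pwm_mixture <- function(x, ...) {
  tibble(weight1 = x$weights[1], weight2 = x$weights[2],
         loglik = x$loglik, n_iter = x$n_iter, jsd = motif_jsd(x))
}
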