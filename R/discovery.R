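#' Random initial latent configuration
#'
#' Start positions uniform on the valid range of each sequence, strands
#' uniform on F/R. Reproducible under a seed.
#'
#' @param data Sequence-set tibble.
#' @param width Motif width W.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return Latent-configuration tibble (`id`, `start`, `strand`).
#' @export
init_latents <- function(data, width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- nchar(data$seq)
  short <- L < width
  if (any(short)) {
    abort(paste0("sequence(s) shorter than the motif width: ",
                 paste(utils::head(data$id[short], 5), collapse = ", ")))
  }
  nv <- L - width + 1L
  start <- vapply(nv, function(n) sample.int(n, 1L), 1L)
  strand <- sample(c("F", "R"), nrow(data), replace = TRUE)
  latent_config(data$id, start, strand)
}

#' Sample a latent configuration from the current model
#'
#' For each sequence independently, draws `(start, strand)` from the
#' categorical distribution proportional to the exponentiated conditional
#' log-likelihood over all valid windows and both strands (normalized in
#' log space). This is the stochastic step of the discovery algorithm,
#' related to Gibbs motif sampling.
#'
#' @param model An `oops_model`.
#' @param data Sequence-set tibble.
#' @param seed Optional integer seed.
#' @return Latent-configuration tibble.
#' @export
sample_latents <- function(model, data, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sample_latents_int(model, lapply(data$seq, encode_seq), data$id)
}

# integer site matrix straight from encoded sequences and latents
site_matrix_int <- function(xs, start, strand, width) {
  n <- length(xs)
  M <- matrix(0L, nrow = n, ncol = width)
  for (i in seq_len(n)) {
    w <- xs[[i]][start[i]:(start[i] + width - 1L)]
    M[i, ] <- if (strand[i] == "R") int_revcomp(w) else w
  }
  M
}

# per-sequence flank window scores (prefix + suffix), reusable across
# iterations of the discovery loop since the flanking model is fixed
flank_window_caches <- function(fm, xs, width) {
  lapply(xs, function(x) {
    nv <- length(x) - width + 1L
    P <- prefix_flank_scores(fm, x)
    S <- suffix_flank_scores(fm, x)
    P[seq_len(nv)] + S[seq_len(nv) + width]
  })
}

# internal worker on pre-encoded sequences
sample_latents_int <- function(model, xs, ids, caches = NULL) {
  n <- length(xs)
  start <- integer(n)
  strand <- character(n)
  for (i in seq_len(n)) {
    sc <- scan_sequence(model, xs[[i]], flank_cache = caches[[i]])
    ll <- c(sc$condF, sc$condR)
    p <- exp(ll - max(ll))
    k <- sample.int(length(p), 1L, prob = p)
    nv <- sc$n_windows
    if (k <= nv) {
      start[i] <- k; strand[i] <- "F"
    } else {
      start[i] <- k - nv; strand[i] <- "R"
    }
  }
  latent_config(ids, start, strand)
}

#' De novo motif discovery by stochastic model selection
#'
#' Seeks the latent variable configuration (per-sequence start position and
#' strand) that maximizes the summed per-position BIC structure score of the
#' parsimonious Markov motif model fitted to the implied binding sites.
#' Each restart initializes latents at random and then alternates: fit the
#' motif (exact BIC-optimal PCTs, fsNML parameters) from the current sites;
#' record the structure score; resample latents from the current OOPS model.
#' A restart runs at least `min_iter` iterations and stops once the score
#' has not improved during the last `patience` iterations. The best
#' (score, latents) over all iterations and restarts wins, and the final
#' model is refit exactly from the best latents.
#'
#' The flanking model is estimated once from the input data (or supplied)
#' and held fixed; the objective involves only the motif structure score.
#'
#' @param data Sequence-set tibble of motif-containing (positive) sequences.
#' @param width Motif width W.
#' @param order Maximal context depth d of the motif model.
#' @param flanking Optional prefit `flanking_model`; default fits an
#'   order-`flank_order` model on `data`.
#' @param flank_order Flanking model order when `flanking` is `NULL`.
#' @param restarts Number of independent restarts R.
#' @param min_iter Minimum iterations T per restart.
#' @param patience Stop after this many iterations without improvement (T').
#' @param seed Integer master seed; per-restart streams are derived from it
#'   so runs are reproducible and restart-order independent.
#' @return A `motif_discovery` object: `model` (an `oops_model`), `motif`
#'   (the `pmm`), `latents`, `score`, `restart`, `iteration`, and the
#'   per-restart best scores.
#' @export
discover <- function(data, width, order,
                     flanking = NULL, flank_order = 2L,
                     restarts = 10L, min_iter = 50L, patience = 10L,
                     seed = NULL) {
  if (restarts < 1 || min_iter < 1 || patience < 1) {
    abort("restarts, min_iter and patience must all be >= 1")
  }
  if (any(nchar(data$seq) < width)) {
    abort("all sequences must be at least as long as the motif width")
  }
  if (is.null(flanking)) flanking <- fit_flanking(data, order = flank_order)
  xs <- lapply(data$seq, encode_seq)
  caches <- flank_window_caches(flanking, xs, width)
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max - 1L, restarts)
  tol <- 1e-9

  best <- list(score = -Inf, latents = NULL, restart = NA_integer_,
               iteration = NA_integer_)
  restart_scores <- numeric(restarts)
  for (r in seq_len(restarts)) {
    set.seed(restart_seeds[r])
    lat <- init_latents(data, width)
    r_best <- -Inf
    last_improve <- 0L
    t <- 0L
    repeat {
      t <- t + 1L
      motif <- fit_motif_mat(site_matrix_int(xs, lat$start, lat$strand, width),
                             order)
      if (motif$score > r_best + tol) {
        r_best <- motif$score
        last_improve <- t
        if (motif$score > best$score + tol) {
          best <- list(score = motif$score, latents = lat,
                       restart = r, iteration = t)
        }
      }
      if (t >= min_iter && (t - last_improve) >= patience) break
      lat <- sample_latents_int(oops_model(motif, flanking), xs, data$id,
                                caches = caches)
    }
    restart_scores[r] <- r_best
  }

  sites <- extract_sites(data, best$latents, width)
  motif <- fit_motif(sites, order)
  structure(
    list(model = oops_model(motif, flanking), motif = motif,
         latents = best$latents, score = motif$score,
         restart = best$restart, iteration = best$iteration,
         restart_scores = restart_scores,
         width = as.integer(width), order = as.integer(order)),
    class = "motif_discovery"
  )
}

#' @export
print.motif_discovery <- function(x, ...) {
  cat("<motif_discovery> width", x$width, "order", x$order,
      "structure score", format(x$score, digits = 8),
      "\n  best found in restart", x$restart, "iteration", x$iteration, "\n")
  invisible(x)
}
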