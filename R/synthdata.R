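#' Sample aligned sites from a motif model
#'
#' Generative use of the parsimonious Markov motif model: per position, a
#' symbol is drawn from the conditional probability vector of the context
#' matching the already-sampled prefix.
#'
#' @param model A `pmm`.
#' @param n Number of sites.
#' @param seed Optional integer seed.
#' @return Character vector of `n` sites of width `model$width`.
#' @export
sample_motif_sites <- function(model, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- model$width
  M <- matrix(0L, nrow = n, ncol = W)
  for (l in seq_len(W)) {
    p <- model$positions[[l]]
    code <- pos_codes(M, l, p$deff)
    leaf <- p$leaf_map[code + 1L]
    # draw per distinct leaf to keep vectorized
    for (ci in unique(leaf)) {
      idx <- which(leaf == ci)
      M[idx, l] <- sample.int(4L, length(idx), replace = TRUE,
                              prob = p$theta[ci, ])
    }
  }
  apply(M, 1, function(r) paste(DNA[r], collapse = ""))
}

# sample n background sequences of given lengths from a flanking model
sample_background <- function(fm, lengths) {
  h <- fm$order
  vapply(lengths, function(L) {
    x <- integer(L)
    for (u in seq_len(L)) {
      j <- min(u - 1L, h)
      code <- if (j == 0) 0L else ctx_code(as.list(x[u - seq_len(j)]))
      pr <- if (j < h) fm$init[[j + 1L]][code + 1L, ] else fm$cond[code + 1L, ]
      x[u] <- sample.int(4L, 1L, prob = pr)
    }
    decode_seq(x)
  }, "")
}

#' Motif model presets for synthetic benchmarks
#'
#' * `"pwm"`: an order-0 motif with a random consensus; each position puts
#'   probability `strength` on the consensus symbol and spreads the rest
#'   uniformly.
#' * `"tf_pwm"`: an order-0 motif with the information-content profile of a
#'   typical transcription factor: a strongly conserved core flanked by
#'   weakly informative positions (consensus probabilities drawn from
#'   0.7–0.95 in the core and 0.3–0.5 in the flanks). Default width 20.
#' * `"order2"`: a consensus head as in `"pwm"`, then two positions with
#'   uniform nucleotide distributions, then two positions that each depend
#'   on the symbol two back (skipping one position) through a maximal
#'   depth-2 PCT, placing probability `strength` on a context-determined
#'   symbol. Because the referenced positions are uniform, the dependent
#'   positions have flat marginals: genuine second-order intra-motif
#'   dependencies that a PWM cannot express at all.
#'
#' @param name `"pwm"` or `"order2"`.
#' @param width Motif width.
#' @param strength Probability mass on the favored symbol (default 0.9).
#' @param seed Optional seed for the random consensus.
#' @return A `pmm` usable as a generating motif.
#' @export
motif_preset <- function(name = c("pwm", "tf_pwm", "order2"), width = 8L,
                         strength = 0.9, seed = NULL) {
  name <- match.arg(name)
  if (name == "tf_pwm" && missing(width)) width <- 20L
  if (!is.null(seed)) set.seed(seed)
  spread <- (1 - strength) / 3
  consensus <- sample.int(4L, width, replace = TRUE)
  row_for <- function(a) {
    r <- rep(spread, 4)
    r[a] <- strength
    r
  }
  if (name == "pwm") {
    prob <- t(vapply(consensus, row_for, numeric(4)))
    return(pwm_motif(prob))
  }
  if (name == "tf_pwm") {
    flank <- max(1L, width %/% 3L)
    s <- c(stats::runif(flank, 0.3, 0.5),
           stats::runif(width - 2L * flank, 0.7, 0.95),
           stats::runif(flank, 0.3, 0.5))
    prob <- t(vapply(seq_len(width), function(l) {
      r <- rep((1 - s[l]) / 3, 4)
      r[consensus[l]] <- s[l]
      r
    }, numeric(4)))
    return(pwm_motif(prob))
  }
  # order-2 preset: consensus head, two uniform positions, two positions
  # depending (with a one-position skip) on the uniform ones
  if (width < 5L) abort("the order2 preset needs width >= 5")
  head_len <- max(1L, width - 4L)
  kind <- c(rep("cons", head_len), rep("unif", 2L),
            rep("dep", width - head_len - 2L))
  positions <- vector("list", width)
  for (l in seq_len(width)) {
    if (kind[l] == "cons") {
      th <- matrix(row_for(consensus[l]), nrow = 1, dimnames = list(NULL, DNA))
      positions[[l]] <- list(pct = pct_minimal(0L), theta = th,
                             log_theta = log(th), leaf_map = 1L,
                             deff = 0L, score = NA_real_)
    } else if (kind[l] == "unif") {
      th <- matrix(0.25, nrow = 1, ncol = 4, dimnames = list(NULL, DNA))
      positions[[l]] <- list(pct = pct_minimal(0L), theta = th,
                             log_theta = log(th), leaf_map = 1L,
                             deff = 0L, score = NA_real_)
    } else {
      pct <- pct_maximal(2L)
      # favored symbol = function of the symbol two back (digit 1 of the
      # context code); the proximal symbol is ignored, so the dependency
      # skips one position, and since the referenced position is uniform
      # the marginal here stays flat
      th <- matrix(spread, nrow = 16, ncol = 4, dimnames = list(NULL, DNA))
      codes <- 0:15
      distal <- codes %/% 4L
      fav <- 1L + (distal + l) %% 4L
      lm <- pct_leaf_map(pct)
      for (cd in codes) th[lm[cd + 1L], fav[cd + 1L]] <- strength
      positions[[l]] <- list(pct = pct, theta = th, log_theta = log(th),
                             leaf_map = lm, deff = 2L, score = NA_real_)
    }
  }
  structure(list(width = as.integer(width), order = 2L,
                 positions = positions, score = NA_real_, n = NA_integer_),
            class = "pmm")
}

#' Generate a synthetic ChIP-seq-like benchmark
#'
#' Emulates the structure of a ChIP-seq study: each positive sequence is
#' background from a homogeneous Markov chain with exactly one motif
#' instance planted at a uniformly random position (reverse-complemented
#' with probability `strand_prob`); negatives are pure background of
#' matched lengths at `neg_ratio` sequences per positive. The planting
#' truth is recorded in the same layout as prediction output.
#'
#' @param motif Generating `pmm` (e.g. from [motif_preset()]).
#' @param n_pos Number of positive sequences.
#' @param length Sequence length(s); scalar or vector of length `n_pos`.
#' @param background A `flanking_model` used as background chain; default
#'   is a uniform order-2 chain.
#' @param strand_prob Probability of planting on the reverse strand.
#' @param neg_ratio Negatives per positive (default 2).
#' @param seed Optional integer seed.
#' @return List with `positives`, `negatives` (sequence-set tibbles),
#'   `truth` (tibble `id`, `start`, `strand`, `site`) and `width`.
#' @export
make_benchmark <- function(motif, n_pos = 200L, length = 100L,
                           background = NULL, strand_prob = 0.5,
                           neg_ratio = 2L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- motif$width
  lens <- rep_len(as.integer(length), n_pos)
  if (any(lens < W)) abort("sequence length must be at least the motif width")
  if (strand_prob < 0 || strand_prob > 1) abort("strand_prob must be in [0, 1]")
  if (is.null(background)) background <- uniform_flanking(2L)

  bg <- sample_background(background, lens)
  sites <- sample_motif_sites(motif, n_pos)
  start <- vapply(lens - W + 1L, function(n) sample.int(n, 1L), 1L)
  strand <- ifelse(stats::runif(n_pos) < strand_prob, "R", "F")
  planted <- ifelse(strand == "R", reverse_complement(sites), sites)
  seqs <- paste0(substr(bg, 1, start - 1), planted,
                 substr(bg, start + W, lens))
  positives <- seq_set(seqs, id = paste0("pos_", seq_len(n_pos)))
  neg_lens <- rep(lens, each = neg_ratio)
  negatives <- seq_set(sample_background(background, neg_lens),
                       id = paste0("neg_", seq_along(neg_lens)))
  truth <- tibble(id = positives$id, start = start, strand = strand,
                  site = sites)
  list(positives = positives, negatives = negatives, truth = truth, width = W)
}
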