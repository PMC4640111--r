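#' Build a sequence set
#'
#' A sequence set is a tibble with columns `id` (unique identifiers) and
#' `seq` (DNA strings over A, C, G, T). It is the container for ChIP-seq
#' positive or negative sequences throughout the package.
#'
#' @param seq Character vector of DNA sequences.
#' @param id Optional identifiers; defaults to `seq_1`, `seq_2`, ...
#' @return A tibble with columns `id` and `seq`.
#' @examples
#' seq_set(c("ACGT", "TTTT"))
#' @export
seq_set <- function(seq, id = NULL) {
  if (length(seq) < 1) abort("a sequence set needs at least one sequence")
  if (is.null(id)) id <- paste0("seq_", seq_along(seq))
  seq <- unname(toupper(seq))
  id <- unname(id)
  validate_seqs(seq)
  if (anyDuplicated(id)) abort("sequence ids must be unique")
  tibble(id = as.character(id), seq = seq)
}

validate_seqs <- function(seq) {
  bad <- grepl("[^ACGT]", seq)
  if (any(bad)) {
    abort(paste0(
      "sequences contain symbols outside {A,C,G,T} (e.g. ambiguous 'N'): ",
      "offending record(s) ", paste(utils::head(which(bad), 5), collapse = ", "),
      "; ambiguous nucleotides are not supported"
    ))
  }
  invisible(seq)
}

#' Read DNA sequences from a FASTA file
#'
#' Records are upper-cased and order is preserved. Records containing
#' ambiguous nucleotides (anything outside A, C, G, T) are rejected with an
#' error, since downstream models are defined over the four-letter alphabet
#' only.
#'
#' @param path Path to a FASTA file.
#' @return A sequence-set tibble (columns `id`, `seq`).
#' @examples
#' # a small synthetic aligned-site set shipped with the package
#' fa <- system.file("extdata", "synthetic_sites.fa", package = "parsimotif")
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA file '", path, "': ",
                                     conditionMessage(e)))
  )
  if (length(ss) == 0) abort(paste0("no sequences in FASTA file '", path, "'"))
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  seq_set(toupper(as.character(ss)), id = ids)
}

#' Write a sequence set (or aligned sites) to FASTA
#'
#' @param x A sequence-set tibble or a character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.character(x)) x <- seq_set(x, id = paste0("site_", seq_along(x)))
  ss <- Biostrings::DNAStringSet(x$seq)
  names(ss) <- x$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement of DNA strings
#'
#' Vectorized; an involution on strings over A, C, G, T.
#'
#' @param seq Character vector of DNA strings (may contain empty strings).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")
#' @export
reverse_complement <- function(seq) {
  out <- character(length(seq))
  nonempty <- nchar(seq) > 0
  if (any(nonempty)) {
    validate_seqs(toupper(seq[nonempty]))
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[nonempty]))
    )
  }
  out
}

#' Build a latent configuration
#'
#' One row per sequence: `start` is the 1-based first position of the motif
#' window and `strand` is `"F"` (forward) or `"R"` (reverse complementary).
#'
#' @param id Sequence identifiers.
#' @param start Integer start positions, 1-based.
#' @param strand Character vector of "F"/"R".
#' @return Tibble with columns `id`, `start`, `strand`.
#' @export
latent_config <- function(id, start, strand) {
  strand <- as.character(strand)
  if (!all(strand %in% c("F", "R"))) abort("strand must be 'F' or 'R'")
  tibble(id = as.character(id), start = as.integer(start), strand = strand)
}

#' Extract aligned binding sites given a latent configuration
#'
#' For a forward record the window of `width` symbols starting at `start` is
#' taken as-is; for a reverse record its reverse complement is taken, so the
#' returned sites are orientation-aligned.
#'
#' @param data Sequence-set tibble.
#' @param latents Latent-configuration tibble (`id`, `start`, `strand`),
#'   aligned with `data` by `id`.
#' @param width Motif width W.
#' @return Character vector of sites, each of length `width`.
#' @export
extract_sites <- function(data, latents, width) {
  lat <- latents[match(data$id, latents$id), ]
  if (anyNA(lat$start)) abort("latents must cover every sequence id in data")
  L <- nchar(data$seq)
  if (any(lat$start < 1 | lat$start > L - width + 1)) {
    abort("latent start position out of range for the given width")
  }
  win <- substr(data$seq, lat$start, lat$start + width - 1)
  rev_idx <- lat$strand == "R"
  if (any(rev_idx)) win[rev_idx] <- reverse_complement(win[rev_idx])
  win
}

# integer site matrix n x W from a character vector of equal-width sites
site_matrix <- function(sites) {
  w <- unique(nchar(sites))
  if (length(sites) == 0) abort("empty site set")
  if (length(w) != 1) abort("all sites must have equal width")
  m <- matrix(match(unlist(strsplit(toupper(sites), "", fixed = TRUE)), DNA),
              ncol = w, byrow = TRUE)
  if (anyNA(m)) abort("sites contain symbols outside {A,C,G,T}")
  m
}

#' Context-symbol counts at one motif position
#'
#' Counts occurrences of each symbol at position `position` stratified by the
#' concatenation of the preceding `min(depth, position - 1)` symbols (the
#' context sequence). Row `r` of the returned matrix corresponds to the
#' context sequence whose base-4 code is `r - 1`, with the symbol directly
#' preceding the position as the least significant digit; columns are
#' A, C, G, T.
#'
#' @param sites Character vector of aligned sites (equal width), or an empty
#'   vector for an all-zero table (then `width` must be given).
#' @param position Motif position (1-based, within the site width).
#' @param depth Maximal context depth d; the effective depth at `position`
#'   is `min(depth, position - 1)`.
#' @param width Site width, required only when `sites` is empty.
#' @return Integer matrix with `4^min(depth, position - 1)` rows and 4
#'   columns; cells sum to `length(sites)`.
#' @export
context_counts <- function(sites, position, depth, width = NULL) {
  if (length(sites) == 0) {
    if (is.null(width)) abort("width required for an empty site set")
    deff <- min(depth, position - 1L)
    return(matrix(0L, nrow = 4L^deff, ncol = 4L,
                  dimnames = list(NULL, DNA)))
  }
  M <- site_matrix(sites)
  context_counts_mat(M, position, depth)
}

context_counts_mat <- function(M, position, depth) {
  W <- ncol(M)
  if (position < 1 || position > W) abort("position out of range")
  deff <- min(depth, position - 1L)
  sym <- M[, position]
  code <- 0L
  if (deff > 0) {
    cols <- lapply(seq_len(deff), function(j) M[, position - j])
    code <- ctx_code(cols)
  }
  idx <- code * 4L + sym
  counts <- tabulate(idx, nbins = 4L^deff * 4L)
  matrix(counts, ncol = 4L, byrow = TRUE, dimnames = list(NULL, DNA))
}
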