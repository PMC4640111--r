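#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

DNA <- c("A", "C", "G", "T")

# alphabet used for general (possibly non-DNA) PCT work; m <= 4
alph <- function(m) DNA[seq_len(m)]

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Encode a DNA string as integers 1..4
#'
#' Internal encoding used by all numeric routines: A=1, C=2, G=3, T=4.
#' @noRd
encode_seq <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA)
  if (anyNA(x)) {
    abort(paste0("invalid DNA symbol in sequence; only A, C, G, T allowed"))
  }
  x
}

decode_seq <- function(x) paste(DNA[x], collapse = "")

# reverse complement on the integer encoding (A<->T, C<->G)
int_revcomp <- function(x) rev(5L - x)

# context code of digits (proximal symbol = least significant digit);
# syms is a list/matrix of symbol columns ordered proximal first
ctx_code <- function(sym_cols, m = 4L) {
  if (length(sym_cols) == 0L) {
    return(0L)
  }
  code <- 0L
  for (j in seq_along(sym_cols)) {
    code <- code + (sym_cols[[j]] - 1L) * m^(j - 1L)
  }
  code
}

# all non-empty subsets of 1..m, ordered by size then lexicographically;
# each element an increasing integer vector
nonempty_subsets <- function(m) {
  subs <- list()
  for (k in seq_len(m)) {
    cmb <- utils::combn(m, k)
    for (i in seq_len(ncol(cmb))) subs[[length(subs) + 1L]] <- cmb[, i]
  }
  subs[order(vapply(subs, length, 1L),
             vapply(subs, function(s) paste(s, collapse = ""), ""))]
}

# all set partitions of 1..m in a deterministic canonical order:
# fewest blocks first, then lexicographic on the block signature.
# Each partition is a list of increasing integer vectors (blocks sorted
# by their smallest element).
set_partitions <- function(m) {
  # restricted growth strings
  parts <- list()
  rgs <- function(prefix, mx) {
    if (length(prefix) == m) {
      nb <- max(prefix)
      blocks <- lapply(seq_len(nb), function(b) which(prefix == b))
      parts[[length(parts) + 1L]] <<- blocks
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) rgs(c(prefix, v), max(mx, v))
  }
  rgs(integer(0), 0L)
  key <- vapply(parts, function(p) {
    paste(vapply(p, function(b) paste(b, collapse = ""), ""), collapse = "|")
  }, "")
  parts[order(vapply(parts, length, 1L), key)]
}
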