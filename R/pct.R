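#' Parsimonious context trees
#'
#' A parsimonious context tree (PCT) of depth `d` over an alphabet of size
#' `m` is a rooted, balanced tree whose non-root nodes are labeled by
#' non-empty subsets of the alphabet, such that the labels of the children
#' of any node form a partition of the alphabet. The cross product of the
#' labels along a root-to-leaf path is a *context*: a set of length-`d`
#' context sequences sharing one conditional probability vector. The
#' contexts of all leaves partition the set of all `m^d` context sequences.
#'
#' Level 1 (children of the root) conditions on the symbol directly
#' preceding the modeled position; the deepest level conditions on the most
#' distal context symbol. A depth-0 PCT is the bare root with a single empty
#' context, i.e. a PWM position.
#'
#' @param depth Tree depth `d >= 0`.
#' @param m Alphabet size (default 4, DNA).
#' @name pct
NULL

new_pct <- function(depth, m, root) {
  structure(list(depth = as.integer(depth), m = as.integer(m), root = root),
            class = "pct")
}

# node: list(children = list(list(label = int vector, node = <node>))) or
# leaf: list(children = NULL)
pct_leaf_node <- function() list(children = NULL)

#' @describeIn pct Minimal PCT: every level one node labeled by the whole
#'   alphabet; a single context, equivalent to a PWM position.
#' @export
pct_minimal <- function(depth, m = 4L) {
  node <- pct_leaf_node()
  for (k in seq_len(depth)) {
    node <- list(children = list(list(label = seq_len(m), node = node)))
  }
  new_pct(depth, m, node)
}

#' @describeIn pct Maximal PCT: singleton labels everywhere; one context per
#'   context sequence, equivalent to a full order-`depth` Markov position.
#' @export
pct_maximal <- function(depth, m = 4L) {
  build <- function(k) {
    if (k == 0) return(pct_leaf_node())
    list(children = lapply(seq_len(m), function(a) {
      list(label = a, node = build(k - 1))
    }))
  }
  new_pct(depth, m, build(depth))
}

#' Build a PCT from nested label partitions
#'
#' `spec` is a recursive list: each element is `list(label = <symbols>,
#' children = <list or NULL>)` where symbols are given as characters from
#' the alphabet (e.g. `c("A","G")`). Used mainly for constructing worked
#' examples and fixtures.
#'
#' @param depth Tree depth.
#' @param spec List of child specs under the root.
#' @param m Alphabet size.
#' @return A `pct` object.
#' @export
pct_from_spec <- function(depth, spec, m = 4L) {
  a <- alph(m)
  build <- function(children_spec, k) {
    if (k == 0) return(pct_leaf_node())
    if (is.null(children_spec)) abort("spec shallower than stated depth")
    kids <- lapply(children_spec, function(ch) {
      lab <- sort(match(ch$label, a))
      if (anyNA(lab)) abort("unknown symbol in PCT spec label")
      list(label = lab, node = build(ch$children, k - 1))
    })
    list(children = kids)
  }
  p <- new_pct(depth, m, build(spec, depth))
  validate_pct(p)
  p
}

validate_pct <- function(pct) {
  m <- pct$m
  walk <- function(node, k) {
    if (k == 0) {
      if (!is.null(node$children)) abort("leaf nodes must be at depth d")
      return(invisible())
    }
    if (is.null(node$children)) abort("non-leaf node without children")
    labs <- unlist(lapply(node$children, `[[`, "label"))
    if (length(labs) != m || anyDuplicated(labs) || !setequal(labs, seq_len(m))) {
      abort("child labels of a PCT node must form a partition of the alphabet")
    }
    for (ch in node$children) walk(ch$node, k - 1)
  }
  walk(pct$root, pct$depth)
  invisible(pct)
}

# leaves ordered canonically by the smallest context code they contain, so
# that for a maximal tree leaf i corresponds to context code i - 1; each
# leaf is the chain of labels from level 1 (proximal) to level d (distal)
pct_leaf_chains <- function(pct) {
  chains <- list()
  walk <- function(node, chain) {
    if (is.null(node$children)) {
      chains[[length(chains) + 1L]] <<- chain
      return(invisible())
    }
    for (ch in node$children) walk(ch$node, c(chain, list(ch$label)))
  }
  walk(pct$root, list())
  m <- pct$m
  min_code <- vapply(chains, function(chain) {
    code <- 0
    for (j in seq_along(chain)) {
      code <- code + (min(chain[[j]]) - 1) * m^(j - 1)
    }
    code
  }, 0)
  chains[order(min_code)]
}

#' Contexts of a PCT
#'
#' Returns, per leaf, the set of context sequences it represents. A context
#' sequence is written with its most distal symbol first, so the string
#' reads in the 5'-to-3' direction of the motif (e.g. context sequence "AC"
#' means A two positions back and C directly before the modeled position).
#'
#' @param pct A `pct` object.
#' @return A list with one character vector of context sequences per leaf;
#'   the vectors are disjoint and jointly cover all `m^depth` sequences.
#'   For depth 0, a single empty-string context.
#' @export
pct_contexts <- function(pct) {
  validate_pct(pct)
  a <- alph(pct$m)
  lapply(pct_leaf_chains(pct), function(chain) {
    if (length(chain) == 0) return("")
    # chain is proximal..distal; print distal..proximal
    grids <- rev(chain)
    g <- expand.grid(rev(lapply(grids, function(s) a[s])),
                     stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; order columns distal..prox
    sort(apply(g[, rev(seq_along(grids)), drop = FALSE], 1, paste, collapse = ""))
  })
}

# integer codes (0-based) of the context sequences of each leaf
pct_leaf_codes <- function(pct) {
  m <- pct$m
  lapply(pct_leaf_chains(pct), function(chain) {
    if (length(chain) == 0) return(0L)
    code <- 0L
    for (j in seq_along(chain)) {
      code <- as.vector(outer(code, (chain[[j]] - 1L) * m^(j - 1L), `+`))
    }
    sort(code)
  })
}

# map from context code + 1 -> leaf index
pct_leaf_map <- function(pct) {
  codes <- pct_leaf_codes(pct)
  map <- integer(pct$m^pct$depth)
  for (i in seq_along(codes)) map[codes[[i]] + 1L] <- i
  map
}

pct_n_leaves <- function(pct) length(pct_leaf_chains(pct))

#' Aggregate a raw context count table over the contexts of a PCT
#'
#' @param raw Count matrix with `m^depth` rows (context sequences, coded with
#'   the proximal symbol as least significant digit) and `m` columns.
#' @param pct A `pct` object whose depth matches `raw`.
#' @return Matrix with one row per leaf context; totals are conserved.
#' @export
aggregate_counts <- function(raw, pct) {
  raw <- as.matrix(raw)
  if (nrow(raw) != pct$m^pct$depth) {
    abort("count table depth does not match PCT depth")
  }
  map <- pct_leaf_map(pct)
  n_leaf <- max(map)
  agg <- rowsum(raw, group = map, reorder = TRUE)
  # rowsum orders by group label, which is leaf index
  rownames(agg) <- NULL
  agg
}

# log-likelihood term of one leaf count vector (ML plug-in)
leaf_loglik <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  nz <- counts > 0
  sum(counts[nz] * log(counts[nz] / tot))
}

#' BIC structure score of a PCT
#'
#' Penalized maximum log-likelihood (natural log): the sum over contexts and
#' symbols of `N_ca * log(N_ca / N_c.)` minus `|tau| * (m - 1) * log(N) / 2`,
#' where `|tau|` is the number of leaves. Zero-count cells contribute zero to
#' the likelihood; zero-count contexts still pay the parameter penalty.
#'
#' @param pct A `pct` object.
#' @param raw Raw count table (see [aggregate_counts()]).
#' @param n Sample size N (must equal the table total).
#' @return The BIC score (natural-log scale).
#' @export
bic_score <- function(pct, raw, n) {
  if (n <= 0) abort("BIC score undefined for sample size 0")
  agg <- aggregate_counts(raw, pct)
  ll <- sum(apply(agg, 1, leaf_loglik))
  ll - 0.5 * nrow(agg) * (pct$m - 1) * log(n)
}

#' Exact BIC-optimal PCT by dynamic programming
#'
#' Bottom-up recursion over subset chains: the optimal subtree under a node
#' is computed from the count table marginalized over the node's root-path
#' labels, maximizing at each node over all set partitions of the alphabet
#' (Bell-number enumeration). Exact for the depths and alphabet sizes used
#' here; ties are broken toward fewer leaves, then toward the canonical
#' partition order, so results are deterministic.
#'
#' @param raw Raw count table, `m^depth` rows by `m` columns.
#' @param depth Tree depth d.
#' @param n Sample size N.
#' @param m Alphabet size.
#' @return A list with elements `pct` (the optimal tree) and `score`.
#' @export
maximize_bic <- function(raw, depth, n, m = 4L) {
  raw <- as.matrix(raw)
  if (n <= 0) abort("sample size must be >= 1")
  if (depth < 0) abort("depth must be >= 0")
  if (nrow(raw) != m^depth || ncol(raw) != m) {
    abort("count table dimensions do not match depth/alphabet")
  }
  pen <- 0.5 * (m - 1) * log(n)
  subsets <- nonempty_subsets(m)
  partitions <- set_partitions(m)
  # partitions as indices into `subsets`
  sub_key <- vapply(subsets, paste, "", collapse = ",")
  part_idx <- lapply(partitions, function(p) {
    match(vapply(p, paste, "", collapse = ","), sub_key)
  })
  tol <- 1e-9

  best_node <- function(tab, k) {
    if (k == 0) {
      list(score = leaf_loglik(tab[1, ]) - pen,
           node = pct_leaf_node(), leaves = 1L)
    } else {
      nr <- nrow(tab) %/% m
      child_best <- vector("list", length(subsets))
      for (si in seq_along(subsets)) {
        s <- subsets[[si]]
        # marginalize the proximal digit over subset s
        sub <- tab[rep((seq_len(nr) - 1L) * m, each = length(s)) +
                     rep(s, nr), , drop = FALSE]
        if (length(s) > 1) {
          grp <- rep(seq_len(nr), each = length(s))
          sub <- rowsum(sub, group = grp, reorder = TRUE)
        }
        child_best[[si]] <- best_node(sub, k - 1)
      }
      best <- NULL
      for (pi in seq_along(part_idx)) {
        ids <- part_idx[[pi]]
        sc <- sum(vapply(child_best[ids], `[[`, 0, "score"))
        lv <- sum(vapply(child_best[ids], `[[`, 0L, "leaves"))
        take <- if (is.null(best)) TRUE
          else if (sc > best$score + tol) TRUE
          else if (sc > best$score - tol && lv < best$leaves) TRUE
          else FALSE
        if (take) {
          kids <- lapply(seq_along(ids), function(j) {
            list(label = partitions[[pi]][[j]], node = child_best[[ids[j]]]$node)
          })
          best <- list(score = sc, node = list(children = kids), leaves = lv)
        }
      }
      best
    }
  }

  res <- best_node(raw, depth)
  list(pct = new_pct(depth, m, res$node), score = res$score)
}

# number of distinct PCTs of given depth/alphabet
count_pcts <- function(depth, m) {
  if (depth == 0) return(1)
  parts <- set_partitions(m)
  f <- 1
  for (k in seq_len(depth)) {
    f <- sum(vapply(parts, function(p) f^length(p), 0))
  }
  f
}

#' Enumerate all PCTs of a given depth (test oracle)
#'
#' Brute-force enumeration; refuses to run when the number of structures
#' exceeds `cap`. Intended as an independent oracle for [maximize_bic()].
#'
#' @param depth Tree depth.
#' @param m Alphabet size.
#' @param cap Maximal number of structures to enumerate.
#' @return List of `pct` objects, each structure exactly once.
#' @export
enumerate_pcts <- function(depth, m = 4L, cap = 10000) {
  n <- count_pcts(depth, m)
  if (n > cap) abort(paste0("refusing to enumerate ", n, " structures (cap ", cap, ")"))
  parts <- set_partitions(m)
  enum_nodes <- function(k) {
    if (k == 0) return(list(pct_leaf_node()))
    sub_nodes <- enum_nodes(k - 1)
    out <- list()
    for (p in parts) {
      # all assignments of subtrees to the blocks of p
      idx <- rep(list(seq_along(sub_nodes)), length(p))
      combos <- expand.grid(idx)
      for (r in seq_len(nrow(combos))) {
        kids <- lapply(seq_along(p), function(j) {
          list(label = p[[j]], node = sub_nodes[[combos[r, j]]])
        })
        out[[length(out) + 1L]] <- list(children = kids)
      }
    }
    out
  }
  lapply(enum_nodes(depth), function(nd) new_pct(depth, m, nd))
}

#' Serialize / parse a PCT as a nested label string
#'
#' Children are pipe-separated, labels comma-joined, subtrees in
#' parentheses: the minimal depth-2 DNA tree prints as
#' `"(A,C,G,T(A,C,G,T))"`, the maximal depth-1 tree as `"(A|C|G|T)"`.
#' `pct_from_string()` inverts `pct_to_string()`.
#'
#' @param pct A `pct` object.
#' @return A single string.
#' @export
pct_to_string <- function(pct) {
  a <- alph(pct$m)
  render <- function(node) {
    paste(vapply(node$children, function(ch) {
      lab <- paste(a[ch$label], collapse = ",")
      if (is.null(ch$node$children)) lab
      else paste0(lab, "(", render(ch$node), ")")
    }, ""), collapse = "|")
  }
  if (pct$depth == 0) return("()")
  paste0("(", render(pct$root), ")")
}

#' @rdname pct_to_string
#' @param s A string produced by `pct_to_string()`.
#' @param m Alphabet size.
#' @export
pct_from_string <- function(s, m = 4L) {
  a <- alph(m)
  s <- gsub("\\s", "", s)
  if (s == "()") return(new_pct(0L, m, pct_leaf_node()))
  pos <- 2L  # skip outer "("
  n <- nchar(s)
  peek <- function() substr(s, pos, pos)
  parse_children <- function() {
    kids <- list()
    repeat {
      lab <- integer(0)
      repeat {
        ch <- peek()
        sym <- match(ch, a)
        if (is.na(sym)) break
        lab <- c(lab, sym)
        pos <<- pos + 1L
        if (peek() == ",") pos <<- pos + 1L else break
      }
      node <- pct_leaf_node()
      if (peek() == "(") {
        pos <<- pos + 1L
        node <- list(children = parse_children())
      }
      kids[[length(kids) + 1L]] <- list(label = sort(lab), node = node)
      ch <- peek()
      if (ch == "|") { pos <<- pos + 1L; next }
      if (ch == ")" || pos > n) { pos <<- pos + 1L; break }
      abort("malformed PCT string")
    }
    kids
  }
  root <- list(children = parse_children())
  dep <- 0L
  nd <- root
  while (!is.null(nd$children)) { dep <- dep + 1L; nd <- nd$children[[1]]$node }
  p <- new_pct(dep, m, root)
  validate_pct(p)
  p
}

# JSON-friendly nested-list dump and its inverse
pct_to_list <- function(pct) {
  a <- alph(pct$m)
  conv <- function(node) {
    if (is.null(node$children)) return(list())
    lapply(node$children, function(ch) {
      list(label = a[ch$label], children = conv(ch$node))
    })
  }
  list(depth = pct$depth, m = pct$m, children = conv(pct$root))
}

pct_from_list <- function(x) {
  m <- as.integer(x$m)
  a <- alph(m)
  conv <- function(kids) {
    if (length(kids) == 0) return(pct_leaf_node())
    list(children = lapply(kids, function(ch) {
      list(label = sort(match(unlist(ch$label), a)), node = conv(ch$children))
    }))
  }
  p <- new_pct(as.integer(x$depth), m, conv(x$children))
  validate_pct(p)
  p
}

#' @export
print.pct <- function(x, ...) {
  cat("<pct> depth", x$depth, "alphabet", x$m,
      "leaves", pct_n_leaves(x), "\n ", pct_to_string(x), "\n")
  invisible(x)
}
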