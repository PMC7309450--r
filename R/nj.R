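#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()]): at each step the pair
#' minimising `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined
#' and branch lengths follow the canonical formulas; the result is an
#' unrooted tree with a trifurcation at the last join. On additive
#' (tree-realisable) input the leaf-to-leaf path lengths reproduce the input
#' distances exactly.
#'
#' Non-additive input can yield negative branch lengths; by default each is
#' clamped to zero with the deficit moved onto its sibling branch (so the
#' path length through the parent is preserved where possible). Set
#' `clamp_negative = FALSE` to keep raw values.
#'
#' @param D symmetric labelled distance matrix, n >= 3
#'   (see [pairwise_distance_matrix()]).
#' @param clamp_negative clamp negative branch lengths (default `TRUE`).
#' @return an [ape::phylo] tree whose tip labels are the matrix labels.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  validate_distance_matrix(D)
  if (nrow(D) < 3) {
    kfc_error("neighbour joining needs at least 3 samples",
              "kfc_too_few_samples")
  }
  tree <- ape::nj(as.dist(D))
  if (clamp_negative) tree <- clamp_negative_branches(tree)
  tree
}

# Move each negative branch length onto its sibling (first sibling edge in
# edge-matrix order), then zero it; residual negatives after max_iter sweeps
# are clamped outright.
clamp_negative_branches <- function(tree, max_iter = 10L) {
  for (iter in seq_len(max_iter)) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0) return(tree)
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

quote_newick_label <- function(label) {
  needs <- grepl("[][(),:;'\" \t]", label)
  ifelse(needs, paste0("'", gsub("'", "''", label), "'"), label)
}

#' Serialise a tree as a Newick string
#'
#' Branch lengths are written with a fixed number of decimals so identical
#' trees always serialise byte-identically; labels are quoted only when they
#' contain Newick structural characters. The output round-trips through any
#' standard Newick parser.
#'
#' @param tree an [ape::phylo] object.
#' @param precision decimal places for branch lengths (default 6).
#' @return a single Newick string terminated by `";"`.
#' @seealso [write_newick()]
#' @export
to_newick <- function(tree, precision = 6) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  fmt <- paste0("%.", precision, "f")
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  recurse <- function(node, incoming) {
    len <- if (is.na(incoming)) "" else
      paste0(":", sprintf(fmt, tree$edge.length[incoming]))
    if (node <= ntip) {
      return(paste0(quote_newick_label(tree$tip.label[node]), len))
    }
    kids <- children[[as.character(node)]]
    inner <- vapply(kids, function(e) recurse(tree$edge[e, 2], e),
                    character(1))
    paste0("(", paste(inner, collapse = ","), ")", len)
  }
  paste0(recurse(ntip + 1L, NA_integer_), ";")
}

#' Write a tree to a Newick file
#'
#' @inheritParams to_newick
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, precision = 6) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(to_newick(tree, precision), con, sep = "\n")
  invisible(path)
}
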