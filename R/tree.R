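# Unrooted phylogenetic trees as points of BHV space.
#
# A tree is a leaf set plus a vector of edges: every external (pendant) edge
# and every internal split, each with a nonnegative length. Edges are stored
# as canonical split masks in canonical edge order (externals by leaf label,
# then internals ordered by the smaller block's leaf sequence), so the length
# vector is the orthant coordinate vector of the tree.

new_tree <- function(leaves, masks, lengths, validate = TRUE) {
  n <- length(leaves)
  full <- full_mask(n)
  ord <- order_edges(masks, full, n)
  t <- structure(list(leaves = leaves, split = masks[ord], length = lengths[ord]),
                 class = "bhv_tree")
  if (validate) validate_tree(t)
  t
}

validate_tree <- function(t) {
  n <- length(t$leaves)
  full <- full_mask(n)
  if (n < 3L) stop("a tree needs at least 3 leaves")
  if (length(t$split) != length(t$length)) stop("split/length mismatch")
  if (any(t$length < 0)) stop("negative edge length")
  if (anyDuplicated(t$split)) stop("duplicate split")
  ext <- split_is_external(t$split, n)
  if (sum(ext) != n) stop("every leaf must have exactly one external edge")
  sint <- t$split[!ext]
  if (length(sint) > n - 3L) stop("too many internal splits")
  if (!all_compatible(t$split, full)) stop("splits are not pairwise compatible")
  invisible(t)
}

#' Construct a phylogenetic tree from splits
#'
#' @param external named numeric vector of pendant edge lengths; names are the
#'   leaf labels.
#' @param internal list of character vectors, each one block of an internal
#'   split.
#' @param internal_lengths numeric vector of internal edge lengths, parallel
#'   to `internal`.
#' @return an object of class `bhv_tree`.
#' @examples
#' t <- make_tree(c(A = 2, B = 2, C = 1, D = 3),
#'                internal = list(c("A", "B")), internal_lengths = 4)
#' write_newick(t)
#' @export
make_tree <- function(external, internal = list(), internal_lengths = numeric()) {
  if (is.null(names(external))) stop("`external` must be named by leaf label")
  leaves <- leaf_set(names(external))
  n <- length(leaves)
  full <- full_mask(n)
  ext_masks <- vapply(leaves, function(l) canon_mask(mask_of(l, leaves), full), integer(1))
  ext_len <- as.numeric(external[leaves])
  if (length(internal) != length(internal_lengths)) stop("internal/internal_lengths mismatch")
  int_masks <- vapply(internal, function(s) canon_mask(mask_of(s, leaves), full), integer(1))
  if (length(int_masks) && any(split_is_external(int_masks, n)))
    stop("internal split has a singleton block")
  new_tree(leaves, c(ext_masks, int_masks), c(ext_len, as.numeric(internal_lengths)))
}

n_leaves <- function(t) length(t$leaves)

internal_mask_flags <- function(t) !split_is_external(t$split, length(t$leaves))

#' Internal splits of a tree
#'
#' @param t a `bhv_tree`.
#' @return list of character vectors (the canonical block of each internal
#'   split), in canonical edge order.
#' @export
internal_splits <- function(t) {
  lapply(t$split[internal_mask_flags(t)], labels_of, leaves = t$leaves)
}

#' @export
print.bhv_tree <- function(x, ...) {
  n <- length(x$leaves)
  ints <- internal_mask_flags(x)
  cat(sprintf("BHV tree: %d leaves, %d internal split(s)%s\n", n, sum(ints),
              if (sum(ints) == n - 3L) " (binary)" else ""))
  cat("  ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Is the tree fully resolved?
#'
#' @param t a `bhv_tree`.
#' @return `TRUE` iff the tree has `n - 3` internal splits.
#' @export
is_binary <- function(t) {
  sum(internal_mask_flags(t)) == length(t$leaves) - 3L
}

#' Compare two trees as vectors of edge lengths
#'
#' Trees are equal when they have the same leaf set and every split has the
#' same length in both (a split absent from one tree counts as length zero,
#' so zero-length edges compare equal to absent edges).
#'
#' @param a,b trees.
#' @param tol absolute tolerance on each edge length.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(a, b, tol = 1e-9) {
  if (!identical(a$leaves, b$leaves)) return(FALSE)
  all_splits <- union(a$split, b$split)
  la <- a$length[match(all_splits, a$split)]
  lb <- b$length[match(all_splits, b$split)]
  la[is.na(la)] <- 0
  lb[is.na(lb)] <- 0
  all(abs(la - lb) <= tol)
}

# ---- Newick I/O -----------------------------------------------------------

phylo_to_tree <- function(ph, universe = NULL, default_length = NULL,
                          keep_root = FALSE) {
  if (is.null(ph$edge.length)) {
    if (is.null(default_length)) stop("tree has no branch lengths (set default_length to fill)")
    ph$edge.length <- rep(as.numeric(default_length), nrow(ph$edge))
  }
  if (anyNA(ph$edge.length)) {
    if (is.null(default_length)) stop("tree has edges without branch lengths (set default_length to fill)")
    ph$edge.length[is.na(ph$edge.length)] <- as.numeric(default_length)
  }
  ntip <- length(ph$tip.label)
  root <- ntip + 1L
  tips <- if (keep_root) c(ph$tip.label, "__root__") else ph$tip.label
  leaves <- leaf_set(tips)
  n <- length(leaves)
  full <- full_mask(n)
  edge <- ph$edge

  # tip mask below each node (the pseudo root-leaf, if kept, sits above every
  # edge, so it never enters a `below` mask)
  below <- integer(max(edge))
  for (i in seq_len(ntip)) below[i] <- bitwShiftL(1L, match(ph$tip.label[i], leaves) - 1L)
  pending <- setdiff(unique(edge[, 1L]), seq_len(ntip))
  while (length(pending)) {
    solved <- FALSE
    for (nd in pending) {
      kids <- edge[edge[, 1L] == nd, 2L]
      if (all(below[kids] > 0L)) {
        below[nd] <- Reduce(bitwOr, below[kids])
        pending <- setdiff(pending, nd)
        solved <- TRUE
      }
    }
    if (!solved) stop("malformed tree structure")
  }

  masks <- integer(0)
  lens <- numeric(0)
  for (i in seq_len(nrow(edge))) {
    m <- below[edge[i, 2L]]
    if (m == full || m == 0L) next  # a full-mask edge can only arise unrooted-degenerate
    cm <- canon_mask(m, full)
    j <- match(cm, masks)
    if (is.na(j)) {
      masks <- c(masks, cm)
      lens <- c(lens, ph$edge.length[i])
    } else {
      # same split twice: a degree-2 vertex (e.g. a suppressed binary root);
      # merge by summing the incident lengths
      lens[j] <- lens[j] + ph$edge.length[i]
    }
  }
  if (keep_root) {
    rmask <- canon_mask(bitwShiftL(1L, match("__root__", leaves) - 1L), full)
    masks <- c(masks, rmask)
    lens <- c(lens, 0)
  }
  if (!is.null(universe)) {
    universe <- leaf_set(universe)
    missing <- setdiff(leaves, universe)
    if (length(missing)) stop("leaf not in universe: ", paste(missing, collapse = ", "))
  }
  new_tree(leaves, masks, lens)
}

#' Parse a Newick string into a tree
#'
#' Reads a (possibly rooted) Newick description and returns the unrooted
#' tree: a binary root of degree 2 is suppressed and its two incident edge
#' lengths summed, unless `keep_root = TRUE`, in which case the root is
#' retained as a pseudo-leaf named `__root__`. Internal node labels and
#' bootstrap values are parsed and discarded; bracket comments and quoted
#' labels are supported.
#'
#' @param text a Newick string (or a connection/path accepted by
#'   [ape::read.tree()] when `file = TRUE`).
#' @param universe optional leaf universe; parsing errors if the tree uses a
#'   label outside it.
#' @param default_length if supplied, fills edges written without a branch
#'   length; otherwise missing lengths are an error.
#' @param keep_root keep a degree-2 root as a pseudo-leaf instead of
#'   suppressing it.
#' @param file interpret `text` as a file path.
#' @return a `bhv_tree`.
#' @examples
#' parse_newick("((A:1,B:1):1,(C:1,D:1):0);")
#' @export
parse_newick <- function(text, universe = NULL, default_length = NULL,
                         keep_root = FALSE, file = FALSE) {
  ph <- if (file) ape::read.tree(file = text) else ape::read.tree(text = text)
  if (is.null(ph)) stop("malformed Newick text")
  if (inherits(ph, "multiPhylo")) ph <- ph[[1L]]
  if (anyDuplicated(ph$tip.label)) stop("duplicate leaf labels")
  phylo_to_tree(ph, universe = universe, default_length = default_length,
                keep_root = keep_root)
}

# nesting structure of the canonical clusters (blocks away from leaf 1)
#' Serialize a tree to Newick
#'
#' Output is deterministic: the tree is written from the vertex adjacent to
#' the first leaf, children ordered by their smallest contained leaf.
#' Zero-length edges are retained.
#'
#' @param t a `bhv_tree`.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(t, digits = 12) {
  leaves <- t$leaves
  n <- length(leaves)
  full <- full_mask(n)
  ints <- internal_mask_flags(t)
  clusters <- t$split[ints]            # canonical: never contain leaf 1
  clens <- t$length[ints]
  ext_len <- numeric(n)
  for (i in which(!ints)) {
    ext_len[external_leaf_index(t$split[i], full, n)] <- t$length[i]
  }
  fmt <- function(x) trimws(formatC(x, digits = digits, format = "g"))
  # children of a cluster: maximal proper sub-clusters and uncovered leaves
  render <- function(mask, parents) {
    inside <- which(clusters != mask & bitwAnd(clusters, mask) == clusters &
                      !(seq_along(clusters) %in% parents))
    # maximal among `inside`
    maxi <- inside[vapply(inside, function(i) {
      !any(clusters[inside] != clusters[i] &
             bitwAnd(clusters[inside], clusters[i]) == clusters[i])
    }, logical(1))]
    covered <- Reduce(bitwOr, clusters[maxi], 0L)
    loose <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1L))) > 0L &
                     bitwAnd(covered, bitwShiftL(1L, 0:(n - 1L))) == 0L)
    items <- c(
      lapply(loose, function(li) list(min = li, str = paste0(quote_label(leaves[li]), ":", fmt(ext_len[li])))),
      lapply(maxi, function(ci) {
        sub <- render(clusters[ci], c(parents, ci))
        list(min = sub$min, str = paste0("(", sub$str, "):", fmt(clens[ci])))
      })
    )
    items <- items[order(vapply(items, `[[`, numeric(1), "min"))]
    list(min = if (length(items)) items[[1L]]$min else Inf,
         str = paste(vapply(items, `[[`, character(1), "str"), collapse = ","))
  }
  top <- render(full, integer(0))
  # leaf 1 is "loose" at the top level (clusters never contain it)
  paste0("(", top$str, ");")
}

quote_label <- function(x) {
  if (grepl("[ ():,;\\[\\]']", x)) paste0("'", gsub("'", "''", x), "'") else x
}
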