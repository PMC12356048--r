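# Leaf sets and splits.
#
# A leaf set is a sorted character vector of unique labels. A split (the
# bipartition of the leaf set induced by removing one edge) is stored as an
# integer bitmask over the leaf ordering, canonicalized so that the stored
# block is the one NOT containing the first leaf. This makes split equality
# integer equality, across trees and orthants.

.pc_table <- local({
  tab <- integer(65536L)
  for (b in 0:15) tab[bitwAnd(0:65535, bitwShiftL(1L, b)) > 0L] <-
      tab[bitwAnd(0:65535, bitwShiftL(1L, b)) > 0L] + 1L
  tab
})

popcount <- function(x) {
  .pc_table[bitwAnd(x, 65535L) + 1L] + .pc_table[bitwShiftR(x, 16L) + 1L]
}

full_mask <- function(n) {
  if (n > 30L) stop("at most 30 leaves are supported by the mask representation")
  bitwShiftL(1L, n) - 1L
}

#' Canonicalize a leaf set
#'
#' Leaf sets are deterministic: unique, non-empty labels in lexicographic
#' order regardless of input order.
#'
#' @param labels character vector of leaf names.
#' @return sorted character vector.
#' @export
leaf_set <- function(labels) {
  labels <- as.character(labels)
  if (anyNA(labels) || any(!nzchar(labels))) stop("leaf labels must be non-empty strings")
  if (anyDuplicated(labels)) stop("duplicate leaf labels: ",
                                  paste(unique(labels[duplicated(labels)]), collapse = ", "))
  sort(labels, method = "radix")
}

# mask of a set of labels within ordered universe `leaves`
mask_of <- function(labels, leaves) {
  idx <- match(labels, leaves)
  if (anyNA(idx)) stop("leaf not in universe: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  if (anyDuplicated(idx)) stop("duplicate leaves in block")
  sum(bitwShiftL(1L, idx - 1L))
}

labels_of <- function(mask, leaves) {
  leaves[bitwAnd(bitwShiftR(mask, seq_along(leaves) - 1L), 1L) == 1L]
}

# canonical form: the block not containing the first leaf (bit 1)
canon_mask <- function(mask, full) {
  ifelse(bitwAnd(mask, 1L) == 1L, bitwXor(full, mask), mask)
}

split_is_valid <- function(mask, n) {
  k <- popcount(mask)
  k >= 1L & k <= n - 1L
}

split_is_external <- function(mask, n) {
  k <- popcount(mask)
  k == 1L | k == n - 1L
}

# the leaf of an external split (index into the universe)
external_leaf_index <- function(mask, full, n) {
  m <- ifelse(popcount(mask) == 1L, mask, bitwXor(full, mask))
  as.integer(round(log2(m))) + 1L
}

# Ordering key for an internal split: the smaller block's sorted leaf
# sequence, compared lexicographically; ties broken by the block containing
# the first leaf. Matches the conventional presentation G | L \ G with G the
# smaller block.
split_key <- function(mask, full, n) {
  a <- popcount(mask)
  g <- if (a < n - a) mask else if (a > n - a) bitwXor(full, mask) else {
    m2 <- bitwXor(full, mask)
    if (bitwAnd(mask, 1L) == 1L) mask else m2  # block containing leaf 1
  }
  idx <- which(bitwAnd(bitwShiftR(g, 0:(n - 1L)), 1L) == 1L)
  paste(sprintf("%03d", idx), collapse = ".")
}

# order of edge masks: externals by leaf index first, then internals by key
order_edges <- function(masks, full, n) {
  ext <- split_is_external(masks, n)
  keys <- character(length(masks))
  for (i in seq_along(masks)) {
    keys[i] <- if (ext[i]) sprintf("0.%03d", external_leaf_index(masks[i], full, n))
    else paste0("1.", split_key(masks[i], full, n))
  }
  order(keys, method = "radix")
}

compat_mask <- function(a, b, full) {
  bitwAnd(a, b) == 0L |
    bitwAnd(a, bitwXor(full, b)) == 0L |
    bitwAnd(bitwXor(full, a), b) == 0L |
    bitwAnd(bitwXor(full, a), bitwXor(full, b)) == 0L
}

# are all splits in `masks` pairwise compatible?
all_compatible <- function(masks, full) {
  k <- length(masks)
  if (k < 2L) return(TRUE)
  for (i in seq_len(k - 1L)) {
    a <- masks[i]
    b <- masks[(i + 1L):k]
    ok <- bitwAnd(a, b) == 0L | bitwAnd(a, bitwXor(full, b)) == 0L |
      bitwAnd(bitwXor(full, a), b) == 0L |
      bitwAnd(bitwXor(full, a), bitwXor(full, b)) == 0L
    if (!all(ok)) return(FALSE)
  }
  TRUE
}

# one split vs a vector of splits
compat_vec <- function(a, bs, full) {
  bitwAnd(a, bs) == 0L | bitwAnd(a, bitwXor(full, bs)) == 0L |
    bitwAnd(bitwXor(full, a), bs) == 0L |
    bitwAnd(bitwXor(full, a), bitwXor(full, bs)) == 0L
}

#' Test whether two splits are compatible
#'
#' Two bipartitions of the same leaf set are compatible (can occur in one
#' tree) iff at least one of the four pairwise block intersections is empty.
#'
#' @param a,b character vectors: one block of each split.
#' @param leaves the shared universe of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @examples
#' splits_compatible(c("A", "B"), c("D", "E"), LETTERS[1:7])
#' splits_compatible(c("A", "B"), c("A", "C"), LETTERS[1:4])
#' @export
splits_compatible <- function(a, b, leaves) {
  leaves <- leaf_set(leaves)
  n <- length(leaves)
  full <- full_mask(n)
  ma <- mask_of(a, leaves)
  mb <- mask_of(b, leaves)
  if (!split_is_valid(ma, n) || !split_is_valid(mb, n)) stop("both blocks of a split must be non-empty")
  compat_mask(ma, mb, full)
}

#' Test whether a set of splits forms a legitimate tree topology
#'
#' A set of internal splits over `leaves` is a valid topology iff the splits
#' are pairwise compatible; with at most `length(leaves) - 3` splits the
#' topology is realizable, and equality holds exactly for binary trees.
#'
#' @param splits list of character vectors, one block per split.
#' @param leaves universe of leaf labels.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_topology <- function(splits, leaves) {
  leaves <- leaf_set(leaves)
  n <- length(leaves)
  full <- full_mask(n)
  if (length(splits) == 0L) return(TRUE)
  masks <- vapply(splits, function(s) canon_mask(mask_of(s, leaves), full), integer(1))
  if (any(!split_is_valid(masks, n))) return(FALSE)
  if (any(split_is_external(masks, n))) return(FALSE)
  if (anyDuplicated(masks)) return(FALSE)
  length(masks) <= n - 3L && all_compatible(masks, full)
}

#' Format a split as a string
#'
#' Splits are reported as `"G|complement"` with leaf names sorted within each
#' block and the smaller block first.
#'
#' @param block character vector: one block of the split.
#' @param leaves the universe of leaf labels.
#' @return a string.
#' @export
split_label <- function(block, leaves) {
  leaves <- leaf_set(leaves)
  g <- sort(block, method = "radix")
  h <- sort(setdiff(leaves, g), method = "radix")
  if (length(g) > length(h) || (length(g) == length(h) && paste(g, collapse = ",") > paste(h, collapse = ","))) {
    tmp <- g; g <- h; h <- tmp
  }
  paste0(paste(g, collapse = ","), "|", paste(h, collapse = ","))
}

split_label_mask <- function(mask, leaves) {
  split_label(labels_of(mask, leaves), leaves)
}
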