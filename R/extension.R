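# Extension spaces: tree dimensionality reduction (TDR), connection-cluster
# enumeration, projection matrices and the mutually restricted reduced system.
#
# For a tree T on leaves L inside a BHV space on N >= L, the extension space
# E_T^N is the preimage of T under the TDR map Psi_L. Restricted to one
# maximal orthant O of the connection cluster it is the affine slice
# M x = v_T, x >= 0, where M is the 0/1 projection matrix of Psi_L on O's
# edges. For an orthant pair the mutually restricted system pins every
# inconsequential edge by a copy or zero rule, leaving the block system
# diag(M1, M2) x = (v1, v2) over consequential edges only.

#' Construct a topology orthant
#'
#' @param leaves universe of leaf labels.
#' @param internal list of character vectors, one block per internal split.
#' @return an object of class `bhv_orthant`.
#' @export
make_orthant <- function(leaves, internal = list()) {
  leaves <- leaf_set(leaves)
  n <- length(leaves)
  full <- full_mask(n)
  masks <- vapply(internal, function(s) canon_mask(mask_of(s, leaves), full), integer(1))
  if (length(masks)) {
    if (any(split_is_external(masks, n))) stop("internal split has a singleton block")
    if (anyDuplicated(masks)) stop("duplicate split")
    if (!all_compatible(masks, full)) stop("splits are not pairwise compatible")
    if (length(masks) > n - 3L) stop("too many internal splits")
  }
  new_orthant(leaves, masks)
}

new_orthant <- function(leaves, masks) {
  n <- length(leaves)
  full <- full_mask(n)
  if (length(masks)) masks <- masks[order_edges(masks, full, n)]
  structure(list(leaves = leaves, splits = masks), class = "bhv_orthant")
}

#' @export
print.bhv_orthant <- function(x, ...) {
  cat(sprintf("BHV orthant: %d leaves, %d internal split(s)%s\n",
              length(x$leaves), length(x$splits),
              if (length(x$splits) == length(x$leaves) - 3L) " (maximal)" else ""))
  for (m in x$splits) cat("  ", split_label_mask(m, x$leaves), "\n", sep = "")
  invisible(x)
}

#' The lowest-dimensional orthant containing a tree
#'
#' @param t a `bhv_tree`.
#' @return a `bhv_orthant` over the tree's leaf set.
#' @export
orthant_of <- function(t) {
  new_orthant(t$leaves, t$split[internal_mask_flags(t)])
}

orthant_key <- function(o) paste(sort(o$splits), collapse = ",")

# all edges of a maximal (or any) orthant: n external splits + internals,
# in canonical edge order
orthant_edges <- function(o) {
  n <- length(o$leaves)
  full <- full_mask(n)
  ext <- vapply(seq_len(n), function(i) canon_mask(bitwShiftL(1L, i - 1L), full), integer(1))
  masks <- c(ext, o$splits)
  masks[order_edges(masks, full, n)]
}

#' Project a split onto a subset of its universe
#'
#' The projection of the split `G | N\\G` onto `L` is `(L n G) | (L \\ G)`.
#' When either block is empty the split vanishes under TDR (it lies on no
#' path between leaves of `L`).
#'
#' @param s character vector: one block of the split over `leaves`.
#' @param leaves the universe of leaf labels.
#' @param L the target leaf subset.
#' @return a list with `block` (character vector over `L`, canonical side, or
#'   `NULL`) and `kind` (`"internal"`, `"external"` or `"empty"`).
#' @export
project_split <- function(s, leaves, L) {
  leaves <- leaf_set(leaves)
  L <- leaf_set(L)
  if (!all(L %in% leaves)) stop("L is not a subset of the universe")
  g <- intersect(L, s)
  if (length(g) == 0L || length(g) == length(L)) {
    return(list(block = NULL, kind = "empty"))
  }
  nl <- length(L)
  fullL <- full_mask(nl)
  m <- canon_mask(mask_of(g, L), fullL)
  list(block = labels_of(m, L),
       kind = if (split_is_external(m, nl)) "external" else "internal")
}

# mask-level projection: mask over `leaves`-indexing -> mask over L-indexing
# (canonical), or NA when empty
proj_mask <- function(mask, leaves, L, fullL) {
  g <- intersect(L, labels_of(mask, leaves))
  if (length(g) == 0L || length(g) == length(L)) return(NA_integer_)
  canon_mask(mask_of(g, L), fullL)
}

#' Restrict a tree to a leaf subset (TDR map)
#'
#' Removes edges on no path between leaves of `L` and merges the edges
#' around each induced degree-2 vertex by summing lengths: each edge `q` of
#' the projected tree has length equal to the sum over its preimage.
#'
#' @param t a `bhv_tree`.
#' @param L leaf subset, at least 3 leaves.
#' @return a `bhv_tree` on `L`.
#' @export
tdr_project <- function(t, L) {
  L <- leaf_set(L)
  if (length(L) < 3L) stop("projection target needs at least 3 leaves")
  if (!all(L %in% t$leaves)) stop("L is not a subset of the tree's leaves")
  fullL <- full_mask(length(L))
  masks <- integer(0)
  lens <- numeric(0)
  for (i in seq_along(t$split)) {
    pm <- proj_mask(t$split[i], t$leaves, L, fullL)
    if (is.na(pm)) next
    j <- match(pm, masks)
    if (is.na(j)) {
      masks <- c(masks, pm)
      lens <- c(lens, t$length[i])
    } else {
      lens[j] <- lens[j] + t$length[i]
    }
  }
  new_tree(L, masks, lens)
}

#' Enumerate the connection cluster of a tree
#'
#' Lists every maximal orthant of the BHV space on `N` whose TDR projection
#' onto the tree's leaves yields the tree's topology, by sequentially
#' attaching the missing leaves (in fixed lexicographic order) to every edge
#' of the growing tree. With a fixed attachment order each sequence yields a
#' distinct topology, so the number of orthants is the double-factorial
#' product (2n-5)!!/(2l-5)!!.
#'
#' @param t a binary `bhv_tree` on leaves `L`.
#' @param N universe of leaf labels containing `L`.
#' @return a list of `bhv_orthant` objects.
#' @export
connection_cluster <- function(t, N) {
  N <- leaf_set(N)
  if (!all(t$leaves %in% N)) stop("tree leaves must be contained in N")
  if (!is_binary(t)) stop("connection clusters are defined for binary trees")
  n <- length(N)
  full <- full_mask(n)
  # embed the tree's edges as one-block masks over N
  blocks <- vapply(t$split, function(m) mask_of(labels_of(m, t$leaves), N), integer(1))
  missing <- setdiff(N, t$leaves)
  out <- vector("list", prod(if (length(missing)) 2 * (length(t$leaves) + seq_along(missing) - 1L) - 3 else 1))
  cnt <- 0L
  emit <- function(edges) {
    cnt <<- cnt + 1L
    cm <- canon_mask(edges, full)
    ints <- cm[!split_is_external(cm, n)]
    out[[cnt]] <<- new_orthant(N, ints)
  }
  grow <- function(edges, attached, k) {
    if (k > length(missing)) {
      emit(edges)
      return(invisible())
    }
    x <- bitwShiftL(1L, match(missing[k], N) - 1L)
    for (e in seq_along(edges)) {
      s0 <- edges[e]
      s0c <- bitwAnd(bitwXor(full, s0), attached)
      others <- edges[-e]
      # x lands on the side of each split containing the subdivided edge:
      # the block that wholly contains one block of s0
      gains <- bitwAnd(others, s0) == s0 | bitwAnd(others, s0c) == s0c
      grow(c(ifelse(gains, bitwOr(others, x), others), s0, bitwOr(s0, x), x),
           bitwOr(attached, x), k + 1L)
    }
    invisible()
  }
  grow(blocks, mask_of(t$leaves, N), 1L)
  out
}

#' Number of maximal orthants in an extension space
#'
#' Closed form `(2n-5)!!/(2l-5)!!` for a binary tree with `l` leaves embedded
#' in a BHV space on `n` leaves.
#'
#' @param n,l leaf counts, `3 <= l <= n`.
#' @return an integer-valued numeric (exact for all supported sizes).
#' @export
cluster_size <- function(n, l) {
  if (l < 3 || n < l) stop("need 3 <= l <= n")
  if (n == l) return(1)
  prod(2 * (l:(n - 1)) - 3)
}

#' Projection matrix of the TDR map on one orthant
#'
#' The 0/1 matrix whose rows are the `2l-3` edges of `t` and whose columns
#' are the `2n-3` edges of the maximal orthant `O`; entry (i, j) is 1 iff
#' edge `p_j` of `O` projects onto edge `q_i` of `t`. Zero columns are the
#' inconsequential edges.
#'
#' @param t a binary `bhv_tree` on leaves `L`.
#' @param O a `bhv_orthant` over `N` with `L` a subset of `N`, belonging to
#'   the connection cluster of `t`.
#' @return an object of class `projection_matrix`: `rows` and `cols` (edge
#'   masks in canonical order), `row_of_col` (0 for zero columns),
#'   `consequential` (logical per column). Use [as.matrix()] for the dense
#'   form.
#' @export
projection_matrix <- function(t, O) {
  L <- t$leaves
  N <- O$leaves
  if (!all(L %in% N)) stop("tree leaves must be contained in the orthant's universe")
  fullL <- full_mask(length(L))
  cols <- orthant_edges(O)
  row_of_col <- integer(length(cols))
  for (j in seq_along(cols)) {
    pm <- proj_mask(cols[j], N, L, fullL)
    if (is.na(pm)) { row_of_col[j] <- 0L; next }
    i <- match(pm, t$split)
    if (is.na(i)) stop("orthant is not in the connection cluster: column ",
                       split_label_mask(cols[j], N), " projects to ",
                       split_label_mask(pm, L), ", not an edge of the tree")
    row_of_col[j] <- i
  }
  if (!all(seq_along(t$split) %in% row_of_col))
    stop("orthant is not in the connection cluster: some tree edge has empty preimage")
  structure(list(rows = t$split, cols = cols, row_of_col = row_of_col,
                 consequential = row_of_col > 0L, tree = t, orthant = O),
            class = "projection_matrix")
}

#' @export
as.matrix.projection_matrix <- function(x, ...) {
  m <- matrix(0L, length(x$rows), length(x$cols))
  for (j in seq_along(x$cols)) if (x$row_of_col[j] > 0L) m[x$row_of_col[j], j] <- 1L
  rownames(m) <- vapply(x$rows, split_label_mask, character(1), leaves = x$tree$leaves)
  colnames(m) <- vapply(x$cols, split_label_mask, character(1), leaves = x$orthant$leaves)
  m
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat(sprintf("TDR projection matrix: %d x %d, %d consequential column(s)\n",
              length(x$rows), length(x$cols), sum(x$consequential)))
  print(as.matrix(x))
  invisible(x)
}

#' Build the mutually restricted reduced system for an orthant pair
#'
#' Drops the zero (inconsequential) columns of the two projection matrices
#' and records the rules of the mutually restricted extension space: common
#' edges inconsequential in exactly one tree are copied from the tree where
#' they are consequential; common edges inconsequential in both, and
#' uncommon inconsequential edges, are pinned at zero.
#'
#' @param t1,t2 binary trees on leaf subsets of the shared universe.
#' @param O1,O2 maximal orthants from the connection clusters of `t1`, `t2`
#'   over the same universe.
#' @return an object of class `projection_system`.
#' @export
build_reduced_system <- function(t1, O1, t2, O2) {
  if (!identical(O1$leaves, O2$leaves)) stop("orthants must share the same universe")
  N <- O1$leaves
  M1 <- projection_matrix(t1, O1)
  M2 <- projection_matrix(t2, O2)
  c1 <- which(M1$consequential)
  c2 <- which(M2$consequential)
  nr1 <- length(M1$rows)
  var_tree <- c(rep(1L, length(c1)), rep(2L, length(c2)))
  var_mask <- c(M1$cols[c1], M2$cols[c2])
  var_row <- c(M1$row_of_col[c1], nr1 + M2$row_of_col[c2])
  v <- c(t1$length, t2$length)
  nrow_tot <- nr1 + length(M2$rows)
  row_cols <- lapply(seq_len(nrow_tot), function(r) which(var_row == r))

  var_of <- function(tree, mask) {
    w <- which(var_tree == tree & var_mask == mask)
    if (length(w)) w else NA_integer_
  }
  common <- intersect(M1$cols, M2$cols)
  kpairs <- NULL
  copy_rules <- list()
  zero_rules <- list()
  for (m in common) {
    q1 <- M1$row_of_col[match(m, M1$cols)] > 0L
    q2 <- M2$row_of_col[match(m, M2$cols)] > 0L
    if (q1 && q2) {
      kpairs <- rbind(kpairs, c(var_of(1L, m), var_of(2L, m)))
    } else if (q1) {
      copy_rules[[length(copy_rules) + 1L]] <- list(mask = m, from = 1L, to = 2L,
                                                    var = var_of(1L, m))
    } else if (q2) {
      copy_rules[[length(copy_rules) + 1L]] <- list(mask = m, from = 2L, to = 1L,
                                                    var = var_of(2L, m))
    } else {
      zero_rules[[length(zero_rules) + 1L]] <- list(mask = m, tree = 0L)  # both
    }
  }
  for (m in setdiff(M1$cols, common)) {
    if (M1$row_of_col[match(m, M1$cols)] == 0L)
      zero_rules[[length(zero_rules) + 1L]] <- list(mask = m, tree = 1L)
  }
  for (m in setdiff(M2$cols, common)) {
    if (M2$row_of_col[match(m, M2$cols)] == 0L)
      zero_rules[[length(zero_rules) + 1L]] <- list(mask = m, tree = 2L)
  }

  # per-orthant reconstruction sources: variable index per edge, 0 = zero rule
  src_for <- function(M, tree) {
    vapply(seq_along(M$cols), function(j) {
      m <- M$cols[j]
      if (M$row_of_col[j] > 0L) return(var_of(tree, m))
      # inconsequential: copied if consequential in the other tree, else zero
      other <- if (tree == 1L) 2L else 1L
      w <- var_of(other, m)
      if (is.na(w)) 0L else w
    }, integer(1))
  }
  o1_src <- src_for(M1, 1L)
  o2_src <- src_for(M2, 2L)

  # K-dot partner per variable (NA if none), and copy-source flags
  kpartner <- rep(NA_integer_, length(var_tree))
  if (!is.null(kpairs)) {
    kpartner[kpairs[, 1L]] <- kpairs[, 2L]
    kpartner[kpairs[, 2L]] <- kpairs[, 1L]
  }
  copy_source <- rep(FALSE, length(var_tree))
  for (cr in copy_rules) copy_source[cr$var] <- TRUE

  structure(list(
    t1 = t1, t2 = t2, O1 = O1, O2 = O2, leaves = N,
    M1 = M1, M2 = M2,
    nvar = length(var_tree), nrow = nrow_tot,
    var_tree = var_tree, var_mask = var_mask, var_row = var_row,
    v = v, row_cols = row_cols,
    kpairs = kpairs, kpartner = kpartner, copy_source = copy_source,
    copy_rules = copy_rules, zero_rules = zero_rules,
    o1_cols = M1$cols, o2_cols = M2$cols,
    o1_src = o1_src, o2_src = o2_src), class = "projection_system")
}

#' @export
print.projection_system <- function(x, ...) {
  cat(sprintf("Reduced projection system: %d variables (%d + %d), %d constraint rows\n",
              x$nvar, sum(x$var_tree == 1L), sum(x$var_tree == 2L), x$nrow))
  cat(sprintf("  %d copy rule(s), %d zero rule(s), %d common consequential pair(s)\n",
              length(x$copy_rules), length(x$zero_rules),
              if (is.null(x$kpairs)) 0L else nrow(x$kpairs)))
  invisible(x)
}

# dense block matrix diag(M1.., M2..) over consequential columns
system_matrix <- function(sys) {
  m <- matrix(0, sys$nrow, sys$nvar)
  for (j in seq_len(sys$nvar)) m[sys$var_row[j], j] <- 1
  m
}

# residual of the linear constraints
feasibility_residual <- function(x, sys) {
  rs <- vapply(seq_len(sys$nrow), function(r) sum(x[sys$row_cols[[r]]]), numeric(1))
  max(abs(rs - sys$v))
}

# fast reconstruction of the two edge-length vectors (masks are sys$o*_cols)
reconstruct_lengths <- function(x, sys) {
  list(l1 = ifelse(sys$o1_src > 0L, x[pmax(sys$o1_src, 1L)], 0),
       l2 = ifelse(sys$o2_src > 0L, x[pmax(sys$o2_src, 1L)], 0))
}

#' Reconstruct the tree pair encoded by a feasible point
#'
#' Applies the variable assignments, copy rules and zero rules of a reduced
#' system to produce the unique pair of trees in the mutually restricted
#' extension space corresponding to `x`.
#'
#' @param x numeric vector over the system's variables, `x >= 0`.
#' @param sys a `projection_system`.
#' @param check verify `x` satisfies the linear constraints.
#' @param tol feasibility tolerance (absolute, per row).
#' @return list of two `bhv_tree` objects.
#' @export
reconstruct_pair <- function(x, sys, check = TRUE, tol = 1e-9) {
  if (length(x) != sys$nvar) stop("x has wrong length")
  if (any(x < -tol)) stop("x must be nonnegative")
  if (check && feasibility_residual(x, sys) > tol)
    stop("infeasible point: constraint residual exceeds tolerance")
  le <- reconstruct_lengths(pmax(x, 0), sys)
  list(new_tree(sys$leaves, sys$o1_cols, le$l1),
       new_tree(sys$leaves, sys$o2_cols, le$l2))
}

#' Serialize a reduced system to a JSON debug dump
#'
#' Mirrors the worked-example presentation: the reduced matrices as row
#' strings of 0/1, the target vector, and the copy/zero rules as split
#' strings.
#'
#' @param sys a `projection_system`.
#' @return a JSON string.
#' @export
system_json <- function(sys) {
  A <- system_matrix(sys)
  n1 <- sum(sys$var_tree == 1L)
  nr1 <- length(sys$M1$rows)
  lab <- function(m) split_label_mask(m, sys$leaves)
  rows_of <- function(block) apply(block, 1, paste, collapse = "")
  obj <- list(
    variables = vapply(seq_len(sys$nvar), function(j)
      sprintf("T%d:%s", sys$var_tree[j], lab(sys$var_mask[j])), character(1)),
    M1_reduced = rows_of(A[seq_len(nr1), seq_len(n1), drop = FALSE]),
    M2_reduced = rows_of(A[(nr1 + 1):sys$nrow, (n1 + 1):sys$nvar, drop = FALSE]),
    v = sys$v,
    copy_rules = vapply(sys$copy_rules, function(cr)
      sprintf("%s: T%d -> T%d", lab(cr$mask), cr$from, cr$to), character(1)),
    zero_rules = vapply(sys$zero_rules, function(zr)
      sprintf("%s: %s", lab(zr$mask),
              if (zr$tree == 0L) "both" else paste0("T", zr$tree)), character(1)))
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
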