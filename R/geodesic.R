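# BHV geodesics via the geodesic treepath (GTP) support search.
#
# The geodesic between trees T1, T2 on a common leaf set is characterized by
# its proper support: ordered partitions (A_1..A_k) of T1's uncommon internal
# splits and (B_1..B_k) of T2's, with nondecreasing norm ratios
# ||A_i||/||B_i||, cross-compatibility of B_i with A_j for i < j, and, for
# each pair, no vertex cover of the bipartite incompatibility graph (vertices
# weighted |a|^2/||A_i||^2, |b|^2/||B_i||^2) of weight below one. The squared
# length is sum_i (||A_i|| + ||B_i||)^2 plus squared length differences over
# common edges (common internal splits and all external edges).
#
# The support is found by successive refinement: starting from the single
# pair of all uncommon splits, each pair whose minimum-weight cover weighs
# less than one is split along that cover and the halves refined further.

cover_eps <- 1e-12

# minimum-weight vertex cover of a bipartite incompatibility graph.
# inc: |A| x |B| logical matrix, TRUE = incompatible (edge present).
# Exact subset enumeration over the smaller side when feasible, s-t min cut
# (igraph max-flow) otherwise. Returns list(weight, a (logical), b (logical)).
min_weight_cover <- function(wa, wb, inc) {
  na <- length(wa); nb <- length(wb)
  dega <- rowSums(inc); degb <- colSums(inc)
  act_a <- which(dega > 0L); act_b <- which(degb > 0L)
  a_in <- rep(FALSE, na); b_in <- rep(FALSE, nb)
  if (length(act_a) == 0L) return(list(weight = 0, a = a_in, b = b_in))
  flip <- length(act_b) < length(act_a)
  if (flip) {
    tmp <- wa; wa <- wb; wb <- tmp
    inc <- t(inc)
    tmp <- act_a; act_a <- act_b; act_b <- tmp
    tmp <- a_in; a_in <- b_in; b_in <- tmp
  }
  if (length(act_a) <= 14L) {
    best_w <- Inf; best_sub <- NULL; best_forced <- NULL
    m <- length(act_a)
    for (code in 0:(2^m - 1L)) {
      sel <- bitwAnd(bitwShiftR(code, 0:(m - 1L)), 1L) == 1L
      chosen <- act_a[sel]
      rest <- act_a[!sel]
      forced <- if (length(rest)) which(colSums(inc[rest, , drop = FALSE]) > 0L) else integer(0)
      w <- sum(wa[chosen]) + sum(wb[forced])
      if (w < best_w) { best_w <- w; best_sub <- chosen; best_forced <- forced }
    }
    a_in[best_sub] <- TRUE; b_in[best_forced] <- TRUE
    res <- list(weight = best_w, a = a_in, b = b_in)
  } else {
    res <- min_weight_cover_flow(wa, wb, inc, a_in, b_in)
  }
  if (flip) list(weight = res$weight, a = res$b, b = res$a) else res
}

min_weight_cover_flow <- function(wa, wb, inc, a_in, b_in) {
  na <- length(wa); nb <- length(wb)
  # nodes: 1 = source, 2..(na+1) = A, (na+2)..(na+nb+1) = B, na+nb+2 = sink
  src <- 1L; snk <- na + nb + 2L
  e_from <- c(rep(src, na), na + 1L + seq_len(nb))
  e_to <- c(1L + seq_len(na), rep(snk, nb))
  caps <- c(wa, wb)
  idx <- which(inc, arr.ind = TRUE)
  if (nrow(idx)) {
    e_from <- c(e_from, 1L + idx[, 1L])
    e_to <- c(e_to, na + 1L + idx[, 2L])
    caps <- c(caps, rep(sum(wa) + sum(wb) + 1, nrow(idx)))
  }
  g <- igraph::graph_from_edgelist(cbind(e_from, e_to), directed = TRUE)
  fl <- igraph::max_flow(g, source = src, target = snk, capacity = caps)
  srcside <- as.integer(fl$partition1)
  a_in[setdiff(1L + seq_len(na), srcside) - 1L] <- TRUE
  b_sel <- intersect(na + 1L + seq_len(nb), srcside) - na - 1L
  b_in[b_sel] <- TRUE
  list(weight = fl$value, a = a_in, b = b_in)
}

# refine the support pair (A, B) (index vectors into masksA/masksB);
# returns list of legs list(A = idx, B = idx)
refine_pair <- function(ia, ib, masksA, masksB, wA2, wB2, full) {
  if (length(ia) == 0L || length(ib) == 0L) {
    return(list(list(A = ia, B = ib)))
  }
  if (sum(wA2[ia]) == 0 || sum(wB2[ib]) == 0) {
    # a zero-norm side: both sides collapse onto the common-edge treatment
    return(list(list(A = integer(0), B = ib), list(A = ia, B = integer(0))))
  }
  inc <- matrix(FALSE, length(ia), length(ib))
  for (i in seq_along(ia)) inc[i, ] <- !compat_vec(masksA[ia[i]], masksB[ib], full)
  if (!any(inc)) {
    # fully compatible: both sides collapse onto the common-edge treatment
    return(list(list(A = integer(0), B = ib), list(A = ia, B = integer(0))))
  }
  na2 <- sum(wA2[ia]); nb2 <- sum(wB2[ib])
  cov <- min_weight_cover(wA2[ia] / na2, wB2[ib] / nb2, inc)
  if (cov$weight >= 1 - cover_eps) {
    return(list(list(A = ia, B = ib)))
  }
  c1 <- ia[cov$a]; c2 <- ia[!cov$a]
  d2 <- ib[cov$b]; d1 <- ib[!cov$b]
  c(refine_pair(c1, d1, masksA, masksB, wA2, wB2, full),
    refine_pair(c2, d2, masksA, masksB, wA2, wB2, full))
}

# core support computation on raw mask/length vectors (both trees share
# `leaves`); returns legs, common-edge table and squared length
geodesic_support_core <- function(leaves, m1, l1, m2, l2) {
  n <- length(leaves)
  full <- full_mask(n)
  common <- intersect(m1, m2)
  i1 <- match(common, m1); i2 <- match(common, m2)
  u1 <- setdiff(seq_along(m1), i1)
  u2 <- setdiff(seq_along(m2), i2)
  # uncommon splits must be internal (external edges are shared by leaf set)
  masksA <- m1[u1]; lensA <- l1[u1]
  masksB <- m2[u2]; lensB <- l2[u2]
  legs_idx <- refine_pair(seq_along(masksA), seq_along(masksB),
                          masksA, masksB, lensA^2, lensB^2, full)
  legs <- lapply(legs_idx, function(lg) {
    nA <- sqrt(sum(lensA[lg$A]^2)); nB <- sqrt(sum(lensB[lg$B]^2))
    list(A = masksA[lg$A], lenA = lensA[lg$A], normA = nA,
         B = masksB[lg$B], lenB = lensB[lg$B], normB = nB)
  })
  # drop empty legs, order by ratio ||A||/||B|| (0-norm legs at the ends)
  keep <- vapply(legs, function(lg) length(lg$A) + length(lg$B) > 0L, logical(1))
  legs <- legs[keep]
  ratio <- vapply(legs, function(lg) {
    if (lg$normA == 0 && lg$normB == 0) 0 else if (lg$normB == 0) Inf else lg$normA / lg$normB
  }, numeric(1))
  legs <- legs[order(ratio)]
  kdiff <- l1[i1] - l2[i2]
  leg2 <- vapply(legs, function(lg) (lg$normA + lg$normB)^2, numeric(1))
  list(legs = legs,
       common = list(split = common, len1 = l1[i1], len2 = l2[i2]),
       dist2 = sum(leg2) + sum(kdiff^2))
}

#' Compute the BHV geodesic between two trees
#'
#' Both trees must be on the same leaf set. Returns the geodesic's proper
#' support (ordered dropped/added split sets with their norms), the common
#' edges, and the geodesic length.
#'
#' @param t1,t2 trees (`bhv_tree`) on the same leaf set.
#' @return an object of class `bhv_geodesic` with elements `source`,
#'   `target`, `legs`, `common` and `length`.
#' @examples
#' t1 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 2)
#' t2 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "C")), 3)
#' compute_geodesic(t1, t2)$length  # cone path: 2 + 3
#' @export
compute_geodesic <- function(t1, t2) {
  if (!identical(t1$leaves, t2$leaves)) stop("trees must share the same leaf set")
  if (any(t1$length < 0) || any(t2$length < 0)) stop("negative edge length")
  sup <- geodesic_support_core(t1$leaves, t1$split, t1$length, t2$split, t2$length)
  structure(list(source = t1, target = t2, legs = sup$legs, common = sup$common,
                 length = sqrt(sup$dist2)),
            class = "bhv_geodesic")
}

#' @export
print.bhv_geodesic <- function(x, ...) {
  cat(sprintf("BHV geodesic: length %.6g, %d support pair(s), %d common edge(s)\n",
              x$length, length(x$legs), length(x$common$split)))
  invisible(x)
}

#' BHV distance between two trees on the same leaf set
#'
#' @param t1,t2 trees on the same leaf set.
#' @return the geodesic length (branch-length units).
#' @export
bhv_distance <- function(t1, t2) {
  compute_geodesic(t1, t2)$length
}

#' Evaluate a point on a geodesic
#'
#' Returns the tree at parameter `lam` along the geodesic: common edges are
#' linearly interpolated; a dropped split `e` in support set `A_j` survives
#' with length `((1-lam)||A_j|| - lam ||B_j||) |e| / ||A_j||` while that
#' value is positive, and added splits symmetrically.
#'
#' @param g a `bhv_geodesic`.
#' @param lam parameter in `[0, 1]`.
#' @return a `bhv_tree`.
#' @export
geodesic_point <- function(g, lam) {
  if (!inherits(g, "bhv_geodesic")) stop("`g` must be a bhv_geodesic")
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1)
    stop("`lam` must be a number in [0, 1]")
  masks <- g$common$split
  lens <- (1 - lam) * g$common$len1 + lam * g$common$len2
  for (lg in g$legs) {
    if (lg$normA > 0) {
      fA <- (1 - lam) * lg$normA - lam * lg$normB
      if (fA > 0) {
        masks <- c(masks, lg$A)
        lens <- c(lens, fA * lg$lenA / lg$normA)
      }
    }
    if (lg$normB > 0) {
      fB <- lam * lg$normB - (1 - lam) * lg$normA
      if (fB > 0) {
        masks <- c(masks, lg$B)
        lens <- c(lens, fB * lg$lenB / lg$normB)
      }
    }
  }
  new_tree(g$source$leaves, masks, lens)
}

#' Serialize a geodesic to JSON
#'
#' The support as lists of split strings with the leg norms, the common
#' edges with both lengths, and the geodesic length.
#'
#' @param g a `bhv_geodesic`.
#' @return a JSON string.
#' @export
geodesic_json <- function(g) {
  leaves <- g$source$leaves
  obj <- list(
    length = g$length,
    support = lapply(g$legs, function(lg) list(
      A = vapply(lg$A, split_label_mask, character(1), leaves = leaves),
      B = vapply(lg$B, split_label_mask, character(1), leaves = leaves),
      norm_A = lg$normA, norm_B = lg$normB)),
    common = list(
      splits = vapply(g$common$split, split_label_mask, character(1),
                      leaves = leaves),
      length_source = g$common$len1,
      length_target = g$common$len2))
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
}
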