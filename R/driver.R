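# Global search over orthant pairs: the distance between two extension
# spaces is the minimum, over all pairs of connection-cluster orthants, of
# the per-pair constrained minimum. Candidate supertrees are the geodesic
# midpoints of the optimal pairs.

#' Number of orthant pairs to search
#'
#' Exact integer evaluation of `{(2n-5)!!}^2 / ((2l1-5)!! (2l2-5)!!)`, the
#' product of the two connection-cluster sizes for trees with `l1` and `l2`
#' leaves in a BHV space on `n` leaves.
#'
#' @param n size of the leaf-set union.
#' @param l1,l2 leaf counts of the two trees, `3 <= li <= n`.
#' @return an integer-valued numeric.
#' @examples
#' count_orthant_pairs(7, 6, 4)   # 2835
#' count_orthant_pairs(10, 8, 7)  # 418275
#' @export
count_orthant_pairs <- function(n, l1, l2) {
  if (n < 3 || l1 < 3 || l2 < 3 || l1 > n || l2 > n)
    stop("need 3 <= l1, l2 <= n")
  cluster_size(n, l1) * cluster_size(n, l2)
}

#' Distance between the extension spaces of two trees
#'
#' Computes the shortest BHV distance between the extension spaces of `t1`
#' and `t2` in the BHV space on `N` (default: the union of the two leaf
#' sets), by enumerating every orthant pair of the two connection clusters
#' and minimizing the squared distance over each pair's mutually restricted
#' extension space. Returns the global minimum, all tied optimal pairs, and
#' their geodesic midpoints (candidate supertrees).
#'
#' @param t1,t2 binary `bhv_tree` objects; leaf sets may differ.
#' @param N optional universe of leaves containing both leaf sets.
#' @param opts optimizer options from [pair_options()].
#' @param tie_tol relative tolerance under which per-pair minima count as
#'   tied with the global minimum.
#' @param tree_tol absolute edge-length tolerance for deduplicating optimal
#'   pairs and midpoints.
#' @param verbose print progress every 1000 orthant pairs.
#' @return an object of class `extension_distance`: `distance`,
#'   `optimal_pairs` (list of tree pairs), `midpoints` (list of trees),
#'   `n_orthant_pairs`, `per_pair` (iteration/convergence summary),
#'   `all_converged`.
#' @examples
#' t1 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 1)
#' t2 <- make_tree(c(A = 1, B = 1, C = 1, E = 1), list(c("A", "B")), 2)
#' res <- extension_distance(t1, t2)
#' res$distance
#' @export
extension_distance <- function(t1, t2, N = NULL, opts = pair_options(),
                               tie_tol = 1e-6, tree_tol = 1e-7,
                               verbose = FALSE) {
  if (!is_binary(t1) || !is_binary(t2)) stop("both trees must be binary")
  if (is.null(N)) N <- union(t1$leaves, t2$leaves)
  N <- leaf_set(N)
  if (!all(t1$leaves %in% N) || !all(t2$leaves %in% N))
    stop("N must contain both leaf sets")
  if (length(N) < 4L) stop("the union leaf set needs at least 4 leaves")
  cl1 <- connection_cluster(t1, N)
  cl2 <- connection_cluster(t2, N)
  n_pairs <- length(cl1) * length(cl2)
  best <- Inf
  results <- vector("list", n_pairs)
  iters <- integer(n_pairs)
  convs <- logical(n_pairs)
  dists <- numeric(n_pairs)
  k <- 0L
  for (o1 in cl1) for (o2 in cl2) {
    k <- k + 1L
    sys <- build_reduced_system(t1, o1, t2, o2)
    res <- minimize_orthant_pair(sys, opts)
    results[[k]] <- res
    iters[k] <- res$iterations
    convs[k] <- res$converged
    dists[k] <- res$distance
    if (res$distance < best) best <- res$distance
    if (verbose && k %% 1000L == 0L)
      message(sprintf("  %d / %d orthant pairs searched (current min %.6g)",
                      k, n_pairs, best))
  }
  tied <- which(dists <= best * (1 + tie_tol) + tie_tol * 1e-12)
  # deduplicate optimal pairs split-set-wise with length tolerance
  pair_key_seen <- list()
  optimal_pairs <- list()
  for (i in tied) {
    tr <- results[[i]]$trees
    dup <- any(vapply(pair_key_seen, function(p)
      tree_equal(p[[1]], tr[[1]], tree_tol) && tree_equal(p[[2]], tr[[2]], tree_tol),
      logical(1)))
    if (!dup) {
      pair_key_seen[[length(pair_key_seen) + 1L]] <- tr
      optimal_pairs[[length(optimal_pairs) + 1L]] <- tr
    }
  }
  midpoints <- list()
  for (p in optimal_pairs) {
    m <- geodesic_point(compute_geodesic(p[[1]], p[[2]]), 0.5)
    if (!any(vapply(midpoints, tree_equal, logical(1), b = m, tol = tree_tol)))
      midpoints[[length(midpoints) + 1L]] <- m
  }
  structure(list(distance = best, optimal_pairs = optimal_pairs,
                 midpoints = midpoints, n_orthant_pairs = n_pairs,
                 per_pair = data.frame(pair = seq_len(n_pairs),
                                       distance = dists,
                                       iterations = iters,
                                       converged = convs),
                 all_converged = all(convs),
                 leaves = N),
            class = "extension_distance")
}

#' @export
print.extension_distance <- function(x, ...) {
  cat(sprintf("Extension-space distance: %.8g\n", x$distance))
  cat(sprintf("  %d orthant pair(s) searched; %d optimal pair(s); %d midpoint supertree(s)\n",
              x$n_orthant_pairs, length(x$optimal_pairs), length(x$midpoints)))
  if (!x$all_converged)
    cat(sprintf("  WARNING: %d pair(s) did not converge\n", sum(!x$per_pair$converged)))
  it <- x$per_pair$iterations
  cat(sprintf("  iterations per pair: mean %.2f [median %.0f, 90%% %.0f, max %d]\n",
              mean(it), stats::median(it), stats::quantile(it, 0.9), max(it)))
  invisible(x)
}
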