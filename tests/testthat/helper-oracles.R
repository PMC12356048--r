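# Independent oracles.
#
# brute_distance: minimizes the geodesic-length expression over every
# ratio-ordered valid path-space support by exhaustive enumeration of
# ordered partitions (degenerate one-sided legs included); tractable for
# trees with up to ~3 uncommon splits per side.
#
# brute_pair_min: dense projected search over the feasible polytope of a
# reduced system (zooming grid over the free coordinates, dependents
# eliminated through the constraints).

.support_assignments <- function(nitem, k) {
  if (nitem == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  as.matrix(expand.grid(rep(list(seq_len(k)), nitem)))
}

brute_distance <- function(t1, t2) {
  stopifnot(identical(t1$leaves, t2$leaves))
  leaves <- t1$leaves
  n <- length(leaves)
  full <- extspace:::full_mask(n)
  common <- intersect(t1$split, t2$split)
  i1 <- match(common, t1$split); i2 <- match(common, t2$split)
  kterm <- sum((t1$length[i1] - t2$length[i2])^2)
  A0 <- setdiff(seq_along(t1$split), i1)
  B0 <- setdiff(seq_along(t2$split), i2)
  mA <- t1$split[A0]; lA <- t1$length[A0]
  mB <- t2$split[B0]; lB <- t2$length[B0]
  if (length(mA) == 0L && length(mB) == 0L) return(sqrt(kterm))
  best <- Inf
  for (k in seq_len(length(mA) + length(mB))) {
    asA <- .support_assignments(length(mA), k)
    asB <- .support_assignments(length(mB), k)
    for (ra in seq_len(nrow(asA))) for (rb in seq_len(nrow(asB))) {
      pa <- lapply(seq_len(k), function(b) which(asA[ra, ] == b))
      pb <- lapply(seq_len(k), function(b) which(asB[rb, ] == b))
      if (any(lengths(pa) + lengths(pb) == 0L)) next
      nA <- vapply(pa, function(ix) sqrt(sum(lA[ix]^2)), numeric(1))
      nB <- vapply(pb, function(ix) sqrt(sum(lB[ix]^2)), numeric(1))
      r <- ifelse(nB == 0, Inf, nA / nB)
      if (length(r) > 1L && is.unsorted(r)) next
      ok <- TRUE
      for (i in 0:k) {
        sp <- c(common,
                if (i >= 1) mB[unlist(pb[seq_len(i)])],
                if (i < k) mA[unlist(pa[(i + 1L):k])])
        if (!extspace:::all_compatible(sp, full)) { ok <- FALSE; break }
      }
      if (!ok) next
      best <- min(best, sum((nA + nB)^2))
    }
  }
  sqrt(best + kterm)
}

brute_pair_min <- function(sys, rounds = 12, pts = 5) {
  free_vars <- unlist(lapply(sys$row_cols, function(cols) cols[-1]))
  dep_vars <- vapply(sys$row_cols, function(cols) cols[1L], integer(1))
  row_of <- integer(sys$nvar)
  for (r in seq_len(sys$nrow)) row_of[sys$row_cols[[r]]] <- r
  nf <- length(free_vars)
  build_x <- function(z) {
    x <- numeric(sys$nvar)
    x[free_vars] <- z
    for (r in seq_len(sys$nrow))
      x[dep_vars[r]] <- sys$v[r] - sum(z[free_vars %in% sys$row_cols[[r]]])
    x
  }
  if (nf == 0L) return(sqrt(objective_delta(build_x(numeric(0)), sys, check = FALSE)))
  hi_cap <- sys$v[row_of[free_vars]]
  ctr <- hi_cap / 2
  wid <- hi_cap
  best <- Inf
  bestz <- ctr
  for (rd in seq_len(rounds)) {
    grids <- lapply(seq_len(nf), function(i)
      seq(max(0, ctr[i] - wid[i] / 2), min(hi_cap[i], ctr[i] + wid[i] / 2),
          length.out = pts))
    gr <- as.matrix(expand.grid(grids))
    for (r in seq_len(nrow(gr))) {
      x <- build_x(gr[r, ])
      if (any(x < -1e-12)) next
      val <- objective_delta(pmax(x, 0), sys, check = FALSE)
      if (val < best) { best <- val; bestz <- gr[r, ] }
    }
    ctr <- bestz
    wid <- wid * (2 / (pts - 1))
  }
  sqrt(best)
}

# random strictly positive feasible point of a reduced system (Dirichlet
# mass split within each constraint row)
random_feasible <- function(sys) {
  x <- numeric(sys$nvar)
  for (r in seq_len(sys$nrow)) {
    cols <- sys$row_cols[[r]]
    w <- stats::rgamma(length(cols), shape = 1)
    x[cols] <- sys$v[r] * w / sum(w)
  }
  x
}

# random reduced system drawn from two random trees and random cluster
# orthants over n leaves
random_system <- function(n, l1, l2, seed) {
  set.seed(seed)
  N <- sprintf("L%02d", seq_len(n))
  t1 <- random_binary_tree(sort(sample(N, l1)), seed = seed * 13 + 1)
  t2 <- random_binary_tree(sort(sample(N, l2)), seed = seed * 13 + 2)
  cl1 <- connection_cluster(t1, N)
  cl2 <- connection_cluster(t2, N)
  build_reduced_system(t1, cl1[[pick1(seq_along(cl1))]],
                       t2, cl2[[pick1(seq_along(cl2))]])
}
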