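test_that("the objective vanishes iff the reconstructed pair coincides", {
  # same orthant pair, same base tree: the initializer's point gives delta 0
  t <- rtree(5, seed = 31)
  N <- sprintf("L%02d", 1:6)
  cl <- connection_cluster(t, N)
  sys <- build_reduced_system(t, cl[[2]], t, cl[[2]])
  res <- minimize_orthant_pair(sys)
  expect_equal(res$distance, 0, tolerance = 1e-10)
  expect_tree_equal(res$trees[[1]], res$trees[[2]], tol = 1e-8)
})

test_that("in a shared orthant the objective is the squared Euclidean gap", {
  t1 <- rtree(5, seed = 41)
  t2 <- rtree(5, seed = 42)
  sys <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  x <- sys$v
  u <- x[seq_len(7)]
  v <- x[8:14]
  expect_equal(objective_delta(x, sys), bhv_distance(t1, t2)^2, tolerance = 1e-12)
})

test_that("objective agrees with the independent geodesic evaluation", {
  set.seed(17)
  for (s in 1:5) {
    sys <- random_system(6, 5, 4, seed = s)
    for (rep in 1:3) {
      x <- random_feasible(sys)
      pr <- reconstruct_pair(x, sys)
      expect_equal(objective_delta(x, sys), bhv_distance(pr[[1]], pr[[2]])^2,
                   tolerance = 1e-10)
    }
  }
})

test_that("gradient entries follow the support formulas", {
  # common consequential edge with lengths 3 and 5: entries -4 and +4
  t1 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 3)
  t2 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 5)
  sys <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  g <- gradient_delta(sys$v, sys)
  lab <- vapply(seq_len(sys$nvar), function(j)
    extspace:::split_label_mask(sys$var_mask[j], sys$leaves), character(1))
  i1 <- which(lab == "A,B|C,D" & sys$var_tree == 1L)
  i2 <- which(lab == "A,B|C,D" & sys$var_tree == 2L)
  expect_equal(g$gradient[i1], -4)
  expect_equal(g$gradient[i2], 4)
  # single-leg support with equal norms: entry 4 x_p
  t3 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 2)
  t4 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "C")), 2)
  sys2 <- build_reduced_system(t3, orthant_of(t3), t4, orthant_of(t4))
  g2 <- gradient_delta(sys2$v, sys2)
  j1 <- which(vapply(seq_len(sys2$nvar), function(j)
    extspace:::split_label_mask(sys2$var_mask[j], sys2$leaves), character(1)) ==
      "A,B|C,D")
  expect_equal(g2$gradient[j1], 4 * 2)
})

test_that("gradient matches central finite differences at interior points", {
  set.seed(23)
  h <- 1e-6
  for (s in 1:4) {
    sys <- random_system(6, 5, 5, seed = s)
    for (rep in 1:3) {
      x <- random_feasible(sys)
      g <- gradient_delta(x, sys)
      if (any(g$undefined)) next
      fd <- vapply(seq_len(sys$nvar), function(j) {
        xp <- x; xm <- x
        xp[j] <- xp[j] + h; xm[j] <- max(xm[j] - h, 0)
        (objective_delta(xp, sys, check = FALSE) -
            objective_delta(xm, sys, check = FALSE)) / (xp[j] - xm[j])
      }, numeric(1))
      expect_equal(g$gradient, fd, tolerance = 1e-4)
    }
  }
})

test_that("reduced gradient eliminates dependents through the permutation", {
  set.seed(3)
  sys <- random_system(6, 5, 4, seed = 2)
  x <- random_feasible(sys)
  g <- gradient_delta(x, sys)$gradient
  D <- vapply(sys$row_cols, function(cols) cols[1L], integer(1))
  F_ <- setdiff(seq_len(sys$nvar), D)
  part <- list(D = D, F = F_, N = integer(0))
  gphi <- reduced_gradient(g, sys, part)
  # dense oracle: grad_F f - M_F^T (M_D^T)^{-1} grad_D f
  A <- extspace:::system_matrix(sys)
  dense <- g[F_] - t(A[, F_]) %*% solve(t(A[, D])) %*% g[D]
  expect_equal(gphi, as.numeric(dense), tolerance = 1e-12)
  expect_length(reduced_gradient(g, sys, list(D = D, F = integer(0), N = F_)), 0L)
  # identity-block system: reduced gradient is the free restriction
  t1 <- rtree(5, seed = 1); t2 <- rtree(5, seed = 2)
  sid <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  gid <- gradient_delta(sid$v, sid)$gradient
  expect_length(reduced_gradient(gid, sid,
                                 list(D = seq_len(sid$nvar), F = integer(0),
                                      N = integer(0))), 0L)
})

test_that("line search solves the one-dimensional restriction", {
  t1 <- rtree(5, seed = 51)
  t2 <- rtree(5, seed = 52)
  N <- sprintf("L%02d", 1:6)
  cl1 <- connection_cluster(t1, N)
  cl2 <- connection_cluster(t2, N)
  sys <- build_reduced_system(t1, cl1[[1]], t2, cl2[[1]])
  set.seed(8)
  x <- random_feasible(sys)
  # a constraint-respecting direction inside one row, oriented downhill
  # (the uphill orientation must be rejected as an ascent direction)
  r <- which(lengths(sys$row_cols) >= 2)[1]
  cols <- sys$row_cols[[r]]
  d <- numeric(sys$nvar)
  d[cols[1]] <- 1; d[cols[2]] <- -1
  f <- function(tau) objective_delta(x + tau * d, sys, check = FALSE)
  if (f(1e-7) > f(0)) d <- -d
  tau <- line_search(x, d, sys)
  tau_max <- min(x[d < 0] / -d[d < 0])
  grid <- seq(0, tau_max, length.out = 2001)
  expect_lte(f(tau), min(vapply(grid, f, numeric(1))) + 1e-8)
  expect_error(line_search(x, -d, sys), "ascent")
  expect_equal(line_search(x, numeric(sys$nvar), sys), 0)
})

test_that("line search clamps at the boundary and flags ascent directions", {
  t1 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 1)
  t2 <- make_tree(c(A = 1, B = 1, C = 1, D = 1), list(c("A", "B")), 5)
  sys <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  x <- sys$v
  lab <- vapply(seq_len(sys$nvar), function(j)
    extspace:::split_label_mask(sys$var_mask[j], sys$leaves), character(1))
  j1 <- which(lab == "A,B|C,D" & sys$var_tree == 1L)
  d <- numeric(sys$nvar)
  d[j1] <- -1  # shrinking the short common edge increases the gap: ascent
  expect_error(line_search(x, d, sys), "ascent")
  d[j1] <- 1   # growing it toward 5 descends, clamped at tau = 4 is beyond
  tau <- line_search(x, d, sys)
  expect_equal(tau, 4, tolerance = 1e-6)  # minimizer: x1 = 5 = x2
})

test_that("orthant-pair minimization matches the dense polytope search", {
  set.seed(12)
  worst <- 0
  for (s in 1:10) {
    n <- pick1(5:6)
    sys <- random_system(n, pick1(4:(n - 1)), pick1(4:(n - 1)), seed = s + 60)
    if (sys$nvar - sys$nrow > 4) next
    res <- minimize_orthant_pair(sys)
    expect_true(res$converged)
    bf <- brute_pair_min(sys)
    expect_lte(res$distance, bf + 1e-5)
    expect_gte(res$distance, bf - 1e-4)  # grid resolution bounds the oracle
    if (length(res$certificate)) expect_gte(min(res$certificate), -1e-7)
    expect_lte(extspace:::feasibility_residual(res$x, sys), 1e-8)
  }
})

test_that("iterates never increase the objective and stay feasible", {
  # instrumented re-run: objective at the returned point never exceeds the
  # starting point's, and the returned point is feasible
  set.seed(2)
  for (s in 1:6) {
    sys <- random_system(6, 4, 4, seed = s + 80)
    x0 <- numeric(sys$nvar)
    for (r in seq_len(sys$nrow)) {
      cols <- sys$row_cols[[r]]
      x0[cols] <- sys$v[r] / length(cols)
    }
    res <- minimize_orthant_pair(sys)
    expect_lte(res$objective, objective_delta(x0, sys) + 1e-12)
    expect_lte(extspace:::feasibility_residual(res$x, sys), 1e-8)
    expect_true(all(res$x >= 0))
  }
})

test_that("a degenerate system converges without iterations", {
  t1 <- rtree(6, seed = 91)
  t2 <- rtree(6, seed = 92)
  sys <- build_reduced_system(t1, orthant_of(t1), t2, orthant_of(t2))
  res <- minimize_orthant_pair(sys)
  expect_identical(res$iterations, 0L)
  expect_true(res$converged)
  expect_equal(res$distance, bhv_distance(t1, t2), tolerance = 1e-12)
})
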