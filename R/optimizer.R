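# Reduced gradient minimization of the squared BHV distance between the
# orthant-specific mutually restricted extension spaces of one orthant pair.
#
# Objective: delta(x) = d^2(T1'(x), T2'(x))
#          = sum_i (||A_i|| + ||B_i||)^2 + sum_{s in K-dot} (x_s^1 - x_s^2)^2
# subject to the block system M x = v, x >= 0, whose matrix has exactly one
# unit entry per column. Variables are classified as dependent (one per
# constraint row), free, or null (pinned at zero); descent happens in the
# free variables with dependents eliminated through the constraints, and a
# multiplier vector mu over the null set certifies global optimality of this
# convex program.

#' Optimizer options
#'
#' @param grad_tol stopping tolerance on the reduced gradient norm.
#' @param feas_tol feasibility tolerance on the linear constraints.
#' @param max_iter iteration cap per orthant pair.
#' @param line_tol relative tolerance of the one-dimensional line search.
#' @return a list of options.
#' @export
pair_options <- function(grad_tol = 1e-8, feas_tol = 1e-9, max_iter = 500L,
                         line_tol = 1e-12) {
  list(grad_tol = grad_tol, feas_tol = feas_tol, max_iter = as.integer(max_iter),
       line_tol = line_tol)
}

#' Squared-distance objective of a reduced system
#'
#' Evaluates `delta(x) = d^2(T1'(x), T2'(x))` through the geodesic support of
#' the reconstructed pair: the support-leg terms over uncommon consequential
#' edges plus squared differences over common edges consequential in both
#' trees.
#'
#' @param x numeric vector over the system's variables (nonnegative).
#' @param sys a `projection_system`.
#' @param check verify feasibility of `x` first.
#' @param tol feasibility tolerance.
#' @return the squared distance (nonnegative scalar).
#' @export
objective_delta <- function(x, sys, check = TRUE, tol = 1e-9) {
  if (check && feasibility_residual(x, sys) > tol)
    stop("infeasible point: constraint residual exceeds tolerance")
  sup <- delta_support(x, sys)
  leg2 <- sum(vapply(sup$legs, function(lg) (lg$normA + lg$normB)^2, numeric(1)))
  kterm <- if (is.null(sys$kpairs)) 0 else
    sum((x[sys$kpairs[, 1L]] - x[sys$kpairs[, 2L]])^2)
  leg2 + kterm
}

# geodesic support of the reconstructed pair (no tree validation)
delta_support <- function(x, sys) {
  le <- reconstruct_lengths(pmax(x, 0), sys)
  geodesic_support_core(sys$leaves, sys$o1_cols, le$l1, sys$o2_cols, le$l2)
}

#' Gradient of the squared-distance objective
#'
#' Entries follow the support of the current geodesic: a variable `p` in
#' dropped set `A_i` has derivative `2 x_p (1 + ||B_i||/||A_i||)` (added sets
#' symmetrically), a common consequential pair contributes `2(x^1 - x^2)`,
#' and entries whose support leg has a zero norm are flagged undefined and
#' replaced by zero (the subgradient convention).
#'
#' @inheritParams objective_delta
#' @return list with `gradient` (numeric) and `undefined` (logical mask).
#' @export
gradient_delta <- function(x, sys, check = TRUE, tol = 1e-9) {
  if (check && feasibility_residual(x, sys) > tol)
    stop("infeasible point: constraint residual exceeds tolerance")
  sup <- delta_support(x, sys)
  g <- numeric(sys$nvar)
  undef <- rep(FALSE, sys$nvar)
  for (j in seq_len(sys$nvar)) {
    if (!is.na(sys$kpartner[j])) {
      g[j] <- 2 * (x[j] - x[sys$kpartner[j]])
    } else if (sys$copy_source[j]) {
      g[j] <- 0  # copied common edge: identical in both trees, zero K term
    } else {
      m <- sys$var_mask[j]
      found <- FALSE
      for (lg in sup$legs) {
        if (sys$var_tree[j] == 1L && m %in% lg$A) {
          if (lg$normA == 0) { undef[j] <- TRUE; g[j] <- 0 }
          else g[j] <- 2 * x[j] * (1 + lg$normB / lg$normA)
          found <- TRUE; break
        }
        if (sys$var_tree[j] == 2L && m %in% lg$B) {
          if (lg$normB == 0) { undef[j] <- TRUE; g[j] <- 0 }
          else g[j] <- 2 * x[j] * (1 + lg$normA / lg$normB)
          found <- TRUE; break
        }
      }
      if (!found) stop("internal error: uncommon variable not in any support leg")
    }
  }
  list(gradient = g, undefined = undef)
}

#' Reduced gradient over the free variables
#'
#' Computes `grad(phi) = grad_F f - M_F^T (M_D^T)^{-1} grad_D f`, exploiting
#' that every column of the constraint matrix holds a single 1, so the
#' dependent block is a permutation.
#'
#' @param grad full gradient vector of the objective.
#' @param sys a `projection_system`.
#' @param part variable partition: list with integer index sets `D`, `F`, `N`.
#' @return numeric vector over `part$F` (empty when `F` is empty).
#' @export
reduced_gradient <- function(grad, sys, part) {
  if (length(part$D) != sys$nrow) stop("D must contain one variable per constraint row")
  rowdep <- integer(sys$nrow)
  rowdep[sys$var_row[part$D]] <- part$D
  if (any(rowdep == 0L)) stop("singular dependent block: a row has no dependent variable")
  if (length(part$F) == 0L) return(numeric(0))
  grad[part$F] - grad[rowdep[sys$var_row[part$F]]]
}

#' Exact line search along a feasible direction
#'
#' Minimizes `delta(x + tau d)` over `tau` in `[0, tau_max]`, where `tau_max`
#' is the largest step keeping `x + tau d >= 0`. The restriction of the
#' convex objective to the ray is minimized by bracketed one-dimensional
#' search, with the boundary step compared explicitly.
#'
#' @param x feasible point.
#' @param d direction with `M d = 0`.
#' @param sys a `projection_system`.
#' @param tol relative line-search tolerance.
#' @return the optimal step `tau`.
#' @export
line_search <- function(x, d, sys, tol = 1e-12) {
  if (max(abs(d)) == 0) return(0)
  neg <- d < 0
  tau_max <- if (any(neg)) min(-x[neg] / d[neg]) else Inf
  if (tau_max <= 0) return(0)
  f <- function(tau) objective_delta(x + tau * d, sys, check = FALSE)
  # phi'(tau) is nondecreasing (convex restriction); the analytic slope
  # resolves the minimizer far below the precision of function values
  dphi <- function(tau)
    sum(gradient_delta(pmax(x + tau * d, 0), sys, check = FALSE)$gradient * d)
  d0 <- dphi(0)
  if (d0 > 1e-9 * (1 + sum(abs(d)))) stop("ascent direction passed to line_search")
  if (d0 >= 0) return(0)
  if (!is.finite(tau_max)) {
    # feasible set is compact in practice (a nonzero constraint-respecting
    # direction always has a negative entry), but guard by doubling
    hi <- 1
    while (dphi(hi) < 0 && hi < 1e12) hi <- 2 * hi
    tau_max <- hi
  }
  if (dphi(tau_max) <= 0) return(tau_max)
  root <- stats::uniroot(dphi, c(0, tau_max),
                         tol = max(tol * max(1, tau_max), 1e-300))$root
  # guard against support-change kinks: return the best of the candidates
  cands <- c(root, tau_max)
  cands[which.min(c(f(root), f(tau_max)))]
}

#' Minimize the distance over one orthant pair
#'
#' Runs the reduced gradient loop on a mutually restricted system:
#' initializes each constraint row's mass equally over its columns, descends
#' along the projected steepest-descent direction with exact line search,
#' reclassifies variables that hit zero, and terminates when the reduced
#' gradient vanishes and the multiplier certificate over the null variables
#' is nonnegative.
#'
#' @param sys a `projection_system`.
#' @param opts options from [pair_options()].
#' @return an object of class `pair_result`: `x`, `trees`, `distance`,
#'   `objective`, `iterations`, `converged`, `certificate`.
#' @export
minimize_orthant_pair <- function(sys, opts = pair_options()) {
  nv <- sys$nvar
  # strictly positive feasible start: split each row's value equally
  x <- numeric(nv)
  for (r in seq_len(sys$nrow)) {
    cols <- sys$row_cols[[r]]
    x[cols] <- sys$v[r] / length(cols)
  }
  # initial dependent set: canonically first column of each row
  D <- vapply(sys$row_cols, function(cols) cols[1L], integer(1))
  F_ <- setdiff(seq_len(nv), D)
  N <- integer(0)
  iter <- 0L
  converged <- FALSE
  mu_cert <- numeric(0)
  obj <- objective_delta(x, sys, check = FALSE)

  eps0 <- 1e-13
  # effective gradient: undefined entries (zero-norm support legs, which
  # only occur for variables at zero) are replaced by a forward-difference
  # estimate of the one-sided derivative, which exists by convexity
  fd_h <- 1e-7 * max(1, max(abs(sys$v)))
  eff_gradient <- function(x) {
    gr <- gradient_delta(x, sys, check = FALSE)
    g <- gr$gradient
    if (any(gr$undefined)) {
      f0 <- objective_delta(x, sys, check = FALSE)
      for (j in which(gr$undefined)) {
        xp <- x; xp[j] <- xp[j] + fd_h
        g[j] <- (objective_delta(xp, sys, check = FALSE) - f0) / fd_h
      }
    }
    g
  }
  build_dir <- function(gphi) {
    d <- numeric(nv)
    d[F_] <- -gphi
    for (r in seq_len(sys$nrow)) {
      dep <- D[sys$var_row[D] == r]
      d[dep] <- -sum(d[intersect(sys$row_cols[[r]], F_)])
    }
    d
  }

  repeat {
    # ---- descent phase over the current facet (steps 1-7) ----
    repeat {
      g <- eff_gradient(x)
      if (length(F_) == 0L) break
      gphi <- reduced_gradient(g, sys, list(D = D, F = F_, N = N))
      if (sqrt(sum(gphi^2)) <= opts$grad_tol) break
      if (iter >= opts$max_iter) break
      d <- build_dir(gphi)
      # variables already at zero that the direction would push negative
      # block the step entirely; null them (free) or pivot them out
      # (dependent) before searching
      blocked <- FALSE
      bf <- F_[x[F_] <= eps0 & d[F_] < -1e-15]
      if (length(bf)) {
        N <- c(N, bf); F_ <- setdiff(F_, bf)
        next
      }
      bd <- D[x[D] <= eps0 & d[D] < -1e-15]
      for (pick in bd) {
        r <- sys$var_row[pick]
        cand <- intersect(sys$row_cols[[r]], F_)
        if (length(cand)) {
          swap <- cand[which.max(x[cand])]
          D <- c(setdiff(D, pick), swap)
          F_ <- setdiff(F_, swap)
          N <- c(N, pick)
          blocked <- TRUE
        }
      }
      if (blocked) next
      iter <- iter + 1L
      tau <- tryCatch(line_search(x, d, sys, tol = opts$line_tol),
                      error = function(e) 0)
      x_new <- x + tau * d
      x_new[x_new < eps0] <- 0
      obj_new <- objective_delta(x_new, sys, check = FALSE)
      if (obj_new > obj + 1e-14 * (1 + obj)) break  # no progress possible
      hit <- which(x_new == 0 & d < 0 & x > eps0)
      moved <- tau * max(abs(d))
      x <- x_new
      obj <- obj_new
      if (length(hit)) {
        # reclassify the variable with the most negative gradient entry
        g2 <- eff_gradient(x)
        pick <- hit[which.min(g2[hit])]
        if (pick %in% F_) {
          F_ <- setdiff(F_, pick)
          N <- c(N, pick)
        } else if (pick %in% D) {
          r <- sys$var_row[pick]
          cand <- intersect(sys$row_cols[[r]], F_)
          if (length(cand)) {
            swap <- cand[which.max(x[cand])]
            D <- c(setdiff(D, pick), swap)
            F_ <- setdiff(F_, swap)
            N <- c(N, pick)
          }
        }
      } else if (moved <= 1e-15 * (1 + max(abs(x)))) {
        break
      }
    }
    # ---- optimality certificate over the null variables (step 8) ----
    g <- eff_gradient(x)
    rowdep <- integer(sys$nrow)
    rowdep[sys$var_row[D]] <- D
    mu_cert <- if (length(N)) g[N] - g[rowdep[sys$var_row[N]]] else numeric(0)
    names(mu_cert) <- vapply(N, function(j)
      split_label_mask(sys$var_mask[j], sys$leaves), character(1))
    release <- N[mu_cert < -opts$grad_tol]
    gphi_norm <- if (length(F_)) {
      sqrt(sum(reduced_gradient(g, sys, list(D = D, F = F_, N = N))^2))
    } else 0
    if (length(release) == 0L) {
      converged <- gphi_norm <= 10 * opts$grad_tol
      break
    }
    if (iter >= opts$max_iter) { converged <- FALSE; break }
    F_ <- c(F_, release)
    N <- setdiff(N, release)
  }
  trees <- reconstruct_pair(x, sys, check = FALSE)
  structure(list(x = x, trees = trees, distance = sqrt(max(obj, 0)),
                 objective = obj, iterations = iter, converged = converged,
                 certificate = mu_cert,
                 partition = list(D = D, F = F_, N = N)),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("Orthant-pair minimum: distance %.8g after %d iteration(s)%s\n",
              x$distance, x$iterations,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}
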