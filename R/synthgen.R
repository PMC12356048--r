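# Synthetic tree pairs for benchmarking: random binary topologies by
# sequential random attachment, branch lengths from a unimodal lognormal
# (mean 5, variance 1 of the lognormal variable itself) or a 75/25 mixture
# of lognormals with means 5 and 60 (variances 1 and 10). Named scenario
# presets reproduce the leaf-count triples (|L1 u L2|, |L1|, |L2|) of the
# simulation settings (a)-(f).

#' Branch-length model
#'
#' @param kind `"unimodal"` (one lognormal, mean 5 / variance 1) or
#'   `"bimodal"` (mixture: lognormal mean 5 / variance 1 with weight 0.75 and
#'   lognormal mean 60 / variance 10 with weight 0.25).
#' @param parameterization `"moments"` interprets mean/variance as the
#'   moments of the lognormal variable itself (default); `"underlying"`
#'   interprets them as the mean and variance of the underlying normal.
#' @return a list describing the model.
#' @export
length_model <- function(kind = c("unimodal", "bimodal"),
                         parameterization = c("moments", "underlying")) {
  kind <- match.arg(kind)
  parameterization <- match.arg(parameterization)
  comp <- function(m, v) {
    if (parameterization == "moments") {
      s2 <- log(1 + v / m^2)
      list(meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    } else {
      list(meanlog = m, sdlog = sqrt(v))
    }
  }
  if (kind == "unimodal") {
    structure(list(kind = kind, parameterization = parameterization,
                   components = list(comp(5, 1)), weights = 1),
              class = "length_model")
  } else {
    structure(list(kind = kind, parameterization = parameterization,
                   components = list(comp(5, 1), comp(60, 10)),
                   weights = c(0.75, 0.25)),
              class = "length_model")
  }
}

# draw k branch lengths from the model (uses the current RNG stream)
sample_lengths <- function(model, k) {
  ix <- if (length(model$weights) == 1L) rep(1L, k) else
    sample.int(length(model$weights), k, replace = TRUE, prob = model$weights)
  vapply(ix, function(i)
    stats::rlnorm(1, model$components[[i]]$meanlog, model$components[[i]]$sdlog),
    numeric(1))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random binary tree by sequential attachment
#'
#' Grows a uniformly random binary topology by attaching each leaf (in the
#' leaf set's deterministic order) to one of the `2m - 3` edges of the
#' current `m`-leaf tree, chosen uniformly; every binary topology is equally
#' likely. Branch lengths are drawn i.i.d. from the length model.
#'
#' @param leaves leaf labels (at least 3).
#' @param model a [length_model()].
#' @param seed integer seed; the same seed reproduces the same tree. `NULL`
#'   uses (and advances) the current RNG stream.
#' @return a binary `bhv_tree`.
#' @export
random_binary_tree <- function(leaves, model = length_model("unimodal"),
                               seed = NULL) {
  leaves <- leaf_set(leaves)
  n <- length(leaves)
  if (n < 3L) stop("need at least 3 leaves")
  with_seed(seed, {
    full <- full_mask(n)
    edges <- bitwShiftL(1L, 0:2)  # 3-leaf star, blocks over attached set
    attached <- bitwOr(bitwOr(1L, 2L), 4L)
    for (m in seq_len(n)[-(1:3)]) {
      x <- bitwShiftL(1L, m - 1L)
      e <- sample.int(length(edges), 1L)
      s0 <- edges[e]
      s0c <- bitwAnd(bitwXor(full, s0), attached)
      others <- edges[-e]
      gains <- bitwAnd(others, s0) == s0 | bitwAnd(others, s0c) == s0c
      edges <- c(ifelse(gains, bitwOr(others, x), others), s0, bitwOr(s0, x), x)
      attached <- bitwOr(attached, x)
    }
    lens <- sample_lengths(model, length(edges))
    new_tree(leaves, canon_mask(edges, full), lens)
  })
}

#' Scenario presets for simulated tree pairs
#'
#' The named presets `"a"`-`"f"` carry the leaf-count triples
#' (7,6,4), (7,6,4), (7,5,4), (10,9,8), (10,8,8), (10,8,7).
#'
#' @param preset one of `"a"` to `"f"`, or `NULL` to pass sizes directly.
#' @param n,l1,l2 leaf counts when no preset is used.
#' @return a list with `n`, `l1`, `l2`.
#' @export
scenario <- function(preset = NULL, n = NULL, l1 = NULL, l2 = NULL) {
  presets <- list(a = c(7, 6, 4), b = c(7, 6, 4), c = c(7, 5, 4),
                  d = c(10, 9, 8), e = c(10, 8, 8), f = c(10, 8, 7))
  if (!is.null(preset)) {
    preset <- match.arg(preset, names(presets))
    v <- presets[[preset]]
    n <- v[1]; l1 <- v[2]; l2 <- v[3]
  }
  if (is.null(n) || is.null(l1) || is.null(l2)) stop("give a preset or n, l1, l2")
  if (l1 < 3 || l2 < 3 || l1 > n || l2 > n || l1 + l2 < n)
    stop("need 3 <= l1, l2 <= n and l1 + l2 >= n (leaf sets must cover N)")
  list(n = n, l1 = l1, l2 = l2, preset = preset)
}

#' Generate a simulated tree pair
#'
#' Draws two leaf subsets of the required sizes (their overlap is forced to
#' `l1 + l2 - n` so the union is the full leaf set), then two independent
#' random binary trees with branch lengths from the model.
#'
#' @param sc a [scenario()].
#' @param model a [length_model()].
#' @param seed master seed driving leaf-subset choice, topologies and
#'   lengths through derived substreams.
#' @return list with `t1`, `t2` (trees), `leaves` (the union), and the two
#'   leaf subsets.
#' @export
make_scenario_pair <- function(sc, model = length_model("unimodal"),
                               seed = NULL) {
  n <- sc$n; l1 <- sc$l1; l2 <- sc$l2
  leaves <- sprintf("L%02d", seq_len(n))
  with_seed(seed, {
    sub <- sample.int(.Machine$integer.max, 4L)
    shared_n <- l1 + l2 - n
    with_seed(sub[1], {
      L1 <- sort(sample(leaves, l1))
      shared <- sort(sample(L1, shared_n))
      L2 <- sort(c(shared, setdiff(leaves, L1)))
    })
    t1 <- random_binary_tree(L1, model, seed = sub[2])
    t2 <- random_binary_tree(L2, model, seed = sub[3])
    list(t1 = t1, t2 = t2, leaves = leaves, L1 = L1, L2 = L2, scenario = sc)
  })
}
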