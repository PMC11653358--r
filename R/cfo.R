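# Catch Fish Optimization (CFO): a population metaheuristic alternating an
# exploration phase — independent search toward/away from a random reference
# agent, and cooperative "group capture" toward a 3-4 agent centroid — with
# an exploitation phase that resamples agents from a Gaussian centred on the
# global best with a shrinking spread. Minimization convention throughout.

#' CFO run parameters
#'
#' @param M Population size (>= 4; group capture draws 3-4 agents).
#' @param max_evals Total objective-evaluation budget (>= `M`).
#' @param seed RNG seed; fixes the whole run.
#' @param phase_split Fraction of the budget spent exploring (0.5: the
#'   exploration/exploitation ratio is evenly distributed).
#' @param group_sizes Allowed group-capture sizes.
#' @return A `cfo_params` list.
#' @export
cfo_params <- function(M = 30L, max_evals = 5000L, seed = 1L,
                       phase_split = 0.5, group_sizes = c(3L, 4L)) {
  M <- as.integer(M); max_evals <- as.integer(max_evals)
  if (M < 4L) stop("population size M must be >= 4 (group capture needs 3-4 agents)")
  if (max_evals < M) stop("evaluation budget (", max_evals, ") smaller than population (", M, ")")
  structure(list(M = M, max_evals = max_evals, seed = as.integer(seed),
                 phase_split = phase_split, group_sizes = as.integer(group_sizes)),
            class = "cfo_params")
}

#' Initialize a fisher population uniformly within bounds
#'
#' Position `x[j, k] = (ub[k] - lb[k]) * n + lb[k]` with `n ~ U(0, 1)`,
#' drawn under the params seed. Fitness starts unevaluated.
#'
#' @param params A [cfo_params()].
#' @param lb,ub Bound vectors (recycled to a common length).
#' @return An object of class `fisher_population`.
#' @export
init_population <- function(params, lb, ub) {
  w <- max(length(lb), length(ub))
  lb <- rep_len(as.numeric(lb), w); ub <- rep_len(as.numeric(ub), w)
  if (any(lb > ub)) {
    stop("lower bound exceeds upper bound in dimension(s) ",
         paste(which(lb > ub), collapse = ", "))
  }
  set.seed(params$seed)
  n <- matrix(stats::runif(params$M * w), params$M, w)
  pos <- sweep(sweep(n, 2L, ub - lb, `*`), 2L, lb, `+`)
  structure(list(positions = pos, fitness = rep(NA_real_, params$M),
                 lb = lb, ub = ub, EFs = 0L, max_evals = params$max_evals,
                 Gbest = NULL, Gbest_fitness = Inf, params = params),
            class = "fisher_population")
}

#' @export
print.fisher_population <- function(x, ...) {
  cat(sprintf("<fisher_population> %d agents x %d dims, %d/%d evaluations, best %s\n",
              nrow(x$positions), ncol(x$positions), x$EFs, x$max_evals,
              format(x$Gbest_fitness)))
  invisible(x)
}

#' Capture-rate schedule of the exploration phase
#'
#' `(1 - 3*EFs/(2*MaxEFs)) ^ (3*EFs/(2*MaxEFs))`: 1 at the start, decaying
#' as the budget is spent. Defined only while `EFs/MaxEFs < 2/3` (the base
#' turns negative beyond that; the exploration phase ends at 1/2 anyway).
#' Agents with a uniform draw below the capture rate search independently;
#' the rest join group captures.
#'
#' @param EFs Evaluations spent so far.
#' @param max_evals Total budget.
#' @return The capture rate, in `[0, 1]`.
#' @export
capture_rate <- function(EFs, max_evals) {
  u <- 1.5 * EFs / max_evals
  if (u >= 1) {
    stop("capture rate undefined for EFs/max_evals >= 2/3 (negative base, fractional exponent)")
  }
  (1 - u)^u
}

clamp_bounds <- function(x, lb, ub) pmin(pmax(x, lb), ub)

#' Independent-search move of one agent
#'
#' Picks a random reference agent, computes the empirical factor
#' `Exp = (fit_j - fit_ref) / (fit_max - fit_min)` (0 when all fitness
#' values are equal), and moves `Exp` of the way toward the reference (away
#' when the reference is worse), plus isotropic noise of radius
#' `S = D * Exp * (1 - EFs/MaxEFs)` along a random unit vector (`D` is the
#' distance to the reference). The result is clamped to the bounds.
#'
#' @param pop A [init_population()] with evaluated fitness.
#' @param j Agent index.
#' @return New position vector for agent `j`.
#' @export
independent_search <- function(pop, j) {
  M <- nrow(pop$positions)
  if (M < 2L) stop("independent search needs at least two agents")
  pos <- sample(setdiff(seq_len(M), j), 1L)
  fmax <- max(pop$fitness); fmin <- min(pop$fitness)
  Exp <- if (fmax == fmin) 0 else (pop$fitness[j] - pop$fitness[pos]) / (fmax - fmin)
  xj <- pop$positions[j, ]; xp <- pop$positions[pos, ]
  D <- sqrt(sum((xp - xj)^2))
  S <- D * Exp * (1 - pop$EFs / pop$max_evals)
  e <- stats::rnorm(length(xj))
  e <- if (all(e == 0)) e else e / sqrt(sum(e^2))
  ns <- stats::runif(1)
  clamp_bounds(xj + (xp - xj) * Exp + ns * e * S, pop$lb, pop$ub)
}

#' Group-capture move of a 3-4 agent group
#'
#' Each member moves toward the group centroid with a per-agent speed
#' `n2 ~ U(0, 1)`, plus a per-dimension offset `(1 - 2*EFs/MaxEFs)^2 * n3`
#' with `n3 ~ U(-1, 1)`; clamped to the bounds.
#'
#' @param pop A [init_population()].
#' @param group Vector of 3 or 4 distinct agent indices.
#' @return Matrix of new positions, one row per group member.
#' @export
group_capture <- function(pop, group) {
  if (!length(group) %in% c(3L, 4L) || anyDuplicated(group)) {
    stop("group capture needs 3 or 4 distinct agents, got ", length(group))
  }
  centre <- colMeans(pop$positions[group, , drop = FALSE])
  decay <- (1 - 2 * pop$EFs / pop$max_evals)^2
  out <- matrix(NA_real_, length(group), ncol(pop$positions))
  for (i in seq_along(group)) {
    j <- group[i]
    n2 <- stats::runif(1)
    n3 <- stats::runif(ncol(pop$positions), -1, 1)
    out[i, ] <- clamp_bounds(
      pop$positions[j, ] + n2 * (centre - pop$positions[j, ]) + decay * n3,
      pop$lb, pop$ub)
  }
  out
}

#' Exploitation move: Gaussian resampling around the global best
#'
#' Each agent is redrawn from a normal centred at the global best with a
#' per-dimension spread `n4 * eta * mean(|positions - Gbest|) / 3` (the
#' population's mean absolute deviation from the global best in that
#' dimension), where `n4` is a random integer in {1, 2, 3} and
#' `eta = 2 * (1 - r) / (1 - 2r)^2` (r = `EFs/MaxEFs`) clamped to `[0, 1]`,
#' so the spread anneals from the population's own dispersion toward 0 over
#' the second half of the budget and vanishes once the population has
#' collapsed onto the best point.
#'
#' @param pop A [init_population()] with a current global best.
#' @return Matrix of new positions (all agents).
#' @export
exploitation_step <- function(pop) {
  r <- pop$EFs / pop$max_evals
  if (r < 0.5) stop("exploitation phase requires EFs/max_evals >= 0.5")
  eta <- min(1, max(0, 2 * (1 - r) / (1 - 2 * r)^2))
  if (r == 1) eta <- 0
  dev <- abs(sweep(pop$positions, 2L, pop$Gbest, `-`))
  spread_base <- eta * colMeans(dev) / 3
  M <- nrow(pop$positions); w <- ncol(pop$positions)
  out <- matrix(NA_real_, M, w)
  for (j in seq_len(M)) {
    n4 <- sample(1:3, 1L)
    out[j, ] <- clamp_bounds(pop$Gbest + stats::rnorm(w, 0, n4 * spread_base),
                             pop$lb, pop$ub)
  }
  out
}

# split n agents into groups of 3-4; returns list of index vectors plus the
# leftover (0-2 agents) that fall back to independent search
partition_groups <- function(idx) {
  n <- length(idx)
  sizes <- integer(0)
  while (n >= 3L) {
    s <- if (n == 3L || n == 5L || n == 6L) 3L else 4L
    sizes <- c(sizes, s)
    n <- n - s
  }
  groups <- list()
  at <- 1L
  for (s in sizes) {
    groups[[length(groups) + 1L]] <- idx[at:(at + s - 1L)]
    at <- at + s
  }
  list(groups = groups, leftover = if (at <= length(idx)) idx[at:length(idx)] else integer(0))
}

#' Minimize an objective over a box with Catch Fish Optimization
#'
#' Spends the first half of the evaluation budget exploring (independent
#' search vs. group capture, chosen per agent against the capture-rate
#' schedule) and the second half exploiting (Gaussian resampling around the
#' global best). The global best is tracked over every evaluation and its
#' trace is strictly non-increasing. Fully reproducible from the params
#' seed; the final evaluation count equals the budget exactly.
#'
#' @param fobj Objective: `function(x)` returning a scalar, or with
#'   `vectorized = TRUE` a `function(X)` mapping a matrix (rows = positions)
#'   to a vector.
#' @param lb,ub Box bounds.
#' @param params A [cfo_params()].
#' @param vectorized Whether `fobj` accepts a position matrix.
#' @return An object of class `cfo_result`: `Gbest`, `Gbest_fitness`, a
#'   `trace` tibble (`eval`, `fitness` = best-so-far), and the final
#'   population.
#' @export
cfo_optimize <- function(fobj, lb, ub, params = cfo_params(), vectorized = FALSE) {
  pop <- init_population(params, lb, ub)
  evalf <- if (vectorized) fobj else function(X) apply(X, 1L, fobj)
  M <- params$M
  trace <- numeric(params$max_evals)

  register <- function(pop, idx, fit) {
    for (i in seq_along(idx)) {
      pop$fitness[idx[i]] <- fit[i]
      pop$EFs <- pop$EFs + 1L
      if (fit[i] < pop$Gbest_fitness) {
        pop$Gbest_fitness <- fit[i]
        pop$Gbest <- pop$positions[idx[i], ]
      }
      trace[pop$EFs] <<- pop$Gbest_fitness
    }
    pop
  }

  k0 <- min(M, params$max_evals)
  pop <- register(pop, seq_len(k0), evalf(pop$positions[seq_len(k0), , drop = FALSE]))

  while (pop$EFs < params$max_evals) {
    r <- pop$EFs / pop$max_evals
    k <- min(M, params$max_evals - pop$EFs)
    active <- seq_len(k)
    newpos <- pop$positions
    if (r < params$phase_split) {
      a_hat <- capture_rate(pop$EFs, pop$max_evals)
      p <- stats::runif(k)
      indep <- active[p < a_hat]
      grouped <- setdiff(active, indep)
      part <- partition_groups(sample(grouped))
      indep <- c(indep, part$leftover)
      for (j in indep) newpos[j, ] <- independent_search(pop, j)
      for (gr in part$groups) newpos[gr, ] <- group_capture(pop, gr)
    } else {
      newpos[active, ] <- exploitation_step(pop)[active, , drop = FALSE]
    }
    pop$positions[active, ] <- newpos[active, , drop = FALSE]
    pop <- register(pop, active, evalf(pop$positions[active, , drop = FALSE]))
  }

  structure(list(Gbest = pop$Gbest, Gbest_fitness = pop$Gbest_fitness,
                 trace = tibble::tibble(eval = seq_len(params$max_evals),
                                        fitness = trace),
                 population = pop, params = params),
            class = "cfo_result")
}

#' @export
print.cfo_result <- function(x, ...) {
  cat(sprintf("<cfo_result> best fitness %.6g after %d evaluations (%d-dim)\n",
              x$Gbest_fitness, nrow(x$trace), length(x$Gbest)))
  invisible(x)
}

#' @export
tidy.cfo_result <- function(x, ...) x$trace

#' @export
glance.cfo_result <- function(x, ...) {
  tibble::tibble(best_fitness = x$Gbest_fitness, evals = nrow(x$trace),
                 dims = length(x$Gbest), M = x$params$M, seed = x$params$seed)
}

#' Named test objectives for optimizer checks
#'
#' `sphere` (sum of squares), `quadratic1d` ((x - 3)^2) and `rastrigin`,
#' addressable by name; all vectorized over position matrices.
#'
#' @param name Objective name.
#' @return A vectorized objective `function(X)`.
#' @export
test_objective <- function(name = c("sphere", "quadratic1d", "rastrigin")) {
  name <- match.arg(name)
  switch(name,
         sphere = function(X) rowSums(as.matrix(X)^2),
         quadratic1d = function(X) (as.matrix(X)[, 1] - 3)^2,
         rastrigin = function(X) {
           X <- as.matrix(X)
           10 * ncol(X) + rowSums(X^2 - 10 * cos(2 * pi * X))
         })
}
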