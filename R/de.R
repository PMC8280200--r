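#' Differential-evolution optimizer (rand/1/bin)
#'
#' Minimal differential evolution over box constraints, used by all fitting
#' stages.  The cost callback receives the candidate vector and the current
#' generation index, so stochastic costs can derive a per-generation seed and
#' rank all candidates of a generation on identical noise draws (common
#' random numbers).
#'
#' @param fn cost function \code{fn(par, gen)} returning a finite scalar
#'   (large values act as penalties).
#' @param lower,upper numeric bounds (equal length).
#' @param n_pop population size (>= 4).
#' @param strategy mutation base: "rand" (rand/1/bin, default) explores;
#'   "best" (best/1/bin) exploits the current best member, useful as a
#'   final refinement phase on shallow cost valleys.
#' @param F mutation factor.
#' @param CR crossover rate.
#' @param max_gen maximum generations.
#' @param target stop early once the best cost is <= \code{target}.
#' @param tol,tol_steps stop early when the relative improvement of the best
#'   cost over the last \code{tol_steps} generations falls below \code{tol}.
#' @param init optional initial population matrix (n_pop x length(lower));
#'   rows are clamped to the bounds.
#' @param reevaluate if \code{TRUE}, re-score the surviving population at
#'   the start of every generation (with that generation's index passed to
#'   \code{fn}).  With stochastic costs under common random numbers this
#'   makes parent/trial comparisons consistent and prevents members from
#'   surviving on a lucky noise draw, at the price of twice the number of
#'   cost evaluations.
#' @param seed RNG seed for the optimizer's own draws.
#' @return list with \code{par}, \code{value}, \code{pop} (final population),
#'   \code{values} (final costs), \code{n_gen}, \code{trace} (best cost per
#'   generation).
#' @export
de_optimize <- function(fn, lower, upper, n_pop = 50, F = 0.7, CR = 0.9,
                        max_gen = 200, target = -Inf, tol = 0,
                        tol_steps = 20, init = NULL, reevaluate = FALSE,
                        strategy = c("rand", "best"), seed = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(length(lower) == length(upper), all(upper >= lower), n_pop >= 4)
  d <- length(lower)
  if (!is.null(seed)) set.seed(seed)
  clamp <- function(x) pmin(pmax(x, lower), upper)
  pop <- matrix(runif(n_pop * d, rep(lower, each = n_pop),
                      rep(upper, each = n_pop)), n_pop, d)
  if (!is.null(init)) {
    stopifnot(ncol(init) == d)
    k <- min(nrow(init), n_pop)
    pop[seq_len(k), ] <- t(apply(init[seq_len(k), , drop = FALSE], 1, clamp))
  }
  vals <- vapply(seq_len(n_pop), function(j) fn(pop[j, ], 0L), numeric(1))
  trace <- min(vals)
  for (g in seq_len(max_gen)) {
    if (reevaluate)
      vals <- vapply(seq_len(n_pop), function(j) fn(pop[j, ], g),
                     numeric(1))
    # pre-draw the optimizer's own randomness so fn's RNG use cannot
    # interfere with the evolution
    r_idx <- matrix(0L, n_pop, 3)
    for (j in seq_len(n_pop))
      r_idx[j, ] <- sample(setdiff(seq_len(n_pop), j), 3)
    r_cr <- matrix(runif(n_pop * d), n_pop, d)
    j_rand <- sample.int(d, n_pop, replace = TRUE)
    best_j <- which.min(vals)
    for (j in seq_len(n_pop)) {
      a <- if (strategy == "best") pop[best_j, ] else pop[r_idx[j, 1], ]
      b <- pop[r_idx[j, 2], ]
      cc <- pop[r_idx[j, 3], ]
      mutant <- clamp(a + F * (b - cc))
      cross <- r_cr[j, ] < CR
      cross[j_rand[j]] <- TRUE
      trial <- ifelse(cross, mutant, pop[j, ])
      v <- fn(trial, g)
      if (v <= vals[j]) { pop[j, ] <- trial; vals[j] <- v }
    }
    trace <- c(trace, min(vals))
    if (min(vals) <= target) break
    if (tol > 0 && length(trace) > tol_steps) {
      prev <- trace[length(trace) - tol_steps]
      if (prev - min(vals) <= tol * max(abs(prev), 1e-12)) break
    }
  }
  best <- which.min(vals)
  list(par = pop[best, ], value = vals[best], pop = pop, values = vals,
       n_gen = length(trace) - 1L, trace = trace)
}
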