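# Simulation front-ends over the compiled integrators.

# Internal: resolve step/recording layout.  The integration step is nudged
# to the nearest exact divisor of the sampling interval (dt_eff =
# sample_h / round(sample_h / dt)), so recorded times fall exactly on the
# requested grid and any two simulations sharing (dt, sample_h) share the
# same discretization.
sim_layout <- function(t_end, dt, sample_h) {
  stopifnot(t_end > 0, dt > 0, sample_h > 0)
  thin <- max(1L, as.integer(round(sample_h / dt)))
  dt_eff <- sample_h / thin
  n_steps <- as.integer(floor(t_end / dt_eff + 1e-9))
  list(thin = thin, n_steps = n_steps, dt = dt_eff)
}

traj_df <- function(mat) {
  out <- as.data.frame(mat)
  names(out) <- c("time_h", "M", "P", "R", "lum")
  out
}

#' Simulate one stochastic cell
#'
#' Integrates the clock SDE by fixed-step Euler-Maruyama: at each step every
#' state variable receives its drift increment plus an independent
#' \code{sigma * sqrt(dt) * N(0, 1)} perturbation.  The reporter luminescence
#' is the activation fraction \code{f(R, A)} at each recorded time.
#'
#' @param params a \code{\link{clock_parameters}} object.
#' @param protocol a \code{\link{light_protocol}}.
#' @param x0 initial state \code{c(M, P, R)}; defaults to the 10-day
#'   light-dark burn-in state (\code{\link{burn_in_state}}).
#' @param t_end simulation span in hours (defaults to the protocol duration).
#' @param dt integration step (h), default 0.01.
#' @param sample_h recording interval (h), default 2/3 h (the 40-min plate
#'   reader cadence).  \code{dt} is nudged to the nearest exact divisor of
#'   \code{sample_h} so recorded times fall exactly on this grid.
#' @param seed RNG seed; identical seed and inputs give an identical
#'   trajectory.  Each (seed, cell) pair keys an independent counter-based
#'   random stream, so a cell's draws never depend on what else is
#'   simulated.
#' @param cell stream index within the seed (cell 1 of
#'   \code{\link{simulate_population}} with the same seed is this exact
#'   trajectory).
#' @return a \code{clock_trajectory}: data.frame with columns \code{time_h},
#'   \code{M}, \code{P}, \code{R}, \code{lum}.
#' @export
simulate_single_cell <- function(params, protocol, x0 = NULL, t_end = NULL,
                                 dt = 0.01, sample_h = 2 / 3, seed = 1,
                                 cell = 1) {
  stopifnot(inherits(params, "clock_parameters"),
            inherits(protocol, "light_protocol"))
  if (is.null(t_end)) t_end <- protocol$total_duration
  if (is.null(x0)) x0 <- burn_in_state(params)
  lay <- sim_layout(t_end, dt, sample_h)
  res <- cpp_simulate_cell(par_vec(params), protocol_matrix(protocol),
                           as.numeric(x0), lay$dt, lay$n_steps, lay$thin,
                           params$sigma, seed, cell)
  out <- traj_df(res$traj)
  attr(out, "params") <- params
  attr(out, "final_state") <- res$final
  attr(out, "seed") <- seed
  class(out) <- c("clock_trajectory", class(out))
  out
}

#' Simulate the deterministic clock
#'
#' Integrates the noise-free model (\code{sigma} forced to 0) with a
#' fixed-step classical Runge-Kutta scheme; the result is independent of the
#' RNG state.
#'
#' @inheritParams simulate_single_cell
#' @return a \code{clock_trajectory} data.frame.
#' @export
simulate_deterministic <- function(params, protocol, x0 = NULL, t_end = NULL,
                                   dt = 0.01, sample_h = 2 / 3) {
  stopifnot(inherits(params, "clock_parameters"),
            inherits(protocol, "light_protocol"))
  if (is.null(t_end)) t_end <- protocol$total_duration
  if (is.null(x0)) x0 <- burn_in_state(params)
  lay <- sim_layout(t_end, dt, sample_h)
  res <- cpp_simulate_rk4(par_vec(params), protocol_matrix(protocol),
                          as.numeric(x0), lay$dt, lay$n_steps, lay$thin,
                          TRUE)
  out <- traj_df(res$traj)
  attr(out, "params") <- params
  attr(out, "final_state") <- res$final
  class(out) <- c("clock_trajectory", class(out))
  out
}

#' Burn-in initial state under entraining light-dark cycles
#'
#' Runs the deterministic model under 12:12 LD cycles (dark phase first) for
#' the given number of days and returns the final state.  Because each cycle
#' ends with its light phase, the returned state sits exactly at a
#' light-to-dark transition, the reference point used when initial conditions
#' are fixed for compound-series fitting.
#'
#' @param params a \code{\link{clock_parameters}} object.
#' @param days burn-in length in days (default 10).
#' @param x0 starting state, default \code{c(0, 0, 0)}.
#' @param dt integration step (h).
#' @return numeric state vector \code{c(M, P, R)}.
#' @export
burn_in_state <- function(params, days = 10, x0 = c(0, 0, 0), dt = 0.02) {
  stopifnot(inherits(params, "clock_parameters"), days > 0)
  prot <- ld_cycle(12, 12, ceiling(days))
  n_steps <- as.integer(round(days * 24 / dt))
  res <- cpp_simulate_rk4(par_vec(params), protocol_matrix(prot),
                          as.numeric(x0), dt, n_steps, n_steps, FALSE)
  as.numeric(res$final)
}

#' Simulate a population of independent cells
#'
#' Runs \code{n} independent single-cell stochastic simulations and averages
#' their luminescence pointwise, emulating a plate well in which thousands of
#' uncoupled cellular oscillators contribute to one bioluminescence signal.
#' All cells start from the same burn-in state; cell-to-cell diversity arises
#' from the noise during simulation (optionally preceded by a stochastic
#' dark pre-roll that disperses phases before t = 0).
#'
#' Each cell draws from its own RNG stream (a per-cell seed derived from
#' \code{seed}), so the draws of cell j do not depend on \code{n} or on
#' \code{record_cells}.
#'
#' @inheritParams simulate_single_cell
#' @param n number of cells (>= 1); 30,000 reproduces reported population
#'   traces, 1,000 is the economical setting used during fitting.
#' @param record_cells how many single-cell luminescence traces to retain
#'   (0 = none).
#' @param preroll_h hours of stochastic constant-darkness simulation run per
#'   cell before t = 0 (discarded) to de-correlate phases; default 0.
#' @param seed root RNG seed (required for reproducibility; defaults to 1).
#' @return a \code{population_result} list with \code{time_h},
#'   \code{mean_lum}, \code{n}, \code{cells} (matrix time x retained cells or
#'   NULL), \code{seed}, \code{params}, \code{protocol}.
#' @export
simulate_population <- function(params, protocol, n = 1000, x0 = NULL,
                                t_end = NULL, dt = 0.01, sample_h = 2 / 3,
                                seed = 1, record_cells = 0, preroll_h = 0) {
  stopifnot(inherits(params, "clock_parameters"),
            inherits(protocol, "light_protocol"))
  if (n < 1) stop("'n' must be >= 1")
  if (is.null(t_end)) t_end <- protocol$total_duration
  if (is.null(x0)) x0 <- burn_in_state(params)
  lay <- sim_layout(t_end, dt, sample_h)
  record_cells <- min(record_cells, n)
  n_pre <- if (preroll_h > 0) as.integer(round(preroll_h / lay$dt)) else 0L
  res <- cpp_simulate_population(par_vec(params), protocol_matrix(protocol),
                                 as.numeric(x0), lay$dt, lay$n_steps,
                                 lay$thin, params$sigma, as.integer(n),
                                 seed, as.integer(record_cells), n_pre)
  structure(list(time_h = res$time, mean_lum = res$mean_lum, n = n,
                 cells = if (record_cells > 0) res$cells else NULL,
                 seed = seed, params = params, protocol = protocol),
            class = "population_result")
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf("Population luminescence: %d cells, %d samples over %.6g h\n",
              x$n, length(x$time_h), max(x$time_h)))
  cat(sprintf("  mean level %.4g, seed %d, %s retained single-cell trace(s)\n",
              mean(x$mean_lum), x$seed,
              if (is.null(x$cells)) "no" else as.character(ncol(x$cells))))
  invisible(x)
}

#' @export
plot.population_result <- function(x, ...) {
  plot_trace_with_light(x$time_h, x$mean_lum, x$protocol,
                        ylab = "mean luminescence (a.u.)", ...)
  invisible(x)
}

# Internal shared plotting helper: trace with shaded dark intervals.
plot_trace_with_light <- function(time_h, value, protocol = NULL,
                                  ylab = "value", main = NULL, ...) {
  plot(time_h, value, type = "n", xlab = "time (h)", ylab = ylab,
       main = main, ...)
  if (!is.null(protocol)) {
    s <- protocol$segments
    usr <- graphics::par("usr")
    for (k in seq_len(nrow(s))) {
      if (s$level[k] == 0)
        graphics::rect(s$start[k], usr[3], min(s$end[k], max(time_h)), usr[4],
                       col = grDevices::grey(0.9), border = NA)
    }
  }
  graphics::lines(time_h, value)
  graphics::box()
}
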