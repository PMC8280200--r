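# Four-stage differential-evolution fitting pipeline:
#   C1 deterministic period/phase targets (equal degradation, sigma = 0)
#   C2 noise intensity from the population damping ratio
#   C3 full trace fit, equal degradation kept, oscillation screen on
#   C4 compound-series fit, constraints relaxed, iterated over concentrations

#' Control settings for the fitting pipeline
#'
#' Collects integration steps, simulation sizes, parameter bounds and
#' per-stage differential-evolution settings.  Defaults reproduce the study
#' conditions (50 stage-1 runs, 1,000 cells per stochastic cost evaluation);
#' tests and examples pass reduced sizes.
#'
#' @param dt deterministic integration step (h).
#' @param dt_sde stochastic integration step (h).
#' @param sample_h recording cadence (h), default 40 min.
#' @param n_cells cells per stochastic population evaluation.
#' @param bounds named list of \code{c(lower, upper)} for \code{A}, \code{d}
#'   (common degradation), \code{i}, \code{sigma}.
#' @param max_cost penalty returned when the deterministic screen fails or a
#'   simulation cannot be scored; dominates any attainable mean squared
#'   error.
#' @param stage1,stage2,stage3,stage4 per-stage lists overriding the
#'   defaults shown in the function definition (population size, mutation
#'   factor \code{F}, crossover \code{CR}, generation caps, early-stop
#'   settings, stage-specific sizes).
#' @param seed root seed; every stage derives its own streams from it.
#' @return list of class \code{clock_fit_control}.
#' @export
clock_fit_control <- function(dt = 0.02, dt_sde = 0.05, sample_h = 2 / 3,
                              n_cells = 1000,
                              bounds = list(A = c(0.001, 5),
                                            d = c(0.01, 2),
                                            i = c(0, 0.2),
                                            sigma = c(0, 0.5)),
                              max_cost = 1e6,
                              stage1 = list(), stage2 = list(),
                              stage3 = list(), stage4 = list(),
                              seed = 1) {
  s1 <- utils::modifyList(list(n_runs = 50, n_pop = 50, F = 0.7, CR = 0.9,
                               max_gen = 200, target = 0.05, tol = 1e-4,
                               tol_steps = 15, accept = 0.25, retries = 5),
                          stage1)
  s2 <- utils::modifyList(list(n_pop = 8, F = 0.7, CR = 0.9, max_gen = 20,
                               entrain_cycles = 3, dd_days = 6,
                               n_cells = NULL), stage2)
  s3 <- utils::modifyList(list(n_pop = NULL, F = 0.7, CR = 0.9,
                               max_gen = 100, tol = 1e-3, tol_steps = 20),
                          stage3)
  s4 <- utils::modifyList(list(n_pop = NULL, F = 0.7, CR = 0.9,
                               max_gen = 100, tol = 1e-3, tol_steps = 20),
                          stage4)
  structure(list(dt = dt, dt_sde = dt_sde, sample_h = sample_h,
                 n_cells = n_cells, bounds = bounds, max_cost = max_cost,
                 stage1 = s1, stage2 = s2, stage3 = s3, stage4 = s4,
                 seed = seed),
            class = "clock_fit_control")
}

wrap_12 <- function(x) ((x + 12) %% 24) - 12

# Internal: grow an initial DE population to n_pop rows by adding
# multiplicatively jittered copies of the seed members (10% lognormal),
# preserving diversity around the previous stage's solutions.
pad_init <- function(init, n_pop, seed) {
  if (nrow(init) >= n_pop) return(init)
  set.seed(seed)
  extra <- init[sample.int(nrow(init), n_pop - nrow(init),
                           replace = TRUE), , drop = FALSE]
  extra <- extra * matrix(exp(rnorm(length(extra), 0, 0.1)),
                          nrow(extra), ncol(extra))
  rbind(init, extra)
}

params_from_x <- function(x) {
  # x = (A, d, i, sigma) equal degradation, or (A, d_M, d_P, d_R, i, sigma)
  if (length(x) == 4L)
    clock_parameters(A = x[1], d_M = x[2], i = x[3], sigma = x[4])
  else
    clock_parameters(A = x[1], d_M = x[2], d_P = x[3], d_R = x[4],
                     i = x[5], sigma = x[6])
}

#' Stage-1 cost: deterministic circadian period and phase tracking
#'
#' For a noise-free, equal-degradation parameter set, measures the
#' free-running period in constant darkness \eqn{T_{DD}}, the entrained
#' period under a 12:12 light-dark cycle \eqn{T_{LD}}, and the entrained
#' peak phases \eqn{P_{LD}}, \eqn{P_{LDs}} under the cycle and the cycle
#' offset by 12 h, and returns
#' \deqn{C_1 = (T_{DD} - 24)^2 + (T_{LD} - 24)^2 +
#'       (P_{LD} - P_{LDs} + 12)^2,}
#' with the phase term wrapped to \eqn{(-12, 12]} before squaring.  Phases
#' are peak times of the deterministic luminescence after a 5-day transient,
#' taken modulo the 24-h cycle.  Non-oscillatory sets (or failed
#' simulations) return the penalty \code{max_cost}.
#'
#' @param A,d,i activator concentration, common degradation rate, light
#'   sensitivity.
#' @param control a \code{\link{clock_fit_control}}.
#' @return scalar cost.
#' @export
cost_c1 <- function(A, d, i, control = clock_fit_control()) {
  params <- clock_parameters(A = A, d_M = d, i = i, sigma = 0)
  res <- tryCatch({
    x0 <- burn_in_state(params, days = 6, dt = control$dt)
    dd <- simulate_deterministic(params, constant_protocol(0, 240),
                                 x0 = x0, dt = control$dt,
                                 sample_h = control$sample_h)
    if (!sustained_oscillations(dd$time_h, dd$lum, transient_h = 48))
      stop("no sustained free-running oscillations")
    t_dd <- estimate_period(dd$time_h, dd$lum, transient_h = 120)

    ld <- simulate_deterministic(params, ld_cycle(12, 12, 10), x0 = x0,
                                 dt = control$dt, sample_h = control$sample_h)
    t_ld <- estimate_period(ld$time_h, ld$lum, transient_h = 120)
    pk_ld <- detect_peaks(ld$time_h[ld$time_h >= 120],
                          ld$lum[ld$time_h >= 120])
    lds <- simulate_deterministic(params,
                                  ld_cycle(12, 12, 10,
                                           lights_on_first = TRUE),
                                  x0 = x0, dt = control$dt,
                                  sample_h = control$sample_h)
    pk_lds <- detect_peaks(lds$time_h[lds$time_h >= 120],
                           lds$lum[lds$time_h >= 120])
    if (nrow(pk_ld) < 1 || nrow(pk_lds) < 1) stop("no entrained peaks")
    p_ld <- tail(pk_ld$time, 1) %% 24
    p_lds <- tail(pk_lds$time, 1) %% 24
    (t_dd - 24)^2 + (t_ld - 24)^2 + wrap_12(p_ld - p_lds + 12)^2
  }, error = function(e) control$max_cost)
  res
}

new_parameter_population <- function(members, costs, stage,
                                     treatment = NA_character_,
                                     concentration = NA_real_) {
  stopifnot(nrow(members) == length(costs))
  structure(list(members = members, costs = costs, stage = stage,
                 treatment = treatment, concentration = concentration),
            class = "parameter_population")
}

#' @export
print.parameter_population <- function(x, ...) {
  cat(sprintf("Parameter population: %d member(s), stage %s\n",
              nrow(x$members), x$stage))
  cat(sprintf("  cost: best %.4g, median %.4g\n", min(x$costs),
              median(x$costs)))
  print(head(x$members, 4))
  if (nrow(x$members) > 4) cat("  ...\n")
  invisible(x)
}

#' @export
`[.parameter_population` <- function(x, idx) {
  new_parameter_population(x$members[idx, , drop = FALSE], x$costs[idx],
                           x$stage, x$treatment, x$concentration)
}

member_params <- function(pop, j) {
  m <- pop$members[j, ]
  clock_parameters(A = m$A, d_M = m$d_M, d_P = m$d_P, d_R = m$d_R,
                   i = m$i, sigma = m$sigma)
}

#' Stage 1: fit a population of deterministic circadian parameter sets
#'
#' Repeats an independent differential-evolution minimization of
#' \code{\link{cost_c1}} over (A, d, i) with sigma = 0 and equal degradation
#' rates; the winner of each run becomes one member of the returned
#' population (50 members under default settings).  Runs whose final cost
#' exceeds the acceptance threshold (default 0.25, i.e. a combined
#' period/phase error of half an hour) are retried with a fresh seed.
#'
#' @param control a \code{\link{clock_fit_control}}.
#' @param verbose print per-run progress.
#' @return a \code{parameter_population} (stage "C1", sigma = 0 members).
#' @export
stage1_fit <- function(control = clock_fit_control(), verbose = FALSE) {
  b <- control$bounds
  s1 <- control$stage1
  lower <- c(b$A[1], b$d[1], b$i[1])
  upper <- c(b$A[2], b$d[2], b$i[2])
  members <- NULL
  costs <- numeric(0)
  for (r in seq_len(s1$n_runs)) {
    res <- NULL
    for (att in 0:s1$retries) {
      run_seed <- control$seed + 1009L * r + 31L * att
      cand <- de_optimize(function(x, gen) cost_c1(x[1], x[2], x[3],
                                                   control),
                          lower, upper, n_pop = s1$n_pop, F = s1$F,
                          CR = s1$CR, max_gen = s1$max_gen,
                          target = s1$target, tol = s1$tol,
                          tol_steps = s1$tol_steps, seed = run_seed)
      if (cand$value <= s1$accept) { res <- cand; break }
      if (verbose)
        message(sprintf("stage 1 run %d attempt %d: cost %.3g, retrying",
                        r, att + 1, cand$value))
    }
    if (is.null(res))
      stop("stage 1 run ", r, " failed to reach an acceptable cost after ",
           s1$retries + 1, " attempts")
    members <- rbind(members,
                     data.frame(A = res$par[1], d_M = res$par[2],
                                d_P = res$par[2], d_R = res$par[2],
                                i = res$par[3], sigma = 0))
    costs <- c(costs, res$value)
    if (verbose)
      message(sprintf("stage 1 run %d: C1 = %.4g (%d generations)", r,
                      res$value, res$n_gen))
  }
  rownames(members) <- NULL
  new_parameter_population(members, costs, "C1")
}

# Internal: population-mean luminescence in DD after LD entrainment,
# z-scored, with time measured from the release into darkness.
dd_release_trace <- function(params, control, seed,
                             entrain_cycles = 3, dd_days = 6,
                             n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- control$n_cells
  prot <- concat_protocols(ld_cycle(12, 12, entrain_cycles),
                           constant_protocol(0, dd_days * 24))
  x0 <- burn_in_state(params, days = 6, dt = control$dt)
  pop <- simulate_population(params, prot, n = n_cells, x0 = x0,
                             dt = control$dt_sde,
                             sample_h = control$sample_h, seed = seed)
  keep <- pop$time_h >= entrain_cycles * 24
  list(time_h = pop$time_h[keep] - entrain_cycles * 24,
       value = pop$mean_lum[keep])
}

#' Stage-2 cost: match the population damping ratio
#'
#' Simulates the population with candidate noise intensity \code{sigma} in
#' constant darkness after light-dark entrainment, fits a damped sine to the
#' z-scored population mean, and returns \eqn{C_2 = (d_{data} -
#' d_{model})^2}.
#'
#' @param sigma candidate noise intensity.
#' @param base_params a \code{\link{clock_parameters}} set from stage 1
#'   (all parameters but sigma are held fixed).
#' @param d_data damping ratio estimated from the recordings (1/h).
#' @param control a \code{\link{clock_fit_control}}.
#' @param seed RNG seed for the population simulation.
#' @return scalar cost.
#' @export
cost_c2 <- function(sigma, base_params, d_data,
                    control = clock_fit_control(), seed = 1) {
  params <- clock_parameters(A = base_params$A, d_M = base_params$d_M,
                             d_P = base_params$d_P, d_R = base_params$d_R,
                             i = base_params$i, sigma = sigma)
  s2 <- control$stage2
  tryCatch({
    tr <- dd_release_trace(params, control, seed,
                           entrain_cycles = s2$entrain_cycles,
                           dd_days = s2$dd_days, n_cells = s2$n_cells)
    z <- zscore(tr$value)
    fit <- fit_damped_sine(tr$time_h, z)
    # over-damped guard: when the rhythm is dead within the first day the
    # sine locks onto flat Monte-Carlo noise and would report a spuriously
    # small damping; such fits explain almost none of the variance, so a
    # poor fit (R^2 < 0.3) counts as faster-than-measurable damping
    r2 <- 1 - fit$residual / sum(z^2)
    d_model <- if (r2 < 0.3) 0.2 else fit$damping
    (d_data - d_model)^2
  }, error = function(e) control$max_cost)
}

#' Stage 2: estimate the noise intensity for each parameter set
#'
#' For every member of the stage-1 population, fits \code{sigma} by
#' differential evolution on \code{\link{cost_c2}} while all other
#' parameters stay fixed.  Candidates within a generation share a seed, so
#' they are ranked on identical noise draws.
#'
#' @param population a stage-1 \code{parameter_population}.
#' @param d_data damping ratio of the recordings (1/h), e.g. from
#'   \code{\link{fit_damped_sine}} on the first six days of the data.
#' @param control a \code{\link{clock_fit_control}}.
#' @param verbose print per-member progress.
#' @return the population with fitted \code{sigma} values (stage "C2").
#' @export
stage2_estimate_noise <- function(population, d_data,
                                  control = clock_fit_control(),
                                  verbose = FALSE) {
  stopifnot(inherits(population, "parameter_population"))
  s2 <- control$stage2
  b <- control$bounds$sigma
  members <- population$members
  costs <- numeric(nrow(members))
  for (j in seq_len(nrow(members))) {
    base <- member_params(population, j)
    res <- de_optimize(
      function(x, gen) cost_c2(x[1], base, d_data, control,
                               seed = control$seed + 131L * gen + j),
      lower = b[1], upper = b[2], n_pop = s2$n_pop, F = s2$F, CR = s2$CR,
      max_gen = s2$max_gen, reevaluate = TRUE,
      seed = control$seed + 977L * j)
    members$sigma[j] <- res$par[1]
    costs[j] <- res$value
    if (verbose)
      message(sprintf("stage 2 member %d: sigma = %.4g (C2 = %.3g)", j,
                      res$par[1], res$value))
  }
  new_parameter_population(members, costs, "C2")
}

# Internal: z-scored population-mean trace on the data's time grid.
model_trace_on <- function(params, protocol, data_time, control, seed,
                           x0 = NULL, ref_stats = NULL) {
  pop <- simulate_population(params, protocol, n = control$n_cells,
                             x0 = x0, t_end = max(data_time),
                             dt = control$dt_sde,
                             sample_h = control$sample_h, seed = seed)
  m <- approx(pop$time_h, pop$mean_lum, xout = data_time, rule = 2)$y
  if (is.null(ref_stats)) zscore(m) else model_zscore(m, ref_stats)
}

#' Stage-3 cost: mean squared error against the normalized recording
#'
#' \eqn{C_3 = \frac{1}{n} \sum_i (x_i - \hat x_i)^2} between the z-scored
#' data and the z-scored simulated population mean.  Before the stochastic
#' model is evaluated, the deterministic (sigma = 0) model is screened for
#' sustained oscillations in constant darkness; if none are found the cost
#' returns \code{max_cost} without a stochastic evaluation.  Initial
#' conditions come from a 10-day light-dark burn-in, and the
#' equal-degradation constraint is kept.
#'
#' @param params a \code{\link{clock_parameters}} object (equal
#'   degradation).
#' @param data data.frame with \code{time_h} and \code{value} (the raw or
#'   already z-scored recording; z-scoring is applied internally and is
#'   idempotent up to scale).
#' @param protocol the recording's \code{\link{light_protocol}}.
#' @param control a \code{\link{clock_fit_control}}.
#' @param seed RNG seed for the stochastic evaluation.
#' @return scalar cost.
#' @export
cost_c3 <- function(params, data, protocol, control = clock_fit_control(),
                    seed = 1) {
  tryCatch({
    det_params <- clock_parameters(A = params$A, d_M = params$d_M,
                                   d_P = params$d_P, d_R = params$d_R,
                                   i = params$i, sigma = 0)
    x0 <- burn_in_state(det_params, days = 10, dt = control$dt)
    dd <- simulate_deterministic(det_params, constant_protocol(0, 192),
                                 x0 = x0, dt = control$dt,
                                 sample_h = control$sample_h)
    if (!sustained_oscillations(dd$time_h, dd$lum, transient_h = 48))
      return(control$max_cost)
    z_data <- zscore(data$value)
    z_model <- model_trace_on(params, protocol, data$time_h, control, seed,
                              x0 = x0)
    mean((z_data - z_model)^2)
  }, error = function(e) control$max_cost)
}

#' Stage 3: refine all parameters against an untreated recording
#'
#' Differential evolution over (A, d, i, sigma) minimizing
#' \code{\link{cost_c3}}, initialized with the stage-2 population.
#'
#' @param population stage-2 \code{parameter_population}.
#' @param data,protocol as in \code{\link{cost_c3}}.
#' @param control a \code{\link{clock_fit_control}}.  The stage-3 list may
#'   carry a \code{schedule}: a list of phases, each a list with
#'   \code{n_cells}, \code{max_gen}, optional \code{strategy}
#'   (\code{"rand"} or \code{"best"}) and optional \code{n_pop} (shrink to
#'   the best members), run back to back with each phase's final population
#'   seeding the next.  A coarse exploratory phase (few cells, rand/1)
#'   followed by a finer best/1 refinement converges along the shallow
#'   (A, i, sigma) valley of the trace cost at a fraction of the
#'   single-phase cost.
#' @return list with \code{params} (best member), \code{cost},
#'   \code{population} (stage "C3"), \code{e_f} (model efficiency of the
#'   best member against the z-scored data), \code{model} (best-member
#'   normalized trace on the data grid) and \code{trace} (best cost per
#'   generation).
#' @export
stage3_fit <- function(population, data, protocol,
                       control = clock_fit_control()) {
  stopifnot(inherits(population, "parameter_population"))
  s3 <- control$stage3
  b <- control$bounds
  init <- as.matrix(population$members[, c("A", "d_M", "i", "sigma")])
  n_pop <- if (is.null(s3$n_pop)) max(nrow(init), 16L) else s3$n_pop
  n_pop <- max(n_pop, 4L)
  init <- pad_init(init, n_pop, control$seed + 4271L)
  phases <- s3$schedule
  if (is.null(phases))
    phases <- list(list(n_cells = control$n_cells, max_gen = s3$max_gen))
  res <- NULL
  vals <- NULL
  for (ph in seq_along(phases)) {
    ctl_ph <- control
    ctl_ph$n_cells <- phases[[ph]]$n_cells %||% control$n_cells
    np <- phases[[ph]]$n_pop %||% nrow(init)
    if (np < nrow(init) && !is.null(vals))
      init <- init[order(vals)[seq_len(np)], , drop = FALSE]
    res <- de_optimize(
      function(x, gen) cost_c3(params_from_x(x), data, protocol, ctl_ph,
                               seed = control$seed + 131L * gen +
                                 100003L * ph),
      lower = c(b$A[1], b$d[1], b$i[1], b$sigma[1]),
      upper = c(b$A[2], b$d[2], b$i[2], b$sigma[2]),
      n_pop = nrow(init), F = s3$F, CR = s3$CR,
      max_gen = phases[[ph]]$max_gen %||% s3$max_gen,
      strategy = phases[[ph]]$strategy %||% "rand",
      tol = s3$tol, tol_steps = s3$tol_steps, init = init,
      reevaluate = TRUE, seed = control$seed + 7919L + ph)
    init <- res$pop
    vals <- res$values
  }
  best <- params_from_x(res$par)
  members <- data.frame(A = res$pop[, 1], d_M = res$pop[, 2],
                        d_P = res$pop[, 2], d_R = res$pop[, 2],
                        i = res$pop[, 3], sigma = res$pop[, 4])
  x0 <- burn_in_state(best, days = 10, dt = control$dt)
  z_data <- zscore(data$value)
  z_model <- model_trace_on(best, protocol, data$time_h, control,
                            seed = control$seed + 131L * (res$n_gen + 1L),
                            x0 = x0)
  list(params = best, cost = res$value,
       population = new_parameter_population(members, res$values, "C3"),
       e_f = model_efficiency(z_data, z_model), model = z_model,
       trace = res$trace)
}

#' Stage-4 cost: two-segment squared error with relaxed constraints
#'
#' \eqn{C_4 = \frac{1}{n} \sum_i (x_i - \hat x_i)^2 + \frac{1}{m} \sum_i
#' (y_i - \hat y_i)^2} over a light-dark-cycle segment and a constant-dark
#' segment of the same recording.  The initial state \code{x0} is fixed for
#' the whole optimization (taken from the untreated model at a
#' light-to-dark transition), the degradation rates are free to differ, and
#' no oscillation screen is applied, since treated cells need not sustain
#' free-running rhythms.  Data are expected on the adjusted Z-score scale;
#' the model is normalized by the control-parameter simulation's statistics
#' (\code{ref_stats}).
#'
#' @param params a \code{\link{clock_parameters}} object (degradation rates
#'   may differ).
#' @param data_ld,data_dd data.frames with \code{time_h}, \code{value}
#'   (normalized), both on the full protocol's clock.
#' @param protocol the full recording protocol.
#' @param x0 fixed initial state \code{c(M, P, R)}.
#' @param ref_stats control-simulation statistics from
#'   \code{\link{trace_stats}}.
#' @param control a \code{\link{clock_fit_control}}.
#' @param seed RNG seed.
#' @return scalar cost.
#' @export
cost_c4 <- function(params, data_ld, data_dd, protocol, x0, ref_stats,
                    control = clock_fit_control(), seed = 1) {
  tryCatch({
    all_t <- c(data_ld$time_h, data_dd$time_h)
    z_model <- model_trace_on(params, protocol, all_t, control, seed,
                              x0 = x0, ref_stats = ref_stats)
    n_ld <- nrow(data_ld)
    mean((data_ld$value - z_model[seq_len(n_ld)])^2) +
      mean((data_dd$value - z_model[-seq_len(n_ld)])^2)
  }, error = function(e) control$max_cost)
}

#' Stage 4: iterative refit over a compound concentration series
#'
#' Fits each treatment of an ordered concentration series (low to high) by
#' differential evolution on \code{\link{cost_c4}}, seeding every step's
#' initial population with the final population of the previous step
#' (control first).  Fits whose model efficiency is \eqn{\le 0} on the
#' combined data are flagged \code{excluded}.
#'
#' @param control_population the fitted control population (stage 3 result's
#'   \code{population}, or any \code{parameter_population}).
#' @param series named list, ordered low to high concentration; each element
#'   a list with \code{ld} and \code{dd} data.frames (\code{time_h},
#'   \code{value} on the adjusted Z-score scale) and optionally
#'   \code{concentration}.
#' @param protocol the recording protocol.
#' @param control a \code{\link{clock_fit_control}}.
#' @param x0 fixed initial state; default: 10-day burn-in of the control
#'   population's best member, i.e. the untreated model at a light-to-dark
#'   transition.
#' @param ref_stats control-simulation statistics; default: computed from
#'   the control population's best member on \code{protocol}.
#' @return list of per-treatment results, each with \code{params},
#'   \code{cost}, \code{population}, \code{e_f}, \code{excluded},
#'   \code{treatment}, \code{seeded_from}.
#' @export
stage4_refit_series <- function(control_population, series, protocol,
                                control = clock_fit_control(), x0 = NULL,
                                ref_stats = NULL) {
  stopifnot(inherits(control_population, "parameter_population"))
  if (length(series) == 0L) stop("empty concentration series")
  if (is.null(names(series)))
    names(series) <- paste0("treatment_", seq_along(series))
  s4 <- control$stage4
  b <- control$bounds
  best0 <- member_params(control_population,
                         which.min(control_population$costs))
  if (is.null(x0)) x0 <- burn_in_state(best0, days = 10, dt = control$dt)
  if (is.null(ref_stats)) {
    ref <- simulate_population(best0, protocol, n = control$n_cells,
                               x0 = x0, dt = control$dt_sde,
                               sample_h = control$sample_h,
                               seed = control$seed)
    ref_stats <- trace_stats(ref$mean_lum)
  }
  init <- as.matrix(control_population$members[, c("A", "d_M", "d_P",
                                                   "d_R", "i", "sigma")])
  seeded_from <- "control"
  out <- vector("list", length(series))
  names(out) <- names(series)
  for (k in seq_along(series)) {
    el <- series[[k]]
    np <- max(if (is.null(s4$n_pop)) nrow(init) else s4$n_pop, 4L)
    init <- pad_init(init, np, control$seed + 8887L + k)
    res <- de_optimize(
      function(x, gen) cost_c4(params_from_x(x), el$ld, el$dd, protocol,
                               x0, ref_stats, control,
                               seed = control$seed + 131L * gen + 17L * k),
      lower = c(b$A[1], b$d[1], b$d[1], b$d[1], b$i[1], b$sigma[1]),
      upper = c(b$A[2], b$d[2], b$d[2], b$d[2], b$i[2], b$sigma[2]),
      n_pop = np,
      F = s4$F, CR = s4$CR, max_gen = s4$max_gen, tol = s4$tol,
      tol_steps = s4$tol_steps, init = init, reevaluate = TRUE,
      seed = control$seed + 104729L + k)
    best <- params_from_x(res$par)
    all_t <- c(el$ld$time_h, el$dd$time_h)
    z_model <- model_trace_on(best, protocol, all_t, control,
                              seed = control$seed + 131L * (res$n_gen + 1L),
                              x0 = x0, ref_stats = ref_stats)
    e_f <- model_efficiency(c(el$ld$value, el$dd$value), z_model)
    members <- data.frame(A = res$pop[, 1], d_M = res$pop[, 2],
                          d_P = res$pop[, 3], d_R = res$pop[, 4],
                          i = res$pop[, 5], sigma = res$pop[, 6])
    out[[k]] <- list(params = best, cost = res$value,
                     population = new_parameter_population(
                       members, res$values, "C4",
                       treatment = names(series)[k],
                       concentration = el$concentration %||% NA_real_),
                     e_f = e_f, excluded = e_f <= 0,
                     treatment = names(series)[k],
                     seeded_from = seeded_from)
    init <- as.matrix(members)
    seeded_from <- names(series)[k]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
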