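#' Fit the stochastic clock model to a luminescence recording
#'
#' The main modelling entry point: runs the staged fitting pipeline on an
#' untreated plate recording and returns a fitted-model object.  Stage 1
#' builds a population of deterministic parameter sets with circadian
#' free-running period and light entrainment; stage 2 estimates the noise
#' intensity from the damping of the population signal in darkness; stage 3
#' refines all parameters against the normalized recording by minimizing the
#' mean squared error.
#'
#' @param data either a single averaged trace as a data.frame with columns
#'   \code{time_h} and \code{value}, or a plate table (\code{time_h} plus one
#'   column per well), in which case each well is z-scored and the wells are
#'   averaged before fitting.
#' @param protocol the recording's \code{\link{light_protocol}}.
#' @param control a \code{\link{clock_fit_control}}.
#' @param d_data damping ratio of the recording (1/h); by default estimated
#'   by \code{\link{fit_damped_sine}} on the window given by
#'   \code{d_window_h} (the first six days, normally the constant-darkness
#'   portion of the recording).
#' @param d_window_h window (h) of the data used for the damping estimate.
#' @param stage1_population optionally reuse a precomputed stage-1
#'   population (it does not depend on the data).
#' @param verbose print stage progress.
#' @return an object of class \code{clock_fit}; see
#'   \code{\link{coef.clock_fit}}, \code{\link{predict.clock_fit}},
#'   \code{\link{simulate.clock_fit}}, \code{\link{plot.clock_fit}}.
#' @export
clock_fit <- function(data, protocol, control = clock_fit_control(),
                      d_data = NULL, d_window_h = c(0, 144),
                      stage1_population = NULL, verbose = FALSE) {
  stopifnot(inherits(protocol, "light_protocol"), is.data.frame(data),
            "time_h" %in% names(data))
  wells <- setdiff(names(data), "time_h")
  if (length(wells) == 0L) stop("no value columns in 'data'")
  if (length(wells) == 1L) {
    trace <- data.frame(time_h = data$time_h, value = data[[wells]])
  } else {
    z <- vapply(wells, function(w) zscore(data[[w]]),
                numeric(nrow(data)))
    trace <- data.frame(time_h = data$time_h, value = rowMeans(z))
  }
  trace$value <- zscore(trace$value)

  if (is.null(d_data)) {
    w <- trace$time_h >= d_window_h[1] & trace$time_h <= d_window_h[2]
    ds <- fit_damped_sine(trace$time_h[w] - d_window_h[1], trace$value[w])
    d_data <- max(ds$damping, 0)
  }
  if (verbose) message(sprintf("data damping ratio: %.4g /h", d_data))

  pop1 <- stage1_population
  if (is.null(pop1)) {
    if (verbose) message("stage 1: deterministic circadian screen")
    pop1 <- stage1_fit(control, verbose = verbose)
  }
  if (verbose) message("stage 2: noise intensity from damping")
  pop2 <- stage2_estimate_noise(pop1, d_data, control, verbose = verbose)
  if (verbose) message("stage 3: trace fit")
  s3 <- stage3_fit(pop2, trace, protocol, control)

  structure(list(params = s3$params, e_f = s3$e_f, cost = s3$cost,
                 population = s3$population, stage1 = pop1, stage2 = pop2,
                 d_data = d_data, data = trace, model = s3$model,
                 protocol = protocol, control = control,
                 de_trace = s3$trace,
                 call = match.call()),
            class = "clock_fit")
}

#' @export
print.clock_fit <- function(x, ...) {
  cat("Stochastic circadian clock model fit\n")
  cat(sprintf("  C3 cost: %.4g   model efficiency E_f: %.3f\n",
              x$cost, x$e_f))
  print(x$params)
  invisible(x)
}

#' @export
coef.clock_fit <- function(object, ...) as.numeric(object$params)

#' @export
summary.clock_fit <- function(object, ...) {
  m <- object$population$members
  spread <- t(vapply(m, function(col) c(median = median(col),
                                        mad = mad(col)), numeric(2)))
  structure(list(params = object$params, e_f = object$e_f,
                 cost = object$cost, d_data = object$d_data,
                 spread = spread, n_members = nrow(m)),
            class = "summary.clock_fit")
}

#' @export
print.summary.clock_fit <- function(x, ...) {
  cat("Stochastic circadian clock model fit\n")
  print(x$params)
  cat(sprintf("  data damping ratio: %.4g /h\n", x$d_data))
  cat(sprintf("  C3 cost %.4g, model efficiency E_f = %.3f\n",
              x$cost, x$e_f))
  cat(sprintf("  final population (%d members), median +/- MAD:\n",
              x$n_members))
  print(round(x$spread, 4))
  invisible(x)
}

#' Predicted normalized population trace of a fitted model
#'
#' Simulates the fitted population mean and returns it z-scored on the
#' requested time grid.
#'
#' @param object a \code{\link{clock_fit}}.
#' @param newdata optional data.frame with \code{time_h} (default: the
#'   fitting data's grid).
#' @param protocol optional alternative \code{\link{light_protocol}}.
#' @param seed RNG seed for the population simulation.
#' @param ... unused.
#' @return numeric vector of normalized predictions.
#' @export
predict.clock_fit <- function(object, newdata = NULL, protocol = NULL,
                              seed = NULL, ...) {
  ctl <- object$control
  if (is.null(protocol)) protocol <- object$protocol
  times <- if (is.null(newdata)) object$data$time_h else newdata$time_h
  x0 <- burn_in_state(object$params, days = 10, dt = ctl$dt)
  model_trace_on(object$params, protocol, times, ctl,
                 seed = seed %||% (ctl$seed + 555L), x0 = x0)
}

#' @export
fitted.clock_fit <- function(object, ...) object$model

#' @export
residuals.clock_fit <- function(object, ...)
  object$data$value - object$model

#' Simulate population traces from a fitted model
#'
#' @param object a \code{\link{clock_fit}}.
#' @param nsim number of population replicates.
#' @param seed root seed.
#' @param n cells per population (default: the control's \code{n_cells}).
#' @param protocol optional alternative protocol.
#' @param ... unused.
#' @return a list of \code{population_result} objects (length \code{nsim}).
#' @export
simulate.clock_fit <- function(object, nsim = 1, seed = 1, n = NULL,
                               protocol = NULL, ...) {
  ctl <- object$control
  if (is.null(protocol)) protocol <- object$protocol
  x0 <- burn_in_state(object$params, days = 10, dt = ctl$dt)
  lapply(seq_len(nsim), function(k)
    simulate_population(object$params, protocol, n = n %||% ctl$n_cells,
                        x0 = x0, dt = ctl$dt_sde, sample_h = ctl$sample_h,
                        seed = seed + k - 1L))
}

#' @export
plot.clock_fit <- function(x, ...) {
  plot_trace_with_light(x$data$time_h, x$data$value, x$protocol,
                        ylab = "normalized luminescence",
                        main = sprintf("clock model fit (E_f = %.2f)",
                                       x$e_f), ...)
  graphics::lines(x$data$time_h, x$model, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c("data", "model"),
                   col = c("black", "firebrick"), lwd = c(1, 2),
                   bty = "n")
  invisible(x)
}
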