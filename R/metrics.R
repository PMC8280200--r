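# Trace normalization, goodness of fit, damped-sine fitting and
# peak/period/phase detection.

#' Z-score normalization of a trace
#'
#' Centers and scales a trace by its own sample mean and standard deviation
#' (n - 1 denominator), removing per-well amplitude and offset variation.
#'
#' @param x numeric trace.
#' @return normalized trace (mean 0, sd 1).
#' @export
zscore <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("undefined normalization: constant trace (sd = 0)")
  (x - mean(x)) / s
}

#' Group statistics for adjusted Z-score normalization
#'
#' Aggregates traces of one treatment group into the mean of per-trace means
#' and the mean of per-trace standard deviations.
#'
#' @param traces a list of numeric traces, or a matrix with one trace per
#'   column.
#' @return list with \code{mean_of_means}, \code{mean_of_sds},
#'   \code{n_traces}.
#' @export
group_stats <- function(traces) {
  if (is.matrix(traces) || is.data.frame(traces))
    traces <- lapply(seq_len(ncol(traces)), function(j) traces[, j])
  stopifnot(length(traces) >= 1L)
  list(mean_of_means = mean(vapply(traces, mean, numeric(1))),
       mean_of_sds = mean(vapply(traces, sd, numeric(1))),
       n_traces = length(traces))
}

#' Adjusted Z-score normalization for compound-treated traces
#'
#' Trace-by-trace Z-scores would erase treatment-induced changes in mean and
#' variance, so compound traces are rescaled relative to the control group:
#' \deqn{z_d(x) = \frac{x - \bar x}{S_x} \frac{S_d}{S_c} +
#'       \frac{\bar x_d - \bar x_c}{S_c},}
#' where \eqn{\bar x_d, S_d} are the compound group's mean of means / mean of
#' sds and \eqn{\bar x_c, S_c} the control group's.  For the control group
#' itself this reduces exactly to \code{\link{zscore}}.
#'
#' @param x numeric trace.
#' @param compound,control group statistics from \code{\link{group_stats}}.
#' @return normalized trace.
#' @export
adjusted_zscore <- function(x, compound, control) {
  if (control$mean_of_sds <= 0) stop("zero control group sd")
  zscore(x) * compound$mean_of_sds / control$mean_of_sds +
    (compound$mean_of_means - control$mean_of_means) / control$mean_of_sds
}

#' Per-trace statistics
#'
#' @param x numeric trace.
#' @return list with \code{mean} and \code{sd} (unbiased).
#' @export
trace_stats <- function(x) list(mean = mean(x), sd = sd(x))

#' Normalize model output by a reference simulation's statistics
#'
#' Centers and scales a simulated trace by the mean and standard deviation of
#' the \emph{control-parameter} simulation (not the trace's own statistics),
#' the model-side counterpart of \code{\link{adjusted_zscore}}.  When the
#' reference is the trace itself this is the ordinary Z-score.
#'
#' @param x simulated trace.
#' @param ref reference statistics from \code{\link{trace_stats}}.
#' @return normalized trace.
#' @export
model_zscore <- function(x, ref) {
  if (!is.finite(ref$sd) || ref$sd <= 0) stop("zero reference sd")
  (x - ref$mean) / ref$sd
}

#' Model efficiency coefficient
#'
#' Goodness of fit \eqn{E_f = 1 - \sum (x_i - \hat x_i)^2 / \sum (x_i -
#' \bar x)^2}, ranging over \eqn{(-\infty, 1]}: 1 for a perfect fit, 0 when
#' the model predicts no better than the data mean, negative when worse.
#'
#' @param data observed trace.
#' @param model predicted trace of the same length.
#' @return scalar coefficient.
#' @export
model_efficiency <- function(data, model) {
  if (length(data) != length(model))
    stop("data and model traces differ in length")
  denom <- sum((data - mean(data))^2)
  if (denom == 0) stop("constant data trace")
  1 - sum((data - model)^2) / denom
}

#' Detect peaks in a trace
#'
#' Local maxima whose topographic prominence exceeds a threshold (by default
#' 10\% of the trace's interquartile range).  Peak times are refined by a
#' parabolic fit through the three samples around each maximum.
#'
#' @param time_h sample times (h), strictly increasing.
#' @param value trace values.
#' @param min_prominence prominence threshold; default
#'   \code{0.1 * IQR(value)}.
#' @param refine logical; parabolic sub-sample refinement of peak times.
#' @return data.frame with columns \code{time}, \code{height},
#'   \code{prominence} (possibly zero rows).
#' @export
detect_peaks <- function(time_h, value, min_prominence = NULL,
                         refine = TRUE) {
  stopifnot(length(time_h) == length(value), length(value) >= 3L)
  if (is.null(min_prominence)) min_prominence <- 0.1 * IQR(value)
  n <- length(value)
  cand <- which(value[c(-1, -n)] > value[seq_len(n - 2)] &
                value[c(-1, -n)] >= value[-(1:2)]) + 1L
  if (length(cand) == 0L)
    return(data.frame(time = numeric(), height = numeric(),
                      prominence = numeric()))
  prom <- vapply(cand, function(i) {
    h <- value[i]
    left <- if (i > 1) {
      j <- i - 1L
      lo <- value[j]
      while (j > 1 && value[j] <= h) { j <- j - 1L; lo <- min(lo, value[j]) }
      lo
    } else h
    right <- if (i < n) {
      j <- i + 1L
      lo <- value[j]
      while (j < n && value[j] <= h) { j <- j + 1L; lo <- min(lo, value[j]) }
      lo
    } else h
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  cand <- cand[keep]; prom <- prom[keep]
  tt <- time_h[cand]; hh <- value[cand]
  if (refine && length(cand) > 0) {
    for (k in seq_along(cand)) {
      i <- cand[k]
      if (i > 1 && i < n) {
        y0 <- value[i - 1]; y1 <- value[i]; y2 <- value[i + 1]
        den <- y0 - 2 * y1 + y2
        if (den < 0) {
          delta <- 0.5 * (y0 - y2) / den
          h_step <- (time_h[i + 1] - time_h[i - 1]) / 2
          tt[k] <- time_h[i] + delta * h_step
          hh[k] <- y1 - 0.25 * (y0 - y2) * delta
        }
      }
    }
  }
  data.frame(time = tt, height = hh, prominence = prom)
}

#' Estimate the oscillation period from inter-peak intervals
#'
#' Mean spacing of detected peaks after discarding an initial transient.
#'
#' @inheritParams detect_peaks
#' @param transient_h hours discarded from the start (default 24).
#' @return period in hours.
#' @export
estimate_period <- function(time_h, value, transient_h = 24,
                            min_prominence = NULL) {
  keep <- time_h >= transient_h
  pk <- detect_peaks(time_h[keep], value[keep],
                     min_prominence = min_prominence)
  if (nrow(pk) < 2L) stop("aperiodic: fewer than 2 peaks after transient")
  mean(diff(pk$time))
}

#' Screen a deterministic trajectory for sustained oscillations
#'
#' \code{TRUE} iff at least \code{min_peaks} peaks are found after the
#' transient and the last peak's prominence is at least
#' \code{min_rel_amplitude} times the first post-transient peak's prominence.
#' Used as the cheap deterministic screen before evaluating the stochastic
#' model during fitting.
#'
#' @inheritParams estimate_period
#' @param min_peaks minimum number of post-transient peaks (default 3).
#' @param min_rel_amplitude minimum ratio of last to first post-transient
#'   peak prominence (default 0.1).
#' @return logical flag.
#' @export
sustained_oscillations <- function(time_h, value, min_peaks = 3,
                                   min_rel_amplitude = 0.1,
                                   transient_h = 24) {
  keep <- time_h >= transient_h
  if (sum(keep) < 3L) return(FALSE)
  v <- value[keep]
  if (diff(range(v)) == 0) return(FALSE)
  pk <- detect_peaks(time_h[keep], v)
  if (nrow(pk) < min_peaks) return(FALSE)
  pk$prominence[nrow(pk)] >= min_rel_amplitude * pk$prominence[1]
}

#' Fit a damped sine to a trace
#'
#' Least-squares fit of \eqn{f(t) = A e^{-d t} \sin(2 \pi t / T + \theta)}
#' by Levenberg-Marquardt with multi-start initialization: phases
#' \eqn{\theta \in \{0, \pi/2, \pi, 3\pi/2\}}, periods
#' \eqn{T \in \{20, 24, 28\}} h, damping initialized from a log-envelope
#' regression on detected peaks.  The trace is mean-centered before fitting
#' (the model has no offset term; normalized traces are centered anyway).
#'
#' @inheritParams detect_peaks
#' @param period_starts,phase_starts initialization grids.
#' @return object of class \code{damped_sine_fit} with fields
#'   \code{amplitude}, \code{damping}, \code{period}, \code{phase},
#'   \code{residual} (RSS) and \code{fitted}.
#' @export
fit_damped_sine <- function(time_h, value,
                            period_starts = c(20, 24, 28),
                            phase_starts = c(0, pi / 2, pi, 3 * pi / 2)) {
  stopifnot(length(time_h) == length(value), length(value) >= 8L)
  y <- value - mean(value)
  A0 <- max(abs(y))
  if (A0 == 0) stop("constant trace")
  # damping start from log-envelope regression on peak heights
  d0 <- 0
  pk <- detect_peaks(time_h, y)
  pk <- pk[pk$height > 0, ]
  if (nrow(pk) >= 2) {
    sl <- unname(coef(lm(log(pk$height) ~ pk$time))[2])
    if (is.finite(sl) && sl < 0) d0 <- -sl
  }
  d0 <- max(d0, 1e-3)  # a start of exactly 0 makes the Jacobian singular
  best <- NULL
  for (T0 in period_starts) for (th0 in phase_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ A * exp(-d * t) * sin(2 * pi * t / T + theta),
        data = list(y = y, t = time_h),
        start = list(A = A0, d = d0, T = T0, theta = th0),
        lower = c(A = 0, d = -0.05, T = 4, theta = -2 * pi),
        upper = c(A = 10 * A0, d = 1, T = 80, theta = 4 * pi),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(residuals(fit)^2)
      if (is.null(best) || rss < best$residual) {
        cf <- coef(fit)
        best <- list(amplitude = unname(cf["A"]), damping = unname(cf["d"]),
                     period = unname(cf["T"]),
                     phase = unname(cf["theta"]) %% (2 * pi),
                     residual = rss,
                     fitted = unname(fitted(fit)) + mean(value))
      }
    }
  }
  if (is.null(best))
    stop("damped-sine fit failed to converge from every start")
  structure(best, class = "damped_sine_fit")
}

#' @export
print.damped_sine_fit <- function(x, ...) {
  cat(sprintf(paste0("Damped sine fit: amplitude %.4g, damping %.4g /h, ",
                     "period %.4g h, phase %.4g rad (RSS %.4g)\n"),
              x$amplitude, x$damping, x$period, x$phase, x$residual))
  invisible(x)
}
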