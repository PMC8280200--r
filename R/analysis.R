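# Post-fit analyses: phase response curves, entrainment phase angles,
# single-cell phase histograms, mean activation in darkness, and PCA over
# fitted parameter ensembles.

#' Simulated phase response curve to light pulses
#'
#' Entrains the deterministic model, releases it into constant darkness, and
#' delivers one light pulse (default 12 h) at each of \code{n_phases} onset
#' times spanning one circadian cycle.  The phase shift is the displacement
#' of the pulsed trajectory's peaks relative to the unpulsed control,
#' measured on the fourth peak after pulse end and wrapped to (-12, 12] h;
#' the new phase is old phase plus shift, modulo 24.
#'
#' @param params an oscillatory \code{\link{clock_parameters}} set (sigma is
#'   ignored; the simulation is deterministic).
#' @param pulse_h pulse duration in hours (default 12).
#' @param n_phases number of pulse onset phases (>= 8 recommended).
#' @param dd_before_h constant darkness before the earliest pulse onset
#'   (>= one cycle).
#' @param measure_peak which post-pulse peak carries the measurement
#'   (default 4).
#' @param dt integration step (h).
#' @return object of class \code{phase_response_curve}: data.frame with
#'   \code{pulse_phase}, \code{shift}, \code{new_phase} (hours).
#' @export
phase_response_curve <- function(params, pulse_h = 12, n_phases = 12,
                                 dd_before_h = 36, measure_peak = 4,
                                 dt = 0.02) {
  stopifnot(inherits(params, "clock_parameters"), n_phases >= 2)
  x0 <- burn_in_state(params, days = 6, dt = dt)
  span <- dd_before_h + 24 + pulse_h + 24 * (measure_peak + 3)
  ctrl <- simulate_deterministic(params, constant_protocol(0, span),
                                 x0 = x0, dt = dt, sample_h = 0.25)
  if (!sustained_oscillations(ctrl$time_h, ctrl$lum, transient_h = 24))
    stop("non-oscillatory parameter set: no sustained free-running peaks")
  pk_ctrl <- detect_peaks(ctrl$time_h, ctrl$lum)
  if (nrow(pk_ctrl) < measure_peak + 2)
    stop("non-oscillatory parameter set: too few free-running peaks")
  t_dd <- mean(diff(pk_ctrl$time))
  ref_peak <- pk_ctrl$time[which(pk_ctrl$time >= dd_before_h)[1] - 1]
  if (is.na(ref_peak)) ref_peak <- pk_ctrl$time[1]

  onsets <- dd_before_h + (seq_len(n_phases) - 1) * 24 / n_phases
  shifts <- numeric(n_phases)
  old_phase <- numeric(n_phases)
  for (k in seq_len(n_phases)) {
    on <- onsets[k]
    prot <- with_pulse(constant_protocol(0, span), on, pulse_h)
    run <- simulate_deterministic(params, prot, x0 = x0, dt = dt,
                                  sample_h = 0.25)
    pk <- detect_peaks(run$time_h, run$lum)
    after <- pk$time[pk$time > on + pulse_h]
    if (length(after) < measure_peak)
      stop("too few peaks after the pulse at onset ", round(on, 2), " h")
    tp <- after[measure_peak]
    ctrl_after <- pk_ctrl$time[pk_ctrl$time > on + pulse_h]
    # control peak phase at the measurement time, using the model's own
    # free-running period
    dphi <- (ctrl_after - tp) %% t_dd
    dphi <- dphi[1]
    if (dphi > t_dd / 2) dphi <- dphi - t_dd
    shifts[k] <- dphi * 24 / t_dd
    old_phase[k] <- ((on - ref_peak) %% t_dd) * 24 / t_dd
  }
  out <- data.frame(pulse_phase = old_phase, shift = shifts,
                    new_phase = (old_phase + shifts) %% 24)
  out <- out[order(out$pulse_phase), ]
  rownames(out) <- NULL
  structure(out, class = c("phase_response_curve", "data.frame"),
            period_dd = t_dd, pulse_h = pulse_h)
}

#' Classify a phase response curve as type 0 or type 1
#'
#' Computes the average slope of the phase transition curve (new phase
#' against old phase) from its wrapped increments: near 0 for strong
#' (type 0) resetting -- all pulses funnel the oscillator to the same
#' phase -- and near 1 for weak (type 1) resetting, where the new phase
#' follows the old.  The slope is rounded to the nearest integer; slopes
#' within \code{margin} of one half are refused as undecidable.
#'
#' @param prc a \code{\link{phase_response_curve}} (>= 8 phases).
#' @param margin undecidability half-width around slope 0.5.
#' @return integer 0 or 1.
#' @export
prc_type <- function(prc, margin = 0.15) {
  stopifnot(nrow(prc) >= 8)
  o <- order(prc$pulse_phase)
  np <- prc$new_phase[o]
  d_new <- diff(np)
  d_new <- ((d_new + 12) %% 24) - 12   # wrap increments to (-12, 12]
  slope <- sum(d_new) / sum(diff(prc$pulse_phase[o]))
  if (abs(abs(slope) - 0.5) < margin)
    stop(sprintf("PRC type undecidable: average transition slope %.3f",
                 slope))
  min(as.integer(round(abs(slope))), 1L)
}

#' Phase angle of entrainment across zeitgeber periods
#'
#' For each tested period T, simulates the model under symmetric T/2:T/2
#' light-dark cycles and measures the phase angle of the first steady-state
#' population peak at or after a lights-on event:
#' \code{-(t_peak - t_lights_on) * 24 / T}.  Negative values mean the peak
#' is delayed with respect to lights-on.  Periods where the simulated
#' rhythm does not adopt T (within 10\%) are reported as \code{NA}.
#'
#' @param params a \code{\link{clock_parameters}} set (with its fitted
#'   sigma; set \code{n_cells = 1} with sigma = 0 for the deterministic
#'   curve).
#' @param T_values zeitgeber periods to test (h).
#' @param n_cells cells per population simulation.
#' @param n_cycles cycles per simulation (>= 7; the first 5 are treated as
#'   transient).
#' @param seed RNG seed.
#' @param dt integration step for the stochastic simulation.
#' @return object of class \code{phase_angle_curve}: data.frame with
#'   \code{T} and \code{phase_angle} (h, normalized by T/24).
#' @export
phase_angle_curve <- function(params, T_values = seq(16, 32, by = 2),
                              n_cells = 1000, n_cycles = 8, seed = 1,
                              dt = 0.05) {
  stopifnot(inherits(params, "clock_parameters"), n_cycles >= 7)
  angles <- vapply(T_values, function(Tz) {
    prot <- ld_cycle(Tz / 2, Tz / 2, n_cycles)
    x0 <- burn_in_state(params, days = 6)
    tr <- if (params$sigma > 0 && n_cells > 1) {
      pop <- simulate_population(params, prot, n = n_cells, x0 = x0,
                                 dt = dt, sample_h = 1 / 3, seed = seed)
      list(time_h = pop$time_h, value = pop$mean_lum)
    } else {
      det <- simulate_deterministic(params, prot, x0 = x0, dt = 0.02,
                                    sample_h = 1 / 3)
      list(time_h = det$time_h, value = det$lum)
    }
    per <- tryCatch(estimate_period(tr$time_h, tr$value,
                                    transient_h = 5 * Tz),
                    error = function(e) NA_real_)
    if (!is.finite(per) || abs(per - Tz) > 0.1 * Tz) return(NA_real_)
    pk <- detect_peaks(tr$time_h, tr$value)
    pk <- pk$time[pk$time >= 5 * Tz]
    t_on <- Tz / 2 + 5 * Tz  # dark-first cycles: lights on at T/2 + k T
    peak <- pk[pk >= t_on][1]
    if (is.na(peak)) return(NA_real_)
    -(peak - t_on) * 24 / Tz
  }, numeric(1))
  structure(data.frame(T = T_values, phase_angle = angles),
            class = c("phase_angle_curve", "data.frame"))
}

#' Single-cell peak phases within a time window
#'
#' Extracts the peak positions of each retained single-cell trace inside a
#' window and maps them to circadian phase in [0, 24); cells with several
#' peaks in the window contribute each peak.
#'
#' @param population a \code{population_result} with retained cells
#'   (\code{record_cells > 0} in \code{\link{simulate_population}}).
#' @param window numeric \code{c(start_h, end_h)} within the simulation
#'   span.
#' @return numeric vector of phases (h in [0, 24)).
#' @export
cell_peak_phases <- function(population, window) {
  stopifnot(inherits(population, "population_result"),
            !is.null(population$cells))
  t <- population$time_h
  if (window[1] < min(t) || window[2] > max(t) + 1e-9)
    stop("window outside the simulation span")
  sel <- t >= window[1] & t <= window[2]
  phases <- unlist(lapply(seq_len(ncol(population$cells)), function(j) {
    pk <- detect_peaks(t[sel], population$cells[sel, j])
    pk$time %% 24
  }))
  as.numeric(phases)
}

#' Histogram of single-cell phases
#'
#' Probability density of single-cell peak phases within a window,
#' normalized so the densities integrate to 1 over [0, 24).  Under
#' entrainment the histogram is sharply peaked; deep into constant darkness
#' with noise it flattens as cells desynchronize.
#'
#' @inheritParams cell_peak_phases
#' @param n_bins number of bins over [0, 24) (default 24).
#' @return object of class \code{phase_histogram} with \code{bin_edges},
#'   \code{densities}, \code{window}, \code{n_peaks}.
#' @export
phase_histogram <- function(population, window, n_bins = 24) {
  phases <- cell_peak_phases(population, window)
  edges <- seq(0, 24, length.out = n_bins + 1)
  counts <- if (length(phases) > 0)
    tabulate(findInterval(phases, edges, rightmost.closed = TRUE),
             nbins = n_bins) else rep(0L, n_bins)
  width <- 24 / n_bins
  dens <- if (sum(counts) > 0) counts / (sum(counts) * width)
          else rep(0, n_bins)
  structure(list(bin_edges = edges, densities = dens, window = window,
                 n_peaks = sum(counts)),
            class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("Phase histogram: %d peaks in window [%.6g, %.6g] h, %d bins\n",
              x$n_peaks, x$window[1], x$window[2],
              length(x$densities)))
  invisible(x)
}

#' @export
plot.phase_histogram <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::barplot(x$densities, names.arg = round(mids),
                    xlab = "phase (h)", ylab = "density", ...)
  invisible(x)
}

#' Circular variance of phases
#'
#' \eqn{1 - |mean(e^{2 \pi i \phi / period})|}: 0 for perfectly aligned
#' phases, approaching 1 for phases spread uniformly around the cycle.
#'
#' @param phases numeric phases (h).
#' @param period cycle length (h), default 24.
#' @return scalar in [0, 1].
#' @export
circular_variance <- function(phases, period = 24) {
  if (length(phases) == 0) return(NA_real_)
  ang <- 2 * pi * phases / period
  1 - Mod(mean(exp(1i * ang)))
}

#' Mean transcription activation in constant darkness
#'
#' Entrains the population under 12:12 light-dark cycles, releases it into
#' constant darkness, and returns the time-average of the population-mean
#' luminescence over the dark span (un-normalized model units; with
#' piecewise activation and non-negative states the value lies in [0, 1]).
#'
#' @param params a \code{\link{clock_parameters}} set.
#' @param n_cells cells per population.
#' @param dd_span_h hours of constant darkness averaged over.
#' @param entrain_cycles 12:12 cycles before release.
#' @param seed RNG seed.
#' @param dt integration step.
#' @return scalar mean activation.
#' @export
mean_activation_dd <- function(params, n_cells = 1000, dd_span_h = 120,
                               entrain_cycles = 5, seed = 1, dt = 0.05) {
  prot <- concat_protocols(ld_cycle(12, 12, entrain_cycles),
                           constant_protocol(0, dd_span_h))
  x0 <- burn_in_state(params, days = 6)
  pop <- simulate_population(params, prot, n = n_cells, x0 = x0, dt = dt,
                             sample_h = 2 / 3, seed = seed)
  mean(pop$mean_lum[pop$time_h >= entrain_cycles * 24])
}

#' PCA over fitted parameter populations
#'
#' Pools the members of several parameter populations (e.g. the final
#' optimizer populations for control and each compound treatment), z-scales
#' each of the six parameters across the pooled members, and projects onto
#' principal components.  Per-population location and spread in PC space are
#' summarized as median and median absolute deviation.
#'
#' @param populations list of \code{parameter_population} objects (>= 2).
#' @param labels optional population labels.
#' @return object of class \code{clock_pca}: list with \code{scores}
#'   (data.frame of projections with a \code{population} column),
#'   \code{explained} (variance fractions), \code{rotation},
#'   \code{centers} (per-population median and MAD of PC1/PC2).
#' @export
pca_parameter_populations <- function(populations, labels = NULL) {
  stopifnot(length(populations) >= 2,
            all(vapply(populations, inherits, logical(1),
                       "parameter_population")))
  if (is.null(labels)) {
    labels <- vapply(seq_along(populations), function(k) {
      tr <- populations[[k]]$treatment
      if (is.na(tr)) paste0("pop_", k) else tr
    }, character(1))
  }
  cols <- c("A", "d_M", "d_P", "d_R", "i", "sigma")
  mat <- do.call(rbind, lapply(populations, function(p)
    as.matrix(p$members[, cols])))
  grp <- rep(labels, vapply(populations, function(p) nrow(p$members),
                            integer(1)))
  keep <- apply(mat, 2, function(col) sd(col) > 0)
  if (!all(keep))
    message("dropping constant parameter(s) from PCA: ",
            paste(cols[!keep], collapse = ", "))
  pc <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- as.data.frame(pc$x)
  scores$population <- grp
  centers <- do.call(rbind, lapply(split(scores, scores$population),
    function(s) data.frame(population = s$population[1],
                           pc1_median = median(s$PC1),
                           pc1_mad = mad(s$PC1),
                           pc2_median = if ("PC2" %in% names(s))
                             median(s$PC2) else NA_real_,
                           pc2_mad = if ("PC2" %in% names(s))
                             mad(s$PC2) else NA_real_)))
  rownames(centers) <- NULL
  structure(list(scores = scores, explained = expl,
                 rotation = pc$rotation, centers = centers),
            class = "clock_pca")
}

#' @export
print.clock_pca <- function(x, ...) {
  cat("PCA of fitted parameter populations\n")
  cat("  explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n")
  print(x$centers)
  invisible(x)
}

#' @export
plot.clock_pca <- function(x, ...) {
  pops <- unique(x$scores$population)
  cols <- grDevices::hcl.colors(length(pops), "Dark 3")
  plot(x$scores$PC1, x$scores$PC2, col = cols[match(x$scores$population,
                                                    pops)],
       pch = 16, xlab = sprintf("PC1 (%.0f%%)", 100 * x$explained[1]),
       ylab = sprintf("PC2 (%.0f%%)", 100 * x$explained[2]), ...)
  graphics::legend("topright", legend = pops, col = cols, pch = 16,
                   bty = "n")
  invisible(x)
}
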