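# Synthetic plate recordings with known ground truth: multi-day circadian
# traces with amplitude damping in darkness, light-driven peaks, per-well
# scale/offset variation and measurement noise, mimicking a plate reader
# sampling wells of ~30,000 uncoupled cellular oscillators every 40 min.

#' Reference ground-truth parameter set
#'
#' The parameter set used as the default ground truth of the synthetic plate
#' generator.  It was chosen once to express the canonical phenotypes of the
#' light-entrainable cellular clock: a deterministic free-running period of
#' 24 h in constant darkness, stable entrainment by 12:12 (and 15:15 and
#' 10:10) light-dark cycles, full repression of the rhythm under constant
#' light, strong (type 0) resetting by 12-h light pulses, and a noise
#' intensity at which the population signal damps over a few days in
#' darkness while single cells keep oscillating.
#'
#' @return a \code{\link{clock_parameters}} object.
#' @export
reference_parameters <- function() {
  clock_parameters(A = 2, d_M = 0.1885, i = 0.02, sigma = 0.02)
}

#' Design of a synthetic plate recording
#'
#' @param wells data.frame with columns \code{well}, \code{treatment},
#'   \code{concentration}; well ids must be unique.
#' @param params a single \code{\link{clock_parameters}} (shared ground
#'   truth) or a list with one entry per well.
#' @param protocol the plate's \code{\link{light_protocol}}.
#' @param sampling_min sampling interval in minutes (default 40).
#' @param duration_h recording span (default: protocol duration).
#' @param n_cells cells simulated per well (default 1,000).
#' @param noise_sd_frac measurement noise sd as a fraction of each well's
#'   trace sd (default 0.05; set 0 for exactness tests).
#' @param scale_range,offset_range per-well affine distortion ranges
#'   emulating between-well amplitude/offset variation.
#' @param dt stochastic integration step (h).
#' @return object of class \code{plate_design}.
#' @export
plate_design <- function(wells, params, protocol, sampling_min = 40,
                         duration_h = NULL, n_cells = 1000,
                         noise_sd_frac = 0.05, scale_range = c(0.5, 2),
                         offset_range = c(0, 1), dt = 0.05) {
  stopifnot(is.data.frame(wells),
            all(c("well", "treatment", "concentration") %in% names(wells)),
            inherits(protocol, "light_protocol"))
  if (anyDuplicated(wells$well)) stop("well ids must be unique")
  if (inherits(params, "clock_parameters"))
    params <- rep(list(params), nrow(wells))
  stopifnot(length(params) == nrow(wells),
            all(vapply(params, inherits, logical(1), "clock_parameters")))
  if (is.null(duration_h)) duration_h <- protocol$total_duration
  structure(list(wells = wells, params = params, protocol = protocol,
                 sampling_min = sampling_min, duration_h = duration_h,
                 n_cells = n_cells, noise_sd_frac = noise_sd_frac,
                 scale_range = scale_range, offset_range = offset_range,
                 dt = dt),
            class = "plate_design")
}

#' Generate a synthetic plate recording
#'
#' Simulates each well's population at its ground-truth parameters, samples
#' on the plate-reader grid, applies a per-well affine distortion (scale and
#' offset drawn from the design ranges) plus additive Gaussian measurement
#' noise, and returns the plate table together with a manifest holding every
#' ground truth and seed, from which the plate can be regenerated
#' bit-exactly.
#'
#' @param design a \code{\link{plate_design}}.
#' @param seed root RNG seed.
#' @return list with \code{plate} (data.frame: \code{time_h} + one column
#'   per well), \code{meta} (well, treatment, concentration, scale, offset,
#'   seed), \code{manifest} (design + seed, see
#'   \code{\link{regenerate_plate}}).
#' @export
generate_plate <- function(design, seed = 1) {
  stopifnot(inherits(design, "plate_design"))
  n_wells <- nrow(design$wells)
  sample_h <- design$sampling_min / 60
  set.seed(seed)
  well_seeds <- sample.int(.Machine$integer.max - 1L, n_wells)
  scales <- runif(n_wells, design$scale_range[1], design$scale_range[2])
  offsets <- runif(n_wells, design$offset_range[1], design$offset_range[2])
  meas_seeds <- sample.int(.Machine$integer.max - 1L, n_wells)

  plate <- NULL
  for (w in seq_len(n_wells)) {
    pop <- simulate_population(design$params[[w]], design$protocol,
                               n = design$n_cells,
                               t_end = design$duration_h, dt = design$dt,
                               sample_h = sample_h, seed = well_seeds[w])
    y <- scales[w] * pop$mean_lum + offsets[w]
    if (design$noise_sd_frac > 0) {
      set.seed(meas_seeds[w])
      y <- y + rnorm(length(y), 0, design$noise_sd_frac * sd(pop$mean_lum) *
                       scales[w])
    }
    if (is.null(plate)) plate <- data.frame(time_h = pop$time_h)
    plate[[design$wells$well[w]]] <- y
  }
  meta <- cbind(design$wells,
                data.frame(scale = scales, offset = offsets,
                           seed = well_seeds))
  manifest <- list(seed = seed,
                   wells = design$wells,
                   params = lapply(design$params, unclass),
                   protocol = design$protocol$segments,
                   sampling_min = design$sampling_min,
                   duration_h = design$duration_h,
                   n_cells = design$n_cells,
                   noise_sd_frac = design$noise_sd_frac,
                   scale_range = design$scale_range,
                   offset_range = design$offset_range,
                   dt = design$dt)
  list(plate = plate, meta = meta, manifest = manifest)
}

#' Rebuild a plate from its manifest
#'
#' @param manifest the manifest returned by \code{\link{generate_plate}}
#'   (possibly round-tripped through JSON).
#' @return the same list as \code{\link{generate_plate}}.
#' @export
regenerate_plate <- function(manifest) {
  plist <- manifest$params
  if (is.data.frame(plist))   # a JSON round trip tabularizes the list
    plist <- lapply(seq_len(nrow(plist)), function(r) as.list(plist[r, ]))
  params <- lapply(plist, function(p) {
    K <- p$K
    if (is.null(K) || !is.finite(K)) K <- NULL
    clock_parameters(A = p$A, d_M = p$d_M, d_P = p$d_P, d_R = p$d_R,
                     i = p$i, sigma = p$sigma, K = K)
  })
  design <- plate_design(as.data.frame(manifest$wells), params,
                         light_protocol(as.data.frame(manifest$protocol)),
                         sampling_min = manifest$sampling_min,
                         duration_h = manifest$duration_h,
                         n_cells = manifest$n_cells,
                         noise_sd_frac = manifest$noise_sd_frac,
                         scale_range = unlist(manifest$scale_range),
                         offset_range = unlist(manifest$offset_range),
                         dt = manifest$dt)
  generate_plate(design, seed = manifest$seed)
}

#' Canonical varied-lighting fixture plate
#'
#' A 16-well plate under the canonical varied-lighting schedule used for
#' fitting: 6 days of constant darkness, three 12:12 light-dark cycles, and
#' 3 days of constant light (288 h total).
#'
#' @param params ground-truth \code{\link{clock_parameters}}.
#' @param seed root RNG seed.
#' @param n_wells number of replicate wells (default 16).
#' @param ... further arguments to \code{\link{plate_design}}.
#' @return as \code{\link{generate_plate}}.
#' @export
fig2a_fixture <- function(params, seed = 1, n_wells = 16, ...) {
  prot <- concat_protocols(constant_protocol(0, 144), ld_cycle(12, 12, 3),
                           constant_protocol(1, 72))
  wells <- data.frame(well = sprintf("W%02d", seq_len(n_wells)),
                      treatment = "untreated", concentration = 0)
  generate_plate(plate_design(wells, params, prot, ...), seed = seed)
}

#' Synthetic compound concentration series
#'
#' Builds plates for a control group plus an ordered concentration series in
#' which the ground-truth parameters drift progressively away from control
#' (e.g. a reduced-activator series mimicking amplitude-suppressing
#' compounds, or a raised-noise series mimicking desynchronizing ones).
#'
#' @param control_params control \code{\link{clock_parameters}}.
#' @param perturbations ordered list (low to high concentration) of named
#'   numeric vectors of parameter deltas, e.g.
#'   \code{list(c(A = -0.2), c(A = -0.4))}; names among A, d_M, d_P, d_R,
#'   i, sigma.
#' @param protocol plate protocol; default 5 days of 12:12 light-dark cycles
#'   followed by 5 days of darkness.
#' @param n_wells wells per group.
#' @param seed root seed.
#' @param concentrations optional numeric labels (default 1, 2, ...).
#' @param ... further arguments to \code{\link{plate_design}}.
#' @return named list of plates (control first), each as
#'   \code{\link{generate_plate}}; ground-truth parameters are in each
#'   manifest.
#' @export
compound_series_fixture <- function(control_params, perturbations,
                                    protocol = NULL, n_wells = 8, seed = 1,
                                    concentrations = NULL, ...) {
  stopifnot(length(perturbations) >= 1)
  if (is.null(protocol))
    protocol <- concat_protocols(ld_cycle(12, 12, 5),
                                 constant_protocol(0, 120))
  if (is.null(concentrations))
    concentrations <- seq_along(perturbations)
  groups <- c(list(control = numeric(0)),
              setNames(perturbations,
                       paste0("conc_", concentrations)))
  out <- vector("list", length(groups))
  names(out) <- names(groups)
  for (g in seq_along(groups)) {
    delta <- groups[[g]]
    base <- unclass(control_params)
    for (nm in names(delta)) base[[nm]] <- base[[nm]] + delta[[nm]]
    pars <- clock_parameters(A = base$A, d_M = base$d_M, d_P = base$d_P,
                             d_R = base$d_R, i = base$i,
                             sigma = max(base$sigma, 0), K = base$K)
    wells <- data.frame(
      well = sprintf("%s_W%02d", names(groups)[g], seq_len(n_wells)),
      treatment = names(groups)[g],
      concentration = if (g == 1) 0 else concentrations[g - 1])
    out[[g]] <- generate_plate(plate_design(wells, pars, protocol, ...),
                               seed = seed + 7717L * g)
  }
  out
}
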