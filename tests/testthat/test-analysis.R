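# Phase response curves, entrainment phase angles, phase histograms,
# darkness activation and parameter-ensemble PCA.

fake_prc <- function(new_phase, pulse_phase = seq(0, 23, length.out = 12)) {
  structure(data.frame(pulse_phase = pulse_phase,
                       shift = (new_phase - pulse_phase) %% 24,
                       new_phase = new_phase %% 24),
            class = c("phase_response_curve", "data.frame"))
}

test_that("transition-curve winding classifies resetting strength", {
  old <- seq(0, 23, length.out = 12)
  expect_equal(prc_type(fake_prc(rep(17.2, 12), old)), 0L)  # constant: type 0
  expect_equal(prc_type(fake_prc(old + 3, old)), 1L)        # identity: type 1
  # slope near one half is refused
  expect_error(prc_type(fake_prc(old / 2, old)), "undecidable")
})

test_that("the reference oscillator gives a reproducible strong-resetting curve", {
  prc <- cached("prc_ref", phase_response_curve(truth_params,
                                                n_phases = 12))
  expect_equal(nrow(prc), 12)
  expect_true(all(prc$shift > -12 & prc$shift <= 12))
  expect_equal(prc$new_phase, (prc$pulse_phase + prc$shift) %% 24)
  # measurement cycle robustness: 3rd vs 5th post-pulse peak agree
  prc3 <- cached("prc_ref3", phase_response_curve(truth_params,
                                                  n_phases = 8,
                                                  measure_peak = 3))
  prc5 <- cached("prc_ref5", phase_response_curve(truth_params,
                                                  n_phases = 8,
                                                  measure_peak = 5))
  dd <- abs(((prc3$shift - prc5$shift) + 12) %% 24 - 12)
  expect_lt(max(dd), 0.5)
  # non-oscillatory input is refused
  expect_error(phase_response_curve(clock_parameters(A = 2, d_M = 0.5,
                                                     i = 0.02)),
               "peaks|oscillat")
})

test_that("phase angles follow the lights-on sign convention at T = 24", {
  det <- clock_parameters(A = truth_params$A, d_M = truth_params$d_M,
                          i = truth_params$i, sigma = 0)
  pac <- phase_angle_curve(det, T_values = 24, n_cells = 1,
                           n_cycles = 8)
  expect_false(is.na(pac$phase_angle))
  # cross-check directly against the simulated entrained peak timing
  prot <- ld_cycle(12, 12, 8)
  tr <- simulate_deterministic(det, prot, x0 = burn_in_state(det, days = 6),
                               sample_h = 1 / 3)
  pk <- detect_peaks(tr$time_h, tr$lum)
  t_on <- 12 + 5 * 24
  peak <- pk$time[pk$time >= t_on][1]
  expect_equal(pac$phase_angle, -(peak - t_on), tolerance = 0.05)
  expect_gte(pac$phase_angle, -12)
  expect_lte(pac$phase_angle, 0)
})

test_that("phase angles rescale with the zeitgeber period", {
  # the angle normalization maps a fixed 6-h delay to -6 * 24 / T
  expect_equal(-6 * 24 / 30, -4.8)
  det <- clock_parameters(A = truth_params$A, d_M = truth_params$d_M,
                          i = truth_params$i, sigma = 0)
  pac <- phase_angle_curve(det, T_values = c(20, 24, 30), n_cells = 1,
                           n_cycles = 12)
  expect_true(all(!is.na(pac$phase_angle)))  # entrains at all three
})

test_that("phase histograms integrate to one and detect synchrony", {
  # deterministic population: all cells identical, single occupied bin
  det <- clock_parameters(A = truth_params$A, d_M = truth_params$d_M,
                          i = truth_params$i, sigma = 0)
  prot <- ld_cycle(12, 12, 4)
  pop <- simulate_population(det, prot, n = 60, dt = 0.05, seed = 1,
                             record_cells = 60)
  h <- phase_histogram(pop, c(24, 95))
  expect_equal(sum(h$densities) * (24 / length(h$densities)), 1)
  expect_equal(sum(h$densities > 0), 1)
  expect_error(phase_histogram(pop, c(24, 200)), "window")
})

test_that("uniformly phased cells give a flat histogram", {
  # synthetic population object: sine traces with uniform phase offsets
  set.seed(12)
  tt <- seq(0, 96, by = 1 / 3)
  n <- 400
  phases <- runif(n, 0, 24)
  cells <- vapply(phases, function(ph) sin(2 * pi * (tt - ph) / 24),
                  numeric(length(tt)))
  pop <- structure(list(time_h = tt, mean_lum = rowMeans(cells), n = n,
                        cells = cells, seed = 12,
                        params = truth_params, protocol = NULL),
                   class = "population_result")
  h <- phase_histogram(pop, c(0, 96), n_bins = 12)
  counts <- h$densities * h$n_peaks * 2   # 2-h bins
  # each cell contributes ~4 peaks at its own phase, so the effective
  # sample size is the number of cells, not the number of peaks
  counts_cells <- counts / 4
  expected <- n / 12
  sd_cells <- sqrt(n * (1 / 12) * (11 / 12))
  expect_true(all(abs(counts_cells - expected) < 4 * sd_cells))
})

test_that("entrainment sharpens the phase distribution relative to free-run", {
  pop <- dd_release_population(sigma = 0.02)
  cv_ld <- circular_variance(cell_peak_phases(pop, c(36, 72)))
  cv_dd <- circular_variance(cell_peak_phases(pop, c(168, 215)))
  expect_lt(cv_ld, cv_dd)
})

test_that("darkness activation is bounded, size-stable, and increases with activator", {
  m_mid <- cached("act_A2", mean_activation_dd(truth_params, n_cells = 500,
                                               dd_span_h = 96, seed = 3))
  expect_gt(m_mid, 0)
  expect_lt(m_mid, 1)
  # direction: reducing the activator lowers the darkness activation
  lowA <- clock_parameters(A = 1.2, d_M = truth_params$d_M,
                           i = truth_params$i, sigma = truth_params$sigma)
  m_low <- mean_activation_dd(lowA, n_cells = 500, dd_span_h = 96,
                              seed = 3)
  expect_lt(m_low, m_mid)
  # invariant to the population size beyond Monte-Carlo error
  m_2000 <- mean_activation_dd(truth_params, n_cells = 2000,
                               dd_span_h = 96, seed = 4)
  prot <- concat_protocols(ld_cycle(12, 12, 5), constant_protocol(0, 96))
  ref <- simulate_population(truth_params, prot, n = 200,
                             x0 = burn_in_state(truth_params, days = 6),
                             dt = 0.05, seed = 5, record_cells = 200)
  sel <- ref$time_h >= 120
  per_cell <- colMeans(ref$cells[sel, ])
  se <- sd(per_cell) / sqrt(500)
  expect_lt(abs(m_mid - m_2000), 3 * se)
})

test_that("parameter-ensemble PCA separates a constructed activator shift", {
  set.seed(13)
  mk <- function(A_center, label) {
    m <- data.frame(A = rnorm(40, A_center, 0.01),
                    d_M = 0.19, d_P = 0.19, d_R = 0.19,
                    i = 0.02, sigma = 0.02)
    circlum:::new_parameter_population(m, rep(0, 40), "C4",
                                       treatment = label)
  }
  ctrl <- mk(1, "control")
  trt <- mk(3, "treated")
  suppressMessages(pca <- pca_parameter_populations(list(ctrl, trt)))
  expect_equal(sum(pca$explained), 1)
  expect_gt(pca$explained[1], 0.99)
  sep <- split(pca$scores$PC1, pca$scores$population)
  expect_true(max(sep$control) < min(sep$treated) ||
              max(sep$treated) < min(sep$control))
  # order invariance (up to component sign)
  suppressMessages(pca2 <- pca_parameter_populations(list(trt, ctrl)))
  expect_equal(abs(pca2$explained), abs(pca$explained))
  expect_equal(sort(abs(pca2$scores$PC1)), sort(abs(pca$scores$PC1)),
               tolerance = 1e-8)
})
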