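# Differential evolution and the staged cost functions.  Heavy recovery
# experiments live with the acceptance suite; these tests check the
# contracts of each stage at desk scale.

test_that("the DE optimizer solves a smooth box-constrained problem", {
  sphere <- function(x, gen) sum((x - c(1, -2, 0.5))^2)
  res <- de_optimize(sphere, lower = rep(-5, 3), upper = rep(5, 3),
                     n_pop = 20, max_gen = 150, seed = 1)
  expect_lt(res$value, 1e-4)
  expect_equal(res$par, c(1, -2, 0.5), tolerance = 0.02)
  # monotone best-cost trace
  expect_true(all(diff(res$trace) <= 0))
  # init rows are used and clamped
  res2 <- de_optimize(sphere, rep(-5, 3), rep(5, 3), n_pop = 10,
                      max_gen = 5, init = matrix(9, 2, 3), seed = 2)
  expect_true(all(res2$pop <= 5))
})

test_that("the circadian screen cost rewards 24-h rhythms and punishes silence", {
  ctl <- clock_fit_control()
  good <- cost_c1(A = 2, d = 0.1885, i = 0.02, control = ctl)
  expect_lt(good, 0.5)
  # non-oscillatory set maps to the penalty value
  expect_equal(cost_c1(A = 2, d = 0.5, i = 0.02, control = ctl),
               ctl$max_cost)
})

test_that("stage 1 returns oscillatory, circadian, and diverse members", {
  pop <- stage1_pop_small()
  expect_s3_class(pop, "parameter_population")
  expect_equal(pop$stage, "C1")
  expect_true(all(pop$costs < 0.5))
  for (j in seq_len(nrow(pop$members))) {
    p <- clock_parameters(A = pop$members$A[j], d_M = pop$members$d_M[j],
                          i = pop$members$i[j])
    x0 <- burn_in_state(p, days = 6)
    dd <- simulate_deterministic(p, constant_protocol(0, 240), x0 = x0)
    expect_true(sustained_oscillations(dd$time_h, dd$lum,
                                       transient_h = 48))
    t_dd <- estimate_period(dd$time_h, dd$lum, transient_h = 120)
    expect_gte(t_dd, 23.5)
    expect_lte(t_dd, 24.5)
  }
  # distinct members
  d <- as.matrix(dist(pop$members[, c("A", "d_M", "i")]))
  expect_true(all(d[upper.tri(d)] > 0))
})

test_that("the noise-matching cost is anchored at zero noise and scans to a minimum", {
  ctl <- clock_fit_control(stage2 = list(n_cells = 150), dt_sde = 0.05)
  base <- clock_parameters(A = 2, d_M = 0.1885, i = 0.02)
  d_data <- 0.015
  c0 <- cost_c2(0, base, d_data, ctl, seed = 3)
  expect_equal(c0, d_data^2, tolerance = 0.35)
  grid <- c(0, 0.02, 0.2)
  cc <- vapply(grid, function(s) cost_c2(s, base, d_data, ctl, seed = 3),
               numeric(1))
  expect_lt(cc[2], cc[1])   # interior minimum bracketed
  expect_lt(cc[2], cc[3])
  # damping grows with noise over the scanned range
  dm <- vapply(c(0.005, 0.02, 0.08), function(s) {
    sqrt(cost_c2(s, base, 0, ctl, seed = 3))  # = |d_model| when d_data = 0
  }, numeric(1))
  expect_true(all(diff(dm) > 0))
})

test_that("stage 2 fits noise per member and leaves everything else alone", {
  ctl <- desk_control()
  pop <- stage1_pop_small()[1:2]
  d_data <- 0.015
  pop2 <- stage2_estimate_noise(pop, d_data, ctl)
  expect_equal(pop2$stage, "C2")
  expect_equal(nrow(pop2$members), 2)
  expect_equal(pop2$members[, c("A", "d_M", "d_P", "d_R", "i")],
               pop$members[, c("A", "d_M", "d_P", "d_R", "i")])
  expect_true(all(pop2$members$sigma > 0))
  # doubling the target damping raises the fitted noise (allowing the
  # per-member optimizer jitter of the small desk-scale DE)
  pop2b <- stage2_estimate_noise(pop, 2 * d_data, ctl)
  expect_true(all(pop2b$members$sigma >= pop2$members$sigma - 0.005))
  expect_gt(mean(pop2b$members$sigma), mean(pop2$members$sigma))
})

test_that("the trace cost screens non-oscillatory sets without stochastic work", {
  ctl <- clock_fit_control(n_cells = 150)
  prot <- concat_protocols(ld_cycle(12, 12, 3), constant_protocol(0, 72))
  tt <- seq(0, 144, by = 2 / 3)
  data <- data.frame(time_h = tt, value = sin(2 * pi * tt / 24))
  bad <- clock_parameters(A = 2, d_M = 0.5, i = 0.02, sigma = 0.02)
  t0 <- Sys.time()
  expect_equal(cost_c3(bad, data, prot, ctl, seed = 1), ctl$max_cost)
  expect_lt(as.numeric(Sys.time()) - as.numeric(t0), 1)  # no population run
  # cost is invariant to shifting the raw data by a constant
  good <- truth_params
  c_a <- cost_c3(good, data, prot, ctl, seed = 1)
  data2 <- data.frame(time_h = tt, value = data$value + 100)
  expect_equal(cost_c3(good, data2, prot, ctl, seed = 1), c_a)
})

test_that("self-fit trace cost sits at the Monte-Carlo floor", {
  ctl <- clock_fit_control(n_cells = 1000, dt_sde = 0.05)
  prot <- concat_protocols(ld_cycle(12, 12, 3), constant_protocol(0, 72))
  p <- truth_params
  x0 <- burn_in_state(p, days = 10)
  self <- simulate_population(p, prot, n = 1000, x0 = x0, dt = 0.05,
                              seed = 99, record_cells = 200)
  data <- data.frame(time_h = self$time_h, value = self$mean_lum)
  cost <- cost_c3(p, data, prot, ctl, seed = 1)
  # oracle: the expected floor is the per-time single-cell variance over n,
  # once for the data trace and once for the model trace, on the z scale
  var_cell <- mean(apply(self$cells, 1, var))
  floor_exp <- 2 * var_cell / 1000 / var(self$mean_lum)
  expect_gt(cost, 0.2 * floor_exp)
  expect_lt(cost, 3 * floor_exp)
})

test_that("the two-segment compound cost decomposes additively and relaxes constraints", {
  ctl <- clock_fit_control(n_cells = 150)
  prot <- concat_protocols(ld_cycle(12, 12, 3), constant_protocol(0, 72))
  p_uneq <- clock_parameters(A = 2, d_M = 0.17, d_P = 0.21, d_R = 0.19,
                             i = 0.02, sigma = 0.02)  # admissible in C4
  x0 <- burn_in_state(truth_params, days = 10)
  sim <- simulate_population(truth_params, prot, n = 300, x0 = x0,
                             dt = 0.05, seed = 5)
  ref <- trace_stats(sim$mean_lum)
  z <- model_zscore(sim$mean_lum, ref)
  ld <- data.frame(time_h = sim$time_h, value = z)[sim$time_h < 72, ]
  dd <- data.frame(time_h = sim$time_h, value = z)[sim$time_h >= 72, ]
  c_both <- cost_c4(p_uneq, ld, dd, prot, x0, ref, ctl, seed = 2)
  expect_true(is.finite(c_both) && c_both < ctl$max_cost)
  # additive decomposition: segments scored separately and summed
  m_all <- circlum:::model_trace_on(p_uneq, prot,
                                    c(ld$time_h, dd$time_h), ctl,
                                    seed = 2, x0 = x0, ref_stats = ref)
  manual <- mean((ld$value - m_all[seq_len(nrow(ld))])^2) +
    mean((dd$value - m_all[-seq_len(nrow(ld))])^2)
  expect_equal(c_both, manual, tolerance = 1e-12)
})

test_that("series refitting chains populations and flags hopeless fits", {
  ctl <- desk_control(seed = 31)
  ctl$n_cells <- 120
  prot <- concat_protocols(ld_cycle(12, 12, 3), constant_protocol(0, 72))
  x0 <- burn_in_state(truth_params, days = 10)
  sim <- simulate_population(truth_params, prot, n = 300, x0 = x0,
                             dt = 0.05, seed = 41)
  ref <- trace_stats(sim$mean_lum)
  z <- model_zscore(sim$mean_lum, ref)
  ld <- data.frame(time_h = sim$time_h, value = z)[sim$time_h < 72, ]
  dd <- data.frame(time_h = sim$time_h, value = z)[sim$time_h >= 72, ]
  ctrl_pop <- circlum:::new_parameter_population(
    data.frame(A = truth_params$A, d_M = truth_params$d_M,
               d_P = truth_params$d_P, d_R = truth_params$d_R,
               i = truth_params$i, sigma = truth_params$sigma)[rep(1, 4), ],
    rep(0, 4), "C3")
  series <- list(low = list(ld = ld, dd = dd, concentration = 1),
                 high = list(ld = ld,
                             dd = data.frame(time_h = dd$time_h,
                                             value = rev(dd$value)),
                             concentration = 2))
  res <- stage4_refit_series(ctrl_pop, series, prot, ctl, x0 = x0,
                             ref_stats = ref)
  expect_named(res, c("low", "high"))
  expect_equal(res$low$seeded_from, "control")
  expect_equal(res$high$seeded_from, "low")
  expect_equal(res$low$excluded, res$low$e_f <= 0)
  expect_false(res$low$excluded)    # near-self data fits well
  expect_error(stage4_refit_series(ctrl_pop, list(), prot, ctl), "empty")
})
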