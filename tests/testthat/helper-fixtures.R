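# Shared fixtures, built once per test run.  Sizes are desk-scale: small
# enough for the default suite, large enough for the behaviors under test.

truth_params <- reference_parameters()

fig2a_protocol <- function() {
  concat_protocols(constant_protocol(0, 144), ld_cycle(12, 12, 3),
                   constant_protocol(1, 72))
}

# small control settings reused by fitting tests
desk_control <- function(seed = 11, ...) {
  clock_fit_control(n_cells = 200, dt_sde = 0.05,
                    stage1 = list(n_runs = 3, n_pop = 20, max_gen = 60),
                    stage2 = list(n_pop = 5, max_gen = 6, n_cells = 200),
                    stage3 = list(max_gen = 8, tol = 0),
                    stage4 = list(max_gen = 6, tol = 0),
                    seed = seed, ...)
}

# memoised heavy fixtures
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# a small stage-1 population (3 members), used across fitting/acceptance
stage1_pop_small <- function() {
  cached("stage1_small", stage1_fit(desk_control()))
}

# entrained population released into darkness, with retained cells
dd_release_population <- function(sigma = 0.02, n = 400, record = 100,
                                  seed = 7) {
  key <- sprintf("ddrel_%g_%d_%d_%d", sigma, n, record, seed)
  cached(key, {
    p <- clock_parameters(A = truth_params$A, d_M = truth_params$d_M,
                          i = truth_params$i, sigma = sigma)
    prot <- concat_protocols(ld_cycle(12, 12, 3), constant_protocol(0, 144))
    simulate_population(p, prot, n = n, x0 = burn_in_state(p, days = 6),
                        dt = 0.05, seed = seed, record_cells = record)
  })
}
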