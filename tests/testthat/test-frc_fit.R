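# unit-scale problems: 30 components on k in [1e-3, 1], 1201-sample records
unit_cfg <- function(...) {
  fit_config(k_min = 1e-3, k_max = 1, n_components = 30, ...)
}

test_that("rough fit localizes an on-grid component and handles edge inputs", {
  g <- unit_grid()
  cmp <- grid_component(g, 15, amplitude = 20)
  cv <- truth_curve(list(cmp))
  m <- initialize_model(cv, unit_cfg())
  w <- m$amplitude
  expect_gte(sum(w[14:16]) / sum(w), 0.8)

  # zero curve: all amplitudes zero
  z <- adsorption_curve("z", 0:1200, numeric(1201))
  expect_true(all(initialize_model(z, unit_cfg())$amplitude == 0))

  # two well-separated components: asymptote within 10 percent
  comps <- list(grid_component(g, 8, 12), grid_component(g, 22, 6))
  m2 <- initialize_model(truth_curve(comps), unit_cfg())
  expect_lt(abs(model_summary(m2)$asymptote - zeroed_asymptote(comps)) /
              zeroed_asymptote(comps), 0.1)

  # underdetermined record triggers a warning but still returns a model
  short <- adsorption_curve("s", seq(0, 1200, length.out = 40),
                            seq(0, 5, length.out = 40))
  expect_warning(initialize_model(short, unit_cfg()), "underdetermined")
})

test_that("refinement reaches the noise floor and is a near fixed point", {
  g <- unit_grid()
  cmp <- grid_component(g, 15, amplitude = 25)
  cv <- truth_curve(list(cmp))

  # noise-free: residual far below the amplitude
  m <- refine_model(cv, initialize_model(cv, unit_cfg()), unit_cfg())
  expect_lt(m$diagnostics$rmsd, 1e-6 * cmp$amplitude)

  # noisy: residual lands at the injected noise level
  set.seed(31)
  sigma <- 0.1
  noisy <- adsorption_curve("n", cv$time, cv$response +
                              rnorm(length(cv$time), sd = sigma))
  mn <- refine_model(noisy, initialize_model(noisy, unit_cfg()), unit_cfg())
  expect_gte(mn$diagnostics$rmsd, 0.8 * sigma)
  expect_lte(mn$diagnostics$rmsd, 1.2 * sigma)

  # refining an already-refined model barely moves it
  mn2 <- refine_model(noisy, mn, unit_cfg())
  expect_lte(mn2$diagnostics$rmsd, mn$diagnostics$rmsd + 1e-9)
  expect_lt(max(abs(mn2$amplitude - mn$amplitude)), 1e-2)
})

test_that("pruning implements the strict logical-switch semantics", {
  g <- unit_grid(30)
  amp <- c(10, rep(0.005, 29))
  m <- frc_model(g, amp, rep(100, 30), rep(0.01, 30))

  expect_identical(prune(m, 0)$amplitude, m$amplitude)

  # one dominant component among near-zero dust: only it survives eps = 1e-3
  p2 <- prune(m, 1e-3)
  expect_equal(sum(p2$amplitude > 0), 1L)

  # strict-< boundary: dust exactly at eps * max survives
  m_edge <- frc_model(g, c(10, rep(0.01, 29)), rep(100, 30), numeric(30))
  expect_identical(prune(m_edge, 1e-3)$amplitude, m_edge$amplitude)
  # vertical-shift total is conserved, so asymptote and prediction are kept
  expect_equal(sum(p2$v_shift), sum(m$v_shift))
  expect_equal(model_summary(p2)$asymptote,
               model_summary(m)$asymptote - sum(amp[-1]))
  tt <- seq(0, 1200, by = 50)
  expect_lte(max(abs(frc_value(m, tt) - frc_value(p2, tt))), sum(amp[-1]))

  # all-equal amplitudes: nothing is strictly below eps * max
  meq <- frc_model(g, rep(2, 30), rep(100, 30), numeric(30))
  expect_identical(prune(meq, 0.5)$amplitude, meq$amplitude)
})

test_that("the fit pipeline is deterministic and objective-monotone", {
  g <- unit_grid()
  comps <- list(grid_component(g, 10, 9), grid_component(g, 22, 14))
  cv <- truth_curve(comps)
  set.seed(32)
  cv$response <- cv$response + rnorm(length(cv$response), sd = 0.05)

  m1 <- fit_frc(cv, unit_cfg())
  m2 <- fit_frc(cv, unit_cfg())
  expect_identical(m1$amplitude, m2$amplitude)
  expect_identical(m1$t_shift, m2$t_shift)
  expect_identical(m1$v_shift, m2$v_shift)

  sr <- m1$diagnostics$stage_rmsd
  expect_lte(sr[["refined"]], sr[["initialized"]] + 1e-9)
  # pruning may cost at most the pruned amplitude total
  expect_lte(sr[["pruned"]], sr[["refined"]] +
               sum(m1$amplitude) * unit_cfg()$prune_eps * g$n)
})

test_that("fitting recovers well-separated ground-truth components", {
  g <- unit_grid()
  comps <- list(grid_component(g, 10, 9), grid_component(g, 22, 14))
  cv <- truth_curve(comps)
  set.seed(33)
  cv$response <- cv$response + rnorm(length(cv$response), sd = 0.05)

  m <- fit_frc(cv, unit_cfg())
  sp <- extract_spectrum(m)
  pk <- spectrum_peaks(sp)
  for (idx in c(10, 22)) {
    expect_true(any(abs(pk - idx) <= 1))
  }
  asym <- zeroed_asymptote(comps)
  expect_lt(abs(model_summary(m)$asymptote - asym) / asym, 0.05)
})

test_that("a pure Langmuir record concentrates weight around its rate", {
  tt <- 0:1200
  k_true <- 0.02
  cv <- adsorption_curve("lang", tt,
                         langmuir_value(langmuir_params(20, k_true), tt))
  m <- fit_frc(cv, unit_cfg())
  sp <- extract_spectrum(m)
  step <- diff(sp$log_k_obs[1:2])
  # a single band: at least 70 percent of weight within half a decade
  band <- abs(sp$log_k_obs - log10(k_true)) <= 0.5
  expect_gte(sum(sp$curve_weight[band]) / sum(sp$curve_weight), 0.7)
  # the spectral mode sits at the Langmuir rate
  mode_idx <- which.max(sp$curve_weight)
  expect_lte(abs(sp$log_k_obs[mode_idx] - log10(k_true)), 3 * step)
})

test_that("fitted amplitudes scale with the curve and shift with its clock", {
  g <- unit_grid()
  comps <- list(grid_component(g, 12, 10), grid_component(g, 24, 7))
  cv <- truth_curve(comps)
  set.seed(34)
  cv$response <- cv$response + rnorm(length(cv$response), sd = 0.02)

  m1 <- fit_frc(cv, unit_cfg())
  cs <- 3.7
  cv_s <- adsorption_curve("scaled", cv$time, cs * cv$response)
  m2 <- fit_frc(cv_s, unit_cfg())
  expect_equal(sum(m2$amplitude), cs * sum(m1$amplitude), tolerance = 1e-3)
  expect_equal(model_summary(m2)$asymptote,
               cs * model_summary(m1)$asymptote, tolerance = 1e-3)

  # delaying a single-component curve moves the fitted inflection time
  tau <- 100
  one <- grid_component(g, 15, 18)
  delayed <- sigmoid_component(18, one$k_obs, one$t_shift + tau)
  f1 <- fit_frc(truth_curve(list(one)), unit_cfg())
  f2 <- fit_frc(truth_curve(list(delayed)), unit_cfg())
  ts1 <- sum(f1$t_shift * f1$amplitude) / sum(f1$amplitude)
  ts2 <- sum(f2$t_shift * f2$amplitude) / sum(f2$amplitude)
  expect_equal(ts2 - ts1, tau, tolerance = 0.1)
})
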