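test_that("plateau estimation averages the tail and flags drift", {
  t <- 0:1000
  flat <- adsorption_curve("flat", t, rep(12, length(t)))
  p <- plateau_estimate(flat)
  expect_equal(p$value, 12)
  expect_true(p$converged)

  # Langmuir observed to 7 characteristic times: the tail mean misses A by
  # the analytic average deficit (e^-6.3 - e^-7)/0.7 ~ 0.13 percent
  k <- 0.007
  tt <- seq(0, 7 / k, by = 1)
  lang <- adsorption_curve("lang", tt,
                           langmuir_value(langmuir_params(20, k), tt))
  pl <- plateau_estimate(lang)
  expect_lt(abs(pl$value - 20) / 20, (exp(-6.3) - exp(-7)) / 0.7 * 1.05)
  expect_true(pl$converged)
  # observed to 9 characteristic times the deficit is below 0.1 percent
  tt9 <- seq(0, 9 / k, by = 1)
  lang9 <- adsorption_curve("lang9", tt9,
                            langmuir_value(langmuir_params(20, k), tt9))
  expect_lt(abs(plateau_estimate(lang9)$value - 20) / 20, 0.001)

  rising <- adsorption_curve("rise", t, 0.05 * t)
  pr <- plateau_estimate(rising)
  expect_false(pr$converged)
  expect_equal(pr$value, mean(0.05 * t[t >= 900]))
})

hill_theta <- function(C_uM, n, K_d_M) {
  C <- C_uM * 1e-6
  C^n / (K_d_M^n + C^n)
}

test_that("Hill fit is exact on noise-free data from its own model class", {
  conc <- 10^seq(-1, 1, length.out = 8)   # 0.1 .. 10 uM around K_d = 1 uM
  f_max <- 20

  # n = 1 (Langmuir limit): n and K_eq recovered to machine-level precision
  pts1 <- data.frame(concentration = conc,
                     response = f_max * hill_theta(conc, 1, 1e-6))
  h1 <- hill_fit(pts1, f_max = f_max)
  expect_lt(abs(h1$n - 1), 1e-6)
  expect_lt(abs(h1$K_eq - 1e6) / 1e6, 1e-3)
  expect_gt(h1$r_squared, 1 - 1e-12)
  expect_equal(h1$delta_G, delta_g(h1$K_eq))

  # n = 2: slope recovered
  pts2 <- data.frame(concentration = conc,
                     response = f_max * hill_theta(conc, 2, 1e-6))
  h2 <- hill_fit(pts2, f_max = f_max)
  expect_lt(abs(h2$n - 2), 1e-6)
  expect_lt(abs(h2$K_eq - 1e6) / 1e6, 1e-3)

  # profiled saturation response: same answers without being told f_max
  h1f <- hill_fit(pts1, f_max = "fit")
  expect_lt(abs(h1f$n - 1), 1e-3)
  expect_lt(abs(h1f$f_max - f_max) / f_max, 0.01)
})

test_that("Hill fit enforces preconditions and excludes invalid occupancies", {
  two <- data.frame(concentration = c(0.1, 1), response = c(2, 10))
  expect_error(hill_fit(two, f_max = 20), "3 points")

  conc <- 10^seq(-1, 1, length.out = 8)
  resp <- 20 * hill_theta(conc, 1, 1e-6)
  resp[8] <- 21   # occupancy above 1 at the given f_max
  pts <- data.frame(concentration = conc, response = resp)
  expect_warning(h <- hill_fit(pts, f_max = 20), "excluded")
  expect_identical(h$points_used, 7L)
  expect_identical(h$excluded, 8L)

  expect_error(hill_fit(data.frame(concentration = c(-1, 1, 2),
                                   response = c(1, 2, 3)), f_max = 20),
               "positive")
})

test_that("free-energy conversion follows -RT ln K", {
  expect_identical(delta_g(1), 0)
  expect_equal(delta_g(exp(10)), -10 * 1.987e-3 * 298.15)
  expect_equal(delta_g(exp(1), T = 100), -1.987e-3 * 100)
  expect_error(delta_g(0), "positive")

  # strictly decreasing in K_eq, linear in T
  ks <- 10^seq(0, 8, by = 1)
  expect_true(all(diff(delta_g(ks)) < 0))
  expect_equal(delta_g(1e6, T = 400) / delta_g(1e6, T = 200), 2)
})

test_that("Langmuir fitting recovers its own model and loses to FRC on sigmoids", {
  tt <- 0:1200
  truth <- langmuir_params(20, 0.005)
  cv <- adsorption_curve("l", tt, langmuir_value(truth, tt))
  fit <- langmuir_fit(cv)
  expect_lt(abs(fit$amplitude - 20) / 20, 1e-6)
  expect_lt(abs(fit$k_obs - 0.005) / 0.005, 1e-6)
  expect_false(attr(fit, "degenerate"))

  # cooperative (sigmoidal) input: the non-cooperative model cannot follow
  # the growth phase, the spectral model can
  g <- unit_grid()
  cv_sig <- truth_curve(list(grid_component(g, 12, 20)))
  lf <- langmuir_fit(cv_sig)
  frc <- fit_frc(cv_sig, fit_config(k_min = 1e-3, k_max = 1,
                                    n_components = 30))
  expect_gt(attr(lf, "rmsd"), frc$diagnostics$rmsd)

  z <- adsorption_curve("z", tt, numeric(length(tt)))
  zf <- langmuir_fit(z)
  expect_identical(zf$amplitude, 0)
  expect_true(attr(zf, "degenerate"))
})

test_that("peptide average masses follow the standard residue table", {
  expect_equal(peptide_average_mass("G"), 75.07)
  expect_equal(peptide_average_mass("GG"), 132.12)

  # additivity: mass(s1 + s2) = mass(s1) + mass(s2) - water
  set.seed(41)
  aas <- strsplit("ARNDCEQGHILKMFPSTWYV", "")[[1]]
  for (i in 1:10) {
    s1 <- paste(sample(aas, sample(3:10, 1), replace = TRUE), collapse = "")
    s2 <- paste(sample(aas, sample(3:10, 1), replace = TRUE), collapse = "")
    expect_equal(peptide_average_mass(paste0(s1, s2)),
                 peptide_average_mass(s1) + peptide_average_mass(s2) - 18.02)
  }

  expect_error(peptide_average_mass("GXG"), "position 2")
  expect_error(peptide_average_mass(""), "empty")
})
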