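make_run <- function(id, diss, t = 0:100, conc = NA_real_) {
  adsorption_run(id, t,
                 freq_shift = list(`5` = -seq_along(t) * 0.1),
                 dissipation = if (is.null(diss)) NULL else list(`5` = diss),
                 concentration = conc)
}

test_that("dissipation filter applies the strict excursion threshold", {
  t <- 0:100
  runs <- list(
    flat  = make_run("flat", rep(1e-7, length(t))),
    ramp  = make_run("ramp", seq(0, 2e-6, length.out = length(t))),
    sine  = make_run("sine", 0.15e-6 * sin(2 * pi * t / 50)),
    edge  = make_run("edge", seq(0, 0.5e-6, length.out = length(t))))
  out <- dissipation_filter(runs)
  rep <- out$report
  expect_identical(rep$kept, c(TRUE, FALSE, TRUE, FALSE))

  # excursion equals the brute-force maximum over samples
  for (id in names(runs)) {
    d <- runs[[id]]$dissipation[[1]]
    brute <- 0
    for (i in seq_along(d)) brute <- max(brute, abs(d[i] - d[1]))
    expect_equal(rep$max_dissipation_excursion[rep$run_id == id], brute)
  }
  # boundary case sits exactly at the threshold and is rejected (strict <)
  expect_equal(rep$max_dissipation_excursion[rep$run_id == "edge"], 0.5e-6)
})

test_that("runs without dissipation are unfilterable and the filter partitions", {
  runs <- list(ok = make_run("ok", rep(0, 101)),
               bad = make_run("bad", seq(0, 1e-5, length.out = 101)),
               nodiss = make_run("nodiss", NULL))
  expect_warning(out <- dissipation_filter(runs), "unfilterable")
  rep <- out$report
  expect_identical(sort(rep$run_id), sort(names(runs)))
  expect_true(all(xor(rep$kept, !rep$kept)))
  expect_identical(names(out$kept), "ok")
  expect_true(rep$unfilterable[rep$run_id == "nodiss"])
  expect_false(rep$kept[rep$run_id == "nodiss"])
})

test_that("overtone averaging matches brute-force means and conventions", {
  t <- 0:50
  g <- -(1 - exp(-0.1 * t)) * 10   # raw negative-going shift, g(0) = 0

  # identical shifts on all overtones, un-normalized: response is -g
  r1 <- adsorption_run("r1", t, list(`5` = g, `7` = g, `9` = g))
  cv1 <- average_overtones(r1, normalize_by_overtone = FALSE)
  expect_equal(cv1$response, -g)
  expect_identical(cv1$response[1], 0)

  # constant -5/-7/-9 Hz with overtone normalization: 1 Hz flat
  r2 <- adsorption_run("r2", t, list(`5` = rep(-5, length(t)),
                                     `7` = rep(-7, length(t)),
                                     `9` = rep(-9, length(t))))
  cv2 <- average_overtones(r2, baseline_zero = FALSE)
  expect_equal(cv2$response, rep(1, length(t)))
  # with zeroing, a constant curve flattens to zero (invariant)
  expect_equal(average_overtones(r2)$response, rep(0, length(t)))

  # random shifts: equals the hand-computed mean, unnormalized
  set.seed(7)
  fs <- list(`5` = rnorm(51), `7` = rnorm(51), `9` = rnorm(51))
  r3 <- adsorption_run("r3", t, fs)
  cv3 <- average_overtones(r3, normalize_by_overtone = FALSE,
                           baseline_zero = FALSE)
  expect_rel_equal(cv3$response + 10, -(fs$`5` + fs$`7` + fs$`9`) / 3 + 10)

  expect_error(average_overtones(r3, overtones = c(5, 11)), "11")
})

test_that("overtone averaging is linear in the raw signals", {
  t <- 0:50
  set.seed(8)
  a <- list(`5` = rnorm(51), `7` = rnorm(51), `9` = rnorm(51))
  b <- list(`5` = rnorm(51), `7` = rnorm(51), `9` = rnorm(51))
  ab <- Map(`+`, a, b)
  avg <- function(fs) {
    average_overtones(adsorption_run("x", t, fs), baseline_zero = FALSE)
  }
  expect_equal(avg(ab)$response, avg(a)$response + avg(b)$response)
})

test_that("mean_curve averages pointwise and guards time grids", {
  t <- 0:100
  base <- adsorption_curve("c", t, (1 - exp(-0.05 * t)) * 8)
  up <- adsorption_curve("u", t, base$response + 0.7)
  dn <- adsorption_curve("d", t, base$response - 0.7)

  expect_equal(mean_curve(list(base))$response, base$response)
  expect_equal(mean_curve(list(up, dn))$response, base$response)

  set.seed(9)
  curves <- lapply(1:5, function(i) {
    adsorption_curve(paste0("r", i), t, base$response + rnorm(101, sd = 0.2))
  })
  expect_equal(mean_curve(curves)$response, loop_mean(curves))

  other <- adsorption_curve("o", seq(0, 100, by = 2),
                            (1 - exp(-0.05 * seq(0, 100, by = 2))) * 8)
  expect_error(mean_curve(list(base, other)), "resample")
  expect_silent(mean_curve(list(base, other), resample = TRUE))
})

test_that("representative selection minimizes RMSD with lexicographic ties", {
  t <- 0:100
  shape <- (1 - exp(-0.05 * t)) * 8

  # single curve: chosen, RMSD zero
  one <- select_representative(list(adsorption_curve("only", t, shape)))
  expect_identical(one$chosen_run_id, "only")
  expect_equal(one$rmsd_by_run[["only"]], 0)

  # the curve equal to the mean of the other two is chosen
  trio <- list(adsorption_curve("hi", t, shape + 1),
               adsorption_curve("lo", t, shape - 1),
               adsorption_curve("mid", t, shape))
  expect_identical(select_representative(trio)$chosen_run_id, "mid")

  # exact duplicates: lexicographically first id wins
  dup <- list(adsorption_curve("b", t, shape),
              adsorption_curve("a", t, shape))
  expect_identical(select_representative(dup)$chosen_run_id, "a")
})

test_that("selected replicate attains the exhaustive minimum RMSD", {
  t <- 0:100
  shape <- (1 - exp(-0.05 * t)) * 8
  for (seed in 1:3) {
    set.seed(seed)
    curves <- lapply(1:5, function(i) {
      adsorption_curve(paste0("r", i), t,
                       shape + rnorm(101, sd = runif(1, 0.1, 1)))
    })
    sel <- select_representative(curves)
    m <- loop_mean(curves)
    brute <- vapply(curves, function(cv) {
      sqrt(mean((cv$response - m)^2))
    }, numeric(1))
    expect_identical(sel$chosen_run_id,
                     curves[[which.min(brute)]]$run_id)
    expect_true(all(sel$rmsd_by_run[[sel$chosen_run_id]] <= brute + 1e-15))
  }
})

test_that("resampling is exact on its grid, linear data, and refuses to extrapolate", {
  t <- seq(0, 100, by = 1)
  ramp <- adsorption_curve("ramp", t, 0.3 * t)
  expect_equal(resample_to_grid(ramp, t)$response, ramp$response)
  mid <- seq(0.5, 99.5, by = 1)
  expect_equal(resample_to_grid(ramp, mid)$response, 0.3 * mid)
  expect_error(resample_to_grid(ramp, seq(-1, 50, by = 1)), "extrapolation")

  # sigmoid resampled at 2x density stays within 1e-3 of the amplitude
  cmp <- sigmoid_component(10, 0.05, t_shift = 50)
  sig <- adsorption_curve("sig", t, sigmoid_value(cmp, t))
  dense <- seq(0, 100, by = 0.5)
  out <- resample_to_grid(sig, dense)
  expect_lt(max(abs(out$response - sigmoid_value(cmp, dense))),
            1e-3 * cmp$amplitude)
})
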