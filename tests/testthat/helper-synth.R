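# Shared fixtures: small grids and noise-free curves built from known
# components, so every expected value is constructed, not guessed.

unit_grid <- function(n = 30) make_grid(1e-3, 1, n = n)

# noise-free adsorption curve from ground-truth components, baseline-zeroed
truth_curve <- function(components, t = 0:1200, run_id = "truth",
                        concentration = NA_real_) {
  y <- numeric(length(t))
  for (cmp in components) y <- y + sigmoid_value(cmp, t)
  adsorption_curve(run_id, t, y - y[1], concentration = concentration)
}

# component pinned to a grid index, inflection at its characteristic time
grid_component <- function(grid, idx, amplitude, v_shift = 0) {
  sigmoid_component(amplitude, grid$values[idx],
                    t_shift = 1 / grid$values[idx], v_shift = v_shift)
}

# asymptote of the baseline-zeroed truth (what a fit of the zeroed curve
# can recover): limiting value minus the value at t = 0
zeroed_asymptote <- function(components) {
  a <- sum(vapply(components, `[[`, numeric(1), "amplitude"))
  v <- sum(vapply(components, `[[`, numeric(1), "v_shift"))
  at0 <- sum(vapply(components, sigmoid_value, numeric(1), t = 0))
  (a - v) - at0
}

# brute-force mean of curve responses, independent of mean_curve()
loop_mean <- function(curves) {
  acc <- numeric(length(curves[[1]]$response))
  for (cv in curves) acc <- acc + cv$response
  acc / length(curves)
}

expect_rel_equal <- function(object, expected, tol = 1e-12) {
  denom <- pmax(abs(expected), 1e-300)
  expect_lt(max(abs(object - expected) / denom), tol)
}
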