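test_that("unstimulated systems stay at the resting fixed point", {
  for (v in model_variants()) {
    traj <- simulate_model(v, default_parameters(v), stimulus_protocol(0, 0),
                           times = seq(0, 7200, by = 60))
    expect_equal(max(abs(traj$IKKp)), 0, tolerance = 1e-10)
    expect_equal(max(abs(traj$PP2A - 1)), 0, tolerance = 1e-10)
  }
})

test_that("PP2A under UVB follows exponential decay", {
  p <- default_parameters("original")
  traj <- simulate_model("original", p, stimulus_protocol(0, 1),
                         times = seq(0, 7200, by = 30))
  expect_equal(traj$PP2A, exp(-p[["k_uv"]] * traj$time), tolerance = 1e-7)
})

test_that("ILRc matches its two-exponential closed form", {
  p <- default_parameters("original")
  for (dose in c(0.029, 0.588)) {
    traj <- simulate_model("original", p, stimulus_protocol(dose, 0),
                           times = seq(0, 7200, by = 10))
    expected <- ilrc_closed_form(traj$time, dose, p[["k_a"]], p[["k_i"]])
    rel <- abs(traj$ILRc - expected) / max(expected)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("closed form agrees with a high-accuracy independent integration", {
  # independent oracle: integrate the two-state receptor subsystem with an
  # R-coded RHS at tight tolerance and compare at t = 100 s
  k_a <- 0.01; k_i <- 0.005; il <- 0.588
  rhs <- function(t, y, parms) {
    list(c(-k_a * il * y[1], k_a * il * y[1] - k_i * y[2]))
  }
  out <- deSolve::lsoda(c(1, 0), c(0, 100), rhs, NULL,
                        rtol = 1e-12, atol = 1e-14)
  expect_rel_equal(ilrc_closed_form(100, il, k_a, k_i), out[2, 3], 1e-8)
  # limit branch at k_a*il == k_i
  expect_equal(ilrc_closed_form(100, 1, 0.005, 0.005), 0.005 * 100 * exp(-0.5))
  expect_equal(ilrc_closed_form(0, 0.588, 0.01, 0.005), 0)
  expect_lt(ilrc_closed_form(1e7, 0.588, 0.01, 0.005), 1e-12)
  expect_error(ilrc_closed_form(-1, 1, 1, 1), "non-negative")
})

test_that("compiled and R right-hand sides integrate identically", {
  for (v in model_variants()) {
    p <- default_parameters(v)
    proto <- stimulus_protocol(0.029, 1)
    rfun <- function(t, y, parms) list(model_rhs(v, y, t, p, proto))
    tt <- seq(0, 7200, by = 600)
    ref <- deSolve::lsoda(initial_state(v, I0 = if (v == "irreversible_inhibitor") p[["I_0"]] else 1),
                          tt, rfun, NULL, rtol = 1e-10, atol = 1e-12)
    traj <- simulate_model(v, p, proto, times = tt, rtol = 1e-10, atol = 1e-12)
    expect_equal(traj$IKKp, unname(ref[, "IKKp"]), tolerance = 1e-7)
  }
})

test_that("trajectory characteristics are exact on injected closed forms", {
  # linear ramp: mean 0.5, half-max at T/2, peak at the end
  ramp <- structure(
    data.frame(time = 0:7200, IKKp = (0:7200) / 7200,
               ikkp_obs = (0:7200) / 7200),
    class = c("ikk_trajectory", "data.frame"))
  expect_equal(mean_ikkp(ramp), 0.5)
  expect_equal(time_to_half_max(ramp), 3600)
  expect_equal(peak_amplitude(ramp), 1)
  const <- structure(
    data.frame(time = 0:100, IKKp = rep(0.3, 101), ikkp_obs = rep(0.6, 101)),
    class = c("ikk_trajectory", "data.frame"))
  expect_equal(mean_ikkp(const, horizon = 100), 0.3)
  expect_equal(mean_ikkp(const, horizon = 100, observed = TRUE), 0.6)
  zero <- structure(
    data.frame(time = 0:10, IKKp = rep(0, 11), ikkp_obs = rep(0, 11)),
    class = c("ikk_trajectory", "data.frame"))
  expect_equal(peak_amplitude(zero), 0)
  expect_error(time_to_half_max(zero), "half-maximum")
  expect_error(mean_ikkp(const, horizon = 500), "horizon")
})

test_that("characteristics are stable under grid refinement", {
  p <- truth_params()
  proto <- stimulus_protocol(0.029, 0)
  t1 <- simulate_model("traf", p, proto, times = seq(0, 7200, by = 2))
  t2 <- simulate_model("traf", p, proto, times = seq(0, 7200, by = 1))
  expect_rel_equal(peak_amplitude(t1), peak_amplitude(t2), 1e-6)
  expect_rel_equal(mean_ikkp(t1), mean_ikkp(t2), 1e-5)
  expect_lt(abs(time_to_half_max(t1) - time_to_half_max(t2)) /
              time_to_half_max(t2), 0.01)
  # trapezoidal mean against adaptive quadrature on an interpolant
  fine <- simulate_model("traf", p, proto, times = seq(0, 7200, by = 0.5))
  fint <- splinefun(fine$time, fine$IKKp)
  quad <- integrate(fint, 0, 7200, rel.tol = 1e-9,
                    subdivisions = 2000)$value / 7200
  expect_rel_equal(mean_ikkp(t2), quad, 1e-5)
})

test_that("integration is deterministic and tolerance-controlled", {
  p <- truth_params()
  proto <- stimulus_protocol(0.588, 1)
  tt <- seq(0, 7200, by = 60)
  a <- simulate_model("traf", p, proto, times = tt)
  b <- simulate_model("traf", p, proto, times = tt)
  expect_identical(a$IKKp, b$IKKp)
  tight <- simulate_model("traf", p, proto, times = tt,
                          rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$ikkp_obs - tight$ikkp_obs)), 1e-6)
})

test_that("conservation holds across a random parameter sweep", {
  set.seed(42)
  for (rep in 1:25) {
    for (v in model_variants()) {
      p <- random_params(v)
      proto <- stimulus_protocol(sample(c(0.029, 0.588), 1), sample(0:1, 1))
      traj <- simulate_model(v, p, proto, times = seq(0, 7200, by = 120))
      expect_lt(conservation_residual(traj), 1e-6)
      species <- setdiff(names(traj), c("time", "ikkp_obs", "I"))
      expect_gte(min(as.matrix(traj[species])), -1e-8)
      expect_lte(max(as.matrix(traj[species])), 1 + 1e-8)
      # receptor monotone decreasing, PP2A constant without UV
      expect_true(all(diff(traj$ILR) <= 1e-8))
      if (proto$uv_on == 0) expect_equal(traj$PP2A, rep(1, nrow(traj)))
    }
  }
})

test_that("raising the IL-1 dose never lowers the core-model peak", {
  set.seed(7)
  for (rep in 1:10) {
    p <- random_params("original")
    peaks <- vapply(c(0.01, 0.05, 0.2, 0.588), function(d) {
      peak_amplitude(simulate_model("original", p, stimulus_protocol(d, 0),
                                    times = seq(0, 7200, by = 30)))
    }, numeric(1))
    expect_true(all(diff(peaks) >= -1e-9))
  }
})

test_that("a delayed stimulus onset leaves the system at rest until onset", {
  p <- truth_params()
  traj <- simulate_model("traf", p, stimulus_protocol(0.588, 1, onset_time = 600),
                         times = seq(0, 3600, by = 60))
  pre <- traj$time < 600
  expect_equal(max(abs(traj$IKKp[pre])), 0)
  expect_equal(max(abs(traj$ILRc[pre])), 0)
  expect_gt(traj$ILRc[traj$time == 1200], 0)
  # identical to an unshifted simulation displaced by the onset
  ref <- simulate_model("traf", p, stimulus_protocol(0.588, 1),
                        times = seq(0, 3000, by = 60))
  expect_equal(traj$IKKp[traj$time >= 600], ref$IKKp, tolerance = 1e-7)
})

test_that("trajectory CSV export writes the tidy column layout", {
  p <- truth_params()
  traj <- simulate_model("traf", p, stimulus_protocol(0.029, 0),
                         times = seq(0, 1200, by = 60))
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read.csv(path)
  expect_true(all(c("time_s", "IKKp", "ikkp_obs") %in% names(back)))
  expect_equal(back$IKKp, traj$IKKp, tolerance = 1e-12)
})

test_that("simulation rejects invalid inputs", {
  p <- default_parameters("original")
  expect_error(simulate_model("original", p, stimulus_protocol(1, 0),
                              times = c(-10, 0, 10)), "negative")
  expect_error(simulate_model("original", p[-1], stimulus_protocol(1, 0)),
               "missing parameter")
})
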