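test_that("chi-square matches hand computations and a naive-loop oracle", {
  ds <- noisefree_dataset()
  theta <- truth_theta()
  # predictions identical to data -> 0
  expect_equal(chi_squared(ds, "traf", theta), 0, tolerance = 1e-12)

  # residuals of exactly 1 and 2 sigma -> 1^2 + 2^2 = 5
  two <- ds
  two$records <- ds$records[1:2, ]
  clean <- two$records$y
  two$records$y <- clean + c(1, 2) * two$records$sigma
  expect_equal(chi_squared(two, "traf", theta), 5, tolerance = 1e-8)

  # independently coded naive double loop over conditions and points
  set.seed(5)
  noisy <- noisy_dataset()
  sub <- noisy
  sub$records <- noisy$records[sample(nrow(noisy$records), 20), ]
  obs <- truth_obs()
  naive <- 0
  for (cid in unique(sub$records$condition_id)) {
    rows <- sub$records[sub$records$condition_id == cid, ]
    proto <- stimulus_protocol(rows$il_nM[1], rows$uv[1])
    for (j in seq_len(nrow(rows))) {
      traj <- simulate_model("traf", truth_params(), proto, obs = obs,
                             times = sort(unique(c(0, rows$time_s[j], 7200))))
      yhat <- traj$ikkp_obs[match(rows$time_s[j], traj$time)]
      naive <- naive + ((rows$y[j] - yhat) / rows$sigma[j])^2
    }
  }
  expect_equal(chi_squared(sub, "traf", theta), naive, tolerance = 1e-6)
})

test_that("chi-square is reorder-invariant and additive over conditions", {
  ds <- noisy_dataset()
  theta <- truth_theta()
  full <- chi_squared(ds, "traf", theta)
  shuffled <- ds
  set.seed(3)
  shuffled$records <- ds$records[sample(nrow(ds$records)), ]
  expect_equal(chi_squared(shuffled, "traf", theta), full, tolerance = 1e-9)
  parts <- vapply(unique(ds$records$condition_id), function(cid) {
    one <- ds
    one$records <- ds$records[ds$records$condition_id == cid, ]
    one$conditions <- ds$conditions[ds$conditions$condition_id == cid, ]
    chi_squared(one, "traf", theta)
  }, numeric(1))
  expect_equal(sum(parts), full, tolerance = 1e-9)
})

test_that("fitting a noise-free dataset recovers the generating truth", {
  ds <- noisefree_dataset()
  theta <- truth_theta()
  f <- fit_model("traf", ds, theta)
  expect_lt(f$chi2, 1e-6)

  f2 <- fit_model("traf", ds, theta * 1.5)
  expect_lt(f2$chi2, 1e-6)
  expect_true(all(abs(f2$theta / theta[names(f2$theta)] - 1) < 1e-3))
})

test_that("fit contract: bounds checked, objective never increases", {
  ds <- noisy_dataset()
  theta <- truth_theta()
  bad <- theta
  bad["scale_low"] <- 5  # above the experimental bound of 4
  expect_error(fit_model("traf", ds, bad), "upper bound")
  expect_error(fit_model("traf", ds, replace(theta, "k_a", -1)),
               "strictly positive")

  set.seed(21)
  for (i in 1:3) {
    start <- pmin(theta * 10^runif(length(theta), -1, 1),
                  default_bounds("traf"))
    f <- fit_model("traf", ds, start,
                   control = minpack.lm::nls.lm.control(maxiter = 50))
    expect_lte(f$chi2, f$chi2_start + 1e-9)
    # accepted-step objective trace decreases (up to the solver-noise-level
    # wiggle of the final, possibly rejected, evaluation)
    tr <- f$chi2_trace
    expect_true(all(diff(tr) <= 1e-6 * tr[-length(tr)]))
    expect_lte(tr[length(tr)], tr[1] + 1e-9)
  }
})

test_that("fixing the shared downstream rates still fits delayed data well", {
  ds <- noisy_dataset()
  theta <- truth_theta()
  free_fit <- fit_model("traf", ds, theta)
  down <- unlist(kinetic_constants()$downstream_rates$original)
  fixed_fit <- fit_model("traf", ds, theta,
                         fixed = down[c("k_p", "k_dp", "k_uv")])
  expect_identical(unname(fixed_fit$theta["k_p"]), unname(down["k_p"]))
  expect_gte(fixed_fit$chi2, free_fit$chi2 - 1e-6)
  # only slightly worse than the free fit: still a good description
  expect_lt(fixed_fit$chi2, 2 * max(free_fit$chi2, n_records(ds)))
})

test_that("multistart is seeded, deterministic and sorted", {
  ds <- noisy_dataset()
  theta <- truth_theta()
  e0 <- multistart("traf", ds, theta, n_fits = 3, decades = 0, seed = 1)
  expect_true(all(abs(e0$results$chi2 - e0$results$chi2[1]) < 1e-9))
  e1 <- multistart("traf", ds, theta, n_fits = 4, decades = 2, seed = 8)
  e2 <- multistart("traf", ds, theta, n_fits = 4, decades = 2, seed = 8)
  expect_equal(e1$results, e2$results)
  expect_true(!is.unsorted(e1$results$chi2))
  expect_error(multistart("traf", ds, theta, n_fits = 0), "n_fits")
})

test_that("identifiability spread follows the sample-sd convention", {
  ds <- noisy_dataset()
  theta <- truth_theta()
  ens <- multistart("traf", ds, theta, n_fits = 2, decades = 0, seed = 1)
  # identical fits -> zero spread
  expect_true(all(identifiability_spread(ens, keep_fraction = 1) < 1e-6))
  # hand computation: values 1 and 3 -> 100 * sd(c(1,3)) / 2 = 70.71%
  ens2 <- ens
  ens2$results$k_a <- c(1, 3)
  ens2$free <- "k_a"
  expect_equal(unname(identifiability_spread(ens2, keep_fraction = 1)),
               100 * sd(c(1, 3)) / 2, tolerance = 1e-12)
  expect_error(identifiability_spread(ens, keep_fraction = 0), "keep_fraction")
})

test_that("fits to noisy data recover the generating dynamics predictively", {
  # individual rate constants lie on soft (sloppy) directions of the
  # likelihood, but the fitted model must reproduce the generating
  # trajectories: compare noise-free predictions at all design points
  ds <- generate_dataset(noise = noise_model(cv = 0.10), seed = 7)
  f <- fit_model("traf", ds, truth_theta())
  clean <- generate_dataset(noise = noise_model(cv = 0), seed = 1)$records
  obs_fit <- observation_parameters(scale_high = 1,
                                    scale_low = f$theta[["scale_low"]])
  err <- numeric(0)
  for (cid in unique(clean$condition_id)) {
    r <- clean[clean$condition_id == cid, ]
    tr <- simulate_model("traf", f$theta,
                         stimulus_protocol(r$il_nM[1], r$uv[1]),
                         obs = obs_fit, times = sort(unique(c(0, r$time_s))))
    err <- c(err, tr$ikkp_obs[match(r$time_s, tr$time)] - r$y)
  }
  expect_lt(sqrt(mean(err^2)), 0.06)
  expect_lt(max(abs(err)), 0.25)
})
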