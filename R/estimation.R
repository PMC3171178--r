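# Chi-square objective against blot time courses, bounded local fitting in
# log10-parameter space, multi-start ensembles and identifiability spread.

# finite objective sentinel for failed integrations, so the optimizer can
# retreat from pathological parameter regions
.CHI2_SENTINEL <- 1e12

#' Names of the fitted parameters of a variant
#'
#' Kinetic rates plus the observation scale factors that are estimated:
#' the low-dose scale is always fitted; the high-dose scale is fixed to 1
#' by normalization unless `fit_scale_high` is set.
#'
#' @param variant One of [model_variants()].
#' @param fit_scale_high Also fit the high-dose scale factor.
#' @return Character vector of parameter names.
#' @export
fitted_parameter_names <- function(variant, fit_scale_high = FALSE) {
  c(variant_parameters(variant), "scale_low",
    if (fit_scale_high) "scale_high")
}

#' Default upper parameter bounds
#'
#' Positivity is enforced structurally (optimization runs in log10 space,
#' so no lower bounds are needed). Upper bounds: 10 for every rate
#' constant (s^-1, or nM^-1 s^-1 for `k_a`) and for the inhibitor pool
#' `I_0`; 4 for the low-dose scale factor (the experimentally derived
#' bound); 10 for the high-dose scale if it is fitted.
#'
#' @inheritParams fitted_parameter_names
#' @return Named numeric vector of upper bounds.
#' @export
default_bounds <- function(variant, fit_scale_high = FALSE) {
  nm <- fitted_parameter_names(variant, fit_scale_high)
  ub <- rep(10, length(nm))
  names(ub) <- nm
  ub["scale_low"] <- 4
  ub
}

theta_observation <- function(theta, dose_threshold = 0.1) {
  observation_parameters(
    scale_high = if ("scale_high" %in% names(theta)) theta[["scale_high"]] else 1,
    scale_low = if ("scale_low" %in% names(theta)) theta[["scale_low"]] else 1,
    dose_threshold = dose_threshold
  )
}

# weighted residual vector (y - yhat)/sigma over all records; a constant
# sentinel vector (summing to .CHI2_SENTINEL) on integration failure
model_residuals <- function(dataset, variant, theta,
                            rtol = 1e-8, atol = 1e-10) {
  rec <- dataset$records
  obs <- theta_observation(theta, dataset$dose_threshold)
  pred <- numeric(nrow(rec))
  for (i in seq_len(nrow(dataset$conditions))) {
    ci <- dataset$conditions[i, ]
    sel <- rec$condition_id == ci$condition_id
    if (!any(sel)) next
    t_s <- rec$time_s[sel]
    grid <- sort(unique(c(0, t_s)))
    if (length(grid) < 2L) grid <- c(grid, grid + 60)
    proto <- stimulus_protocol(ci$il_nM, ci$uv)
    traj <- tryCatch(
      simulate_model(variant, theta, proto, obs = obs, times = grid,
                     rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(traj)) {
      return(rep(sqrt(.CHI2_SENTINEL / nrow(rec)), nrow(rec)))
    }
    pred[sel] <- traj$ikkp_obs[match(t_s, traj$time)]
  }
  (rec$y - pred) / rec$sigma
}

#' Chi-square objective
#'
#' Weighted sum of squared residuals over all conditions and time points,
#' `sum_ij ((y_ij - y(t_ij, theta)) / sigma_ij)^2`. A failed integration
#' yields the finite sentinel value `1e12` (documented surrogate for
#' +Inf, so optimizers can retreat).
#'
#' @param dataset An `ikk_dataset`.
#' @param variant Model variant to simulate.
#' @param theta Named parameter vector: kinetic rates plus `scale_low`
#'   (and optionally `scale_high`, otherwise fixed at 1).
#' @param rtol,atol Solver tolerances used during objective evaluation.
#' @return Non-negative objective value.
#' @export
chi_squared <- function(dataset, variant, theta, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(dataset, "ikk_dataset"))
  if (any(!(dataset$records$sigma > 0))) {
    stop("all measurement standard deviations must be > 0", call. = FALSE)
  }
  sum(model_residuals(dataset, variant, theta, rtol, atol)^2)
}

#' Fit a model variant to a dataset
#'
#' Local weighted least-squares minimization of [chi_squared()] with the
#' Levenberg-Marquardt algorithm, parametrized in log10 space (which
#' enforces positivity; explicit lower bounds are not needed). Parameters
#' listed in `fixed` are held at the given values.
#'
#' @param variant Model variant.
#' @param dataset An `ikk_dataset`.
#' @param theta0 Named start vector covering the free parameters (values
#'   for fixed parameters are taken from `fixed`).
#' @param bounds Named upper bounds, as from [default_bounds()].
#' @param fixed Optional named vector of parameters to hold fixed.
#' @param fit_scale_high Also fit the high-dose scale factor.
#' @param control A [minpack.lm::nls.lm.control()] list.
#' @param rtol,atol Solver tolerances during fitting.
#' @return Object of class `ikk_fit`: the full parameter vector
#'   `theta`, `chi2`, the free-parameter names, convergence metadata and
#'   the per-iteration objective trace.
#' @export
fit_model <- function(variant, dataset, theta0,
                      bounds = default_bounds(variant, fit_scale_high),
                      fixed = NULL, fit_scale_high = FALSE,
                      control = minpack.lm::nls.lm.control(
                        maxiter = 300, maxfev = 5000,
                        ftol = 1e-12, ptol = 1e-12, epsfcn = 1e-6),
                      rtol = 1e-8, atol = 1e-10) {
  variant <- match_variant(variant)
  all_names <- fitted_parameter_names(variant, fit_scale_high)
  if (!all(names(fixed) %in% all_names)) {
    stop("fixed contains parameters unknown to this variant", call. = FALSE)
  }
  free <- setdiff(all_names, names(fixed))
  missing <- setdiff(free, names(theta0))
  if (length(missing) > 0) {
    stop("theta0 lacks start value(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  th0 <- setNames(numeric(length(all_names)), all_names)
  th0[free] <- theta0[free]
  th0[names(fixed)] <- fixed
  if (any(th0 <= 0)) {
    stop("all start values must be strictly positive", call. = FALSE)
  }
  over <- free[th0[free] > bounds[free]]
  if (length(over) > 0) {
    stop("start value(s) above the upper bound: ", paste(over, collapse = ", "),
         call. = FALSE)
  }

  resfun <- function(x) {
    th <- th0
    th[free] <- 10^x
    model_residuals(dataset, variant, th, rtol, atol)
  }
  r0 <- resfun(log10(th0[free]))
  chi2_0 <- sum(r0^2)
  if (!is.finite(chi2_0)) {
    stop("objective is not finite at the start point", call. = FALSE)
  }
  # iteration-limit warnings are redundant with the `converged` flag
  ans <- suppressWarnings(minpack.lm::nls.lm(
    par = log10(th0[free]), fn = resfun,
    lower = rep(-12, length(free)), upper = log10(bounds[free]),
    control = control
  ))
  theta_hat <- th0
  theta_hat[free] <- 10^ans$par
  chi2 <- ans$deviance
  if (chi2 > chi2_0) {  # LM never accepts an uphill step, but be explicit
    theta_hat <- th0
    chi2 <- chi2_0
  }
  structure(list(variant = variant, theta = theta_hat, chi2 = chi2,
                 free = free, fixed = fixed,
                 converged = ans$info %in% 1:4,
                 n_evaluations = ans$niter, info = ans$info,
                 message = ans$message, chi2_trace = ans$rsstrace,
                 start = th0, chi2_start = chi2_0),
            class = "ikk_fit")
}

#' @export
print.ikk_fit <- function(x, ...) {
  cat(sprintf("ikk_fit [%s]: chi2 = %.4g (%s, %d evaluations)\n",
              x$variant, x$chi2,
              if (x$converged) "converged" else "not converged",
              x$n_evaluations))
  print(signif(x$theta, 4))
  invisible(x)
}

#' Multi-start fitting ensemble
#'
#' Runs `n_fits` local fits started from `theta_ref` perturbed
#' per-parameter by factors `10^U`, `U ~ Uniform(-decades, decades)`,
#' clipped to the bounds. The resulting ensemble (sorted by chi-square)
#' is the raw material of the identifiability analysis.
#'
#' @param variant Model variant.
#' @param dataset An `ikk_dataset`.
#' @param theta_ref Named reference parameter vector (free parameters).
#' @param n_fits Number of starts (>= 1).
#' @param decades Perturbation magnitude in orders of magnitude (default 4).
#' @param seed Integer seed; reproducible, global RNG left untouched.
#' @param bounds,fixed,fit_scale_high,control,rtol,atol Passed to [fit_model()].
#' @return Object of class `ikk_ensemble`: `results` (one row per start,
#'   sorted by `chi2`: fitted parameters, `chi2`, `converged`), `fits`
#'   (the individual `ikk_fit` objects in the same order), and the
#'   perturbation settings.
#' @export
multistart <- function(variant, dataset, theta_ref, n_fits = 200,
                       decades = 4, seed = 1,
                       bounds = default_bounds(variant, fit_scale_high),
                       fixed = NULL, fit_scale_high = FALSE,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 300, maxfev = 5000,
                         ftol = 1e-12, ptol = 1e-12, epsfcn = 1e-6),
                       rtol = 1e-8, atol = 1e-10) {
  variant <- match_variant(variant)
  if (n_fits < 1) stop("n_fits must be >= 1", call. = FALSE)
  if (decades < 0) stop("decades must be >= 0", call. = FALSE)
  free <- setdiff(fitted_parameter_names(variant, fit_scale_high), names(fixed))
  missing <- setdiff(free, names(theta_ref))
  if (length(missing) > 0) {
    stop("theta_ref lacks value(s) for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  U <- with_seed(seed,
    matrix(runif(n_fits * length(free), -decades, decades),
           nrow = n_fits, dimnames = list(NULL, free)))
  fits <- vector("list", n_fits)
  for (k in seq_len(n_fits)) {
    start <- theta_ref[free] * 10^U[k, ]
    start <- pmin(pmax(start, 1e-10), bounds[free])
    fits[[k]] <- fit_model(variant, dataset, theta0 = start, bounds = bounds,
                           fixed = fixed, fit_scale_high = fit_scale_high,
                           control = control, rtol = rtol, atol = atol)
  }
  ord <- order(vapply(fits, function(f) f$chi2, numeric(1)))
  fits <- fits[ord]
  results <- do.call(rbind, lapply(fits, function(f) {
    as.data.frame(c(as.list(f$theta[free]),
                    list(chi2 = f$chi2, converged = f$converged)))
  }))
  structure(list(results = results, fits = fits, variant = variant,
                 theta_ref = theta_ref[free], decades = decades,
                 n_fits = n_fits, seed = seed, free = free),
            class = "ikk_ensemble")
}

#' @export
print.ikk_ensemble <- function(x, ...) {
  cat(sprintf("ikk_ensemble [%s]: %d fits (decades = %g, seed = %d)\n",
              x$variant, x$n_fits, x$decades, x$seed))
  cat(sprintf("best chi2 = %.4g, worst = %.4g\n",
              x$results$chi2[1], x$results$chi2[nrow(x$results)]))
  invisible(x)
}

#' Best fit of an ensemble
#' @param ensemble An `ikk_ensemble`.
#' @return The lowest-chi-square `ikk_fit`.
#' @export
best_fit <- function(ensemble) {
  stopifnot(inherits(ensemble, "ikk_ensemble"))
  ensemble$fits[[1]]
}

#' Identifiability spread of a multi-start ensemble
#'
#' Relative standard deviation (percent of the mean, sample n-1
#' convention) of every fitted parameter over the best
#' `ceiling(keep_fraction * n)` fits. A spread of at most ~1% for all
#' parameters indicates a single, well-determined optimum.
#'
#' @param ensemble An `ikk_ensemble`.
#' @param keep_fraction Fraction of best fits to keep, in (0, 1];
#'   default 0.4.
#' @param scale `"linear"` computes the spread on the parameter values,
#'   `"log10"` on their base-10 logarithms.
#' @return Named vector of per-parameter spreads in percent.
#' @export
identifiability_spread <- function(ensemble, keep_fraction = 0.4,
                                   scale = c("linear", "log10")) {
  stopifnot(inherits(ensemble, "ikk_ensemble"))
  scale <- match.arg(scale)
  if (!(keep_fraction > 0 && keep_fraction <= 1)) {
    stop("keep_fraction must be in (0, 1]", call. = FALSE)
  }
  n <- nrow(ensemble$results)
  if (n == 0) stop("empty ensemble", call. = FALSE)
  keep <- seq_len(ceiling(keep_fraction * n))
  m <- as.matrix(ensemble$results[keep, ensemble$free, drop = FALSE])
  if (scale == "log10") m <- log10(m)
  if (length(keep) == 1L) {
    return(setNames(rep(0, ncol(m)), colnames(m)))
  }
  100 * apply(m, 2, sd) / abs(colMeans(m))
}
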