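# Local relative sensitivity (elasticity) of IKKp trajectory
# characteristics with respect to model parameters, across IL-1 doses.

#' Trajectory characteristic of a parametrized model
#'
#' Evaluates a scalar, time-independent characteristic of the IKKp time
#' course: the peak amplitude `max(IKKp(t))` (grid maximum refined by
#' local quadratic interpolation) or the mean over the observation
#' horizon. Solver tolerances are tighter than in ordinary simulation
#' because these values feed finite-difference derivatives.
#'
#' @param variant Model variant.
#' @param theta Named parameter vector (kinetic rates, optionally
#'   `scale_low`/`scale_high` when `observed = TRUE`).
#' @param protocol An [stimulus_protocol()].
#' @param characteristic `"peak"` or `"mean"`.
#' @param observed Evaluate on the scaled observable instead of latent IKKp.
#' @param horizon Averaging horizon for the mean, seconds.
#' @param dt Dense evaluation grid spacing, seconds.
#' @param rtol,atol Solver tolerances.
#' @return Scalar characteristic value.
#' @export
characteristic_value <- function(variant, theta, protocol,
                                 characteristic = c("peak", "mean"),
                                 observed = FALSE, horizon = 7200, dt = 1,
                                 rtol = 1e-10, atol = 1e-12) {
  characteristic <- match.arg(characteristic)
  obs <- theta_observation(theta)
  traj <- simulate_model(variant, theta, protocol, obs = obs,
                         times = seq(0, horizon, by = dt),
                         rtol = rtol, atol = atol)
  if (characteristic == "peak") {
    peak_amplitude(traj, observed = observed, refine = TRUE)
  } else {
    mean_ikkp(traj, horizon = horizon, observed = observed)
  }
}

#' Relative sensitivity of an IKKp characteristic to one parameter
#'
#' The dimensionless elasticity `s = (p/x) dx/dp`, computed by central
#' differences on a relative step: `s = (x(p(1+h)) - x(p(1-h))) / (2 h x(p))`.
#'
#' @inheritParams characteristic_value
#' @param param Name of the perturbed parameter.
#' @param rel_step Relative step `h` (default 1e-3).
#' @return Data frame with one row: `parameter`, `characteristic`,
#'   `il_dose`, `uv_on`, `s`.
#' @export
relative_sensitivity <- function(variant, theta, protocol, param,
                                 characteristic = c("peak", "mean"),
                                 rel_step = 1e-3, observed = FALSE,
                                 horizon = 7200) {
  characteristic <- match.arg(characteristic)
  if (!param %in% names(theta)) {
    stop("parameter '", param, "' not present in theta", call. = FALSE)
  }
  p <- theta[[param]]
  if (!(p > 0)) stop("perturbed parameter must be > 0", call. = FALSE)
  x0 <- characteristic_value(variant, theta, protocol, characteristic,
                             observed = observed, horizon = horizon)
  if (!(x0 > 0)) {
    stop("characteristic is zero at theta; relative sensitivity undefined",
         call. = FALSE)
  }
  th_p <- th_m <- theta
  th_p[[param]] <- p * (1 + rel_step)
  th_m[[param]] <- p * (1 - rel_step)
  x_p <- characteristic_value(variant, th_p, protocol, characteristic,
                              observed = observed, horizon = horizon)
  x_m <- characteristic_value(variant, th_m, protocol, characteristic,
                              observed = observed, horizon = horizon)
  s <- (x_p - x_m) / (2 * rel_step * x0)
  data.frame(parameter = param, characteristic = characteristic,
             il_dose = protocol$il_dose, uv_on = protocol$uv_on, s = s)
}

#' Sensitivity sweep over parameters and IL-1 doses
#'
#' Evaluates [relative_sensitivity()] on the full grid
#' `params x doses`; the default doses are the two experimental IL-1
#' concentrations (0.029 and 0.588 nM).
#'
#' @inheritParams relative_sensitivity
#' @param params Character vector of parameter names.
#' @param doses IL-1 doses in nM (> 0).
#' @param uv_on UVB indicator applied to every protocol.
#' @return Tidy data frame, one row per (parameter, dose).
#' @export
dose_sweep <- function(variant, theta, params = c("k_a", "k_i", "k_aut", "k_du"),
                       doses = c(0.029, 0.588),
                       characteristic = c("peak", "mean"),
                       uv_on = 0, rel_step = 1e-3, observed = FALSE,
                       horizon = 7200) {
  characteristic <- match.arg(characteristic)
  if (length(params) == 0 || length(doses) == 0) {
    stop("params and doses must be non-empty", call. = FALSE)
  }
  if (any(doses <= 0)) stop("doses must be > 0", call. = FALSE)
  grid <- expand.grid(parameter = params, il_dose = doses,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    relative_sensitivity(variant, theta,
                         stimulus_protocol(grid$il_dose[i], uv_on),
                         param = grid$parameter[i],
                         characteristic = characteristic,
                         rel_step = rel_step, observed = observed,
                         horizon = horizon)
  })
  do.call(rbind, rows)
}
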