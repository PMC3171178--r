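# Numerical integration of the model variants and trajectory-derived
# characteristics (peak, mean, half-maximum time).

#' Western-blot observation scale factors
#'
#' Blot band intensities relate to normalized IKKp through an unknown
#' multiplicative factor; one factor per IL-1 dose level. Doses at or above
#' `dose_threshold` (nM) use `scale_high`, lower doses `scale_low`.
#'
#' @param scale_high,scale_low Positive scale factors.
#' @param dose_threshold Dose (nM) separating the two levels.
#' @return Object of class `ikk_observation`.
#' @export
observation_parameters <- function(scale_high = 1, scale_low = 1,
                                   dose_threshold = 0.1) {
  stopifnot(scale_high > 0, scale_low > 0, dose_threshold > 0)
  structure(list(scale_high = scale_high, scale_low = scale_low,
                 dose_threshold = dose_threshold),
            class = "ikk_observation")
}

scale_for_dose <- function(obs, il_dose) {
  if (il_dose >= obs$dose_threshold) obs$scale_high else obs$scale_low
}

#' Simulate a model variant over a stimulus protocol
#'
#' Integrates the chosen variant with a stiff-capable solver (`lsoda`,
#' compiled right-hand sides) and returns the state time courses together
#' with the scaled observable IKKp_obs and per-time conservation residuals.
#' Before stimulation onset the system rests at its initial state, so
#' integration starts exactly at onset and no input discontinuity falls
#' inside the integration window.
#'
#' @param variant One of [model_variants()].
#' @param params Named parameter vector covering [variant_parameters()].
#' @param protocol An [stimulus_protocol()].
#' @param obs [observation_parameters()] used to scale IKKp to IKKp_obs.
#' @param times Output time grid in seconds (non-negative, increasing).
#'   Defaults to a 1 s grid over 0--7200 s (120 min).
#' @param rtol,atol Solver tolerances.
#' @return A data frame of class `ikk_trajectory` with columns `time`, the
#'   model species, and `ikkp_obs`; attributes carry the variant, protocol,
#'   applied scale and the maximum conservation residual per time point.
#' @export
simulate_model <- function(variant, params, protocol,
                           obs = observation_parameters(),
                           times = seq(0, 7200, by = 1),
                           rtol = 1e-8, atol = 1e-10) {
  variant <- match_variant(variant)
  pv <- check_params(variant, params)
  if (length(times) < 2L) stop("need at least two output times", call. = FALSE)
  if (any(times < 0)) stop("negative output times are not allowed", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)

  I0 <- if (variant == "irreversible_inhibitor") pv[["I_0"]] else 1
  y0 <- initial_state_aug(variant, I0 = I0)
  ext <- setdiff(variant_parameters(variant), c(.CORE_RATES, "I_0"))
  parms <- c(variant_code(variant), protocol$il_dose, protocol$uv_on,
             protocol$onset_time,
             pv[.CORE_RATES],
             if (length(ext)) pv[ext], numeric(3 - length(ext)))

  onset <- protocol$onset_time
  pre <- times[times < onset]
  post <- times[times >= onset]
  sol_pre <- NULL
  if (length(pre) > 0) {
    # system is at rest before onset
    sol_pre <- cbind(time = pre,
                     matrix(rep(y0, each = length(pre)), nrow = length(pre),
                            dimnames = list(NULL, names(y0))))
  }
  sol_post <- NULL
  if (length(post) > 0) {
    t_int <- if (post[1] > onset) c(onset, post) else post
    out <- deSolve::lsoda(y = y0, times = t_int, func = "ikk_derivs",
                          parms = parms, dllname = "ikkdelay",
                          initfunc = "ikk_initmod",
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (any(!is.finite(out)) || nrow(out) < length(t_int)) {
      stop("integration failed for variant '", variant,
           "' (non-finite state or premature solver stop)", call. = FALSE)
    }
    if (post[1] > onset) out <- out[-1, , drop = FALSE]
    sol_post <- out
  }
  sol <- rbind(sol_pre, sol_post)
  traj <- as.data.frame(sol)
  names(traj)[1] <- "time"

  resid <- abs(traj$IKK + traj$IKKp - 1)
  if (variant == "traf") {
    resid <- pmax(resid, abs(traj$T + traj$Tu - 1))
  } else if (variant == "double_phos") {
    resid <- pmax(resid, abs(traj$Y + traj$Yp + traj$Ypp - 1))
  } else if (variant == "irreversible_inhibitor") {
    resid <- pmax(resid, abs(traj$I - (traj$X + traj$Xa + I0 - 1)))
  }

  sc <- scale_for_dose(obs, protocol$il_dose)
  traj$ikkp_obs <- traj$IKKp * sc
  structure(traj,
            class = c("ikk_trajectory", "data.frame"),
            variant = variant, protocol = protocol, obs = obs,
            scale = sc, conservation_residuals = resid)
}

#' Maximum conservation violation of a trajectory
#' @param traj An `ikk_trajectory`.
#' @return Largest absolute conservation residual over all output times.
#' @export
conservation_residual <- function(traj) {
  max(attr(traj, "conservation_residuals"))
}

#' Closed-form receptor complex time course
#'
#' For a constant IL-1 input the receptor subsystem is linear and ILRc(t)
#' has the two-exponential solution
#' `(a/(k_i - a)) (exp(-a t) - exp(-k_i t))` with `a = k_a * il`,
#' degenerating to `a t exp(-a t)` when `a = k_i`. Used as an independent
#' oracle for the numerical integrator.
#'
#' @param t Time(s) in seconds (>= 0).
#' @param il IL-1 concentration in nM (>= 0).
#' @param k_a Association rate (nM^-1 s^-1).
#' @param k_i Receptor-complex inactivation rate (s^-1).
#' @return ILRc at the requested times.
#' @export
ilrc_closed_form <- function(t, il, k_a, k_i) {
  if (any(t < 0) || il < 0 || k_a < 0 || k_i < 0) {
    stop("ilrc_closed_form requires non-negative arguments", call. = FALSE)
  }
  a <- k_a * il
  if (a == 0) return(rep(0, length(t)))
  if (abs(a - k_i) < 1e-12 * max(a, k_i)) {
    a * t * exp(-a * t)
  } else {
    (a / (k_i - a)) * (exp(-a * t) - exp(-k_i * t))
  }
}

traj_signal <- function(traj, observed) {
  if (observed) traj$ikkp_obs else traj$IKKp
}

#' Peak IKKp amplitude of a trajectory
#'
#' @param traj An `ikk_trajectory`.
#' @param observed Use the scaled observable instead of latent IKKp.
#' @param refine Refine the grid maximum by local quadratic interpolation
#'   (used by the sensitivity analysis, where a grid-locked peak location
#'   would corrupt finite differences).
#' @return Maximum IKKp (or IKKp_obs) over the trajectory grid.
#' @export
peak_amplitude <- function(traj, observed = FALSE, refine = FALSE) {
  if (is.null(traj) || nrow(traj) == 0L) {
    stop("empty trajectory", call. = FALSE)
  }
  x <- traj_signal(traj, observed)
  i <- which.max(x)
  if (!refine || i == 1L || i == length(x)) return(x[i])
  # quadratic through the three points around the grid maximum
  t3 <- traj$time[(i - 1):(i + 1)]
  x3 <- x[(i - 1):(i + 1)]
  d1 <- (x3[3] - x3[1]) / (t3[3] - t3[1])
  d2 <- (x3[3] - 2 * x3[2] + x3[1]) / ((t3[2] - t3[1]) * (t3[3] - t3[2]))
  if (d2 >= 0) return(x[i])
  dt <- -d1 / d2
  x3[2] + d1 * dt + 0.5 * d2 * dt^2
}

#' Time-averaged IKKp over an observation horizon
#'
#' Trapezoidal mean of IKKp (or the observable) over `[0, horizon]`;
#' the default horizon is 7200 s, the longest observed period (120 min).
#'
#' @param traj An `ikk_trajectory`.
#' @param horizon Averaging horizon in seconds.
#' @param observed Use the scaled observable instead of latent IKKp.
#' @return Mean concentration over the horizon.
#' @export
mean_ikkp <- function(traj, horizon = 7200, observed = FALSE) {
  if (is.null(traj) || nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  tt <- traj$time
  if (horizon > max(tt) + 1e-9) {
    stop("horizon exceeds the simulated time span", call. = FALSE)
  }
  x <- traj_signal(traj, observed)
  keep <- tt <= horizon
  t_k <- tt[keep]
  x_k <- x[keep]
  if (max(t_k) < horizon) {  # interpolate the endpoint onto the horizon
    xe <- stats::approx(tt, x, xout = horizon)$y
    t_k <- c(t_k, horizon)
    x_k <- c(x_k, xe)
  }
  sum(diff(t_k) * (utils::head(x_k, -1) + utils::tail(x_k, -1)) / 2) / horizon
}

#' Time to half-maximal IKKp
#'
#' First time at which IKKp crosses half its peak value (linear
#' interpolation between grid points); quantifies the activation delay.
#'
#' @param traj An `ikk_trajectory`.
#' @param observed Use the scaled observable instead of latent IKKp.
#' @return Time in seconds.
#' @export
time_to_half_max <- function(traj, observed = FALSE) {
  if (is.null(traj) || nrow(traj) == 0L) stop("empty trajectory", call. = FALSE)
  x <- traj_signal(traj, observed)
  peak <- max(x)
  if (peak <= 0) {
    stop("trajectory never rises above zero; half-maximum time undefined",
         call. = FALSE)
  }
  half <- peak / 2
  i <- which(x >= half)[1]
  if (i == 1L) return(traj$time[1])
  t0 <- traj$time[i - 1]; t1 <- traj$time[i]
  x0 <- x[i - 1]; x1 <- x[i]
  t0 + (half - x0) / (x1 - x0) * (t1 - t0)
}

#' Export a trajectory as tidy CSV
#'
#' @param traj An `ikk_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- as.data.frame(traj)
  names(df)[names(df) == "time"] <- "time_s"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
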