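# Synthetic western-blot-style datasets: the measurement structure the
# fitting stage assumes, generated from a known model variant so that
# recovery, identifiability and discrimination studies have a ground truth.

#' Multiplicative blot-noise model
#'
#' Band densitometry noise is modelled as multiplicative Gaussian with
#' coefficient of variation `cv`; reported standard deviations are floored
#' at `sigma_floor` (in observed units) so unstimulated (zero-signal)
#' points do not get infinite weight.
#'
#' @param cv Coefficient of variation (>= 0), default 0.15.
#' @param sigma_floor Minimum reported standard deviation (> 0), default 0.05.
#' @return Object of class `ikk_noise`.
#' @export
noise_model <- function(cv = 0.15, sigma_floor = 0.05) {
  stopifnot(cv >= 0, sigma_floor > 0)
  structure(list(cv = cv, sigma_floor = sigma_floor), class = "ikk_noise")
}

#' Default four-condition measurement design
#'
#' Two IL-1 doses (0.588 and 0.029 nM, i.e. 10 and 0.5 ng/ml) each with and
#' without UVB co-irradiation; base sampling at 0, 5, 15, 30, 60, 90 and
#' 120 min with three blot replicates, plus two extra replicates at 2.5,
#' 10, 20 and 25 min for the low-dose condition without UVB (the early
#' window where the delay is resolved).
#'
#' @param high_dose,low_dose IL-1 doses in nM.
#' @return Data frame with columns `condition_id`, `il_nM`, `uv`,
#'   `time_min`, `replicate` — a design skeleton for [generate_dataset()].
#' @export
default_design <- function(high_dose = 0.588, low_dose = 0.029) {
  stopifnot(high_dose > low_dose, low_dose > 0)
  base_times <- c(0, 5, 15, 30, 60, 90, 120)
  extra_times <- c(2.5, 10, 20, 25)
  conds <- data.frame(
    condition_id = c("high_uv0", "high_uv1", "low_uv0", "low_uv1"),
    il_nM = c(high_dose, high_dose, low_dose, low_dose),
    uv = c(0, 1, 0, 1)
  )
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    d <- expand.grid(time_min = base_times, replicate = 1:3)
    cbind(conds[rep(i, nrow(d)), ], d, row.names = NULL)
  })
  extra <- cbind(conds[rep(3, length(extra_times) * 2), ],
                 expand.grid(time_min = extra_times, replicate = 4:5),
                 row.names = NULL)
  out <- rbind(do.call(rbind, rows), extra)
  out <- out[order(out$condition_id, out$time_min, out$replicate), ]
  rownames(out) <- NULL
  out
}

# evaluate local expr with a private, restored RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

new_dataset <- function(records, dose_threshold = 0.1, truth = NULL) {
  req <- c("condition_id", "il_nM", "uv", "time_min", "y", "sigma", "replicate")
  missing <- setdiff(req, names(records))
  if (length(missing) > 0) {
    stop("dataset records lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!(records$sigma > 0))
  if (length(bad) > 0) {
    stop("non-positive sigma in record row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(records$time_min < 0)
  if (length(bad) > 0) {
    stop("negative time in record row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  records$time_s <- records$time_min * 60
  conditions <- unique(records[, c("condition_id", "il_nM", "uv")])
  rownames(conditions) <- NULL
  structure(list(records = records, conditions = conditions,
                 dose_threshold = dose_threshold, truth = truth),
            class = "ikk_dataset")
}

#' @export
print.ikk_dataset <- function(x, ...) {
  cat(sprintf("ikk_dataset: %d records in %d conditions\n",
              nrow(x$records), nrow(x$conditions)))
  print(x$conditions)
  invisible(x)
}

condition_protocols <- function(dataset) {
  lapply(seq_len(nrow(dataset$conditions)), function(i) {
    stimulus_protocol(dataset$conditions$il_nM[i], dataset$conditions$uv[i])
  })
}

#' Generate a synthetic western-blot dataset
#'
#' Simulates the chosen variant for every condition of the design, scales
#' IKKp by the per-dose observation factor and applies multiplicative
#' Gaussian noise: `y = scale * IKKp * (1 + e)`, `e ~ N(0, cv^2)` i.i.d.;
#' the reported standard deviation is `max(cv * scale * IKKp, sigma_floor)`.
#'
#' @param variant Generating model variant.
#' @param params Named ground-truth parameter vector.
#' @param obs Ground-truth [observation_parameters()].
#' @param design Design skeleton, as from [default_design()].
#' @param noise An [noise_model()].
#' @param seed Integer seed; the generator is reproducible per seed and
#'   leaves the global RNG stream untouched.
#' @return An `ikk_dataset`; its `truth` element records the generating
#'   variant, parameters, observation scales, noise and seed.
#' @export
generate_dataset <- function(variant = "traf",
                             params = synthetic_truth()$parameters,
                             obs = synthetic_truth()$observation,
                             design = default_design(),
                             noise = noise_model(),
                             seed = 1) {
  variant <- match_variant(variant)
  stopifnot(inherits(noise, "ikk_noise"))
  conds <- unique(design[, c("condition_id", "il_nM", "uv")])
  records <- design
  records$y <- NA_real_
  records$sigma <- NA_real_
  for (i in seq_len(nrow(conds))) {
    sel <- design$condition_id == conds$condition_id[i]
    t_s <- design$time_min[sel] * 60
    grid <- sort(unique(c(0, t_s)))
    proto <- stimulus_protocol(conds$il_nM[i], conds$uv[i])
    traj <- simulate_model(variant, params, proto, obs = obs, times = grid)
    pred <- traj$ikkp_obs[match(t_s, traj$time)]
    records$y[sel] <- pred
    records$sigma[sel] <- pmax(noise$cv * pred, noise$sigma_floor)
  }
  eps <- with_seed(seed, rnorm(nrow(records), mean = 0, sd = noise$cv))
  records$y <- records$y * (1 + eps)
  truth <- list(variant = variant, parameters = params, observation = obs,
                noise = noise, seed = seed)
  new_dataset(records, dose_threshold = obs$dose_threshold, truth = truth)
}

#' Check that the latent low-dose amplitude is below the high-dose one
#'
#' Removes the per-dose observation scale factors from the observed
#' maxima and tests the strict inequality max(low) < max(high) — the
#' qualitative feature (lower maximal phosphorylation at 0.5 ng/ml than at
#' 10 ng/ml IL-1) that motivates separate per-dose scaling.
#'
#' @param dataset An `ikk_dataset` containing both dose levels.
#' @param obs Observation scales used to de-scale; defaults to the
#'   dataset's generating truth.
#' @return `TRUE` or `FALSE`.
#' @export
low_dose_amplitude_check <- function(dataset, obs = dataset$truth$observation) {
  stopifnot(inherits(dataset, "ikk_dataset"))
  if (is.null(obs)) {
    stop("observation scales required to de-scale the two dose levels",
         call. = FALSE)
  }
  rec <- dataset$records
  is_high <- rec$il_nM >= obs$dose_threshold
  if (!any(is_high) || all(is_high)) {
    stop("dataset must contain both dose levels", call. = FALSE)
  }
  max_high <- max(rec$y[is_high]) / obs$scale_high
  max_low <- max(rec$y[!is_high]) / obs$scale_low
  max_low < max_high
}
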