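# Figure-style panels: observed blot intensities and model curves in a
# dose x UVB grid (rows = IL-1 dose level, columns = with/without UVB).

#' Plot a dataset with optional fitted model curves
#'
#' Four-panel layout mirroring the experimental design: points with
#' +/- sigma error bars per condition; if a fit is supplied, the
#' corresponding simulated observable is overlaid.
#'
#' @param dataset An `ikk_dataset`.
#' @param fit Optional `ikk_fit` whose variant and parameters are
#'   simulated over each condition.
#' @return A ggplot object.
#' @export
plot_dataset <- function(dataset, fit = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_dataset requires the ggplot2 package", call. = FALSE)
  }
  stopifnot(inherits(dataset, "ikk_dataset"))
  rec <- dataset$records
  rec$dose <- ifelse(rec$il_nM >= dataset$dose_threshold,
                     "high IL-1", "low IL-1")
  rec$uvlab <- ifelse(rec$uv > 0, "+ UVB", "- UVB")
  p <- ggplot2::ggplot(rec, ggplot2::aes(x = time_min, y = y)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = y - sigma, ymax = y + sigma),
                           width = 2, colour = "grey50") +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_grid(dose ~ uvlab) +
    ggplot2::labs(x = "time (min)", y = "IKKp (blot intensity, a.u.)") +
    ggplot2::theme_bw()
  if (!is.null(fit)) {
    obs <- theta_observation(fit$theta, dataset$dose_threshold)
    curves <- do.call(rbind, lapply(seq_len(nrow(dataset$conditions)),
      function(i) {
        ci <- dataset$conditions[i, ]
        traj <- simulate_model(fit$variant, fit$theta,
                               stimulus_protocol(ci$il_nM, ci$uv),
                               obs = obs, times = seq(0, 7200, by = 30))
        data.frame(time_min = traj$time / 60, y = traj$ikkp_obs,
                   dose = ifelse(ci$il_nM >= dataset$dose_threshold,
                                 "high IL-1", "low IL-1"),
                   uvlab = ifelse(ci$uv > 0, "+ UVB", "- UVB"))
      }))
    p <- p + ggplot2::geom_line(data = curves, colour = "#c0392b")
  }
  p
}

#' Plot a dose-dependent sensitivity sweep
#'
#' Line plot of relative sensitivities against IL-1 dose (log scale),
#' one line per parameter.
#'
#' @param sweep Output of [dose_sweep()].
#' @return A ggplot object.
#' @export
plot_sensitivity <- function(sweep) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sensitivity requires the ggplot2 package", call. = FALSE)
  }
  ggplot2::ggplot(sweep, ggplot2::aes(x = il_dose, y = s,
                                      colour = parameter)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "IL-1 dose (nM)", y = "relative sensitivity s") +
    ggplot2::theme_bw()
}
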