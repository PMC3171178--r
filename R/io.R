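# Dataset I/O: tidy CSV records (times in minutes, matching how blot time
# courses are reported) plus an optional YAML manifest carrying the
# generating seed, noise model and ground truth for recovery studies.

.DATASET_COLUMNS <- c("condition_id", "il_nM", "uv", "time_min", "y",
                      "sigma", "replicate")

manifest_path <- function(path) paste0(path, ".manifest.yaml")

#' Write a dataset to CSV (plus manifest)
#'
#' @param dataset An `ikk_dataset`.
#' @param path Output CSV path; if the dataset carries generating truth, a
#'   YAML manifest is written next to it (`<path>.manifest.yaml`).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "ikk_dataset"))
  write.csv(dataset$records[, .DATASET_COLUMNS], path, row.names = FALSE)
  if (!is.null(dataset$truth)) {
    tr <- dataset$truth
    yaml::write_yaml(list(
      variant = tr$variant,
      seed = tr$seed,
      noise = list(cv = tr$noise$cv, sigma_floor = tr$noise$sigma_floor),
      parameters = as.list(tr$parameters),
      observation = list(scale_high = tr$observation$scale_high,
                         scale_low = tr$observation$scale_low,
                         dose_threshold = tr$observation$dose_threshold)
    ), manifest_path(path))
  }
  invisible(path)
}

#' Read a dataset from CSV
#'
#' Validates the required columns and per-row constraints (positive
#' standard deviations, non-negative times), converts times from minutes
#' to seconds, and reattaches the generating truth from a manifest file
#' if one is present.
#'
#' @param path CSV path with columns `condition_id`, `il_nM`, `uv`,
#'   `time_min`, `y`, `sigma`, `replicate`.
#' @param dose_threshold Dose (nM) separating the high and low scale level.
#' @return An `ikk_dataset`.
#' @export
read_dataset <- function(path, dose_threshold = 0.1) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  rec <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.DATASET_COLUMNS, names(rec))
  if (length(missing) > 0) {
    stop("dataset file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!all(rec$uv %in% c(0, 1))) {
    stop("uv column must be 0 or 1 (rows ",
         paste(which(!rec$uv %in% c(0, 1)), collapse = ", "), ")",
         call. = FALSE)
  }
  truth <- NULL
  mp <- manifest_path(path)
  if (file.exists(mp)) {
    m <- yaml::read_yaml(mp)
    truth <- list(variant = m$variant, seed = m$seed,
                  parameters = unlist(m$parameters),
                  noise = noise_model(m$noise$cv, m$noise$sigma_floor),
                  observation = do.call(observation_parameters,
                                        m$observation))
  }
  new_dataset(rec, dose_threshold = dose_threshold, truth = truth)
}

#' Number of measurement records in a dataset
#' @param dataset An `ikk_dataset`.
#' @return Integer record count (the `N` of the AICc computation).
#' @export
n_records <- function(dataset) {
  stopifnot(inherits(dataset, "ikk_dataset"))
  nrow(dataset$records)
}
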