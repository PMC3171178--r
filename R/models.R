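# Model catalogue: the core IKKbeta phosphorylation model and its three
# delay-generating extensions. All concentrations are normalized so that
# non-zero initial values are 1 (except the inhibitor pool I_0); rate
# constants are in s^-1 except k_a (nM^-1 s^-1).

.VARIANTS <- c("original", "traf", "double_phos", "irreversible_inhibitor")

.CORE_RATES <- c("k_a", "k_i", "k_p", "k_dp", "k_uv")

.EXT_RATES <- list(
  original               = character(0),
  traf                   = c("k_aut", "k_du"),
  double_phos            = c("k_ph1", "k_ph2", "k_dph"),
  irreversible_inhibitor = c("k_xa", "k_inh", "I_0")
)

# which species acts as the effective IKKbeta kinase [kin]
.KIN_SOURCE <- c(original = "ILRc", traf = "Tu", double_phos = "Ypp",
                 irreversible_inhibitor = "Xa")

#' Model variant catalogue
#'
#' The four competing mechanisms for IKKbeta phosphorylation dynamics:
#' the core receptor-driven model (`"original"`, the phosphorylating
#' activity is the receptor complex ILRc), a positive-feedback
#' auto-ubiquitination extension (`"traf"`), a sequential
#' double-modification extension (`"double_phos"`), and an
#' irreversible-inhibitor extension (`"irreversible_inhibitor"`).
#'
#' @return Character vector of the four variant tags.
#' @export
model_variants <- function() .VARIANTS

match_variant <- function(variant) {
  if (length(variant) != 1L || !variant %in% .VARIANTS) {
    stop("unknown model variant: ", paste(variant, collapse = ", "),
         " (expected one of ", paste(.VARIANTS, collapse = ", "), ")",
         call. = FALSE)
  }
  variant
}

variant_code <- function(variant) match(match_variant(variant), .VARIANTS) - 1L

#' Kinetic parameter names of a model variant
#'
#' @param variant One of [model_variants()].
#' @return Character vector: the five core rates (`k_a`, `k_i`, `k_p`,
#'   `k_dp`, `k_uv`) followed by the extension parameters, if any.
#' @export
variant_parameters <- function(variant) {
  variant <- match_variant(variant)
  c(.CORE_RATES, .EXT_RATES[[variant]])
}

kin_source <- function(variant) .KIN_SOURCE[[match_variant(variant)]]

#' Stimulus protocol
#'
#' Describes one stimulation condition: an IL-1 concentration step and an
#' optional UVB step (300 J/m^2, encoded as a unit input), both switched on
#' at `onset_time` and held afterwards.
#'
#' @param il_dose IL-1 concentration after onset, in nM (>= 0).
#' @param uv_on 0 or 1; whether UVB irradiation is applied.
#' @param onset_time Stimulation onset in seconds (default 0).
#' @return An object of class `ikk_protocol`.
#' @export
stimulus_protocol <- function(il_dose, uv_on = 0, onset_time = 0) {
  stopifnot(is.numeric(il_dose), length(il_dose) == 1L, is.finite(il_dose))
  if (il_dose < 0) stop("il_dose must be >= 0", call. = FALSE)
  if (!uv_on %in% c(0, 1)) stop("uv_on must be 0 or 1", call. = FALSE)
  if (onset_time < 0) stop("onset_time must be >= 0", call. = FALSE)
  structure(list(il_dose = as.numeric(il_dose), uv_on = as.numeric(uv_on),
                 onset_time = as.numeric(onset_time)),
            class = "ikk_protocol")
}

#' @export
print.ikk_protocol <- function(x, ...) {
  cat(sprintf("Stimulus: IL-1 %.3g nM, UVB %s, onset %g s\n",
              x$il_dose, if (x$uv_on > 0) "on" else "off", x$onset_time))
  invisible(x)
}

#' Initial conditions of a model variant
#'
#' Unstimulated initial state: free receptor and phosphatase at 1, all
#' activated species at 0; the inhibitor variant additionally starts with
#' its target pool X at 1 and the inhibitor at `I0`.
#'
#' @param variant One of [model_variants()].
#' @param I0 Initial inhibitor level (irreversible-inhibitor variant only).
#' @return Named numeric vector of the stored (non-derived) species.
#' @export
initial_state <- function(variant, I0 = 1) {
  variant <- match_variant(variant)
  if (I0 < 0) stop("I0 must be >= 0", call. = FALSE)
  core <- c(ILR = 1, ILRc = 0, IKKp = 0, PP2A = 1)
  switch(variant,
    original               = core,
    traf                   = c(core, Tu = 0),
    double_phos            = c(core, Yp = 0, Ypp = 0),
    irreversible_inhibitor = c(core, X = 1, Xa = 0, I = as.numeric(I0))
  )
}

# initial state augmented with the conservation partners (IKK, T, Y) that the
# integrator carries redundantly so conservation drift can be monitored
initial_state_aug <- function(variant, I0 = 1) {
  variant <- match_variant(variant)
  core <- c(ILR = 1, ILRc = 0, IKKp = 0, PP2A = 1, IKK = 1)
  switch(variant,
    original               = core,
    traf                   = c(core, Tu = 0, T = 1),
    double_phos            = c(core, Yp = 0, Ypp = 0, Y = 1),
    irreversible_inhibitor = c(core, X = 1, Xa = 0, I = as.numeric(I0))
  )
}

check_params <- function(variant, params) {
  need <- variant_parameters(variant)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0) {
    stop("missing parameter(s) for variant '", variant, "': ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(params[need])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all kinetic parameters must be finite and >= 0", call. = FALSE)
  }
  vals
}

#' Time derivative of the model state
#'
#' Evaluates the right-hand side of the chosen variant at one state and time.
#' Derived species follow from mass conservation: IKK = 1 - IKKp,
#' T = 1 - Tu, Y = 1 - Yp - Ypp.
#'
#' @param variant One of [model_variants()].
#' @param state Named state vector as returned by [initial_state()].
#' @param t Time in seconds.
#' @param params Named parameter vector covering [variant_parameters()].
#' @param protocol An [stimulus_protocol()].
#' @return Named derivative vector matching `state`.
#' @export
model_rhs <- function(variant, state, t, params, protocol) {
  variant <- match_variant(variant)
  pv <- check_params(variant, params)
  if (any(!is.finite(state))) {
    stop("non-finite model state passed to model_rhs", call. = FALSE)
  }
  il <- if (t >= protocol$onset_time) protocol$il_dose else 0
  uv <- if (t >= protocol$onset_time) protocol$uv_on else 0
  s <- as.list(state)
  d <- numeric(length(state))
  names(d) <- names(state)
  d["ILR"]  <- -pv["k_a"] * il * s$ILR
  d["ILRc"] <- pv["k_a"] * il * s$ILR - pv["k_i"] * s$ILRc
  d["PP2A"] <- -pv["k_uv"] * uv * s$PP2A
  kin <- switch(variant,
    original               = s$ILRc,
    traf                   = s$Tu,
    double_phos            = s$Ypp,
    irreversible_inhibitor = s$Xa
  )
  d["IKKp"] <- pv["k_p"] * kin * (1 - s$IKKp) - pv["k_dp"] * s$PP2A * s$IKKp
  if (variant == "traf") {
    d["Tu"] <- pv["k_aut"] * (s$ILRc + s$Tu) * (1 - s$Tu) - pv["k_du"] * s$Tu
  } else if (variant == "double_phos") {
    Y <- 1 - s$Yp - s$Ypp
    d["Yp"]  <- pv["k_ph1"] * s$ILRc * Y - pv["k_ph2"] * s$ILRc * s$Yp
    d["Ypp"] <- pv["k_ph2"] * s$ILRc * s$Yp - pv["k_dph"] * s$Ypp
  } else if (variant == "irreversible_inhibitor") {
    d["X"]  <- -pv["k_xa"] * s$ILRc * s$X
    d["Xa"] <- pv["k_xa"] * s$ILRc * s$X - pv["k_inh"] * s$Xa * s$I
    d["I"]  <- -pv["k_inh"] * s$Xa * s$I
  }
  d
}

#' Number of fitted parameters of a variant
#'
#' Core kinetic rates (5) plus extension parameters (2 for the
#' positive-feedback extension, 3 each for double phosphorylation and the
#' irreversible inhibitor), plus any fitted observation scale factors.
#'
#' @param variant One of [model_variants()].
#' @param n_scales Number of fitted western-blot scale factors to add.
#' @return Integer parameter count.
#' @export
count_parameters <- function(variant, n_scales = 0) {
  length(variant_parameters(variant)) + as.integer(n_scales)
}

#' Packaged kinetic constants
#'
#' Reads the constants file shipped with the package: the reported
#' downstream rates (k_p, k_dp, k_uv) for each fitted variant, and the
#' ground-truth parameter set used by the synthetic-data generator.
#'
#' @return Nested list mirroring the JSON constants file.
#' @export
kinetic_constants <- function() {
  path <- system.file("extdata", "kinetic_constants.json", package = "ikkdelay",
                      mustWork = TRUE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Default kinetic parameters for a variant
#'
#' Downstream rates (`k_p`, `k_dp`, `k_uv`) come from the packaged
#' per-variant constants; receptor and extension rates default to the
#' synthetic ground-truth values (or order-of-magnitude analogues for the
#' extensions the generator does not use).
#'
#' @param variant One of [model_variants()].
#' @return Named numeric parameter vector for [variant_parameters()].
#' @export
default_parameters <- function(variant) {
  variant <- match_variant(variant)
  kc <- kinetic_constants()
  down <- unlist(kc$downstream_rates[[variant]])
  truth <- unlist(kc$synthetic_ground_truth$parameters)
  ext <- switch(variant,
    original               = numeric(0),
    traf                   = truth[c("k_aut", "k_du")],
    double_phos            = c(k_ph1 = 2e-3, k_ph2 = 2e-3, k_dph = 2e-3),
    irreversible_inhibitor = c(k_xa = 2e-3, k_inh = 2e-3, I_0 = 2)
  )
  out <- c(truth[c("k_a", "k_i")], down[c("k_p", "k_dp", "k_uv")], ext)
  out[variant_parameters(variant)]
}

#' Ground truth of the synthetic-data generator
#'
#' @return List with elements `variant`, `parameters` (named vector) and
#'   `observation` (scale factors), as stored in the packaged constants.
#' @export
synthetic_truth <- function() {
  kc <- kinetic_constants()$synthetic_ground_truth
  list(variant = kc$variant,
       parameters = unlist(kc$parameters),
       observation = do.call(observation_parameters, as.list(kc$observation)))
}

#' Convert an IL-1 mass concentration to molarity
#'
#' @param ngml Concentration in ng/ml.
#' @param mw_kda Molecular weight in kDa (default 17, mature IL-1).
#' @return Concentration in nM.
#' @examples
#' il1_ngml_to_nM(10)   # 0.588 nM
#' il1_ngml_to_nM(0.5)  # 0.029 nM
#' @export
il1_ngml_to_nM <- function(ngml, mw_kda = 17) {
  stopifnot(ngml >= 0, mw_kda > 0)
  ngml / mw_kda
}
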