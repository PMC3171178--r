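# Independent oracle for relative sensitivities of the TRAF variant:
# forward sensitivity equations (hand-derived Jacobians) integrated jointly
# with the states. Characteristic derivatives follow from the envelope
# theorem (peak) or by averaging the IKKp sensitivity (mean).

traf_forward_sensitivity <- function(theta, protocol,
                                     characteristic = c("peak", "mean"),
                                     param, horizon = 7200) {
  characteristic <- match.arg(characteristic)
  pn <- c("k_a", "k_i", "k_p", "k_dp", "k_uv", "k_aut", "k_du")
  np <- length(pn)
  il <- protocol$il_dose
  uv <- protocol$uv_on
  rhs <- function(t, y, p) {
    ILR <- y[1]; ILRc <- y[2]; IKKp <- y[3]; PP2A <- y[4]; Tu <- y[5]
    S <- matrix(y[-(1:5)], nrow = 5)  # sensitivities d(state)/d(param)
    with(as.list(p), {
      f <- c(-k_a * il * ILR,
             k_a * il * ILR - k_i * ILRc,
             k_p * Tu * (1 - IKKp) - k_dp * PP2A * IKKp,
             -k_uv * uv * PP2A,
             k_aut * (ILRc + Tu) * (1 - Tu) - k_du * Tu)
      J <- matrix(0, 5, 5)
      J[1, 1] <- -k_a * il
      J[2, 1] <- k_a * il; J[2, 2] <- -k_i
      J[3, 3] <- -k_p * Tu - k_dp * PP2A
      J[3, 4] <- -k_dp * IKKp
      J[3, 5] <- k_p * (1 - IKKp)
      J[4, 4] <- -k_uv * uv
      J[5, 2] <- k_aut * (1 - Tu)
      J[5, 5] <- k_aut * (1 - Tu) - k_aut * (ILRc + Tu) - k_du
      Fp <- matrix(0, 5, np, dimnames = list(NULL, pn))
      Fp[1, "k_a"] <- -il * ILR
      Fp[2, "k_a"] <- il * ILR
      Fp[2, "k_i"] <- -ILRc
      Fp[3, "k_p"] <- Tu * (1 - IKKp)
      Fp[3, "k_dp"] <- -PP2A * IKKp
      Fp[4, "k_uv"] <- -uv * PP2A
      Fp[5, "k_aut"] <- (ILRc + Tu) * (1 - Tu)
      Fp[5, "k_du"] <- -Tu
      dS <- J %*% S + Fp
      list(c(f, as.vector(dS)))
    })
  }
  y0 <- c(1, 0, 0, 1, 0, rep(0, 5 * np))
  p <- theta[pn]
  out <- deSolve::lsoda(y0, seq(0, horizon, by = 1), rhs, p,
                        rtol = 1e-10, atol = 1e-12)
  ikkp <- out[, 4]
  s_ikkp <- out[, 5 + 5 * (match(param, pn) - 1) + 3 + 1]
  if (characteristic == "peak") {
    i <- which.max(ikkp)
    x <- ikkp[i]
    dx <- s_ikkp[i]
  } else {
    tt <- out[, 1]
    trap <- function(v) sum(diff(tt) * (head(v, -1) + tail(v, -1)) / 2)
    x <- trap(ikkp) / horizon
    dx <- trap(s_ikkp) / horizon
  }
  (theta[[param]] / x) * dx
}
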