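# State ordering is fixed; the compiled right-hand side and every consumer
# of a state vector rely on it.
.rci_state_names <- c(
  "N_st_ud", "M_st_ud", "M_st_d", "F_st_ud", "F_st_d", "L_st_ud", "L_st_d",
  "Dam_tb", "Deb_tb", "N_tb", "M1_tb", "M2_tb", "F_tb", "L1_tb", "L2_tb",
  "P_tb"
)

#' State variable names
#'
#' The 16 state variables in canonical order: resting/undamaged and damaged
#' populations in the surrounding irradiated tissue (`*_st_*`), then damage,
#' debris, activated cells and pathogen at the thermal burn (`*_tb`).
#'
#' @return character vector of length 16.
#' @export
rci_state_names <- function() .rci_state_names

#' Exposure scenario
#'
#' A thermal fluence (J/cm^2) and/or a prompt locally absorbed radiation
#' dose (Gy). `DR = 0` encodes burn-only scenarios. As a convenience the
#' burn may be given as a named severity instead of a fluence:
#' `"superficial"` and `"superficial-partial"` map directly to initial
#' damage/debris levels 0.1 and 0.9, bypassing the fluence map.
#'
#' @param f thermal fluence in J/cm^2 (>= 0), or `NULL` when `severity`
#'   is given.
#' @param DR prompt radiation absorbed dose in Gy (>= 0).
#' @param severity optional severity name, `"superficial"` or
#'   `"superficial-partial"`.
#' @return an `rci_exposure` list with fields `f`, `DR`, `severity`.
#' @export
rci_exposure <- function(f = NULL, DR = 0, severity = NULL) {
  if (!is.null(severity)) {
    severity <- match.arg(severity, c("superficial", "superficial-partial"))
    if (!is.null(f))
      stop("give either a fluence or a severity name, not both",
           call. = FALSE)
  } else if (is.null(f)) {
    stop("an exposure needs a thermal fluence `f` or a `severity` name",
         call. = FALSE)
  }
  if (!is.null(f)) {
    stopifnot(is.numeric(f), length(f) == 1L, is.finite(f))
    if (f < 0) stop("thermal fluence must be non-negative", call. = FALSE)
  }
  stopifnot(is.numeric(DR), length(DR) == 1L, is.finite(DR))
  if (DR < 0) stop("radiation dose must be non-negative", call. = FALSE)
  structure(list(f = f, DR = DR, severity = severity),
            class = "rci_exposure")
}

#' Inhibitory saturation function
#'
#' `omega_i(X; (Y1, Y1inf), ...) = X / (1 + sum (Yk/Ykinf)^2)`: a flux `X`
#' divided down by the squared scaled levels of its inhibitors. With no
#' inhibitors the flux passes through unchanged.
#'
#' @param X non-negative level or flux.
#' @param inhibitors list of `c(Y, Yinf)` pairs (possibly empty); each
#'   `Yinf` must be strictly positive.
#' @return the inhibited value, `<= X`.
#' @export
inhibitory_omega <- function(X, inhibitors = list()) {
  stopifnot(is.numeric(X), length(X) == 1L)
  denom <- 1
  for (pair in inhibitors) {
    if (length(pair) != 2L)
      stop("each inhibitor must be a (level, saturation) pair", call. = FALSE)
    if (!is.finite(pair[[2]]) || pair[[2]] <= 0)
      stop("inhibitor saturation constants must be positive", call. = FALSE)
    denom <- denom + (pair[[1]] / pair[[2]])^2
  }
  X / denom
}

#' Hill saturation function
#'
#' `omega_H(X, n, XH) = X^n / (XH^n + X^n)`, increasing in `X` from 0
#' towards 1, equal to 1/2 at `X = XH`.
#'
#' @param X non-negative level.
#' @param n Hill exponent, integer >= 1.
#' @param XH half-saturation constant, > 0.
#' @return fraction in `[0, 1)`.
#' @export
hill_omega <- function(X, n, XH) {
  stopifnot(is.numeric(X), is.numeric(n), is.numeric(XH))
  if (any(XH <= 0)) stop("Hill half-saturation must be positive", call. = FALSE)
  if (any(n < 1)) stop("Hill exponent must be >= 1", call. = FALSE)
  X^n / (XH^n + X^n)
}

#' Dose-dependent recovery of blood influx
#'
#' Microvascular damage from local irradiation transiently shuts down
#' extravasation from the bloodstream. The influx multiplier is 1 for an
#' unirradiated scenario and `1 - exp(-gamma * DR * t)` otherwise: zero at
#' the moment of exposure, recovering towards 1 with a dose-dependent rate.
#'
#' @param t time since exposure, hours (>= 0); vectorised.
#' @param DR radiation dose, Gy.
#' @param gamma recovery constant, per Gy-hour (> 0).
#' @return fraction in `[0, 1]`.
#' @export
dose_delay_v <- function(t, DR, gamma) {
  stopifnot(is.numeric(t), is.numeric(DR), length(DR) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (DR < 0) stop("radiation dose must be non-negative", call. = FALSE)
  if (gamma <= 0) stop("gamma must be positive", call. = FALSE)
  if (DR == 0) rep(1, length(t)) else 1 - exp(-gamma * DR * t)
}

# Validate & clip a state vector for use in the right-hand side.
# Phagocytosis and transition terms can numerically overshoot slightly
# below zero; levels are clipped at 0 before entering any flux.
.rci_state_clip <- function(state) {
  if (length(state) != 16L)
    stop("state vector must have 16 components", call. = FALSE)
  if (is.null(names(state))) names(state) <- .rci_state_names
  pmax(state[.rci_state_names], 0)
}

#' Instantaneous activation rates
#'
#' The five activation-rate expressions driving transitions from resting
#' populations in the surrounding tissue to activated populations at the
#' wound: neutrophils (`Rn`, driven by debris, pathogen and neutrophils,
#' inhibited by M2 macrophages and L2 lymphocytes), M1 macrophages (`Rm1`),
#' M2 macrophages (`Rm2`, inhibited by neutrophils, M1 and fibroblasts),
#' and pro-/anti-inflammatory lymphocytes (`Rl1`, `Rl2`).
#'
#' `Rm2` is returned unmodified; the additional inhibition of M2 activation
#' by damaged surrounding-tissue macrophages, applied only for doses of
#' 2 Gy and above, acts downstream where the activation flux is assembled
#' (see [rci_rhs()]).
#'
#' @param state named 16-component state vector.
#' @param params `rci_params` vector.
#' @param DR radiation dose in Gy (present for interface symmetry; the raw
#'   rates do not depend on it).
#' @return named numeric vector `c(Rn, Rm1, Rm2, Rl1, Rl2)`, all >= 0.
#' @export
activation_rates <- function(state, params, DR = 0) {
  p <- validate_params(params)
  y <- .rci_state_clip(state)
  inh_m2l2 <- 1 + (y[["M2_tb"]] / p[["M2_inf"]])^2 +
    (y[["L2_tb"]] / p[["L21_inf"]])^2
  Rn <- (p[["knd"]] * y[["Deb_tb"]] + p[["knp"]] * y[["P_tb"]] +
           p[["knn"]] * y[["N_tb"]]) / inh_m2l2
  Rm1 <- (p[["km1d"]] * y[["Deb_tb"]] + p[["km1p"]] * y[["P_tb"]] +
            p[["km1n"]] * y[["N_tb"]] + p[["km1m1"]] * y[["M1_tb"]] +
            p[["km1l1"]] * y[["L1_tb"]]) / inh_m2l2
  Rm2 <- (p[["km2m1"]] * y[["M1_tb"]] + p[["km2m2"]] * y[["M2_tb"]] +
            p[["km2l2"]] * y[["L2_tb"]]) /
    (1 + (y[["N_tb"]] / p[["N1_inf"]])^2 +
       (y[["M1_tb"]] / p[["M11_inf"]])^2 +
       (y[["F_tb"]] / p[["F_inf"]])^2)
  Rl1 <- (p[["kl1"]] * y[["M1_tb"]]) / (1 + (y[["L2_tb"]] / p[["L21_inf"]])^2)
  Rl2 <- (p[["kl2"]] * y[["M2_tb"]]) / (1 + (y[["F_tb"]] / p[["F_inf"]])^2)
  c(Rn = unname(Rn), Rm1 = unname(Rm1), Rm2 = unname(Rm2),
    Rl1 = unname(Rl1), Rl2 = unname(Rl2))
}

#' Right-hand side of the model ODE system
#'
#' Assembles all 16 derivatives term by term: collateral damage and debris
#' generation through steep (exponent 6) Hill functions of
#' lymphocyte-inhibited neutrophil and M1 levels; debris phagocytosis;
#' radiation-inhibited blood influx into the surrounding tissue via
#' [dose_delay_v()]; activation fluxes from [activation_rates()] with the
#' dose-conditional inhibition of M2 activation by damaged macrophages
#' (applied exactly when `DR >= 2` Gy); the neutrophil-mediated M1-to-M2
#' transition; fibroblast recruitment and inhibited proliferation; and
#' pathogen logistic growth minus background and cell-mediated clearance.
#'
#' State components are clipped at zero on entry (numerical overshoot
#' guard); a non-finite state yields an error, which the feasibility
#' pipeline records as an integration failure.
#'
#' @param t time in hours.
#' @param state named 16-component state vector.
#' @param params `rci_params` vector.
#' @param exposure an [rci_exposure()] (only its dose `DR` enters the
#'   right-hand side).
#' @return named numeric vector of the 16 derivatives (per hour).
#' @export
rci_rhs <- function(t, state, params, exposure) {
  if (any(!is.finite(state)))
    stop("non-finite state passed to rci_rhs", call. = FALSE)
  if (t < 0) stop("time must be non-negative", call. = FALSE)
  p <- validate_params(params)
  DR <- if (inherits(exposure, "rci_exposure")) exposure$DR else exposure
  y <- .rci_state_clip(state)
  n <- .rci_hill_n

  N_st <- y[["N_st_ud"]]; M_ud <- y[["M_st_ud"]]; M_d <- y[["M_st_d"]]
  F_ud <- y[["F_st_ud"]]; F_d <- y[["F_st_d"]]
  L_ud <- y[["L_st_ud"]]; L_d <- y[["L_st_d"]]
  Dam <- y[["Dam_tb"]]; Deb <- y[["Deb_tb"]]
  N <- y[["N_tb"]]; M1 <- y[["M1_tb"]]; M2 <- y[["M2_tb"]]
  Fb <- y[["F_tb"]]; L1 <- y[["L1_tb"]]; L2 <- y[["L2_tb"]]
  P <- y[["P_tb"]]

  R <- activation_rates(y, p, DR)
  ## dose-conditional inhibition of the M2 activation flux
  Rm2_eff <- if (DR >= 2) {
    R[["Rm2"]] / (1 + (M_d / p[["omega_m2"]])^2)
  } else R[["Rm2"]]

  ## collateral damage / debris generation (shared constants)
  gen_n <- p[["kdn"]] *
    hill_omega(N / (1 + (L2 / p[["L22_inf"]])^2), n, p[["N_H"]])
  gen_m1 <- p[["kdm1"]] *
    hill_omega(M1 / (1 + (L2 / p[["L22_inf"]])^2), n, p[["M1_H"]])

  res_core <- Dam / (1 + (Deb / p[["Deb_dam_inf"]])^2)
  dDam <- gen_n + gen_m1 - p[["rho_dam"]] * res_core -
    (Fb / (1 + (F_d / p[["omega_dam"]])^2)) * p[["kdf"]] * res_core

  deb_sat <- hill_omega(Deb, 1, p[["Deb_H"]])
  inh_n1 <- 1 + (N / p[["N1_inf"]])^2
  dDeb <- gen_n + gen_m1 -
    p[["kdnp"]] * N * deb_sat -
    p[["kdm1p"]] * (M1 / inh_n1) * deb_sat -
    p[["kdm2p"]] * (M2 / inh_n1) * deb_sat -
    p[["ddeb"]] * Deb

  dN_st <- dose_delay_v(t, DR, p[["gamma_n"]]) * p[["snr"]] * Dam -
    R[["Rn"]] * N_st - p[["dnr"]] * N_st
  m1_phag <- p[["knm1p"]] * N * (M1 / inh_n1)
  dN <- R[["Rn"]] * N_st - m1_phag -
    p[["knm2p"]] * N * (M2 / inh_n1) - p[["dn"]] * N

  dM_ud <- dose_delay_v(t, DR, p[["gamma_m"]]) * p[["smr"]] -
    R[["Rm1"]] * M_ud - Rm2_eff * M_ud - p[["dmr_ud"]] * M_ud
  dM_d <- -R[["Rm1"]] * M_d - Rm2_eff * M_d - p[["dmr_d"]] * M_d
  dM1 <- R[["Rm1"]] * (M_ud + M_d) - p[["theta_m1m2"]] * m1_phag -
    p[["dm1"]] * M1
  dM2 <- Rm2_eff * (M_ud + M_d) + p[["theta_m1m2"]] * m1_phag -
    p[["dm2"]] * M2

  dL_ud <- dose_delay_v(t, DR, p[["gamma_l"]]) * p[["slr"]] -
    R[["Rl1"]] * L_ud - R[["Rl2"]] * L_ud - p[["dlr_ud"]] * L_ud
  dL_d <- -R[["Rl1"]] * L_d - R[["Rl2"]] * L_d - p[["dlr_d"]] * L_d
  dL1 <- R[["Rl1"]] * (L_ud + L_d) - p[["dl"]] * L1
  dL2 <- R[["Rl2"]] * (L_ud + L_d) - p[["dl"]] * L2

  dF_ud <- dose_delay_v(t, DR, p[["gamma_f"]]) * p[["sf"]] -
    p[["ksttb_ud"]] * F_ud - p[["dfr_ud"]] * F_ud
  dF_d <- -p[["ksttb_d"]] * F_d - p[["dfr_d"]] * F_d
  dF <- (1 / (1 + (F_d / p[["omega_f"]])^2)) *
    (Fb / (1 + (N / p[["N2_inf"]])^2 + (M1 / p[["M12_inf"]])^2)) *
    (p[["kf"]] + p[["alpha_dam"]] * Dam + p[["alpha_m2"]] * M2) +
    p[["ksttb_ud"]] * F_ud + p[["ksttb_d"]] * F_d - p[["df"]] * Fb

  dP <- p[["kpg"]] * P * (1 - P / p[["P_inf"]]) -
    p[["kpb"]] * p[["sb"]] * P / (p[["mu_b"]] + p[["kbp"]] * P) -
    p[["kpn"]] * P * N -
    p[["kpm1"]] * P * (M1 / inh_n1) -
    p[["kpm2"]] * P * (M2 / inh_n1)

  out <- c(dN_st, dM_ud, dM_d, dF_ud, dF_d, dL_ud, dL_d,
           dDam, dDeb, dN, dM1, dM2, dF, dL1, dL2, dP)
  names(out) <- .rci_state_names
  out
}
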