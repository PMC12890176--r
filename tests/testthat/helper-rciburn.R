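# Shared fixtures: jittered parameter sets, random states, and an
# independent straight-line transcription of the model equations used as
# the oracle for the packaged right-hand side.

# Baseline multiplied by independent uniform factors; optionally filtered
# to sets with a stable healed state.
jittered_params <- function(seed, spread = 0.2, stable_only = FALSE) {
  set.seed(seed)
  repeat {
    p <- unclass(rci_default_params()) *
      stats::runif(length(rci_param_names()), 1 - spread, 1 + spread)
    p <- validate_params(p)
    if (!stable_only || healed_state_stable(p)) return(p)
  }
}

# Random non-negative state on plausible magnitudes.
random_state <- function(seed) {
  set.seed(seed)
  y <- stats::runif(16, 0, 1.2)
  names(y) <- rci_state_names()
  y
}

# Independent term-by-term oracle for the 16 derivatives, written as flat
# arithmetic with no shared helpers.
naive_rhs <- function(t, y, p, DR) {
  y <- pmax(y[rci_state_names()], 0)
  Nst <- y[["N_st_ud"]]; Mud <- y[["M_st_ud"]]; Md <- y[["M_st_d"]]
  Fud <- y[["F_st_ud"]]; Fd <- y[["F_st_d"]]
  Lud <- y[["L_st_ud"]]; Ld <- y[["L_st_d"]]
  Dam <- y[["Dam_tb"]]; Deb <- y[["Deb_tb"]]; N <- y[["N_tb"]]
  M1 <- y[["M1_tb"]]; M2 <- y[["M2_tb"]]; Fb <- y[["F_tb"]]
  L1 <- y[["L1_tb"]]; L2 <- y[["L2_tb"]]; P <- y[["P_tb"]]

  v <- function(g) if (DR == 0) 1 else 1 - exp(-g * DR * t)
  den_a <- 1 + (M2 / p[["M2_inf"]])^2 + (L2 / p[["L21_inf"]])^2
  Rn <- (p[["knd"]] * Deb + p[["knp"]] * P + p[["knn"]] * N) / den_a
  Rm1 <- (p[["km1d"]] * Deb + p[["km1p"]] * P + p[["km1n"]] * N +
            p[["km1m1"]] * M1 + p[["km1l1"]] * L1) / den_a
  Rm2 <- (p[["km2m1"]] * M1 + p[["km2m2"]] * M2 + p[["km2l2"]] * L2) /
    (1 + (N / p[["N1_inf"]])^2 + (M1 / p[["M11_inf"]])^2 +
       (Fb / p[["F_inf"]])^2)
  if (DR >= 2) Rm2e <- Rm2 / (1 + (Md / p[["omega_m2"]])^2) else Rm2e <- Rm2
  Rl1 <- p[["kl1"]] * M1 / (1 + (L2 / p[["L21_inf"]])^2)
  Rl2 <- p[["kl2"]] * M2 / (1 + (Fb / p[["F_inf"]])^2)

  xn <- N / (1 + (L2 / p[["L22_inf"]])^2)
  xm <- M1 / (1 + (L2 / p[["L22_inf"]])^2)
  gn <- p[["kdn"]] * xn^6 / (p[["N_H"]]^6 + xn^6)
  gm <- p[["kdm1"]] * xm^6 / (p[["M1_H"]]^6 + xm^6)
  rc <- Dam / (1 + (Deb / p[["Deb_dam_inf"]])^2)
  ds <- Deb / (p[["Deb_H"]] + Deb)
  in1 <- 1 + (N / p[["N1_inf"]])^2

  c(N_st_ud = v(p[["gamma_n"]]) * p[["snr"]] * Dam - Rn * Nst -
      p[["dnr"]] * Nst,
    M_st_ud = v(p[["gamma_m"]]) * p[["smr"]] - Rm1 * Mud - Rm2e * Mud -
      p[["dmr_ud"]] * Mud,
    M_st_d = -Rm1 * Md - Rm2e * Md - p[["dmr_d"]] * Md,
    F_st_ud = v(p[["gamma_f"]]) * p[["sf"]] - p[["ksttb_ud"]] * Fud -
      p[["dfr_ud"]] * Fud,
    F_st_d = -p[["ksttb_d"]] * Fd - p[["dfr_d"]] * Fd,
    L_st_ud = v(p[["gamma_l"]]) * p[["slr"]] - Rl1 * Lud - Rl2 * Lud -
      p[["dlr_ud"]] * Lud,
    L_st_d = -Rl1 * Ld - Rl2 * Ld - p[["dlr_d"]] * Ld,
    Dam_tb = gn + gm - p[["rho_dam"]] * rc -
      (Fb / (1 + (Fd / p[["omega_dam"]])^2)) * p[["kdf"]] * rc,
    Deb_tb = gn + gm - p[["kdnp"]] * N * ds -
      p[["kdm1p"]] * (M1 / in1) * ds - p[["kdm2p"]] * (M2 / in1) * ds -
      p[["ddeb"]] * Deb,
    N_tb = Rn * Nst - p[["knm1p"]] * N * (M1 / in1) -
      p[["knm2p"]] * N * (M2 / in1) - p[["dn"]] * N,
    M1_tb = Rm1 * (Mud + Md) -
      p[["theta_m1m2"]] * p[["knm1p"]] * N * (M1 / in1) - p[["dm1"]] * M1,
    M2_tb = Rm2e * (Mud + Md) +
      p[["theta_m1m2"]] * p[["knm1p"]] * N * (M1 / in1) - p[["dm2"]] * M2,
    F_tb = (1 / (1 + (Fd / p[["omega_f"]])^2)) *
      (Fb / (1 + (N / p[["N2_inf"]])^2 + (M1 / p[["M12_inf"]])^2)) *
      (p[["kf"]] + p[["alpha_dam"]] * Dam + p[["alpha_m2"]] * M2) +
      p[["ksttb_ud"]] * Fud + p[["ksttb_d"]] * Fd - p[["df"]] * Fb,
    L1_tb = Rl1 * (Lud + Ld) - p[["dl"]] * L1,
    L2_tb = Rl2 * (Lud + Ld) - p[["dl"]] * L2,
    P_tb = p[["kpg"]] * P * (1 - P / p[["P_inf"]]) -
      p[["kpb"]] * p[["sb"]] * P / (p[["mu_b"]] + p[["kbp"]] * P) -
      p[["kpn"]] * P * N - p[["kpm1"]] * P * (M1 / in1) -
      p[["kpm2"]] * P * (M2 / in1))
}

# Quick burn-only healing lookup used by several tests.
healing_days <- function(p, severity, DR = 0, horizon = 400,
                         solver = rci_solver_options(dt = 0.25)) {
  expo <- rci_exposure(severity = severity, DR = DR)
  traj <- simulate_rci(build_initial_state(expo, p), p, expo,
                       horizon = horizon, solver = solver)
  stopifnot(traj$success)
  traj$derived$healing_h / 24
}
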