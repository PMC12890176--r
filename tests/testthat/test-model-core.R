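test_that("inhibitory function divides a flux by squared scaled inhibitors", {
  expect_equal(inhibitory_omega(3), 3)
  expect_equal(inhibitory_omega(2, list(c(1, 1))), 1)
  expect_equal(inhibitory_omega(1, list(c(2, 1), c(3, 3))), 1 / 6)
  expect_error(inhibitory_omega(1, list(c(1, 0))), "positive")
  ## never exceeds the uninhibited flux; decreasing in each inhibitor
  set.seed(1)
  for (i in 1:20) {
    X <- runif(1, 0, 5); Y <- runif(1, 0, 3); Yinf <- runif(1, 0.1, 2)
    expect_lte(inhibitory_omega(X, list(c(Y, Yinf))), X)
    expect_lt(inhibitory_omega(X, list(c(Y + 0.5, Yinf))),
              inhibitory_omega(X, list(c(Y, Yinf))) + 1e-15)
  }
})

test_that("Hill function saturates with half-point at XH", {
  expect_equal(hill_omega(1.7, 6, 1.7), 0.5)
  expect_equal(hill_omega(0, 6, 1), 0)
  expect_equal(hill_omega(2, 6, 1), 64 / 65)
  expect_error(hill_omega(1, 6, 0), "positive")
  expect_error(hill_omega(1, 0.5, 1), ">= 1")
  x <- seq(0, 5, by = 0.1)
  expect_true(all(diff(hill_omega(x, 6, 1)) > 0))
})

test_that("dose-dependent influx factor recovers from zero towards one", {
  expect_equal(dose_delay_v(c(0, 3, 100), 0, 0.02), c(1, 1, 1))
  expect_equal(dose_delay_v(0, 5, 0.02), 0)
  expect_equal(dose_delay_v(log(2) / (0.02 * 5), 5, 0.02), 0.5)
  expect_error(dose_delay_v(-1, 5, 0.02), "non-negative")
  t <- seq(0, 300, by = 10)
  v <- dose_delay_v(t, 5, 0.02)
  expect_true(all(diff(v) > 0))
  expect_lt(1 - dose_delay_v(1000, 5, 0.02), 1e-8)
})

test_that("activation rates vanish in an empty wound and match hand algebra", {
  p <- rci_default_params()
  y <- healed_steady_state(p)
  y["F_tb"] <- 0  # truly empty burn compartment
  r <- activation_rates(y, p)
  expect_equal(unname(r[c("Rm1", "Rm2", "Rl1", "Rl2")]), rep(0, 4))

  y2 <- random_state(42)
  y2[c("Deb_tb", "P_tb")] <- 0
  r2 <- activation_rates(y2, p)
  expect_equal(r2[["Rn"]],
               p[["knn"]] * y2[["N_tb"]] /
                 (1 + (y2[["M2_tb"]] / p[["M2_inf"]])^2 +
                    (y2[["L2_tb"]] / p[["L21_inf"]])^2))
})

test_that("rhs matches an independent term-by-term oracle to 1e-12", {
  for (i in 1:100) {
    p <- jittered_params(1000 + i, spread = 0.4)
    y <- random_state(2000 + i)
    DR <- sample(c(0, 1, 1.9, 2, 5, 14), 1)
    t <- runif(1, 0, 300)
    got <- rci_rhs(t, y, p, rci_exposure(severity = "superficial", DR = DR))
    want <- naive_rhs(t, y, unclass(p), DR)
    expect_equal(unname(got), unname(want), tolerance = 1e-12)
  }
})

test_that("the 2 Gy switch alters only the M2-activation flux", {
  p <- rci_default_params()
  y <- random_state(7)
  y["M_st_d"] <- 0.8  # a substantial damaged-macrophage signal
  lo <- rci_rhs(10, y, p, rci_exposure(severity = "superficial", DR = 1.9))
  hi <- rci_rhs(10, y, p, rci_exposure(severity = "superficial", DR = 2.0))
  affected <- c("M_st_ud", "M_st_d", "M2_tb")
  ## v() also depends on dose, so compare at doses straddling 2 Gy with the
  ## influx terms removed: the influx-carrying components are the st_ud
  ## rows; isolate the switch by checking flux ratios instead
  r <- activation_rates(y, p)
  shrink <- 1 / (1 + (y[["M_st_d"]] / p[["omega_m2"]])^2)
  ## M2 activation flux: below 2 Gy rate Rm2, at/above 2 Gy inhibited
  flux_lo <- r[["Rm2"]] * (y[["M_st_ud"]] + y[["M_st_d"]])
  flux_hi <- flux_lo * shrink
  trans <- p[["theta_m1m2"]] * p[["knm1p"]] * y[["N_tb"]] *
    y[["M1_tb"]] / (1 + (y[["N_tb"]] / p[["N1_inf"]])^2)
  expect_equal(lo[["M2_tb"]], flux_lo + trans - p[["dm2"]] * y[["M2_tb"]])
  expect_equal(hi[["M2_tb"]], flux_hi + trans - p[["dm2"]] * y[["M2_tb"]])
  ## all components not touched by the switch or the influx factor agree
  untouched <- setdiff(rci_state_names(),
                       c(affected, "N_st_ud", "F_st_ud", "L_st_ud"))
  expect_equal(lo[untouched], hi[untouched])
  ## at identical dose the switch is the only difference around 2 Gy:
  ## approaching from below leaves the flux unmodified
  just_below <- rci_rhs(10, y, p,
                        rci_exposure(severity = "superficial", DR = 1.999999))
  expect_equal(just_below[["M2_tb"]], lo[["M2_tb"]], tolerance = 1e-4)
})

test_that("inhibited fluxes are monotone non-increasing in each inhibitor", {
  p <- rci_default_params()
  for (i in 1:25) {
    y <- random_state(300 + i)
    r0 <- activation_rates(y, p)
    ## raising M2 or L2 weakens neutrophil and M1 activation
    for (v in c("M2_tb", "L2_tb")) {
      y2 <- y; y2[v] <- y[v] + 0.3
      r1 <- activation_rates(y2, p)
      expect_lte(r1[["Rn"]], r0[["Rn"]] + 1e-12)
      expect_lte(r1[["Rm1"]], r0[["Rm1"]] + 1e-12)
    }
    ## raising neutrophils or fibroblasts weakens M2 activation
    for (v in c("N_tb", "F_tb")) {
      y2 <- y; y2[v] <- y[v] + 0.3
      r1 <- activation_rates(y2, p)
      expect_lte(r1[["Rm2"]], r0[["Rm2"]] + 1e-12)
    }
    ## raising damaged surrounding fibroblasts slows damage resolution
    y3 <- y; y3["F_st_d"] <- y[["F_st_d"]] + 0.5
    d0 <- rci_rhs(5, y, p, rci_exposure(severity = "superficial", DR = 0))
    d1 <- rci_rhs(5, y3, p, rci_exposure(severity = "superficial", DR = 0))
    expect_gte(d1[["Dam_tb"]], d0[["Dam_tb"]] - 1e-12)
  }
})

test_that("degenerate states have vanishing derivatives where expected", {
  p <- rci_default_params()
  expo <- rci_exposure(severity = "superficial", DR = 0)
  ## no pathogen: every pathogen term carries P
  y <- random_state(11); y["P_tb"] <- 0
  expect_equal(rci_rhs(3, y, p, expo)[["P_tb"]], 0)
  ## clean wound over resting tissue: no damage or debris turnover
  y2 <- healed_steady_state(p)
  y2[c("Dam_tb", "Deb_tb", "F_tb")] <- 0
  d <- rci_rhs(0, y2, p, expo)
  expect_equal(d[["Dam_tb"]], 0)
  expect_equal(d[["Deb_tb"]], 0)
})

test_that("states stay non-negative along burn and combined trajectories", {
  p <- rci_default_params()
  for (sev in c("superficial", "superficial-partial")) {
    for (DR in c(0, 5)) {
      expo <- rci_exposure(severity = sev, DR = DR)
      traj <- simulate_rci(build_initial_state(expo, p), p, expo,
                           horizon = 300,
                           solver = rci_solver_options(dt = 0.25))
      expect_true(traj$success)
      expect_gte(min(traj$states), -1e-9)
    }
  }
})
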