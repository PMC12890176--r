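test_that("Latin hypercube sample is stratified, seeded and midpoint-fixed", {
  design <- rci_design(n_samples = 4, seed = 3, estimate = "kdn")
  s <- lhs_sample(design)
  rng <- design$ranges[design$ranges$parameter == "kdn", ]
  ## exactly one draw per quartile of the kdn range
  q <- findInterval(s[, "kdn"], seq(rng$min, rng$max, length.out = 5),
                    rightmost.closed = TRUE)
  expect_setequal(q, 1:4)
  ## every other parameter pinned at its midpoint
  mid <- (design$ranges$min + design$ranges$max) / 2
  other <- setdiff(rci_param_names(), "kdn")
  expect_equal(unname(s[1, other]),
               mid[match(other, design$ranges$parameter)])
  ## reproducible; empty design yields an empty sample
  expect_identical(s, lhs_sample(design))
  s0 <- lhs_sample(rci_design(n_samples = 0, seed = 3))
  expect_equal(nrow(s0), 0L)
  expect_error(rci_design(estimate = "no_such_parameter"), "unknown")
})

test_that("feasibility verdicts implement the three acceptance criteria", {
  ## the baseline passes all three
  v <- assess_feasibility(rci_default_params())
  expect_true(v$passed_numerics && v$passed_ordering && v$passed_windows)
  expect_true(v$accepted)
  expect_true(all(v$healing_h / 24 > 4 & v$healing_h / 24 < 8.4))

  ## runaway proliferation trips the numerical-error criterion
  p <- unclass(rci_default_params())
  p["kf"] <- 40; p["df"] <- 0.001
  v2 <- suppressWarnings(assess_feasibility(
    validate_params(p), solver = rci_solver_options(dt = 0.25,
                                                    maxsteps = 2000)))
  expect_false(v2$passed_numerics)
  expect_false(v2$accepted)
  expect_match(v2$reason, "integration failure")

  ## stalled debris clearance leaves debris unresolved before healing
  p3 <- unclass(rci_default_params())
  p3[c("kdnp", "kdm1p", "kdm2p")] <- 1e-5
  p3["ddeb"] <- 1e-4
  v3 <- assess_feasibility(validate_params(p3))
  expect_false(v3$passed_ordering)

  ## slowed resolution misses the healing windows
  p4 <- unclass(rci_default_params())
  p4[c("rho_dam", "kdf")] <- p4[c("rho_dam", "kdf")] / 4
  v4 <- assess_feasibility(validate_params(p4))
  expect_false(v4$passed_windows)
})

test_that("acceptance is deterministic for fixed inputs", {
  p <- jittered_params(17, spread = 0.3)
  v1 <- assess_feasibility(p)
  v2 <- assess_feasibility(p)
  expect_identical(v1, v2)
})

test_that("refined bounds are elementwise extrema inside the initial box", {
  a <- unclass(jittered_params(1)); b <- unclass(jittered_params(2))
  acc <- rbind(a, b)
  bounds <- refine_bounds(acc)
  expect_equal(bounds$min, unname(pmin(a, b)))
  expect_equal(bounds$max, unname(pmax(a, b)))
  expect_false(any(attr(bounds, "degenerate")))
  ## a single accepted set gives degenerate, flagged ranges
  b1 <- refine_bounds(acc[1, , drop = FALSE])
  expect_true(all(attr(b1, "degenerate")))
  expect_error(refine_bounds(acc[0, , drop = FALSE]), "sample size")
  ## containment: accepted subsets of a screen stay inside the design box
  design <- rci_design(n_samples = 60, seed = 5)
  s <- lhs_sample(design)
  scr <- screen_samples(s)
  if (any(scr$accepted)) {
    rb <- refine_bounds(s[scr$accepted, , drop = FALSE])
    expect_true(all(rb$min >= design$ranges$min - 1e-12))
    expect_true(all(rb$max <= design$ranges$max + 1e-12))
  }
})

test_that("representative selection minimises the weighted MSE to the mean", {
  one <- matrix(unclass(jittered_params(8, stable_only = TRUE)), nrow = 1,
                dimnames = list(NULL, rci_param_names()))
  sel1 <- select_representative(one, t_grid = seq(0, 200, by = 4))
  expect_equal(sel1$index, 1L)
  expect_equal(unclass(sel1$params), one[1, ])

  ## identical candidates tie-break to the first index
  three_same <- one[c(1, 1, 1), ]
  sel2 <- select_representative(three_same, t_grid = seq(0, 200, by = 4))
  expect_equal(sel2$index, 1L)

  ## brute-force oracle over three distinct candidates
  cand <- do.call(rbind, lapply(c(8, 21, 34), function(s)
    unclass(jittered_params(s, spread = 0.15, stable_only = TRUE))))
  t_grid <- seq(0, 200, by = 4)
  sel3 <- select_representative(cand, t_grid = t_grid)
  sims <- lapply(seq_len(nrow(cand)), function(i) {
    p <- validate_params(cand[i, ])
    do.call(rbind, lapply(c("superficial", "superficial-partial"),
      function(sev) {
        expo <- rci_exposure(severity = sev, DR = 0)
        tr <- simulate_rci(build_initial_state(expo, p), p, expo,
                           horizon = 200,
                           solver = rci_solver_options(dt = 0.25))
        tr$states[match(t_grid, tr$times), ]
      }))
  })
  mbar <- (sims[[1]] + sims[[2]] + sims[[3]]) / 3
  v <- apply(mbar, 2, var)
  w <- ifelse(v > 1e-12, 1 / v, 0)
  mse <- sapply(sims, function(s) sum(w * colMeans((s - mbar)^2)) / sum(w))
  expect_equal(sel3$index, which.min(mse))
  expect_equal(sel3$mse, mse, tolerance = 1e-10)
})

test_that("healed-state stability screen rejects unstable parameter sets", {
  expect_true(healed_state_stable(rci_default_params()))
  ## self-amplifying M1 activation destabilises the healed state
  p <- unclass(rci_default_params())
  p["km1m1"] <- 1.5
  expect_false(healed_state_stable(validate_params(p)))
  ## pathogen growth beyond background clearance does too
  p2 <- unclass(rci_default_params())
  p2["kpg"] <- 0.5
  expect_false(healed_state_stable(validate_params(p2)))
  ## df <= kf has no finite healed fibroblast level
  p3 <- unclass(rci_default_params())
  p3["df"] <- p3["kf"] / 2
  expect_false(healed_state_stable(validate_params(p3)))
})
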