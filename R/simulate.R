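#' Closed-form damaged-fibroblast decay
#'
#' The damaged surrounding-tissue fibroblast population obeys a linear ODE
#' (loss to wound recruitment plus decay) with exact solution
#' `F0 * exp(-(k + d) * t)`, used by the simulator in place of numerical
#' integration.
#'
#' @param t time in hours (>= 0); vectorised.
#' @param F0 initial damaged-fibroblast level (>= 0).
#' @param k recruitment rate to the wound, per hour (> 0).
#' @param d decay rate, per hour (> 0).
#' @return level at `t`.
#' @export
fstd_closed_form <- function(t, F0, k, d) {
  stopifnot(is.numeric(t), is.numeric(F0), is.numeric(k), is.numeric(d))
  if (any(t < 0)) stop("time must be non-negative", call. = FALSE)
  if (F0 < 0) stop("F0 must be non-negative", call. = FALSE)
  if (k <= 0 || d <= 0) stop("rates must be positive", call. = FALSE)
  F0 * exp(-(k + d) * t)
}

#' Event thresholds for healing and debris resolution
#'
#' The wound counts as healed (resp. debris as resolved) at the first time
#' the damage (resp. debris) level falls below the threshold and stays
#' below it for `sustain_hours`. The model gives healing windows in days
#' but no numeric threshold; the default is a small absolute floor robust
#' to solver ripple.
#'
#' @param healed_level damage threshold (default 0.02).
#' @param resolved_level debris threshold (default 0.02).
#' @param sustain_hours sustained time below threshold (default 12 h).
#' @return an `rci_thresholds` list.
#' @export
rci_thresholds <- function(healed_level = 0.02, resolved_level = 0.02,
                           sustain_hours = 12) {
  stopifnot(healed_level > 0, resolved_level > 0, sustain_hours > 0)
  structure(list(healed_level = healed_level,
                 resolved_level = resolved_level,
                 sustain_hours = sustain_hours),
            class = "rci_thresholds")
}

#' Solver options
#'
#' @param rtol,atol relative / absolute integration tolerances.
#' @param dt dense-output step in hours (event detection resolution).
#' @param maxsteps maximal internal steps between output times.
#' @param compiled use the compiled right-hand side (default) or the
#'   reference R implementation.
#' @return an `rci_solver_options` list.
#' @export
rci_solver_options <- function(rtol = 1e-8, atol = 1e-10, dt = 0.1,
                               maxsteps = 10000, compiled = TRUE) {
  if (!is.numeric(rtol) || rtol <= 0 || !is.numeric(atol) || atol <= 0)
    stop("tolerances must be positive numbers", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("dense-output step must be positive", call. = FALSE)
  structure(list(rtol = rtol, atol = atol, dt = dt,
                 maxsteps = as.integer(maxsteps),
                 compiled = isTRUE(compiled)),
            class = "rci_solver_options")
}

#' Simulate the model
#'
#' Integrates the 16-state system with a stiff-capable adaptive solver
#' (lsoda) on a dense output grid. The damaged surrounding-tissue
#' fibroblast series is taken from its closed-form solution
#' ([fstd_closed_form()]). Integration failure (solver error or non-finite
#' state) is recorded in the returned trajectory, not raised, so the
#' feasibility screen can consume it.
#'
#' @param state0 named 16-component initial state (e.g. from
#'   [build_initial_state()] or [healed_steady_state()]).
#' @param params `rci_params` vector.
#' @param exposure an [rci_exposure()] (the dose enters the dynamics).
#' @param horizon simulation horizon in hours (> 0).
#' @param solver an [rci_solver_options()].
#' @param thresholds an [rci_thresholds()] used for the derived healing /
#'   debris-resolution times.
#' @return an `rci_trajectory` list: `times`, `states` (matrix, one row per
#'   time), `success`, `exposure`, and `derived` (M1-ratio series, healing
#'   time, debris-resolution time, damage-peak time, final pathogen level).
#' @export
simulate_rci <- function(state0, params, exposure, horizon = 336,
                         solver = rci_solver_options(),
                         thresholds = rci_thresholds()) {
  stopifnot(inherits(exposure, "rci_exposure"), horizon > 0)
  if (!inherits(solver, "rci_solver_options"))
    stop("invalid solver options; use rci_solver_options()", call. = FALSE)
  p <- validate_params(params)
  y0 <- state0[rci_state_names()]
  if (any(is.na(y0)))
    stop("initial state must contain all 16 named components", call. = FALSE)
  times <- seq(0, horizon, by = solver$dt)

  out <- if (solver$compiled) {
    try(deSolve::lsoda(
      y = unname(y0), times = times, func = "rci_derivs",
      parms = c(unname(p), unname(exposure$DR)),
      dllname = "rciburn", initfunc = "rci_initmod",
      rtol = solver$rtol, atol = solver$atol,
      maxsteps = solver$maxsteps), silent = TRUE)
  } else {
    rhs_fn <- function(t, y, parms) {
      names(y) <- rci_state_names()
      list(unname(rci_rhs(t, y, p, exposure)))
    }
    try(deSolve::lsoda(y = unname(y0), times = times, func = rhs_fn,
                       parms = NULL, rtol = solver$rtol, atol = solver$atol,
                       maxsteps = solver$maxsteps), silent = TRUE)
  }

  bad <- inherits(out, "try-error") || nrow(out) < length(times) ||
    any(!is.finite(out[, -1]))
  if (!bad) {
    states <- out[, -1, drop = FALSE]
    colnames(states) <- rci_state_names()
    ## exact closed-form damaged-fibroblast series
    states[, "F_st_d"] <- fstd_closed_form(
      times, y0[["F_st_d"]], p[["ksttb_d"]], p[["dfr_d"]])
  } else {
    n_ok <- if (inherits(out, "try-error")) 0L else nrow(out)
    states <- matrix(NA_real_, length(times), 16L,
                     dimnames = list(NULL, rci_state_names()))
    if (n_ok > 0) states[seq_len(n_ok), ] <- out[, -1, drop = FALSE]
  }

  traj <- structure(list(times = times, states = states, success = !bad,
                         exposure = exposure, thresholds = thresholds),
                    class = "rci_trajectory")
  traj$derived <- if (bad) list() else .derive_series(traj, thresholds)
  traj
}

.derive_series <- function(traj, thresholds) {
  res <- resolution_times(traj, thresholds)
  dam <- traj$states[, "Dam_tb"]
  peak_i <- which.max(dam)  # ties broken by earliest time
  list(m1_ratio = m1_ratio(traj),
       healing_h = res[["healing_h"]],
       debris_h = res[["debris_h"]],
       peak_h = traj$times[peak_i],
       final_P = traj$states[nrow(traj$states), "P_tb"])
}

# First sustained down-crossing of `x` below `level`: the earliest time
# after which x stays below `level` for `sustain` hours (or through the end
# of the grid). The crossing is refined by linear interpolation between the
# bracketing grid points.
.first_sustained_crossing <- function(times, x, level, sustain) {
  below <- x < level
  if (!any(below)) return(NA_real_)
  ## run-length scan over the below/above pattern
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dt_grid <- times[2] - times[1]
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    run_len <- times[ends[j]] - times[starts[j]]
    sustained <- run_len >= sustain || ends[j] == length(times)
    if (!sustained) next
    i <- starts[j]
    if (i == 1L) return(times[1])
    ## interpolate the crossing within (i-1, i)
    x0 <- x[i - 1L]; x1 <- x[i]
    frac <- if (x0 == x1) 0 else (x0 - level) / (x0 - x1)
    return(times[i - 1L] + frac * dt_grid)
  }
  NA_real_
}

#' Healing and debris-resolution times
#'
#' First sustained down-crossing times of the damage and debris series
#' below their thresholds; `NA` marks an unresolved level within the
#' simulated horizon.
#'
#' @param traj successful `rci_trajectory`.
#' @param thresholds an [rci_thresholds()].
#' @return named numeric vector `c(healing_h, debris_h)` in hours.
#' @export
resolution_times <- function(traj, thresholds = rci_thresholds()) {
  stopifnot(inherits(traj, "rci_trajectory"))
  if (!traj$success)
    stop("resolution times are undefined for a failed trajectory",
         call. = FALSE)
  c(healing_h = .first_sustained_crossing(
      traj$times, traj$states[, "Dam_tb"],
      thresholds$healed_level, thresholds$sustain_hours),
    debris_h = .first_sustained_crossing(
      traj$times, traj$states[, "Deb_tb"],
      thresholds$resolved_level, thresholds$sustain_hours))
}

#' M1 macrophage ratio
#'
#' `M1 / (M1 + M2)` along a trajectory: 1 when the activated macrophage
#' response is entirely pro-inflammatory, 0 when entirely pro-resolution.
#' Time points with no activated macrophages are `NA`.
#'
#' @param traj `rci_trajectory`.
#' @param eps positivity floor for the denominator.
#' @return numeric series in `[0, 1]` (with `NA` where undefined).
#' @export
m1_ratio <- function(traj, eps = 1e-12) {
  stopifnot(inherits(traj, "rci_trajectory"))
  m1 <- traj$states[, "M1_tb"]; m2 <- traj$states[, "M2_tb"]
  tot <- m1 + m2
  ifelse(tot > eps, m1 / tot, NA_real_)
}

#' Healed steady state
#'
#' The model's fixed point with zero damage, debris and pathogen, empty
#' activated compartments except wound fibroblasts (whose recruitment from
#' the surrounding tissue balances net decay at
#' `ksttb_ud * F_st_ud / (df - kf)`), and surrounding-tissue populations at
#' their resting levels. Requires `df > kf`.
#'
#' @param params `rci_params` vector.
#' @return named 16-component state vector, a root of [rci_rhs()].
#' @export
healed_steady_state <- function(params) {
  p <- validate_params(params)
  if (p[["df"]] <= p[["kf"]])
    stop("infeasible parameters: df must exceed kf for a finite healed ",
         "wound-fibroblast level", call. = FALSE)
  lev <- resting_steady_levels(p)
  F_ud <- lev$F_st_0
  F_tb <- p[["ksttb_ud"]] * F_ud / (p[["df"]] - p[["kf"]])
  y <- c(N_st_ud = 0, M_st_ud = lev$M_st_0, M_st_d = 0,
         F_st_ud = F_ud, F_st_d = 0, L_st_ud = lev$L_st_0, L_st_d = 0,
         Dam_tb = 0, Deb_tb = 0, N_tb = 0, M1_tb = 0, M2_tb = 0,
         F_tb = unname(F_tb), L1_tb = 0, L2_tb = 0, P_tb = 0)
  y[rci_state_names()]
}

#' Write a trajectory to disk
#'
#' Tidy CSV (`time_h`, `variable`, `value`) plus a JSON summary with the
#' derived healing, debris-resolution and damage-peak times and the final
#' pathogen level.
#'
#' @param traj `rci_trajectory`.
#' @param dir output directory (created if needed).
#' @param stem file stem (default "trajectory").
#' @return invisibly, the paths written.
#' @export
write_trajectory <- function(traj, dir, stem = "trajectory") {
  stopifnot(inherits(traj, "rci_trajectory"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  long <- data.frame(
    time_h = rep(traj$times, times = ncol(traj$states)),
    variable = rep(colnames(traj$states), each = length(traj$times)),
    value = as.vector(traj$states))
  utils::write.csv(long, csv, row.names = FALSE)
  js <- file.path(dir, paste0(stem, "_summary.json"))
  summ <- list(success = traj$success,
               healing_h = traj$derived$healing_h,
               debris_h = traj$derived$debris_h,
               peak_h = traj$derived$peak_h,
               final_P = traj$derived$final_P)
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(csv = csv, json = js))
}
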