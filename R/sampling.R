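#' Sampling design
#'
#' Per-parameter bounds, sample count, seed and the estimate/fix split for
#' a Latin-hypercube feasibility stage. Parameters in `fix` are pinned to
#' the midpoint of their range (the baseline); parameters in `estimate`
#' are sampled.
#'
#' @param ranges data.frame with columns `parameter`, `min`, `max` covering
#'   every canonical parameter (`min < max`, or `min == max` for a pinned
#'   degenerate range).
#' @param n_samples number of Latin-hypercube samples.
#' @param seed integer seed.
#' @param estimate character vector of sampled parameter names; the rest
#'   are fixed at midpoint. Defaults to the shipped split
#'   ([rci_default_split()]).
#' @return an `rci_design` list.
#' @export
rci_design <- function(ranges = rci_default_ranges(), n_samples = 5000,
                       seed = 1, estimate = rci_default_split()$estimate) {
  need <- c("parameter", "min", "max")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges)))
    stop("ranges must be a data.frame with columns parameter, min, max",
         call. = FALSE)
  missing <- setdiff(rci_param_names(), ranges$parameter)
  if (length(missing))
    stop("ranges missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (any(ranges$min > ranges$max))
    stop("every range needs min <= max", call. = FALSE)
  unknown <- setdiff(estimate, rci_param_names())
  if (length(unknown))
    stop("unknown parameter(s) in estimate set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  structure(list(ranges = ranges[match(rci_param_names(), ranges$parameter), ],
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 estimate = estimate,
                 fix = setdiff(rci_param_names(), estimate)),
            class = "rci_design")
}

#' Latin-hypercube parameter sample
#'
#' Draws `n_samples` parameter sets: each sampled parameter is stratified
#' (exactly one draw per equal-probability stratum of its range) via a
#' random Latin hypercube; fixed parameters sit at the midpoint of their
#' range. Reproducible from the design seed.
#'
#' @param design an [rci_design()].
#' @return a numeric matrix, one row per sample, one column per canonical
#'   parameter.
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "rci_design"))
  n <- design$n_samples
  nm <- rci_param_names()
  rng <- design$ranges
  mid <- (rng$min + rng$max) / 2
  if (n == 0L)
    return(matrix(numeric(0), nrow = 0, ncol = length(nm),
                  dimnames = list(NULL, nm)))
  out <- matrix(rep(mid, each = n), nrow = n, dimnames = list(NULL, nm))
  est <- design$estimate
  if (length(est)) {
    set.seed(design$seed)
    u <- lhs::randomLHS(n, length(est))
    for (j in seq_along(est)) {
      i <- match(est[j], nm)
      out[, i] <- rng$min[i] + u[, j] * (rng$max[i] - rng$min[i])
    }
  }
  out
}

#' Stability screen for the healed state
#'
#' Cheap pre-simulation predicate applied to every sampled set: all
#' parameters positive, `df > kf` (finite positive healed wound-fibroblast
#' level), and every eigenvalue of the right-hand-side Jacobian at the
#' healed steady state (burn-only conditions) has negative real part, so
#' the healed state is locally attracting. The Jacobian is formed by
#' central finite differences on [rci_rhs()].
#'
#' @param params `rci_params` vector (or plain named vector).
#' @param tol eigenvalue real-part tolerance.
#' @return logical.
#' @export
healed_state_stable <- function(params, tol = 1e-8) {
  p <- try(validate_params(params), silent = TRUE)
  if (inherits(p, "try-error")) return(FALSE)
  if (p[["df"]] <= p[["kf"]]) return(FALSE)
  y0 <- healed_steady_state(p)
  expo <- rci_exposure(severity = "superficial", DR = 0)
  h <- pmax(abs(y0), 1) * 1e-6
  J <- matrix(0, 16, 16)
  for (j in 1:16) {
    up <- y0; up[j] <- up[j] + h[j]
    dn <- y0; dn[j] <- dn[j] - h[j]
    ## states are clipped at 0 inside the rhs; keep the stencil one-sided
    ## at the boundary instead
    if (dn[j] < 0) {
      J[, j] <- (rci_rhs(1, up, p, expo) - rci_rhs(1, y0, p, expo)) / h[j]
    } else {
      J[, j] <- (rci_rhs(1, up, p, expo) - rci_rhs(1, dn, p, expo)) /
        (2 * h[j])
    }
  }
  ev <- eigen(J, only.values = TRUE)$values
  all(Re(ev) < tol)
}

#' Assess the feasibility of a parameter set
#'
#' Simulates a burn-only superficial (initial damage 0.1) and superficial
#' partial-thickness (0.9) scenario and applies the three acceptance
#' criteria: (a) no numerical errors, (b) debris resolved before damage in
#' both scenarios, and (c) the superficial burn healed within
#' 4.667 +/- 0.5 days and the partial-thickness burn within
#' 7.833 +/- 0.5 days.
#'
#' @param params `rci_params` vector.
#' @param thresholds an [rci_thresholds()].
#' @param solver an [rci_solver_options()].
#' @param horizon simulation horizon in hours.
#' @return an `rci_verdict` list: `passed_numerics`, `passed_ordering`,
#'   `passed_windows`, `accepted`, per-severity healing and debris times
#'   (hours), and a `reason` string for rejects.
#' @export
assess_feasibility <- function(params, thresholds = rci_thresholds(),
                               solver = rci_solver_options(dt = 0.25),
                               horizon = 260) {
  p <- try(validate_params(params), silent = TRUE)
  verdict <- function(num, ord, win, heal, deb, reason = "") {
    structure(list(passed_numerics = num, passed_ordering = ord,
                   passed_windows = win, accepted = num && ord && win,
                   healing_h = heal, debris_h = deb, reason = reason),
              class = "rci_verdict")
  }
  heal <- c(superficial = NA_real_, partial = NA_real_)
  deb <- heal
  if (inherits(p, "try-error"))
    return(verdict(FALSE, FALSE, FALSE, heal, deb, "invalid parameters"))

  windows_h <- list(superficial = (4.667 + c(-0.5, 0.5)) * 24,
                    partial = (7.833 + c(-0.5, 0.5)) * 24)
  sev <- c(superficial = "superficial", partial = "superficial-partial")
  ok_num <- TRUE; ok_ord <- TRUE; ok_win <- TRUE; why <- character()
  for (s in names(sev)) {
    expo <- rci_exposure(severity = sev[[s]], DR = 0)
    y0 <- build_initial_state(expo, p)
    traj <- simulate_rci(y0, p, expo, horizon = horizon, solver = solver,
                         thresholds = thresholds)
    if (!traj$success) {
      ok_num <- FALSE; why <- c(why, paste0(s, ": integration failure"))
      next
    }
    heal[s] <- traj$derived$healing_h
    deb[s] <- traj$derived$debris_h
    if (is.na(deb[s]) || is.na(heal[s]) || deb[s] >= heal[s]) {
      ok_ord <- FALSE
      why <- c(why, paste0(s, ": debris not resolved before damage"))
    }
    w <- windows_h[[s]]
    if (is.na(heal[s]) || heal[s] < w[1] || heal[s] > w[2]) {
      ok_win <- FALSE
      why <- c(why, paste0(s, ": healing time outside window"))
    }
  }
  verdict(ok_num, ok_ord && ok_num, ok_win && ok_num, heal, deb,
          paste(why, collapse = "; "))
}

#' Run the feasibility screen over a sample
#'
#' Applies the stability screen and then [assess_feasibility()] to every
#' row of a parameter sample matrix.
#'
#' @param samples matrix from [lhs_sample()].
#' @param thresholds,solver,horizon passed to [assess_feasibility()].
#' @return a data.frame manifest: `sample_id`, the verdict booleans,
#'   healing times per severity (hours), and `accepted`.
#' @export
screen_samples <- function(samples, thresholds = rci_thresholds(),
                           solver = rci_solver_options(dt = 0.25),
                           horizon = 260) {
  n <- nrow(samples)
  res <- data.frame(sample_id = seq_len(n), stable = FALSE,
                    passed_numerics = FALSE, passed_ordering = FALSE,
                    passed_windows = FALSE, accepted = FALSE,
                    healing_superficial_h = NA_real_,
                    healing_partial_h = NA_real_,
                    debris_superficial_h = NA_real_,
                    debris_partial_h = NA_real_)
  for (i in seq_len(n)) {
    p <- samples[i, ]
    if (!healed_state_stable(p)) next
    res$stable[i] <- TRUE
    v <- assess_feasibility(p, thresholds, solver, horizon)
    res$passed_numerics[i] <- v$passed_numerics
    res$passed_ordering[i] <- v$passed_ordering
    res$passed_windows[i] <- v$passed_windows
    res$accepted[i] <- v$accepted
    res$healing_superficial_h[i] <- v$healing_h[["superficial"]]
    res$healing_partial_h[i] <- v$healing_h[["partial"]]
    res$debris_superficial_h[i] <- v$debris_h[["superficial"]]
    res$debris_partial_h[i] <- v$debris_h[["partial"]]
  }
  res
}

#' Refine sampling bounds from accepted sets
#'
#' Per-parameter minimum and maximum over the accepted parameter sets,
#' used as the bounds of the sensitivity stage.
#'
#' @param accepted matrix of accepted parameter sets (rows).
#' @return data.frame with columns `parameter`, `min`, `max` and a logical
#'   attribute `degenerate` flagging zero-width ranges (single accepted
#'   set).
#' @export
refine_bounds <- function(accepted) {
  if (is.null(dim(accepted))) accepted <- matrix(accepted, nrow = 1,
    dimnames = list(NULL, names(accepted)))
  if (nrow(accepted) == 0L)
    stop("no accepted parameter sets; increase the sample size",
         call. = FALSE)
  out <- data.frame(parameter = colnames(accepted),
                    min = apply(accepted, 2, min),
                    max = apply(accepted, 2, max),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "degenerate") <- out$min == out$max
  out
}

#' Select the representative parameter set
#'
#' Simulates every accepted set on the burn-only superficial and
#' partial-thickness scenarios over a common time grid, forms the temporal
#' mean trajectory across sets for each state variable, and ranks sets by
#' the weighted mean squared error to that mean (primary criterion; the
#' coefficient of determination across all variables is reported
#' alongside). Per-variable weights default to the inverse variance of the
#' pooled mean series, putting the variables on a comparable scale;
#' near-constant variables get weight 0. Ties break to the lowest sample
#' index.
#'
#' @param accepted matrix of accepted parameter sets (rows).
#' @param t_grid evaluation times in hours.
#' @param weights optional named per-variable weights.
#' @param solver an [rci_solver_options()].
#' @return list with `params` (the representative `rci_params`), `index`
#'   (row in `accepted`), `mse` and `r2` vectors over the candidates.
#' @export
select_representative <- function(accepted,
                                  t_grid = seq(0, 260, by = 2),
                                  weights = NULL,
                                  solver = rci_solver_options(dt = 0.25)) {
  if (is.null(dim(accepted))) accepted <- matrix(accepted, nrow = 1,
    dimnames = list(NULL, names(accepted)))
  n <- nrow(accepted)
  if (n == 0L) stop("no accepted parameter sets", call. = FALSE)
  horizon <- max(t_grid)
  sev <- c("superficial", "superficial-partial")
  ## stacked (time x scenario) x variable array per candidate
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    p <- validate_params(accepted[i, ])
    blocks <- lapply(sev, function(s) {
      expo <- rci_exposure(severity = s, DR = 0)
      traj <- simulate_rci(build_initial_state(expo, p), p, expo,
                           horizon = horizon, solver = solver)
      if (!traj$success)
        stop("candidate ", i, " failed to integrate", call. = FALSE)
      traj$states[match(t_grid, traj$times), , drop = FALSE]
    })
    sims[[i]] <- do.call(rbind, blocks)
  }
  mean_traj <- Reduce(`+`, sims) / n
  if (is.null(weights)) {
    v <- apply(mean_traj, 2, stats::var)
    weights <- ifelse(v > 1e-12, 1 / v, 0)
    names(weights) <- colnames(mean_traj)
  }
  w <- weights[colnames(mean_traj)]
  mse <- vapply(sims, function(s) {
    sum(w * colMeans((s - mean_traj)^2)) / sum(w)
  }, numeric(1))
  sst <- sum(w * colMeans(sweep(mean_traj, 2,
                                colMeans(mean_traj))^2))
  r2 <- vapply(sims, function(s) {
    1 - sum(w * colMeans((s - mean_traj)^2)) / sst
  }, numeric(1))
  idx <- which.min(mse)  # ties -> first index
  list(params = validate_params(accepted[idx, ]), index = idx,
       mse = mse, r2 = r2, weights = w)
}
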