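#' Sensitivity design
#'
#' Settings of the extended FAST screen: samples per search curve `NS`
#' (at least `4*M^2 + 1`), resampling size `NR` (independent random phase
#' shifts per parameter), interference factor `M`, the radiation doses and
#' post-injury days at which model readouts are taken, and the
#' significance level of the test battery.
#'
#' @param NS samples per search curve (default 2000).
#' @param NR number of resample curves (default 32).
#' @param M interference factor (default 4).
#' @param doses radiation doses in Gy at which the model is read out.
#' @param output_days days post-injury at which states are read out.
#' @param alpha significance level of the MeFAST battery.
#' @param seed integer seed for the random phases.
#' @return an `rci_sens_design` list.
#' @export
rci_sens_design <- function(NS = 2000, NR = 32, M = 4,
                            doses = c(1, 7, 14),
                            output_days = c(1, 3, 7, 10, 14),
                            alpha = 0.05, seed = 1) {
  NS <- as.integer(NS); NR <- as.integer(NR); M <- as.integer(M)
  if (NS < 4 * M^2 + 1)
    stop("NS must be at least 4*M^2 + 1 (", 4 * M^2 + 1,
         ") for interference factor M = ", M, call. = FALSE)
  if (NR < 1) stop("NR must be at least 1", call. = FALSE)
  structure(list(NS = NS, NR = NR, M = M, doses = doses,
                 output_days = output_days, alpha = alpha,
                 seed = as.integer(seed)),
            class = "rci_sens_design")
}

# one-parameter spectrum -> (Si, STi) given the FFT power at integer
# frequencies. lambda[w] is the spectral power at frequency w.
.efast_from_power <- function(lambda, omega, M) {
  D <- sum(lambda)
  if (D <= 0) return(c(Si = 0, STi = 0))
  Di <- sum(lambda[seq_len(M) * omega])
  Dc <- sum(lambda[seq_len(max(1L, floor(omega / 2)))])
  c(Si = Di / D, STi = 1 - Dc / D)
}

#' Extended FAST sensitivity indices
#'
#' First-order (`Si`) and total-order (`STi`) variance-based indices by
#' the Fourier amplitude method: each parameter in turn is driven along a
#' space-filling search curve at a high frequency
#' `omega = floor((NS-1)/(2M))` while the complementary parameters cycle
#' through low frequencies `1..max(1, floor(omega/(2M)))`; the readout's
#' power spectrum at the driving frequency and its first `M` harmonics
#' estimates the parameter's first-order variance share, and the power
#' below `omega/2` estimates the complementary share (1 minus it is the
#' total-order index). `NR` independent random phase shifts give a
#' resample distribution per index. A `dummy` parameter with no effect on
#' the readout is appended to calibrate estimator noise.
#'
#' Readout failures (non-finite values) at individual design points are
#' excluded from the spectrum with a warning.
#'
#' @param design an [rci_sens_design()].
#' @param ranges data.frame (`parameter`, `min`, `max`) for the sampled
#'   parameters (the dummy is added internally).
#' @param readout function `(X, dose)` taking a design matrix (one column
#'   per parameter in `ranges` order, one row per design point) and a dose,
#'   returning a numeric matrix with one named column per model output.
#' @param include_dummy append the dummy parameter (default `TRUE`).
#' @return an `rci_sens_report` list with arrays
#'   `Si[parameter, output, dose, resample]` and `STi[...]`, plus the
#'   design and ranges.
#' @export
efast_indices <- function(design, ranges, readout, include_dummy = TRUE) {
  stopifnot(inherits(design, "rci_sens_design"))
  need <- c("parameter", "min", "max")
  if (!is.data.frame(ranges) || !all(need %in% names(ranges)))
    stop("ranges must have columns parameter, min, max", call. = FALSE)
  pars <- ranges$parameter
  if (include_dummy) pars <- c(pars, "dummy")
  k <- length(pars)
  NS <- design$NS; NR <- design$NR; M <- design$M
  omega_max <- floor((NS - 1) / (2 * M))
  max_wc <- max(1L, floor(omega_max / (2 * M)))
  s <- pi * (2 * seq_len(NS) - 1 - NS) / NS
  lo <- c(ranges$min, if (include_dummy) 0)
  hi <- c(ranges$max, if (include_dummy) 1)

  doses <- design$doses
  set.seed(design$seed)
  dims <- NULL
  Si <- STi <- NULL
  n_failed <- 0L
  for (i in seq_len(k)) {
    omega <- rep_len(seq_len(max_wc), k)
    omega[i] <- omega_max
    for (r in seq_len(NR)) {
      phi <- stats::runif(k, 0, 2 * pi)
      X <- matrix(0, NS, k, dimnames = list(NULL, pars))
      for (j in seq_len(k)) {
        x01 <- 0.5 + asin(sin(omega[j] * s + phi[j])) / pi
        X[, j] <- lo[j] + x01 * (hi[j] - lo[j])
      }
      Xr <- X[, ranges$parameter, drop = FALSE]
      for (d in seq_along(doses)) {
        Y <- readout(Xr, doses[d])
        if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1,
                                         dimnames = list(NULL, "output"))
        if (is.null(Si)) {
          dims <- list(parameter = pars, output = colnames(Y),
                       dose = as.character(doses),
                       resample = as.character(seq_len(NR)))
          Si <- array(NA_real_, lengths(dims), dims)
          STi <- Si
        }
        wmax <- floor((NS - 1) / 2)
        for (o in seq_len(ncol(Y))) {
          y <- Y[, o]
          ok <- is.finite(y)
          n_failed <- n_failed + sum(!ok)
          ny <- sum(ok)
          if (ny < ceiling(0.75 * NS)) {
            next  # too many failed points to trust the spectrum
          }
          lambda <- if (all(ok)) {
            z <- stats::fft(y - mean(y))
            2 * Mod(z[2:(wmax + 1)])^2 / NS^2
          } else {
            ## failed points excluded: direct trigonometric sums on the
            ## retained curve positions
            yc <- y[ok] - mean(y[ok])
            sk <- s[ok]
            ws <- outer(seq_len(wmax), sk)
            A <- (cos(ws) %*% yc) / ny
            B <- (sin(ws) %*% yc) / ny
            2 * as.vector(A^2 + B^2)
          }
          est <- .efast_from_power(lambda, omega_max, M)
          Si[i, o, d, r] <- est[["Si"]]
          STi[i, o, d, r] <- est[["STi"]]
        }
      }
    }
  }
  if (n_failed > 0)
    warning(n_failed, " design point(s) had failed readouts and were ",
            "excluded from the spectra", call. = FALSE)
  structure(list(Si = Si, STi = STi, design = design, ranges = ranges,
                 has_dummy = include_dummy),
            class = "rci_sens_report")
}

#' MeFAST multi-test significance battery
#'
#' Compares every parameter's resample distribution of first- and
#' total-order indices against the dummy parameter's with three tests: a
#' two-sample t-test, one-way ANOVA across all parameters followed by the
#' Tukey honest-significant-difference contrast against the dummy, and the
#' Wilcoxon rank-sum test. The t and Wilcoxon tests are one-sided
#' (parameter index exceeds the dummy's); Tukey contrasts are two-sided
#' with family-wise adjustment. Results are recorded per parameter, output,
#' dose and index type.
#'
#' @param report an `rci_sens_report` from [efast_indices()] (must include
#'   the dummy).
#' @param alpha significance level (defaults to the design's).
#' @return the report with a `tests` data.frame added (columns `parameter`,
#'   `output`, `dose`, `index`, `p_t`, `p_anova`, `p_wilcoxon`,
#'   `n_significant`) and `alpha`.
#' @export
mefast_tests <- function(report, alpha = NULL) {
  stopifnot(inherits(report, "rci_sens_report"))
  if (!report$has_dummy)
    stop("MeFAST tests need the dummy parameter in the report",
         call. = FALSE)
  if (dim(report$Si)[4] < 2)
    stop("MeFAST tests need at least 2 resamples (NR >= 2)", call. = FALSE)
  if (is.null(alpha)) alpha <- report$design$alpha
  dn <- dimnames(report$Si)
  pars <- setdiff(dn$parameter, "dummy")
  rows <- list()
  for (idx_name in c("Si", "STi")) {
    arr <- report[[idx_name]]
    for (o in dn$output) for (d in dn$dose) {
      dummy <- arr["dummy", o, d, ]
      ## one ANOVA across all parameters, Tukey contrast vs dummy
      long <- data.frame(
        index = as.vector(t(arr[, o, d, ])),
        parameter = factor(rep(dn$parameter, each = length(dummy))))
      tk <- stats::TukeyHSD(stats::aov(index ~ parameter, data = long))
      tkp <- tk$parameter[, "p adj"]
      contrast_p <- function(p1) {
        nm1 <- paste0(p1, "-dummy"); nm2 <- paste0("dummy-", p1)
        if (nm1 %in% names(tkp)) tkp[[nm1]] else tkp[[nm2]]
      }
      for (p1 in pars) {
        xi <- arr[p1, o, d, ]
        p_t <- tryCatch(
          stats::t.test(xi, dummy, alternative = "greater")$p.value,
          error = function(e) 1)
        p_w <- suppressWarnings(
          stats::wilcox.test(xi, dummy, alternative = "greater")$p.value)
        p_a <- contrast_p(p1)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p1, output = o, dose = d, index = idx_name,
          p_t = p_t, p_anova = p_a, p_wilcoxon = p_w,
          n_significant = sum(c(p_t, p_a, p_w) < alpha))
      }
    }
  }
  report$tests <- do.call(rbind, rows)
  report$alpha <- alpha
  report
}

#' Classify parameters as estimate or fix
#'
#' A parameter is highly influential (to be estimated) if, for at least
#' `min_contexts` output/dose combinations and either index type, at least
#' `min_tests` of the three battery tests are significant. All other
#' parameters are fixed at their baseline (range midpoint).
#'
#' @param report an `rci_sens_report` after [mefast_tests()].
#' @param min_tests tests that must agree (default 2 of 3).
#' @param min_contexts output/dose combinations required (default 1).
#' @return list with character vectors `estimate` and `fix`.
#' @export
classify_parameters <- function(report, min_tests = 2, min_contexts = 1) {
  stopifnot(inherits(report, "rci_sens_report"))
  if (is.null(report$tests))
    stop("run mefast_tests() before classification", call. = FALSE)
  tt <- report$tests
  sig <- tt$n_significant >= min_tests
  hits <- tapply(sig, tt$parameter, sum)
  pars <- setdiff(dimnames(report$Si)$parameter, "dummy")
  est <- names(hits)[hits >= min_contexts]
  list(estimate = intersect(pars, est), fix = setdiff(pars, est))
}

#' Model readout for sensitivity analysis
#'
#' Builds a readout function for [efast_indices()] over the full model: for
#' each design row, the sampled parameters overwrite the baseline set, the
#' burn scenario is simulated at the given dose, and the selected state
#' variables at the selected days post-injury form the outputs (columns
#' named `variable@dayN`). Design rows whose parameter set is invalid or
#' whose integration fails yield `NA` outputs (excluded downstream).
#'
#' @param base_params baseline `rci_params` supplying unsampled parameters.
#' @param variables state variables to read out (default all 16).
#' @param days days post-injury (default the design's canonical five).
#' @param severity burn severity name (default `"superficial"`).
#' @param solver an [rci_solver_options()].
#' @return function `(X, dose)` suitable as an [efast_indices()] readout.
#' @export
rci_model_readout <- function(base_params,
                              variables = rci_state_names(),
                              days = c(1, 3, 7, 10, 14),
                              severity = "superficial",
                              solver = rci_solver_options(dt = 0.5)) {
  base <- validate_params(base_params)
  horizon <- max(days) * 24
  ## day index varies fastest, matching the unrolling of the state matrix
  out_names <- as.vector(outer(days, variables,
                               function(d, v) paste0(v, "@day", d)))
  function(X, dose) {
    Y <- matrix(NA_real_, nrow(X), length(out_names),
                dimnames = list(NULL, out_names))
    for (i in seq_len(nrow(X))) {
      p <- base
      p[colnames(X)] <- X[i, ]
      p <- try(validate_params(unclass(p)), silent = TRUE)
      if (inherits(p, "try-error")) next
      expo <- rci_exposure(severity = severity, DR = dose)
      traj <- simulate_rci(build_initial_state(expo, p), p, expo,
                           horizon = horizon, solver = solver)
      if (!traj$success) next
      rows <- match(days * 24, traj$times)
      Y[i, ] <- as.vector(traj$states[rows, variables, drop = FALSE])
    }
    Y
  }
}

#' Write a sensitivity report
#'
#' CSV with one row per parameter, output, dose and index type (resample
#' means of the indices plus the battery p-values and the influential
#' flag), and a JSON summary with the estimate/fix classification.
#'
#' @param report an `rci_sens_report` after [mefast_tests()].
#' @param dir output directory.
#' @param min_tests,min_contexts passed to [classify_parameters()].
#' @return invisibly, the paths written.
#' @export
write_sensitivity_report <- function(report, dir, min_tests = 2,
                                     min_contexts = 1) {
  stopifnot(inherits(report, "rci_sens_report"), !is.null(report$tests))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cls <- classify_parameters(report, min_tests, min_contexts)
  tt <- report$tests
  mean_idx <- function(row) {
    arr <- report[[row["index"]]]
    mean(arr[row["parameter"], row["output"], row["dose"], ])
  }
  tt$index_mean <- apply(tt[, c("parameter", "output", "dose", "index")],
                         1, mean_idx)
  tt$influential <- tt$parameter %in% cls$estimate
  csv <- file.path(dir, "sensitivity_report.csv")
  utils::write.csv(tt, csv, row.names = FALSE)
  js <- file.path(dir, "sensitivity_summary.json")
  jsonlite::write_json(list(alpha = report$alpha, estimate = cls$estimate,
                            fix = cls$fix),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
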