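#' Fit a linear-quadratic survival curve
#'
#' Minimises the residual sum of squares on the survival scale between
#' `exp(-alpha*D - beta*D^2)` and a dose-survival table, with a
#' derivative-free simplex (Nelder-Mead) search started from
#' `alpha = 0.1, beta = 0.01`; coefficients are constrained non-negative
#' (negative proposals are clipped to zero inside the objective). With
#' `order = "linear"` only `alpha` is fitted (one-dimensional golden-section
#' search; a single non-zero-dose pair is solved exactly as
#' `alpha = -log(S)/D`).
#'
#' @param doses numeric vector of doses in Gy.
#' @param fractions surviving fractions in `(0, 1]`, same length.
#' @param order `"linear-quadratic"` (default) or `"linear"`.
#' @param start starting point `c(alpha, beta)` for the simplex search.
#' @param reltol convergence tolerance passed to the optimiser.
#' @return list with `alpha`, `beta`, `rss` and `order`.
#' @export
fit_lq <- function(doses, fractions, order = c("linear-quadratic", "linear"),
                   start = c(alpha = 0.1, beta = 0.01), reltol = 1e-12) {
  order <- match.arg(order)
  stopifnot(is.numeric(doses), is.numeric(fractions))
  if (length(doses) != length(fractions))
    stop("doses and fractions must have equal length", call. = FALSE)
  if (any(fractions <= 0) || any(fractions > 1))
    stop("surviving fractions must lie in (0, 1]", call. = FALSE)
  if (any(doses < 0)) stop("doses must be non-negative", call. = FALSE)
  if (length(unique(doses)) < 2L)
    stop("need at least two distinct doses to fit", call. = FALSE)
  if (any(doses == 0 & fractions != 1))
    stop("dose 0 must map to surviving fraction 1", call. = FALSE)

  model <- function(ab) exp(-ab[1] * doses - ab[2] * doses^2)
  rss <- function(ab) sum((model(pmax(ab, 0)) - fractions)^2)

  if (order == "linear") {
    nz <- doses > 0
    if (sum(nz) == 1L) {
      ## exact interpolation through the single informative pair
      alpha <- -log(fractions[nz]) / doses[nz]
      return(list(alpha = unname(alpha), beta = 0,
                  rss = rss(c(alpha, 0)), order = order))
    }
    ## least-squares slope of -log(S) on D brackets the optimum
    a0 <- sum(doses * (-log(fractions))) / sum(doses^2)
    opt <- stats::optim(max(a0, 1e-8), function(a) rss(c(a, 0)),
                        method = "Brent", lower = 0,
                        upper = max(4 * a0, 1))
    return(list(alpha = opt$par, beta = 0, rss = opt$value,
                order = order))
  }

  opt <- stats::optim(start, rss, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 5000))
  ## simplex restart from the first solution polishes the optimum
  opt <- stats::optim(opt$par, rss, method = "Nelder-Mead",
                      control = list(reltol = reltol, maxit = 5000))
  ab <- pmax(opt$par, 0)
  list(alpha = unname(ab[1]), beta = unname(ab[2]), rss = opt$value,
       order = order)
}

#' Fit a linear-quadratic curve from a CSV table
#'
#' Reads a `(dose, fraction)` CSV, fits with [fit_lq()], and optionally
#' writes the `(alpha, beta, rss)` result as JSON.
#'
#' @param path CSV with columns `dose`, `fraction`.
#' @param out optional JSON output path.
#' @param ... passed to [fit_lq()].
#' @return the [fit_lq()] result, invisibly if `out` is given.
#' @export
fit_lq_file <- function(path, out = NULL, ...) {
  tab <- utils::read.csv(path)
  if (!all(c("dose", "fraction") %in% names(tab)))
    stop("survival table must have columns dose, fraction", call. = FALSE)
  fit <- fit_lq(tab$dose, tab$fraction, ...)
  if (!is.null(out)) {
    jsonlite::write_json(fit, out, auto_unbox = TRUE, digits = NA)
    return(invisible(fit))
  }
  fit
}
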