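#' Linear-quadratic cell survival
#'
#' Surviving fraction `exp(-alpha*DR - beta*DR^2)` of a cell population
#' after an absorbed dose `DR` (Gy). `beta = 0` gives a pure-exponential
#' curve.
#'
#' @param DR dose in Gy (>= 0); vectorised.
#' @param coeff list or named vector with `alpha` (per Gy, >= 0) and
#'   `beta` (per Gy^2, >= 0).
#' @return surviving fraction in `(0, 1]`.
#' @export
lq_survival_fraction <- function(DR, coeff) {
  alpha <- coeff[["alpha"]]; beta <- coeff[["beta"]]
  stopifnot(is.numeric(DR), is.numeric(alpha), is.numeric(beta))
  if (any(DR < 0)) stop("dose must be non-negative", call. = FALSE)
  if (alpha < 0 || beta < 0)
    stop("LQ coefficients must be non-negative", call. = FALSE)
  exp(-alpha * DR - beta * DR^2)
}

#' Default linear-quadratic coefficients
#'
#' The survival-curve coefficients used for the surrounding-tissue split:
#' monocytes/macrophages (alpha = 0.1826, beta = 0), T lymphocytes
#' (0.3481, 0.0723) and fibroblasts (0.5084, 0.0549).
#'
#' @return data.frame with columns `cell_type`, `alpha`, `beta`.
#' @export
rci_default_lq_table <- function() {
  data.frame(
    cell_type = c("monocyte", "lymphocyte", "fibroblast"),
    alpha = c(0.1826, 0.3481, 0.5084),
    beta = c(0, 0.0723, 0.0549),
    stringsAsFactors = FALSE
  )
}

#' Read a linear-quadratic coefficient table
#'
#' CSV with columns `cell_type`, `alpha`, `beta`; must contain rows for
#' `monocyte`, `lymphocyte` and `fibroblast`.
#'
#' @param path CSV path; `NULL` returns the default table.
#' @return data.frame as [rci_default_lq_table()].
#' @export
read_lq_table <- function(path = NULL) {
  if (is.null(path)) return(rci_default_lq_table())
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_type", "alpha", "beta")
  if (!all(need %in% names(tab)))
    stop("LQ table must have columns cell_type, alpha, beta", call. = FALSE)
  missing <- setdiff(c("monocyte", "lymphocyte", "fibroblast"),
                     tab$cell_type)
  if (length(missing))
    stop("LQ table is missing cell type(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tab
}

.lq_row <- function(tab, type) {
  r <- tab[tab$cell_type == type, , drop = FALSE][1, ]
  list(alpha = r$alpha, beta = r$beta)
}

#' Resting steady-state levels in the surrounding tissue
#'
#' Healed-state totals of the tissue-resident populations fed from the
#' bloodstream: monocytes `smr/dmr_ud`, lymphocytes `slr/dlr_ud`, and
#' fibroblasts `sf/(ksttb_ud + dfr_ud)` (influx balanced against decay plus
#' recruitment to the wound). These are the fixed points of the
#' surrounding-tissue equations with all wound populations at zero.
#'
#' @param params `rci_params` vector.
#' @return named list with `M_st_0`, `L_st_0`, `F_st_0`, all > 0.
#' @export
resting_steady_levels <- function(params) {
  p <- validate_params(params)
  denF <- p[["ksttb_ud"]] + p[["dfr_ud"]]
  if (p[["dmr_ud"]] <= 0 || p[["dlr_ud"]] <= 0 || denF <= 0)
    stop("infeasible parameters: steady-state denominators must be positive",
         call. = FALSE)
  list(M_st_0 = p[["smr"]] / p[["dmr_ud"]],
       L_st_0 = p[["slr"]] / p[["dlr_ud"]],
       F_st_0 = p[["sf"]] / denF)
}

#' Surrounding-tissue initial state
#'
#' Splits each resting population between undamaged and damaged
#' compartments by its linear-quadratic surviving fraction at dose `DR`.
#' Neutrophils have no tissue-resident population and start at zero.
#'
#' @param params `rci_params` vector.
#' @param DR dose in Gy.
#' @param lq_table coefficient table as [rci_default_lq_table()].
#' @return named numeric vector of the seven surrounding-tissue states.
#' @export
surrounding_initial_state <- function(params, DR,
                                      lq_table = rci_default_lq_table()) {
  if (DR < 0) stop("dose must be non-negative", call. = FALSE)
  lev <- resting_steady_levels(params)
  sM <- lq_survival_fraction(DR, .lq_row(lq_table, "monocyte"))
  sL <- lq_survival_fraction(DR, .lq_row(lq_table, "lymphocyte"))
  sF <- lq_survival_fraction(DR, .lq_row(lq_table, "fibroblast"))
  c(N_st_ud = 0,
    M_st_ud = lev$M_st_0 * sM, M_st_d = lev$M_st_0 * (1 - sM),
    F_st_ud = lev$F_st_0 * sF, F_st_d = lev$F_st_0 * (1 - sF),
    L_st_ud = lev$L_st_0 * sL, L_st_d = lev$L_st_0 * (1 - sL))
}

#' Piecewise thermal-fluence-to-damage map
#'
#' Coefficients of the quadratic core `q(f) = a f^2 + b f + c` together
#' with the branch boundaries and multipliers of the piecewise map from
#' thermal fluence (J/cm^2) to the initial damage/debris level: zero below
#' `f_low`; `scale_mid * q(f)` on `[f_low, f_high]` (epidermal damage,
#' reaching the superficial anchor 0.1 at `f_high`); and
#' `scale_high * q(f) + offset_high` above `f_high` (dermal damage). The
#' default `scale_high = 80/3` makes the map continuous at `f_high` to
#' within 3e-5.
#'
#' @param a,b,c quadratic coefficients.
#' @param f_low,f_high branch boundaries in J/cm^2 (`f_low < f_high`).
#' @param scale_mid,scale_high,offset_high branch multipliers and offset.
#' @return an `rci_fluence_map` list.
#' @export
rci_fluence_map <- function(a = -8.9795e-5, b = 7.2019e-3, c = -3.1822e-2,
                            f_low = 5.016, f_high = 5.168,
                            scale_mid = 100 / 3, scale_high = 80 / 3,
                            offset_high = 0.02) {
  if (f_low >= f_high) stop("f_low must be below f_high", call. = FALSE)
  structure(list(a = a, b = b, c = c, f_low = f_low, f_high = f_high,
                 scale_mid = scale_mid, scale_high = scale_high,
                 offset_high = offset_high),
            class = "rci_fluence_map")
}

#' Map thermal fluence to the initial damage level
#'
#' @param f thermal fluence in J/cm^2 (>= 0); vectorised.
#' @param map an [rci_fluence_map()].
#' @return unitless initial damage/debris level (0 below threshold,
#'   unclipped above; the most severe fluence considered, 19 J/cm^2,
#'   exceeds 0.9).
#' @export
fluence_to_damage <- function(f, map = rci_fluence_map()) {
  stopifnot(is.numeric(f))
  if (any(f < 0)) stop("fluence must be non-negative", call. = FALSE)
  q <- map$a * f^2 + map$b * f + map$c
  out <- ifelse(f < map$f_low, 0,
         ifelse(f <= map$f_high, map$scale_mid * q,
                map$scale_high * q + map$offset_high))
  unname(out)
}

#' Maximum initial damage level
#'
#' The damage level at the most severe thermal fluence considered,
#' 19 J/cm^2; used as the scale for pathogen seeding.
#'
#' @param map an [rci_fluence_map()].
#' @return unitless damage level.
#' @export
rci_dam_max <- function(map = rci_fluence_map()) fluence_to_damage(19, map)

#' Initial pathogen load
#'
#' Zero for burn-only scenarios; for irradiated scenarios the initial load
#' scales linearly between 0 (no thermal injury) and the carrying capacity
#' `P_inf` (the most severe burn considered, `Dam0 = Dam_max`).
#'
#' @param Dam0 initial damage level, in `[0, Dam_max]`.
#' @param DR dose in Gy.
#' @param params `rci_params` vector (for `P_inf`).
#' @param Dam_max scaling anchor; defaults to [rci_dam_max()].
#' @return initial pathogen level.
#' @export
pathogen_initial <- function(Dam0, DR, params, Dam_max = rci_dam_max()) {
  p <- validate_params(params)
  if (Dam0 < 0 || Dam0 > Dam_max)
    stop("Dam0 must lie in [0, Dam_max]", call. = FALSE)
  if (DR < 0) stop("dose must be non-negative", call. = FALSE)
  if (DR == 0) 0 else p[["P_inf"]] * Dam0 / Dam_max
}

#' Build the full initial state for an exposure
#'
#' Damage and debris start at the fluence-mapped level (or at 0.1 / 0.9 for
#' the named severities `"superficial"` / `"superficial-partial"`); all
#' wound cell populations start at zero (thermal injury is assumed to leave
#' no viable cells at the burn site); the surrounding tissue is split by
#' linear-quadratic survival at the dose; pathogen is seeded by
#' [pathogen_initial()].
#'
#' @param exposure an [rci_exposure()].
#' @param params `rci_params` vector.
#' @param lq_table LQ coefficient table.
#' @param map an [rci_fluence_map()].
#' @return named 16-component state vector.
#' @export
build_initial_state <- function(exposure, params,
                                lq_table = rci_default_lq_table(),
                                map = rci_fluence_map()) {
  stopifnot(inherits(exposure, "rci_exposure"))
  Dam0 <- if (!is.null(exposure$severity)) {
    switch(exposure$severity, "superficial" = 0.1,
           "superficial-partial" = 0.9)
  } else {
    fluence_to_damage(exposure$f, map)
  }
  st <- surrounding_initial_state(params, exposure$DR, lq_table)
  P0 <- pathogen_initial(Dam0, exposure$DR, params, rci_dam_max(map))
  y0 <- c(st,
          Dam_tb = Dam0, Deb_tb = Dam0,
          N_tb = 0, M1_tb = 0, M2_tb = 0, F_tb = 0,
          L1_tb = 0, L2_tb = 0, P_tb = P0)
  y0[rci_state_names()]
}
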