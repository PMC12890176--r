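#' @useDynLib rciburn
"_PACKAGE"

# Canonical parameter order. The compiled right-hand side indexes the
# parameter vector positionally, so this vector is the single source of
# truth for ordering; do not reorder without updating src/rci_derivs.c.
.rci_param_groups <- list(
  inhibition = c("N1_inf", "N2_inf", "M11_inf", "M12_inf", "M2_inf",
                 "F_inf", "L21_inf", "L22_inf", "Deb_dam_inf",
                 "Deb_H", "N_H", "M1_H"),
  radiation  = c("gamma_n", "gamma_m", "gamma_l", "gamma_f",
                 "omega_m2", "omega_f", "omega_dam"),
  damage_debris = c("kdn", "kdm1", "rho_dam", "kdf",
                    "kdnp", "kdm1p", "kdm2p", "ddeb"),
  neutrophil = c("snr", "dnr", "knd", "knp", "knn",
                 "knm1p", "knm2p", "dn"),
  macrophage = c("smr", "dmr_ud", "dmr_d", "km1d", "km1p", "km1n",
                 "km1m1", "km1l1", "km2m1", "km2m2", "km2l2",
                 "theta_m1m2", "dm1", "dm2"),
  lymphocyte = c("slr", "dlr_ud", "dlr_d", "kl1", "kl2", "dl"),
  fibroblast = c("sf", "ksttb_ud", "ksttb_d", "kf",
                 "alpha_dam", "alpha_m2", "dfr_ud", "dfr_d", "df"),
  pathogen   = c("kpg", "P_inf", "kpb", "sb", "mu_b", "kbp",
                 "kpn", "kpm1", "kpm2")
)

#' Canonical parameter names
#'
#' Names of all rate, saturation and inhibition constants of the model, in
#' the fixed order used by the compiled right-hand side.
#'
#' @param group optional group name (one of `names(rci_param_groups())`);
#'   if given, only that group's parameter names are returned.
#' @return character vector of parameter names.
#' @export
rci_param_names <- function(group = NULL) {
  if (is.null(group)) return(unname(unlist(.rci_param_groups)))
  if (!group %in% names(.rci_param_groups))
    stop("unknown parameter group: ", group, call. = FALSE)
  .rci_param_groups[[group]]
}

#' Parameter groups
#'
#' @return named list mapping group name to parameter names.
#' @export
rci_param_groups <- function() .rci_param_groups

# Structural Hill exponent of the collateral-damage terms; a fixed model
# constant, not a sampled parameter.
.rci_hill_n <- 6L

#' Hill exponent of the collateral-damage terms
#'
#' The steep Hill nonlinearity through which activated neutrophils and M1
#' macrophages generate collateral damage and debris uses a fixed integer
#' exponent of 6. It is a structural constant of the model.
#'
#' @return integer, 6.
#' @export
rci_hill_exponent <- function() .rci_hill_n

#' Baseline parameter set
#'
#' The package's shipped baseline: the midpoint of every parameter's default
#' sampling range (see [rci_default_ranges()]). Units are per hour (rates),
#' per Gy-hour (radiation delay constants `gamma_*`) or model cell/level
#' units (saturation constants). The baseline satisfies the healed-state
#' stability screen and the burn-only healing-time calibration windows; see
#' the methods vignette for how it was chosen.
#'
#' @return a named numeric `rci_params` vector with one entry per parameter.
#' @export
rci_default_params <- function() {
  p <- c(
    ## inhibition saturations (model units)
    N1_inf = 1, N2_inf = 1.5, M11_inf = 1, M12_inf = 1.5, M2_inf = 0.2,
    F_inf = 1, L21_inf = 0.2, L22_inf = 1, Deb_dam_inf = 0.5,
    Deb_H = 0.5, N_H = 0.08, M1_H = 0.12,
    ## radiation-related (gamma_*: per Gy-hour; omega_*: model units)
    gamma_n = 0.02, gamma_m = 0.02, gamma_l = 0.02, gamma_f = 0.02,
    omega_m2 = 0.3, omega_f = 0.5, omega_dam = 0.5,
    ## damage / debris (per hour)
    kdn = 0.004, kdm1 = 0.002, rho_dam = 0.0085, kdf = 0.028,
    kdnp = 0.2, kdm1p = 0.2, kdm2p = 0.2, ddeb = 0.01,
    ## neutrophils
    snr = 0.5, dnr = 0.1, knd = 0.15, knp = 0.1, knn = 0.02,
    knm1p = 0.4, knm2p = 0.4, dn = 0.07,
    ## monocytes / macrophages
    smr = 0.05, dmr_ud = 0.05, dmr_d = 0.015,
    km1d = 0.05, km1p = 0.08, km1n = 0.08, km1m1 = 0.02, km1l1 = 0.02,
    km2m1 = 0.04, km2m2 = 0.03, km2l2 = 0.04,
    theta_m1m2 = 0.5, dm1 = 0.06, dm2 = 0.06,
    ## T lymphocytes
    slr = 0.05, dlr_ud = 0.05, dlr_d = 0.05,
    kl1 = 0.03, kl2 = 0.03, dl = 0.03,
    ## fibroblasts
    sf = 0.02, ksttb_ud = 0.005, ksttb_d = 0.004, kf = 0.01,
    alpha_dam = 0.013, alpha_m2 = 0.05, dfr_ud = 0.015, dfr_d = 0.008,
    df = 0.02,
    ## pathogen
    kpg = 0.08, P_inf = 1, kpb = 0.1, sb = 1, mu_b = 1, kbp = 10,
    kpn = 0.3, kpm1 = 0.15, kpm2 = 0.15
  )
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks that a named numeric vector contains exactly the canonical
#' parameters (unknown or missing names are an error) and that every value
#' is finite and strictly positive.
#'
#' @param params named numeric vector.
#' @return the parameter vector, reordered canonically, with class
#'   `rci_params`.
#' @export
validate_params <- function(params) {
  nm <- rci_param_names()
  if (is.list(params)) params <- unlist(params)
  if (is.null(names(params)))
    stop("parameter set must be named", call. = FALSE)
  unknown <- setdiff(names(params), nm)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(nm, names(params))
  if (length(missing))
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  p <- params[nm]
  if (any(!is.finite(p)))
    stop("non-finite parameter value(s): ",
         paste(nm[!is.finite(p)], collapse = ", "), call. = FALSE)
  if (any(p <= 0))
    stop("non-positive parameter value(s): ",
         paste(nm[p <= 0], collapse = ", "), call. = FALSE)
  structure(p, class = "rci_params")
}

#' Default sampling ranges
#'
#' Per-parameter (min, max) bounds for the Latin-hypercube feasibility
#' stage. Each range spans 50% below to 50% above its midpoint, so the
#' midpoint of every range is the shipped baseline value
#' ([rci_default_params()]); parameters that the screen leaves fixed are
#' pinned to exactly that midpoint.
#'
#' @param spread half-width of each range relative to the baseline
#'   (default 0.5, i.e. baseline times `[0.5, 1.5]`).
#' @return a data.frame with columns `parameter`, `min`, `max`.
#' @export
rci_default_ranges <- function(spread = 0.5) {
  stopifnot(is.numeric(spread), length(spread) == 1L, spread > 0, spread < 1)
  p <- rci_default_params()
  data.frame(parameter = names(p),
             min = unname(p) * (1 - spread),
             max = unname(p) * (1 + spread),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Estimate / fix split of the parameters
#'
#' The model's global sensitivity screen classifies parameters as highly
#' influential ("estimate": resampled in the second feasibility stage) or
#' non-influential ("fix": pinned to the midpoint of the initial range).
#' This function returns the shipped default split used by the pipeline
#' configuration; [classify_parameters()] computes a split from a
#' sensitivity report.
#'
#' @return list with character vectors `estimate` and `fix`.
#' @export
rci_default_split <- function() {
  estimate <- c("N1_inf", "M11_inf", "M2_inf",
                "gamma_n", "gamma_m", "omega_f",
                "kdnp", "kdm1p",
                "knd", "snr", "knm1p", "dn",
                "km1d", "km1n", "km2m1", "smr", "dmr_ud", "dm1", "km1p",
                "kl1",
                "kpg", "P_inf", "kpb", "sb", "kbp", "kpn")
  list(estimate = estimate,
       fix = setdiff(rci_param_names(), estimate))
}

#' Read a parameter set from a YAML or JSON config file
#'
#' The file must contain a flat mapping of parameter name to value; unknown
#' keys are rejected.
#'
#' @param path file path; format inferred from the extension
#'   (`.yml`/`.yaml`/`.json`).
#' @return validated `rci_params` vector.
#' @export
read_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  if (!is.list(x) && is.null(names(x)))
    stop("parameter file must be a flat name: value mapping", call. = FALSE)
  validate_params(unlist(x))
}

#' Write a parameter set to a YAML or JSON config file
#'
#' @param params `rci_params` vector (validated on the way out).
#' @param path destination; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  p <- validate_params(params)
  ext <- tolower(tools::file_ext(path))
  lst <- as.list(unclass(p))
  switch(ext,
    yml = , yaml = yaml::write_yaml(lst, path, precision = 15),
    json = jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA),
    stop("unsupported parameter file extension: .", ext, call. = FALSE))
  invisible(path)
}

#' Representative parameter set shipped with the package
#'
#' The accepted parameter set closest (weighted mean squared error) to the
#' temporal mean trajectory of the accepted cohort, produced by the
#' package's own feasibility pipeline at the seed recorded alongside it
#' (see `inst/extdata/representative_params.json`).
#'
#' @return validated `rci_params` vector.
#' @export
rci_representative_params <- function() {
  path <- system.file("extdata", "representative_params.json",
                      package = "rciburn", mustWork = TRUE)
  read_params(path)
}
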