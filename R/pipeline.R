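#' Canonical scenario bundle
#'
#' The simulation scenarios the model is routinely exercised on: both burn
#' severities crossed with prompt doses of 0, 1, 5, 7 and 14 Gy. Burn-only
#' scenarios carry no initial pathogen.
#'
#' @param horizon_hours simulation horizon attached to each scenario.
#' @return list of scenario lists (`severity`, `dose_Gy`, `horizon_hours`).
#' @export
scenario_fixtures <- function(horizon_hours = 336) {
  sev <- c("superficial", "superficial-partial")
  doses <- c(0, 1, 5, 7, 14)
  out <- list()
  for (s in sev) for (d in doses)
    out[[length(out) + 1L]] <- list(severity = s, dose_Gy = d,
                                    horizon_hours = horizon_hours)
  out
}

#' Read a scenario config
#'
#' YAML/JSON mapping with either `severity` or `fluence`, plus `dose_Gy`
#' and `horizon_hours`.
#'
#' @param path config path.
#' @return list with `exposure` (an [rci_exposure()]) and `horizon_hours`.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path),
    stop("unsupported scenario file extension: .", ext, call. = FALSE))
  for (key in c("dose_Gy", "horizon_hours"))
    if (is.null(x[[key]]))
      stop("scenario config is missing key: ", key, call. = FALSE)
  expo <- if (!is.null(x$severity)) {
    rci_exposure(severity = x$severity, DR = x$dose_Gy)
  } else if (!is.null(x$fluence)) {
    rci_exposure(f = x$fluence, DR = x$dose_Gy)
  } else {
    stop("scenario config needs `severity` or `fluence`", call. = FALSE)
  }
  list(exposure = expo, horizon_hours = x$horizon_hours)
}

#' Run the sampling / sensitivity / selection pipeline
#'
#' Executes the stages in order: Latin-hypercube sampling over the initial
#' ranges; the stability and feasibility screens; bound refinement from
#' the accepted sets; optionally the eFAST/MeFAST screen on the refined
#' bounds with estimate/fix classification followed by a resampling stage
#' in which non-influential parameters are pinned to their baseline; and
#' representative-set selection from the final accepted cohort. All
#' artifacts are written under `out_dir` and listed in the returned
#' manifest.
#'
#' @param config nested list with sections `sampling` (`n_samples`, `seed`,
#'   optional `spread`, optional `estimate`), optional `sensitivity`
#'   (`enabled`, `NS`, `NR`, `doses`, `days`, `variables`, `n_resample`),
#'   `events` (threshold overrides) and `solver` (tolerance overrides);
#'   may be a YAML/JSON path.
#' @param out_dir artifact directory.
#' @return an `rci_manifest` list: config hash, seeds, stage artifact
#'   paths, acceptance counts, the representative parameter set and
#'   timestamps.
#' @export
run_pipeline <- function(config, out_dir = tempfile("rci_pipeline_")) {
  if (is.character(config) && length(config) == 1L)
    config <- switch(tolower(tools::file_ext(config)),
                     yml = , yaml = yaml::read_yaml(config),
                     json = jsonlite::fromJSON(config),
                     stop("unsupported config file type", call. = FALSE))
  for (key in c("sampling"))
    if (is.null(config[[key]]))
      stop("pipeline config is missing section: ", key, call. = FALSE)
  for (key in c("n_samples", "seed"))
    if (is.null(config$sampling[[key]]))
      stop("pipeline config is missing key: sampling$", key, call. = FALSE)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  thresholds <- do.call(rci_thresholds,
                        if (is.null(config$events)) list() else config$events)
  solver <- do.call(rci_solver_options,
                    c(list(dt = 0.25),
                      if (is.null(config$solver)) list() else config$solver))
  spread <- if (is.null(config$sampling$spread)) 0.5 else
    config$sampling$spread
  estimate <- if (is.null(config$sampling$estimate))
    rci_default_split()$estimate else config$sampling$estimate

  manifest <- list(config_hash = cfg_hash, out_dir = out_dir,
                   seed = config$sampling$seed,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                   stages = list())

  ## stage 1: LHS + screens
  design <- rci_design(rci_default_ranges(spread),
                       n_samples = config$sampling$n_samples,
                       seed = config$sampling$seed, estimate = estimate)
  samples <- lhs_sample(design)
  screen <- screen_samples(samples, thresholds, solver)
  screen_path <- file.path(out_dir, "screen_manifest.csv")
  utils::write.csv(cbind(screen, samples), screen_path, row.names = FALSE)
  manifest$stages$screen <- list(path = screen_path,
                                 n_samples = nrow(samples),
                                 n_accepted = sum(screen$accepted))
  accepted <- samples[screen$accepted, , drop = FALSE]
  if (nrow(accepted) == 0L) {
    manifest$status <- "no accepted sets"
    .write_manifest(manifest, out_dir)
    return(invisible(structure(manifest, class = "rci_manifest")))
  }

  ## stage 2: refined bounds
  bounds <- refine_bounds(accepted)
  bounds_path <- file.path(out_dir, "refined_bounds.csv")
  utils::write.csv(bounds, bounds_path, row.names = FALSE)
  manifest$stages$refine <- list(path = bounds_path)

  ## stage 3 (optional): sensitivity screen + classification + resampling
  sens_cfg <- config$sensitivity
  if (!is.null(sens_cfg) && isTRUE(sens_cfg$enabled)) {
    baseline <- rci_default_params()
    vars <- if (is.null(sens_cfg$variables)) c("Dam_tb", "Deb_tb", "N_tb")
      else sens_cfg$variables
    days <- if (is.null(sens_cfg$days)) c(1, 3, 7) else sens_cfg$days
    doses <- if (is.null(sens_cfg$doses)) c(1, 7, 14) else sens_cfg$doses
    sdesign <- rci_sens_design(
      NS = if (is.null(sens_cfg$NS)) 65 else sens_cfg$NS,
      NR = if (is.null(sens_cfg$NR)) 4 else sens_cfg$NR,
      doses = doses, output_days = days,
      seed = config$sampling$seed + 1L)
    sample_pars <- bounds[!attr(bounds, "degenerate") &
                            bounds$parameter %in% estimate, , drop = FALSE]
    readout <- rci_model_readout(baseline, variables = vars, days = days,
                                 solver = solver)
    report <- efast_indices(sdesign, sample_pars, readout)
    report <- mefast_tests(report)
    sens_paths <- write_sensitivity_report(report,
                                           file.path(out_dir, "sensitivity"))
    cls <- classify_parameters(report)
    manifest$stages$sensitivity <- list(paths = as.list(sens_paths),
                                        estimate = cls$estimate,
                                        fix = cls$fix)
    ## stage 4: resample the influential parameters over refined bounds
    n2 <- if (is.null(sens_cfg$n_resample)) config$sampling$n_samples
      else sens_cfg$n_resample
    rdesign <- rci_design(bounds, n_samples = n2,
                          seed = config$sampling$seed + 2L,
                          estimate = cls$estimate)
    samples2 <- lhs_sample(rdesign)
    screen2 <- screen_samples(samples2, thresholds, solver)
    res_path <- file.path(out_dir, "resample_manifest.csv")
    utils::write.csv(cbind(screen2, samples2), res_path, row.names = FALSE)
    manifest$stages$resample <- list(path = res_path,
                                     n_accepted = sum(screen2$accepted))
    if (any(screen2$accepted))
      accepted <- samples2[screen2$accepted, , drop = FALSE]
  }

  ## final stage: representative set
  rep_sel <- select_representative(accepted, solver = solver)
  rep_path <- file.path(out_dir, "representative_params.json")
  write_params(rep_sel$params, rep_path)
  manifest$stages$representative <- list(path = rep_path,
                                         index = rep_sel$index,
                                         mse = min(rep_sel$mse),
                                         r2 = rep_sel$r2[rep_sel$index])
  manifest$representative <- as.list(unclass(rep_sel$params))
  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  .write_manifest(manifest, out_dir)
  invisible(structure(manifest, class = "rci_manifest"))
}

.write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
}
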