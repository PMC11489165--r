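#' Load and validate an assessment configuration
#'
#' The configuration bundles everything a full assessment run needs:
#' per-population kinetic parameters, the consumer-product scenario
#' library, the point-of-departure entries (BMDL/BMDU feeding the TDI and
#' the PoD used for margins of safety), the assessment-factor config, the
#' LOQ policy, reference values and the seed. Validation is strict:
#' unknown keys and missing required fields are errors naming the field
#' path.
#'
#' @param path Path to a YAML configuration; default the packaged
#'   `assessment_default.yaml`.
#' @return A validated list of class `assessment_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "assessment_default.yaml",
                        package = "phthalrisk", mustWork = TRUE)
  cf <- yaml::read_yaml(path)

  top_known <- c("populations", "scenarios", "pod", "tdi", "loq_policy",
                 "reference", "seed")
  unknown <- setdiff(names(cf), top_known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in c("populations", "pod", "tdi", "seed"))
    if (is.null(cf[[k]])) stop("missing configuration section: ", k)

  pop_fields <- c("q_u", "f_ue", "mw_parent", "mw_metabolite", "f_ue_sed")
  for (pn in names(cf$populations)) {
    p <- cf$populations[[pn]]
    unknown <- setdiff(names(p), pop_fields)
    if (length(unknown))
      stop("populations.", pn, ": unknown key(s) ",
           paste(unknown, collapse = ", "))
    for (f in c("q_u", "f_ue", "mw_parent", "mw_metabolite"))
      if (is.null(p[[f]]))
        stop("populations.", pn, ".", f, " is required")
  }

  pod_fields <- c("bmdl", "bmdu", "pod_for_mos")
  unknown <- setdiff(names(cf$pod), pod_fields)
  if (length(unknown))
    stop("pod: unknown key(s) ", paste(unknown, collapse = ", "))
  for (f in pod_fields)
    if (is.null(cf$pod[[f]])) stop("pod.", f, " is required")
  if (!(cf$pod$bmdl > 0 && cf$pod$bmdu > cf$pod$bmdl))
    stop("pod: need 0 < bmdl < bmdu")

  tdi_fields <- c("coverage", "bw_animal", "bw_human", "deterministic_af",
                  "af_config")
  unknown <- setdiff(names(cf$tdi), tdi_fields)
  if (length(unknown))
    stop("tdi: unknown key(s) ", paste(unknown, collapse = ", "))
  cf$tdi$coverage <- cf$tdi$coverage %||% 0.90
  cf$tdi$bw_animal <- cf$tdi$bw_animal %||% 0.2
  cf$tdi$bw_human <- cf$tdi$bw_human %||% 60
  cf$tdi$deterministic_af <- cf$tdi$deterministic_af %||% 100

  if (!is.null(cf$scenarios)) {
    sc_fields <- c("concentration_mgkg", "migration_rate")
    unknown <- setdiff(names(cf$scenarios), sc_fields)
    if (length(unknown))
      stop("scenarios: unknown key(s) ", paste(unknown, collapse = ", "))
  }
  cf$scenarios$concentration_mgkg <- cf$scenarios$concentration_mgkg %||% 16
  cf$scenarios$migration_rate <- cf$scenarios$migration_rate %||% 0.007
  cf$loq_policy <- cf$loq_policy %||% "loq_half"
  cf$reference$group_tdi_dehp <- cf$reference$group_tdi_dehp %||% 50

  structure(cf, class = "assessment_config", path = path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialise an assessment configuration back to YAML
#'
#' Round-trips losslessly with [load_config()].
#'
#' @param config An `assessment_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "assessment_config"))
  out <- unclass(config)
  attr(out, "path") <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

config_kinetics <- function(config) {
  out <- list()
  for (pn in names(config$populations)) {
    p <- config$populations[[pn]]
    out[[pn]] <- kinetic_parameters(
      q_u = p$q_u, f_ue = p$f_ue, mw_parent = p$mw_parent,
      mw_metabolite = p$mw_metabolite,
      f_ue_sed = p$f_ue_sed %||% p$f_ue, population = pn)
  }
  out
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the full assessment pipeline
#'
#' Drives the whole chain: reverse dosimetry over any supplied urine
#' tables, benchmark-dose modelling if litter-level dose-response data are
#' supplied (otherwise the configured BMDL/BMDU are used), TDI derivation
#' by the approximate probabilistic approach, scenario SEDs, forward
#' dosimetry, and the risk-characterisation report. Missing inputs skip
#' their stage with a log notice; every stage logs the parameter values it
#' used.
#'
#' @param config An `assessment_config` from [load_config()].
#' @param urine Optional: a `biomonitoring_dataset`, a path to one, or a
#'   named list of either (one per cohort); reverse dosimetry uses the
#'   `"child"` population parameters unless the list names match
#'   populations.
#' @param dose_response Optional: a `dose_response_dataset` or a path; when
#'   supplied, the fitted BMDL/BMDU replace the configured ones for the
#'   TDI stage.
#' @param n_bootstrap Bootstrap replicates for the BMD stage (default 200).
#' @param quiet Suppress log messages.
#' @return A list of class `assessment_run` with elements `report`
#'   ([build_report()] output), `tdi` (`tdi_result`), `bmd`
#'   (`bmd_estimate` or `NULL`), `intakes`, `seds` and `metadata`
#'   (including the config hash and seed).
#' @export
run_pipeline <- function(config, urine = NULL, dose_response = NULL,
                         n_bootstrap = 200, quiet = FALSE) {
  stopifnot(inherits(config, "assessment_config"))
  say <- function(...) if (!quiet) message(...)
  kin <- config_kinetics(config)
  seed <- config$seed
  say("[config] hash ", config_hash(config), ", seed ", seed)

  # -- reverse dosimetry ----------------------------------------------------
  intakes <- list()
  if (!is.null(urine)) {
    if (!is.list(urine) || inherits(urine, "data.frame"))
      urine <- list(cohort = urine)
    for (nm in names(urine)) {
      u <- urine[[nm]]
      if (is.character(u)) u <- read_biomonitoring(u)
      pop <- if (nm %in% names(kin)) nm else
        if ("child" %in% names(kin)) "child" else names(kin)[1]
      say("[reverse-dosimetry] cohort ", nm, ": n=", nrow(u),
          ", population ", pop, ", LOQ policy ", config$loq_policy)
      intakes[[nm]] <- summarize_intakes(u, kin[[pop]],
                                         loq_policy = config$loq_policy)
    }
  } else say("[reverse-dosimetry] no urine data supplied; stage skipped")

  # -- benchmark dose -------------------------------------------------------
  bmd <- NULL
  bmdl <- config$pod$bmdl
  bmdu <- config$pod$bmdu
  if (!is.null(dose_response)) {
    if (is.character(dose_response))
      dose_response <- read_dose_response(dose_response)
    say("[bmd] fitting model suite, BMR 20%, ", n_bootstrap,
        " bootstrap replicates")
    bmd <- fit_bmd_models(dose_response, bmr = 0.20,
                          n_bootstrap = n_bootstrap, seed = seed)
    bmdl <- bmd$bmdl
    bmdu <- bmd$bmdu
    say(sprintf("[bmd] BMD %.3g [%.3g, %.3g] mg/kg bw/day",
                bmd$bmd, bmdl, bmdu))
  } else say("[bmd] no dose-response data; using configured BMDL/BMDU ",
             bmdl, "/", bmdu)

  # -- TDI ------------------------------------------------------------------
  af <- who_af_defaults(bw_animal = config$tdi$bw_animal,
                        bw_human = config$tdi$bw_human,
                        config = config$tdi$af_config)
  tdi <- approximate_probabilistic_tdi(
    bmdl, bmdu, af_config = af, coverage = config$tdi$coverage,
    deterministic_af = config$tdi$deterministic_af)
  say(sprintf(
    "[tdi] approximate probabilistic %.3g (interval %.3g-%.3g), deterministic %.3g ug/kg bw/day",
    tdi$tdi, tdi$lower, tdi$upper, tdi$deterministic_tdi))

  # -- scenario SEDs --------------------------------------------------------
  lib <- scenario_library(concentration = config$scenarios$concentration_mgkg,
                          m_r = config$scenarios$migration_rate)
  seds <- list(
    adult = lapply(lib[c("sunscreen_adult", "lip_balm_adult",
                         "pump_spray_adult")], sed),
    child = lapply(lib[c("sunscreen_child", "lip_balm_child",
                         "pump_spray_child", "sandals_child")], sed)
  )
  for (pop in names(seds))
    say("[sed] ", pop, ": ",
        paste(sprintf("%s=%.3g", vapply(seds[[pop]], `[[`, "", "label"),
                      vapply(seds[[pop]], `[[`, 0, "sed")), collapse = ", "))

  # -- report ---------------------------------------------------------------
  wf <- potency_weighting_factor(config$reference$group_tdi_dehp, tdi$tdi)
  report <- build_report(
    intakes = intakes, seds = seds, kinetics = kin, tdi = tdi,
    pod_ug = config$pod$pod_for_mos * 1000, weighting_factor = wf,
    seed = seed)

  structure(list(report = report, tdi = tdi, bmd = bmd, intakes = intakes,
                 seds = seds,
                 metadata = list(config_hash = config_hash(config),
                                 seed = seed)),
            class = "assessment_run")
}
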