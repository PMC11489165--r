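#' Exposure as a percentage of the tolerable daily intake
#'
#' @param exposure Exposure estimate, ug/kg bw/day.
#' @param tdi Tolerable daily intake, ug/kg bw/day (> 0).
#' @return Percent of TDI.
#' @examples
#' fraction_of_tdi(2.68, 63)  # ~4.3 %
#' @export
fraction_of_tdi <- function(exposure, tdi) {
  if (any(tdi <= 0)) stop("tdi must be positive")
  if (any(exposure < 0)) stop("exposure must be non-negative")
  100 * exposure / tdi
}

#' Margin of safety relative to the point of departure
#'
#' @param pod Point of departure, ug/kg bw/day.
#' @param exposure Exposure estimate, ug/kg bw/day.
#' @return Dimensionless MoS (`pod / exposure`); `Inf` with a warning for
#'   zero exposure.
#' @examples
#' margin_of_safety(14700, 4.5)  # ~3267
#' @export
margin_of_safety <- function(pod, exposure) {
  if (any(pod <= 0)) stop("pod must be positive")
  if (any(exposure < 0)) stop("exposure must be non-negative")
  if (any(exposure == 0)) {
    warning("zero exposure: margin of safety is unbounded")
  }
  ifelse(exposure == 0, Inf, pod / exposure)
}

#' Convert an exposure to DEHP equivalents
#'
#' Multiplies the exposure by the substance's potency weighting factor so
#' it can be compared with the EFSA group TDI of 50 ug DEHP
#' equivalents/kg bw/day.
#'
#' @param exposure Exposure, ug/kg bw/day.
#' @param weighting_factor Potency weighting factor (> 0), see
#'   [potency_weighting_factor()].
#' @return Exposure in ug DEHP equivalents/kg bw/day.
#' @export
dehp_equivalents <- function(exposure, weighting_factor) {
  if (any(weighting_factor <= 0)) stop("weighting_factor must be positive")
  if (any(exposure < 0)) stop("exposure must be non-negative")
  exposure * weighting_factor
}

#' Render a value at display precision
#'
#' All computation in the package is at full floating precision; rounding
#' happens only when a report is rendered. Reported values use significant
#' figures matching the source tables (2 for SEDs, 3 elsewhere).
#'
#' @param x Numeric vector.
#' @param digits Significant figures.
#' @return Rounded numeric vector.
#' @export
render_signif <- function(x, digits = 3) signif(x, digits)

#' Assemble a risk-characterisation report
#'
#' Combines intake summaries, scenario SEDs, the TDI and the PoD into the
#' two standard report tables: an intake table (percentiles of daily intake
#' with their percent of TDI) and a scenario table (per-scenario SED, the
#' urinary metabolite concentration predicted by forward dosimetry, percent
#' of TDI and margin of safety). Scenario SEDs are displayed at 2
#' significant figures and the aggregate rows are sums of the displayed
#' pathway values, mirroring how aggregated doses are reported in
#' assessment practice; full-precision values are kept alongside.
#'
#' @param intakes Named list of [summarize_intakes()] results (may be
#'   empty).
#' @param seds Named list of population -> list of `sed_result` objects.
#' @param kinetics Named list of population -> [kinetic_parameters()] for
#'   forward dosimetry; names must cover those of `seds`.
#' @param tdi TDI, ug/kg bw/day (a number or a `tdi_result`).
#' @param pod_ug Point of departure for the MoS, ug/kg bw/day.
#' @param weighting_factor Potency weighting factor for DEHP equivalents
#'   (default `NULL`: column omitted).
#' @param seed Seed recorded in the metadata (reports must regenerate
#'   byte-identically from the same inputs).
#' @return An object of class `risk_report`: list with `intake_table`,
#'   `scenario_table`, `aggregate_table` and `metadata`.
#' @export
build_report <- function(intakes = list(), seds = list(), kinetics = list(),
                         tdi, pod_ug, weighting_factor = NULL, seed = NA) {
  if (inherits(tdi, "tdi_result")) tdi <- tdi$tdi
  if (!(is.numeric(tdi) && tdi > 0)) stop("tdi must be a positive number")
  if (!(is.numeric(pod_ug) && pod_ug > 0)) stop("pod must be positive")
  if (length(seds)) {
    missing_kin <- setdiff(names(seds), names(kinetics))
    if (length(missing_kin))
      stop("no kinetic parameters for population(s): ",
           paste(missing_kin, collapse = ", "))
  }

  intake_rows <- list()
  for (nm in names(intakes)) {
    s <- intakes[[nm]]
    qs <- c(s$quantiles, maximum = s$max)
    intake_rows[[nm]] <- data.frame(
      cohort = nm, statistic = names(qs), intake_ugkgday = unname(qs),
      percent_of_tdi = fraction_of_tdi(unname(qs), tdi),
      n = s$n, loq_policy = s$loq_policy, stringsAsFactors = FALSE)
  }
  intake_table <- if (length(intake_rows))
    do.call(rbind, c(intake_rows, make.row.names = FALSE)) else
    data.frame()

  scen_rows <- list()
  agg_rows <- list()
  for (pop in names(seds)) {
    kp <- kinetics[[pop]]
    rs <- seds[[pop]]
    sed_vals <- vapply(rs, function(r) r$sed, numeric(1))
    sed_disp <- render_signif(sed_vals, 2)
    scen_rows[[pop]] <- data.frame(
      population = pop,
      scenario = vapply(rs, function(r) r$label, character(1)),
      route = vapply(rs, function(r) r$route, character(1)),
      sed_ugkgday = sed_vals,
      sed_display = sed_disp,
      # urine level derived from the displayed SED, so the table's SED and
      # urine columns are mutually consistent at report precision
      urine_ugL = forward_dosimetry(sed_disp, kp),
      urine_full_ugL = forward_dosimetry(sed_vals, kp),
      percent_of_tdi = fraction_of_tdi(sed_vals, tdi),
      mos = margin_of_safety(pod_ug, sed_vals),
      stringsAsFactors = FALSE)
    if (!is.null(weighting_factor))
      scen_rows[[pop]]$dehp_eq_ugkgday <-
        dehp_equivalents(sed_vals, weighting_factor)
    # aggregate covers the product-use pathways; migration-contact scenarios
    # (different wearer, different body weight) are reported individually
    routes <- vapply(rs, function(r) r$route, character(1))
    keep <- routes != "dermal_migration"
    if (any(keep)) {
      agg <- sum(sed_disp[keep])  # sum of displayed pathway values
      agg_rows[[pop]] <- data.frame(
        population = pop,
        aggregated_sed_ugkgday = agg,
        aggregated_sed_full = sum(sed_vals[keep]),
        urine_ugL = forward_dosimetry(agg, kp),
        percent_of_tdi = fraction_of_tdi(agg, tdi),
        stringsAsFactors = FALSE)
    }
  }
  scenario_table <- if (length(scen_rows))
    do.call(rbind, c(scen_rows, make.row.names = FALSE)) else data.frame()
  aggregate_table <- if (length(agg_rows))
    do.call(rbind, c(agg_rows, make.row.names = FALSE)) else data.frame()

  structure(list(
    intake_table = intake_table,
    scenario_table = scenario_table,
    aggregate_table = aggregate_table,
    metadata = list(tdi_ugkgday = tdi, pod_ugkgday = pod_ug,
                    weighting_factor = weighting_factor, seed = seed,
                    package_version =
                      as.character(utils::packageVersion("phthalrisk")))
  ), class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat("Risk characterisation report\n")
  cat(sprintf("  TDI %.3g ug/kg bw/day, PoD %.3g ug/kg bw/day\n",
              x$metadata$tdi_ugkgday, x$metadata$pod_ugkgday))
  if (nrow(x$intake_table)) {
    cat("\nIntake summary:\n")
    it <- x$intake_table
    it$intake_ugkgday <- signif(it$intake_ugkgday, 3)
    it$percent_of_tdi <- signif(it$percent_of_tdi, 2)
    print(it, row.names = FALSE)
  }
  if (nrow(x$scenario_table)) {
    cat("\nScenario SEDs and predicted urine levels:\n")
    st <- x$scenario_table
    st$sed_ugkgday <- NULL
    st$urine_full_ugL <- NULL
    st$urine_ugL <- signif(st$urine_ugL, 3)
    st$percent_of_tdi <- signif(st$percent_of_tdi, 2)
    st$mos <- signif(st$mos, 4)
    print(st, row.names = FALSE)
  }
  if (nrow(x$aggregate_table)) {
    cat("\nAggregated SEDs:\n")
    at <- x$aggregate_table
    at$urine_ugL <- signif(at$urine_ugL, 3)
    at$percent_of_tdi <- signif(at$percent_of_tdi, 2)
    at$aggregated_sed_full <- signif(at$aggregated_sed_full, 4)
    print(at, row.names = FALSE)
  }
  invisible(x)
}
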