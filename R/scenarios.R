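#' Define a consumer-product exposure scenario
#'
#' A scenario carries the route-specific parameters needed to compute the
#' systemic exposure dose (SED) of a product contaminant. Internal canonical
#' units: product amount g/day, contamination mg/kg product, volumes L,
#' durations min (spray boxes) or h (dermal contact), skin area cm^2,
#' migration rate ug/cm^2/h, body weight kg. With these units,
#' `m_prod [g] * c [mg/kg]` is numerically the contaminant amount in ug.
#'
#' @param route One of `"dermal"`, `"oral"`, `"inhalation"`,
#'   `"dermal_migration"`.
#' @param bw Body weight, kg.
#' @param m_prod Product amount applied/ingested/sprayed per day, g.
#' @param concentration Contaminant concentration in the product, mg/kg.
#' @param f_abs Absorption fraction for dermal/oral/migration routes, (0, 1].
#' @param f_air Airborne (droplet) fraction for a spray, [0, 1].
#' @param f_ret Lung retention fraction, [0, 1].
#' @param r_inh Inhalation rate, L/min.
#' @param v_a,v_b Volumes of the 2-Box model near field (breathing zone) and
#'   far field (room), L.
#' @param t_a,t_b Exposure durations in each box, min.
#' @param a_skin Exposed skin area, cm^2 (migration route).
#' @param m_r Migration rate, ug/cm^2/h (migration route).
#' @param t_contact Duration of dermal contact, h (migration route).
#' @param label Free-text scenario name.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(route = c("dermal", "oral", "inhalation",
                                        "dermal_migration"),
                              bw, m_prod = NULL, concentration = NULL,
                              f_abs = NULL, f_air = NULL, f_ret = NULL,
                              r_inh = NULL, v_a = NULL, v_b = NULL,
                              t_a = NULL, t_b = NULL, a_skin = NULL,
                              m_r = NULL, t_contact = NULL,
                              label = route) {
  route <- match.arg(route)
  need <- switch(route,
    dermal = c("m_prod", "concentration", "f_abs"),
    oral = c("m_prod", "concentration", "f_abs"),
    inhalation = c("m_prod", "concentration", "f_air", "f_ret", "r_inh",
                   "v_a", "v_b", "t_a", "t_b"),
    dermal_migration = c("a_skin", "m_r", "t_contact", "f_abs")
  )
  sc <- list(route = route, bw = bw, m_prod = m_prod,
             concentration = concentration, f_abs = f_abs, f_air = f_air,
             f_ret = f_ret, r_inh = r_inh, v_a = v_a, v_b = v_b, t_a = t_a,
             t_b = t_b, a_skin = a_skin, m_r = m_r, t_contact = t_contact,
             label = label)
  miss <- need[vapply(sc[need], is.null, logical(1))]
  if (length(miss))
    stop("scenario '", label, "' (route ", route, ") is missing: ",
         paste(miss, collapse = ", "))
  if (!is.finite(bw) || bw <= 0) stop("body weight must be positive")
  for (f in c("f_abs", "f_air", "f_ret")) {
    v <- sc[[f]]
    if (!is.null(v) && (!is.finite(v) || v < 0 || v > 1))
      stop(f, " must lie in [0, 1]")
  }
  pos <- c("m_prod", "r_inh", "v_a", "v_b", "a_skin")
  for (f in pos) {
    v <- sc[[f]]
    if (!is.null(v) && (!is.finite(v) || v <= 0))
      stop(f, " must be strictly positive")
  }
  nonneg <- c("concentration", "t_a", "t_b", "m_r", "t_contact")
  for (f in nonneg) {
    v <- sc[[f]]
    if (!is.null(v) && (!is.finite(v) || v < 0))
      stop(f, " must be non-negative")
  }
  structure(sc, class = "exposure_scenario")
}

new_sed_result <- function(sed, scenario, intermediates = NULL) {
  structure(list(sed = sed, route = scenario$route, bw = scenario$bw,
                 label = scenario$label, intermediates = intermediates,
                 scenario = scenario),
            class = "sed_result")
}

#' @export
print.sed_result <- function(x, ...) {
  cat(sprintf("SED [%s, %s]: %.4g ug/kg bw/day (BW %g kg)\n",
              x$label, x$route, x$sed, x$bw))
  if (!is.null(x$intermediates))
    cat(sprintf("  airborne %.4g ug, inhaled %.4g ug\n",
                x$intermediates$a_expo, x$intermediates$a_inh))
  invisible(x)
}

#' SED for direct dermal or oral product contact
#'
#' `SED = m_prod * c / BW * f_abs`, in ug/kg bw/day (g x mg/kg = ug).
#'
#' @param scenario An [exposure_scenario()] with route `"dermal"` or
#'   `"oral"`.
#' @return A `sed_result`.
#' @examples
#' sun <- exposure_scenario("dermal", bw = 60, m_prod = 18,
#'                          concentration = 300, f_abs = 0.05)
#' sed_contact(sun)$sed  # 4.5
#' @export
sed_contact <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (!scenario$route %in% c("dermal", "oral"))
    stop("sed_contact requires route dermal or oral")
  sed <- scenario$m_prod * scenario$concentration / scenario$bw *
    scenario$f_abs
  new_sed_result(sed, scenario)
}

#' Airborne contaminant amount released by a spray
#'
#' `a_expo = m_prod * c * f_air`, ug: the non-volatile fraction of the
#' sprayed product that becomes airborne as droplets.
#'
#' @param scenario An inhalation [exposure_scenario()].
#' @return Airborne amount, ug.
#' @export
spray_airborne_amount <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (scenario$route != "inhalation")
    stop("spray_airborne_amount requires route inhalation")
  scenario$m_prod * scenario$concentration * scenario$f_air
}

#' Inhaled amount under the SCCS 2-Box spray model
#'
#' `a_inh = a_expo * r_inh * (t_A/V_A + t_B/V_B)`, ug. Box A is the
#' near-field breathing zone, Box B the rest of the room; no air exchange
#' between Box B and the environment is assumed.
#'
#' @param a_expo Airborne amount, ug (from [spray_airborne_amount()]).
#' @param scenario An inhalation [exposure_scenario()].
#' @return Inhaled amount, ug.
#' @export
two_box_inhaled_amount <- function(a_expo, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (scenario$route != "inhalation")
    stop("two_box_inhaled_amount requires route inhalation")
  if (scenario$v_a <= 0 || scenario$v_b <= 0)
    stop("box volumes must be strictly positive")
  a_expo * scenario$r_inh * (scenario$t_a / scenario$v_a +
                               scenario$t_b / scenario$v_b)
}

#' SED for the inhalation pathway
#'
#' `SED = a_inh / BW * f_ret`. Conservatively, the non-respirable part of
#' the retained fraction is assumed to be swallowed and hence systemically
#' available, so `f_ret` covers the whole retained amount.
#'
#' @param a_inh Inhaled amount, ug.
#' @param scenario An inhalation [exposure_scenario()].
#' @return A `sed_result` carrying `a_expo`/`a_inh` intermediates.
#' @export
sed_inhalation <- function(a_inh, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  sed <- a_inh / scenario$bw * scenario$f_ret
  new_sed_result(sed, scenario,
                 intermediates = list(a_expo = spray_airborne_amount(scenario),
                                      a_inh = a_inh))
}

#' SED for dermal contact with a migrating contaminant
#'
#' `SED = A_skin * M_R * t_contact * f_abs / BW`, ug/kg bw/day.
#'
#' @param scenario An [exposure_scenario()] with route `"dermal_migration"`.
#' @return A `sed_result`.
#' @examples
#' sandals <- exposure_scenario("dermal_migration", bw = 22, a_skin = 300,
#'                              m_r = 0.007, t_contact = 10, f_abs = 0.05)
#' sed_migration(sandals)$sed  # ~0.048
#' @export
sed_migration <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (scenario$route != "dermal_migration")
    stop("sed_migration requires route dermal_migration")
  sed <- scenario$a_skin * scenario$m_r * scenario$t_contact *
    scenario$f_abs / scenario$bw
  new_sed_result(sed, scenario)
}

#' Compute the SED for any scenario route
#'
#' Dispatches to the route-appropriate chain: direct contact (Eq.-style
#' product formula), the three-step spray model, or migration contact.
#'
#' @param scenario An [exposure_scenario()].
#' @return A `sed_result`.
#' @export
sed <- function(scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  switch(scenario$route,
    dermal = sed_contact(scenario),
    oral = sed_contact(scenario),
    inhalation = sed_inhalation(
      two_box_inhaled_amount(spray_airborne_amount(scenario), scenario),
      scenario),
    dermal_migration = sed_migration(scenario)
  )
}

#' Aggregate systemic exposure doses across pathways
#'
#' Arithmetic sum of per-pathway SEDs for one population; all results must
#' share the same body weight.
#'
#' @param results A list of `sed_result` objects.
#' @return Aggregated SED, ug/kg bw/day.
#' @export
aggregate_sed <- function(results) {
  if (!length(results)) stop("cannot aggregate an empty list of SED results")
  ok <- vapply(results, inherits, logical(1), what = "sed_result")
  if (!all(ok)) stop("all elements must be sed_result objects")
  bws <- vapply(results, function(r) r$bw, numeric(1))
  if (length(unique(bws)) != 1L)
    stop("SED results stem from different populations (body weights: ",
         paste(unique(bws), collapse = ", "), ")")
  sum(vapply(results, function(r) r$sed, numeric(1)))
}

#' Migration-rate regression from product concentration data
#'
#' Ordinary least squares of measured migration rates (ug/cm^2/h) on
#' product contaminant concentrations (mg/kg), through the origin by
#' default. Used to predict a migration rate at a product concentration of
#' interest when only concentration data are available.
#'
#' @param concentration Product concentrations, mg/kg (>= 3 values).
#' @param migration Measured migration rates, ug/cm^2/h.
#' @param intercept Include an intercept? Default `FALSE` (through origin).
#' @return An object of class `migration_fit`: list with `slope`,
#'   `slope_se`, `intercept`, `fit` (the `lm` object) and `predict(conc)`.
#' @export
fit_migration_rate <- function(concentration, migration, intercept = FALSE) {
  if (length(concentration) < 3 || length(migration) != length(concentration))
    stop("need at least 3 (concentration, migration) pairs of equal length")
  if (any(concentration < 0) || any(migration < 0))
    stop("concentrations and migration rates must be non-negative")
  if (diff(range(concentration)) == 0)
    stop("degenerate design: all concentrations are equal")
  d <- data.frame(conc = concentration, mig = migration)
  fit <- if (intercept) stats::lm(mig ~ conc, data = d)
         else stats::lm(mig ~ 0 + conc, data = d)
  # exact (noise-free) input is legitimate here; silence summary.lm's
  # "essentially perfect fit" warning
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["conc", "Estimate"]
  structure(list(
    slope = slope,
    slope_se = co["conc", "Std. Error"],
    intercept = if (intercept) co["(Intercept)", "Estimate"] else 0,
    fit = fit,
    predict = function(conc) {
      unname(stats::predict(fit, newdata = data.frame(conc = conc)))
    }
  ), class = "migration_fit")
}

#' Packaged consumer-product scenario library
#'
#' The scenario set used in the DnHexP assessment: sunscreen (dermal, 18
#' g/day adult; 0.971 g/kg bw/day child), lip balm (oral, 0.057 g/day,
#' `f_abs` 1), face pump spray (inhalation, 1.54 g sprayed, `f_air` 0.2,
#' `f_ret` 0.75, adult `r_inh` 13 L/min, 2-Box volumes 1000/10000 L for
#' 2/10 min) and plastic sandals (migration, 300 cm^2, 0.007 ug/cm^2/h,
#' 10 h). Child cosmetic scenarios reuse the adult product-side amounts
#' (same ingested/inhaled amount) with a 10-kg body weight; the sandals
#' scenario uses a 22-kg 6-10-year-old. The default contamination is 16
#' mg/kg, the maximum found in 57 sunscreen samples.
#'
#' The dermal absorption fraction defaults to 0.05 (5 %). The underlying
#' assessment literature states "0.05 %" in one place, but every parameter
#' table and worked value uses 5 %; 5 % is itself conservative (dermal
#' absorption in humans is more likely around 1.5 %).
#'
#' @param concentration Contaminant concentration in the cosmetic products,
#'   mg/kg (default 16).
#' @param m_r Migration rate for the sandals scenario, ug/cm^2/h (default
#'   0.007, from the pooled migration regression).
#' @return Named list of `exposure_scenario` objects.
#' @export
scenario_library <- function(concentration = 16, m_r = 0.007) {
  spray <- function(bw, label) {
    exposure_scenario("inhalation", bw = bw, m_prod = 1.54,
                      concentration = concentration, f_air = 0.2,
                      f_ret = 0.75, r_inh = 13, v_a = 1000, v_b = 10000,
                      t_a = 2, t_b = 10, label = label)
  }
  list(
    sunscreen_adult = exposure_scenario("dermal", bw = 60, m_prod = 18,
                                        concentration = concentration,
                                        f_abs = 0.05,
                                        label = "sunscreen_adult"),
    # child amount is the 95th-percentile application rate 0.971 g/kg bw/day
    sunscreen_child = exposure_scenario("dermal", bw = 10,
                                        m_prod = 0.971 * 10,
                                        concentration = concentration,
                                        f_abs = 0.05,
                                        label = "sunscreen_child"),
    lip_balm_adult = exposure_scenario("oral", bw = 60, m_prod = 0.057,
                                       concentration = concentration,
                                       f_abs = 1, label = "lip_balm_adult"),
    lip_balm_child = exposure_scenario("oral", bw = 10, m_prod = 0.057,
                                       concentration = concentration,
                                       f_abs = 1, label = "lip_balm_child"),
    pump_spray_adult = spray(60, "pump_spray_adult"),
    pump_spray_child = spray(10, "pump_spray_child"),
    sandals_child = exposure_scenario("dermal_migration", bw = 22,
                                      a_skin = 300, m_r = m_r,
                                      t_contact = 10, f_abs = 0.05,
                                      label = "sandals_child")
  )
}
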