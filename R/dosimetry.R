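#' Toxicokinetic parameters linking urinary metabolite levels and intake
#'
#' Bundles the quantities needed to convert between a urinary concentration of
#' a monoester metabolite (here MnHexP) and the daily intake of the parent
#' diester (DnHexP): the body-weight-adjusted urinary output rate `Q_U`, the
#' molar fraction of an oral dose excreted in urine as the metabolite within
#' 24 h (`f_UE`), its route-specific counterpart used when converting a
#' systemic exposure dose back to urine (`f_UE_SED`), and the two molecular
#' weights.
#'
#' @param q_u Urinary output rate, L per kg body weight per day (> 0).
#' @param f_ue Molar fraction of the oral parent dose excreted in urine as the
#'   metabolite within 24 h; in (0, 1].
#' @param mw_parent Molecular weight of the parent diester, g/mol.
#' @param mw_metabolite Molecular weight of the monoester metabolite, g/mol.
#' @param f_ue_sed Molar fraction of a systemic exposure dose excreted as the
#'   metabolite; defaults to `f_ue` (oral bioavailability close to 1). Kept as
#'   a separate field because route-dependent values are conceivable.
#' @param population Free-text label, e.g. `"adult"` or `"child 1-3 y"`.
#' @return An object of class `kinetic_parameters`.
#' @examples
#' kinetic_parameters(0.025, 0.69, 334.45, 250.29, population = "adult")
#' @export
kinetic_parameters <- function(q_u, f_ue, mw_parent, mw_metabolite,
                               f_ue_sed = f_ue, population = "unspecified") {
  vals <- c(q_u = q_u, f_ue = f_ue, mw_parent = mw_parent,
            mw_metabolite = mw_metabolite, f_ue_sed = f_ue_sed)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all kinetic parameters must be finite and strictly positive")
  if (f_ue > 1 || f_ue_sed > 1)
    stop("excretion fractions f_ue and f_ue_sed must not exceed 1")
  if (mw_parent <= mw_metabolite)
    warning("mw_parent <= mw_metabolite: unusual for a diester/monoester pair")
  structure(
    list(q_u = q_u, f_ue = f_ue, f_ue_sed = f_ue_sed,
         mw_parent = mw_parent, mw_metabolite = mw_metabolite,
         population = population),
    class = "kinetic_parameters"
  )
}

#' @export
print.kinetic_parameters <- function(x, ...) {
  cat("Kinetic parameters (", x$population, ")\n", sep = "")
  cat(sprintf("  Q_U      %.3f L/kg bw/day\n", x$q_u))
  cat(sprintf("  f_UE     %.3f   f_UE_SED %.3f\n", x$f_ue, x$f_ue_sed))
  cat(sprintf("  MW       %.2f (parent) / %.2f (metabolite) g/mol\n",
              x$mw_parent, x$mw_metabolite))
  invisible(x)
}

#' Default populations for the DnHexP/MnHexP pair
#'
#' Returns the kinetic parameter set used throughout the assessment:
#' adults (1.5 L urine/day at 60 kg, `Q_U` = 0.025) and 1-3-year-old
#' children (`Q_U` = 0.030), both with `f_UE` = 0.69 (value determined for
#' the monoester metabolite of DBP, which shares the linear alkyl side
#' chain) and MW 334.45 / 250.29 g/mol.
#'
#' @param population `"adult"` or `"child"`.
#' @return A `kinetic_parameters` object.
#' @export
population_parameters <- function(population = c("adult", "child")) {
  population <- match.arg(population)
  switch(population,
    adult = kinetic_parameters(0.025, 0.69, 334.45, 250.29,
                               population = "adult"),
    child = kinetic_parameters(0.030, 0.69, 334.45, 250.29,
                               population = "child 1-3 y")
  )
}

#' Reverse dosimetry: urinary metabolite concentration to daily intake
#'
#' Estimates the daily intake `DI` (ug/kg bw/day) of the parent compound from
#' a spot/morning-urine metabolite concentration `C_U` (ug/L):
#' `DI = C_U * (Q_U / f_UE) * (MW_p / MW_m)`.
#'
#' @param concentration Urinary metabolite concentration, ug/L (vectorised,
#'   all values >= 0).
#' @param params A [kinetic_parameters()] object.
#' @return An object of class `intake_estimate`: a list with `daily_intake`
#'   (ug/kg bw/day), `source_concentration` and `params`.
#' @examples
#' reverse_dosimetry(45.7, population_parameters("adult"))$daily_intake
#' @export
reverse_dosimetry <- function(concentration, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(concentration)) || any(concentration < 0))
    stop("concentration must be finite and non-negative")
  if (params$f_ue == 0) stop("f_ue must be non-zero")
  di <- concentration * (params$q_u / params$f_ue) *
    (params$mw_parent / params$mw_metabolite)
  structure(list(daily_intake = di,
                 source_concentration = concentration,
                 params = params),
            class = "intake_estimate")
}

#' Forward dosimetry: systemic exposure dose to urinary concentration
#'
#' Converts a systemic exposure dose (ug/kg bw/day) into the corresponding
#' urinary metabolite concentration (ug/L):
#' `C_U = SED * (MW_m / MW_p) * (f_UE_SED / Q_U)`.
#'
#' @param sed Systemic exposure dose, ug/kg bw/day (vectorised, >= 0).
#' @param params A [kinetic_parameters()] object.
#' @return Urinary concentration(s), ug/L.
#' @examples
#' forward_dosimetry(4.5, population_parameters("adult"))  # ~93 ug/L
#' @export
forward_dosimetry <- function(sed, params) {
  stopifnot(inherits(params, "kinetic_parameters"))
  if (any(!is.finite(sed)) || any(sed < 0))
    stop("sed must be finite and non-negative")
  if (params$q_u == 0) stop("q_u must be non-zero")
  sed * (params$mw_metabolite / params$mw_parent) *
    (params$f_ue_sed / params$q_u)
}

#' Construct a biomonitoring dataset of urinary concentrations
#'
#' @param records A data.frame with columns `sample_id`, `concentration_ugL`,
#'   `below_loq` (logical), `loq_ugL`, `age_group`.
#' @return An object of class `biomonitoring_dataset` (a validated data.frame).
#' @export
biomonitoring_dataset <- function(records) {
  need <- c("sample_id", "concentration_ugL", "below_loq", "loq_ugL",
            "age_group")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing biomonitoring columns: ", paste(miss, collapse = ", "))
  records <- as.data.frame(records)[need]
  records$below_loq <- as.logical(records$below_loq)
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_ids in biomonitoring dataset")
  if (any(records$concentration_ugL < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  bad <- records$below_loq & !(records$loq_ugL > 0)
  if (any(bad, na.rm = TRUE))
    stop("records flagged below LOQ must carry a positive loq_ugL")
  class(records) <- c("biomonitoring_dataset", "data.frame")
  records
}

#' Read a biomonitoring table from delimited text
#'
#' Expects header columns `sample_id, concentration_ugL, below_loq, loq_ugL,
#' age_group`. Concentration entries written as `"<LOQ"` are accepted and
#' mapped to `below_loq = TRUE` with the concentration set to `NA`.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (comma by default).
#' @return A `biomonitoring_dataset`.
#' @export
read_biomonitoring <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, colClasses = "character",
                           strip.white = TRUE)
  need <- c("sample_id", "concentration_ugL", "below_loq", "loq_ugL",
            "age_group")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("missing biomonitoring columns: ", paste(miss, collapse = ", "))
  is_cens <- grepl("^<", raw$concentration_ugL)
  conc <- suppressWarnings(as.numeric(ifelse(is_cens, NA,
                                             raw$concentration_ugL)))
  bad <- which(!is_cens & is.na(conc))
  if (length(bad))
    stop("unparseable concentration at line ", bad[1] + 1L,
         " of ", path)
  below <- tolower(raw$below_loq) %in% c("true", "t", "1", "yes") | is_cens
  loq <- suppressWarnings(as.numeric(raw$loq_ugL))
  biomonitoring_dataset(data.frame(
    sample_id = raw$sample_id,
    concentration_ugL = conc,
    below_loq = below,
    loq_ugL = loq,
    age_group = raw$age_group,
    stringsAsFactors = FALSE
  ))
}

#' Substitute censored concentrations according to an LOQ policy
#'
#' @param dataset A `biomonitoring_dataset`.
#' @param policy One of `"loq_half"` (LOQ/2, default), `"loq_sqrt2"`
#'   (LOQ/sqrt(2)), `"zero"`, `"exclude"`.
#' @return Numeric vector of working concentrations (ug/L); `"exclude"` drops
#'   censored records.
#' @export
apply_loq_policy <- function(dataset,
                             policy = c("loq_half", "loq_sqrt2", "zero",
                                        "exclude")) {
  stopifnot(inherits(dataset, "biomonitoring_dataset"))
  policy <- match.arg(policy)
  conc <- dataset$concentration_ugL
  cens <- dataset$below_loq
  sub <- switch(policy,
    loq_half  = dataset$loq_ugL / 2,
    loq_sqrt2 = dataset$loq_ugL / sqrt(2),
    zero      = 0,
    exclude   = NA_real_
  )
  conc[cens] <- if (policy == "exclude") NA_real_ else
    rep_len(sub, nrow(dataset))[cens]
  if (policy == "exclude") conc <- conc[!cens]
  conc
}

#' Summarise reverse-dosimetry intakes over a biomonitoring dataset
#'
#' Applies the LOQ substitution policy, converts every record to a daily
#' intake via [reverse_dosimetry()], and returns percentile summaries.
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7); this convention is fixed because reported
#' percentiles depend on it.
#'
#' @param dataset A `biomonitoring_dataset`.
#' @param params A [kinetic_parameters()] object.
#' @param loq_policy Passed to [apply_loq_policy()].
#' @param probs Quantile levels to report (default median and P95).
#' @return A list with `n`, `quantiles` (named vector, ug/kg bw/day), `max`,
#'   `loq_policy`, and `params`.
#' @export
summarize_intakes <- function(dataset, params, loq_policy = "loq_half",
                              probs = c(0.5, 0.95)) {
  stopifnot(inherits(dataset, "biomonitoring_dataset"))
  if (nrow(dataset) == 0) stop("empty biomonitoring dataset")
  conc <- apply_loq_policy(dataset, loq_policy)
  if (!length(conc) || all(is.na(conc)))
    stop("no usable records after LOQ policy '", loq_policy, "'")
  di <- reverse_dosimetry(conc, params)$daily_intake
  qs <- stats::quantile(di, probs = probs, type = 7, names = TRUE)
  list(n = length(di), quantiles = qs, max = max(di),
       loq_policy = loq_policy, params = params)
}
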