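#' Lognormal uncertainty distribution specified by two quantiles
#'
#' The WHO/IPCS approximate probabilistic approach represents every
#' uncertainty source (point of departure, interspecies differences,
#' intraspecies variability) as a lognormal distribution. This constructor
#' solves for the unique lognormal matching two given quantiles.
#'
#' @param p1,v1 Lower quantile: probability level and value.
#' @param p2,v2 Upper quantile: probability level and value (`p2 > p1`,
#'   `v2 > v1 > 0`).
#' @param label Free-text component name.
#' @return An object of class `lognormal_uncertainty` with `meanlog`,
#'   `sdlog`, `median` and a `quantile(p)` helper.
#' @examples
#' lognormal_from_quantiles(0.05, 14.9, 0.95, 30.0)$median  # ~21.1
#' @export
lognormal_from_quantiles <- function(p1, v1, p2, v2, label = "uncertainty") {
  if (!(p1 > 0 && p1 < p2 && p2 < 1))
    stop("need probability levels 0 < p1 < p2 < 1")
  if (!(v1 > 0 && v2 > v1))
    stop("need values 0 < v1 < v2 consistent with the quantile ordering")
  z1 <- stats::qnorm(p1)
  z2 <- stats::qnorm(p2)
  sdlog <- log(v2 / v1) / (z2 - z1)
  meanlog <- log(v1) - z1 * sdlog
  new_lognormal(meanlog, sdlog, label)
}

new_lognormal <- function(meanlog, sdlog, label = "uncertainty") {
  if (sdlog < 0) stop("sdlog must be non-negative")
  structure(list(label = label, meanlog = meanlog, sdlog = sdlog,
                 median = exp(meanlog),
                 quantile = function(p) stats::qlnorm(p, meanlog, sdlog)),
            class = "lognormal_uncertainty")
}

#' Lognormal from a median and an upper-quantile ratio
#'
#' Convenience parameterisation used for assessment-factor components:
#' a median `P50` and the ratio `P95/P50` (or another level).
#'
#' @param p50 Median of the component.
#' @param p_ratio Ratio of the upper quantile to the median (> 1, or 1 for
#'   a degenerate point mass).
#' @param level Probability level of the upper quantile (default 0.95).
#' @param label Component name.
#' @return A `lognormal_uncertainty`.
#' @export
lognormal_from_ratio <- function(p50, p_ratio, level = 0.95,
                                 label = "uncertainty") {
  if (p50 <= 0) stop("p50 must be positive")
  if (p_ratio < 1) stop("p_ratio must be >= 1")
  new_lognormal(log(p50), log(p_ratio) / stats::qnorm(level), label)
}

#' @export
print.lognormal_uncertainty <- function(x, ...) {
  cat(sprintf("Lognormal [%s]: median %.4g, P05 %.4g, P95 %.4g\n",
              x$label, x$median, x$quantile(0.05), x$quantile(0.95)))
  invisible(x)
}

#' Allometric dose-scaling factor between species
#'
#' Body-size scaling of a dose rate expressed per kg body weight: with
#' allometric exponent `e`, the human-equivalent dose is the animal dose
#' multiplied by `(bw_animal / bw_human)^(1 - e)`.
#'
#' @param bw_animal,bw_human Body weights, kg.
#' @param exponent Allometric exponent in (0, 1); default 0.7.
#' @return Dimensionless multiplicative factor (< 1 when the animal is
#'   smaller than the human).
#' @examples
#' allometric_scaling_factor(0.2, 60)  # ~0.181
#' @export
allometric_scaling_factor <- function(bw_animal, bw_human, exponent = 0.7) {
  if (bw_animal <= 0 || bw_human <= 0) stop("body weights must be positive")
  if (!(exponent > 0 && exponent < 1))
    stop("allometric exponent must lie in (0, 1)")
  (bw_animal / bw_human)^(1 - exponent)
}

#' Combine independent lognormal components
#'
#' Products and quotients of independent lognormals are lognormal: log
#' medians add (with sign) and log variances add. This is the core algebra
#' of the WHO/IPCS approximate probabilistic method.
#'
#' @param components List of `lognormal_uncertainty` objects.
#' @param signs Vector of +1 (multiply) / -1 (divide) per component;
#'   defaults to all +1.
#' @param label Name of the combined distribution.
#' @return A `lognormal_uncertainty`.
#' @export
combine_lognormals <- function(components, signs = NULL,
                               label = "combined") {
  if (!length(components)) stop("need at least one component")
  ok <- vapply(components, inherits, logical(1),
               what = "lognormal_uncertainty")
  if (!all(ok)) stop("all components must be lognormal_uncertainty objects")
  if (is.null(signs)) signs <- rep(1, length(components))
  if (length(signs) != length(components) || !all(signs %in% c(-1, 1)))
    stop("signs must be +1/-1, one per component")
  mus <- vapply(components, function(x) x$meanlog, numeric(1))
  sds <- vapply(components, function(x) x$sdlog, numeric(1))
  new_lognormal(sum(signs * mus), sqrt(sum(sds^2)), label)
}

#' WHO/IPCS approximate-probabilistic default assessment factors
#'
#' Builds the default uncertainty components of the WHO/IPCS (2017)
#' approximate probabilistic hazard characterisation for the given species
#' body weights, from a packaged (editable) configuration file:
#'
#' * interspecies body-size scaling: allometric exponent 0.7, applied as a
#'   deterministic median `(bw_animal/bw_human)^0.3` with lognormal
#'   uncertainty `P95/P50 = (bw_human/bw_animal)^0.04`;
#' * interspecies TK/TD residual (beyond allometry): `P50 = 1`,
#'   `P95/P50 = 3`;
#' * intraspecies human variability, protecting the given population
#'   incidence (default 1 %): `P50 = 9.7`, `P95/P50 = 4.3`.
#'
#' @param bw_animal,bw_human Body weights, kg (defaults 0.2 and 60).
#' @param config Path to a YAML file with the quantile table; default the
#'   packaged `af_who2017.yaml`.
#' @return A list of `lognormal_uncertainty` components with a `signs`
#'   attribute: allometric scaling multiplies the animal PoD, the
#'   interspecies-residual and intraspecies factors divide it.
#' @export
who_af_defaults <- function(bw_animal = 0.2, bw_human = 60, config = NULL) {
  if (is.null(config))
    config <- system.file("extdata", "af_who2017.yaml",
                          package = "phthalrisk", mustWork = TRUE)
  cf <- yaml::read_yaml(config)
  ratio <- bw_human / bw_animal
  allo <- new_lognormal(
    meanlog = (1 - cf$allometric$exponent) * log(1 / ratio),
    sdlog = cf$allometric$exponent_uncertainty_p95_ratio_power *
      log(ratio) / stats::qnorm(0.95),
    label = "interspecies-allometric"
  )
  inter <- lognormal_from_ratio(cf$interspecies_tktd$p50,
                                cf$interspecies_tktd$p95_ratio,
                                label = "interspecies-residual")
  intra <- lognormal_from_ratio(cf$intraspecies$p50,
                                cf$intraspecies$p95_ratio,
                                label = "intraspecies")
  structure(list(allometric = allo, interspecies_residual = inter,
                 intraspecies = intra),
            signs = c(1, -1, -1), config = config)
}

#' Approximate probabilistic tolerable daily intake
#'
#' Implements the WHO/IPCS approximate probabilistic derivation of a
#' health-based guidance value. The animal point of departure is treated as
#' a lognormal with `P05 = bmdl` and `P95 = bmdu`; it is scaled to a human
#' dose by the allometric component and divided by the interspecies-residual
#' and intraspecies components (all lognormal, assumed independent, so log
#' medians and log variances add). The result is the distribution of the
#' "maximum safe" human daily dose; the lower bound of its central coverage
#' interval (default 90 %) is taken as the TDI.
#'
#' @param bmdl,bmdu Lower/upper benchmark-dose bounds, mg/kg bw/day
#'   (`bmdl < bmdu`).
#' @param af_config Component list from [who_af_defaults()] (or a custom
#'   list of `lognormal_uncertainty` with a `signs` attribute).
#' @param coverage Central coverage of the reported interval, in (0.5, 1);
#'   default 0.90.
#' @param deterministic_af Overall assessment factor for the deterministic
#'   comparison value (default 100).
#' @return An object of class `tdi_result` with `tdi` (= `lower`), `lower`,
#'   `upper` (ug/kg bw/day), `coverage`, the combined `distribution`, the
#'   `components`, and `deterministic_tdi` (= `bmdl*1000/deterministic_af`).
#' @examples
#' \donttest{
#' approximate_probabilistic_tdi(14.9, 30.0, who_af_defaults(0.2, 60))
#' }
#' @export
approximate_probabilistic_tdi <- function(bmdl, bmdu,
                                          af_config = who_af_defaults(),
                                          coverage = 0.90,
                                          deterministic_af = 100) {
  if (!(bmdl > 0 && bmdu > bmdl)) stop("need 0 < bmdl < bmdu")
  if (!(coverage > 0.5 && coverage < 1))
    stop("coverage must lie in (0.5, 1)")
  pod <- lognormal_from_quantiles(0.05, bmdl * 1000, 0.95, bmdu * 1000,
                                  label = "PoD")  # mg -> ug/kg bw/day
  signs <- attr(af_config, "signs")
  if (is.null(signs)) signs <- rep(-1, length(af_config))
  hd <- combine_lognormals(c(list(pod), unname(af_config)),
                           signs = c(1, signs), label = "human dose")
  alpha <- (1 - coverage) / 2
  lower <- hd$quantile(alpha)
  upper <- hd$quantile(1 - alpha)
  structure(list(tdi = lower, lower = lower, upper = upper,
                 coverage = coverage, distribution = hd,
                 components = c(list(PoD = pod), af_config),
                 signs = c(1, signs),
                 deterministic_tdi = deterministic_tdi(bmdl,
                                                       deterministic_af)),
            class = "tdi_result")
}

#' @export
print.tdi_result <- function(x, ...) {
  cat(sprintf("Approximate probabilistic TDI: %.3g ug/kg bw/day\n", x$tdi))
  cat(sprintf("  %.0f%% interval of the maximum safe dose: %.3g - %.3g\n",
              100 * x$coverage, x$lower, x$upper))
  cat(sprintf("  deterministic comparison (PoD / overall AF): %.3g\n",
              x$deterministic_tdi))
  invisible(x)
}

#' Deterministic TDI from a point of departure
#'
#' Classical derivation: PoD divided by an overall assessment factor
#' (default 100 for inter- plus intraspecies variability).
#'
#' @param pod Point of departure, mg/kg bw/day.
#' @param overall_af Overall assessment factor (> 0).
#' @return TDI in ug/kg bw/day.
#' @examples
#' deterministic_tdi(14.7, 100)  # 147
#' @export
deterministic_tdi <- function(pod, overall_af = 100) {
  if (pod <= 0 || overall_af <= 0)
    stop("pod and overall_af must be positive")
  pod * 1000 / overall_af
}

#' Potency weighting factor relative to a reference substance
#'
#' Ratio of the reference TDI to the substance TDI: how many times more
#' potent the substance is than the reference. Used to express exposure in
#' reference-substance equivalents against a group TDI.
#'
#' @param tdi_reference Reference-substance TDI (e.g. 50 ug/kg bw/day for
#'   DEHP).
#' @param tdi_substance Substance TDI, same units.
#' @return Dimensionless weighting factor.
#' @examples
#' potency_weighting_factor(50, 63)  # ~0.79
#' @export
potency_weighting_factor <- function(tdi_reference, tdi_substance) {
  if (tdi_reference <= 0 || tdi_substance <= 0)
    stop("both TDIs must be positive")
  tdi_reference / tdi_substance
}
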