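#' Synthetic urinary biomonitoring dataset
#'
#' Draws lognormal urinary metabolite concentrations and censors them at a
#' limit of quantification. Defaults are quantile-matched to the published
#' child-survey distribution of MnHexP (median 0.56 ug/L, 75th percentile
#' 1.93 ug/L): `meanlog = log(0.56)`, `sdlog = log(1.93/0.56)/qnorm(0.75)`.
#' The default LOQ of 0.335 ug/L is the 39th percentile of that
#' distribution, so about 61 % of samples fall above it, matching the
#' published detection fraction; the true analytical LOQ is not public.
#'
#' @param n Number of samples.
#' @param meanlog,sdlog Lognormal parameters of the concentration
#'   distribution (ug/L).
#' @param loq Limit of quantification, ug/L (>= 0; 0 disables censoring).
#' @param age_group Age-group label for all records.
#' @param seed Mandatory RNG seed.
#' @return A `biomonitoring_dataset`. Censored records keep their drawn
#'   concentration in an attribute `latent` but carry `NA` concentration
#'   and `below_loq = TRUE`, as a real laboratory table would.
#' @export
gen_urine_dataset <- function(n = 250,
                              meanlog = log(0.56),
                              sdlog = log(1.93 / 0.56) / stats::qnorm(0.75),
                              loq = 0.335,
                              age_group = "child 2-6 y",
                              seed) {
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (n <= 0) stop("n must be positive")
  if (!is.finite(loq) || loq < 0) stop("loq must be non-negative")
  if (!is.finite(sdlog) || sdlog <= 0) stop("sdlog must be positive")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  x <- stats::rlnorm(n, meanlog, sdlog)
  below <- x < loq
  conc <- ifelse(below, NA_real_, x)
  ds <- biomonitoring_dataset(data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    concentration_ugL = conc,
    below_loq = below,
    loq_ugL = loq,
    age_group = age_group,
    stringsAsFactors = FALSE
  ))
  attr(ds, "latent") <- x
  attr(ds, "seed") <- seed
  ds
}

#' Synthetic litter-level dose-response dataset
#'
#' Simulates a developmental-toxicity design: litter-level responses (one
#' value per litter) at a control plus a ladder of gavage doses, with
#' lognormal litter variability around a decreasing exponential true curve
#' `f(x) = a * (c + (1 - c) * exp(-b * x^d))`. The rate `b` is chosen so
#' that the true BMD at the stated benchmark response equals `true_bmd`.
#' Defaults emulate the published foetal-testosterone design: doses 0, 5,
#' 20, 50, 100, 125, 250, 500, 625 mg/kg bw/day, 8-12 litters per group,
#' control geometric mean 7.7, litter CV about 20 %.
#'
#' @param doses Dose ladder, mg/kg bw/day (must include 0).
#' @param n_litters Litters per group: a single number or one per dose.
#' @param control_gm Geometric mean response of the control group.
#' @param asymptote_fraction Fraction `c` of background to which the
#'   response falls at high dose (default 0.1, a tenfold maximum decrease).
#' @param shape Exponent `d` of the true curve (default 1).
#' @param true_bmd True benchmark dose, mg/kg bw/day.
#' @param bmr Benchmark response (fractional decrease) defining `true_bmd`.
#' @param cv Litter-level coefficient of variation (lognormal sdlog =
#'   `sqrt(log(1 + cv^2))`).
#' @param seed Mandatory RNG seed.
#' @return A `dose_response_dataset` with attributes `true_bmd`, `truth`
#'   (the noise-free group means) and `seed`.
#' @export
gen_dose_response <- function(doses = c(0, 5, 20, 50, 100, 125, 250, 500,
                                        625),
                              n_litters = 10,
                              control_gm = 7.7,
                              asymptote_fraction = 0.1,
                              shape = 1,
                              true_bmd = 21,
                              bmr = 0.20,
                              cv = 0.20,
                              seed) {
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (!any(doses == 0)) stop("dose ladder must include a control (0)")
  cc <- asymptote_fraction
  if (!(cc >= 0 && cc < 1 - bmr))
    stop("asymptote_fraction must lie in [0, 1 - bmr)")
  if (true_bmd > max(doses))
    warning("true BMD lies outside the tested dose range")
  n_litters <- rep_len(n_litters, length(doses))
  if (any(n_litters < 2)) stop("need >= 2 litters per group")
  # rate chosen so the true curve crosses (1 - bmr) at true_bmd
  b <- -log((1 - bmr - cc) / (1 - cc)) / true_bmd^shape
  f <- function(x) control_gm * (cc + (1 - cc) * exp(-b * x^shape))
  sdlog <- sqrt(log(1 + cv^2))
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  rows <- list()
  lid <- 0L
  for (i in seq_along(doses)) {
    mu <- f(doses[i])
    y <- mu * exp(stats::rnorm(n_litters[i], 0, sdlog))
    rows[[i]] <- data.frame(
      dose = doses[i],
      litter_id = sprintf("L%03d", lid + seq_len(n_litters[i])),
      response = y, stringsAsFactors = FALSE)
    lid <- lid + n_litters[i]
  }
  ds <- dose_response_dataset(do.call(rbind, rows))
  attr(ds, "true_bmd") <- true_bmd
  attr(ds, "truth") <- data.frame(dose = doses, mean_response = f(doses))
  attr(ds, "seed") <- seed
  ds
}

#' Synthetic product-concentration survey
#'
#' Emulates a market-surveillance survey of contaminant concentrations in
#' cosmetic products: censored lognormal draws with many non-detects,
#' rescaled so that the sample maximum equals `max_target` (the published
#' survey is summarised only by its size, 57 samples, and its maximum of
#' 16 mg/kg).
#'
#' @param n Number of products sampled (default 57).
#' @param meanlog,sdlog Lognormal parameters of the raw draws.
#' @param loq Reporting limit, mg/kg, applied after rescaling.
#' @param max_target Target sample maximum, mg/kg (default 16).
#' @param seed Mandatory RNG seed.
#' @return A data.frame with `product_id`, `concentration_mgkg` (`NA` when
#'   below the reporting limit) and `below_loq`; attribute `seed`.
#' @export
gen_product_concentrations <- function(n = 57, meanlog = log(0.5),
                                       sdlog = 1.5, loq = 1,
                                       max_target = 16, seed) {
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (n <= 0) stop("n must be positive")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  x <- stats::rlnorm(n, meanlog, sdlog)
  x <- x * max_target / max(x)
  below <- x < loq
  out <- data.frame(
    product_id = sprintf("P%03d", seq_len(n)),
    concentration_mgkg = ifelse(below, NA_real_, x),
    below_loq = below, stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  out
}
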