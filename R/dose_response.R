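#' Construct a litter-level continuous dose-response dataset
#'
#' The litter is the statistical unit: one (mean) response per litter.
#' Responses must be strictly positive; modelling is on the log scale with
#' lognormal errors, the standard assumption for this kind of endpoint.
#'
#' @param data A data.frame with columns `dose` (mg/kg bw/day) and
#'   `response` (continuous, > 0); an optional `litter_id` column is kept.
#' @return An object of class `dose_response_dataset`.
#' @export
dose_response_dataset <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("dose", "response") %in% names(data)))
    stop("need columns 'dose' and 'response'")
  if (any(!is.finite(data$dose)) || any(data$dose < 0))
    stop("doses must be finite and non-negative")
  if (any(!is.finite(data$response)) || any(data$response <= 0))
    stop("responses must be strictly positive (lognormal endpoint)")
  if (!any(data$dose == 0))
    stop("dataset must include a control group (dose 0)")
  n_per <- table(data$dose)
  if (any(n_per < 2))
    stop("every dose group needs >= 2 litters for variance estimation")
  class(data) <- c("dose_response_dataset", "data.frame")
  data
}

#' Read a litter-level dose-response table from delimited text
#'
#' Expects header columns `dose`, `litter_id`, `response`.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator.
#' @return A `dose_response_dataset`.
#' @export
read_dose_response <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!all(c("dose", "response") %in% names(raw)))
    stop("dose-response table needs columns 'dose' and 'response'")
  dose_response_dataset(raw)
}

#' Benchmark response from effect-size theory
#'
#' For a continuous endpoint whose maximum response is an `M`-fold change,
#' the equivalent small-amplitude effect size is `ES = M^(1/8)`; for a
#' decreasing endpoint this maps to a percent decrease of
#' `100 * (1 - 1/ES)`. A 5-10-fold maximum decrease therefore corresponds
#' to an 18-25 % benchmark response band.
#'
#' @param M Maximum fold change of the endpoint (> 1).
#' @return A list with `M`, `effect_size` and `bmr_percent`.
#' @examples
#' effect_size_bmr(5)   # ES 1.223, ~18 %
#' effect_size_bmr(10)  # ES 1.334, ~25 %
#' @export
effect_size_bmr <- function(M) {
  if (!is.finite(M) || M <= 1) stop("maximum fold change M must exceed 1")
  es <- M^(1 / 8)
  list(M = M, effect_size = es, bmr_percent = 100 * (1 - 1 / es))
}

#' Welch two-sample t-test from summary statistics
#'
#' Used to check whether two control groups (e.g. from two experiments
#' contributing different dose ranges) can be pooled. Unequal variances;
#' Satterthwaite degrees of freedom; two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return A list with `t`, `df` and `p_value`.
#' @examples
#' welch_pooling_check(7.73, 0.96, 10, 7.47, 2.08, 11)$p_value  # ~0.71
#' @export
welch_pooling_check <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("standard deviations must be positive")
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in both groups")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tt <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tt, df = df, p_value = 2 * stats::pt(-abs(tt), df))
}

## ---- internal model machinery -------------------------------------------
## Decreasing continuous models, parameterised on doses normalised by the
## maximum dose so that optimisation bounds are scale-free and BMD estimates
## are exactly equivariant under dose rescaling. g(0) = 1 in all families;
## the background a and the lognormal sigma are profiled out analytically.
##
##   exp3 : g = exp(-b x^d)
##   exp5 : g = c + (1-c) exp(-b x^d)
##   hill3: g = 1 / (1 + (x/b)^d)
##   hill5: g = c + (1-c) / (1 + (x/b)^d)

bmd_model_defs <- function() {
  list(
    exp3 = list(
      npar = 2L, k = 4L,  # + background a + sigma
      g = function(x, p) exp(-exp(p[1]) * x^exp(p[2])),
      bmd = function(p, bmr) (-log(1 - bmr) / exp(p[1]))^(1 / exp(p[2])),
      start = function() c(log(2), log(1))
    ),
    exp5 = list(
      npar = 3L, k = 5L,
      g = function(x, p) {
        cc <- stats::plogis(p[3])
        cc + (1 - cc) * exp(-exp(p[1]) * x^exp(p[2]))
      },
      bmd = function(p, bmr) {
        cc <- stats::plogis(p[3])
        if (cc >= 1 - bmr) return(Inf)
        (-log((1 - bmr - cc) / (1 - cc)) / exp(p[1]))^(1 / exp(p[2]))
      },
      start = function() c(log(4), log(1), stats::qlogis(0.15))
    ),
    hill3 = list(
      npar = 2L, k = 4L,
      g = function(x, p) 1 / (1 + (x / exp(p[1]))^exp(p[2])),
      bmd = function(p, bmr) exp(p[1]) * (bmr / (1 - bmr))^(1 / exp(p[2])),
      start = function() c(log(0.3), log(1))
    ),
    hill5 = list(
      npar = 3L, k = 5L,
      g = function(x, p) {
        cc <- stats::plogis(p[3])
        cc + (1 - cc) / (1 + (x / exp(p[1]))^exp(p[2]))
      },
      bmd = function(p, bmr) {
        cc <- stats::plogis(p[3])
        if (cc >= 1 - bmr) return(Inf)
        exp(p[1]) * (bmr / (1 - bmr - cc))^(1 / exp(p[2]))
      },
      start = function() c(log(0.3), log(1), stats::qlogis(0.15))
    )
  )
}

## Concentrated negative log-likelihood on the log-response scale: given the
## shape parameters, log(a) enters linearly and its MLE is the mean residual;
## sigma^2 is the mean squared residual.
bmd_negll <- function(p, xs, logy, gfun) {
  gx <- gfun(xs, p)
  if (any(!is.finite(gx)) || any(gx <= 0)) return(1e10)
  r <- logy - log(gx)
  mu_a <- mean(r)
  s2 <- mean((r - mu_a)^2)
  if (!is.finite(s2) || s2 <= 0) return(1e10)
  n <- length(logy)
  0.5 * n * (log(2 * pi * s2) + 1) + sum(logy)  # full lognormal -LL
}

fit_one_model <- function(def, xs, logy, bmr, starts = NULL) {
  lower <- rep(-15, def$npar)
  upper <- rep(15, def$npar)
  # shape parameter d (index 2) restricted to [0.25, 8] on the natural scale
  lower[2] <- log(0.25); upper[2] <- log(8)
  if (is.null(starts)) {
    base <- def$start()
    starts <- list(base)
    for (db in c(log(0.5), log(2)))
      starts <- c(starts, list(replace(base, 2, db)))
    for (bb in c(-2, 2))
      starts <- c(starts, list(replace(base, 1, base[1] + bb)))
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower), upper)
    o <- tryCatch(
      stats::nlminb(st, bmd_negll, xs = xs, logy = logy, gfun = def$g,
                    lower = lower, upper = upper,
                    control = list(iter.max = 300, eval.max = 400)),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$objective)) next
    if (is.null(best) || o$objective < best$objective) best <- o
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  gx <- def$g(xs, p)
  r <- logy - log(gx)
  log_a <- mean(r)
  s2 <- mean((r - log_a)^2)
  ll <- -best$objective
  list(par = p, log_a = log_a, sigma = sqrt(s2), loglik = ll,
       aic = 2 * def$k - 2 * ll, bmd_scaled = def$bmd(p, bmr))
}

ma_bmd_from_fits <- function(fits, xmax) {
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  w <- exp(-(aics - min(aics)) / 2)
  w <- w / sum(w)
  bmds <- vapply(fits, function(f) f$bmd_scaled, numeric(1)) * xmax
  fin <- is.finite(bmds) & bmds > 0
  if (!any(fin) || sum(w[fin]) < 1e-8) return(list(bmd = NA_real_, w = w,
                                                   bmds = bmds))
  wf <- w[fin] / sum(w[fin])
  list(bmd = exp(sum(wf * log(bmds[fin]))), w = w, bmds = bmds)
}

#' Benchmark-dose modelling with model averaging
#'
#' Fits a suite of decreasing continuous dose-response models (exponential
#' and Hill families, 3- and 5-parameter forms) to litter-level responses by
#' maximum likelihood with lognormal errors, defines the BMD as the dose at
#' which the median response falls to `(1 - bmr)` times background, and
#' averages across models with AIC-based pseudo-Bayesian weights. The
#' BMDL/BMDU are the 5th/95th percentiles of the model-averaged parametric
#' bootstrap distribution of the BMD: each bootstrap replicate simulates a
#' dataset from one fitted model drawn by its weight, refits the whole
#' suite, and records the refit model-averaged BMD.
#'
#' @param data A [dose_response_dataset()] with at least 4 dose groups
#'   including control.
#' @param bmr Benchmark response as a fractional decrease from background,
#'   in (0, 1); default 0.20.
#' @param families Model families to fit (default all four).
#' @param n_bootstrap Parametric bootstrap replicates (default 1000; 0
#'   skips the interval and leaves `bmdl`/`bmdu` as `NA`).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @return An object of class `bmd_estimate` with `bmd`, `bmdl`, `bmdu`,
#'   `bmr`, a per-model table (`models`), `n_bootstrap` and `seed`.
#' @export
fit_bmd_models <- function(data, bmr = 0.20,
                           families = c("exp3", "exp5", "hill3", "hill5"),
                           n_bootstrap = 1000, seed) {
  stopifnot(inherits(data, "dose_response_dataset"))
  if (missing(seed) || !is.finite(seed)) stop("a numeric seed is required")
  if (!(bmr > 0 && bmr < 1)) stop("bmr must lie in (0, 1)")
  if (length(unique(data$dose)) < 4)
    stop("need at least 4 dose groups (including control) for BMD modelling")
  defs <- bmd_model_defs()[families]
  if (any(vapply(defs, is.null, logical(1))))
    stop("unknown model family among: ", paste(families, collapse = ", "))

  xmax <- max(data$dose)
  xs <- data$dose / xmax
  logy <- log(data$response)

  fits <- list()
  fails <- character()
  for (nm in names(defs)) {
    f <- fit_one_model(defs[[nm]], xs, logy, bmr)
    if (is.null(f)) fails <- c(fails, nm) else fits[[nm]] <- f
  }
  if (!length(fits))
    stop("no dose-response model converged; failures: ",
         paste(fails, collapse = ", "))

  ma <- ma_bmd_from_fits(fits, xmax)

  # Gate: is the model-averaged fitted decrease at the top dose at least the
  # BMR? If not (flat or increasing data), the BMD is undefined.
  g_top <- sum(ma$w * mapply(function(f, nm) defs[[nm]]$g(1, f$par),
                             fits, names(fits)))
  if (!is.finite(ma$bmd) || g_top > (1 - bmr) || ma$bmd > 10 * xmax)
    stop("BMD undefined: estimated decrease at the highest dose (",
         sprintf("%.1f%%", 100 * (1 - g_top)),
         ") does not reach the benchmark response of ",
         sprintf("%.0f%%", 100 * bmr))

  bmdl <- bmdu <- NA_real_
  boot_bmd <- numeric(0)
  if (n_bootstrap > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(as.integer(seed))
    w <- ma$w
    model_idx <- sample.int(length(fits), n_bootstrap, replace = TRUE,
                            prob = w)
    n <- length(xs)
    boot_bmd <- rep(NA_real_, n_bootstrap)
    starts_by_model <- lapply(fits, function(f) list(f$par))
    for (b in seq_len(n_bootstrap)) {
      fm <- fits[[model_idx[b]]]
      gm <- defs[[names(fits)[model_idx[b]]]]$g
      mu <- fm$log_a + log(gm(xs, fm$par))
      yb <- mu + stats::rnorm(n, 0, fm$sigma)
      bfits <- list()
      for (nm in names(fits)) {
        f <- fit_one_model(defs[[nm]], xs, yb, bmr,
                           starts = starts_by_model[[nm]])
        if (!is.null(f)) bfits[[nm]] <- f
      }
      if (!length(bfits)) next
      mb <- ma_bmd_from_fits(bfits, xmax)
      if (is.finite(mb$bmd) && mb$bmd <= 100 * xmax) boot_bmd[b] <- mb$bmd
    }
    ok <- boot_bmd[is.finite(boot_bmd)]
    if (length(ok) < max(20, 0.5 * n_bootstrap))
      warning("only ", length(ok), " of ", n_bootstrap,
              " bootstrap replicates yielded a defined BMD")
    if (length(ok) >= 2) {
      qq <- stats::quantile(ok, c(0.05, 0.95), type = 7, names = FALSE)
      bmdl <- qq[1]
      bmdu <- qq[2]
    }
  }

  models <- data.frame(
    model = names(fits),
    k = vapply(names(fits), function(nm) defs[[nm]]$k, integer(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    weight = ma$w,
    bmd = ma$bmds,
    sigma = vapply(fits, function(f) f$sigma, numeric(1)),
    row.names = NULL
  )

  structure(list(bmr = bmr, bmd = ma$bmd, bmdl = bmdl, bmdu = bmdu,
                 models = models, fits = fits, dose_scale = xmax,
                 n_bootstrap = n_bootstrap, seed = seed,
                 n_boot_defined = length(boot_bmd[is.finite(boot_bmd)])),
            class = "bmd_estimate")
}

#' @export
print.bmd_estimate <- function(x, ...) {
  cat(sprintf("Model-averaged BMD at BMR %.0f%% decrease\n", 100 * x$bmr))
  cat(sprintf("  BMD  %.3g   BMDL %.3g   BMDU %.3g  (mg/kg bw/day)\n",
              x$bmd, x$bmdl, x$bmdu))
  cat(sprintf("  %d bootstrap replicates (seed %s)\n", x$n_bootstrap,
              format(x$seed)))
  m <- x$models
  m$weight <- round(m$weight, 3)
  m$bmd <- signif(m$bmd, 3)
  print(m[c("model", "k", "aic", "weight", "bmd")], row.names = FALSE)
  invisible(x)
}
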