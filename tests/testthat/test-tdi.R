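test_that("lognormal quantile matching has the closed-form median", {
  ln <- lognormal_from_quantiles(0.05, 14.9, 0.95, 30.0)
  expect_equal(ln$median, sqrt(14.9 * 30.0), tolerance = 1e-12)  # ~21.1
  expect_equal(ln$quantile(0.05), 14.9, tolerance = 1e-9)
  expect_equal(ln$quantile(0.95), 30.0, tolerance = 1e-9)
  # symmetric construction: median is x * sqrt(r)
  for (r in c(1.5, 4, 20)) {
    ln2 <- lognormal_from_quantiles(0.05, 2, 0.95, 2 * r)
    expect_equal(ln2$median, 2 * sqrt(r), tolerance = 1e-9)
  }
  expect_error(lognormal_from_quantiles(0.05, 3, 0.95, 3), "v1 < v2|v2 > v1")
  expect_error(lognormal_from_quantiles(0.95, 1, 0.05, 2), "p1 < p2")
})

test_that("allometric scaling behaves at its limits", {
  expect_equal(allometric_scaling_factor(0.2, 60, 0.7), (1 / 300)^0.3,
               tolerance = 1e-12)  # ~0.181
  expect_equal(allometric_scaling_factor(0.2, 60, 0.7), 0.181,
               tolerance = 0.005)
  expect_equal(allometric_scaling_factor(60, 60), 1)
  expect_equal(allometric_scaling_factor(0.2, 60, 1 - 1e-12), 1,
               tolerance = 1e-9)
  expect_error(allometric_scaling_factor(-1, 60), "positive")
  expect_error(allometric_scaling_factor(0.2, 60, 1.2), "\\(0, 1\\)")
})

test_that("lognormal combination follows the product/quotient algebra", {
  a <- lognormal_from_ratio(2, 3)
  # single component is the identity
  same <- combine_lognormals(list(a))
  expect_equal(same$meanlog, a$meanlog)
  expect_equal(same$sdlog, a$sdlog)
  # dividing twice by the same component: median / median^2, log-var doubled
  both <- combine_lognormals(list(a, a, a), signs = c(1, -1, -1))
  expect_equal(both$median, a$median / a$median^2, tolerance = 1e-12)
  expect_equal(both$sdlog, sqrt(3) * a$sdlog, tolerance = 1e-12)
  expect_error(combine_lognormals(list()), "at least one")
  expect_error(combine_lognormals(list(a), signs = 2), "\\+1/-1")
})

test_that("closed-form combination matches Monte-Carlo sampling", {
  pod <- lognormal_from_quantiles(0.05, 14.9, 0.95, 30.0)
  inter <- lognormal_from_ratio(1, 3)
  intra <- lognormal_from_ratio(9.7, 4.3)
  comb <- combine_lognormals(list(pod, inter, intra), signs = c(1, -1, -1))
  set.seed(77)
  n <- 2e5
  draws <- stats::rlnorm(n, pod$meanlog, pod$sdlog) /
    stats::rlnorm(n, inter$meanlog, inter$sdlog) /
    stats::rlnorm(n, intra$meanlog, intra$sdlog)
  for (p in c(0.05, 0.5, 0.95))
    expect_equal(unname(stats::quantile(draws, p)), comb$quantile(p),
                 tolerance = 0.01)
})

test_that("the approximate probabilistic TDI reproduces the published interval", {
  res <- approximate_probabilistic_tdi(14.9, 30.0,
                                       who_af_defaults(0.2, 60))
  expect_equal(res$lower, 63, tolerance = 0.10)
  expect_equal(res$upper, 2780, tolerance = 0.10)
  expect_identical(res$tdi, res$lower)
  expect_lt(res$lower, res$upper)
  # the probabilistic TDI is more conservative than PoD/100
  expect_lt(res$tdi, res$deterministic_tdi)
  expect_error(approximate_probabilistic_tdi(30, 14.9), "bmdl < bmdu")
  expect_error(approximate_probabilistic_tdi(14.9, 30, coverage = 0.3),
               "coverage")
})

test_that("degenerate uncertainty collapses the interval to the scaled PoD", {
  point <- function(m, lab) lognormal_from_ratio(m, 1, label = lab)
  af <- structure(list(allo = point(0.181, "allo"),
                       inter = point(1, "inter"),
                       intra = point(1, "intra")),
                  signs = c(1, -1, -1))
  res <- approximate_probabilistic_tdi(21, 21 + 1e-9, af_config = af)
  expect_equal(res$lower, 21000 * 0.181, tolerance = 1e-4)
  expect_equal(res$upper, res$lower, tolerance = 1e-4)
})

test_that("the TDI interval is monotone in its inputs", {
  af <- who_af_defaults(0.2, 60)
  base <- approximate_probabilistic_tdi(14.9, 30.0, af)
  up <- approximate_probabilistic_tdi(16.5, 30.0, af)
  expect_gte(up$lower, base$lower)
  # widening the intraspecies component must not narrow the interval
  af_wide <- af
  af_wide$intraspecies <- lognormal_from_ratio(9.7, 8,
                                               label = "intraspecies")
  attr(af_wide, "signs") <- attr(af, "signs")
  wide <- approximate_probabilistic_tdi(14.9, 30.0, af_wide)
  expect_lte(wide$lower, base$lower)
  expect_gte(wide$upper, base$upper)
})

test_that("deterministic TDI and potency weighting match the worked values", {
  expect_equal(deterministic_tdi(14.7, 100), 147, tolerance = 1e-12)
  expect_equal(deterministic_tdi(14.9, 100), 149, tolerance = 1e-12)
  expect_equal(deterministic_tdi(14.7, 1), 14700, tolerance = 1e-12)
  expect_equal(potency_weighting_factor(50, 63), 0.79, tolerance = 0.005)
  expect_equal(potency_weighting_factor(50, 10), 5)
  expect_equal(potency_weighting_factor(42, 42), 1)
  expect_error(deterministic_tdi(-1, 100), "positive")
  expect_error(potency_weighting_factor(0, 1), "positive")
})
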