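test_that("contact SEDs reproduce the published sunscreen and lip balm values", {
  sun300 <- exposure_scenario("dermal", bw = 60, m_prod = 18,
                              concentration = 300, f_abs = 0.05)
  expect_equal(sed_contact(sun300)$sed, 4.5, tolerance = 1e-12)
  # child: 95th-percentile application rate 0.971 g/kg bw/day at 10 kg
  sun300_child <- exposure_scenario("dermal", bw = 10, m_prod = 9.71,
                                    concentration = 300, f_abs = 0.05)
  expect_equal(sed_contact(sun300_child)$sed, 14.6, tolerance = 0.005)
  lip <- exposure_scenario("oral", bw = 60, m_prod = 0.057,
                           concentration = 16, f_abs = 1)
  expect_equal(sed_contact(lip)$sed, 0.015, tolerance = 0.02)
  zero <- exposure_scenario("dermal", bw = 60, m_prod = 18,
                            concentration = 0, f_abs = 0.05)
  expect_identical(sed_contact(zero)$sed, 0)
})

test_that("the spray chain reproduces the 2-Box worked example", {
  sp <- scenario_library(16)$pump_spray_adult
  a_expo <- spray_airborne_amount(sp)
  expect_equal(a_expo, 1.54 * 16 * 0.2, tolerance = 1e-12)  # 4.928 ug
  a_inh <- two_box_inhaled_amount(a_expo, sp)
  expect_equal(a_inh, 4.928 * 13 * 0.003, tolerance = 1e-12)  # 0.1922 ug
  res <- sed_inhalation(a_inh, sp)
  expect_equal(res$sed, 0.0024, tolerance = 0.01)
  expect_named(res$intermediates, c("a_expo", "a_inh"))
  # same inhaled amount, 10-kg child
  child <- scenario_library(16)$pump_spray_child
  expect_equal(sed_inhalation(a_inh, child)$sed, 0.014, tolerance = 0.03)
  # degenerate cases
  sp0 <- exposure_scenario("inhalation", bw = 60, m_prod = 1.54,
                           concentration = 16, f_air = 0, f_ret = 0.75,
                           r_inh = 13, v_a = 1000, v_b = 10000,
                           t_a = 2, t_b = 10)
  expect_identical(spray_airborne_amount(sp0), 0)
  spt0 <- exposure_scenario("inhalation", bw = 60, m_prod = 1.54,
                            concentration = 16, f_air = 0.2, f_ret = 0.75,
                            r_inh = 13, v_a = 1000, v_b = 10000,
                            t_a = 0, t_b = 0)
  expect_identical(two_box_inhaled_amount(4.928, spt0), 0)
  # linearity in the airborne amount
  expect_equal(two_box_inhaled_amount(2 * a_expo, sp), 2 * a_inh,
               tolerance = 1e-12)
})

test_that("chained spray route equals its closed-form expression", {
  set.seed(31)
  for (i in 1:20) {
    sc <- exposure_scenario("inhalation",
                            bw = runif(1, 5, 100),
                            m_prod = runif(1, 0.1, 10),
                            concentration = runif(1, 1, 500),
                            f_air = runif(1), f_ret = runif(1),
                            r_inh = runif(1, 5, 25),
                            v_a = runif(1, 100, 2000),
                            v_b = runif(1, 2000, 20000),
                            t_a = runif(1, 0, 10), t_b = runif(1, 0, 60))
    closed <- sc$m_prod * sc$concentration * sc$f_air * sc$r_inh *
      (sc$t_a / sc$v_a + sc$t_b / sc$v_b) * sc$f_ret / sc$bw
    expect_equal(sed(sc)$sed, closed, tolerance = 1e-12)
  }
})

test_that("migration SED reproduces the plastic-sandals value", {
  sandals <- scenario_library()$sandals_child
  expect_equal(sed_migration(sandals)$sed, 0.048, tolerance = 0.01)
  s0 <- exposure_scenario("dermal_migration", bw = 22, a_skin = 300,
                          m_r = 0.007, t_contact = 0, f_abs = 0.05)
  expect_identical(sed_migration(s0)$sed, 0)
  s2 <- exposure_scenario("dermal_migration", bw = 22, a_skin = 600,
                          m_r = 0.007, t_contact = 10, f_abs = 0.05)
  expect_equal(s2$a_skin / sandals$a_skin *
                 sed_migration(sandals)$sed, sed_migration(s2)$sed,
               tolerance = 1e-12)
})

test_that("every SED is homogeneous of degree 1 in concentration", {
  lib <- scenario_library(16)
  lib2 <- scenario_library(32)
  for (nm in setdiff(names(lib), "sandals_child"))
    expect_equal(sed(lib2[[nm]])$sed, 2 * sed(lib[[nm]])$sed,
                 tolerance = 1e-12)
  # migration route scales with the migration rate instead
  expect_equal(sed(scenario_library(m_r = 0.014)$sandals_child)$sed,
               2 * sed(lib$sandals_child)$sed, tolerance = 1e-12)
})

test_that("aggregation is an order-independent sum within one population", {
  lib <- scenario_library(16)
  parts <- lapply(lib[c("sunscreen_adult", "lip_balm_adult",
                        "pump_spray_adult")], sed)
  total <- aggregate_sed(parts)
  expect_equal(total, sum(vapply(parts, `[[`, 0, "sed")), tolerance = 1e-15)
  expect_equal(aggregate_sed(rev(parts)), total, tolerance = 1e-15)
  expect_equal(aggregate_sed(parts[1]), parts[[1]]$sed)
  # the published aggregate is the sum of the displayed pathway values
  expect_equal(sum(signif(vapply(parts, `[[`, 0, "sed"), 2)), 0.2574,
               tolerance = 1e-12)
  expect_error(aggregate_sed(list()), "empty")
  expect_error(aggregate_sed(c(parts, list(sed(lib$sunscreen_child)))),
               "different populations")
})

test_that("scenario validation catches missing and out-of-range fields", {
  expect_error(exposure_scenario("dermal", bw = 60, m_prod = 18,
                                 concentration = 300), "f_abs")
  expect_error(exposure_scenario("inhalation", bw = 60, m_prod = 1.54,
                                 concentration = 16, f_air = 1.2,
                                 f_ret = 0.75, r_inh = 13, v_a = 1000,
                                 v_b = 10000, t_a = 2, t_b = 10),
               "\\[0, 1\\]")
  expect_error(exposure_scenario("dermal", bw = -1, m_prod = 18,
                                 concentration = 300, f_abs = 0.05),
               "body weight")
})

test_that("migration regression recovers a known slope", {
  # exact line through the origin
  conc <- c(10, 50, 100, 200, 500)
  fit <- fit_migration_rate(conc, 3.5e-5 * conc)
  expect_equal(fit$slope, 3.5e-5, tolerance = 1e-12)
  expect_equal(fit$predict(200), 0.007, tolerance = 1e-9)
  # noisy data at the survey size: truth within 2 standard errors
  set.seed(42)
  conc <- stats::runif(138, 50, 500)
  mig <- 3.5e-5 * conc + stats::rnorm(138, 0, 5e-4)
  fit <- fit_migration_rate(conc, mig)
  expect_lt(abs(fit$slope - 3.5e-5), 2 * fit$slope_se)
  expect_equal(fit$slope, 3.5e-5, tolerance = 0.05)
  # preconditions
  expect_error(fit_migration_rate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_migration_rate(c(5, 5, 5), c(1, 2, 3)), "degenerate")
  # optional intercept
  fit_i <- fit_migration_rate(c(10, 50, 100, 200), 0.001 + 3.5e-5 *
                                c(10, 50, 100, 200), intercept = TRUE)
  expect_equal(fit_i$intercept, 0.001, tolerance = 1e-9)
  expect_equal(fit_i$slope, 3.5e-5, tolerance = 1e-9)
})
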