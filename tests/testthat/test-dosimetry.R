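test_that("reverse dosimetry reproduces the published worked examples", {
  # adult maximum from the national survey interim analysis
  expect_equal(reverse_dosimetry(45.7, adult_kp())$daily_intake, 2.21,
               tolerance = 0.005)
  # child-survey maximum and median, Q_U = 0.030
  expect_equal(reverse_dosimetry(46.18, child_kp())$daily_intake, 2.68,
               tolerance = 0.005)
  expect_equal(reverse_dosimetry(0.56, child_kp())$daily_intake, 0.032,
               tolerance = 0.02)
  # zero in, zero out
  expect_identical(reverse_dosimetry(0, adult_kp())$daily_intake, 0)
})

test_that("forward dosimetry reproduces the published urine levels", {
  expect_equal(forward_dosimetry(4.5, adult_kp()), 93, tolerance = 0.005)
  expect_equal(forward_dosimetry(0.24, adult_kp()), 4.96, tolerance = 0.005)
  expect_identical(forward_dosimetry(0, child_kp()), 0)
})

test_that("forward and reverse dosimetry are exact inverses", {
  set.seed(11)
  for (i in 1:25) {
    kp <- random_kp()
    conc <- stats::runif(1, 0, 100)
    di <- reverse_dosimetry(conc, kp)$daily_intake
    expect_equal(forward_dosimetry(di, kp), conc, tolerance = 1e-12)
  }
})

test_that("reverse dosimetry is linear and monotone in its inputs", {
  kp <- adult_kp()
  set.seed(12)
  for (k in c(0, 0.5, 2, 17.3)) {
    expect_equal(reverse_dosimetry(k * 3.1, kp)$daily_intake,
                 k * reverse_dosimetry(3.1, kp)$daily_intake,
                 tolerance = 1e-12)
  }
  base <- reverse_dosimetry(10, kp)$daily_intake
  # increasing C_U or Q_U increases DI; increasing f_UE decreases it
  expect_gt(reverse_dosimetry(10.1, kp)$daily_intake, base)
  kp_hi_qu <- kinetic_parameters(kp$q_u * 1.2, kp$f_ue, kp$mw_parent,
                                 kp$mw_metabolite)
  expect_gt(reverse_dosimetry(10, kp_hi_qu)$daily_intake, base)
  kp_hi_fue <- kinetic_parameters(kp$q_u, min(1, kp$f_ue * 1.2),
                                  kp$mw_parent, kp$mw_metabolite)
  expect_lt(reverse_dosimetry(10, kp_hi_fue)$daily_intake, base)
})

test_that("invalid dosimetry inputs are rejected", {
  expect_error(reverse_dosimetry(-1, adult_kp()), "non-negative")
  expect_error(forward_dosimetry(-0.1, adult_kp()), "non-negative")
  expect_error(kinetic_parameters(0, 0.69, 334.45, 250.29), "positive")
  expect_error(kinetic_parameters(0.025, 1.2, 334.45, 250.29), "exceed 1")
  expect_warning(kinetic_parameters(0.025, 0.69, 200, 250.29), "unusual")
})

test_that("intake summaries honour the LOQ substitution policy", {
  ds <- biomonitoring_dataset(data.frame(
    sample_id = c("a", "b"),
    concentration_ugL = c(0, NA),
    below_loq = c(FALSE, TRUE),
    loq_ugL = c(0.3, 0.3),
    age_group = "child"
  ))
  kp <- child_kp()
  # LOQ/2 policy: working concentrations {0, 0.15}
  s <- summarize_intakes(ds, kp, loq_policy = "loq_half")
  expect_equal(unname(s$quantiles["50%"]),
               reverse_dosimetry(mean(c(0, 0.15)), kp)$daily_intake)
  s2 <- summarize_intakes(ds, kp, loq_policy = "loq_sqrt2")
  expect_equal(s2$max,
               reverse_dosimetry(0.3 / sqrt(2), kp)$daily_intake)
  s3 <- summarize_intakes(ds, kp, loq_policy = "zero")
  expect_equal(s3$max, 0)
  s4 <- summarize_intakes(ds, kp, loq_policy = "exclude")
  expect_equal(s4$n, 1)
  expect_error(summarize_intakes(ds, kp, loq_policy = "nonsense"))
})

test_that("a constant dataset has equal median, P95 and maximum", {
  ds <- biomonitoring_dataset(data.frame(
    sample_id = sprintf("s%d", 1:5),
    concentration_ugL = 46.18,
    below_loq = FALSE, loq_ugL = 0.3, age_group = "child"))
  s <- summarize_intakes(ds, child_kp())
  expect_equal(unname(s$quantiles["50%"]), 2.68, tolerance = 0.005)
  expect_equal(unname(s$quantiles["50%"]), unname(s$quantiles["95%"]))
  expect_equal(unname(s$quantiles["95%"]), s$max)
})

test_that("synthetic survey intakes match the published median intake", {
  # generator quantile-matched to the survey distribution: the median
  # intake must follow from the dosimetry equation applied to 0.56 ug/L
  ds <- gen_urine_dataset(n = 250, seed = 23)
  s <- summarize_intakes(ds, child_kp())
  expect_equal(unname(s$quantiles["50%"]), 0.032, tolerance = 0.15)
})

test_that("biomonitoring tables read from text, including <LOQ entries", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,concentration_ugL,below_loq,loq_ugL,age_group",
    "s1,1.25,FALSE,0.3,child",
    "s2,<LOQ,FALSE,0.3,child",
    "s3,0.56,FALSE,0.3,child"), tf)
  ds <- read_biomonitoring(tf)
  expect_s3_class(ds, "biomonitoring_dataset")
  expect_equal(ds$below_loq, c(FALSE, TRUE, FALSE))
  expect_equal(ds$concentration_ugL, c(1.25, NA, 0.56))
  # corrupted numeric field names the line
  writeLines(c(
    "sample_id,concentration_ugL,below_loq,loq_ugL,age_group",
    "s1,oops,FALSE,0.3,child"), tf)
  expect_error(read_biomonitoring(tf), "line 2")
  unlink(tf)
})

test_that("duplicate ids and inconsistent censoring are rejected", {
  expect_error(biomonitoring_dataset(data.frame(
    sample_id = c("a", "a"), concentration_ugL = 1, below_loq = FALSE,
    loq_ugL = 0.3, age_group = "x")), "duplicate")
  expect_error(biomonitoring_dataset(data.frame(
    sample_id = "a", concentration_ugL = NA, below_loq = TRUE,
    loq_ugL = 0, age_group = "x")), "positive loq")
})
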