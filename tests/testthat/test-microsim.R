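test_that("5-year death probabilities annualise by constant hazard", {
  expect_equal(annual_mortality(0), 0)
  expect_equal(annual_mortality(1), 1)
  # algebraic inversion oracle: compounding the annual probability recovers p5
  p1 <- annual_mortality(0.226)
  expect_equal(1 - (1 - p1)^5, 0.226, tolerance = 1e-12)
  expect_equal(p1, 0.0500, tolerance = 2e-3)
  expect_error(annual_mortality(1.01), "\\[0, 1\\]")
})

test_that("degenerate mortality settings give the obvious QALY totals", {
  flat <- flat_utility(0.9, 0.6, 0.3)
  curve0 <- const_pain_curve(0)
  # certain death after one year: QALYs equal one year's utility
  certain <- list(utility = flat, life_table = const_life_table(1),
                  pain_curve = curve0)
  q <- simulate_individual(50, "non_maori", "male", "oa", certain,
                           det_params(30, 0.5), seed = 5)
  expect_equal(as.numeric(q), 0.6)
  expect_equal(attr(q, "years"), 1L)
  q_no <- simulate_individual(50, "non_maori", "male", "no_oa", certain,
                              det_params(), seed = 5)
  expect_equal(as.numeric(q_no), 0.9)
  # zero mortality until closure: full horizon at constant utility
  immortal <- list(utility = flat, life_table = const_life_table(0),
                   pain_curve = curve0)
  horizon <- 110 - 42 + 1
  q2 <- simulate_individual(42, "maori", "female", "no_oa", immortal,
                            det_params(), seed = 1)
  expect_equal(as.numeric(q2), horizon * 0.9)
  expect_equal(attr(q2, "years"), horizon)
})

test_that("simulator equals the closed-form QALE when pain is deterministic", {
  tables <- list(utility = FIX$utilities, life_table = LT_DEFAULT,
                 pain_curve = const_pain_curve(0))
  params <- det_params(30, 0.5)
  for (start in c(42, 67, 82)) {
    levels <- det_oa_levels(start, params)
    oracle <- qale_closed_form(start, "non_maori", "female", levels, tables)
    # mortality is the only randomness left: Monte Carlo mean must converge
    co <- simulate_cohort("non_maori", "female",
                          paste0(start - 2, "-", start + 2), "oa",
                          n = 4000, tables, params, seed = 9)
    expect_lt(abs(co$mean_qalys - oracle), 4 * co$se_qalys)
  }
  # fully deterministic check: certain one-year survival horizon
  tables1 <- list(utility = flat_utility(), life_table = const_life_table(1),
                  pain_curve = const_pain_curve(0))
  expect_equal(qale_closed_form(55, "maori", "male", "moderate", tables1), 0.6)
})

test_that("closed-form QALE matches the geometric series for constant hazard", {
  p5 <- 0.226
  q1 <- annual_mortality(p5)
  tables <- list(utility = flat_utility(0.8, 0.5, 0.2),
                 life_table = const_life_table(p5),
                 pain_curve = const_pain_curve(0))
  got <- qale_closed_form(42, "non_maori", "male", "none", tables)
  horizon <- 110 - 42 + 1
  series <- 0.8 * (1 - (1 - q1)^horizon) / q1  # sum of finite geometric series
  expect_equal(got, series, tolerance = 1e-10)
  # immortal until closure, utility 1: QALE equals the horizon length
  tables1 <- list(utility = flat_utility(1, 1, 1),
                  life_table = const_life_table(0),
                  pain_curve = const_pain_curve(0))
  expect_equal(qale_closed_form(42, "non_maori", "male", "none", tables1), horizon)
})

test_that("cohort summaries behave like Monte Carlo estimates", {
  tables <- default_tables()
  co1 <- simulate_cohort("maori", "female", "60-64", "oa", 1, tables, seed = 4)
  expect_equal(co1$se_qalys, 0)
  ind <- simulate_individual(62, "maori", "female", "oa", tables,
                             seed = oaburden:::derive_seed(4, which(
                               strata_grid()$ethnicity == "maori" &
                               strata_grid()$sex == "female" &
                               strata_grid()$age_band == "60-64"), 1))
  expect_equal(co1$mean_qalys, as.numeric(ind))
  # SE shrinks like 1/sqrt(n)
  co_a <- simulate_cohort("non_maori", "male", "50-54", "no_oa", 500, tables, seed = 2)
  co_b <- simulate_cohort("non_maori", "male", "50-54", "no_oa", 2000, tables, seed = 2)
  expect_gt(co_a$se_qalys / co_b$se_qalys, 1.5)
  expect_lt(co_a$se_qalys / co_b$se_qalys, 2.7)
  expect_error(simulate_cohort("maori", "male", "40-44", "oa", 0, tables), "at least 1")
})

test_that("fixed seed reproduces cohorts; order of individuals is irrelevant", {
  tables <- default_tables()
  a <- simulate_cohort("non_maori", "female", "70-74", "oa", 200, tables,
                       seed = 7, return_individuals = TRUE)
  b <- simulate_cohort("non_maori", "female", "70-74", "oa", 200, tables,
                       seed = 7, return_individuals = TRUE)
  expect_identical(a$qalys, b$qalys)
  # first 100 individuals of a 200-run equal a 100-run (counter-based streams)
  c100 <- simulate_cohort("non_maori", "female", "70-74", "oa", 100, tables,
                          seed = 7, return_individuals = TRUE)
  expect_identical(a$qalys[1:100], c100$qalys)
})

test_that("OA cohorts never out-accrue their matched no-OA cohorts", {
  tables <- default_tables()
  for (st in list(c("non_maori", "male", "45-49"), c("maori", "female", "65-69"),
                  c("non_maori", "female", "80-84"))) {
    oa <- simulate_cohort(st[1], st[2], st[3], "oa", 400, tables, seed = 21)
    no <- simulate_cohort(st[1], st[2], st[3], "no_oa", 400, tables, seed = 21)
    expect_lt(oa$mean_qalys, no$mean_qalys)
  }
})

test_that("raising every utility cell weakly raises every individual's QALYs", {
  lo <- flat_utility(0.85, 0.55, 0.25)
  hi <- flat_utility(0.90, 0.60, 0.30)
  base <- list(life_table = LT_DEFAULT, pain_curve = PC_DEFAULT)
  for (arm in c("oa", "no_oa")) {
    q_lo <- simulate_cohort("maori", "male", "55-59", arm, 300,
                            c(base, list(utility = lo)), seed = 13,
                            return_individuals = TRUE)$qalys
    q_hi <- simulate_cohort("maori", "male", "55-59", arm, 300,
                            c(base, list(utility = hi)), seed = 13,
                            return_individuals = TRUE)$qalys
    expect_true(all(q_hi >= q_lo))  # common random numbers: monotone coupling
  }
})

test_that("simulated longevity reproduces the life-table survival curve", {
  tables <- default_tables()
  start <- 42; n <- 3000
  g <- strata_grid()
  sid <- which(g$ethnicity == "non_maori" & g$sex == "male" & g$age_band == "40-44")
  yrs <- vapply(seq_len(n), function(i) {
    attr(simulate_individual(start, "non_maori", "male", "no_oa", tables,
                             seed = oaburden:::derive_seed(31, sid, i)), "years")
  }, integer(1))
  # life expectancy oracle: sum over years of survival-to-year-start
  ctx <- oaburden:::sim_context(start, "non_maori", "male", tables)
  surv_begin <- cumprod(c(1, (1 - ctx$p1_year)[-ctx$T]))
  e_years <- sum(surv_begin)
  se <- sd(yrs) / sqrt(n)
  expect_lt(abs(mean(yrs) - e_years), 4 * se)
  # survival at 10 and 25 years within binomial error
  for (h in c(10, 25)) {
    p_surv <- prod(1 - ctx$p1_year[seq_len(h)])
    emp <- mean(yrs > h)
    expect_lt(abs(emp - p_surv), 4 * sqrt(p_surv * (1 - p_surv) / n))
  }
})
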