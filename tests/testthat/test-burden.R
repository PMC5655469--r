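test_that("OA age distribution weights prevalent cases correctly", {
  expect_equal(unname(oa_age_distribution(uniform_prevalence(0.1),
                                          uniform_population(500),
                                          "non_maori", "male")),
               rep(1 / 9, 9))
  # prevalence concentrated in one band takes all the weight
  g <- strata_grid()
  g$prevalence <- ifelse(g$age_band == "60-64", 0.2, 0)
  w <- oa_age_distribution(prevalence_table(g), uniform_population(100),
                           "maori", "female")
  expect_equal(unname(w["60-64"]), 1)
  # spreadsheet-style oracle on published prevalence x decaying counts
  pop <- generate_population_counts(total = 1e6, age_decay = 0.8)
  w2 <- oa_age_distribution(FIX$prevalence, pop, "non_maori", "female")
  pr <- FIX$prevalence
  po <- pop
  manual <- sapply(core_age_bands(), function(b) {
    pr$prevalence[pr$ethnicity == "non_maori" & pr$sex == "female" & pr$age_band == b] *
      po$count[po$ethnicity == "non_maori" & po$sex == "female" & po$age_band == b]
  })
  expect_equal(unname(w2), unname(manual / sum(manual)), tolerance = 1e-12)
  expect_equal(sum(w2), 1)
  # all-zero numerator is degenerate
  expect_error(oa_age_distribution(uniform_prevalence(0), uniform_population(10),
                                   "maori", "male"), "degenerate")
})

test_that("counterfactual QALE is the weighted band average", {
  q <- setNames(c(30, 25, 20, 16, 12, 9, 7, 5, 4), core_age_bands())
  w1 <- setNames(c(1, rep(0, 8)), core_age_bands())
  expect_equal(counterfactual_qale(q, w1), 30)
  w <- setNames(rep(1 / 9, 9), core_age_bands())
  expect_equal(counterfactual_qale(setNames(rep(14.2, 9), core_age_bands()), w), 14.2)
  expect_equal(counterfactual_qale(q, w), mean(q))  # dot-product oracle
  expect_error(counterfactual_qale(q, w * 2), "sum to 1")
  expect_error(counterfactual_qale(q[1:3], setNames(c(0.5, 0.5), c("40-44", "95-99"))),
               "lacks band")
})

test_that("loss identities reproduce the published reference arithmetic", {
  expect_equal(per_person_loss(28.82, 22.34), 6.48)
  expect_equal(per_person_loss(15.54, 12.20), 3.34)
  expect_equal(per_person_loss(7, 7), 0)
  expect_equal(population_loss(2, 0, 1000), 0)
  expect_equal(population_loss(2, 0.1, 1000), 200)
  expect_equal(proportion_lost(3.34, 15.54), 0.215, tolerance = 1e-3)
  expect_equal(proportion_lost(2.60, 12.64), 0.2057, tolerance = 1e-4)
  expect_equal(proportion_lost(0, 4), 0)
  expect_error(proportion_lost(1, 0), "positive")
})

test_that("PPV adjustment scales prevalence and is invertible", {
  pr <- uniform_prevalence(0.18)
  adj <- adjust_prevalence(pr, 0.9)
  expect_equal(adj$prevalence, rep(0.162, 36))
  expect_true(attr(adj, "adjusted"))
  back <- adjust_prevalence(adj, 0.9, "unadjust")
  expect_equal(back$prevalence, pr$prevalence, tolerance = 1e-12)
  per_group <- adjust_prevalence(pr, c(non_maori.male = 1, non_maori.female = 1,
                                       maori.male = 0.8, maori.female = 0.8))
  expect_equal(unique(per_group$prevalence[per_group$ethnicity == "maori"]), 0.144)
  expect_error(adjust_prevalence(pr, 0), "\\(0, 1\\]")
})

fake_cohorts <- function(qale_no, qale_oa) {
  g <- strata_grid()
  rbind(data.frame(g, oa_status = "no_oa", mean_qalys = qale_no),
        data.frame(g, oa_status = "oa", mean_qalys = qale_oa))
}

test_that("burden tables aggregate consistently", {
  # identical QALE everywhere: every loss equals the stratum value
  bt <- build_burden_tables(fake_cohorts(20, 15), uniform_prevalence(0.1),
                            uniform_population(1000))
  expect_equal(bt$by_stratum$per_person_loss, rep(5, 36))
  expect_equal(bt$summary$per_person_loss, rep(5, 5))
  expect_equal(bt$summary$population_loss[5], 5 * 0.1 * 1000 * 36)

  # structured case: grand total is the sum of the four group totals
  g <- strata_grid()
  qale_no <- 30 - 2.5 * (match(g$age_band, core_age_bands()) - 1)
  qale_oa <- qale_no * 0.78
  pr <- FIX$prevalence
  pop <- generate_population_counts()
  bt2 <- build_burden_tables(fake_cohorts(qale_no, qale_oa), pr, pop)
  grp <- bt2$summary[bt2$summary$ethnicity != "all", ]
  tot <- bt2$summary[bt2$summary$ethnicity == "all", ]
  expect_equal(tot$population_loss, sum(grp$population_loss), tolerance = 1e-12)
  expect_equal(tot$population_loss, sum(bt2$by_stratum$population_loss),
               tolerance = 1e-12)
  expect_equal(tot$n_with_oa, sum(bt2$by_stratum$n_with_oa))
  # aggregate identity: per-person loss x cases = summed band losses
  expect_equal(grp$per_person_loss * grp$n_with_oa, grp$population_loss,
               tolerance = 1e-10)

  # missing stratum reported by name
  broken <- fake_cohorts(20, 15)
  broken <- broken[!(broken$age_band == "55-59" & broken$sex == "male" &
                       broken$ethnicity == "maori" & broken$oa_status == "oa"), ]
  expect_error(build_burden_tables(broken, pr, pop), "maori male 55-59 \\[oa\\]")
})

test_that("burden tables are order-invariant and scale linearly in prevalence", {
  g <- strata_grid()
  qale_no <- 28 - 2.2 * (match(g$age_band, core_age_bands()) - 1)
  cohorts <- fake_cohorts(qale_no, qale_no - 4)
  pr <- FIX$prevalence
  pop <- POP_DEFAULT
  bt <- build_burden_tables(cohorts, pr, pop)
  shuffled <- cohorts[rev(seq_len(nrow(cohorts))), ]
  expect_equal(build_burden_tables(shuffled, pr, pop), bt)
  # doubled prevalence: population losses double exactly; per-person losses
  # move only through the counterfactual weighting (here: unchanged weights)
  pr2 <- prevalence_table(within(as.data.frame(pr), prevalence <- prevalence * 2))
  bt2 <- build_burden_tables(cohorts, pr2, pop)
  expect_equal(bt2$by_stratum$population_loss, 2 * bt$by_stratum$population_loss,
               tolerance = 1e-12)
  expect_equal(bt2$summary$population_loss, 2 * bt$summary$population_loss,
               tolerance = 1e-12)
  expect_equal(bt2$summary$per_person_loss, bt$summary$per_person_loss,
               tolerance = 1e-12)
})
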