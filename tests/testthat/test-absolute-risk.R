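test_that("genotype relative risks follow the multiplicative model", {
  expect_equal(unname(genotypeRelativeRisks(1)), c(1, 1, 1))
  expect_equal(unname(genotypeRelativeRisks(1.33)), c(1, 1.33, 1.7689))
  expect_equal(unname(genotypeRelativeRisks(0.8)), c(1, 0.8, 0.64))
  expect_error(genotypeRelativeRisks(0), "positive")
})

test_that("population normalisation rescales to frequency-weighted mean 1", {
  # combined control genotype frequencies of the strongest marker
  f <- c(767, 836, 247) / 1850
  r <- populationNormalize(genotypeRelativeRisks(1.33), f)
  expect_equal(unname(round(r, 4)), c(0.7989, 1.0625, 1.4131))
  expect_lt(abs(sum(f * r) - 1), 1e-10)
  expect_equal(unname(populationNormalize(c(1, 1, 1), c(.2, .3, .5))),
               c(1, 1, 1))
  expect_equal(unname(populationNormalize(c(1, 3), c(.5, .5))), c(0.5, 1.5))
  expect_error(populationNormalize(c(1, 2), c(.7, .5)), "sum to 1")
})

test_that("every factor table normalises to mean 1 and combines by product", {
  cfg <- defaultSimulationConfig()
  ds <- simulateStudy(cfg, seed = 301)
  snp_ors <- setNames(cfg@snpAllelicOrs, snpInfo(ds)$snp_id)
  clin_ors <- list(menarche_cat = c(early = 3.118, normal = 1.622),
                   first_birth_cat = c(late = 1.868))
  tabs <- relativeRiskTables(ds, snp_ors, clin_ors)
  for (tab in tabs)
    expect_lt(abs(sum(tab$freq * tab$r) - 1), 1e-10)
  rr <- combinedRelativeRisk(ds, tabs)
  # product oracle for a hom-risk / early-menarche / late-birth subject
  d <- matrix(2L, 5, 1, dimnames = list(snpInfo(ds)$snp_id, "H01"))
  hom <- StudyDataset(d, snpInfo(ds), data.frame(
    subject_id = "H01", status = "case", stage = "testing", age = 50,
    menarche_cat = "early", first_birth_cat = "late", menopause = "pre"))
  expected <- prod(vapply(snpInfo(ds)$snp_id,
                          function(s) tabs[[s]]$r[3], numeric(1))) *
    tabs$menarche_cat$r[tabs$menarche_cat$level == "early"] *
    tabs$first_birth_cat$r[tabs$first_birth_cat$level == "late"]
  expect_equal(unname(combinedRelativeRisk(hom, tabs)), expected,
               tolerance = 1e-12)
  # frequency-weighted averaging keeps the cohort mean near 1 under
  # independence of the factors
  expect_lt(abs(mean(rr[!isCase(ds)], na.rm = TRUE) - 1), 0.05)
})

test_that("closed-form projection matches its analytic special cases", {
  flat <- HazardSchedule(data.frame(age_start = 20, age_end = 85,
                                    incidence = 0.01, mortality = 0))
  expect_equal(projectAbsoluteRisk(1, flat), 1 - exp(-0.65),
               tolerance = 1e-12)
  none <- HazardSchedule(data.frame(age_start = 20, age_end = 85,
                                    incidence = 0, mortality = 0.01))
  expect_equal(projectAbsoluteRisk(1, none), 0)
  expect_error(projectAbsoluteRisk(-1, flat), "positive")
  expect_error(projectAbsoluteRisk(1, flat, age_start = 10), "covers")
})

test_that("closed form agrees with numerical ODE integration to 1e-8", {
  skip_if_not_installed("deSolve")
  sched <- syntheticHazardSchedule()
  bands <- hazardBands(sched)
  for (r in c(0.4, 1, 2.7)) {
    state <- c(S = 1, A = 0)
    for (j in seq_len(nrow(bands))) {
      h1 <- r * bands$incidence[j]; h2 <- bands$mortality[j]
      sol <- deSolve::lsoda(
        state, times = c(0, bands$age_end[j] - bands$age_start[j]),
        func = function(t, y, parms)
          list(c(-(h1 + h2) * y[1], h1 * y[1])),
        rtol = 1e-12, atol = 1e-14)
      state <- c(S = unname(sol[2, "S"]), A = unname(sol[2, "A"]))
    }
    expect_equal(projectAbsoluteRisk(r, sched), unname(state["A"]),
                 tolerance = 1e-8)
  }
})

test_that("absolute risk is monotone in r and in competing mortality", {
  sched <- syntheticHazardSchedule()
  rs <- c(0.25, 0.5, 1, 2, 4, 8)
  ar <- projectAbsoluteRisk(rs, sched)
  expect_true(all(diff(ar) > 0))
  expect_true(all(ar >= 0 & ar <= 1))
  heavier <- HazardSchedule(within(hazardBands(sched),
                                   mortality <- mortality * 5))
  expect_true(all(projectAbsoluteRisk(rs, heavier) < ar))
})

test_that("small cumulative hazards reduce to the first-order limit", {
  tiny <- HazardSchedule(data.frame(age_start = c(20, 50), age_end = c(50, 85),
                                    incidence = c(2e-5, 5e-5),
                                    mortality = c(1e-5, 4e-5)))
  expected <- 1.3 * (2e-5 * 30 + 5e-5 * 35)
  expect_equal(projectAbsoluteRisk(1.3, tiny), expected, tolerance = 0.01)
})

test_that("high-risk classification uses multiples of the median", {
  ars <- c(0.05, 0.06, 0.07, 0.08, 0.30)
  cls <- classifyHighRisk(ars, 2)
  expect_equal(cls$threshold, 0.14)
  expect_identical(cls$flag, ars >= 0.14)
  expect_equal(classifyHighRisk(ars, 3)$threshold, 0.21)
  all_eq <- classifyHighRisk(rep(0.07, 10), 1)
  expect_true(all(all_eq$flag))
  expect_error(classifyHighRisk(ars, 0), "positive")
})

test_that("median relative and absolute risk rise across allele-count bins", {
  cfg <- defaultSimulationConfig()
  ds <- simulateStudy(cfg, seed = 302)
  snp_ors <- setNames(cfg@snpAllelicOrs, snpInfo(ds)$snp_id)
  tabs <- relativeRiskTables(ds, snp_ors,
                             list(menarche_cat = c(early = 3.118,
                                                   normal = 1.622),
                                  first_birth_cat = c(late = 1.868)))
  rr <- combinedRelativeRisk(ds, tabs)
  ar <- projectAbsoluteRisk(rr, syntheticHazardSchedule())
  bins <- riskCountBins(countRiskAlleles(ds), 1, 6)
  med_rr <- tapply(rr, bins, median, na.rm = TRUE)
  med_ar <- tapply(ar, bins, median, na.rm = TRUE)
  expect_true(all(diff(med_rr) > 0))
  expect_true(all(diff(med_ar) > 0))
})
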