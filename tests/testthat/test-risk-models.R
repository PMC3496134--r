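# a deterministic dataset with known dosages for the five-marker panel
fixedDataset <- function(dosages, menarche = "late", first_birth = "early") {
  panel <- publishedPanel()
  n <- ncol(dosages)
  subj <- data.frame(
    subject_id = sprintf("F%02d", seq_len(n)),
    status = rep_len(c("case", "control"), n),
    stage = "testing", age = 50,
    menarche_cat = rep_len(menarche, n),
    first_birth_cat = rep_len(first_birth, n),
    menopause = "pre", stringsAsFactors = FALSE)
  rownames(dosages) <- panel$snp_id
  colnames(dosages) <- subj$subject_id
  StudyDataset(dosages, panel, subj)
}

test_that("risk-allele and risk-factor counts follow the counting rules", {
  d <- cbind(rep(1L, 5), rep(2L, 5), rep(0L, 5), c(2L, 1L, 0L, 2L, NA))
  ds <- fixedDataset(d, menarche = c("early", "late", "late", "normal"),
                     first_birth = c("late", "early", "early", "late"))
  expect_equal(unname(countRiskAlleles(ds)), c(5, 10, 0, NA))
  expect_equal(unname(countRiskFactors(ds)), c(7, 10, 0, NA))
  expect_equal(unname(countRiskFactors(ds, menarche_ordinal = TRUE)),
               c(8, 10, 0, NA))
})

test_that("counts flip dosage for a major risk allele", {
  panel <- publishedPanel()
  panel$risk_allele[1] <- panel$major_allele[1]
  d <- matrix(0L, 5, 2, dimnames = list(panel$snp_id, c("F01", "F02")))
  d[1, ] <- c(0L, 2L)
  subj <- toySubjects(2)
  subj$subject_id <- c("F01", "F02")
  ds <- StudyDataset(d, panel, subj)
  expect_equal(unname(countRiskAlleles(ds)), c(2, 0))
})

test_that("published additive ORs map to the expected log-OR weights", {
  ors <- c(rs13387042 = 1.25, rs2307032 = 1.14, rs2180341 = 1.08,
           rs2046210 = 1.33, rs2981582 = 1.27)
  model <- buildRiskScore(ors)
  expect_equal(unname(round(snpWeights(model), 3)),
               c(0.223, 0.131, 0.077, 0.285, 0.239))
  expect_error(buildRiskScore(c(rs1 = -2)), "positive")
  expect_error(buildRiskScore(1.2), "named")
})

test_that("scores respect trivial invariances", {
  d <- matrix(sample(0:2, 5 * 40, TRUE), 5)
  ds <- fixedDataset(d)
  ors <- c(rs13387042 = 1.25, rs2307032 = 1.14, rs2180341 = 1.08,
           rs2046210 = 1.33, rs2981582 = 1.27)
  model <- buildRiskScore(ors)
  s <- scoreSubjects(model, ds, include_clinical = FALSE)
  # zero-weight model scores everyone 0
  null_model <- buildRiskScore(setNames(rep(1, 5), names(ors)))
  expect_equal(unname(scoreSubjects(null_model, ds, FALSE)), rep(0, 40))
  # SNP order inside the model does not matter
  model_rev <- buildRiskScore(rev(ors))
  expect_equal(scoreSubjects(model_rev, ds, FALSE), s)
  # hom-risk-everywhere subject scores twice the weight sum
  hom <- fixedDataset(matrix(2L, 5, 1))
  expect_equal(unname(scoreSubjects(model, hom, FALSE)),
               2 * sum(snpWeights(model)))
})

test_that("quartile grouping uses control quartiles, boundaries upward", {
  ctrl <- c(1, 2, 3, 4, 5, 6, 7, 8)           # Q25=2.75, Q50=4.5, Q75=6.25
  g <- quartileGroups(c(1, 2.75, 4.5, 6.25, 10), ctrl)
  expect_equal(as.integer(g), c(0, 1, 2, 3, 3))
  expect_equal(attr(g, "cutpoints"),
               unname(quantile(ctrl, c(.25, .5, .75))))
  # controls grouped on themselves split about evenly
  set.seed(15)
  cs <- runif(4000)
  gg <- quartileGroups(cs, cs)
  expect_true(all(abs(table(gg) / 4000 - 0.25) < 0.02))
  expect_error(quartileGroups(1:5, rep(2, 10)), "distinct")
})

test_that("grouped OR analysis matches the crude cross-product on 2 groups", {
  # published top-vs-bottom allele-count counts: cases 97/187, controls 57/295
  n_top <- 97 + 57; n_bot <- 187 + 295
  subj <- data.frame(
    subject_id = sprintf("G%03d", seq_len(n_top + n_bot)),
    status = c(rep(c("case", "control"), c(97, 57)),
               rep(c("case", "control"), c(187, 295))),
    stage = "testing", age = 50, menarche_cat = "late",
    first_birth_cat = "early", menopause = "pre",
    stringsAsFactors = FALSE)
  panel <- toyPanel()
  d <- matrix(0L, 2, n_top + n_bot,
              dimnames = list(panel$snp_id, subj$subject_id))
  ds <- StudyDataset(d, panel, subj)
  groups <- rep(c(1L, 0L), c(n_top, n_bot))
  res <- groupedOrAnalysis(groups, ds, covariates = character(0))
  expect_equal(res$or_point[2], (97 * 295) / (57 * 187), tolerance = 1e-6)
  expect_equal(res$or_point[2], 2.685, tolerance = 1e-3)
  expect_equal(res$n_cases, c(187, 97))
  # relabelling but keeping membership and order leaves the OR alone
  res2 <- groupedOrAnalysis(groups * 10L + 5L, ds, covariates = character(0))
  expect_equal(res2$or_point[2], res$or_point[2])
})

test_that("grouped ORs and case fractions rise across risk bins", {
  cfg <- defaultSimulationConfig()
  ds <- simulateStudy(cfg, seed = 2024)
  counts <- countRiskFactors(ds)
  bins <- riskCountBins(counts, first = 2, last = 7)
  frac <- tapply(isCase(ds), bins, mean)
  expect_true(all(diff(frac) > 0))
  res <- groupedOrAnalysis(bins, ds, covariates = c("age", "menopause"))
  expect_true(all(diff(res$or_point) > 0))
  expect_lt(attr(res, "p_trend"), 1e-6)
  # weighted-score quartiles show the same pattern
  model <- estimateRiskScore(ds)
  s <- scoreSubjects(model, ds)
  g <- quartileGroups(s, s[!isCase(ds)])
  res_q <- groupedOrAnalysis(g, ds)
  expect_true(all(diff(res_q$or_point) > 0))
})

test_that("trend P is uniform under the null grouping", {
  cfg <- defaultSimulationConfig()
  cfg@snpAllelicOrs[] <- 1
  cfg@clinicalOrs <- list(menarche_cat = c(early = 1, normal = 1, late = 1),
                          first_birth_cat = c(early = 1, late = 1))
  p <- vapply(1:40, function(i) {
    ds <- sampleCaseControl(simulatePopulation(cfg, 8000, seed = 1500 + i),
                            200, 200, seed = 1600 + i)
    counts <- countRiskAlleles(ds)
    attr(groupedOrAnalysis(riskCountBins(counts), ds,
                           covariates = character(0)), "p_trend")
  }, numeric(1))
  expect_lte(mean(p <= 0.05), 0.15)
  expect_gt(mean(p), 0.3)
})
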