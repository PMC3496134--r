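test_that("HWE exact test equals brute-force enumeration on small tables", {
  for (n_tot in c(5, 12, 25)) {
    for (hom_minor in 0:floor(n_tot / 2)) {
      for (het in 0:(n_tot - 2 * hom_minor)) {
        counts <- c(n_tot - het - hom_minor, het, hom_minor)
        expect_equal(hweExactTest(counts),
                     bruteForceHwe(counts[1], counts[2], counts[3]),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("HWE exact test handles degenerate and published inputs", {
  expect_equal(hweExactTest(c(100, 0, 0)), 1)   # monomorphic
  expect_error(hweExactTest(c(-1, 2, 3)), "non-negative")
  ctrl <- publishedTable("rs2046210")["control", ]
  expect_lt(abs(hweExactTest(ctrl) - 0.50), 0.005)
})

test_that("HWE test P-values are near-uniform under simulated equilibrium", {
  set.seed(404)
  p <- replicate(400, {
    g <- rbinom(300, 2, 0.3)
    hweExactTest(c(sum(g == 0), sum(g == 1), sum(g == 2)))
  })
  # discreteness pushes the rejection rate at or below nominal
  expect_lte(mean(p <= 0.05), 0.07)
  expect_gt(mean(p), 0.35)
})

test_that("FFH exact test equals independent oracles", {
  # full enumeration oracle on every 2x3 table with small margins
  set.seed(101)
  for (rep in 1:150) {
    N <- sample(6:40, 1)
    cells <- as.vector(stats::rmultinom(1, N, prob = runif(6, 0.2, 1)))
    tab <- matrix(cells, 2, 3)
    if (any(rowSums(tab) == 0) || sum(colSums(tab) > 0) < 2) next
    p <- genotypeTableTest(tab[1, ], tab[2, ])
    expect_equal(p, fisher.test(tab[, colSums(tab) > 0])$p.value,
                 tolerance = 1e-7)
    if (sum(tab) <= 24)
      expect_equal(p, bruteForceFfh(tab[, colSums(tab) > 0, drop = FALSE]),
                   tolerance = 1e-10)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("FFH and chi-square behave on published genotype tables", {
  for (s in c("rs2981582", "rs2180341", "rs2307032")) {
    tab <- publishedTable(s)
    p_exact <- genotypeTableTest(tab["case", ], tab["control", ])
    p_chi <- genotypeTableTest(tab["case", ], tab["control", ],
                               method = "chi2")
    # dense tables: the two tests agree to 2 significant figures
    expect_equal(signif(p_exact, 2), signif(p_chi, 2))
  }
  # identical proportions give P = 1 under chi-square
  expect_equal(genotypeTableTest(c(10, 20, 30), c(10, 20, 30), "chi2"), 1)
  expect_error(genotypeTableTest(c(0, 0, 0), c(1, 2, 3)), "non-empty")
})

test_that("chi-square path matches stats::chisq.test and drops empty columns", {
  tab <- publishedTable("rs2046210")
  expect_equal(
    genotypeTableTest(tab["case", ], tab["control", ], "chi2"),
    suppressWarnings(chisq.test(tab, correct = FALSE))$p.value,
    tolerance = 1e-12)
  # empty third genotype column: reduces to a 2x2, 1 df
  expect_equal(
    genotypeTableTest(c(30, 10, 0), c(20, 20, 0), "chi2"),
    suppressWarnings(
      chisq.test(rbind(c(30, 10), c(20, 20)), correct = FALSE))$p.value,
    tolerance = 1e-12)
})

test_that("fitLogistic matches a reference IRLS and the 2x2 closed form", {
  set.seed(77)
  for (rep in 1:5) {
    n <- 300
    X <- cbind(`(Intercept)` = 1, x1 = rnorm(n), x2 = rbinom(n, 1, 0.4))
    y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, "x1"] - 0.4 * X[, "x2"]))
    fit <- fitLogistic(y, X)
    expect_equal(unname(fit$coefficients), irlsOracle(y, X),
                 tolerance = 1e-6)
  }
  # combined-set carrier table: OR identical to the cross-product ratio
  y <- rep(c(1, 0, 1, 0), c(1186, 1083, 582, 767))
  x <- rep(c(1, 1, 0, 0), c(1186, 1083, 582, 767))
  fit <- fitLogistic(y, cbind(carrier = x))
  expect_equal(unname(exp(fit$coefficients["carrier"])),
               (1186 * 767) / (582 * 1083), tolerance = 1e-8)
})

test_that("fitLogistic reports separation and degenerate designs", {
  y <- c(rep(0, 10), rep(1, 10))
  x <- c(rep(0, 10), rep(1, 10))
  expect_error(fitLogistic(y, cbind(sep_pred = x)), "sep_pred")
  expect_error(fitLogistic(y, cbind(a = 1:20, b = 2 * (1:20))),
               "rank deficient")
  expect_error(fitLogistic(c(0, 1, 2), cbind(x = 1:3)), "binary")
})

test_that("snpAssociation reduces to the closed form without covariates", {
  cfg <- defaultSimulationConfig()
  ds <- sampleCaseControl(simulatePopulation(cfg, 20000, seed = 31),
                          400, 400, seed = 32)
  s <- "rs2046210"
  res <- snpAssociation(ds, s, "dominant", covariates = character(0))
  cc <- genotypeCounts(ds, s, "case"); ct <- genotypeCounts(ds, s, "control")
  a <- cc[["het"]] + cc[["hom_minor"]]; b <- cc[["hom_major"]]
  c2 <- ct[["het"]] + ct[["hom_minor"]]; d <- ct[["hom_major"]]
  expect_equal(res$or_point, (a * d) / (b * c2), tolerance = 1e-8)
  expect_true(res$ci_low <= res$or_point && res$or_point <= res$ci_high)
  # genotype coding: two terms against the hom-major reference
  g <- snpAssociation(ds, s, "genotype", covariates = character(0))
  expect_identical(g$term, c("het", "hom_minor"))
})

test_that("additive Wald CIs cover a null odds ratio at about 95%", {
  cfg <- defaultSimulationConfig()
  cfg@snpAllelicOrs[] <- 1
  cfg@clinicalOrs <- list(menarche_cat = c(early = 1, normal = 1, late = 1),
                          first_birth_cat = c(early = 1, late = 1))
  covered <- vapply(1:60, function(i) {
    ds <- sampleCaseControl(simulatePopulation(cfg, 6000, seed = 500 + i),
                            150, 150, seed = 600 + i)
    res <- snpAssociation(ds, "rs2046210", "additive",
                          covariates = character(0))
    res$ci_low <= 1 && 1 <= res$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("two-stage screening thresholds the testing-set exact P-values", {
  panel <- publishedScreeningPanel()
  dummy <- snpPanel(panel$snp_id, panel$chrom_band, seq_len(nrow(panel)),
                    "G", "A")
  sel <- twoStageScreen(panel = dummy,
                        p_values = setNames(panel$p_assoc, panel$snp_id))
  expect_setequal(sel$snp_id, c("rs13387042", "rs2307032", "rs2180341",
                                "rs2046210", "rs2981582"))
  expect_identical(
    twoStageScreen(panel = dummy, alpha = 1e-300,
                   p_values = setNames(panel$p_assoc, panel$snp_id))$snp_id,
    character(0))
  expect_identical(
    twoStageScreen(panel = dummy, alpha = 1,
                   p_values = setNames(panel$p_assoc, panel$snp_id))$snp_id,
    dummy$snp_id)
})

test_that("screening on simulated data has the nominal type-I error", {
  cfg <- defaultSimulationConfig()
  cfg@snpAllelicOrs[] <- 1
  hits <- vapply(1:60, function(i) {
    ds <- sampleCaseControl(simulatePopulation(cfg, 6000, seed = 700 + i),
                            150, 150, seed = 800 + i)
    nrow(twoStageScreen(ds, alpha = 0.05))
  }, numeric(1))
  # 5 SNPs x 60 replicates, expected false-positive rate ~0.05 per SNP
  expect_lte(mean(hits) / 5, 0.12)
})

test_that("baseline comparisons use the right test family", {
  expect_equal(compareBaseline(c(1, 2, 3, 4), c(1, 2, 3, 4), "continuous"), 1)
  set.seed(9)
  a <- rnorm(1000); b <- rnorm(1000, 1)
  expect_lt(compareBaseline(a, b, "continuous"), 1e-3)
  # heteroscedastic groups trigger Welch's t'
  aa <- rnorm(200, sd = 1); bb <- rnorm(200, mean = 0.2, sd = 4)
  expect_equal(compareBaseline(aa, bb, "continuous"),
               t.test(aa, bb, var.equal = FALSE)$p.value, tolerance = 1e-12)
  # 2x2 categorical equals the classic two-sided Fisher exact test
  cases <- rep(c("yes", "no"), c(30, 20))
  ctrls <- rep(c("yes", "no"), c(18, 40))
  expect_equal(compareBaseline(cases, ctrls, "categorical"),
               fisher.test(rbind(c(20, 30), c(40, 18)))$p.value,
               tolerance = 1e-9)
  expect_error(compareBaseline(rep("a", 5), rep("a", 5), "categorical"),
               "2 categories")
})
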