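## Exact genotype tests, adjusted logistic odds ratios and the two-stage
## screening workflow.

## relative tolerance for "probability <= observed" in two-sided exact tests;
## keeps the probability-ordering rule stable under floating-point noise
.TIE_TOL <- 1e-7

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the heterozygote count given the allele counts:
#' the two-sided P-value is the sum of the conditional probabilities of all
#' attainable heterozygote counts whose probability does not exceed that of
#' the observed count (probability ordering, capped at 1). Conventionally run
#' on controls.
#'
#' @param counts numeric length-3 vector `c(hom_major, het, hom_minor)`.
#' @return the two-sided exact P-value.
#' @examples
#' hweExactTest(c(387, 393, 110))
#' @export
hweExactTest <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || anyNA(counts) || any(counts < 0))
    stop("counts must be three non-negative numbers (hom_major, het, hom_minor)")
  n <- sum(counts)
  if (n == 0) stop("empty genotype table")
  n_minor <- 2 * counts[3] + counts[2]
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  ## log P(het = h | n, n_minor), up to a constant
  lp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (n_minor + hets) / 2 + 1) + hets * log(2)
  lp <- lp - max(lp)
  p <- exp(lp) / sum(exp(lp))
  p_obs <- p[hets == counts[2]]
  min(1, sum(p[p <= p_obs * (1 + .TIE_TOL)]))
}

## log hypergeometric probability of a full 2xk table given margins
.logTableProb <- function(top, row_tot, col_tot) {
  bottom <- col_tot - top
  if (any(top < 0) || any(bottom < 0)) return(-Inf)
  sum(lgamma(row_tot + 1)) + sum(lgamma(col_tot + 1)) -
    lgamma(sum(row_tot) + 1) - sum(lgamma(top + 1)) - sum(lgamma(bottom + 1))
}

## Fisher-Freeman-Halton exact P for a 2xk table (k = 2 or 3), probability
## ordering, vectorised enumeration over the free cells of the first row
.ffhExact <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) != 2) stop("table must have 2 rows")
  keep <- colSums(tab) > 0
  tab <- tab[, keep, drop = FALSE]
  k <- ncol(tab)
  if (k < 2) stop("table has fewer than 2 non-empty columns")
  if (k > 3) stop("exact test implemented for 2 or 3 categories")
  R <- rowSums(tab); C <- colSums(tab); N <- sum(tab)
  lconst <- sum(lgamma(R + 1)) + sum(lgamma(C + 1)) - lgamma(N + 1)
  if (k == 2) {
    a <- max(0, R[1] - C[2]):min(R[1], C[1])
    ll <- lconst - lgamma(a + 1) - lgamma(C[1] - a + 1) -
      lgamma(R[1] - a + 1) - lgamma(C[2] - R[1] + a + 1)
    lobs <- lconst - lgamma(tab[1, 1] + 1) - lgamma(tab[2, 1] + 1) -
      lgamma(tab[1, 2] + 1) - lgamma(tab[2, 2] + 1)
  } else {
    g <- expand.grid(a = 0:min(R[1], C[1]), b = 0:min(R[1], C[2]))
    cc <- R[1] - g$a - g$b
    ok <- cc >= 0 & cc <= C[3]
    g <- g[ok, ]; cc <- cc[ok]
    ll <- lconst - lgamma(g$a + 1) - lgamma(g$b + 1) - lgamma(cc + 1) -
      lgamma(C[1] - g$a + 1) - lgamma(C[2] - g$b + 1) - lgamma(C[3] - cc + 1)
    lobs <- lconst - sum(lgamma(tab + 1))
  }
  min(1, sum(exp(ll[ll <= lobs + log1p(.TIE_TOL)])))
}

## Pearson chi-square on a 2xk table; zero-margin columns dropped, df reduced
.pearsonChi2 <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  df <- ncol(tab) - 1
  if (df < 1) stop("no degrees of freedom left after dropping empty columns")
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Case-control genotype-table test
#'
#' Compares the 2x3 genotype distribution between cases and controls, either
#' by the Fisher-Freeman-Halton exact test (enumeration of all tables with
#' the observed margins; two-sided P is the total probability of tables no
#' more probable than the observed one) or by the Pearson chi-square on 2 df
#' (empty genotype columns are dropped and the df reduced).
#'
#' @param case_counts,control_counts length-3 counts
#'   `c(hom_major, het, hom_minor)` for cases and controls.
#' @param method `"ffh_exact"` (default) or `"chi2"`.
#' @return the two-sided P-value.
#' @examples
#' genotypeTableTest(c(290, 413, 158), c(387, 393, 110))  # ~1.26e-5
#' @export
genotypeTableTest <- function(case_counts, control_counts,
                              method = c("ffh_exact", "chi2")) {
  method <- match.arg(method)
  tab <- rbind(case = as.numeric(case_counts),
               control = as.numeric(control_counts))
  if (anyNA(tab) || any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0)) stop("both groups must be non-empty")
  if (method == "ffh_exact") .ffhExact(tab) else .pearsonChi2(tab)$p_value
}

#' Maximum-likelihood logistic regression with safety checks
#'
#' Iteratively-reweighted-least-squares fit of a binomial GLM (via
#' [stats::glm.fit]), with explicit failure modes: non-convergence within 100
#' iterations and quasi-complete separation (any non-intercept coefficient
#' with |beta| > 15) raise errors naming the predictor.
#'
#' @param outcome 0/1 vector (or logical).
#' @param design numeric design matrix, one row per subject; an intercept
#'   column is added unless one is present (a column of 1s named
#'   `(Intercept)`).
#' @return list with `coefficients`, `se`, `vcov`, `n`, `loglik`;
#'   odds ratios are `exp(coefficients)` with Wald 95% CIs
#'   `exp(beta +/- 1.96 se)`.
#' @export
fitLogistic <- function(outcome, design) {
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!"(Intercept)" %in% colnames(X))
    X <- cbind(`(Intercept)` = 1, X)
  if (nrow(X) <= ncol(X)) stop("more predictors than observations")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  fit <- stats::glm.fit(X, y, family = stats::binomial(),
                        control = stats::glm.control(epsilon = 1e-10,
                                                     maxit = 100))
  beta <- fit$coefficients
  big <- abs(beta) > 15 & names(beta) != "(Intercept)"
  if (any(big))
    stop("complete or quasi-complete separation on predictor(s): ",
         paste(names(beta)[big], collapse = ", "))
  if (!fit$converged) stop("IRLS did not converge in 100 iterations")
  ## covariance from the weighted cross-product at the optimum
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  vc <- solve(XtWX)
  dimnames(vc) <- list(names(beta), names(beta))
  list(coefficients = beta, se = sqrt(diag(vc)), vcov = vc,
       n = length(y), loglik = -fit$deviance / 2)
}

## design columns for the standard covariate adjustment:
## age continuous; menarche two indicators vs late; menopause post vs pre;
## first birth late vs early
.covariateDesign <- function(subjects, covariates) {
  cols <- list()
  for (cv in covariates) {
    if (cv == "age") cols$age <- subjects$age
    else if (cv == "menarche_cat") {
      cols$menarche_early <- as.numeric(subjects$menarche_cat == "early")
      cols$menarche_normal <- as.numeric(subjects$menarche_cat == "normal")
    } else if (cv == "menopause")
      cols$menopause_post <- as.numeric(subjects$menopause == "post")
    else if (cv == "first_birth_cat")
      cols$first_birth_late <- as.numeric(subjects$first_birth_cat == "late")
    else stop("unknown covariate: ", cv)
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

.genoDesign <- function(dosage, coding) {
  switch(coding,
         additive = cbind(dosage = dosage),
         dominant = cbind(carrier = as.numeric(dosage >= 1)),
         recessive = cbind(hom_minor = as.numeric(dosage == 2)),
         genotype = cbind(het = as.numeric(dosage == 1),
                          hom_minor = as.numeric(dosage == 2)),
         stop("unknown coding: ", coding))
}

#' Covariate-adjusted SNP association under a genetic coding
#'
#' Fits a logistic model of case status on the genotype term(s) of one SNP
#' plus the requested covariates, complete-case on genotype and covariates.
#' Codings: `additive` (0/1/2 dosage), `dominant` (carrier of the minor
#' allele), `recessive` (minor-allele homozygote), `genotype` (two
#' indicators against the major-allele homozygote reference).
#'
#' @param dataset a [StudyDataset-class].
#' @param snp_id marker identifier.
#' @param coding genetic coding, see above.
#' @param covariates subset of
#'   `c("age", "menarche_cat", "menopause", "first_birth_cat")`; empty vector
#'   for a crude model.
#' @param stratum `"combined"`, `"testing"` or `"validation"`.
#' @return `data.frame` with one row per genotype term: `snp_id, coding,
#'   term, stratum, n_used, or_point, ci_low, ci_high, p_value, covariates`.
#' @export
snpAssociation <- function(dataset, snp_id,
                           coding = c("additive", "dominant", "recessive",
                                      "genotype"),
                           covariates = c("age", "menarche_cat", "menopause",
                                          "first_birth_cat"),
                           stratum = c("combined", "testing", "validation")) {
  coding <- match.arg(coding)
  stratum <- match.arg(stratum)
  ds <- subsetStage(dataset, stratum)
  if (ncol(ds) == 0) stop("empty stratum: ", stratum)
  if (!snp_id %in% rownames(ds)) stop("SNP not in panel: ", snp_id)
  subj <- subjectInfo(ds)
  dosage <- dosageMatrix(ds)[snp_id, ]
  cov_design <- .covariateDesign(subj, covariates)
  keep <- !is.na(dosage)
  if (!is.null(cov_design)) keep <- keep & stats::complete.cases(cov_design)
  dosage <- dosage[keep]
  if (length(unique(dosage)) < 2) stop("SNP monomorphic in stratum: ", snp_id)
  if (coding == "recessive" && !any(dosage == 2))
    stop("no minor-allele homozygotes; recessive coding undefined for ",
         snp_id)
  X <- .genoDesign(dosage, coding)
  if (!is.null(cov_design)) X <- cbind(X, cov_design[keep, , drop = FALSE])
  y <- as.numeric(subj$status[keep] == "case")
  fit <- fitLogistic(y, X)
  terms <- colnames(.genoDesign(dosage, coding))
  beta <- fit$coefficients[terms]
  se <- fit$se[terms]
  data.frame(
    snp_id = snp_id, coding = coding, term = terms, stratum = stratum,
    n_used = fit$n,
    or_point = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    covariates = paste(covariates, collapse = "+"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-1 significance screen of a marker panel
#'
#' Selects the markers whose testing-set genotype-table exact P-value falls
#' below `alpha`, preserving panel order — the first stage of the two-stage
#' design. Precomputed screening P-values (e.g. published ones) can be
#' supplied instead of a dataset.
#'
#' @param dataset a [StudyDataset-class]; ignored when `p_values` is given.
#' @param alpha significance level (default 0.05).
#' @param panel SNP panel to screen; defaults to the dataset's panel.
#' @param p_values optional named numeric vector of screening P-values, one
#'   per panel SNP.
#' @return the selected subset of the panel, with a `p_screen` column.
#' @export
twoStageScreen <- function(dataset = NULL, alpha = 0.05, panel = NULL,
                           p_values = NULL) {
  if (is.null(panel)) {
    if (is.null(dataset)) stop("need a dataset or an explicit panel")
    panel <- snpInfo(dataset)
  }
  if (is.null(p_values)) {
    ts <- subsetStage(dataset, "testing")
    if (ncol(ts) == 0) stop("no testing-stage subjects")
    p_values <- vapply(panel$snp_id, function(s)
      genotypeTableTest(genotypeCounts(ts, s, "case"),
                        genotypeCounts(ts, s, "control")), numeric(1))
  } else {
    if (is.null(names(p_values))) names(p_values) <- panel$snp_id
    p_values <- p_values[panel$snp_id]
    if (anyNA(p_values)) stop("p_values must cover every panel SNP")
  }
  out <- panel[p_values < alpha, , drop = FALSE]
  out$p_screen <- unname(p_values[p_values < alpha])
  rownames(out) <- NULL
  out
}

#' Stage-2 confirmation of screened markers
#'
#' A screened marker is confirmed when its validation-set crude allelic
#' association points in the same direction as in the testing set and its
#' combined-stratum genotype-table exact P-value is below `alpha`.
#'
#' @param dataset a [StudyDataset-class] with both stages.
#' @param candidates panel subset from [twoStageScreen()].
#' @param alpha combined-stratum significance level.
#' @return the confirmed subset of `candidates` with columns
#'   `p_combined` and `direction_consistent`.
#' @export
confirmValidation <- function(dataset, candidates, alpha = 0.05) {
  if (nrow(candidates) == 0) return(cbind(candidates, p_combined = numeric(0)))
  crudeLogOr <- function(stage, s) {
    cc <- genotypeCounts(dataset, s, "case", stage)
    ct <- genotypeCounts(dataset, s, "control", stage)
    ## allelic 2x2 with 0.5 continuity correction to stay finite
    a <- 2 * cc[["hom_minor"]] + cc[["het"]]; b <- 2 * sum(cc) - a
    c <- 2 * ct[["hom_minor"]] + ct[["het"]]; d <- 2 * sum(ct) - c
    log(((a + .5) * (d + .5)) / ((b + .5) * (c + .5)))
  }
  same_dir <- vapply(candidates$snp_id, function(s)
    sign(crudeLogOr("testing", s)) == sign(crudeLogOr("validation", s)),
    logical(1))
  p_comb <- vapply(candidates$snp_id, function(s)
    genotypeTableTest(genotypeCounts(dataset, s, "case"),
                      genotypeCounts(dataset, s, "control")), numeric(1))
  keep <- same_dir & p_comb < alpha
  out <- candidates[keep, , drop = FALSE]
  out$p_combined <- unname(p_comb[keep])
  out$direction_consistent <- TRUE
  rownames(out) <- NULL
  out
}

#' Baseline case-control comparison
#'
#' Continuous variables: Student's t-test with pooled variance when an F-test
#' of variance equality has P >= 0.05, otherwise Welch's t'. Categorical
#' variables: Fisher-Freeman-Halton exact test on the 2xk table of category
#' counts (classic two-sided Fisher exact test when k = 2).
#'
#' @param cases,controls value vectors for the two groups; factors or
#'   characters for `kind = "categorical"`.
#' @param kind `"continuous"` or `"categorical"`.
#' @return the two-sided P-value.
#' @export
compareBaseline <- function(cases, controls,
                            kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!length(cases) || !length(controls))
    stop("both groups must be non-empty")
  if (kind == "continuous") {
    cases <- cases[!is.na(cases)]; controls <- controls[!is.na(controls)]
    if (stats::sd(cases) == 0 && stats::sd(controls) == 0 &&
        mean(cases) == mean(controls)) return(1)
    equal_var <- stats::var.test(cases, controls)$p.value >= 0.05
    stats::t.test(cases, controls, var.equal = equal_var)$p.value
  } else {
    lev <- sort(unique(c(as.character(cases), as.character(controls))))
    if (length(lev) < 2) stop("need at least 2 categories")
    tab <- rbind(table(factor(cases, lev)), table(factor(controls, lev)))
    .ffhExact(tab)
  }
}
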