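## Cumulative risk models: risk-allele/factor counting, and the OR-weighted
## log-odds risk score with control-quartile grouping.

## risk-allele dosage: panel orientation decides whether the stored
## minor-allele dosage is counted directly or flipped
.riskDosage <- function(dataset) {
  panel <- snpInfo(dataset)
  d <- dosageMatrix(dataset)
  flip <- panel$risk_allele == panel$major_allele
  d[flip, ] <- 2L - d[flip, , drop = FALSE]
  d
}

#' Count risk alleles per subject
#'
#' Sum over panel SNPs of the risk-allele dosage (0-2 each; 0-10 for a
#' five-SNP panel). Subjects with any missing panel genotype get `NA`
#' (complete-case exclusion happens downstream).
#'
#' @param dataset a [StudyDataset-class].
#' @return named integer vector, one count per subject.
#' @export
countRiskAlleles <- function(dataset) {
  colSums(.riskDosage(dataset))
}

#' Count risk alleles plus clinical risk factors
#'
#' Adds to [countRiskAlleles()] one point for early menarche (< 15 years)
#' and one for late first live birth (>= 25 years); with
#' `menarche_ordinal = TRUE` the menarche contribution is instead ordinal
#' (early 2, normal 1, late 0). Subjects with a missing clinical category
#' get `NA`.
#'
#' @param dataset a [StudyDataset-class].
#' @param menarche_ordinal use the three-level ordinal menarche coding.
#' @return named integer vector (range 0-12 binary, 0-13 ordinal, for five
#'   SNPs).
#' @export
countRiskFactors <- function(dataset, menarche_ordinal = FALSE) {
  subj <- subjectInfo(dataset)
  men <- if (menarche_ordinal)
    c(early = 2L, normal = 1L, late = 0L)[as.character(subj$menarche_cat)]
  else as.integer(subj$menarche_cat == "early")
  fb <- as.integer(subj$first_birth_cat == "late")
  countRiskAlleles(dataset) + men + fb
}

#' Bin risk counts the way grouped analyses use them
#'
#' Collapses a count vector into ordered bins: everything up to `first`
#' merged into the bottom bin, everything from `last` up merged into the top
#' bin, unit bins in between. The conventional bins are `first = 1, last =
#' 6` for allele counts (0-1, 2, 3, 4, 5, >= 6) and `first = 2, last = 7`
#' for allele-plus-factor counts.
#'
#' @param counts integer vector from [countRiskAlleles()] or
#'   [countRiskFactors()].
#' @param first upper edge of the bottom bin.
#' @param last lower edge of the top bin.
#' @return ordered factor, `NA` preserved.
#' @export
riskCountBins <- function(counts, first = 1, last = 6) {
  breaks <- c(-Inf, first:(last - 1), Inf)
  labels <- c(if (first > 0) paste0("0-", first) else "0",
              if (last - first > 1) as.character((first + 1):(last - 1)),
              paste0(">=", last))
  cut(counts, breaks = breaks, labels = labels, right = TRUE,
      ordered_result = TRUE)
}

#' Build an OR-weighted risk-score model
#'
#' Weights are the logs of the supplied odds ratios: one additive per-allele
#' OR per SNP, and one OR per non-reference clinical category (reference
#' categories get weight 0). The log odds of the score are additive in the
#' number of minor alleles at each locus and additive across SNPs and
#' clinical factors.
#'
#' @param snp_ors named positive numeric: combined-set adjusted additive OR
#'   per SNP.
#' @param clinical_ors optional list of named positive numeric vectors, e.g.
#'   `list(menarche_cat = c(early = 3.1, normal = 1.6), first_birth_cat =
#'   c(late = 1.9))`; omitted categories are reference.
#' @return A [RiskScoreModel-class] (cutpoints empty until
#'   [quartileGroups()]).
#' @export
buildRiskScore <- function(snp_ors, clinical_ors = list()) {
  if (any(unlist(snp_ors) <= 0) || any(unlist(clinical_ors) <= 0))
    stop("odds ratios must be positive")
  if (is.null(names(snp_ors))) stop("snp_ors must be named by snp_id")
  cw <- lapply(clinical_ors, log)
  new("RiskScoreModel", snpWeights = log(unlist(snp_ors)),
      clinicalWeights = cw, cutpoints = numeric(0))
}

#' Estimate a risk-score model from a dataset
#'
#' SNP weights are log combined-set adjusted additive ORs from
#' [snpAssociation()]; clinical weights are log adjusted ORs of the
#' menarche and first-birth categories from one logistic model with the
#' standard covariates.
#'
#' @param dataset a [StudyDataset-class].
#' @param covariates adjustment set for the per-SNP models.
#' @param stratum stratum the weights are estimated in.
#' @return A [RiskScoreModel-class].
#' @export
estimateRiskScore <- function(dataset,
                              covariates = c("age", "menarche_cat",
                                             "menopause", "first_birth_cat"),
                              stratum = "combined") {
  panel <- snpInfo(dataset)
  ors <- vapply(panel$snp_id, function(s)
    snpAssociation(dataset, s, "additive", covariates, stratum)$or_point,
    numeric(1))
  subj <- subjectInfo(subsetStage(dataset, stratum))
  X <- .covariateDesign(subj, c("age", "menarche_cat", "menopause",
                                "first_birth_cat"))
  keep <- stats::complete.cases(X)
  fit <- fitLogistic(as.numeric(subj$status[keep] == "case"),
                     X[keep, , drop = FALSE])
  cw <- list(
    menarche_cat = c(early = unname(fit$coefficients["menarche_early"]),
                     normal = unname(fit$coefficients["menarche_normal"])),
    first_birth_cat = c(late = unname(fit$coefficients["first_birth_late"])))
  new("RiskScoreModel", snpWeights = log(ors), clinicalWeights = cw,
      cutpoints = numeric(0))
}

#' Score subjects with a risk-score model
#'
#' `score = sum(dosage * snp_weight)` over the model's SNPs, plus the
#' subject's clinical category weights when `include_clinical = TRUE`.
#' Dosage here is minor-allele dosage — the weights already carry the
#' direction of effect. Subjects missing any needed variable get `NA`.
#'
#' @param model a [RiskScoreModel-class].
#' @param dataset a [StudyDataset-class].
#' @param include_clinical add the clinical-factor weights.
#' @return named numeric vector of scores.
#' @export
scoreSubjects <- function(model, dataset, include_clinical = TRUE) {
  w <- snpWeights(model)
  missing_snps <- setdiff(names(w), rownames(dataset))
  if (length(missing_snps))
    stop("model SNP(s) absent from dataset: ",
         paste(missing_snps, collapse = ", "))
  d <- dosageMatrix(dataset)[names(w), , drop = FALSE]
  score <- as.vector(t(d) %*% w)
  names(score) <- colnames(dataset)
  if (include_clinical && length(clinicalWeights(model))) {
    subj <- subjectInfo(dataset)
    for (f in names(clinicalWeights(model))) {
      cw <- clinicalWeights(model)[[f]]
      lev <- as.character(subj[[f]])
      contrib <- cw[lev]
      contrib[is.na(contrib) & !is.na(lev)] <- 0  # reference category
      score <- score + as.numeric(contrib)
    }
  }
  n_excluded <- sum(is.na(score))
  if (n_excluded > 0)
    message(n_excluded, " subject(s) excluded from scoring (missing data)")
  score
}

#' Group scores by control quartiles
#'
#' Cutpoints are the 25th/50th/75th percentiles of the control scores
#' (linear-interpolation percentile definition); groups are `[min, Q25)`,
#' `[Q25, Q50)`, `[Q50, Q75)`, `[Q75, Inf)`, with boundary values assigned
#' to the upper group.
#'
#' @param scores numeric scores for all subjects.
#' @param control_scores scores of the control subjects the quartiles are
#'   estimated from.
#' @return integer group index 0-3 per subject (`NA` scores stay `NA`),
#'   with the cutpoints in `attr(, "cutpoints")`.
#' @export
quartileGroups <- function(scores, control_scores) {
  cs <- control_scores[!is.na(control_scores)]
  if (length(unique(cs)) < 4)
    stop("need at least 4 distinct control scores to form quartiles")
  q <- unname(stats::quantile(cs, c(0.25, 0.5, 0.75), type = 7))
  g <- findInterval(scores, q)  # boundary values go up
  attr(g, "cutpoints") <- q
  g
}

#' Grouped odds-ratio analysis of a risk grouping
#'
#' Adjusted OR of each group against the bottom (reference) group from one
#' logistic model with group indicators plus covariates, and a trend
#' P-value from a second model with the group index as a single ordinal
#' term. Groups empty in either status stratum are collapsed into the
#' neighbouring lower group (with a message). When the grouping derives
#' from a score that already contains menarche/first-birth, those
#' covariates should be dropped from the adjustment to avoid
#' double-adjustment — the default covariate set here is age and menopause
#' only; pass the full set explicitly to force it.
#'
#' @param groups group labels (integer or factor), one per subject,
#'   `NA` excluded.
#' @param dataset the [StudyDataset-class] the groups belong to.
#' @param covariates adjustment covariates.
#' @return `data.frame` with per-group `group, n_cases, n_controls,
#'   or_point, ci_low, ci_high, p_value` (reference row OR 1) and the trend
#'   P-value in `attr(, "p_trend")`.
#' @export
groupedOrAnalysis <- function(groups, dataset,
                              covariates = c("age", "menopause")) {
  subj <- subjectInfo(dataset)
  if (is.factor(groups)) {
    g <- as.integer(groups)            # 1-based index into the labels
    labels_all <- levels(groups)
  } else {
    vals <- sort(unique(groups[!is.na(groups)]))
    g <- match(groups, vals)
    labels_all <- as.character(vals)
  }
  cov_design <- .covariateDesign(subj, covariates)
  keep <- !is.na(g)
  if (!is.null(cov_design)) keep <- keep & stats::complete.cases(cov_design)
  g <- g[keep]
  y <- as.numeric(subj$status[keep] == "case")
  ## collapse groups empty in either status into the lower neighbour
  repeat {
    lev <- sort(unique(g))
    bad <- vapply(lev, function(l)
      !any(y[g == l] == 1) || !any(y[g == l] == 0), logical(1))
    if (!any(bad)) break
    l <- lev[which(bad)[1]]
    target <- if (l == min(lev)) lev[lev > l][1] else max(lev[lev < l])
    message("collapsing empty group ", labels_all[l], " into ",
            labels_all[target])
    g[g == l] <- target
  }
  lev <- sort(unique(g))
  g_idx <- match(g, lev) - 1L
  ind <- vapply(seq_along(lev)[-1], function(i)
    as.numeric(g_idx == (i - 1L)), numeric(length(g_idx)))
  colnames(ind) <- paste0("grp", lev[-1])
  X <- if (is.null(cov_design)) ind else
    cbind(ind, cov_design[keep, , drop = FALSE])
  fit <- fitLogistic(y, X)
  beta <- fit$coefficients[colnames(ind)]
  se <- fit$se[colnames(ind)]
  res <- data.frame(
    group = labels_all[lev],
    n_cases = vapply(lev, function(l) sum(y[g == l] == 1), numeric(1)),
    n_controls = vapply(lev, function(l) sum(y[g == l] == 0), numeric(1)),
    or_point = c(1, exp(beta)),
    ci_low = c(NA, exp(beta - 1.96 * se)),
    ci_high = c(NA, exp(beta + 1.96 * se)),
    p_value = c(NA, 2 * stats::pnorm(-abs(beta / se))),
    row.names = NULL, stringsAsFactors = FALSE)
  Xt <- if (is.null(cov_design)) cbind(trend = g_idx) else
    cbind(trend = g_idx, cov_design[keep, , drop = FALSE])
  tfit <- fitLogistic(y, Xt)
  attr(res, "p_trend") <- unname(
    2 * stats::pnorm(-abs(tfit$coefficients["trend"] / tfit$se["trend"])))
  res
}
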