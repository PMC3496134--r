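## ROC/AUC with DeLong variance, the paired DeLong test, Youden operating
## points and stratified cross-validated AUC.

## placement values of DeLong's estimator, midrank tie handling
.placements <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  m <- length(x); n <- length(y)
  if (m == 0 || n == 0) stop("both classes must be present")
  r_all <- rank(c(x, y))
  v10 <- (r_all[seq_len(m)] - rank(x)) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
  list(v10 = v10, v01 = v01, m = m, n = n)
}

#' AUC with DeLong variance
#'
#' The area under the ROC curve as the Mann-Whitney statistic
#' `P(score_case > score_control) + 0.5 P(equal)` computed from midranks,
#' with its variance from DeLong's placement-value components and a Wald
#' 95% CI truncated to `[0, 1]`.
#'
#' @param scores numeric risk scores (`NA` dropped pairwise with labels).
#' @param labels case indicators: logical, 0/1, or `"case"`/`"control"`.
#' @return list with `auc`, `variance`, `ci_low`, `ci_high`, `n_cases`,
#'   `n_controls`.
#' @export
aucDeLong <- function(scores, labels) {
  is_case <- .asCaseIndicator(labels)
  keep <- !is.na(scores) & !is.na(is_case)
  p <- .placements(scores[keep], is_case[keep])
  auc <- mean(p$v10)
  v <- stats::var(p$v10) / p$m + stats::var(p$v01) / p$n
  half <- 1.96 * sqrt(v)
  list(auc = auc, variance = v,
       ci_low = max(0, auc - half), ci_high = min(1, auc + half),
       n_cases = p$m, n_controls = p$n)
}

.asCaseIndicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == "case"
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two scores measured on the same subjects:
#' `z = (auc_a - auc_b) / sqrt(var_a + var_b - 2 cov)` with the covariance
#' from paired placement values, two-sided normal P.
#'
#' @param scores_a,scores_b two scores for the same subjects, same order.
#' @param labels case indicators as in [aucDeLong()].
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`, `var_diff`.
#' @export
delongTest <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("scores must cover the same subjects")
  is_case <- .asCaseIndicator(labels)
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(is_case)
  pa <- .placements(scores_a[keep], is_case[keep])
  pb <- .placements(scores_b[keep], is_case[keep])
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  var_diff <- stats::var(pa$v10 - pb$v10) / pa$m +
    stats::var(pa$v01 - pb$v01) / pa$n
  if (var_diff <= .Machine$double.eps) {
    warning("zero variance of the AUC difference; P set to 1")
    return(list(auc_a = auc_a, auc_b = auc_b, z = 0, p_value = 1,
                var_diff = var_diff))
  }
  z <- (auc_a - auc_b) / sqrt(var_diff)
  list(auc_a = auc_a, auc_b = auc_b, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), var_diff = var_diff)
}

#' Youden-optimal operating point
#'
#' Scans all attainable cutoffs of the rule "positive when
#' `score >= cutoff`" and returns the one maximising Youden's
#' `J = sensitivity + specificity - 1`; ties are broken toward higher
#' specificity (the larger cutoff).
#'
#' @param scores numeric risk scores.
#' @param labels case indicators as in [aucDeLong()].
#' @return list with `cutoff`, `sensitivity`, `specificity`, `youden_j`.
#' @export
youdenPoint <- function(scores, labels) {
  is_case <- .asCaseIndicator(labels)
  keep <- !is.na(scores) & !is.na(is_case)
  s <- scores[keep]; lab <- is_case[keep]
  x <- s[lab]; y <- s[!lab]
  if (!length(x) || !length(y)) stop("both classes must be present")
  cuts <- sort(unique(s))
  sens <- vapply(cuts, function(cc) mean(x >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(y < cc), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  pick <- best[which.max(spec[best])]
  list(cutoff = cuts[pick], sensitivity = sens[pick],
       specificity = spec[pick], youden_j = j[pick])
}

#' ROC coordinates for plotting
#'
#' @param scores,labels as in [aucDeLong()].
#' @return `data.frame` of `cutoff, sensitivity, specificity` over all
#'   attainable cutoffs (descending cutoff: curve from (0,0) to (1,1)).
#' @export
rocCoordinates <- function(scores, labels) {
  is_case <- .asCaseIndicator(labels)
  keep <- !is.na(scores) & !is.na(is_case)
  s <- scores[keep]; lab <- is_case[keep]
  cuts <- c(Inf, rev(sort(unique(s))))
  data.frame(
    cutoff = cuts,
    sensitivity = vapply(cuts, function(cc) mean(s[lab] >= cc), numeric(1)),
    specificity = vapply(cuts, function(cc) mean(s[!lab] < cc), numeric(1)))
}

#' Builder factory for cross-validated risk-score models
#'
#' Returns a `model_builder` for [cvAuc()]: fits the OR-weighted score on
#' the training split via [estimateRiskScore()] and scores held-out
#' subjects, optionally using only the genetic or only the clinical part.
#'
#' @param include_genetic keep the SNP weights.
#' @param include_clinical keep the clinical-factor weights.
#' @param covariates adjustment set used when estimating the weights.
#' @return function(train_dataset) -> function(test_dataset) -> scores.
#' @export
scoreModelBuilder <- function(include_genetic = TRUE,
                              include_clinical = TRUE,
                              covariates = c("age", "menarche_cat",
                                             "menopause",
                                             "first_birth_cat")) {
  if (!include_genetic && !include_clinical)
    stop("the model must include at least one component")
  function(train) {
    model <- estimateRiskScore(train, covariates)
    if (!include_genetic) model@snpWeights[] <- 0
    function(test) scoreSubjects(model, test,
                                 include_clinical = include_clinical)
  }
}

#' Stratified k-fold cross-validated AUC
#'
#' Subjects are split into `k` folds stratified by case status; the model
#' builder is fitted on the other `k - 1` folds and scores the held-out
#' fold; one AUC is computed on the pooled held-out scores (the
#' lower-variance convention, rather than averaging per-fold AUCs). A fold
#' missing a class triggers a re-randomisation (at most 10 attempts).
#'
#' @param dataset a [StudyDataset-class].
#' @param model_builder function(train) -> function(test) -> scores, e.g.
#'   from [scoreModelBuilder()].
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @return list with `auc`, `variance`, `ci_low`, `ci_high`, plus the
#'   pooled held-out `scores` and `folds`.
#' @export
cvAuc <- function(dataset, model_builder, k = 10, seed = 1) {
  if (k < 2) stop("k must be at least 2")
  lab <- isCase(dataset)
  if (min(sum(lab), sum(!lab)) < k)
    stop("fewer subjects than folds in one class")
  for (attempt in seq_len(10)) {
    set.seed(as.integer(seed) + attempt - 1L)
    folds <- integer(ncol(dataset))
    folds[lab] <- sample(rep_len(seq_len(k), sum(lab)))
    folds[!lab] <- sample(rep_len(seq_len(k), sum(!lab)))
    ok <- all(vapply(seq_len(k), function(f)
      any(lab[folds == f]) && any(!lab[folds == f]), logical(1)))
    if (ok) break
    if (attempt == 10) stop("could not stratify folds in 10 attempts")
  }
  scores <- rep(NA_real_, ncol(dataset))
  for (f in seq_len(k)) {
    hold <- folds == f
    scorer <- model_builder(dataset[, !hold])
    scores[hold] <- scorer(dataset[, hold])
  }
  res <- aucDeLong(scores, lab)
  c(res[c("auc", "variance", "ci_low", "ci_high")],
    list(scores = scores, folds = folds))
}
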