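## Config-driven end-to-end orchestration: screen -> validate -> combined
## association -> risk models -> absolute risk -> discrimination, with a
## run log and a deterministic machine-readable summary.

#' Assemble a pipeline configuration
#'
#' Exactly one input source is used, in this order of precedence: an
#' in-memory `dataset`, a delimited `genotype_table` (with `panel`), or —
#' when both are `NULL` — a synthetic study simulated from
#' [defaultSimulationConfig()] with the config seed.
#'
#' @param out_dir output directory (created if needed).
#' @param dataset optional [StudyDataset-class].
#' @param genotype_table optional path for [readGenotypeTable()].
#' @param panel SNP panel for `genotype_table`.
#' @param hazard_schedule optional CSV path for [readHazardSchedule()];
#'   `NULL` uses the bundled [syntheticHazardSchedule()].
#' @param alpha stage-1 screening significance level.
#' @param covariates adjustment covariates for association models.
#' @param cutoff_multiples multiples of the median absolute risk used to
#'   flag high-risk subjects.
#' @param cv_folds folds for cross-validated AUC.
#' @param seed master seed; all pipeline randomness derives from it.
#' @return a validated config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(out_dir, dataset = NULL, genotype_table = NULL,
                           panel = NULL, hazard_schedule = NULL,
                           alpha = 0.05,
                           covariates = c("age", "menarche_cat", "menopause",
                                          "first_birth_cat"),
                           cutoff_multiples = c(2, 3), cv_folds = 10,
                           seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (!is.null(genotype_table)) {
    if (!file.exists(genotype_table))
      stop("genotype_table does not exist: ", genotype_table)
    if (is.null(panel)) stop("genotype_table input needs a panel")
  }
  if (!is.null(hazard_schedule) && !file.exists(hazard_schedule))
    stop("hazard_schedule does not exist: ", hazard_schedule)
  structure(list(out_dir = out_dir, dataset = dataset,
                 genotype_table = genotype_table, panel = panel,
                 hazard_schedule = hazard_schedule, alpha = alpha,
                 covariates = covariates,
                 cutoff_multiples = cutoff_multiples,
                 cv_folds = cv_folds, seed = as.integer(seed)),
            class = "pipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipelineConfig()] (paths only; in-memory
#' datasets cannot be configured from file).
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `pipelineConfig`.
#' @export
readPipelineConfig <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$panel_file)) {
    p <- utils::read.table(y$panel_file, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
    y$panel <- snpPanel(p$snp_id, p$chrom_band, p$position, p$major_allele,
                        p$minor_allele, p$risk_allele)
    y$panel_file <- NULL
  }
  y$out_dir <- if (!is.null(out_dir)) out_dir else y$out_dir
  do.call(pipelineConfig, y)
}

.logLine <- function(log_path, ...) {
  line <- paste0(...)
  cat(line, "\n", file = log_path, append = TRUE, sep = "")
  message(line)
}

#' Run the full risk-assessment pipeline
#'
#' Executes, in order: data loading, baseline case-control comparisons,
#' stage-1 screening, stage-2 confirmation, combined adjusted association
#' for the confirmed markers, both cumulative risk models (counting and
#' OR-weighted score) with grouped odds ratios, modified-Gail absolute-risk
#' projection with high-risk classification, and ROC/AUC discrimination
#' with DeLong comparison and cross-validation. Every stage writes its
#' result table under `config$out_dir`; a run log and a deterministic
#' machine-readable `summary.json` close the run. A stage failure aborts
#' with the stage name; tables already written are left in place. When the
#' screen confirms no marker, the genetic downstream stages are skipped and
#' the skip is logged.
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, the summary list.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  cat("", file = log_path)
  summary <- list(seed = config$seed, alpha = config$alpha,
                  package_version = as.character(
                    utils::packageVersion("snpRiskAssess")))
  stage <- "load_data"
  run <- function(stage_name, expr) {
    stage <- stage_name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage_name, "' failed: ",
           conditionMessage(e), call. = FALSE))
  }

  ds <- run("load_data", {
    if (!is.null(config$dataset)) config$dataset
    else if (!is.null(config$genotype_table))
      readGenotypeTable(config$genotype_table, config$panel)
    else {
      .logLine(log_path, "no input data; simulating the default study, seed ",
               config$seed)
      simulateStudy(defaultSimulationConfig(), seed = config$seed)
    }
  })
  .logLine(log_path, "loaded ", ncol(ds), " subjects x ", nrow(ds), " SNPs; ",
           sum(isCase(ds)), " cases / ", sum(!isCase(ds)), " controls")
  summary$n_subjects <- ncol(ds); summary$n_snps <- nrow(ds)

  run("baseline", {
    subj <- subjectInfo(ds)
    cs <- subj$status == "case"
    baseline <- data.frame(
      variable = c("age", "menarche_cat", "first_birth_cat"),
      kind = c("continuous", "categorical", "categorical"),
      p_value = c(
        compareBaseline(subj$age[cs], subj$age[!cs], "continuous"),
        compareBaseline(subj$menarche_cat[cs], subj$menarche_cat[!cs],
                        "categorical"),
        compareBaseline(subj$first_birth_cat[cs], subj$first_birth_cat[!cs],
                        "categorical")))
    writeResultsTsv(baseline, file.path(config$out_dir, "baseline.tsv"))
    summary$baseline <- stats::setNames(as.list(baseline$p_value),
                                         baseline$variable)
  })

  screened <- run("screen", {
    sc <- twoStageScreen(ds, alpha = config$alpha)
    writeResultsTsv(sc, file.path(config$out_dir, "screen.tsv"))
    sc
  })
  .logLine(log_path, "stage-1 screen at alpha=", config$alpha, ": ",
           nrow(screened), " marker(s) pass")
  summary$screened_snps <- screened$snp_id

  validated <- run("validate", {
    v <- confirmValidation(ds, screened, alpha = config$alpha)
    writeResultsTsv(v, file.path(config$out_dir, "validated.tsv"))
    v
  })
  summary$validated_snps <- validated$snp_id
  if (nrow(validated) == 0) {
    .logLine(log_path,
             "no marker confirmed; skipping genetic risk models, absolute ",
             "risk and discrimination stages")
    summary$skipped <- c("association", "risk_models", "absolute_risk",
                         "discrimination")
    writeResultsJson(summary, file.path(config$out_dir, "summary.json"))
    return(invisible(summary))
  }

  dsv <- ds[validated$snp_id, ]
  assoc <- run("association", {
    a <- do.call(rbind, lapply(validated$snp_id, function(s) rbind(
      snpAssociation(dsv, s, "additive", config$covariates, "combined"),
      snpAssociation(dsv, s, "dominant", config$covariates, "combined"))))
    writeResultsTsv(a, file.path(config$out_dir, "association.tsv"))
    a
  })

  risk <- run("risk_models", {
    model <- estimateRiskScore(dsv, config$covariates)
    complete <- !is.na(countRiskFactors(dsv))
    .logLine(log_path, "complete-case subjects for risk models: ",
             sum(complete), " of ", ncol(dsv))
    dcc <- dsv[, complete]
    alleles <- countRiskAlleles(dcc)
    factors <- countRiskFactors(dcc)
    score_g <- scoreSubjects(model, dcc, include_clinical = FALSE)
    score_gc <- scoreSubjects(model, dcc, include_clinical = TRUE)
    ctrl <- !isCase(dcc)
    groupings <- list(
      allele_counts = as.integer(riskCountBins(alleles, 1, 6)) - 1L,
      factor_counts = as.integer(riskCountBins(factors, 2, 7)) - 1L,
      genetic_score = quartileGroups(score_g, score_g[ctrl]),
      genetic_clinical_score = quartileGroups(score_gc, score_gc[ctrl]))
    tabs <- lapply(names(groupings), function(nm) {
      covs <- if (nm %in% c("allele_counts", "genetic_score"))
        config$covariates else c("age", "menopause")
      g <- groupedOrAnalysis(groupings[[nm]], dcc, covs)
      g$model <- nm
      g$p_trend <- attr(g, "p_trend")
      g
    })
    writeResultsTsv(do.call(rbind, tabs),
                    file.path(config$out_dir, "risk_groups.tsv"))
    list(model = model, data = dcc, scores = list(genetic = score_g,
                                                  combined = score_gc),
         counts = list(alleles = alleles, factors = factors))
  })
  summary$snp_weights <- as.list(snpWeights(risk$model))

  run("absolute_risk", {
    schedule <- if (is.null(config$hazard_schedule)) syntheticHazardSchedule()
      else readHazardSchedule(config$hazard_schedule)
    snp_ors <- exp(snpWeights(risk$model))
    clin_ors <- lapply(clinicalWeights(risk$model), exp)
    tables <- relativeRiskTables(risk$data, snp_ors, clin_ors)
    rr <- combinedRelativeRisk(risk$data, tables)
    ar <- projectAbsoluteRisk(rr, schedule)
    out <- data.frame(subject_id = colnames(risk$data),
                      combined_relative_risk = unname(rr),
                      absolute_risk = unname(ar),
                      age_start = 20, age_end = 85)
    writeResultsTsv(out, file.path(config$out_dir, "absolute_risk.tsv"))
    summary$absolute_risk <- list(
      median = stats::median(ar, na.rm = TRUE),
      deciles = as.list(stats::setNames(
        stats::quantile(ar, seq(0.1, 0.9, 0.1), na.rm = TRUE, names = FALSE),
        paste0("d", 1:9))))
    for (k in config$cutoff_multiples) {
      cls <- classifyHighRisk(ar, k)
      .logLine(log_path, sprintf(
        "high-risk at %gx median (threshold %.4f): %.2f%% of subjects",
        k, cls$threshold, 100 * cls$fraction_high))
      summary$absolute_risk[[paste0("frac_above_", k, "x_median")]] <-
        cls$fraction_high
    }
  })

  run("discrimination", {
    lab <- isCase(risk$data)
    apparent <- list(
      weighted_combined = aucDeLong(risk$scores$combined, lab),
      weighted_genetic = aucDeLong(risk$scores$genetic, lab),
      counting_combined = aucDeLong(risk$counts$factors, lab))
    cmp <- delongTest(risk$scores$combined, risk$counts$factors, lab)
    op <- youdenPoint(risk$scores$combined, lab)
    cv <- list(
      snps_only = cvAuc(risk$data, scoreModelBuilder(TRUE, FALSE),
                        k = config$cv_folds, seed = config$seed + 10L),
      factors_only = cvAuc(risk$data, scoreModelBuilder(FALSE, TRUE),
                           k = config$cv_folds, seed = config$seed + 11L),
      snps_plus_factors = cvAuc(risk$data, scoreModelBuilder(TRUE, TRUE),
                                k = config$cv_folds,
                                seed = config$seed + 12L))
    disc <- list(
      apparent_auc = lapply(apparent, function(a)
        a[c("auc", "ci_low", "ci_high")]),
      weighted_vs_counting_p = cmp$p_value,
      youden = op,
      cv_auc = lapply(cv, function(a) a$auc))
    writeResultsJson(disc, file.path(config$out_dir, "discrimination.json"))
    writeResultsTsv(rocCoordinates(risk$scores$combined, lab),
                    file.path(config$out_dir, "roc_weighted_combined.tsv"))
    summary$discrimination <- disc
  })

  writeResultsJson(summary, file.path(config$out_dir, "summary.json"))
  .logLine(log_path, "pipeline complete")
  invisible(summary)
}
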