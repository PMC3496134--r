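#' @import methods
#' @importFrom stats median plogis qlogis quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.table write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

## tokens accepted as a missing genotype in delimited input
.MISSING_TOKENS <- c("", "NA", "NN", ".")

.PANEL_COLUMNS <- c("snp_id", "chrom_band", "position", "major_allele",
                    "minor_allele", "risk_allele", "associated_genes")

.SUBJECT_COLUMNS <- c("subject_id", "status", "stage", "age",
                      "menarche_cat", "first_birth_cat", "menopause")

.MENARCHE_LEVELS    <- c("early", "normal", "late")
.FIRST_BIRTH_LEVELS <- c("early", "late")
.STATUS_LEVELS      <- c("control", "case")
.STAGE_LEVELS       <- c("testing", "validation")
.MENOPAUSE_LEVELS   <- c("pre", "post")

#' Build and validate a SNP panel
#'
#' A panel is a `data.frame` with one row per biallelic marker: identifier,
#' cytoband, 1-based position, major/minor alleles and the designated risk
#' allele. The risk allele is fixed in the panel definition (by convention the
#' minor allele for markers whose per-allele odds ratio exceeds 1) so that
#' risk-allele orientation never silently flips between study stages.
#'
#' @param snp_id character vector of unique marker identifiers.
#' @param chrom_band cytoband labels (e.g. `"6q25.1"`).
#' @param position 1-based genomic coordinates.
#' @param major_allele,minor_allele single-character nucleotide codes.
#' @param risk_allele the allele counted by risk models; must equal the major
#'   or the minor allele of that marker. Defaults to the minor allele.
#' @param associated_genes free-text annotation.
#' @return A validated `data.frame` with columns
#'   `snp_id, chrom_band, position, major_allele, minor_allele, risk_allele,
#'   associated_genes`.
#' @examples
#' snpPanel("rs2046210", "6q25.1", 151990059, "G", "A")
#' @export
snpPanel <- function(snp_id, chrom_band, position, major_allele, minor_allele,
                     risk_allele = minor_allele, associated_genes = "") {
  panel <- data.frame(
    snp_id = as.character(snp_id),
    chrom_band = as.character(chrom_band),
    position = as.integer(position),
    major_allele = as.character(major_allele),
    minor_allele = as.character(minor_allele),
    risk_allele = as.character(risk_allele),
    associated_genes = as.character(associated_genes),
    stringsAsFactors = FALSE
  )
  validateSnpPanel(panel)
  panel
}

#' Validate a SNP panel data.frame
#'
#' @param panel a `data.frame` as returned by [snpPanel()].
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validateSnpPanel <- function(panel) {
  if (!is.data.frame(panel) || !all(.PANEL_COLUMNS %in% names(panel)))
    stop("panel must be a data.frame with columns: ",
         paste(.PANEL_COLUMNS, collapse = ", "))
  if (anyDuplicated(panel$snp_id))
    stop("duplicated snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "))
  if (any(panel$major_allele == panel$minor_allele))
    stop("major_allele must differ from minor_allele")
  ok <- panel$risk_allele == panel$major_allele |
        panel$risk_allele == panel$minor_allele
  if (!all(ok))
    stop("risk_allele must be the major or minor allele for: ",
         paste(panel$snp_id[!ok], collapse = ", "))
  bad <- nchar(panel$major_allele) != 1L | nchar(panel$minor_allele) != 1L
  if (any(bad))
    stop("alleles must be single characters for: ",
         paste(panel$snp_id[bad], collapse = ", "))
  invisible(TRUE)
}

.normalizeSubjects <- function(subjects) {
  missing_cols <- setdiff(.SUBJECT_COLUMNS, names(subjects))
  if (length(missing_cols))
    stop("subject table lacks columns: ", paste(missing_cols, collapse = ", "))
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$status <- factor(as.character(subjects$status), .STATUS_LEVELS)
  subjects$stage <- factor(as.character(subjects$stage), .STAGE_LEVELS)
  subjects$age <- as.numeric(subjects$age)
  subjects$menarche_cat <- factor(as.character(subjects$menarche_cat),
                                  .MENARCHE_LEVELS)
  subjects$first_birth_cat <- factor(as.character(subjects$first_birth_cat),
                                     .FIRST_BIRTH_LEVELS)
  subjects$menopause <- factor(as.character(subjects$menopause),
                               .MENOPAUSE_LEVELS)
  if (anyNA(subjects$status)) stop("status must be 'case' or 'control'")
  if (anyNA(subjects$stage)) stop("every subject needs a stage label")
  if (any(!is.na(subjects$age) & subjects$age <= 0)) stop("age must be > 0")
  subjects
}

#' StudyDataset: genotypes plus covariates for a two-stage case-control study
#'
#' Thin [SummarizedExperiment::SummarizedExperiment] subclass holding a
#' `"dosage"` assay (markers in rows, subjects in columns, minor-allele dosage
#' 0/1/2 or `NA`), the SNP panel as `rowData` and subject covariates
#' (case/control status, stage, age, menarche and first-live-birth categories,
#' menopausal status) as `colData`.
#'
#' @aliases StudyDataset-class
#' @exportClass StudyDataset
setClass("StudyDataset", contains = "SummarizedExperiment")

setValidity("StudyDataset", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    if (!all(d %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(.PANEL_COLUMNS %in% colnames(rd)))
    msg <- c(msg, "rowData must carry the SNP panel columns")
  cd <- SummarizedExperiment::colData(object)
  need <- setdiff(.SUBJECT_COLUMNS, "subject_id")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, paste("colData must carry:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a StudyDataset
#'
#' @param dosage integer matrix, markers x subjects, entries 0/1/2/`NA`
#'   counting copies of each marker's minor allele. Row names must match
#'   `panel$snp_id`, column names `subjects$subject_id`.
#' @param panel SNP panel as from [snpPanel()].
#' @param subjects `data.frame` with columns `subject_id`, `status`
#'   (`"case"`/`"control"`), `stage` (`"testing"`/`"validation"`), `age`,
#'   `menarche_cat` (`"early"`/`"normal"`/`"late"`), `first_birth_cat`
#'   (`"early"`/`"late"`), `menopause` (`"pre"`/`"post"`/`NA`).
#' @return A [StudyDataset-class] object.
#' @export
StudyDataset <- function(dosage, panel, subjects) {
  validateSnpPanel(panel)
  subjects <- .normalizeSubjects(as.data.frame(subjects))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) rownames(dosage) <- panel$snp_id
  if (is.null(colnames(dosage))) colnames(dosage) <- subjects$subject_id
  if (!identical(rownames(dosage), panel$snp_id))
    stop("dosage row names must match panel snp_id (same order)")
  if (!identical(colnames(dosage), subjects$subject_id))
    stop("dosage column names must match subject_id (same order)")
  cd <- S4Vectors::DataFrame(subjects[setdiff(names(subjects), "subject_id")],
                             row.names = subjects$subject_id)
  rd <- S4Vectors::DataFrame(panel, row.names = panel$snp_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dosage = dosage), rowData = rd, colData = cd)
  new("StudyDataset", se)
}

#' @describeIn StudyDataset Minor-allele dosage matrix (markers x subjects).
#' @param x,object a `StudyDataset`.
#' @export
dosageMatrix <- function(x) SummarizedExperiment::assay(x, "dosage")

#' @describeIn StudyDataset SNP panel as a base `data.frame`.
#' @export
snpInfo <- function(x) {
  as.data.frame(SummarizedExperiment::rowData(x))[, .PANEL_COLUMNS,
                                                  drop = FALSE]
}

#' @describeIn StudyDataset Subject covariates as a base `data.frame`
#'   (with a `subject_id` column).
#' @export
subjectInfo <- function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  cbind(subject_id = colnames(x), cd, stringsAsFactors = FALSE)
}

#' @describeIn StudyDataset Logical vector: is each subject a case?
#' @export
isCase <- function(x) {
  SummarizedExperiment::colData(x)$status == "case"
}

#' @describeIn StudyDataset Subset to one stage (`"testing"`,
#'   `"validation"`) or keep everything (`"combined"`).
#' @param stage stage label.
#' @export
subsetStage <- function(x, stage = c("combined", "testing", "validation")) {
  stage <- match.arg(stage)
  if (stage == "combined") return(x)
  x[, SummarizedExperiment::colData(x)$stage == stage]
}

setMethod("show", "StudyDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("StudyDataset with", nrow(object), "SNPs and", ncol(object),
      "subjects\n")
  cat("  cases/controls:", sum(cd$status == "case"), "/",
      sum(cd$status == "control"), "\n")
  cat("  stages:", paste(sprintf("%s=%d", levels(cd$stage),
                                 table(cd$stage)), collapse = ", "), "\n")
  cat("  markers:", paste(utils::head(rownames(object), 5), collapse = ", "),
      if (nrow(object) > 5) "..." else "", "\n")
})

#' HazardSchedule: age-banded disease incidence and competing mortality
#'
#' Ordered, contiguous age bands with a breast-cancer incidence hazard and a
#' competing (all-causes-except-breast-cancer) mortality hazard, both in
#' events per person-year. Used by [projectAbsoluteRisk()].
#'
#' @aliases HazardSchedule-class
#' @exportClass HazardSchedule
setClass("HazardSchedule", representation(bands = "data.frame"))

setValidity("HazardSchedule", function(object) {
  b <- object@bands
  need <- c("age_start", "age_end", "incidence", "mortality")
  if (!all(need %in% names(b))) return("bands need columns age_start, age_end, incidence, mortality")
  if (nrow(b) == 0) return("no bands")
  if (any(b$age_start >= b$age_end)) return("age_start must be < age_end")
  if (any(b$incidence < 0) || any(b$mortality < 0)) return("rates must be >= 0")
  if (nrow(b) > 1) {
    gaps <- which(abs(b$age_end[-nrow(b)] - b$age_start[-1]) > 1e-9)
    if (length(gaps))
      return(paste0("bands not contiguous at: ",
                    paste(sprintf("[%g,%g)->[%g,%g)", b$age_start[gaps],
                                  b$age_end[gaps], b$age_start[gaps + 1],
                                  b$age_end[gaps + 1]), collapse = "; ")))
  }
  TRUE
})

#' Construct a HazardSchedule
#'
#' @param bands `data.frame` with columns `age_start`, `age_end` (years) and
#'   `incidence`, `mortality` (events per person-year), rows ordered by age
#'   and contiguous.
#' @return A [HazardSchedule-class] object.
#' @export
HazardSchedule <- function(bands) {
  bands <- as.data.frame(bands)
  if (nrow(bands)) bands <- bands[order(bands$age_start), , drop = FALSE]
  rownames(bands) <- NULL
  new("HazardSchedule", bands = bands)
}

#' @describeIn HazardSchedule The band table.
#' @param x,object a `HazardSchedule`.
#' @export
hazardBands <- function(x) x@bands

setMethod("show", "HazardSchedule", function(object) {
  b <- object@bands
  cat(sprintf("HazardSchedule: %d bands covering ages [%g, %g)\n",
              nrow(b), min(b$age_start), max(b$age_end)))
  cat(sprintf("  incidence %.3g-%.3g /yr, competing mortality %.3g-%.3g /yr\n",
              min(b$incidence), max(b$incidence),
              min(b$mortality), max(b$mortality)))
})

#' RiskScoreModel: log-odds weights for the cumulative risk score
#'
#' Per-SNP per-minor-allele log odds ratios, per-category clinical log odds
#' ratios (reference categories carry weight 0), and optional control-quartile
#' cutpoints estimated by [quartileGroups()].
#'
#' @aliases RiskScoreModel-class
#' @exportClass RiskScoreModel
setClass("RiskScoreModel",
         representation(snpWeights = "numeric",
                        clinicalWeights = "list",
                        cutpoints = "numeric"))

setValidity("RiskScoreModel", function(object) {
  if (length(object@snpWeights) && is.null(names(object@snpWeights)))
    return("snpWeights must be named by snp_id")
  if (!all(is.finite(object@snpWeights))) return("snpWeights must be finite")
  for (w in object@clinicalWeights)
    if (!all(is.finite(w))) return("clinical weights must be finite")
  if (length(object@cutpoints) && is.unsorted(object@cutpoints))
    return("cutpoints must be non-decreasing")
  TRUE
})

#' @describeIn RiskScoreModel SNP weights (named numeric, log OR per
#'   minor allele).
#' @param x,object a `RiskScoreModel`.
#' @export
snpWeights <- function(x) x@snpWeights

#' @describeIn RiskScoreModel Clinical weights: a list with one named
#'   numeric vector per factor (`menarche_cat`, `first_birth_cat`).
#' @export
clinicalWeights <- function(x) x@clinicalWeights

#' @describeIn RiskScoreModel Control-quartile cutpoints (length 3, or
#'   length 0 before estimation).
#' @export
scoreCutpoints <- function(x) x@cutpoints

setMethod("show", "RiskScoreModel", function(object) {
  cat("RiskScoreModel\n  SNP weights (log OR per minor allele):\n")
  print(round(object@snpWeights, 4))
  if (length(object@clinicalWeights)) {
    cat("  clinical weights:\n")
    for (nm in names(object@clinicalWeights)) {
      cat("   ", nm, ": ")
      cat(paste(sprintf("%s=%.4f", names(object@clinicalWeights[[nm]]),
                        object@clinicalWeights[[nm]]), collapse = ", "), "\n")
    }
  }
  if (length(object@cutpoints))
    cat("  control quartile cutpoints:",
        paste(signif(object@cutpoints, 5), collapse = ", "), "\n")
})
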