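## Readers, writers and QC summaries for genotype/covariate and hazard tables.

#' Categorise age at menarche
#'
#' Half-open intervals partition the axis: early `[0,15)`, normal `[15,17)`,
#' late `[17,Inf)`.
#'
#' @param age_years numeric vector of ages at menarche.
#' @return factor with levels `early`, `normal`, `late`.
#' @export
menarcheCategory <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 15, 17, Inf), right = FALSE,
      labels = .MENARCHE_LEVELS)
}

#' Categorise age at first live birth
#'
#' Early `[0,25)`, late `[25,Inf)`.
#'
#' @param age_years numeric vector of ages at first live birth.
#' @return factor with levels `early`, `late`.
#' @export
firstBirthCategory <- function(age_years) {
  cut(age_years, breaks = c(-Inf, 25, Inf), right = FALSE,
      labels = .FIRST_BIRTH_LEVELS)
}

## parse one genotype column (character) into minor-allele dosage
.parseGenotypeColumn <- function(cells, major, minor, snp_id) {
  d <- rep(NA_integer_, length(cells))
  cells <- trimws(cells)
  miss <- cells %in% .MISSING_TOKENS | is.na(cells)
  num <- !miss & grepl("^[0-2]$", cells)
  d[num] <- as.integer(cells[num])
  pair <- !miss & !num
  if (any(pair)) {
    cc <- toupper(cells[pair])
    if (any(nchar(cc) != 2L))
      stop(sprintf("column '%s': cannot parse genotype '%s' (row %d)",
                   snp_id, cells[pair][nchar(cc) != 2L][1],
                   which(pair)[nchar(cc) != 2L][1]))
    a1 <- substr(cc, 1, 1); a2 <- substr(cc, 2, 2)
    bad <- !(a1 %in% c(major, minor)) | !(a2 %in% c(major, minor))
    if (any(bad))
      stop(sprintf(
        "column '%s': allele not in {%s,%s} in genotype '%s' (row %d)",
        snp_id, major, minor, cells[pair][bad][1], which(pair)[bad][1]))
    d[pair] <- (a1 == minor) + (a2 == minor)
  }
  d
}

#' Read a subject-level genotype/covariate table
#'
#' Delimited text, one row per subject, with the covariate columns
#' `subject_id, status, stage, age, menarche_cat, first_birth_cat, menopause`
#' and one column per panel SNP. Genotype cells may be allele pairs
#' (`"GA"`), dosage integers (0/1/2) or a missing token (empty, `NA`, `NN`,
#' `.`). Dosages are counted on each SNP's minor allele as designated in the
#' panel. Any column that is neither a covariate nor a panel SNP is an error.
#'
#' @param path file path (TSV by default; `.csv` switches to comma).
#' @param panel SNP panel from [snpPanel()].
#' @param sep field separator; guessed from the extension when `NULL`.
#' @return A [StudyDataset-class].
#' @export
readGenotypeTable <- function(path, panel, sep = NULL) {
  validateSnpPanel(panel)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"",
                           stringsAsFactors = FALSE)
  extra <- setdiff(names(raw), c(.SUBJECT_COLUMNS, panel$snp_id))
  if (length(extra))
    stop("unknown SNP column(s) not in panel: ", paste(extra, collapse = ", "))
  missing_snps <- setdiff(panel$snp_id, names(raw))
  if (length(missing_snps))
    stop("panel SNP column(s) absent from table: ",
         paste(missing_snps, collapse = ", "))
  subjects <- raw[, intersect(.SUBJECT_COLUMNS, names(raw)), drop = FALSE]
  subjects[subjects == ""] <- NA
  subjects$age <- suppressWarnings(as.numeric(subjects$age))
  dosage <- vapply(seq_len(nrow(panel)), function(i) {
    .parseGenotypeColumn(raw[[panel$snp_id[i]]], panel$major_allele[i],
                         panel$minor_allele[i], panel$snp_id[i])
  }, integer(nrow(raw)))
  dosage <- t(matrix(dosage, nrow = nrow(raw),
                     dimnames = list(subjects$subject_id, panel$snp_id)))
  n_missing <- rowSums(is.na(dosage))
  if (any(n_missing > 0))
    message("missing genotypes per SNP: ",
            paste(sprintf("%s=%d", names(n_missing[n_missing > 0]),
                          n_missing[n_missing > 0]), collapse = ", "))
  StudyDataset(dosage, panel, subjects)
}

#' Write a StudyDataset as a delimited table
#'
#' Inverse of [readGenotypeTable()]; `genotypes = "alleles"` writes allele
#' pairs (hom-major, het as major-then-minor, hom-minor), `"dosage"` writes
#' 0/1/2. Missing genotypes are written as `NN`.
#'
#' @param x a [StudyDataset-class].
#' @param path output file path.
#' @param genotypes cell format.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
writeGenotypeTable <- function(x, path, genotypes = c("dosage", "alleles"),
                               sep = "\t") {
  genotypes <- match.arg(genotypes)
  panel <- snpInfo(x)
  d <- dosageMatrix(x)
  cells <- if (genotypes == "dosage") {
    m <- matrix(as.character(d), nrow(d), ncol(d)); m[is.na(d)] <- "NN"; m
  } else {
    m <- matrix("NN", nrow(d), ncol(d))
    for (i in seq_len(nrow(d))) {
      g <- c(strrep(panel$major_allele[i], 2),
             paste0(panel$major_allele[i], panel$minor_allele[i]),
             strrep(panel$minor_allele[i], 2))
      ok <- !is.na(d[i, ])
      m[i, ok] <- g[d[i, ok] + 1L]
    }
    m
  }
  out <- cbind(subjectInfo(x),
               as.data.frame(t(cells), stringsAsFactors = FALSE) |>
                 stats::setNames(panel$snp_id))
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Consumes the `GT` field of a standard VCF (biallelic records only) and
#' maps it to minor-allele dosage for each panel SNP, matched by ID. The
#' subject covariates cannot live in a VCF, so they are supplied separately
#' and matched to sample names.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param panel SNP panel; `minor_allele` must be REF or ALT at each record.
#' @param subjects covariate `data.frame` as for [StudyDataset()]; its
#'   `subject_id` must match the VCF sample names.
#' @return A [StudyDataset-class].
#' @export
readGenotypeVcf <- function(path, panel, subjects) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readGenotypeVcf requires the vcfR package")
  validateSnpPanel(panel)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    stop("multi-allelic record(s) not supported: ",
         paste(fix$ID[multi], collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  idx <- match(panel$snp_id, fix$ID)
  if (anyNA(idx))
    stop("panel SNP(s) absent from VCF: ",
         paste(panel$snp_id[is.na(idx)], collapse = ", "))
  dosage <- matrix(NA_integer_, nrow(panel), ncol(gt),
                   dimnames = list(panel$snp_id, colnames(gt)))
  for (i in seq_len(nrow(panel))) {
    rec <- idx[i]
    alleles <- c(fix$REF[rec], fix$ALT[rec])
    if (!panel$minor_allele[i] %in% alleles)
      stop(sprintf("minor allele %s of %s not among VCF alleles %s/%s",
                   panel$minor_allele[i], panel$snp_id[i], alleles[1],
                   alleles[2]))
    minor_code <- which(alleles == panel$minor_allele[i]) - 1L
    g <- gt[rec, ]
    parts <- strsplit(g, "[/|]")
    dosage[i, ] <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_integer_)
      sum(as.integer(p) == minor_code)
    }, integer(1))
  }
  subjects <- as.data.frame(subjects)
  m <- match(colnames(dosage), subjects$subject_id)
  if (anyNA(m))
    stop("covariates missing for sample(s): ",
         paste(colnames(dosage)[is.na(m)], collapse = ", "))
  StudyDataset(dosage, panel, subjects[m, , drop = FALSE])
}

#' Read an age-banded hazard schedule
#'
#' CSV with columns `age_start, age_end, incidence_per_100k,
#' mortality_per_100k`; rates are converted to events per person-year
#' (divided by 100,000) and bands validated as contiguous and non-negative.
#'
#' @param path CSV file path.
#' @return A [HazardSchedule-class].
#' @export
readHazardSchedule <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no bands in hazard schedule file")
  need <- c("age_start", "age_end", "incidence_per_100k", "mortality_per_100k")
  if (!all(need %in% names(raw)))
    stop("hazard schedule needs columns: ", paste(need, collapse = ", "))
  if (any(raw$incidence_per_100k < 0) || any(raw$mortality_per_100k < 0))
    stop("negative rate in hazard schedule")
  HazardSchedule(data.frame(
    age_start = raw$age_start, age_end = raw$age_end,
    incidence = raw$incidence_per_100k / 1e5,
    mortality = raw$mortality_per_100k / 1e5))
}

#' Genotype counts for one SNP in one group
#'
#' @param dataset a [StudyDataset-class].
#' @param snp_id marker identifier.
#' @param status `"case"`, `"control"` or `"all"`.
#' @param stage `"combined"`, `"testing"` or `"validation"`.
#' @return Named integer vector `c(hom_major, het, hom_minor)` over genotyped
#'   subjects in the group.
#' @export
genotypeCounts <- function(dataset, snp_id,
                           status = c("all", "case", "control"),
                           stage = c("combined", "testing", "validation")) {
  status <- match.arg(status)
  dataset <- subsetStage(dataset, match.arg(stage))
  if (!snp_id %in% rownames(dataset)) stop("SNP not in panel: ", snp_id)
  keep <- if (status == "all") rep(TRUE, ncol(dataset)) else
    (isCase(dataset) == (status == "case"))
  d <- dosageMatrix(dataset)[snp_id, keep]
  c(hom_major = sum(d == 0L, na.rm = TRUE),
    het = sum(d == 1L, na.rm = TRUE),
    hom_minor = sum(d == 2L, na.rm = TRUE))
}

#' Per-SNP quality-control summary
#'
#' Call rate over all subjects and minor-allele frequency among genotyped
#' controls; the QC convention of the two-stage screen is call rate above 95%
#' and control MAF of at least 0.05.
#'
#' @param dataset a [StudyDataset-class].
#' @param snp_id marker identifier.
#' @param stage restrict to one stage or use everything (`"combined"`).
#' @return list with `call_rate` and `control_maf`.
#' @export
qcSummary <- function(dataset, snp_id,
                      stage = c("combined", "testing", "validation")) {
  dataset <- subsetStage(dataset, match.arg(stage))
  if (!snp_id %in% rownames(dataset)) stop("SNP not in panel: ", snp_id)
  d <- dosageMatrix(dataset)[snp_id, ]
  cc <- genotypeCounts(dataset, snp_id, status = "control")
  n_controls <- sum(cc)
  if (n_controls == 0) stop("no genotyped controls for ", snp_id)
  list(call_rate = mean(!is.na(d)),
       control_maf = (2 * cc[["hom_minor"]] + cc[["het"]]) / (2 * n_controls))
}

#' Published summary genotype counts of the five validated markers
#'
#' Bundled summary-level genotype counts, by study stage and case/control
#' status, from a published two-stage breast-cancer case-control study of
#' Chinese women (testing set 878 cases/900 controls, validation set 914/967)
#' in which five GWAS-identified susceptibility SNPs were validated. These
#' published tables are the package's reference inputs for exact-test and QC
#' reproduction.
#'
#' @return `data.frame` with columns `snp_id, chrom_band, position,
#'   major_allele, minor_allele, risk_allele, stage, status, hom_major, het,
#'   hom_minor`.
#' @export
publishedGenotypeCounts <- function() {
  utils::read.table(system.file("extdata", "published_genotype_counts.tsv",
                                package = "snpRiskAssess"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Published screening panel of 15 candidate markers
#'
#' The 15 GWAS-identified candidate SNPs of the published study's screening
#' stage, with printed call rates, control-HWE P-values, reference-population
#' and control minor-allele frequencies, and the screening association
#' P-values used by the two-stage design.
#'
#' @return `data.frame` with columns `snp_id, chrom_band, alleles, call_rate,
#'   p_hwe, maf_reference, maf_control, p_assoc`.
#' @export
publishedScreeningPanel <- function() {
  utils::read.table(system.file("extdata", "published_screening_panel.tsv",
                                package = "snpRiskAssess"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a result table as TSV
#'
#' @param x a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result object as JSON
#'
#' @param x a list or data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultsJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
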