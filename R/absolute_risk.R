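## Modified Gail absolute-risk projection: allelic OR -> genotype relative
## risks -> population-normalised relative risks -> multiplicative
## combination -> piecewise-constant-hazard projection with competing
## mortality.

#' Genotype relative risks from a per-allele odds ratio
#'
#' Multiplicative (log-additive) model: the heterozygote carries the
#' per-allele OR, the minor-allele homozygote its square, relative to the
#' major-allele homozygote.
#'
#' @param allelic_or positive per-allele odds ratio.
#' @return numeric `c(rr0 = 1, rr1 = OR, rr2 = OR^2)`.
#' @export
genotypeRelativeRisks <- function(allelic_or) {
  if (allelic_or <= 0) stop("allelic OR must be positive")
  c(rr0 = 1, rr1 = allelic_or, rr2 = allelic_or^2)
}

#' Normalise relative risks against the population
#'
#' Rescales level-specific relative risks so their frequency-weighted mean
#' is exactly 1: `r = rr / sum(f * rr)`. With this convention the
#' population-average projected hazard equals the registry incidence, so no
#' further baseline deflation is needed.
#'
#' @param rr_by_level positive relative risks per level.
#' @param level_freqs level frequencies summing to 1 (within 1e-8).
#' @return risks relative to the population, same names as `rr_by_level`;
#'   `sum(f * r)` is 1 to within 1e-10.
#' @export
populationNormalize <- function(rr_by_level, level_freqs) {
  if (abs(sum(level_freqs) - 1) > 1e-8)
    stop("level frequencies must sum to 1")
  if (any(rr_by_level <= 0)) stop("relative risks must be positive")
  if (length(rr_by_level) != length(level_freqs))
    stop("rr and frequency vectors must align")
  r <- rr_by_level / sum(level_freqs * rr_by_level)
  stopifnot(abs(sum(level_freqs * r) - 1) < 1e-10)
  r
}

#' Per-factor population-relative risk tables
#'
#' Builds, for every SNP and clinical factor, the map from level (genotype
#' 0/1/2 or category) to its risk relative to the population. SNP relative
#' risks come from the additive ORs via [genotypeRelativeRisks()];
#' normalisation frequencies are the pooled control genotype/category
#' frequencies of the dataset (controls approximate the population in a
#' case-control design), unless explicit frequencies are supplied.
#'
#' @param dataset a [StudyDataset-class] supplying control frequencies.
#' @param snp_ors named additive OR per panel SNP.
#' @param clinical_ors list as in [buildRiskScore()]: per-category ORs
#'   against the reference category.
#' @param genotype_freqs optional list of length-3 frequency vectors per
#'   SNP overriding the control frequencies.
#' @return list of per-factor `data.frame`s (`level, freq, rr, r`), one per
#'   SNP and clinical factor.
#' @export
relativeRiskTables <- function(dataset, snp_ors, clinical_ors = list(),
                               genotype_freqs = NULL) {
  tables <- list()
  for (s in names(snp_ors)) {
    rr <- genotypeRelativeRisks(snp_ors[[s]])
    f <- if (!is.null(genotype_freqs)) genotype_freqs[[s]] else {
      cc <- genotypeCounts(dataset, s, "control")
      cc / sum(cc)
    }
    r <- populationNormalize(rr, f)
    tables[[s]] <- data.frame(level = c("0", "1", "2"), freq = as.numeric(f),
                              rr = as.numeric(rr), r = as.numeric(r))
  }
  subj <- subjectInfo(dataset)
  controls <- subj[subj$status == "control", ]
  for (fct in names(clinical_ors)) {
    lev <- levels(subj[[fct]])
    rr <- rep(1, length(lev)); names(rr) <- lev
    rr[names(clinical_ors[[fct]])] <- clinical_ors[[fct]]
    f <- as.numeric(table(controls[[fct]])[lev])
    f <- f / sum(f)
    r <- populationNormalize(rr, f)
    tables[[fct]] <- data.frame(level = lev, freq = f, rr = as.numeric(rr),
                                r = as.numeric(r))
  }
  tables
}

#' Combined relative risk per subject
#'
#' Product over all factors (SNP genotypes and clinical categories) of the
#' subject's level-specific population-relative risk. Subjects missing any
#' factor level get `NA`.
#'
#' @param dataset a [StudyDataset-class].
#' @param rr_tables output of [relativeRiskTables()].
#' @return named positive numeric vector, one combined `r` per subject.
#' @export
combinedRelativeRisk <- function(dataset, rr_tables) {
  subj <- subjectInfo(dataset)
  d <- dosageMatrix(dataset)
  out <- rep(1, ncol(dataset))
  names(out) <- colnames(dataset)
  for (nm in names(rr_tables)) {
    tab <- rr_tables[[nm]]
    lev <- if (nm %in% rownames(dataset)) as.character(d[nm, ])
    else as.character(subj[[nm]])
    out <- out * tab$r[match(lev, tab$level)]
  }
  out
}

## per-band projection shared by the closed form below
.bandTables <- function(schedule, age_start, age_end) {
  b <- hazardBands(schedule)
  if (min(b$age_start) > age_start + 1e-9 || max(b$age_end) < age_end - 1e-9)
    stop(sprintf("schedule covers [%g, %g) but projection needs [%g, %g)",
                 min(b$age_start), max(b$age_end), age_start, age_end))
  lo <- pmax(b$age_start, age_start)
  hi <- pmin(b$age_end, age_end)
  keep <- hi - lo > 1e-12
  data.frame(h1 = b$incidence[keep], h2 = b$mortality[keep],
             width = (hi - lo)[keep])
}

#' Project absolute risk over an age span
#'
#' Probability of developing the disease between `age_start` and `age_end`
#' for a subject with combined population-relative risk `r`, in the
#' presence of competing mortality, under piecewise-constant hazards: with
#' per-band disease hazard `r*h1_j` and competing hazard `h2_j`,
#' `AR = sum_j S_j * (r*h1_j)/(r*h1_j + h2_j) * (1 - exp(-(r*h1_j + h2_j) *
#' width_j))`, where `S_j` is the probability of remaining free of both
#' events at the start of band `j`.
#'
#' @param r combined relative risk(s); vectorised.
#' @param schedule a [HazardSchedule-class] covering the span.
#' @param age_start,age_end projection span in years (default the 65-year
#'   span 20-85, applied uniformly to all subjects; pass a subject's
#'   current age as `age_start` for a residual-risk projection).
#' @return absolute risk(s) in `[0, 1]`; `NA` inputs propagate.
#' @export
projectAbsoluteRisk <- function(r, schedule, age_start = 20, age_end = 85) {
  if (any(!is.na(r) & r <= 0)) stop("relative risk must be positive")
  if (age_start >= age_end) stop("age_start must be below age_end")
  bands <- .bandTables(schedule, age_start, age_end)
  vapply(r, function(ri) {
    if (is.na(ri)) return(NA_real_)
    S <- 1; ar <- 0
    for (j in seq_len(nrow(bands))) {
      htot <- ri * bands$h1[j] + bands$h2[j]
      if (htot > 0)
        ar <- ar + S * (ri * bands$h1[j]) / htot *
          (1 - exp(-htot * bands$width[j]))
      S <- S * exp(-htot * bands$width[j])
    }
    ar
  }, numeric(1))
}

#' Flag high-risk subjects by a multiple of the median risk
#'
#' Threshold is `k` times the median absolute risk over all analysed
#' subjects; subjects at or above it are flagged.
#'
#' @param ars per-subject absolute risks (`NA` excluded from the median and
#'   flagged `NA`).
#' @param k positive multiple of the median (2 and 3 are the conventional
#'   screening cutoffs).
#' @return list with `threshold`, `flag` (logical per subject) and
#'   `fraction_high`.
#' @export
classifyHighRisk <- function(ars, k) {
  if (k <= 0) stop("k must be positive")
  if (!sum(!is.na(ars))) stop("no absolute risks to classify")
  threshold <- k * stats::median(ars, na.rm = TRUE)
  flag <- ars >= threshold
  list(threshold = threshold, flag = flag,
       fraction_high = mean(flag, na.rm = TRUE))
}

#' Bundled synthetic hazard schedule
#'
#' A clearly synthetic default: the schedule is shaped like an urban
#' East-Asian female breast-cancer incidence curve (rising to a plateau
#' near age 50) with an exponentially increasing competing all-cause
#' mortality, scaled so the population-average 65-year absolute risk over
#' ages 20-85 is about 0.07. It is a stand-in for registry rates, which
#' are an external input supplied via [readHazardSchedule()]; it is not
#' fitted to any registry.
#'
#' @return A [HazardSchedule-class].
#' @export
syntheticHazardSchedule <- function() {
  readHazardSchedule(system.file("extdata", "synthetic_hazard_schedule.csv",
                                 package = "snpRiskAssess"))
}
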