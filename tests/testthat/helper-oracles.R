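# Independent oracles and small fixtures used across the suite.

# published testing-set genotype tables as case/control count matrices
publishedTable <- function(snp, stage = "testing") {
  pc <- publishedGenotypeCounts()
  rows <- pc[pc$snp_id == snp & pc$stage == stage, ]
  out <- rbind(case = unlist(rows[rows$status == "case",
                                  c("hom_major", "het", "hom_minor")]),
               control = unlist(rows[rows$status == "control",
                                     c("hom_major", "het", "hom_minor")]))
  colnames(out) <- c("hom_major", "het", "hom_minor")
  out
}

publishedPanel <- function() {
  pc <- publishedGenotypeCounts()
  u <- pc[!duplicated(pc$snp_id), ]
  snpPanel(u$snp_id, u$chrom_band, u$position, u$major_allele,
           u$minor_allele, u$risk_allele)
}

# brute-force FFH: triple loop over first-row cells, plain factorials
bruteForceFfh <- function(tab) {
  if (ncol(tab) == 2) tab <- cbind(tab, c(0, 0))  # zero column changes nothing
  R <- rowSums(tab); C <- colSums(tab); N <- sum(tab)
  prob <- function(m) {
    if (any(m < 0)) return(0)
    prod(factorial(R)) * prod(factorial(C)) /
      (factorial(N) * prod(factorial(m)))
  }
  p_obs <- prob(tab)
  total <- 0
  for (a in 0:C[1]) for (b in 0:C[2]) {
    cc <- R[1] - a - b
    if (cc < 0 || cc > C[3]) next
    p <- prob(rbind(c(a, b, cc), c(C[1] - a, C[2] - b, C[3] - cc)))
    if (p <= p_obs * (1 + 1e-7)) total <- total + p
  }
  min(1, total)
}

# brute-force HWE exact: choose()-based conditional distribution
bruteForceHwe <- function(hom_major, het, hom_minor) {
  n <- hom_major + het + hom_minor
  n_minor <- 2 * hom_minor + het
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  prob <- vapply(hets, function(h) {
    aa <- (n_minor - h) / 2
    choose(n, aa) * choose(n - aa, h) * 2^h
  }, numeric(1))
  prob <- prob / sum(prob)
  min(1, sum(prob[prob <= prob[hets == het] * (1 + 1e-7)]))
}

# reference IRLS, written independently of fitLogistic
irlsOracle <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- as.vector(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, X * w), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.vector(beta_new))
    beta <- as.vector(beta_new)
  }
  as.vector(beta)
}

# pairwise Mann-Whitney AUC, double loop
aucBruteForce <- function(scores, is_case) {
  x <- scores[is_case]; y <- scores[!is_case]
  total <- 0
  for (xi in x) for (yj in y)
    total <- total + (xi > yj) + 0.5 * (xi == yj)
  total / (length(x) * length(y))
}

# four-subject toy panel/dataset builders
toyPanel <- function() {
  snpPanel(c("snpA", "snpB"), c("1p1", "2q2"), c(100L, 200L),
           c("G", "C"), c("A", "T"))
}

toySubjects <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("P%03d", seq_len(n)),
    status = rep_len(c("case", "control"), n),
    stage = rep_len(c("testing", "validation"), n),
    age = sample(30:70, n, TRUE),
    menarche_cat = sample(c("early", "normal", "late"), n, TRUE),
    first_birth_cat = sample(c("early", "late"), n, TRUE),
    menopause = sample(c("pre", "post"), n, TRUE),
    stringsAsFactors = FALSE)
}

toyDataset <- function(n = 8, seed = 1) {
  set.seed(seed + 1)
  d <- matrix(sample(0:2, 2 * n, TRUE), nrow = 2,
              dimnames = list(c("snpA", "snpB"), NULL))
  StudyDataset(d, toyPanel(), toySubjects(n, seed))
}
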