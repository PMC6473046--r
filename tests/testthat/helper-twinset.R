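# shared fixture builders

# generate a cohort without the clip/floor/exclusion messages cluttering
# test output
quiet_cohort <- function(config) suppressMessages(generate_twin_cohort(config))

quiet_pairs <- function(config, exclude = TRUE) {
  coh <- quiet_cohort(config)
  samples <- if (exclude) suppressMessages(exclude_diabetes_pairs(coh$samples))
  else coh$samples
  pd <- compute_pair_differences(samples, coh$meth, coh$annot)
  list(pd = pd, annot = coh$annot, samples = samples, meth = coh$meth)
}

# tiny hand-built cohort: 3 pairs, 2 CpGs, no covariate noise structure
tiny_cohort <- function() {
  samples <- data.frame(
    sample_id = c("A_1", "A_2", "B_1", "B_2", "C_1", "C_2"),
    pair_id = rep(c("A", "B", "C"), each = 2),
    member_id = rep(1:2, 3),
    age = rep(c(50, 55, 60), each = 2),
    glucose = c(90, 95, 100, 98, 102, 97),
    insulin = c(9, 10, 8, 8, 12, 11),
    hba1c = c(5.2, 5.4, 5.6, 5.5, 5.9, 5.7),
    diabetes = FALSE,
    pack_years = c(0, 5, 10, 10, 20, 15),
    alcohol = c(0, 10, 5, 5, 20, 10),
    activity = c(7, 8, 7, 7, 6, 7),
    bdi_ii = c(2, 4, 6, 5, 8, 7),
    bmi = c(25, 26, 30, 29, 28, 28),
    sbp = c(120, 125, 130, 128, 140, 135),
    dbp = c(80, 82, 85, 84, 90, 88),
    hdl_c = c(40, 38, 35, 36, 45, 44),
    ldl_c = c(120, 125, 130, 128, 110, 115),
    stringsAsFactors = FALSE)
  meth <- data.frame(sample_id = samples$sample_id,
                     CLOCK_cg01 = c(5, 3, 2, 2, 4, 1),
                     PER2_cg01 = c(1, 2, 0.5, 0.5, 3, 2.5),
                     stringsAsFactors = FALSE)
  annot <- data.frame(cpg_id = c("CLOCK_cg01", "PER2_cg01"),
                      gene = c("CLOCK", "PER2"),
                      chrom = c("chr4", "chr2"),
                      pos = c(56413229L, 239197634L),
                      tss_offset = c(75L, -386L),
                      stringsAsFactors = FALSE)
  list(samples = samples, meth = meth, annot = annot)
}

# independent OLS oracle: normal equations + t CDF, no shared code with the
# package's QR path
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- b / se
  list(beta = as.numeric(b), se = as.numeric(se),
       p = as.numeric(2 * stats::pt(-abs(tval), df)), df = df)
}

# brute-force BH step-up: literal definition, quadratic time
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) p[o[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cand))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}
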