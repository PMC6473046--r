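test_that("matched OLS handles exact and orthogonal relations", {
  # exact linear relation: beta = 2, zero residual, floored p
  f <- fit_matched_ols(2 * c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(f$beta, 2.0, tolerance = 1e-12)
  expect_equal(f$p, 1e-300)
  # y orthogonal to x with mean zero: beta = 0
  f0 <- fit_matched_ols(c(2, 2, -1, -1), c(1, -1, 2, -2))
  expect_equal(f0$beta, 0, tolerance = 1e-12)
})

test_that("matched OLS matches an independent normal-equations oracle", {
  set.seed(42)
  n <- 20
  x <- rnorm(n); z1 <- rnorm(n); z2 <- rnorm(n); age <- rnorm(n, 55, 3)
  y <- 0.7 * x + 0.3 * z1 + rnorm(n)
  f <- fit_matched_ols(y, x, cbind(z1 = z1, z2 = z2), age)
  o <- ols_oracle(y, cbind(1, x, z1, z2, age))
  expect_equal(f$beta, o$beta[2], tolerance = 1e-10)
  expect_equal(f$se, o$se[2], tolerance = 1e-10)
  expect_equal(f$p, o$p[2], tolerance = 1e-10)
  expect_equal(f$df, o$df)
})

test_that("degenerate designs are reported, not silently fit", {
  set.seed(1)
  x <- rnorm(20); y <- rnorm(20)
  expect_error(fit_matched_ols(y, x, cbind(dup = x)), "collinear.*dup|dup")
  s <- fit_matched_ols(y, rep(0, 20))
  expect_true(s$skipped)
  expect_match(s$skip_reason, "zero-variance")
  expect_error(fit_matched_ols(y[1:3], x[1:3], cbind(a = rnorm(3))),
               "too few pairs")
})

test_that("sign-flip equivariance: negating differences flips beta only", {
  prep <- quiet_pairs(sim_config(n_pairs = 30, n_diabetes_flag_pairs = 0,
                                 seed = 12), exclude = FALSE)
  pd <- prep$pd
  covm <- as.matrix(pd[paste0("d_", twinset_covariates())])
  f1 <- fit_matched_ols(pd$d_homa_ir, pd$CLOCK_cg01, covm, pd$age)
  f2 <- fit_matched_ols(-pd$d_homa_ir, -pd$CLOCK_cg01, -covm, pd$age)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$se, f1$se, tolerance = 1e-12)
  expect_equal(f2$p, f1$p, tolerance = 1e-12)
  f3 <- fit_matched_ols(-pd$d_homa_ir, pd$CLOCK_cg01, -covm, pd$age)
  expect_equal(f3$beta, -f1$beta, tolerance = 1e-12)
  expect_equal(f3$p, f1$p, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
  set.seed(7)
  for (r in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_identical(bh_fdr(p), bh_oracle(p))
  }
  # independent cross-check against the stock implementation
  set.seed(8)
  p <- runif(77)
  expect_equal(bh_fdr(p), stats::p.adjust(p, method = "BH"),
               tolerance = 1e-12)
})

test_that("the scan yields one row per CpG-trait with per-trait q", {
  prep <- quiet_pairs(sim_config(seed = 2))
  scan <- run_single_cpg_scan(prep$pd, prep$annot)
  expect_equal(nrow(scan), 77L * 3L)
  expect_setequal(unique(scan$trait), TWINSET_TRAITS)
  for (tr in TWINSET_TRAITS) {
    sub <- scan[scan$trait == tr, ]
    expect_identical(unname(sub$q), unname(bh_oracle(sub$p)))
    expect_true(all(sub$q >= sub$p))
    # q nondecreasing in p within a trait
    o <- order(sub$p)
    expect_true(all(diff(sub$q[o]) >= -1e-15))
  }
  expect_true(all(scan$se > 0))
  expect_true(all(scan$p > 0 & scan$p <= 1))
  expect_true(all(scan$n_pairs_used == 69L))
})

test_that("a zero-variance CpG becomes a skip record without aborting", {
  tc <- tiny_cohort()
  tc$meth$PER2_cg01 <- 1  # identical members -> zero difference everywhere
  more <- rbind(tc$samples, within(tc$samples, {
    pair_id <- paste0(pair_id, "x"); sample_id <- paste0(sample_id, "x")
  }))
  meth2 <- rbind(tc$meth, within(tc$meth, {
    sample_id <- paste0(sample_id, "x")
    CLOCK_cg01 <- CLOCK_cg01 + c(0.3, -0.2, 0.5, 0.1, -0.4, 0.2)
  }))
  pd <- compute_pair_differences(more, meth2, tc$annot, covariates = "bmi")
  scan <- run_single_cpg_scan(pd, tc$annot, traits = "glucose",
                              covariates = character(0))
  expect_true(scan$skipped[scan$cpg_id == "PER2_cg01"])
  expect_false(scan$skipped[scan$cpg_id == "CLOCK_cg01"])
  expect_true(is.na(scan$q[scan$skipped]))
})

test_that("significance counting uses a strict threshold", {
  res <- data.frame(trait = "glucose", gene = c("A", "A", "B"),
                    p = c(0.049999, 0.050, 0.01), q = c(0.6, 0.6, 0.2))
  ct <- count_significant(res, 0.05, by = "gene")
  expect_equal(ct$n_significant, c(1L, 1L))  # p = 0.050 exactly not counted
  ct_q <- count_significant(res, 0.25, by = "gene", on = "q")
  expect_equal(ct_q$n_significant, c(0L, 1L))
  expect_equal(sum(count_significant(res, 1e-12)$n_significant), 0L)
  expect_error(count_significant(res, 0), "alpha")
  expect_error(count_significant(res[0, ], 0.05), "empty")
})

test_that("empirical FDR of the q < 0.05 rule is controlled", {
  # 10% non-null CpGs planted; FDR among q<0.05 calls over replicates
  nrep <- 120
  fdp <- numeric(nrep)
  any_call <- logical(nrep)
  null_cpgs <- NULL
  for (r in seq_len(nrep)) {
    eff <- data.frame(trait = "glucose",
                      cpg = sprintf("CLOCK_cg%02d", 1:8),
                      beta = 8)
    cfg <- sim_config(n_pairs = 69, effects = eff, rho_within_gene = 0,
                      pair_icc = 0, n_diabetes_flag_pairs = 0,
                      seed = 4000 + r)
    prep <- quiet_pairs(cfg, exclude = FALSE)
    scan <- run_single_cpg_scan(prep$pd, prep$annot, traits = "glucose")
    calls <- scan$cpg_id[scan$q < 0.05]
    any_call[r] <- length(calls) > 0
    fdp[r] <- if (length(calls))
      mean(!calls %in% eff$cpg) else 0
  }
  emp_fdr <- mean(fdp)
  mc_se <- sd(fdp) / sqrt(nrep)
  expect_lt(emp_fdr, 0.05 + 2 * mc_se + 1e-9)
  expect_true(mean(any_call) > 0.9)  # the planted signal is detectable
})
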