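test_that("truncated product statistic: truncation, weights, log space", {
  expect_equal(tpm_statistic(c(0.2, 0.3), 0.05), 1)        # empty product
  expect_equal(tpm_statistic(c(0.01, 0.04, 0.20), 0.05), 4e-4,
               tolerance = 1e-12)
  # weighted: raw weights (2, 1) normalize to (4/3, 2/3)
  w_direct <- exp((4 / 3) * log(0.01) + (2 / 3) * log(0.04))
  expect_equal(tpm_statistic(c(0.01, 0.04), 0.05, weights = c(2, 1)),
               w_direct, tolerance = 1e-12)
  # equal raw weights coincide with the unweighted statistic
  p <- c(0.001, 0.03, 0.2, 0.7)
  expect_equal(tpm_statistic(p, 0.05, weights = c(3, 3, 3, 3)),
               tpm_statistic(p, 0.05), tolerance = 1e-12)
  expect_error(tpm_statistic(c(0.1, 0.2), 0.05, weights = 1), "length")
  expect_error(tpm_statistic(0.1, 0.05, weights = -1), "positive")
  expect_error(tpm_statistic(c(0, 0.1), 0.05), "\\(0, 1\\]")
})

test_that("analytic null reduces to the single p-value at L = 1", {
  expect_equal(tpm_analytic_pvalue(0.3, 1, 1), 0.3, tolerance = 1e-12)
  expect_equal(tpm_analytic_pvalue(0.01, 1, 0.05), 0.01, tolerance = 1e-12)
  # above the truncation point the whole tail collapses to P(p <= tau) + atom
  expect_equal(tpm_analytic_pvalue(1, 1, 0.05), 1, tolerance = 1e-12)
  expect_equal(tpm_analytic_pvalue(1, 5, 0.05), 1, tolerance = 1e-12)
})

test_that("analytic null is monotone in W and equals Fisher at tau = 1", {
  for (L in c(1, 2, 5, 10)) {
    for (tau in c(0.05, 0.5, 1)) {
      W <- 10^seq(-12, -0.1, length.out = 25)
      pv <- vapply(W, tpm_analytic_pvalue, numeric(1), L = L, tau = tau)
      expect_true(all(diff(pv) >= -1e-12))
      expect_true(all(pv > 0 & pv <= 1))
    }
    W <- 10^seq(-8, -0.2, length.out = 6)
    fisher <- pchisq(-2 * log(W), df = 2 * L, lower.tail = FALSE)
    tpm <- vapply(W, tpm_analytic_pvalue, numeric(1), L = L, tau = 1)
    expect_equal(tpm, fisher, tolerance = 1e-10)
  }
})

test_that("analytic null agrees with a Monte-Carlo oracle (spot check)", {
  set.seed(99)
  L <- 3; tau <- 0.05; n_mc <- 2e5
  P <- matrix(runif(n_mc * L), n_mc, L)
  lw <- rowSums(log(P) * (P <= tau))
  for (W in c(1e-4, 1e-6)) {
    phat <- mean(lw <= log(W))
    p_an <- tpm_analytic_pvalue(W, L, tau)
    mc_se <- sqrt(p_an * (1 - p_an) / n_mc)
    expect_lt(abs(p_an - phat), 3 * mc_se + 1e-12)
  }
})

test_that("sign-flip null is deterministic and exact under identity flips", {
  prep <- quiet_pairs(sim_config(n_pairs = 25, n_diabetes_flag_pairs = 0,
                                 seed = 31), exclude = FALSE)
  pd <- prep$pd
  cpgs <- attr(pd, "cpg_ids")[1:10]
  n1 <- signflip_null(pd, cpgs, "glucose", B = 20, seed = 5)
  n2 <- signflip_null(pd, cpgs, "glucose", B = 20, seed = 5)
  expect_identical(n1, n2)
  n3 <- signflip_null(pd, cpgs, "glucose", B = 20, seed = 6)
  expect_false(identical(n1, n3))

  # all-plus-one signs reproduce the observed per-CpG scan exactly
  ones <- matrix(1, nrow(pd), 1)
  obs <- signflip_null(pd, cpgs, "glucose", B = 1, signs = ones)
  covm <- as.matrix(pd[paste0("d_", twinset_covariates())])
  direct <- vapply(cpgs, function(cc)
    fit_matched_ols(pd$d_glucose, pd[[cc]], covm, pd$age)$p, numeric(1))
  expect_equal(as.numeric(obs[1, ]), unname(direct), tolerance = 1e-10)
  expect_error(signflip_null(pd, cpgs, "glucose", B = 0), "B must be")
})

test_that("null p-values are uniform under the global null", {
  prep <- quiet_pairs(sim_config(n_pairs = 69, rho_within_gene = 0.3,
                                 n_diabetes_flag_pairs = 0, seed = 77),
                      exclude = FALSE)
  np <- signflip_null(prep$pd, attr(prep$pd, "cpg_ids")[1:3], "hba1c",
                      B = 2000, seed = 9)
  for (j in 1:3)
    expect_gt(stats::ks.test(np[, j], "punif")$p.value, 0.01)
})

test_that("permutation p-value follows the add-one rule", {
  set.seed(3)
  null_p <- matrix(runif(999 * 4), 999, 4)
  # W_obs = 1: every null statistic is <= 1
  expect_equal(tpm_permutation_pvalue(1, null_p, 0.05), 1)
  # W_obs below every null statistic: p = 1/1000
  expect_equal(tpm_permutation_pvalue(1e-30, null_p, 0.05), 1 / 1000)
  # equal weights match unweighted
  expect_equal(
    tpm_permutation_pvalue(1e-4, null_p, 0.05, weights = rep(2, 4)),
    tpm_permutation_pvalue(1e-4, null_p, 0.05), tolerance = 0)
  expect_error(tpm_permutation_pvalue(1e-4, null_p, 0.05, weights = 1:3),
               "mismatch")
})

test_that("sign-flip group property: relabeling a pair equals flipping it", {
  prep <- quiet_pairs(sim_config(n_pairs = 30, n_diabetes_flag_pairs = 0,
                                 seed = 13), exclude = FALSE)
  pd <- prep$pd
  cpgs <- attr(pd, "cpg_ids")[1:12]
  # whole-cohort relabeling: every difference column negated
  pd_all <- pd
  dcols <- setdiff(names(pd), c("pair_id", "age"))
  pd_all[dcols] <- -pd_all[dcols]
  set.seed(55)
  S <- matrix(sample(c(-1, 1), nrow(pd) * 25, replace = TRUE), nrow(pd), 25)
  # the design columns only change sign, so the null p-value of sign vector
  # s on the relabeled table equals that of -s on the original
  n_orig <- signflip_null(pd, cpgs, "glucose", B = 25, signs = -S)
  n_flip <- signflip_null(pd_all, cpgs, "glucose", B = 25, signs = S)
  expect_equal(unclass(n_flip), unclass(n_orig), tolerance = 1e-10,
               ignore_attr = TRUE)
  # and the observed TPM statistic is invariant under full relabeling
  ones <- matrix(1, nrow(pd), 1)
  p1 <- signflip_null(pd, cpgs, "glucose", B = 1, signs = ones)
  p2 <- signflip_null(pd_all, cpgs, "glucose", B = 1, signs = -ones)
  expect_equal(tpm_statistic(as.numeric(p2[1, ]), 0.05),
               tpm_statistic(as.numeric(p1[1, ]), 0.05), tolerance = 1e-10)
})

test_that("gene scan has Table-3 shape and a brute-force BH q", {
  prep <- quiet_pairs(sim_config(seed = 14))
  gb <- gene_based_scan(prep$pd, prep$annot, tau = 0.05, weighted = TRUE,
                        B = 199, seed = 2)
  expect_equal(nrow(gb), 5L * 3L)
  expect_setequal(unique(gb$unit), TWINSET_GENES)
  for (tr in TWINSET_TRAITS) {
    sub <- gb[gb$trait == tr, ]
    expect_identical(unname(sub$q), unname(bh_oracle(sub$p)))
  }
  expect_true(all(gb$p >= 1 / 200 & gb$p <= 1))
  expect_true(all(gb$W > 0 & gb$W <= 1))
  gs <- gene_set_test(prep$pd, prep$annot, B = 199, seed = 2)
  expect_equal(nrow(gs), 3L)
  expect_true(all(gs$unit == "pathway"))
  expect_equal(gs$L, rep(77L, 3))
})

test_that("a single-gene pathway reduces to the gene-based test", {
  prep <- quiet_pairs(sim_config(n_pairs = 40, n_diabetes_flag_pairs = 0,
                                 seed = 23), exclude = FALSE)
  one_gene <- prep$annot[prep$annot$gene == "PER2", ]
  gb <- gene_based_scan(prep$pd, one_gene, traits = "homa_ir", B = 299,
                        seed = 11)
  gs <- gene_set_test(prep$pd, one_gene, traits = "homa_ir", B = 299,
                      seed = 11)
  expect_equal(gs$W, gb$W, tolerance = 1e-12)
  expect_equal(gs$p, gb$p, tolerance = 1e-12)
})

test_that("with tau = 1 a single-CpG gene recovers the marginal permutation p", {
  prep <- quiet_pairs(sim_config(n_pairs = 40, n_diabetes_flag_pairs = 0,
                                 seed = 24), exclude = FALSE)
  pd <- prep$pd
  one <- prep$annot[prep$annot$cpg_id == "PER3_cg01", ]
  gb <- gene_based_scan(pd, one, traits = "glucose", tau = 1,
                        weighted = FALSE, B = 499, seed = 3)
  np <- signflip_null(pd, "PER3_cg01", "glucose", B = 499, seed = 3)
  covm <- as.matrix(pd[paste0("d_", twinset_covariates())])
  p_obs <- fit_matched_ols(pd$d_glucose, pd$PER3_cg01, covm, pd$age)$p
  marginal <- (1 + sum(np[, 1] <= p_obs)) / 500
  expect_equal(gb$p, marginal, tolerance = 1e-12)
})

test_that("weighted analytic combinations are refused", {
  prep <- quiet_pairs(sim_config(n_pairs = 20, n_diabetes_flag_pairs = 0,
                                 seed = 25), exclude = FALSE)
  expect_error(gene_based_scan(prep$pd, prep$annot, weighted = TRUE,
                               method = "analytic"), "no analytic null")
  gb <- gene_based_scan(prep$pd, prep$annot, traits = "hba1c",
                        weighted = FALSE, method = "analytic")
  expect_true(all(gb$method == "analytic"))
  expect_true(all(gb$p > 0 & gb$p <= 1))
})

test_that("pathway pooling beats the best single gene on multi-gene signal", {
  nrep <- 120
  eff <- data.frame(trait = "hba1c",
                    cpg = c("PER1_cg01", "PER1_cg02", "PER1_cg03",
                            "PER3_cg01", "PER3_cg02", "PER3_cg03"),
                    beta = 0.30)
  hit_path <- hit_gene <- matrix(NA, nrep, 1)
  gene_p <- matrix(NA_real_, nrep, 5)
  path_p <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg <- sim_config(n_pairs = 69, effects = eff,
                      n_diabetes_flag_pairs = 0, seed = 6000 + r)
    prep <- quiet_pairs(cfg, exclude = FALSE)
    gb <- gene_based_scan(prep$pd, prep$annot, traits = "hba1c", B = 199,
                          seed = r)
    gene_p[r, ] <- gb$p
    path_p[r] <- gene_set_test(prep$pd, prep$annot, traits = "hba1c",
                               B = 199, seed = r)$p
  }
  power_path <- mean(path_p < 0.05)
  power_gene <- apply(gene_p < 0.05, 2L, mean)
  # allow 2 binomial SEs of slack for Monte-Carlo noise
  slack <- 2 * sqrt(0.25 / nrep)
  expect_gte(power_path, max(power_gene) - slack)
})
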