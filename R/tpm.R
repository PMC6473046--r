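# (Weighted) truncated product method for joint gene-based and gene-set
# inference on single-CpG p-values.
#
# The unweighted statistic is W = prod over {p_i <= tau} of p_i; its null
# distribution for independent uniforms has a closed form.  The weighted
# variant raises each truncated p to a positive exponent w_i (regression
# effect sizes, mean-normalized to 1); its significance is always assessed by
# a sign-flip permutation null, which also preserves the inter-CpG
# correlation the analytic form ignores.

# log W; used internally so products of hundreds of tiny p-values never
# underflow before comparison
.tpm_log_statistic <- function(p, tau = 0.05, weights = NULL) {
  if (anyNA(p) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  if (is.null(weights)) {
    w <- rep(1, length(p))
  } else {
    if (length(weights) != length(p))
      stop("weights and p have different lengths")
    if (anyNA(weights) || any(weights <= 0)) stop("weights must be positive")
    w <- weights / mean(weights)
  }
  keep <- p <= tau
  sum(w[keep] * log(p[keep]))
}

#' Truncated product statistic
#'
#' Unweighted: `W = prod(p_i ^ I(p_i <= tau))`.  Weighted:
#' `W = prod(p_i ^ (w_i * I(p_i <= tau)))` with raw weights normalized to
#' mean 1.  Computed in log space; `W = 1` when no p-value passes the
#' truncation.
#'
#' @param p P-values in (0, 1].
#' @param tau Truncation threshold in (0, 1].
#' @param weights Optional positive weights, one per p-value.
#' @return The statistic W in (0, 1].
#' @export
tpm_statistic <- function(p, tau = 0.05, weights = NULL) {
  exp(.tpm_log_statistic(p, tau, weights))
}

#' Analytic null p-value of the unweighted truncated product
#'
#' Tail probability `P(W_null <= W)` when the L combined p-values are
#' independent Uniform(0, 1):
#' `sum_{k=1..L} C(L,k) (1-tau)^{L-k} * [ W * sum_{s=0..k-1} (k ln tau - ln W)^s / s!`
#' if `W <= tau^k`, else `tau^k ]`, evaluated in log space; the point mass
#' `(1-tau)^L` at W = 1 is included so that `p(W = 1) = 1`.  For `tau = 1`
#' this is Fisher's method: the chi-squared(2L) tail of `-2 ln W`.
#'
#' @param W Observed statistic in (0, 1] (or its log, with `log_w = TRUE`).
#' @param L Number of combined p-values.
#' @param tau Truncation threshold in (0, 1].
#' @param log_w Is `W` supplied on the log scale?
#' @return The combined p-value.
#' @export
tpm_analytic_pvalue <- function(W, L, tau = 0.05, log_w = FALSE) {
  lw <- if (log_w) W else log(W)
  if (is.na(lw) || lw > 0) stop("W must lie in (0, 1]")
  if (L < 1L) stop("L must be >= 1")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  ltau <- log(tau)
  log_terms <- vapply(seq_len(L), function(k) {
    l1mt <- if (k == L) 0 else (L - k) * log1p(-tau)   # 0 * log(0) guard
    if (!is.finite(l1mt)) return(-Inf)                 # tau == 1, k < L
    lc <- lchoose(L, k)
    if (lw <= k * ltau) {
      a <- k * ltau - lw                               # >= 0
      s <- 0:(k - 1L)
      ls <- if (a == 0) c(0, rep(-Inf, k - 1L)) else s * log(a) - lgamma(s + 1)
      mx <- max(ls)
      lc + l1mt + lw + mx + log(sum(exp(ls - mx)))
    } else {
      lc + l1mt + k * ltau
    }
  }, numeric(1))
  p <- sum(exp(log_terms))
  if (lw >= 0) p <- p + (1 - tau)^L                    # atom at W = 1
  min(p, 1)
}

#' Sign-flip permutation null for the single-CpG scan
#'
#' For each of `B` replicates, every pair's trait difference is multiplied by
#' an independent +/-1 sign (methylation and covariate differences are left
#' untouched) and the matched OLS is re-fit for every CpG.  Under the null of
#' no methylation effect the trait difference of an MZ pair is exchangeable
#' in sign, and because all CpGs share each replicate's flipped outcome the
#' inter-CpG correlation of the p-values is preserved.  An option flips the
#' residuals of the covariates-only model instead (Freedman-Lane style).
#'
#' @param pd Pair-difference table.
#' @param cpg_ids CpG columns to scan.
#' @param trait Trait name (column `d_<trait>`).
#' @param covariates Covariate names (columns `d_<covariate>`).
#' @param B Number of sign-flip replicates (>= 1).
#' @param seed Integer seed; the whole B x n sign matrix is drawn in one
#'   block, so results are reproducible and independent of evaluation order.
#' @param flip Flip the raw trait difference (`"trait"`, default) or the
#'   covariate-model residuals (`"residual"`).
#' @param signs Optional n x B matrix of +/-1 overriding the drawn signs
#'   (diagnostics; e.g. a column of +1 reproduces the observed scan).
#' @return B x length(cpg_ids) matrix of null p-values (attributes `beta`
#'   and `df` carry the matching null effect sizes and residual df).
#' @export
signflip_null <- function(pd, cpg_ids = attr(pd, "cpg_ids"),
                          trait, covariates = attr(pd, "covariates"),
                          B = 499L, seed = 1L,
                          flip = c("trait", "residual"), signs = NULL) {
  flip <- match.arg(flip)
  if (B < 1L) stop("B must be >= 1")
  dat <- .scan_matrices(pd, cpg_ids, trait, covariates)
  n <- length(dat$y)
  if (is.null(signs)) {
    set.seed(seed)
    signs <- matrix(sample(c(-1, 1), n * B, replace = TRUE), n, B)
  } else {
    signs <- as.matrix(signs)
    stopifnot(nrow(signs) == n, ncol(signs) == B)
  }
  y0 <- if (flip == "trait") dat$y else qr.resid(qr(dat$Z), dat$y)
  Y <- y0 * signs
  if (flip == "residual") Y <- Y + (dat$y - y0)  # add fitted part back
  eng <- .matched_ols_engine(Y, dat$X, dat$Z)
  out <- t(eng$p)
  colnames(out) <- cpg_ids
  attr(out, "beta") <- t(eng$beta)
  attr(out, "df") <- eng$df
  out
}

# complete-case outcome/design matrices shared by the joint tests
.scan_matrices <- function(pd, cpg_ids, trait, covariates) {
  stopifnot(all(cpg_ids %in% names(pd)))
  y <- pd[[paste0("d_", trait)]]
  if (is.null(y)) stop("unknown trait: ", trait)
  X <- as.matrix(pd[cpg_ids])
  Z <- cbind(`(Intercept)` = rep(1, nrow(pd)))
  if (length(covariates))
    Z <- cbind(Z, as.matrix(pd[paste0("d_", covariates)]))
  if (!is.null(pd$age)) Z <- cbind(Z, age = pd$age)
  ok <- stats::complete.cases(cbind(y, X, Z))
  if (any(!ok))
    message(sprintf("dropped %d pair(s) with missing values", sum(!ok)))
  list(y = y[ok], X = X[ok, , drop = FALSE], Z = Z[ok, , drop = FALSE])
}

#' Permutation p-value for a truncated product statistic
#'
#' Add-one rule: `p = (1 + #{b : W_b <= W_obs}) / (B + 1)`, where each null
#' `W_b` applies [tpm_statistic()] with the same truncation and weights to
#' row `b` of the null p-value matrix.  Comparisons are done in log space so
#' underflowing products still rank correctly.
#'
#' @param W_obs Observed statistic (or its log with `log_w = TRUE`).
#' @param null_p B x L matrix of null p-values from [signflip_null()] over
#'   the same CpG set.
#' @param tau,weights Passed to [tpm_statistic()] for every null row.
#' @param log_w Is `W_obs` on the log scale?
#' @return Permutation p-value in `[1/(B+1), 1]`.
#' @export
tpm_permutation_pvalue <- function(W_obs, null_p, tau = 0.05, weights = NULL,
                                   log_w = FALSE) {
  lw_obs <- if (log_w) W_obs else log(W_obs)
  M <- as.matrix(null_p)
  if (anyNA(M) || any(M <= 0 | M > 1)) stop("null p-values must lie in (0, 1]")
  if (tau <= 0 || tau > 1) stop("tau must be in (0, 1]")
  w <- if (is.null(weights)) rep(1, ncol(M)) else {
    if (length(weights) != ncol(M)) stop("CpG set mismatch: weights vs null matrix")
    if (any(weights <= 0)) stop("weights must be positive")
    weights / mean(weights)
  }
  lw_null <- as.numeric((log(M) * (M <= tau)) %*% w)   # row-wise log W
  (1 + sum(lw_null <= lw_obs)) / (nrow(M) + 1)
}

# Shared worker: observed scan + one null matrix per trait, then TPM per
# CpG-column subset (each gene, and the pooled pathway).
.joint_tests <- function(pd, annot, traits, tau, weighted, B, seed,
                         covariates, method, pathway_level) {
  genes <- unique(annot$gene)
  rows <- list()
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    dat <- .scan_matrices(pd, annot$cpg_id, tr, covariates)
    eng <- .matched_ols_engine(dat$y, dat$X, dat$Z)
    obs_p <- as.numeric(eng$p)
    obs_beta <- as.numeric(eng$beta)
    names(obs_p) <- names(obs_beta) <- annot$cpg_id
    null_p <- if (method == "permutation")
      signflip_null(pd, annot$cpg_id, tr, covariates, B = B,
                    seed = seed + ti - 1L) else NULL
    null_beta <- attr(null_p, "beta")
    test_unit <- function(unit, ids) {
      wts <- if (weighted) abs(obs_beta[ids]) else NULL
      lW <- .tpm_log_statistic(obs_p[ids], tau, wts)
      if (method == "analytic") {
        pv <- tpm_analytic_pvalue(lW, length(ids), tau, log_w = TRUE)
        np <- NA_integer_
      } else if (!weighted) {
        pv <- tpm_permutation_pvalue(lW, null_p[, ids, drop = FALSE], tau,
                                     NULL, log_w = TRUE)
        np <- B
      } else {
        # weights are data-derived, so each null replicate gets its own
        # weights (|beta| of the flipped fit, mean-normalized within the
        # unit); re-using the observed weights for the null would make the
        # test anti-conservative, since small observed p-values carry large
        # observed |beta| by construction
        P <- null_p[, ids, drop = FALSE]
        Wb <- abs(null_beta[, ids, drop = FALSE])
        Wb <- Wb / rowMeans(Wb)
        lw_null <- rowSums(log(P) * (P <= tau) * Wb)
        pv <- (1 + sum(lw_null <= lW)) / (B + 1)
        np <- B
      }
      data.frame(unit = unit, trait = tr, W = exp(lW), tau = tau,
                 L = length(ids),
                 weighted = weighted, p = pv, method = method, n_perm = np,
                 stringsAsFactors = FALSE)
    }
    gene_rows <- lapply(genes, function(g)
      test_unit(g, annot$cpg_id[annot$gene == g]))
    gene_df <- do.call(rbind, gene_rows)
    gene_df$q <- bh_fdr(gene_df$p)
    path_row <- if (pathway_level == "cpg") {
      pr <- test_unit("pathway", annot$cpg_id)
      pr$q <- NA_real_
      pr
    } else {
      # combine the gene-level combined p-values instead of pooling CpGs
      lWg <- .tpm_log_statistic(gene_df$p, tau, NULL)
      pv <- if (method == "analytic")
        tpm_analytic_pvalue(lWg, nrow(gene_df), tau, log_w = TRUE)
      else NA_real_
      data.frame(unit = "pathway", trait = tr, W = exp(lWg), tau = tau,
                 L = nrow(gene_df), weighted = FALSE, p = pv,
                 method = method, n_perm = NA_integer_, q = NA_real_,
                 stringsAsFactors = FALSE)
    }
    rows[[ti]] <- rbind(gene_df, path_row)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Gene-based truncated product scan
#'
#' One TPM test per (gene, trait), combining the single-CpG matched-OLS
#' p-values of the gene's CpGs.  With `weighted = TRUE` (default) each
#' p-value's exponent is the absolute single-CpG effect size, normalized to
#' mean 1 within the gene, and significance is assessed by the sign-flip
#' permutation null (the weighted statistic has no closed-form null); the
#' same null replicates serve every gene, preserving their correlation.
#' q-values are BH across the genes within each trait.
#'
#' @param pd Pair-difference table.
#' @param annot CpG annotation mapping CpGs to genes.
#' @param traits Trait names.
#' @param tau Truncation threshold (canonical 0.05).
#' @param weighted Weight p-values by |beta|?
#' @param B Sign-flip replicates for the permutation null.
#' @param seed Integer seed.
#' @param covariates Adjustment covariate names.
#' @param method `"permutation"` (default; required when weighted) or
#'   `"analytic"` (independence null, unweighted only).
#' @return Data frame of TPM results (one row per gene x trait).
#' @export
gene_based_scan <- function(pd, annot, traits = attr(pd, "traits"),
                            tau = 0.05, weighted = TRUE, B = 9999L,
                            seed = 1L, covariates = attr(pd, "covariates"),
                            method = c("permutation", "analytic")) {
  method <- match.arg(method)
  if (weighted && method == "analytic")
    stop("the weighted statistic has no analytic null; use permutation")
  res <- .joint_tests(pd, annot, traits, tau, weighted, B, seed, covariates,
                      method, pathway_level = "cpg")
  res[res$unit != "pathway", , drop = FALSE]
}

#' Gene-set (pathway) truncated product test
#'
#' Combines the single-CpG p-values of all CpGs across all genes in one TPM
#' test per trait (`pathway_level = "cpg"`, default); alternatively combines
#' the gene-level combined p-values (`pathway_level = "gene"`).
#'
#' @inheritParams gene_based_scan
#' @param pathway_level Pool CpG-level p-values (`"cpg"`) or combine
#'   gene-level results (`"gene"`, analytic method only).
#' @return Data frame with one `unit = "pathway"` row per trait.
#' @export
gene_set_test <- function(pd, annot, traits = attr(pd, "traits"),
                          tau = 0.05, weighted = TRUE, B = 9999L,
                          seed = 1L, covariates = attr(pd, "covariates"),
                          method = c("permutation", "analytic"),
                          pathway_level = c("cpg", "gene")) {
  method <- match.arg(method)
  pathway_level <- match.arg(pathway_level)
  if (weighted && method == "analytic")
    stop("the weighted statistic has no analytic null; use permutation")
  if (pathway_level == "gene" && method == "permutation")
    stop("gene-level pathway pooling is available with the analytic method")
  res <- .joint_tests(pd, annot, traits, tau, weighted, B, seed, covariates,
                      method, pathway_level)
  res <- res[res$unit == "pathway", , drop = FALSE]
  rownames(res) <- NULL
  res
}
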