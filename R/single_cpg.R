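# Matched-pair single-CpG regression scan (co-twin control OLS) with
# Benjamini-Hochberg FDR and significance tabulation.

# Smallest p-value reported; keeps log-products finite in the joint tests.
P_FLOOR <- 1e-300

#' Matched-pair OLS of a trait difference on a methylation difference
#'
#' Ordinary least squares with intercept, design `[1, x, covars, age]`, on
#' the intra-pair difference scale.  Age enters at pair level (the intra-pair
#' age difference is identically zero in MZ twins).  Two-sided p-value from
#' the t distribution with `n - k` degrees of freedom, `k` the number of
#' design columns.  Rows with any missing value are dropped (complete-case,
#' counted in `n_pairs_used`).
#'
#' @param y Numeric vector, intra-pair trait differences.
#' @param x Numeric vector, intra-pair methylation differences.
#' @param covars Optional numeric matrix/data frame of intra-pair covariate
#'   differences.
#' @param age Optional pair-level age vector.
#' @return One-row data frame: `beta`, `se`, `p`, `n_pairs_used`, `df`,
#'   `skipped`, `skip_reason`.  A zero-variance `x` yields a skip record
#'   (NA estimates) instead of an error.
#' @export
fit_matched_ols <- function(y, x, covars = NULL, age = NULL) {
  X <- cbind(`(Intercept)` = 1, x = x)
  if (!is.null(covars)) {
    covars <- as.matrix(covars)
    if (is.null(colnames(covars)))
      colnames(covars) <- paste0("covar", seq_len(ncol(covars)))
    X <- cbind(X, covars)
  }
  if (!is.null(age)) X <- cbind(X, age = age)
  if (nrow(X) != length(y)) stop("y and design have different lengths")

  ok <- stats::complete.cases(cbind(y, X))
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(sprintf("dropped %d pair(s) with missing values", n_dropped))
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  n <- length(y); k <- ncol(X)

  skip <- function(reason) data.frame(
    beta = NA_real_, se = NA_real_, p = NA_real_, n_pairs_used = n,
    df = NA_integer_, skipped = TRUE, skip_reason = reason,
    stringsAsFactors = FALSE)
  if (stats::var(X[, "x"]) == 0) return(skip("zero-variance methylation difference"))
  if (n <= k + 1L) stop("too few pairs (", n, ") for ", k, " design columns")

  qx <- qr(X)
  if (qx$rank < k) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):k]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qx, y)
  res <- y - X %*% coefs
  df <- n - k
  sigma2 <- sum(res^2) / df
  XtXinv_xx <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)][2L, 2L]
  se <- sqrt(sigma2 * XtXinv_xx)
  beta <- unname(coefs["x"])
  p <- if (se == 0) P_FLOOR else
    max(2 * stats::pt(-abs(beta / se), df), P_FLOOR)
  data.frame(beta = beta, se = se, p = p, n_pairs_used = n, df = df,
             skipped = FALSE, skip_reason = NA_character_,
             stringsAsFactors = FALSE)
}

# Vectorized matched OLS by Frisch-Waugh-Lovell residualization: identical to
# refitting [1, x_c, Z] per CpG, but shares the nuisance projection.
#   Y: n x B outcomes, Xm: n x m CpG differences, Z: n x q nuisance design
#   (must include the intercept).  Returns beta, se, p as m x B matrices.
.matched_ols_engine <- function(Y, Xm, Z) {
  Y <- as.matrix(Y); Xm <- as.matrix(Xm); Z <- as.matrix(Z)
  n <- nrow(Y)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) stop("rank-deficient nuisance design")
  Xr <- qr.resid(qz, Xm)
  Yr <- qr.resid(qz, Y)
  d <- colSums(Xr^2)
  df <- n - ncol(Z) - 1L
  beta <- crossprod(Xr, Yr) / d                    # m x B
  yss <- colSums(Yr^2)                             # length B
  rss <- pmax(sweep(-(beta^2) * d, 2L, yss, "+"), 0)
  se <- sqrt(sweep(rss / df, 1L, d, "/"))
  p <- pmax(2 * stats::pt(-abs(beta / se), df), P_FLOOR)
  list(beta = beta, se = se, p = p, df = df, n = n)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: sort p ascending, `q(i) = min_{j>=i} p(j) * m / j`,
#' capped at 1, mapped back to input order; tied p-values get equal q.
#' Agrees with `stats::p.adjust(method = "BH")` to floating-point rounding.
#'
#' @param p Numeric vector of raw p-values in (0, 1].
#' @return q-values in input order.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  q_sorted <- pmin(rev(cummin(rev(adj))), 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Single-CpG association scan across traits
#'
#' One matched OLS per (CpG, trait); q-values are computed per trait across
#' all scanned CpGs (multiplicity is the total number of CpG sites).
#' Per-CpG skip records (zero-variance differences) propagate without
#' aborting the scan.
#'
#' @param pd Pair-difference table from [compute_pair_differences()].
#' @param annot CpG annotation (defines the scanned CpGs and gene labels).
#' @param traits Trait names (matching `d_<trait>` columns).
#' @param covariates Covariate names (matching `d_<covariate>` columns).
#' @return Data frame with one row per (CpG, trait): annotation columns,
#'   `trait`, `beta`, `se`, `p`, `q`, `n_pairs_used`, `skipped`.
#' @export
run_single_cpg_scan <- function(pd, annot,
                                traits = attr(pd, "traits"),
                                covariates = attr(pd, "covariates")) {
  stopifnot(length(traits) >= 1L, nrow(annot) >= 1L)
  cpgs <- annot$cpg_id
  missing_cpg <- setdiff(cpgs, names(pd))
  if (length(missing_cpg))
    stop("CpG column(s) absent from pair table: ",
         paste(missing_cpg, collapse = ", "))
  covm <- if (length(covariates))
    as.matrix(pd[paste0("d_", covariates)]) else NULL
  out <- vector("list", length(traits))
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    fits <- lapply(cpgs, function(cc)
      fit_matched_ols(pd[[paste0("d_", tr)]], pd[[cc]], covm, pd$age))
    fits <- do.call(rbind, fits)
    q <- rep(NA_real_, nrow(fits))
    ok <- !fits$skipped
    q[ok] <- bh_fdr(fits$p[ok])
    out[[ti]] <- cbind(annot, trait = tr, fits, q = q)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count significant CpGs
#'
#' Counts CpGs whose raw p (or q) falls strictly below `alpha`, grouped by
#' trait and/or gene.  Strict inequality matters at printed boundaries: a
#' p-value reported as exactly `alpha` does not count.
#'
#' @param results Scan results with `trait`, `gene`, `p`, `q` columns.
#' @param alpha Significance threshold in (0, 1).
#' @param by Grouping columns, subset of `c("trait", "gene")`.
#' @param on Which column to threshold, `"p"` (default) or `"q"`.
#' @return Data frame of group keys plus `n_significant`.
#' @export
count_significant <- function(results, alpha = 0.05,
                              by = c("trait", "gene"), on = c("p", "q")) {
  if (!nrow(results)) stop("empty results table")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  on <- match.arg(on)
  by <- match.arg(by, c("trait", "gene"), several.ok = TRUE)
  hit <- !is.na(results[[on]]) & results[[on]] < alpha
  agg <- stats::aggregate(hit, by = results[by], FUN = sum)
  names(agg)[ncol(agg)] <- "n_significant"
  agg[do.call(order, agg[by]), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}
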