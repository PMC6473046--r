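# Synthetic monozygotic-twin cohort generator.
#
# Emulates the statistical structure the matched-pair analysis assumes:
# block-correlated promoter methylation (within-gene equicorrelation, zero
# between genes), a pair-shared methylation component, glucose traits built
# from planted linear effects of intra-pair methylation differences, Table-1
# order covariates, and a diabetes flag driving the pair-exclusion rule.

# gene -> chrom / transcription start / strand / promoter mean methylation (%)
.TWINSET_GENE_INFO <- data.frame(
  gene = c("CLOCK", "BMAL1", "PER1", "PER2", "PER3"),
  chrom = c("chr4", "chr11", "chr17", "chr2", "chr1"),
  tss = c(56413304L, 13299345L, 8055752L, 239197248L, 7844715L),
  strand = c("-", "+", "-", "-", "+"),
  mean_meth = c(1.2, 1.2, 1.3, 0.7, 44),
  stringsAsFactors = FALSE
)

# trait -> member-level mean, pair-baseline SD, positivity floor (Table-1 scale)
.TWINSET_TRAIT_INFO <- list(
  homa_ir = list(mean = 1.87, pair_sd = 1.1, floor = 0.05, lognormal = TRUE),
  glucose = list(mean = 97.2, pair_sd = 9.0, floor = 40, lognormal = FALSE),
  hba1c   = list(mean = 5.5,  pair_sd = 0.4, floor = 3.0, lognormal = FALSE)
)

# covariate -> mean, SD, lower clip (Table-1 scale); half the variance is
# shared within a pair
.TWINSET_COVAR_INFO <- data.frame(
  covariate = c("pack_years", "alcohol", "activity", "bdi_ii", "bmi",
                "sbp", "dbp", "hdl_c", "ldl_c"),
  mean = c(22.3, 12.5, 7.5, 6.0, 28.9, 129.5, 81.6, 38.5, 123.7),
  sd = c(23.8, 38.0, 1.7, 6.6, 4.9, 15.4, 10.9, 10.9, 35.0),
  lo = c(0, 0, 0, 0, 15, 70, 40, 5, 20),
  stringsAsFactors = FALSE
)

#' Simulation recipe for a synthetic MZ twin cohort
#'
#' Defaults reproduce the modelled study conditions: 84 male-male MZ pairs of
#' which 15 carry an overt-diabetes flag (leaving 69 analyzable pairs), and
#' 77 promoter CpGs across five circadian genes (CLOCK 30, BMAL1 18, PER1 10,
#' PER2 9, PER3 10; only the CLOCK and PER2 counts are fixed by the assay the
#' package models, the rest is a configurable split of the remaining 38).
#'
#' @param n_pairs Number of complete twin pairs to simulate.
#' @param cpg_counts Named integer vector, gene -> number of CpGs.
#' @param rho_within_gene Equicorrelation of CpG methylation within a gene
#'   block, in \[0, 1); between-gene correlation is zero.
#' @param sigma_meth SD (percentage points) of a member's total methylation
#'   deviation around the gene mean.
#' @param pair_icc Fraction of methylation variance shared within a pair, in
#'   \[0, 1) — the within-pair methylation correlation.
#' @param effects Planted linear effects of the intra-pair methylation
#'   difference on the intra-pair trait difference: a data frame with columns
#'   `trait`, `cpg`, `beta` (empty by default, i.e. a global-null cohort).
#' @param trait_noise_sd Named vector, trait -> SD of the residual noise on
#'   the intra-pair trait difference (trait units).
#' @param n_diabetes_flag_pairs How many pairs (the first ones) carry an
#'   overt-diabetes flag on at least one member.
#' @param covariate_effects Optional data frame `trait`, `covariate`, `beta`
#'   adding covariate contributions to the trait difference.
#' @param confounding Optional list `list(cpg=, covariate=, coef=)` making
#'   one covariate difference depend on one CpG's methylation difference
#'   (covariates are independent of methylation by default).
#' @param seed Integer RNG seed; identical seeds give bit-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_pairs = 84L,
                       cpg_counts = c(CLOCK = 30L, BMAL1 = 18L, PER1 = 10L,
                                      PER2 = 9L, PER3 = 10L),
                       rho_within_gene = 0.3,
                       sigma_meth = 1.2,
                       pair_icc = 0.5,
                       effects = NULL,
                       trait_noise_sd = c(homa_ir = 1.3, glucose = 11,
                                          hba1c = 0.5),
                       n_diabetes_flag_pairs = 15L,
                       covariate_effects = NULL,
                       confounding = NULL,
                       seed = 1L) {
  cfg <- list(n_pairs = as.integer(n_pairs), cpg_counts = cpg_counts,
              rho_within_gene = rho_within_gene, sigma_meth = sigma_meth,
              pair_icc = pair_icc, effects = effects,
              trait_noise_sd = trait_noise_sd,
              n_diabetes_flag_pairs = as.integer(n_diabetes_flag_pairs),
              covariate_effects = covariate_effects,
              confounding = confounding, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param config A `sim_config` object.
#' @export
validate_sim_config <- function(config) {
  with(config, {
    if (is.na(n_pairs) || n_pairs < 1L) stop("n_pairs must be positive")
    if (is.null(names(cpg_counts)) ||
        !all(names(cpg_counts) %in% TWINSET_GENES))
      stop("cpg_counts must be named by genes among: ",
           paste(TWINSET_GENES, collapse = ", "))
    if (any(cpg_counts < 1L)) stop("cpg_counts must be positive")
    if (rho_within_gene < 0 || rho_within_gene >= 1)
      stop("rho_within_gene must be in [0, 1)")
    if (pair_icc < 0 || pair_icc >= 1) stop("pair_icc must be in [0, 1)")
    if (sigma_meth <= 0) stop("sigma_meth must be positive")
    if (any(trait_noise_sd < 0)) stop("trait_noise_sd must be non-negative")
    if (!all(TWINSET_TRAITS %in% names(trait_noise_sd)))
      stop("trait_noise_sd must name all of: ",
           paste(TWINSET_TRAITS, collapse = ", "))
    if (n_diabetes_flag_pairs < 0L || n_diabetes_flag_pairs > n_pairs)
      stop("n_diabetes_flag_pairs must be in [0, n_pairs]")
    if (!is.null(effects)) {
      stopifnot(is.data.frame(effects),
                all(c("trait", "cpg", "beta") %in% names(effects)))
      if (!all(effects$trait %in% TWINSET_TRAITS))
        stop("effects reference unknown trait(s): ",
             paste(setdiff(effects$trait, TWINSET_TRAITS), collapse = ", "))
      known <- .cpg_ids_for(cpg_counts)
      if (!all(effects$cpg %in% known))
        stop("effects reference unknown CpG(s): ",
             paste(setdiff(effects$cpg, known), collapse = ", "))
    }
  })
  invisible(config)
}

.cpg_ids_for <- function(cpg_counts) {
  unlist(lapply(names(cpg_counts), function(g)
    sprintf("%s_cg%02d", g, seq_len(cpg_counts[[g]]))), use.names = FALSE)
}

# n x m draw from N(0, sd^2 * C), C equicorrelated with parameter rho:
# sqrt(1-rho) * iid + sqrt(rho) * shared-within-row factor
.requicorr <- function(n, m, rho, sd) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (rho > 0) {
    f <- stats::rnorm(n)
    z <- sqrt(1 - rho) * z + sqrt(rho) * f
  }
  sd * z
}

#' Generate a synthetic MZ twin cohort
#'
#' Methylation for member j of pair i at CpG c is
#' `gene_mean + shared_ic + e_ijc`, where the pair-shared component carries a
#' fraction `pair_icc` of the variance `sigma_meth^2` and both components are
#' equicorrelated within a gene (`rho_within_gene`) and independent across
#' genes.  Percentages are clipped to \[0, 100\] (clip counts are logged and
#' attached as attribute `n_clipped`).  Intra-pair trait differences are
#' `sum(effects * d_methylation) + covariate terms + noise`, split into two
#' member levels around Table-1-order trait means; fasting insulin is set so
#' that the derived HOMA-IR reproduces the generated HOMA-IR exactly.
#'
#' @param config A [sim_config()].
#' @return List with `samples` (2 * n_pairs rows), `meth` (sample x CpG
#'   percent methylation) and `annot` (BED-ready CpG annotation with
#'   synthetic GRCh37-style coordinates and signed TSS offsets).
#' @export
generate_twin_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_pairs
  genes <- names(config$cpg_counts)
  cpg_ids <- .cpg_ids_for(config$cpg_counts)
  m_total <- length(cpg_ids)

  # annotation: evenly spaced promoter offsets around each gene's TSS
  annot <- do.call(rbind, lapply(genes, function(g) {
    gi <- .TWINSET_GENE_INFO[.TWINSET_GENE_INFO$gene == g, ]
    m <- config$cpg_counts[[g]]
    offs <- as.integer(round(seq(150, -450, length.out = m)))
    pos <- if (gi$strand == "+") gi$tss + offs else gi$tss - offs
    data.frame(cpg_id = sprintf("%s_cg%02d", g, seq_len(m)), gene = g,
               chrom = gi$chrom, pos = as.integer(pos), tss_offset = offs,
               stringsAsFactors = FALSE)
  }))
  rownames(annot) <- NULL

  # methylation: pair-shared + individual deviations, per gene block
  shared <- matrix(0, n, m_total)
  indiv <- matrix(0, 2L * n, m_total)
  base <- numeric(m_total)
  col0 <- 0L
  for (g in genes) {
    m <- config$cpg_counts[[g]]
    cols <- col0 + seq_len(m)
    gi <- .TWINSET_GENE_INFO[.TWINSET_GENE_INFO$gene == g, ]
    base[cols] <- gi$mean_meth
    shared[, cols] <- .requicorr(n, m, config$rho_within_gene,
                                 sqrt(config$pair_icc) * config$sigma_meth)
    indiv[, cols] <- .requicorr(2L * n, m, config$rho_within_gene,
                                sqrt(1 - config$pair_icc) * config$sigma_meth)
    col0 <- col0 + m
  }
  meth_mat <- matrix(base, 2L * n, m_total, byrow = TRUE) +
    shared[rep(seq_len(n), each = 2L), , drop = FALSE] + indiv
  n_clipped <- sum(meth_mat < 0 | meth_mat > 100)
  if (n_clipped > 0)
    message(sprintf("clipped %d methylation value(s) to [0, 100]", n_clipped))
  meth_mat <- pmin(pmax(meth_mat, 0), 100)
  colnames(meth_mat) <- cpg_ids

  pair_id <- sprintf("P%03d", seq_len(n))
  member_id <- rep(1:2, n)
  sample_id <- paste(rep(pair_id, each = 2L), member_id, sep = "_")
  d_meth <- meth_mat[seq(1L, 2L * n, 2L), , drop = FALSE] -
    meth_mat[seq(2L, 2L * n, 2L), , drop = FALSE]

  # covariates: half the variance pair-shared, clipped to plausible ranges
  samples <- data.frame(sample_id = sample_id, pair_id = rep(pair_id, each = 2L),
                        member_id = member_id,
                        age = rep(round(stats::rnorm(n, 54.8, 2.9), 1), each = 2L),
                        stringsAsFactors = FALSE)
  for (k in seq_len(nrow(.TWINSET_COVAR_INFO))) {
    ci <- .TWINSET_COVAR_INFO[k, ]
    v <- ci$mean + rep(stats::rnorm(n, 0, ci$sd * sqrt(0.5)), each = 2L) +
      stats::rnorm(2L * n, 0, ci$sd * sqrt(0.5))
    samples[[ci$covariate]] <- pmax(v, ci$lo)
  }
  if (!is.null(config$confounding)) {
    cf <- config$confounding
    half <- cf$coef * meth_mat[, cf$cpg] / 2
    samples[[cf$covariate]] <- samples[[cf$covariate]] + half * 2
  }

  # intra-pair trait differences: planted effects + covariate terms + noise
  d_cov <- function(cv) samples[[cv]][seq(1L, 2L * n, 2L)] -
    samples[[cv]][seq(2L, 2L * n, 2L)]
  traits <- list()
  for (tr in TWINSET_TRAITS) {
    d <- stats::rnorm(n, 0, config$trait_noise_sd[[tr]])
    if (!is.null(config$effects)) {
      eff <- config$effects[config$effects$trait == tr, , drop = FALSE]
      for (r in seq_len(nrow(eff)))
        d <- d + eff$beta[r] * d_meth[, eff$cpg[r]]
    }
    if (!is.null(config$covariate_effects)) {
      ce <- config$covariate_effects[config$covariate_effects$trait == tr, ,
                                     drop = FALSE]
      for (r in seq_len(nrow(ce)))
        d <- d + ce$beta[r] * d_cov(ce$covariate[r])
    }
    ti <- .TWINSET_TRAIT_INFO[[tr]]
    pair_base <- if (ti$lognormal) {
      sdlog <- sqrt(log(1 + (ti$pair_sd / ti$mean)^2))
      stats::rlnorm(n, log(ti$mean) - sdlog^2 / 2, sdlog)
    } else {
      ti$mean + stats::rnorm(n, 0, ti$pair_sd)
    }
    m1 <- pmax(pair_base + d / 2, ti$floor)
    m2 <- pmax(pair_base - d / 2, ti$floor)
    n_floored <- sum(pair_base + d / 2 < ti$floor | pair_base - d / 2 < ti$floor)
    if (n_floored > 0)
      message(sprintf("floored %d %s member value(s) at %g", n_floored, tr,
                      ti$floor))
    v <- numeric(2L * n)
    v[seq(1L, 2L * n, 2L)] <- m1
    v[seq(2L, 2L * n, 2L)] <- m2
    traits[[tr]] <- v
  }
  samples$glucose <- traits$glucose
  samples$hba1c <- traits$hba1c
  # insulin chosen so that (glucose/18) * insulin / 22.5 == generated HOMA-IR
  samples$insulin <- 22.5 * traits$homa_ir / (samples$glucose / 18)
  samples$diabetes <- rep(seq_len(n) <= config$n_diabetes_flag_pairs,
                          each = 2L) &
    (stats::runif(2L * n) < 0.75 | rep(c(TRUE, FALSE), n))

  meth <- data.frame(sample_id = sample_id, stringsAsFactors = FALSE)
  meth <- cbind(meth, as.data.frame(meth_mat))
  rownames(meth) <- NULL
  out <- list(samples = samples, meth = meth, annot = annot)
  attr(out, "n_clipped") <- n_clipped
  out
}
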