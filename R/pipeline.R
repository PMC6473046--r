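# Orchestration: simulate/load -> prepare -> single-CpG scan -> gene/gene-set
# tests, with a run manifest and a human-readable report.

#' Assemble and validate a run configuration
#'
#' Either `sim` (a [sim_config()] or a list of its arguments) or the three
#' cohort file paths must be given.
#'
#' @param sim Optional simulation recipe.
#' @param samples,meth,annot Optional cohort file paths (used when `sim` is
#'   absent).
#' @param traits Glucose traits to analyse.
#' @param covariates Adjustment covariates.
#' @param alpha Significance threshold for counting.
#' @param tau TPM truncation threshold.
#' @param weighted Weight TPM p-values by |beta|?
#' @param B Sign-flip replicates.
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Validated `run_config` list.
#' @export
run_config <- function(sim = NULL, samples = NULL, meth = NULL, annot = NULL,
                       traits = TWINSET_TRAITS,
                       covariates = twinset_covariates(),
                       alpha = 0.05, tau = 0.05, weighted = TRUE,
                       B = 9999L, seed = 1L, out_dir = "twinset_run") {
  cfg <- list(sim = sim, samples = samples, meth = meth, annot = annot,
              traits = traits, covariates = covariates, alpha = alpha,
              tau = tau, weighted = weighted, B = as.integer(B),
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
validate_run_config <- function(config) {
  bad_tr <- setdiff(config$traits, TWINSET_TRAITS)
  if (length(bad_tr))
    stop("unknown trait(s): ", paste(bad_tr, collapse = ", "))
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0, 1)")
  if (config$tau <= 0 || config$tau > 1) stop("tau must be in (0, 1]")
  if (config$B < 1L) stop("B must be >= 1")
  if (is.null(config$sim)) {
    paths <- c(config$samples, config$meth, config$annot)
    if (length(paths) != 3L)
      stop("provide either a sim block or all three cohort file paths")
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  invisible(config)
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Configuration file; `.json` is parsed as JSON, anything else
#'   as YAML.  A `sim:` block is converted with [sim_config()] (its `effects`
#'   entry as a list of `{trait, cpg, beta}` records).
#' @return Validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.null(raw$sim)) {
    sim <- raw$sim
    if (!is.null(sim$cpg_counts)) sim$cpg_counts <- unlist(sim$cpg_counts)
    if (!is.null(sim$trait_noise_sd))
      sim$trait_noise_sd <- unlist(sim$trait_noise_sd)
    if (!is.null(sim$effects) && !is.data.frame(sim$effects))
      sim$effects <- do.call(rbind, lapply(sim$effects, as.data.frame))
    raw$sim <- do.call(sim_config, sim)
  }
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] starting", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the whole co-twin analysis pipeline
#'
#' simulate/load -> diabetes-pair exclusion -> intra-pair differencing ->
#' single-CpG matched OLS scan with BH-FDR -> gene-based and gene-set TPM
#' tests.  Writes `pair_differences.tsv`, `single_cpg_results.tsv`,
#' `gene_set_results.tsv`, `significance_counts.tsv`, `manifest.json` and
#' `report.md` under `config$out_dir`.
#'
#' @param config A [run_config()] or path to a YAML/JSON configuration.
#' @return Invisibly, a list with all intermediate tables and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- .stage("input", {
    if (!is.null(config$sim)) generate_twin_cohort(config$sim)
    else list(samples = read_samples(config$samples),
              meth = read_methylation(config$meth),
              annot = read_annotation(config$annot))
  })
  n_pairs_in <- length(unique(cohort$samples$pair_id))

  prepared <- .stage("prepare", {
    kept <- exclude_diabetes_pairs(cohort$samples)
    pd <- compute_pair_differences(kept, cohort$meth, cohort$annot,
                                   covariates = config$covariates,
                                   traits = config$traits)
    list(kept = kept, pd = pd)
  })
  pd <- prepared$pd

  scan <- .stage("scan", run_single_cpg_scan(pd, cohort$annot,
                                             traits = config$traits,
                                             covariates = config$covariates))
  counts <- count_significant(scan, alpha = config$alpha)

  joint <- .stage("geneset", {
    genes <- gene_based_scan(pd, cohort$annot, traits = config$traits,
                             tau = config$tau, weighted = config$weighted,
                             B = config$B, seed = config$seed,
                             covariates = config$covariates)
    path <- gene_set_test(pd, cohort$annot, traits = config$traits,
                          tau = config$tau, weighted = config$weighted,
                          B = config$B, seed = config$seed,
                          covariates = config$covariates)
    rbind(genes, path)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("twinset")),
    seed = config$seed, alpha = config$alpha, tau = config$tau,
    weighted = config$weighted, B = config$B,
    traits = config$traits, covariates = config$covariates,
    n_pairs_in = n_pairs_in,
    n_pairs_retained = nrow(pd),
    n_pairs_excluded = n_pairs_in - nrow(pd),
    n_cpgs = length(attr(pd, "cpg_ids")),
    n_single_cpg_rows = nrow(scan),
    n_gene_rows = sum(joint$unit != "pathway"),
    n_pathway_rows = sum(joint$unit == "pathway"))

  od <- config$out_dir
  .write_full_precision(pd, file.path(od, "pair_differences.tsv"))
  .write_full_precision(scan, file.path(od, "single_cpg_results.tsv"))
  .write_full_precision(joint, file.path(od, "gene_set_results.tsv"))
  .write_full_precision(counts, file.path(od, "significance_counts.tsv"))
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- list(pd = pd, scan = scan, joint = joint, counts = counts,
                  manifest = manifest)
  writeLines(render_report(outputs), file.path(od, "report.md"))
  invisible(outputs)
}

#' Render a markdown summary of a pipeline run
#'
#' @param outputs List from [run_pipeline()] (`scan`, `joint`, `counts`,
#'   `manifest`).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(outputs) {
  m <- outputs$manifest
  lines <- c(
    "# Co-twin methylation analysis report", "",
    sprintf("- pairs analysed: %d (of %d; %d excluded for diabetes)",
            m$n_pairs_retained, m$n_pairs_in, m$n_pairs_excluded),
    sprintf("- CpGs: %d; single-CpG results: %d rows", m$n_cpgs,
            m$n_single_cpg_rows),
    sprintf("- seed %d, alpha %g, tau %g, weighted %s, B %d",
            m$seed, m$alpha, m$tau, m$weighted, m$B), "",
    sprintf("## Significant CpGs (raw p < %g)", m$alpha))
  ct <- outputs$counts
  if (nrow(ct) == 0 || sum(ct$n_significant) == 0) {
    lines <- c(lines, "", "No CpG reached the significance threshold.")
  } else {
    lines <- c(lines, "", sprintf("- %s / %s: %d", ct$trait, ct$gene,
                                  ct$n_significant))
  }
  lines <- c(lines, "", "## Gene-based and gene-set tests", "")
  jt <- outputs$joint
  if (nrow(jt) == 0) {
    lines <- c(lines, "No joint-test results.")
  } else {
    qtxt <- ifelse(is.na(jt$q), "",
                   sprintf(", q = %s", format(jt$q, digits = 4)))
    lines <- c(lines, sprintf("- %s / %s: p = %s%s", jt$unit, jt$trait,
                              format(jt$p, digits = 4), qtxt))
  }
  lines
}

#' Published single-CpG reference results
#'
#' The single-CpG association table (rows with raw p <= 0.1) from the
#' published monozygotic-twin study of circadian promoter methylation and
#' glucose metabolism that this package models: per CpG, its GRCh37
#' coordinate, TSS offset, methylation mean and SD, and the matched-pair
#' regression beta, SE and p for HOMA-IR, fasting glucose and HbA1c.  The
#' published headline counts — at strict p < 0.05, six CpGs for HOMA-IR,
#' eight for fasting glucose, three for HbA1c — are recoverable from these
#' columns with [count_significant()].
#'
#' @param long Return one row per (CpG, trait) with `beta`/`se`/`p`/`q`
#'   columns (scan layout) instead of the wide published layout?
#' @return Data frame of published results.
#' @export
published_single_cpg_results <- function(long = FALSE) {
  path <- system.file("extdata", "published_single_cpg_assoc.tsv",
                      package = "twinset", mustWork = TRUE)
  wide <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  if (!long) return(wide)
  out <- do.call(rbind, lapply(TWINSET_TRAITS, function(tr) {
    data.frame(cpg_id = wide$cpg_id, gene = wide$gene, chrom = wide$chrom,
               pos = wide$pos, tss_offset = wide$tss_offset, trait = tr,
               beta = wide[[paste0("beta_", tr)]],
               se = wide[[paste0("se_", tr)]],
               p = wide[[paste0("p_", tr)]],
               stringsAsFactors = FALSE)
  }))
  # q across the published rows only: the full 77-CpG p set is not published
  out$q <- stats::ave(out$p, out$trait, FUN = bh_fdr)
  rownames(out) <- NULL
  out
}
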