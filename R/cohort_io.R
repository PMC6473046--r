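#' Homeostasis model assessment of insulin resistance (HOMA-IR)
#'
#' Computes the Matthews index from fasting glucose in mg/dL and fasting
#' insulin in uU/mL: glucose is converted to mmol/L (divisor 18.0), then
#' HOMA-IR = glucose_mmol * insulin / 22.5.
#'
#' @param glucose Fasting plasma glucose, mg/dL. Must be positive.
#' @param insulin Fasting plasma insulin, uU/mL. Must be non-negative.
#' @return Dimensionless HOMA-IR index, same length as the inputs.
#' @examples
#' homa_ir(90, 9)   # 2.0
#' homa_ir(126, 12) # 4.666...
#' @export
homa_ir <- function(glucose, insulin) {
  if (length(glucose) != length(insulin))
    stop("glucose and insulin must have equal length")
  bad_g <- !is.na(glucose) & glucose <= 0
  if (any(bad_g))
    stop("non-positive fasting glucose at position(s): ",
         paste(which(bad_g), collapse = ", "))
  bad_i <- !is.na(insulin) & insulin < 0
  if (any(bad_i))
    stop("negative fasting insulin at position(s): ",
         paste(which(bad_i), collapse = ", "))
  (glucose / 18.0) * insulin / 22.5
}

#' Derive HOMA-IR in a sample table
#'
#' Adds (or overwrites) a `homa_ir` column computed from the `glucose` and
#' `insulin` columns.
#'
#' @param samples Sample table with `glucose` (mg/dL) and `insulin` (uU/mL).
#' @return The table with a `homa_ir` column.
#' @export
derive_homa_ir <- function(samples) {
  stopifnot(all(c("glucose", "insulin") %in% names(samples)))
  samples$homa_ir <- homa_ir(samples$glucose, samples$insulin)
  samples
}

# Error if any pair_id does not have exactly two rows with distinct member_id.
.check_complete_pairs <- function(samples) {
  tab <- table(samples$pair_id)
  orphans <- names(tab)[tab != 2L]
  if (length(orphans))
    stop("incomplete twin pair(s) (need exactly 2 members): ",
         paste(orphans, collapse = ", "))
  dup <- vapply(split(samples$member_id, samples$pair_id),
                function(m) anyDuplicated(m) > 0L, logical(1))
  if (any(dup))
    stop("duplicated member_id within pair(s): ",
         paste(names(dup)[dup], collapse = ", "))
  invisible(TRUE)
}

#' Drop twin pairs touched by overt type 2 diabetes
#'
#' A pair is removed when either member carries the diabetes flag, i.e. pairs
#' concordant or discordant for overt diabetes are both excluded (hypoglycemic
#' medication distorts the methylation-glucose relationship).  Incomplete
#' pairs are an error, reported before any filtering.
#'
#' @param samples Sample table with `pair_id`, `member_id` and a logical or
#'   0/1 `diabetes` column.
#' @return The retained complete pairs; a message logs counts removed/kept.
#' @export
exclude_diabetes_pairs <- function(samples) {
  stopifnot(all(c("pair_id", "member_id", "diabetes") %in% names(samples)))
  .check_complete_pairs(samples)
  flagged <- unique(samples$pair_id[as.logical(samples$diabetes)])
  keep <- !(samples$pair_id %in% flagged)
  out <- samples[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("excluded %d diabetes pair(s); %d pair(s) retained",
                  length(flagged), length(unique(out$pair_id))))
  out
}

#' Intra-pair differences for methylation, traits and covariates
#'
#' For every retained pair, computes member1 - member2 (ascending
#' `member_id`) differences of each CpG methylation level, each glucose trait
#' and each covariate.  Age is carried at pair level: it is identical within a
#' monozygotic pair, so its intra-pair difference is identically zero and the
#' shared value is what the models adjust for.  HOMA-IR is derived from
#' glucose and insulin if not already present.
#'
#' @param samples Sample table (exclusion already applied; pairs complete).
#' @param meth Methylation matrix as a data frame: `sample_id` column plus one
#'   percent-methylation column per CpG.
#' @param annot CpG annotation with `cpg_id`, `gene`, `chrom`, `pos`,
#'   `tss_offset`; must match the methylation columns one-to-one.
#' @param covariates Covariate column names to difference.
#' @param traits Trait column names to difference.
#' @return Data frame with one row per pair: `pair_id`, `age`, `d_<trait>`,
#'   `d_<covariate>`, then one column per CpG (named by `cpg_id`) holding the
#'   methylation difference in percentage points.  Attributes `cpg_ids`,
#'   `traits` and `covariates` record the column groups.
#' @export
compute_pair_differences <- function(samples, meth, annot,
                                     covariates = twinset_covariates(),
                                     traits = TWINSET_TRAITS) {
  .check_complete_pairs(samples)
  if (!"homa_ir" %in% names(samples) && "homa_ir" %in% traits)
    samples <- derive_homa_ir(samples)
  missing_tr <- setdiff(traits, names(samples))
  if (length(missing_tr))
    stop("trait column(s) missing from samples: ",
         paste(missing_tr, collapse = ", "))
  missing_cv <- setdiff(covariates, names(samples))
  if (length(missing_cv))
    stop("covariate column(s) missing from samples: ",
         paste(missing_cv, collapse = ", "))

  cpg_cols <- setdiff(names(meth), "sample_id")
  unannotated <- setdiff(cpg_cols, annot$cpg_id)
  if (length(unannotated))
    stop("methylation column(s) without annotation: ",
         paste(unannotated, collapse = ", "))
  cpg_ids <- annot$cpg_id[annot$cpg_id %in% cpg_cols]

  if (!"sample_id" %in% names(samples))
    samples$sample_id <- paste(samples$pair_id, samples$member_id, sep = "_")
  idx <- match(samples$sample_id, meth$sample_id)
  if (anyNA(idx))
    stop("sample(s) absent from methylation matrix: ",
         paste(samples$sample_id[is.na(idx)], collapse = ", "))

  ord <- order(samples$pair_id, samples$member_id)
  samples <- samples[ord, , drop = FALSE]
  m <- as.matrix(meth[idx[ord], cpg_ids, drop = FALSE])

  i1 <- seq(1L, nrow(samples), by = 2L)
  i2 <- i1 + 1L
  age1 <- samples$age[i1]
  if (!isTRUE(all.equal(age1, samples$age[i2])))
    stop("age differs within at least one MZ pair")

  num_diff <- function(col) samples[[col]][i1] - samples[[col]][i2]
  pd <- data.frame(pair_id = samples$pair_id[i1], age = age1,
                   stringsAsFactors = FALSE)
  for (tr in traits) pd[[paste0("d_", tr)]] <- num_diff(tr)
  for (cv in covariates) pd[[paste0("d_", cv)]] <- num_diff(cv)
  dm <- m[i1, , drop = FALSE] - m[i2, , drop = FALSE]
  pd <- cbind(pd, as.data.frame(dm))
  rownames(pd) <- NULL
  attr(pd, "cpg_ids") <- cpg_ids
  attr(pd, "traits") <- traits
  attr(pd, "covariates") <- covariates
  pd
}

#' Per-CpG summary of intra-pair methylation differences
#'
#' @param pd Pair-difference table from [compute_pair_differences()].
#' @param cpg_ids CpG columns to summarize; defaults to the table's own set.
#' @return Data frame with `cpg_id`, `mean_diff` and `sd_diff` (sample SD,
#'   n-1 denominator).
#' @export
summarize_pair_differences <- function(pd, cpg_ids = attr(pd, "cpg_ids")) {
  if (nrow(pd) < 2L) stop("need at least 2 pairs to summarize")
  stopifnot(all(cpg_ids %in% names(pd)))
  data.frame(
    cpg_id = cpg_ids,
    mean_diff = vapply(cpg_ids, function(cc) mean(pd[[cc]]), numeric(1)),
    sd_diff = vapply(cpg_ids, function(cc) stats::sd(pd[[cc]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# ---- delimited-text readers/writers ---------------------------------------
# CSV vs TSV is decided by extension; numbers are written with 17 significant
# digits so a write/read round trip reproduces doubles exactly.

.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

.write_full_precision <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, path, sep = .sep_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname cohort_files
#' @export
write_samples <- function(samples, path) .write_full_precision(samples, path)

#' @rdname cohort_files
#' @export
write_methylation <- function(meth, path) .write_full_precision(meth, path)

#' Cohort file input/output
#'
#' The sample table and methylation matrix are delimited text (comma for
#' `.csv`, tab otherwise) with samples as rows and a header.  The CpG
#' annotation is a 6-column BED-like TSV without header: chrom, pos-1, pos,
#' cpg_id, gene, tss_offset — the interval columns are half-open 0-based for
#' BED compatibility, while `pos` itself stays the 1-based GRCh37 coordinate.
#'
#' @param samples,meth,annot Tables as produced by [generate_twin_cohort()].
#' @param path File path; extension selects the delimiter.
#' @return Readers return a data frame; writers return the path invisibly.
#' @name cohort_files
#' @export
write_annotation <- function(annot, path) {
  bed <- data.frame(chrom = annot$chrom, start = annot$pos - 1L,
                    end = annot$pos, cpg_id = annot$cpg_id,
                    gene = annot$gene, tss_offset = annot$tss_offset)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname cohort_files
#' @export
read_samples <- function(path) {
  df <- utils::read.table(path, sep = .sep_for(path), header = TRUE,
                          stringsAsFactors = FALSE)
  if ("diabetes" %in% names(df)) df$diabetes <- as.logical(df$diabetes)
  df
}

#' @rdname cohort_files
#' @export
read_methylation <- function(path) {
  utils::read.table(path, sep = .sep_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname cohort_files
#' @export
read_annotation <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "cpg_id",
                                         "gene", "tss_offset"))
  if (any(bed$end != bed$start + 1L))
    stop("annotation intervals must be single bases (end == start + 1)")
  if (anyDuplicated(bed$cpg_id))
    stop("duplicated cpg_id in annotation")
  data.frame(cpg_id = bed$cpg_id, gene = bed$gene, chrom = bed$chrom,
             pos = bed$end, tss_offset = bed$tss_offset,
             stringsAsFactors = FALSE)
}

#' @rdname cohort_files
#' @param dir Directory receiving `samples.csv`, `methylation.csv`,
#'   `annotation.bed`.
#' @export
write_cohort <- function(samples, meth, annot, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_samples(samples, file.path(dir, "samples.csv"))
  write_methylation(meth, file.path(dir, "methylation.csv"))
  write_annotation(annot, file.path(dir, "annotation.bed"))
  invisible(dir)
}

#' @rdname cohort_files
#' @export
read_cohort <- function(dir) {
  list(samples = read_samples(file.path(dir, "samples.csv")),
       meth = read_methylation(file.path(dir, "methylation.csv")),
       annot = read_annotation(file.path(dir, "annotation.bed")))
}
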