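#' Demonstration cohort recipe at the modelled study's scale
#'
#' A [sim_config()] reproducing the study conditions end to end: 84 simulated
#' MZ pairs (15 flagged for diabetes, so 69 enter the analysis), 77 CpGs in
#' five circadian genes, and linear effects planted at eleven (trait, CpG)
#' slots whose sizes mirror the published single-CpG effect estimates (see
#' [published_single_cpg_results()]), so that a handful of CpGs per trait sit
#' near the single-test detection boundary while the genes and the pathway
#' carry clearly detectable joint signal.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
demo_sim_config <- function(seed = 42L) {
  effects <- data.frame(
    trait = c(rep("homa_ir", 6),
              rep("glucose", 8),
              rep("hba1c", 3)),
    cpg = c("CLOCK_cg04", "CLOCK_cg05", "CLOCK_cg07", "BMAL1_cg01",
            "BMAL1_cg06", "PER2_cg03",
            "CLOCK_cg03", "CLOCK_cg05", "CLOCK_cg07", "CLOCK_cg08",
            "BMAL1_cg01", "BMAL1_cg09", "PER2_cg03", "PER2_cg04",
            "BMAL1_cg01", "BMAL1_cg03", "PER2_cg04"),
    beta = c(0.204, 0.292, 0.299, 0.530, 0.254, 0.509,
             2.207, 2.863, 3.213, 2.326, 5.586, 1.917, 6.068, 7.025,
             0.228, 0.230, 0.316),
    stringsAsFactors = FALSE)
  sim_config(effects = effects, seed = seed)
}

#' @rdname demo_sim_config
#' @param B Sign-flip replicates for the joint tests.
#' @param out_dir Output directory for [run_pipeline()].
#' @export
demo_run_config <- function(seed = 42L, B = 9999L, out_dir = "twinset_run") {
  run_config(sim = demo_sim_config(seed), B = B, seed = seed,
             out_dir = out_dir)
}
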