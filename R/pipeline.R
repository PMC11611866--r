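#' Pipeline run configuration
#'
#' Bundles every analysis threshold with validation. Defaults reproduce the
#' canonical workflow: instrument-grade eQTL p below 1e-5, clumping at
#' +/-10 Mb with r-squared below 0.001, proxies accepted at r-squared 0.6
#' and up, GRN edges at BH-adjusted p of 0.05 or below, and sensitivity /
#' significance levels of 0.05.
#'
#' @param iv_p instrument eQTL p-value threshold.
#' @param clump_kb,clump_r2 clumping window (kb) and r-squared cutoff.
#' @param proxy_r2,proxy_kb proxy acceptance r-squared and search window (kb).
#' @param grn_alpha BH level for GRN edges.
#' @param q_alpha,egger_alpha heterogeneity / pleiotropy screening levels.
#' @param mr_alpha family-wise significance level for Bonferroni correction.
#' @param palindrome_policy `"infer"` or `"drop"`.
#' @param eaf_band palindromic ambiguity band.
#' @param seed integer seed for any randomized step (e.g. unphased VCF input).
#' @return validated list of class `RunConfig`.
#' @export
runConfig <- function(iv_p = 1e-5, clump_kb = 10000, clump_r2 = 0.001,
                      proxy_r2 = 0.6, proxy_kb = 1000, grn_alpha = 0.05,
                      q_alpha = 0.05, egger_alpha = 0.05, mr_alpha = 0.05,
                      palindrome_policy = "infer",
                      eaf_band = c(0.42, 0.58), seed = 1L) {
  cfg <- list(iv_p = iv_p, clump_kb = clump_kb, clump_r2 = clump_r2,
              proxy_r2 = proxy_r2, proxy_kb = proxy_kb,
              grn_alpha = grn_alpha, q_alpha = q_alpha,
              egger_alpha = egger_alpha, mr_alpha = mr_alpha,
              palindrome_policy = match.arg(palindrome_policy,
                                            c("infer", "drop")),
              eaf_band = eaf_band, seed = as.integer(seed))
  probs <- c(cfg$iv_p, cfg$clump_r2, cfg$proxy_r2, cfg$grn_alpha,
             cfg$q_alpha, cfg$egger_alpha, cfg$mr_alpha)
  stopifnot(all(probs > 0), all(probs < 1), cfg$clump_kb > 0,
            cfg$proxy_kb > 0, length(cfg$eaf_band) == 2,
            cfg$eaf_band[1] < cfg$eaf_band[2])
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full MR workflow for every tissue and outcome
#'
#' For each (tissue GRN, outcome GWAS) pair: select instruments (p
#' threshold, clumping, proxy substitution), harmonize against the outcome,
#' screen multi-instrument exposures with Cochran's Q and the MR-Egger
#' intercept, estimate Wald-ratio / IVW effects and apply per-stratum
#' Bonferroni correction. With three outcomes, the per-outcome significant
#' gene sets (pooled over tissues) are partitioned into Venn regions; with
#' two tissues, per-outcome cross-tissue comparisons are added. Every
#' dropped instrument or exposure appears in the audit tables with a
#' machine-readable reason.
#'
#' @param grns list of [SpatialGrn-class] objects (one per tissue).
#' @param gwas named list of outcome GWAS data.frames ([readGwas()] layout).
#' @param panel A [HaplotypePanel-class].
#' @param config a [runConfig()].
#' @return list with `results` (all estimate rows), `significant`
#'   (significant rows only), `by` (nested per-tissue / per-outcome detail:
#'   `results`, `harmonised`, `instrument_audit`), `comparison` (Venn
#'   partition and/or cross-tissue reports), and `counters` (per-stage
#'   counts: candidates, clumped, proxied, harmonized, dropped, tested,
#'   significant).
#' @export
runPipeline <- function(grns, gwas, panel, config = runConfig()) {
  stopifnot(inherits(config, "RunConfig"), length(grns) >= 1,
            length(gwas) >= 1, !is.null(names(gwas)))
  if (is.null(names(grns)))
    names(grns) <- vapply(grns, grnTissue, character(1))
  by <- list(); all_rows <- list(); counters <- list()
  for (tt in names(grns)) {
    grn <- grns[[tt]]
    by[[tt]] <- list()
    for (oc in names(gwas)) {
      g <- gwas[[oc]]
      sel <- selectInstruments(grn, panel, outcome_snps = g$SNP,
                               p_thresh = config$iv_p,
                               clump_kb = config$clump_kb,
                               clump_r2 = config$clump_r2,
                               proxy_r2 = config$proxy_r2,
                               proxy_kb = config$proxy_kb)
      mr <- mrAnalysis(sel$instruments, g, outcome = oc,
                       palindrome_policy = config$palindrome_policy,
                       eaf_band = config$eaf_band,
                       q_alpha = config$q_alpha,
                       egger_alpha = config$egger_alpha,
                       mr_alpha = config$mr_alpha)
      by[[tt]][[oc]] <- list(results = mr$results,
                             harmonised = mr$harmonised,
                             instrument_audit = sel$audit)
      all_rows[[paste(tt, oc)]] <- mr$results
      counters[[paste(tt, oc)]] <- data.frame(
        tissue = tt, outcome = oc,
        candidates = if (nrow(sel$audit)) sum(sel$audit$n_candidates) else 0L,
        clumped = if (nrow(sel$audit)) sum(sel$audit$n_clumped) else 0L,
        proxied = if (nrow(sel$audit)) sum(sel$audit$n_proxied) else 0L,
        harmonized = sum(mr$harmonised$status != "dropped"),
        dropped_palindromic = sum(mr$harmonised$drop_reason %in%
                                    c("palindromic", "palindromic_ambiguous")),
        tested = sum(mr$results$passed_sensitivity & !is.na(mr$results$p)),
        significant = sum(mr$results$significant))
    }
  }
  results <- do.call(rbind, c(all_rows, make.row.names = FALSE))
  significant <- results[results$significant, , drop = FALSE]

  comparison <- list()
  if (length(gwas) == 3) {
    sets <- lapply(names(gwas), function(oc)
      unique(significant$gene[significant$outcome == oc]))
    names(sets) <- names(gwas)
    tissue_of <- tapply(significant$tissue, significant$gene,
                        function(x) paste(sort(unique(x)), collapse = "+"))
    comparison$venn <- vennPartition(sets, tissue_of = tissue_of)
  }
  if (length(grns) == 2) {
    tn <- names(grns)
    comparison$tissues <- lapply(names(gwas), function(oc) {
      a <- significant[significant$outcome == oc &
                         significant$tissue == tn[1], , drop = FALSE]
      b <- significant[significant$outcome == oc &
                         significant$tissue == tn[2], , drop = FALSE]
      compareTissues(a, b)
    })
    names(comparison$tissues) <- names(gwas)
  }
  list(results = results, significant = significant, by = by,
       comparison = comparison,
       counters = do.call(rbind, c(counters, make.row.names = FALSE)))
}
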