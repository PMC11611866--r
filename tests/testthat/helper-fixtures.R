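# Shared fixtures and independent oracles used across test files.

# a panel built directly from a 0/1 matrix (rows named by variant id)
makePanel <- function(H, chrom = "chr1", pos = NULL, ref = "A", alt = "G") {
  n <- nrow(H)
  if (is.null(pos)) pos <- seq_len(n) * 1000
  snps <- data.frame(snp = rownames(H), chrom = chrom, pos = pos,
                     ref = ref, alt = alt)
  HaplotypePanel(snps, H)
}

# small study conditions for fast end-to-end replicates
smallNullConfig <- function(seed, prop_causal = 0, theta = 0.4,
                            se_scale = 0.05) {
  simulationConfig(n_chromosomes = 1, chrom_length_bp = 2e6, n_snps = 120,
                   n_genes = 12, n_haplotypes = 200,
                   prop_causal_genes = prop_causal,
                   causal_effect_theta = theta,
                   outcome_se_scale = se_scale, ivs_per_gene = 1:2,
                   n_decoy_eqtls = 10, n_decoy_contacts = 10, seed = seed)
}

runSmallPipeline <- function(cfg) {
  s <- simulateStudy(cfg, outcomes = "o1")
  grn <- buildGrn(s$genome, s$contacts, s$eqtl, fragments = s$fragments)
  list(study = s,
       pipeline = runPipeline(list(lung = grn), s$gwas, s$panel, runConfig()))
}

# brute-force clumping oracle: a literal while-loop transcription of the
# greedy definition, with r2 recomputed pairwise from the haplotype rows
clumpOracle <- function(cand, hap, window_bp, r2max) {
  sorted <- cand[order(cand$pval, cand$chrom, cand$pos), , drop = FALSE]
  retained <- character(0)
  active <- sorted$snp
  while (length(active)) {
    idx <- active[1]
    retained <- c(retained, idx)
    i <- match(idx, sorted$snp)
    keep <- vapply(active, function(s) {
      if (s == idx) return(FALSE)
      j <- match(s, sorted$snp)
      if (sorted$chrom[j] != sorted$chrom[i]) return(TRUE)
      if (abs(sorted$pos[j] - sorted$pos[i]) > window_bp) return(TRUE)
      x <- hap[idx, ]; y <- hap[s, ]
      r2 <- if (sd(x) == 0 || sd(y) == 0) 0 else cor(x, y)^2
      r2 < r2max
    }, logical(1))
    active <- active[keep]
  }
  retained
}

# closed-form weighted normal-equations solve for the Egger regression
eggerOracle <- function(bx, by, se) {
  flip <- ifelse(bx < 0, -1, 1)
  x <- bx * flip; y <- by * flip
  w <- 1 / se^2
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2)
  est <- solve(A, c(sum(w * y), sum(w * x * y)))
  r <- y - est[1] - est[2] * x
  k <- length(x)
  s2 <- sum(w * r^2) / (k - 2)
  se_int <- sqrt((s2 * solve(A))[1, 1])
  p <- 2 * stats::pt(-abs(est[1] / se_int), df = k - 2)
  list(intercept = est[1], se = se_int, p = p, slope = est[2])
}

# gene sets reproducing the published three-outcome overlap structure:
# 73/12/2 unique, 21 shared U&C, 2 shared U&A, 1 shared C&A, 5 in all three
publishedVennSets <- function() {
  mk <- function(prefix, n) if (n) paste0(prefix, seq_len(n)) else character()
  uU <- mk("uU", 73); uC <- mk("uC", 12); uA <- mk("uA", 2)
  UC <- mk("UC", 21); UA <- mk("UA", 2); CA <- mk("CA", 1); UCA <- mk("all", 5)
  list(unspecified = c(uU, UC, UA, UCA),
       coa = c(uC, UC, CA, UCA),
       aoa = c(uA, UA, CA, UCA))
}
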