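test_that("genome simulation places the expected restriction sites and is deterministic", {
  cfg <- simulationConfig(n_chromosomes = 1, chrom_length_bp = 1e5,
                          restriction_site_spacing_bp = 4000, n_snps = 50,
                          n_genes = 5, seed = 5)
  gn <- simulateGenome(cfg)
  expect_length(gn$sites$chr1, 25)           # floor(1e5 / 4000) internal sites
  expect_true(all(gn$sites$chr1 > 0 & gn$sites$chr1 < 1e5))
  expect_true(all(diff(gn$sites$chr1) > 0))
  fr <- digestGenome(gn)
  expect_length(fr, 26)                      # n sites -> n + 1 fragments

  # variant positions unique per chromosome, gene spans non-degenerate
  expect_false(anyDuplicated(GenomicRanges::start(gn$snps)) > 0)
  expect_true(all(GenomicRanges::end(gn$genes) > GenomicRanges::start(gn$genes)))

  gn2 <- simulateGenome(cfg)
  expect_identical(gn, gn2)
})

test_that("degenerate genome configs behave as specified", {
  cfg0 <- simulationConfig(n_genes = 0, n_snps = 20, n_chromosomes = 1,
                           chrom_length_bp = 1e5, seed = 2)
  gn <- simulateGenome(cfg0)
  expect_length(gn$genes, 0)
  expect_error(simulationConfig(n_snps = 1000, n_chromosomes = 1,
                                chrom_length_bp = 500),
               "capacity")
})

test_that("haplotype panel LD structure follows the block model", {
  # perfect within-block correlation: all variants in a block are copies
  cfg1 <- simulationConfig(n_chromosomes = 1, chrom_length_bp = 1e5,
                           n_snps = 30, n_genes = 0, ld_block_length_bp = 1e5,
                           within_block_correlation = 1, n_haplotypes = 50,
                           seed = 3)
  gn <- simulateGenome(cfg1)
  p1 <- simulatePanel(cfg1, gn)
  H <- hapMatrix(p1)
  expect_true(all(H %in% c(0L, 1L)))
  for (i in 2:nrow(H)) expect_identical(H[i, ], H[1, ])

  # zero correlation: mean cross-variant r2 is about 1/(n_haplotypes - 1)
  cfg0 <- simulationConfig(n_chromosomes = 1, chrom_length_bp = 1e5,
                           n_snps = 60, n_genes = 0, ld_block_length_bp = 1000,
                           within_block_correlation = 0, n_haplotypes = 1000,
                           seed = 4)
  p0 <- simulatePanel(cfg0, simulateGenome(cfg0))
  C <- cor(t(hapMatrix(p0)))^2
  mean_r2 <- mean(C[upper.tri(C)])
  expect_gt(mean_r2, 0.5 / 999)
  expect_lt(mean_r2, 2 / 999)

  expect_error(simulatePanel(simulationConfig(n_haplotypes = 51, seed = 1),
                             gn),
               "even")
})

test_that("panel round-trips through VCF", {
  cfg <- simulationConfig(n_chromosomes = 2, chrom_length_bp = 1e5,
                          n_snps = 40, n_genes = 0, n_haplotypes = 20, seed = 6)
  gn <- simulateGenome(cfg)
  p <- simulatePanel(cfg, gn)
  f <- tempfile(fileext = ".vcf")
  writePanelVcf(p, f)
  p2 <- readPanelVcf(f)
  expect_identical(unname(hapMatrix(p2)), unname(hapMatrix(p)))
  expect_identical(snpInfo(p2)$snp, snpInfo(p)$snp)
  expect_identical(as.numeric(snpInfo(p2)$pos), as.numeric(snpInfo(p)$pos))
})

test_that("eQTL and contact tables are self-consistent with decoys present", {
  cfg <- simulationConfig(n_chromosomes = 1, chrom_length_bp = 2e6,
                          n_snps = 150, n_genes = 15, n_haplotypes = 100,
                          n_decoy_eqtls = 20, n_decoy_contacts = 20, seed = 8)
  gn <- simulateGenome(cfg)
  tr <- simulateTruth(cfg, gn)
  ec <- simulateEqtlsAndContacts(cfg, gn, tr)

  # every emitted p equals the two-sided normal p of its own beta/se
  expect_equal(ec$eqtl$pval, 2 * pnorm(-abs(ec$eqtl$beta / ec$eqtl$se)),
               tolerance = 1e-12)
  # instrument-grade rows for every true pair
  truth_key <- paste(tr$pairs$snp, tr$pairs$gene)
  eq <- ec$eqtl[ec$eqtl$tissue == cfg$tissues[1], ]
  true_rows <- eq[paste(eq$snp, eq$gene) %in% truth_key, ]
  expect_equal(nrow(true_rows), nrow(tr$pairs))
  expect_true(all(true_rows$pval <= 1e-6))
  # decoy rows exist beyond the true pairs, and decoy contacts beyond the
  # fragment pairs needed by the truth
  expect_gt(nrow(eq), nrow(tr$pairs))
  expect_gt(nrow(ec$contacts), length(unique(truth_key)) * 0)
  # exactly round(prop * n) genes carry a nonzero effect
  expect_equal(sum(tr$genes$theta != 0),
               round(cfg$prop_causal_genes * cfg$n_genes))
})

test_that("outcome GWAS generation is deterministic and frequency-consistent", {
  cfg <- smallNullConfig(seed = 9, prop_causal = 0.25)
  s1 <- simulateStudy(cfg, outcomes = c("a", "b"))
  s2 <- simulateStudy(cfg, outcomes = c("a", "b"))
  expect_identical(s1$gwas, s2$gwas)
  expect_false(identical(s1$gwas$a$beta, s1$gwas$b$beta))

  g <- s1$gwas$a
  expect_equal(g$pval, 2 * pnorm(-abs(g$beta / g$se)), tolerance = 1e-12)
  # effect-allele frequency matches the panel frequency of that allele
  # (palindromic variants excluded: allele identity alone cannot separate a
  # swap from a strand flip there, which is the whole harmonization problem)
  info <- snpInfo(s1$panel); af <- alleleFreq(s1$panel)
  m <- match(g$SNP, info$snp)
  pal <- chartr("ACGT", "TGCA", info$alt[m]) == info$ref[m]
  is_alt <- g$effect_allele == info$alt[m] |
    g$effect_allele == chartr("ACGT", "TGCA", info$alt[m])
  expect_equal(g$eaf[!pal], ifelse(is_alt, af[m], 1 - af[m])[!pal],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noise-free generation recovers theta exactly through the Wald ratio", {
  cfg <- simulationConfig(n_chromosomes = 1, chrom_length_bp = 2e6,
                          n_snps = 100, n_genes = 10, n_haplotypes = 100,
                          prop_causal_genes = 1, causal_effect_theta = 0.4,
                          outcome_se_scale = 1e-30, ivs_per_gene = 1,
                          allele_swap_frac = 0, strand_flip_frac = 0,
                          n_decoy_eqtls = 0, n_decoy_contacts = 0, seed = 10)
  s <- simulateStudy(cfg)
  grn <- buildGrn(s$genome, s$contacts, s$eqtl, fragments = s$fragments)
  e <- grnEdges(grn)
  g <- s$gwas$outcome1
  m <- match(e$snp, g$SNP)
  ratios <- g$beta[m] / e$eqtl_beta
  expect_equal(ratios, rep(0.4, nrow(e)), tolerance = 1e-9)
})
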