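#' @importFrom stats rbinom runif rnorm pnorm
#' @importFrom GenomicRanges GRanges mcols start end findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

complementAlleles <- function(x) chartr("ACGT", "TGCA", x)

isPalindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. The defaults define
#' the reference study conditions used throughout the test suite: a small
#' diploid genome (2 chromosomes of 10 Mb), 1000 variants in 20 kb LD blocks
#' with high within-block correlation, 200 genes of which 10% causally affect
#' the outcome with a log-odds effect of 0.4 per 1-SD expression, and outcome
#' standard errors of 0.05 (roughly a UK-Biobank-scale binary GWAS).
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param n_snps total number of variants (split evenly across chromosomes).
#' @param n_genes total number of genes.
#' @param restriction_site_spacing_bp spacing of the uniform restriction-site
#'   grid; sites sit at `(k - 1/2) * spacing` so all of them are internal.
#' @param ld_block_length_bp length of one LD block; variants within a block
#'   share a latent haplotype signal.
#' @param within_block_correlation target correlation `rho` of variants within
#'   one LD block (expected pairwise r-squared is about `rho^2`); in `[0, 1]`.
#' @param n_haplotypes number of haplotype columns (must be even).
#' @param prop_causal_genes proportion of genes with a nonzero causal effect.
#' @param causal_effect_theta causal effect (log-odds of outcome per 1-SD
#'   change in expression) shared by all causal genes.
#' @param outcome_se_scale standard error of every outcome GWAS effect.
#' @param pleiotropy_sd SD of a balanced horizontal-pleiotropy term added to
#'   instrument SNP outcome effects (0 disables it).
#' @param seed integer seed; all generator outputs are pure functions of
#'   (config, seed).
#' @param tissues tissue labels for the eQTL tables. Effect sizes are shared
#'   across tissues so one outcome model is consistent with every tissue.
#' @param ivs_per_gene integer vector of candidate instrument counts per gene;
#'   one value is sampled per gene.
#' @param n_decoy_eqtls number of eQTL rows without a supporting contact.
#' @param n_decoy_contacts number of contacts between SNP-free fragments.
#' @param allele_swap_frac fraction of GWAS rows written with the allele roles
#'   swapped (beta negated, eaf complemented) to exercise harmonization.
#' @param strand_flip_frac fraction of non-palindromic GWAS rows written on
#'   the opposite strand.
#' @param gwas_missing_frac fraction of panel variants absent from each
#'   outcome GWAS (exercises proxy substitution).
#' @param fragment_jitter_bp uniform jitter applied to restriction sites
#'   (default 0, i.e. a perfectly regular grid).
#' @param sample_size GWAS sample size written to the summary table.
#' @return A validated list of class `SimulationConfig`.
#' @examples
#' cfg <- simulationConfig(n_genes = 10, n_snps = 100, seed = 7)
#' cfg$causal_effect_theta
#' @export
simulationConfig <- function(n_chromosomes = 2L,
                             chrom_length_bp = 1e7,
                             n_snps = 1000L,
                             n_genes = 200L,
                             restriction_site_spacing_bp = 4000,
                             ld_block_length_bp = 2e4,
                             within_block_correlation = 0.9,
                             n_haplotypes = 1000L,
                             prop_causal_genes = 0.1,
                             causal_effect_theta = 0.4,
                             outcome_se_scale = 0.05,
                             pleiotropy_sd = 0,
                             seed = 1L,
                             tissues = "lung",
                             ivs_per_gene = 1:3,
                             n_decoy_eqtls = 50L,
                             n_decoy_contacts = 50L,
                             allele_swap_frac = 0.3,
                             strand_flip_frac = 0.1,
                             gwas_missing_frac = 0,
                             fragment_jitter_bp = 0,
                             sample_size = 400000L) {
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_snps = as.integer(n_snps),
              n_genes = as.integer(n_genes),
              restriction_site_spacing_bp = as.numeric(restriction_site_spacing_bp),
              ld_block_length_bp = as.numeric(ld_block_length_bp),
              within_block_correlation = within_block_correlation,
              n_haplotypes = as.integer(n_haplotypes),
              prop_causal_genes = prop_causal_genes,
              causal_effect_theta = causal_effect_theta,
              outcome_se_scale = outcome_se_scale,
              pleiotropy_sd = pleiotropy_sd,
              seed = as.integer(seed),
              tissues = tissues,
              ivs_per_gene = as.integer(ivs_per_gene),
              n_decoy_eqtls = as.integer(n_decoy_eqtls),
              n_decoy_contacts = as.integer(n_decoy_contacts),
              allele_swap_frac = allele_swap_frac,
              strand_flip_frac = strand_flip_frac,
              gwas_missing_frac = gwas_missing_frac,
              fragment_jitter_bp = fragment_jitter_bp,
              sample_size = as.integer(sample_size))
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length_bp >= 1,
            cfg$n_snps >= 1L, cfg$n_genes >= 0L,
            cfg$restriction_site_spacing_bp > 0, cfg$ld_block_length_bp > 0,
            cfg$within_block_correlation >= 0, cfg$within_block_correlation <= 1,
            cfg$n_haplotypes >= 2L,
            cfg$prop_causal_genes >= 0, cfg$prop_causal_genes <= 1,
            cfg$outcome_se_scale > 0, cfg$pleiotropy_sd >= 0)
  per_chrom <- ceiling(cfg$n_snps / cfg$n_chromosomes)
  if (per_chrom > cfg$chrom_length_bp)
    stop("n_snps exceeds chromosome capacity: ", per_chrom,
         " variants requested for a ", cfg$chrom_length_bp, " bp chromosome")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Simulate a genome annotation
#'
#' Produces chromosome sizes, restriction-site positions, gene spans (with
#' strand and TSS) and variant positions with ref/alt alleles. Restriction
#' sites lie on a uniform grid offset by half a spacing from the chromosome
#' origin, so every one of the `floor(L / spacing)` sites is strictly
#' internal and digestion yields `floor(L / spacing) + 1` fragments.
#'
#' @param config a [simulationConfig()].
#' @return list with `chrom_lengths` (named), `sites` (named list of 0-based
#'   cut offsets per chromosome), `genes` (GRanges with `gene_id`, `tss`),
#'   `snps` (GRanges with `snp`, `ref`, `alt`).
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  chrom_lengths <- setNames(rep(L, length(chroms)), chroms)

  spacing <- config$restriction_site_spacing_bp
  n_sites <- floor(L / spacing)
  base_sites <- floor((seq_len(n_sites) - 0.5) * spacing)
  sites <- lapply(chroms, function(ch) {
    s <- base_sites
    if (config$fragment_jitter_bp > 0) {
      s <- sort(unique(pmax(1, pmin(L - 1, round(
        s + runif(length(s), -config$fragment_jitter_bp,
                  config$fragment_jitter_bp))))))
    }
    s
  })
  names(sites) <- chroms

  # variants: split as evenly as possible across chromosomes, 1-based positions
  idx <- rep(seq_along(chroms), length.out = config$n_snps)
  snp_chrom <- chroms[sort(idx)]
  snp_pos <- unlist(lapply(chroms, function(ch) {
    n <- sum(snp_chrom == ch)
    sort(sample.int(L, n))
  }))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, config$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  snps <- GenomicRanges::GRanges(snp_chrom, IRanges::IRanges(snp_pos, snp_pos),
                                 snp = sprintf("rs%05d", seq_len(config$n_snps)),
                                 ref = ref, alt = unname(alt))

  if (config$n_genes > 0L) {
    g_idx <- rep(seq_along(chroms), length.out = config$n_genes)
    g_chrom <- chroms[sort(g_idx)]
    g_len <- sample(5000:50000, config$n_genes, replace = TRUE)
    g_start <- vapply(g_len, function(l) sample.int(L - l, 1L), numeric(1))
    g_strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    g_end <- g_start + g_len - 1
    tss <- ifelse(g_strand == "+", g_start, g_end)
    genes <- GenomicRanges::GRanges(g_chrom, IRanges::IRanges(g_start, g_end),
                                    strand = g_strand,
                                    gene_id = sprintf("gene%04d", seq_len(config$n_genes)),
                                    tss = tss)
  } else {
    genes <- GenomicRanges::GRanges()
  }
  list(chrom_lengths = chrom_lengths, sites = sites, genes = genes, snps = snps)
}

#' Simulate the causal ground truth
#'
#' Picks `round(prop_causal_genes * n_genes)` causal genes (all sharing the
#' configured effect size) and assigns each gene its true spatial instrument
#' variants: variants within 1 Mb of the TSS, at most one per LD block, and
#' never shared between genes.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()].
#' @return list with `genes` (data.frame `gene`, `theta`), `pairs`
#'   (data.frame `snp`, `gene`) and `snp_is_spatial` (named logical).
#' @export
simulateTruth <- function(config, genome) {
  set.seed(config$seed + 1L)
  gm <- GenomicRanges::mcols(genome$genes)
  gene_ids <- as.character(gm$gene_id)
  n_causal <- round(config$prop_causal_genes * length(gene_ids))
  causal <- if (n_causal > 0) sample(gene_ids, n_causal) else character()
  theta <- setNames(rep(0, length(gene_ids)), gene_ids)
  theta[causal] <- config$causal_effect_theta

  sm <- GenomicRanges::mcols(genome$snps)
  snp_id <- as.character(sm$snp)
  snp_chrom <- as.character(GenomicRanges::seqnames(genome$snps))
  snp_pos <- GenomicRanges::start(genome$snps)
  block <- floor((snp_pos - 1) / config$ld_block_length_bp)
  assigned <- rep(FALSE, length(snp_id))

  pair_snp <- character(); pair_gene <- character()
  g_chrom <- as.character(GenomicRanges::seqnames(genome$genes))
  for (i in seq_along(gene_ids)) {
    k <- if (length(config$ivs_per_gene) == 1L) config$ivs_per_gene else
      sample(config$ivs_per_gene, 1L)
    cand <- which(!assigned & snp_chrom == g_chrom[i] &
                    abs(snp_pos - gm$tss[i]) <= 1e6)
    if (!length(cand)) next
    # at most one instrument per LD block so clumping keeps them all
    cand <- cand[sample.int(length(cand))]
    cand <- cand[!duplicated(block[cand])]
    take <- cand[seq_len(min(k, length(cand)))]
    assigned[take] <- TRUE
    pair_snp <- c(pair_snp, snp_id[take])
    pair_gene <- c(pair_gene, rep(gene_ids[i], length(take)))
  }
  list(genes = data.frame(gene = gene_ids, theta = unname(theta[gene_ids])),
       pairs = data.frame(snp = pair_snp, gene = pair_gene),
       snp_is_spatial = setNames(snp_id %in% pair_snp, snp_id))
}

#' Simulate a phased haplotype panel
#'
#' Haplotypes follow a block-LD model: each LD block has a latent Bernoulli
#' signal per haplotype (block allele frequency drawn uniform on 0.1-0.9) and
#' each variant copies that signal with per-entry flip probability
#' `(1 - sqrt(rho)) / 2`, giving expected within-block pairwise correlation
#' about `rho` (r-squared about `rho^2`). Variants in different blocks are
#' independent.
#'
#' @param config a [simulationConfig()]; `n_haplotypes` must be even.
#' @param genome output of [simulateGenome()].
#' @return A [HaplotypePanel-class].
#' @export
simulatePanel <- function(config, genome) {
  if (config$n_haplotypes %% 2L != 0L)
    stop("n_haplotypes must be even (two haplotypes per individual)")
  set.seed(config$seed + 2L)
  sm <- GenomicRanges::mcols(genome$snps)
  chrom <- as.character(GenomicRanges::seqnames(genome$snps))
  pos <- GenomicRanges::start(genome$snps)
  n_snp <- length(pos); n_hap <- config$n_haplotypes
  block <- paste0(chrom, ":", floor((pos - 1) / config$ld_block_length_bp))
  ublock <- unique(block)
  bfreq <- setNames(runif(length(ublock), 0.1, 0.9), ublock)
  Z <- matrix(rbinom(length(ublock) * n_hap, 1L, rep(bfreq, n_hap)),
              nrow = length(ublock), dimnames = list(ublock, NULL))
  rho <- config$within_block_correlation
  eps <- (1 - sqrt(rho)) / 2
  flips <- matrix(rbinom(n_snp * n_hap, 1L, eps), nrow = n_snp)
  H <- (Z[block, , drop = FALSE] + flips) %% 2L
  snps <- data.frame(snp = as.character(sm$snp), chrom = chrom, pos = pos,
                     ref = as.character(sm$ref), alt = as.character(sm$alt))
  HaplotypePanel(snps, H)
}

#' Simulate eQTL associations and chromatin contacts
#'
#' Every true spatial pair receives (a) a contact between its variant's
#' restriction fragment and the fragment containing the gene's TSS and (b)
#' an instrument-grade eQTL row (|z| drawn uniform on 6-12, so nominal
#' p <= 2e-9). Decoy eQTL rows without any supporting contact and decoy
#' contacts between SNP-free fragments are added; neither can create an edge
#' downstream, so the spatial-GRN stage recovers exactly the true pairs.
#' Effect sizes are shared across tissues.
#'
#' @param config a [simulationConfig()].
#' @param genome output of [simulateGenome()].
#' @param truth output of [simulateTruth()].
#' @return list with `eqtl` (data.frame `snp`, `gene`, `tissue`, `beta`,
#'   `se`, `pval`), `contacts` (data.frame `fid1`, `fid2`), and `fragments`
#'   (GRanges from [digestGenome()]).
#' @export
simulateEqtlsAndContacts <- function(config, genome, truth) {
  set.seed(config$seed + 3L)
  fragments <- digestGenome(genome)
  snp_frag <- assignSnpsToFragments(genome$snps, fragments)
  sm <- GenomicRanges::mcols(genome$snps)
  snp_frag_id <- setNames(snp_frag, as.character(sm$snp))

  gm <- GenomicRanges::mcols(genome$genes)
  gene_ids <- as.character(gm$gene_id)
  tss_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genome$genes),
                                   IRanges::IRanges(gm$tss, gm$tss))
  ov <- GenomicRanges::findOverlaps(tss_gr, fragments)
  tss_frag <- setNames(
    GenomicRanges::mcols(fragments)$fragment_id[S4Vectors::subjectHits(ov)],
    gene_ids[S4Vectors::queryHits(ov)])
  gene_frags <- assignGenesToFragments(genome$genes, fragments)

  pairs <- truth$pairs
  n_true <- nrow(pairs)
  z <- runif(n_true, 6, 12)
  beta <- sample(c(-1, 1), n_true, replace = TRUE) * runif(n_true, 0.3, 0.8)
  se <- abs(beta) / z
  pval <- 2 * pnorm(-z)
  eqtl_core <- data.frame(snp = pairs$snp, gene = pairs$gene,
                          beta = beta, se = se, pval = pval)

  contacts <- unique(data.frame(fid1 = unname(snp_frag_id[pairs$snp]),
                                fid2 = unname(tss_frag[pairs$gene])))
  # random orientation: contact pairs are unordered
  flip <- runif(nrow(contacts)) < 0.5
  tmp <- contacts$fid1[flip]
  contacts$fid1[flip] <- contacts$fid2[flip]
  contacts$fid2[flip] <- tmp
  contact_key <- c(paste(contacts$fid1, contacts$fid2),
                   paste(contacts$fid2, contacts$fid1))

  # decoy eQTLs: random non-true (snp, gene) pairs with no supporting contact
  decoys <- data.frame()
  if (config$n_decoy_eqtls > 0L && length(gene_ids)) {
    d_snp <- sample(as.character(sm$snp), config$n_decoy_eqtls * 2L, replace = TRUE)
    d_gene <- sample(gene_ids, config$n_decoy_eqtls * 2L, replace = TRUE)
    d <- unique(data.frame(snp = d_snp, gene = d_gene))
    d <- d[!paste(d$snp, d$gene) %in% paste(pairs$snp, pairs$gene), , drop = FALSE]
    supported <- mapply(function(s, g) {
      any(paste(snp_frag_id[[s]], gene_frags[[g]]) %in% contact_key)
    }, d$snp, d$gene)
    d <- d[!supported, , drop = FALSE]
    d <- utils::head(d, config$n_decoy_eqtls)
    if (nrow(d)) {
      dz <- runif(nrow(d), 0, 6)
      db <- sample(c(-1, 1), nrow(d), replace = TRUE) * runif(nrow(d), 0.05, 0.4)
      decoys <- data.frame(snp = d$snp, gene = d$gene, beta = db,
                           se = abs(db) / pmax(dz, 1e-3),
                           pval = 2 * pnorm(-dz))
    }
  }
  eqtl_one <- rbind(eqtl_core, decoys)
  eqtl <- do.call(rbind, lapply(config$tissues, function(tt)
    cbind(eqtl_one[1:2], tissue = tt, eqtl_one[-(1:2)])))
  rownames(eqtl) <- NULL

  # decoy contacts: link fragments that harbour no variant at all
  if (config$n_decoy_contacts > 0L) {
    all_fid <- GenomicRanges::mcols(fragments)$fragment_id
    free <- setdiff(all_fid, unname(snp_frag_id))
    n_dc <- min(config$n_decoy_contacts, floor(length(free) / 2))
    if (n_dc > 0) {
      pick <- sample(free, 2L * n_dc)
      contacts <- rbind(contacts,
                        data.frame(fid1 = pick[seq_len(n_dc)],
                                   fid2 = pick[n_dc + seq_len(n_dc)]))
    }
  }
  rownames(contacts) <- NULL
  list(eqtl = eqtl, contacts = contacts, fragments = fragments)
}

#' Simulate outcome GWAS summary statistics
#'
#' For an instrument variant j of gene g the outcome effect is
#' `beta_out = theta_g * beta_exp + eta + eps` with
#' `eta ~ N(0, pleiotropy_sd^2)` and `eps ~ N(0, se^2)`,
#' `se = outcome_se_scale`; all other variants are drawn from the null.
#' Effect-allele frequencies are copied from the panel. A configured fraction
#' of rows is written with allele roles swapped and/or on the opposite strand
#' so that harmonization is exercised end to end, and a fraction of variants
#' can be withheld to exercise proxy search.
#'
#' @param config a [simulationConfig()].
#' @param genome,truth,eqtl,panel upstream simulation outputs; `eqtl` as
#'   returned in [simulateEqtlsAndContacts()]`$eqtl`.
#' @param outcomes character vector of outcome names; one independent GWAS
#'   table is generated per outcome.
#' @return named list of GWAS data.frames with columns `SNP`, `chr`, `pos`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`,
#'   `samplesize`.
#' @export
simulateOutcomeGwas <- function(config, genome, truth, eqtl, panel,
                                outcomes = "outcome1") {
  info <- snpInfo(panel)
  eaf <- unname(alleleFreq(panel))
  first_tissue <- config$tissues[1]
  e1 <- eqtl[eqtl$tissue == first_tissue, ]
  key <- paste(e1$snp, e1$gene)
  tk <- paste(truth$pairs$snp, truth$pairs$gene)
  e_true <- e1[key %in% tk, ]
  theta <- setNames(truth$genes$theta, truth$genes$gene)
  inst_beta <- setNames(e_true$beta * unname(theta[e_true$gene]), e_true$snp)

  out <- lapply(seq_along(outcomes), function(o) {
    set.seed(config$seed + 4L + 101L * o)
    n <- nrow(info)
    se <- rep(config$outcome_se_scale, n)
    mu <- rep(0, n)
    m <- match(info$snp, names(inst_beta))
    hit <- !is.na(m)
    mu[hit] <- unname(inst_beta[m[hit]])
    if (config$pleiotropy_sd > 0)
      mu[hit] <- mu[hit] + rnorm(sum(hit), 0, config$pleiotropy_sd)
    beta <- mu + rnorm(n, 0, se)
    g <- data.frame(SNP = info$snp, chr = info$chrom, pos = info$pos,
                    effect_allele = info$alt, other_allele = info$ref,
                    beta = beta, se = se,
                    pval = 2 * pnorm(-abs(beta / se)),
                    eaf = eaf, samplesize = config$sample_size)
    swap <- runif(n) < config$allele_swap_frac
    g$beta[swap] <- -g$beta[swap]
    g$eaf[swap] <- 1 - g$eaf[swap]
    ea <- g$effect_allele[swap]
    g$effect_allele[swap] <- g$other_allele[swap]
    g$other_allele[swap] <- ea
    pal <- isPalindromic(g$effect_allele, g$other_allele)
    flip <- runif(n) < config$strand_flip_frac & !pal
    g$effect_allele[flip] <- complementAlleles(g$effect_allele[flip])
    g$other_allele[flip] <- complementAlleles(g$other_allele[flip])
    if (config$gwas_missing_frac > 0) {
      keep <- runif(n) >= config$gwas_missing_frac
      g <- g[keep, , drop = FALSE]
    }
    rownames(g) <- NULL
    g
  })
  names(out) <- outcomes
  out
}

#' Simulate a complete study
#'
#' Convenience wrapper running the whole generator: genome, ground truth,
#' haplotype panel, eQTL + contact tables and one GWAS per outcome.
#'
#' @param config a [simulationConfig()].
#' @param outcomes outcome names passed to [simulateOutcomeGwas()].
#' @return list with components `config`, `genome`, `truth`, `panel`,
#'   `fragments`, `contacts`, `eqtl`, `gwas`.
#' @examples
#' study <- simulateStudy(simulationConfig(n_genes = 20, n_snps = 200,
#'                                         n_haplotypes = 100, seed = 3))
#' names(study)
#' @export
simulateStudy <- function(config, outcomes = "outcome1") {
  genome <- simulateGenome(config)
  truth <- simulateTruth(config, genome)
  panel <- simulatePanel(config, genome)
  ec <- simulateEqtlsAndContacts(config, genome, truth)
  gwas <- simulateOutcomeGwas(config, genome, truth, ec$eqtl, panel, outcomes)
  list(config = config, genome = genome, truth = truth, panel = panel,
       fragments = ec$fragments, contacts = ec$contacts, eqtl = ec$eqtl,
       gwas = gwas)
}
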