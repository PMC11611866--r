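#' @importFrom stats p.adjust
NULL

#' Digest one chromosome into restriction fragments
#'
#' Cuts the interval `[0, chrom_length)` at the given 0-based cut offsets.
#' `n` internal sites yield `n + 1` fragments; zero-length fragments (a cut
#' at position 0 or at the chromosome end, or duplicated cuts) are
#' suppressed. Fragments are returned as a 1-based closed GRanges whose
#' `start0`/`end0` metadata carry the 0-based half-open coordinates.
#'
#' @param sites numeric vector of 0-based cut offsets, sorted ascending.
#' @param chrom_length chromosome length in bp.
#' @param chrom chromosome label.
#' @return GRanges of fragments with metadata `frag_ord` (ordinal within the
#'   chromosome), `start0`, `end0`.
#' @examples
#' f <- digest(c(40, 70), 100)
#' GenomicRanges::mcols(f)$start0  # 0 40 70
#' @export
digest <- function(sites, chrom_length, chrom = "chr1") {
  sites <- as.numeric(sites)
  if (is.unsorted(sites, strictly = FALSE))
    stop("restriction sites must be sorted ascending")
  if (length(sites) && (min(sites) < 0 || max(sites) > chrom_length))
    stop("restriction site outside [0, chrom_length]")
  cuts <- unique(c(0, sites, chrom_length))
  s0 <- cuts[-length(cuts)]
  e0 <- cuts[-1]
  keep <- e0 > s0
  s0 <- s0[keep]; e0 <- e0[keep]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0),
                         frag_ord = seq_along(s0), start0 = s0, end0 = e0)
}

#' Digest a whole simulated genome
#'
#' Runs [digest()] on every chromosome and assigns a genome-wide integer
#' `fragment_id`.
#'
#' @param genome output of [simulateGenome()] (or any list with
#'   `chrom_lengths` and `sites` in the same layout).
#' @return GRanges of fragments with `fragment_id`, `frag_ord`, `start0`,
#'   `end0`.
#' @export
digestGenome <- function(genome) {
  frs <- lapply(names(genome$chrom_lengths), function(ch)
    digest(genome$sites[[ch]], genome$chrom_lengths[[ch]], ch))
  out <- suppressWarnings(do.call(c, frs))
  GenomicRanges::mcols(out)$fragment_id <- seq_along(out)
  out
}

#' Assign variants to restriction fragments
#'
#' Each variant position maps to exactly one fragment.
#'
#' @param snps GRanges of width-1 variant positions.
#' @param fragments GRanges from [digestGenome()].
#' @return integer vector of `fragment_id`s, named by variant id when the
#'   `snps` metadata has a `snp` column.
#' @export
assignSnpsToFragments <- function(snps, fragments) {
  ov <- GenomicRanges::findOverlaps(snps, fragments)
  if (length(unique(S4Vectors::queryHits(ov))) != length(snps))
    stop("variant position outside any fragment (outside chromosome bounds?)")
  fid <- GenomicRanges::mcols(fragments)$fragment_id[S4Vectors::subjectHits(ov)]
  nm <- GenomicRanges::mcols(snps)$snp
  if (!is.null(nm)) names(fid) <- as.character(nm)[S4Vectors::queryHits(ov)]
  fid[order(S4Vectors::queryHits(ov))]
}

#' Assign genes to all overlapping fragments
#'
#' A gene maps to every fragment overlapping its transcript span.
#'
#' @param genes GRanges of gene spans with a `gene_id` metadata column.
#' @param fragments GRanges from [digestGenome()].
#' @return named list: gene id -> integer vector of `fragment_id`s.
#' @export
assignGenesToFragments <- function(genes, fragments) {
  ids <- as.character(GenomicRanges::mcols(genes)$gene_id)
  if (!length(ids)) return(setNames(list(), character()))
  ov <- GenomicRanges::findOverlaps(genes, fragments)
  fid <- GenomicRanges::mcols(fragments)$fragment_id[S4Vectors::subjectHits(ov)]
  out <- split(fid, ids[S4Vectors::queryHits(ov)])
  out[ids[ids %in% names(out)]]
}

#' Candidate spatial variant-gene pairs
#'
#' Emits `(snp, gene)` whenever some chromatin contact links the variant's
#' fragment to any fragment of the gene. Contact pairs are unordered; a
#' variant sitting inside one of the gene's own fragments counts only if the
#' self pair `(f, f)` is present in the contact list.
#'
#' @param snp_fragments named integer vector (variant id -> fragment id).
#' @param gene_fragments named list (gene id -> fragment ids).
#' @param contacts data.frame with columns `fid1`, `fid2`.
#' @param known_fragments optional vector of valid fragment ids; contacts
#'   referencing unknown ids raise an error.
#' @return data.frame with columns `snp`, `gene`.
#' @export
spatialPairs <- function(snp_fragments, gene_fragments, contacts,
                         known_fragments = NULL) {
  if (!is.null(known_fragments)) {
    bad <- setdiff(unique(c(contacts$fid1, contacts$fid2)), known_fragments)
    if (length(bad))
      stop("contact references unknown fragment id(s): ",
           paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!nrow(contacts) || !length(gene_fragments) || !length(snp_fragments))
    return(data.frame(snp = character(), gene = character()))
  adj <- rbind(data.frame(a = contacts$fid1, b = contacts$fid2),
               data.frame(a = contacts$fid2, b = contacts$fid1))
  adj <- unique(adj)
  nbr <- split(adj$b, adj$a)
  res_snp <- character(); res_gene <- character()
  for (g in names(gene_fragments)) {
    touching <- unique(unlist(nbr[as.character(gene_fragments[[g]])],
                              use.names = FALSE))
    if (!length(touching)) next
    hit <- names(snp_fragments)[snp_fragments %in% touching]
    if (length(hit)) {
      res_snp <- c(res_snp, hit)
      res_gene <- c(res_gene, rep(g, length(hit)))
    }
  }
  unique(data.frame(snp = res_snp, gene = res_gene))
}

#' Join eQTL evidence and apply chromosome-wise BH correction
#'
#' Candidate pairs lacking an eQTL row are dropped. Benjamini-Hochberg
#' adjustment is applied separately within each (tissue, variant-chromosome)
#' group, and edges are kept when the adjusted p-value is at most `alpha`.
#'
#' @param pairs data.frame `snp`, `gene` from [spatialPairs()].
#' @param eqtl data.frame `snp`, `gene`, `tissue`, `beta`, `se`, `pval`;
#'   duplicate `(snp, gene, tissue)` rows are an error.
#' @param snp_annot data.frame `snp`, `chrom`, `pos` for the variants.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @return data.frame with columns `snp`, `gene`, `tissue`, `eqtl_beta`,
#'   `eqtl_se`, `p_nominal`, `p_adjusted`, `snp_chrom`, `snp_pos`.
#' @export
attachEqtlAndCorrect <- function(pairs, eqtl, snp_annot, alpha = 0.05) {
  if (anyDuplicated(eqtl[c("snp", "gene", "tissue")]))
    stop("duplicate (snp, gene, tissue) rows in eQTL table")
  m <- merge(pairs, eqtl, by = c("snp", "gene"))
  if (!nrow(m))
    return(data.frame(snp = character(), gene = character(),
                      tissue = character(), eqtl_beta = numeric(),
                      eqtl_se = numeric(), p_nominal = numeric(),
                      p_adjusted = numeric(), snp_chrom = character(),
                      snp_pos = numeric()))
  ai <- match(m$snp, snp_annot$snp)
  if (anyNA(ai)) stop("eQTL variant missing from annotation")
  m$snp_chrom <- snp_annot$chrom[ai]
  m$snp_pos <- snp_annot$pos[ai]
  grp <- paste(m$tissue, m$snp_chrom)
  m$p_adjusted <- stats::ave(m$pval, grp,
                             FUN = function(p) p.adjust(p, method = "BH"))
  m <- m[m$p_adjusted <= alpha, , drop = FALSE]
  data.frame(snp = m$snp, gene = m$gene, tissue = m$tissue,
             eqtl_beta = m$beta, eqtl_se = m$se, p_nominal = m$pval,
             p_adjusted = m$p_adjusted, snp_chrom = m$snp_chrom,
             snp_pos = m$snp_pos)
}

#' Classify a regulatory link as cis / trans
#'
#' Same chromosome and variant-to-TSS distance at most 1 Mb (inclusive) is
#' `cis`; same chromosome beyond 1 Mb is `trans_intra`; different
#' chromosomes is `trans_inter`.
#'
#' @param snp_chrom,snp_pos variant chromosome and position (vectors).
#' @param gene_chrom,gene_tss gene chromosome and TSS (vectors).
#' @return data.frame with `regulation_class` and `snp_to_tss_distance`
#'   (`NA` for `trans_inter`).
#' @export
classifyRegulation <- function(snp_chrom, snp_pos, gene_chrom, gene_tss) {
  same <- snp_chrom == gene_chrom
  dist <- ifelse(same, abs(snp_pos - gene_tss), NA_real_)
  cls <- ifelse(!same, "trans_inter",
                ifelse(dist <= 1e6, "cis", "trans_intra"))
  data.frame(regulation_class = cls, snp_to_tss_distance = dist)
}

#' Build a tissue-specific spatially constrained GRN
#'
#' Full construction for one tissue: digest the genome, assign variants and
#' genes to fragments, intersect with the chromatin contacts, join the eQTL
#' table, apply chromosome-wise BH correction and classify each surviving
#' edge as cis / trans.
#'
#' @param genome output of [simulateGenome()] (or equivalent annotation).
#' @param contacts data.frame `fid1`, `fid2` of fragment contacts.
#' @param eqtl eQTL table (`snp`, `gene`, `tissue`, `beta`, `se`, `pval`).
#' @param tissue tissue to build; default the first tissue in `eqtl`.
#' @param alpha BH significance level (default 0.05).
#' @param maf optional named vector of variant minor-allele frequencies; when
#'   supplied, variants with MAF below `maf_min` are removed before pairing.
#' @param maf_min MAF filter threshold (default 0.05).
#' @param fragments optional precomputed [digestGenome()] output.
#' @return A [SpatialGrn-class].
#' @export
buildGrn <- function(genome, contacts, eqtl, tissue = NULL, alpha = 0.05,
                     maf = NULL, maf_min = 0.05, fragments = NULL) {
  if (is.null(tissue)) tissue <- eqtl$tissue[1]
  eqtl <- eqtl[eqtl$tissue == tissue, , drop = FALSE]
  if (is.null(fragments)) fragments <- digestGenome(genome)
  snps <- genome$snps
  if (!is.null(maf)) {
    keep_id <- names(maf)[maf >= maf_min]
    snps <- snps[as.character(GenomicRanges::mcols(snps)$snp) %in% keep_id]
  }
  snp_frag <- assignSnpsToFragments(snps, fragments)
  gene_frags <- assignGenesToFragments(genome$genes, fragments)
  pairs <- spatialPairs(snp_frag, gene_frags, contacts,
                        known_fragments = GenomicRanges::mcols(fragments)$fragment_id)
  sm <- GenomicRanges::mcols(genome$snps)
  snp_annot <- data.frame(snp = as.character(sm$snp),
                          chrom = as.character(GenomicRanges::seqnames(genome$snps)),
                          pos = GenomicRanges::start(genome$snps))
  edges <- attachEqtlAndCorrect(pairs, eqtl, snp_annot, alpha = alpha)
  gm <- GenomicRanges::mcols(genome$genes)
  gi <- match(edges$gene, as.character(gm$gene_id))
  cls <- classifyRegulation(edges$snp_chrom, edges$snp_pos,
                            as.character(GenomicRanges::seqnames(genome$genes))[gi],
                            gm$tss[gi])
  edges <- cbind(edges[c("snp", "gene", "tissue", "eqtl_beta", "eqtl_se",
                         "p_nominal", "p_adjusted")], cls)
  edges <- edges[order(edges$gene, edges$snp), , drop = FALSE]
  rownames(edges) <- NULL
  SpatialGrn(edges, tissue)
}
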