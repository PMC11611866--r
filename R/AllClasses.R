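#' @import methods
#' @importFrom stats setNames
NULL

#' Phased reference haplotype panel
#'
#' Holds a 0/1 haplotype matrix (rows = variants, columns = haplotypes; two
#' columns per diploid individual) together with the per-variant annotation
#' (identifier, chromosome, position, reference and alternate allele). The
#' matrix counts copies of the alternate allele, so the per-variant alternate
#' allele frequency is simply the row mean. The panel is the backbone for all
#' linkage-disequilibrium (r-squared) computations used in clumping and proxy
#' search.
#'
#' @slot snps data.frame with columns `snp`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per variant, unique `snp` ids).
#' @slot haplotypes integer matrix of 0/1 alternate-allele indicators,
#'   `nrow(snps)` rows; row names are the variant ids.
#'
#' @seealso [simulatePanel()], [readPanelVcf()], [panelR2()]
#' @export
setClass("HaplotypePanel",
  representation(snps = "data.frame", haplotypes = "matrix"))

setValidity("HaplotypePanel", function(object) {
  msgs <- character()
  need <- c("snp", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(object@snps)))
    msgs <- c(msgs, paste("snps must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(object@snps$snp))
      msgs <- c(msgs, "duplicated snp ids in panel")
    if (nrow(object@snps) != nrow(object@haplotypes))
      msgs <- c(msgs, "snps and haplotype matrix row counts differ")
  }
  h <- object@haplotypes
  if (length(h)) {
    if (anyNA(h)) msgs <- c(msgs, "haplotype matrix contains missing entries")
    else if (!all(h %in% c(0L, 1L))) msgs <- c(msgs, "haplotypes must be 0/1")
  }
  if (ncol(object@haplotypes) %% 2L != 0L)
    msgs <- c(msgs, "number of haplotype columns must be even (diploid pairing)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param snps data.frame with columns `snp`, `chrom`, `pos`, `ref`, `alt`.
#' @param haplotypes 0/1 matrix, one row per row of `snps`.
#' @return A [HaplotypePanel-class] object.
#' @examples
#' snps <- data.frame(snp = c("rs1", "rs2"), chrom = "chr1", pos = c(100, 200),
#'                    ref = "A", alt = "G")
#' hap <- matrix(c(0L, 1L, 1L, 0L, 0L, 1L, 1L, 0L), nrow = 2)
#' p <- HaplotypePanel(snps, hap)
#' alleleFreq(p)
#' @export
HaplotypePanel <- function(snps, haplotypes) {
  storage.mode(haplotypes) <- "integer"
  rownames(haplotypes) <- snps$snp
  new("HaplotypePanel", snps = as.data.frame(snps), haplotypes = haplotypes)
}

#' @describeIn HaplotypePanel Variant annotation table.
#' @param x,object A `HaplotypePanel`.
#' @export
snpInfo <- function(x) x@snps

#' @describeIn HaplotypePanel The 0/1 haplotype matrix.
#' @export
hapMatrix <- function(x) x@haplotypes

#' @describeIn HaplotypePanel Alternate-allele frequency per variant (row mean).
#' @export
alleleFreq <- function(x) setNames(rowMeans(x@haplotypes), x@snps$snp)

#' @describeIn HaplotypePanel Number of haplotype columns.
#' @export
nHaplotypes <- function(x) ncol(x@haplotypes)

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@snps), "variants x",
      ncol(object@haplotypes), "haplotypes (",
      ncol(object@haplotypes) / 2L, "individuals )\n")
  cat("  chromosomes:", paste(unique(object@snps$chrom), collapse = ", "), "\n")
})

#' Tissue-specific spatially constrained gene regulatory network
#'
#' A set of significant spatial eQTL-gene regulatory links for one tissue.
#' Each edge records a variant whose harbouring restriction fragment
#' physically contacts a fragment of its target gene and whose eQTL
#' association survives chromosome-wise Benjamini-Hochberg correction.
#'
#' @slot edges data.frame with columns `snp`, `gene`, `tissue`, `eqtl_beta`,
#'   `eqtl_se`, `p_nominal`, `p_adjusted`, `regulation_class`
#'   (`cis`, `trans_intra`, or `trans_inter`) and `snp_to_tss_distance`
#'   (`NA` for inter-chromosomal edges).
#' @slot tissue single tissue label.
#'
#' @seealso [buildGrn()], [attachEqtlAndCorrect()]
#' @export
setClass("SpatialGrn",
  representation(edges = "data.frame", tissue = "character"))

setValidity("SpatialGrn", function(object) {
  msgs <- character()
  need <- c("snp", "gene", "tissue", "eqtl_beta", "eqtl_se",
            "p_nominal", "p_adjusted", "regulation_class",
            "snp_to_tss_distance")
  if (!all(need %in% names(object@edges)))
    msgs <- c(msgs, paste("edges must have columns:",
                          paste(setdiff(need, names(object@edges)), collapse = ", ")))
  else if (nrow(object@edges)) {
    e <- object@edges
    if (any(e$p_adjusted + 1e-12 < e$p_nominal))
      msgs <- c(msgs, "p_adjusted must be >= p_nominal")
    if (!all(e$regulation_class %in% c("cis", "trans_intra", "trans_inter")))
      msgs <- c(msgs, "invalid regulation_class")
    if (any(e$eqtl_se <= 0)) msgs <- c(msgs, "eqtl_se must be positive")
    bad <- e$regulation_class == "trans_inter" & !is.na(e$snp_to_tss_distance)
    if (any(bad))
      msgs <- c(msgs, "snp_to_tss_distance must be NA for trans_inter edges")
  }
  if (length(object@tissue) != 1L)
    msgs <- c(msgs, "tissue must be a single label")
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpatialGrn
#'
#' @param edges edge table (see [SpatialGrn-class]).
#' @param tissue tissue label; defaults to the unique tissue in `edges`.
#' @return A [SpatialGrn-class] object.
#' @export
SpatialGrn <- function(edges, tissue = unique(edges$tissue)) {
  if (length(tissue) == 0L) tissue <- NA_character_
  new("SpatialGrn", edges = as.data.frame(edges), tissue = as.character(tissue))
}

#' @describeIn SpatialGrn Edge table.
#' @param x,object A `SpatialGrn`.
#' @export
grnEdges <- function(x) x@edges

#' @describeIn SpatialGrn Tissue label.
#' @export
grnTissue <- function(x) x@tissue

#' @describeIn SpatialGrn Genes with at least one edge.
#' @export
grnGenes <- function(x) unique(x@edges$gene)

setMethod("show", "SpatialGrn", function(object) {
  e <- object@edges
  cat("SpatialGrn [", object@tissue, "]: ", nrow(e), " edges, ",
      length(unique(e$gene)), " genes, ", length(unique(e$snp)),
      " spatial eQTLs\n", sep = "")
  if (nrow(e))
    print(table(factor(e$regulation_class,
                       levels = c("cis", "trans_intra", "trans_inter"))))
})
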