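#' @importFrom utils read.delim write.table head
NULL

writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics
#'
#' Reads a tab-separated summary-statistics table, renaming columns through
#' `column_map` so arbitrary header dialects can be ingested. Alleles are
#' upper-cased; rows with non-finite or non-positive standard errors, or
#' non-finite betas, are dropped with a logged count; duplicated variant ids
#' are an error.
#'
#' @param path TSV file.
#' @param column_map named character vector mapping canonical names
#'   (`SNP`, `effect_allele`, `other_allele`, `beta`, `se`, `pval`, and
#'   optionally `chr`, `pos`, `eaf`, `samplesize`) to the file's headers.
#'   Defaults to the identity mapping.
#' @return data.frame in canonical layout.
#' @export
readGwas <- function(path, column_map = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("SNP", "effect_allele", "other_allele", "beta", "se", "pval")
  optional <- c("chr", "pos", "eaf", "samplesize")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(d))
        stop("column_map names missing column '", src, "' for '", canon, "'")
      names(d)[names(d) == src] <- canon
    }
  }
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("GWAS file lacks required column(s): ", paste(missing, collapse = ", "))
  d <- d[c(required, intersect(optional, names(d)))]
  d$effect_allele <- toupper(d$effect_allele)
  d$other_allele <- toupper(d$other_allele)
  bad <- !is.finite(d$beta) | !is.finite(d$se) | d$se <= 0
  if (any(bad)) {
    message("readGwas: dropping ", sum(bad), " row(s) with invalid beta/se")
    d <- d[!bad, , drop = FALSE]
  }
  if (anyDuplicated(d$SNP))
    stop("duplicated variant id(s) in GWAS file: ",
         paste(head(unique(d$SNP[duplicated(d$SNP)]), 5), collapse = ", "))
  rownames(d) <- NULL
  d
}

#' @rdname readGwas
#' @param gwas canonical GWAS data.frame.
#' @export
writeGwas <- function(gwas, path) writeTsv(gwas, path)

#' Read / write an eQTL association table
#'
#' TSV with columns `snp`, `gene`, `tissue`, `beta`, `se`, `pval`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readEqtlTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp", "gene", "tissue", "beta", "se", "pval")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("eQTL file lacks column(s): ", paste(missing, collapse = ", "))
  d[need]
}

#' @rdname readEqtlTable
#' @param eqtl eQTL data.frame.
#' @export
writeEqtlTable <- function(eqtl, path) writeTsv(eqtl, path)

#' Read / write a fragment-pair contact table
#'
#' Two-column TSV of unordered fragment-id pairs (`fid1`, `fid2`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readContacts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fid1", "fid2") %in% names(d)))
    stop("contact file needs columns fid1, fid2")
  d[c("fid1", "fid2")]
}

#' @rdname readContacts
#' @param contacts data.frame `fid1`, `fid2`.
#' @export
writeContacts <- function(contacts, path) writeTsv(contacts, path)

#' Read / write restriction fragments as BED
#'
#' BED uses 0-based half-open coordinates; the fragment id is stored in the
#' BED name column. Reading restores the 1-based closed GRanges used
#' internally.
#'
#' @param path BED file.
#' @return GRanges with `fragment_id`, `frag_ord`, `start0`, `end0`.
#' @export
readFragmentsBed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(d)[1:4] <- c("chrom", "start0", "end0", "fragment_id")
  ord <- stats::ave(seq_len(nrow(d)), d$chrom, FUN = seq_along)
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start0 + 1, d$end0),
                         frag_ord = ord, start0 = d$start0, end0 = d$end0,
                         fragment_id = as.integer(d$fragment_id))
}

#' @rdname readFragmentsBed
#' @param fragments GRanges from [digestGenome()].
#' @export
writeFragmentsBed <- function(fragments, path) {
  m <- GenomicRanges::mcols(fragments)
  d <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                  start0 = m$start0, end0 = m$end0, name = m$fragment_id)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write a haplotype panel as a phased VCF
#'
#' Minimal VCFv4.2 with GT-only FORMAT; haplotype columns 2i-1 and 2i form
#' sample i, written phased (`0|1`).
#'
#' @param panel A [HaplotypePanel-class].
#' @param path output file.
#' @export
writePanelVcf <- function(panel, path) {
  info <- panel@snps
  H <- panel@haplotypes
  n_ind <- ncol(H) / 2L
  gt <- matrix(paste(H[, seq(1, ncol(H), 2), drop = FALSE],
                     H[, seq(2, ncol(H), 2), drop = FALSE], sep = "|"),
               nrow = nrow(H))
  samples <- sprintf("ind%04d", seq_len(n_ind))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- cbind(info$chrom, info$pos, info$snp, info$ref, info$alt,
                ".", "PASS", ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a haplotype panel from a VCF
#'
#' Accepts phased or unphased GT; unphased heterozygotes are split into two
#' haplotypes in random order using `seed` (logged). Multi-allelic records
#' are skipped with a warning; a missing GT field is an error.
#'
#' @param path VCF file (plain or gzipped).
#' @param seed integer seed used only to randomize unphased heterozygotes.
#' @return A [HaplotypePanel-class].
#' @export
readPanelVcf <- function(path, seed = 1L) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) && ncol(v@gt) < 2)
    stop("VCF has no genotype (GT) data")
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning("skipping ", sum(multi), " multi-allelic record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || anyNA(gt)) stop("missing GT field in VCF")
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  unphased <- grepl("/", gt)
  n_unph_het <- sum(unphased & (gt == "0/1" | gt == "1/0"))
  if (n_unph_het > 0) {
    message("readPanelVcf: randomizing ", n_unph_het,
            " unphased heterozygote(s) with seed ", seed)
  }
  set.seed(seed)
  a1 <- as.integer(substr(gt, 1, 1))
  a2 <- as.integer(substr(gt, 3, 3))
  swap <- unphased & a1 != a2 & matrix(runif(length(gt)) < 0.5, nrow = nrow(gt))
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  H <- matrix(0L, nrow = nrow(gt), ncol = 2L * ncol(gt))
  H[, seq(1, ncol(H), 2)] <- a1
  H[, seq(2, ncol(H), 2)] <- a2
  snps <- data.frame(snp = fix$ID, chrom = fix$CHROM,
                     pos = as.numeric(fix$POS), ref = fix$REF, alt = fix$ALT)
  HaplotypePanel(snps, H)
}

#' Read / write gene-set collections (GMT)
#'
#' Reading delegates to [fgsea::gmtPathways()]; writing emits the standard
#' `name <TAB> description <TAB> gene...` lines.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGmt <- function(path) fgsea::gmtPathways(path)

#' @rdname readGmt
#' @param gene_sets named list of character vectors.
#' @export
writeGmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a spatial GRN table
#'
#' TSV mirroring the published GRN layout: `snp`, `gene`, `tissue`,
#' `eqtl_beta`, `eqtl_se`, `p_nominal`, `p_adjusted`, `regulation_class`,
#' `snp_to_tss_distance`.
#'
#' @param path TSV file.
#' @return A [SpatialGrn-class].
#' @export
readGrnTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  SpatialGrn(d)
}

#' @rdname readGrnTable
#' @param grn A [SpatialGrn-class].
#' @export
writeGrnTable <- function(grn, path) writeTsv(grnEdges(grn), path)

#' Write all simulated study inputs to a directory
#'
#' Serializes every generator output in its on-disk format: one GWAS TSV per
#' outcome, the eQTL TSV, fragments as BED, contacts as TSV, the panel as a
#' phased VCF, and the truth table as TSV.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (o in names(study$gwas)) {
    p <- file.path(dir, paste0("gwas_", o, ".tsv"))
    writeGwas(study$gwas[[o]], p); paths[paste0("gwas_", o)] <- p
  }
  writeEqtlTable(study$eqtl, file.path(dir, "eqtl.tsv"))
  writeContacts(study$contacts, file.path(dir, "contacts.tsv"))
  writeFragmentsBed(study$fragments, file.path(dir, "fragments.bed"))
  writePanelVcf(study$panel, file.path(dir, "panel.vcf"))
  writeTsv(study$truth$genes, file.path(dir, "truth_genes.tsv"))
  writeTsv(study$truth$pairs, file.path(dir, "truth_pairs.tsv"))
  paths <- c(paths, eqtl = file.path(dir, "eqtl.tsv"),
             contacts = file.path(dir, "contacts.tsv"),
             fragments = file.path(dir, "fragments.bed"),
             panel = file.path(dir, "panel.vcf"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             truth_pairs = file.path(dir, "truth_pairs.tsv"))
  invisible(paths)
}
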