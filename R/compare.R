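#' @importFrom stats phyper dist hclust
NULL

#' Cross-tissue comparison of significant causal genes
#'
#' Reports genes significant in both tissues, whether the direction of
#' effect (sign of the causal beta) agrees, and which shared genes are
#' instrumented by at least one identical variant in both tissues.
#'
#' @param results_a,results_b data.frames of significant results with
#'   columns `gene`, `beta`, and optionally `snps` (comma-separated
#'   instrument ids per gene).
#' @return list with `shared_genes`, `n_shared`, `concordant_genes`,
#'   `n_concordant`, `discordant_genes`, `n_discordant`,
#'   `shared_eqtl_genes` (shared genes instrumented by the same variant in
#'   both tissues), and the per-tissue totals.
#' @export
compareTissues <- function(results_a, results_b) {
  shared <- intersect(results_a$gene, results_b$gene)
  ba <- results_a$beta[match(shared, results_a$gene)]
  bb <- results_b$beta[match(shared, results_b$gene)]
  conc <- shared[sign(ba) == sign(bb)]
  disc <- setdiff(shared, conc)
  shared_eqtl <- character()
  if ("snps" %in% names(results_a) && "snps" %in% names(results_b)) {
    sa <- strsplit(results_a$snps[match(shared, results_a$gene)], ",")
    sb <- strsplit(results_b$snps[match(shared, results_b$gene)], ",")
    hit <- mapply(function(x, y) length(intersect(trimws(x), trimws(y))) > 0,
                  sa, sb)
    if (length(shared)) shared_eqtl <- shared[hit]
  }
  list(n_a = length(unique(results_a$gene)),
       n_b = length(unique(results_b$gene)),
       shared_genes = shared, n_shared = length(shared),
       concordant_genes = conc, n_concordant = length(conc),
       discordant_genes = disc, n_discordant = length(disc),
       shared_eqtl_genes = shared_eqtl)
}

#' Three-set Venn partition of significant gene sets
#'
#' Computes the seven disjoint regions of a three-outcome comparison by set
#' algebra. Region counts always sum to the size of the union, and every
#' gene belongs to exactly one region.
#'
#' @param sets named list of exactly three character vectors (gene ids per
#'   outcome).
#' @param tissue_of optional named character vector giving each gene a
#'   tissue-of-origin label carried into the membership table.
#' @return list with `counts` (named integer vector over the seven regions,
#'   names built from the set names), `membership` (data.frame `gene`,
#'   `region`, optional `tissue`), and `union_size`.
#' @examples
#' v <- vennPartition(list(A = c("g1", "g2"), B = c("g2"), C = c("g3")))
#' v$counts
#' @export
vennPartition <- function(sets, tissue_of = NULL) {
  stopifnot(length(sets) == 3L, !is.null(names(sets)))
  nm <- names(sets)
  all_genes <- unique(unlist(sets))
  inA <- all_genes %in% sets[[1]]
  inB <- all_genes %in% sets[[2]]
  inC <- all_genes %in% sets[[3]]
  region <- character(length(all_genes))
  region[inA & !inB & !inC] <- paste0(nm[1], "_only")
  region[!inA & inB & !inC] <- paste0(nm[2], "_only")
  region[!inA & !inB & inC] <- paste0(nm[3], "_only")
  region[inA & inB & !inC] <- paste(nm[1], nm[2], sep = "_")
  region[inA & !inB & inC] <- paste(nm[1], nm[3], sep = "_")
  region[!inA & inB & inC] <- paste(nm[2], nm[3], sep = "_")
  region[inA & inB & inC] <- paste(nm[1], nm[2], nm[3], sep = "_")
  levels <- c(paste0(nm, "_only"),
              paste(nm[1], nm[2], sep = "_"), paste(nm[1], nm[3], sep = "_"),
              paste(nm[2], nm[3], sep = "_"),
              paste(nm[1], nm[2], nm[3], sep = "_"))
  counts <- table(factor(region, levels = levels))
  membership <- data.frame(gene = all_genes, region = region)
  if (!is.null(tissue_of))
    membership$tissue <- unname(tissue_of[all_genes])
  list(counts = setNames(as.integer(counts), levels),
       membership = membership, union_size = length(all_genes))
}

#' Hierarchical clustering of a cell-type effect matrix
#'
#' Clusters rows (variant-gene pairs) and columns (cell types) of an eQTL
#' effect-size matrix. Missing entries are replaced by `fill_missing`
#' (interpreted as "no detected effect") before Euclidean distances and
#' complete-linkage clustering; rows with no observed entry at all are
#' dropped with a warning. Rows and columns are canonically sorted by label
#' first, so the tree is invariant to input order.
#'
#' @param mat numeric matrix with unique row and column labels; `NA` marks
#'   missing effects.
#' @param fill_missing value substituted for missing entries (default 0).
#' @param dist_method,linkage distance and agglomeration method (defaults
#'   `"euclidean"`, `"complete"`).
#' @param drop_all_missing drop rows whose entries are all missing
#'   (default TRUE).
#' @return list with `row_hclust`, `col_hclust` (stats::hclust objects),
#'   `row_order`, `col_order` (labels in dendrogram order), and `matrix`
#'   (the filled, canonically sorted matrix).
#' @export
hclusterEffects <- function(mat, fill_missing = 0, dist_method = "euclidean",
                            linkage = "complete", drop_all_missing = TRUE) {
  stopifnot(is.matrix(mat), nrow(mat) >= 2, ncol(mat) >= 2,
            !is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("row/column labels must be unique")
  all_na <- rowSums(!is.na(mat)) == 0
  if (any(all_na) && drop_all_missing) {
    warning("dropping ", sum(all_na), " all-missing row(s): ",
            paste(utils::head(rownames(mat)[all_na], 5), collapse = ", "))
    mat <- mat[!all_na, , drop = FALSE]
  }
  if (nrow(mat) < 2) stop("fewer than 2 rows left after dropping missing rows")
  mat <- mat[order(rownames(mat)), order(colnames(mat)), drop = FALSE]
  mat[is.na(mat)] <- fill_missing
  rh <- hclust(dist(mat, method = dist_method), method = linkage)
  ch <- hclust(dist(t(mat), method = dist_method), method = linkage)
  list(row_hclust = rh, col_hclust = ch,
       row_order = rownames(mat)[rh$order],
       col_order = colnames(mat)[ch$order],
       matrix = mat)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, computes the hypergeometric upper-tail probability of
#' an overlap with the query at least as large as observed, within the
#' supplied background universe; p-values are Benjamini-Hochberg adjusted
#' across sets and sets with adjusted p at most `alpha` are flagged.
#'
#' @param query character vector of query genes (must lie in `background`;
#'   genes outside it are dropped with a warning).
#' @param gene_sets named list of character vectors; each set is first
#'   intersected with the background.
#' @param background character vector: the tested gene universe (for GRN
#'   results, all genes present in the tissue GRN).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return data.frame with `set`, `set_size`, `overlap`, `p`, `p_adj`,
#'   `significant`, `genes` (comma-separated overlap), sorted by p.
#' @export
oraEnrich <- function(query, gene_sets, background, alpha = 0.05) {
  background <- unique(background)
  query <- unique(query)
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside background dropped")
    query <- intersect(query, background)
  }
  if (!length(query) || !length(gene_sets))
    return(data.frame(set = character(), set_size = integer(),
                      overlap = integer(), p = numeric(), p_adj = numeric(),
                      significant = logical(), genes = character()))
  N <- length(background); k <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    s <- intersect(unique(gene_sets[[nm]]), background)
    ov <- intersect(query, s)
    p <- phyper(length(ov) - 1, length(s), N - length(s), k,
                lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = length(ov), p = p,
               genes = paste(sort(ov), collapse = ","))
  })
  res <- do.call(rbind, rows)
  res$p_adj <- p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj <= alpha
  res <- res[order(res$p, res$set), c("set", "set_size", "overlap", "p",
                                      "p_adj", "significant", "genes")]
  rownames(res) <- NULL
  res
}
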