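#' @importFrom stats cor
NULL

panelRow <- function(panel, snp) {
  i <- match(snp, panel@snps$snp)
  if (is.na(i)) stop("variant not in panel: ", snp)
  panel@haplotypes[i, ]
}

panelCorSigned <- function(panel, snpA, snpB) {
  a <- panelRow(panel, snpA); b <- panelRow(panel, snpB)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("monomorphic variant in r2 computation; returning 0")
    return(0)
  }
  cor(a, b)
}

#' Pairwise r-squared from the haplotype panel
#'
#' Squared Pearson correlation of the two 0/1 haplotype rows. Returns 0 with
#' a warning if either variant is monomorphic in the panel.
#'
#' @param panel A [HaplotypePanel-class].
#' @param snpA,snpB variant ids.
#' @return r-squared in `[0, 1]`.
#' @examples
#' p <- HaplotypePanel(
#'   data.frame(snp = c("a", "b"), chrom = "chr1", pos = c(1, 2),
#'              ref = "A", alt = "G"),
#'   matrix(c(0L, 1L, 0L, 0L, 1L, 1L, 1L, 0L), nrow = 2, byrow = TRUE))
#' panelR2(p, "a", "b")
#' @export
panelR2 <- function(panel, snpA, snpB) {
  panelCorSigned(panel, snpA, snpB)^2
}

#' Greedy LD clumping
#'
#' Canonically sorts the candidates by (p-value, chromosome, position), then
#' repeatedly takes the smallest-p unretired variant as the index, retains
#' it, and retires every other candidate on the same chromosome within
#' `window_kb` kilobases whose panel r-squared with the index is at least
#' `r2_max`. The retained set is the set of index variants, so any two
#' retained variants within the window have r-squared below `r2_max`.
#'
#' @param candidates data.frame with columns `snp`, `chrom`, `pos`, `pval`.
#' @param panel A [HaplotypePanel-class] containing every candidate.
#' @param window_kb clumping window in kb (default 10000, i.e. +/-10 Mb).
#' @param r2_max r-squared threshold (default 0.001).
#' @return the retained rows of `candidates`, in canonical order.
#' @export
clumpVariants <- function(candidates, panel, window_kb = 10000, r2_max = 0.001) {
  if (!nrow(candidates)) return(candidates)
  stopifnot(all(c("snp", "chrom", "pos", "pval") %in% names(candidates)))
  if (any(!is.finite(candidates$pval))) stop("non-finite candidate p-values")
  ord <- order(candidates$pval, candidates$chrom, candidates$pos)
  cand <- candidates[ord, , drop = FALSE]
  i <- match(cand$snp, panel@snps$snp)
  if (anyNA(i)) stop("candidate variant not in panel: ",
                     cand$snp[which(is.na(i))[1]])
  H <- panel@haplotypes[i, , drop = FALSE]
  n <- nrow(cand)
  r2 <- suppressWarnings(cor(t(H)))^2
  mono <- apply(H, 1, function(x) stats::sd(x) == 0)
  if (any(mono)) {
    warning("monomorphic variant(s) in clumping; r2 treated as 0")
    r2[mono, ] <- 0; r2[, mono] <- 0
  }
  r2[is.na(r2)] <- 0
  window_bp <- window_kb * 1000
  state <- rep("open", n)
  for (k in seq_len(n)) {
    if (state[k] != "open") next
    state[k] <- "index"
    near <- state == "open" & cand$chrom == cand$chrom[k] &
      abs(cand$pos - cand$pos[k]) <= window_bp & r2[k, ] >= r2_max
    state[near] <- "retired"
  }
  out <- cand[state == "index", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find a proxy for an instrument missing from the outcome GWAS
#'
#' Among panel variants present in the outcome within `window_kb` of the
#' missing instrument, returns the one maximizing r-squared with it,
#' provided r-squared is at least `r2_min` (ties broken by higher r-squared,
#' then ascending position). The proxy's exposure-side effect is re-looked
#' up from the eQTL table for the proxy variant itself when a row for
#' `(proxy, gene, tissue)` exists; otherwise the original instrument's
#' effect is carried over, with its effect allele mapped to the proxy's
#' alternate allele when the haplotype correlation is positive and to the
#' reference allele when negative.
#'
#' @param missing_iv one-row data.frame (or list) for the missing instrument
#'   with at least `snp`, `beta`, `se`, `pval`; optionally `gene`, `tissue`.
#' @param outcome_snps character vector of variant ids present in the
#'   outcome GWAS.
#' @param panel A [HaplotypePanel-class].
#' @param r2_min minimum acceptable r-squared (default 0.6).
#' @param window_kb proxy search window in kb (default 1000).
#' @param eqtl optional eQTL table used to re-look-up the proxy's own
#'   exposure effect.
#' @return one-row data.frame with `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se`, `pval`, `eaf`, `proxy_of`, `proxy_r2`, or `NULL` when no
#'   variant qualifies (the exposure is then dropped for that outcome).
#' @export
findProxy <- function(missing_iv, outcome_snps, panel, r2_min = 0.6,
                      window_kb = 1000, eqtl = NULL) {
  info <- panel@snps
  mi <- match(missing_iv$snp, info$snp)
  if (is.na(mi)) stop("missing instrument not in panel: ", missing_iv$snp)
  window_bp <- window_kb * 1000
  cand <- which(info$snp %in% outcome_snps & info$snp != missing_iv$snp &
                  info$chrom == info$chrom[mi] &
                  abs(info$pos - info$pos[mi]) <= window_bp)
  if (!length(cand)) return(NULL)
  x <- panel@haplotypes[mi, ]
  if (stats::sd(x) == 0) return(NULL)
  rs <- vapply(cand, function(j) {
    y <- panel@haplotypes[j, ]
    if (stats::sd(y) == 0) 0 else cor(x, y)
  }, numeric(1))
  r2 <- rs^2
  ok <- r2 >= r2_min
  if (!any(ok)) return(NULL)
  o <- order(-r2, info$pos[cand])
  o <- o[ok[o]]
  best <- cand[o[1]]
  r <- rs[o[1]]
  freq <- mean(panel@haplotypes[best, ])
  gene <- if (!is.null(missing_iv$gene)) missing_iv$gene else NA_character_
  tissue <- if (!is.null(missing_iv$tissue)) missing_iv$tissue else NA_character_
  hit <- NULL
  if (!is.null(eqtl) && !is.na(gene)) {
    sel <- eqtl$snp == info$snp[best] & eqtl$gene == gene
    if ("tissue" %in% names(eqtl) && !is.na(tissue))
      sel <- sel & eqtl$tissue == tissue
    if (any(sel)) hit <- eqtl[which(sel)[1], ]
  }
  if (!is.null(hit)) {
    data.frame(snp = info$snp[best], effect_allele = info$alt[best],
               other_allele = info$ref[best], beta = hit$beta, se = hit$se,
               pval = hit$pval, eaf = freq,
               proxy_of = missing_iv$snp, proxy_r2 = r^2)
  } else {
    ea <- if (r >= 0) info$alt[best] else info$ref[best]
    oa <- if (r >= 0) info$ref[best] else info$alt[best]
    data.frame(snp = info$snp[best], effect_allele = ea, other_allele = oa,
               beta = missing_iv$beta, se = missing_iv$se,
               pval = missing_iv$pval,
               eaf = if (r >= 0) freq else 1 - freq,
               proxy_of = missing_iv$snp, proxy_r2 = r^2)
  }
}

#' Select instruments for every exposure gene in a GRN
#'
#' For each gene: keep edges with nominal eQTL p-value below `p_thresh`,
#' clump them against the panel, and (when an outcome variant set is given)
#' substitute proxies for instruments absent from the outcome, dropping
#' instruments with no qualifying proxy. Exposures left without any
#' instrument are dropped and logged.
#'
#' @param grn A [SpatialGrn-class].
#' @param panel A [HaplotypePanel-class].
#' @param outcome_snps optional character vector of outcome GWAS variant ids.
#' @param p_thresh instrument-grade eQTL p-value threshold (default 1e-5).
#' @param clump_kb,clump_r2 clumping window (kb) and r-squared threshold.
#' @param proxy_r2,proxy_kb proxy acceptance r-squared and search window.
#' @return list with `instruments` (data.frame: `gene`, `tissue`, `snp`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval`, `eaf`,
#'   `proxy_of`, `proxy_r2`) and `audit` (per-gene counters with a
#'   machine-readable `status`).
#' @export
selectInstruments <- function(grn, panel, outcome_snps = NULL,
                              p_thresh = 1e-5, clump_kb = 10000,
                              clump_r2 = 0.001, proxy_r2 = 0.6,
                              proxy_kb = 1000) {
  edges <- grnEdges(grn)
  info <- panel@snps
  eaf <- rowMeans(panel@haplotypes)
  strong <- edges[edges$p_nominal < p_thresh, , drop = FALSE]
  out <- list(); audit <- list()
  for (g in unique(strong$gene)) {
    e <- strong[strong$gene == g, , drop = FALSE]
    pi <- match(e$snp, info$snp)
    cand <- data.frame(snp = e$snp, chrom = info$chrom[pi], pos = info$pos[pi],
                       pval = e$p_nominal, beta = e$eqtl_beta, se = e$eqtl_se,
                       effect_allele = info$alt[pi], other_allele = info$ref[pi],
                       eaf = eaf[pi])
    kept <- clumpVariants(cand, panel, window_kb = clump_kb, r2_max = clump_r2)
    n_missing <- 0L; n_proxied <- 0L
    rows <- list()
    for (j in seq_len(nrow(kept))) {
      iv <- kept[j, ]
      if (is.null(outcome_snps) || iv$snp %in% outcome_snps) {
        rows[[length(rows) + 1L]] <-
          data.frame(gene = g, tissue = grnTissue(grn), snp = iv$snp,
                     effect_allele = iv$effect_allele,
                     other_allele = iv$other_allele, beta = iv$beta,
                     se = iv$se, pval = iv$pval, eaf = iv$eaf,
                     proxy_of = NA_character_, proxy_r2 = NA_real_)
      } else {
        n_missing <- n_missing + 1L
        eq <- edges[c("snp", "gene", "tissue")]
        eq$beta <- edges$eqtl_beta; eq$se <- edges$eqtl_se
        eq$pval <- edges$p_nominal
        px <- findProxy(list(snp = iv$snp, beta = iv$beta, se = iv$se,
                             pval = iv$pval, gene = g,
                             tissue = grnTissue(grn)),
                        outcome_snps, panel, r2_min = proxy_r2,
                        window_kb = proxy_kb, eqtl = eq)
        if (!is.null(px)) {
          n_proxied <- n_proxied + 1L
          rows[[length(rows) + 1L]] <-
            data.frame(gene = g, tissue = grnTissue(grn), snp = px$snp,
                       effect_allele = px$effect_allele,
                       other_allele = px$other_allele, beta = px$beta,
                       se = px$se, pval = px$pval, eaf = px$eaf,
                       proxy_of = px$proxy_of, proxy_r2 = px$proxy_r2)
        }
      }
    }
    ivs <- if (length(rows)) do.call(rbind, rows) else NULL
    audit[[g]] <- data.frame(gene = g, n_candidates = nrow(e),
                             n_clumped = nrow(kept), n_missing = n_missing,
                             n_proxied = n_proxied,
                             n_iv = if (is.null(ivs)) 0L else nrow(ivs),
                             status = if (is.null(ivs))
                               "dropped_no_instrument" else "kept")
    if (!is.null(ivs)) out[[g]] <- ivs
  }
  instruments <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(), tissue = character(), snp = character(),
               effect_allele = character(), other_allele = character(),
               beta = numeric(), se = numeric(), pval = numeric(),
               eaf = numeric(), proxy_of = character(), proxy_r2 = numeric())
  rownames(instruments) <- NULL
  list(instruments = instruments,
       audit = if (length(audit)) do.call(rbind, c(audit, make.row.names = FALSE))
               else data.frame())
}
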