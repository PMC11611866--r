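#' Harmonize exposure and outcome summary statistics
#'
#' Aligns every outcome record to its exposure record's effect allele.
#' Identical alleles pass unchanged; swapped alleles negate the outcome beta
#' and complement the outcome effect-allele frequency; a complement-strand
#' match is recoded and re-matched. Palindromic variants (allele pair A/T or
#' C/G) are handled by `palindrome_policy`: `"infer"` keeps the pair when
#' both effect-allele frequencies fall outside the ambiguity band and aligns
#' orientation by frequency (flipping when the two frequencies disagree
#' about the minor allele), otherwise drops it; `"drop"` always drops
#' palindromes. Irreconcilable alleles are dropped with reason
#' `incompatible_alleles`. Exposure rows with no outcome record are dropped
#' with reason `missing_outcome`.
#'
#' @param exposure data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `eaf` (plus any carry-along
#'   columns such as `gene`, `tissue`, `pval`, `proxy_of`).
#' @param outcome data.frame with columns `SNP`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `eaf` (the layout written
#'   by [readGwas()]).
#' @param palindrome_policy `"infer"` (default) or `"drop"`.
#' @param eaf_band ambiguity band for frequency inference
#'   (default `c(0.42, 0.58)`).
#' @return data.frame with the exposure columns plus `beta_outcome`,
#'   `se_outcome`, `eaf_outcome`, `status` (one of `unchanged`, `swapped`,
#'   `strand_flipped`, `palindromic_kept`, `dropped`) and `drop_reason`.
#'   Dropped rows are retained in the audit output but must be excluded
#'   from estimation (`status != "dropped"`).
#' @examples
#' exp <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
#'                   beta = 0.3, se = 0.05, eaf = 0.3)
#' out <- data.frame(SNP = "rs1", effect_allele = "G", other_allele = "A",
#'                   beta = 0.2, se = 0.04, eaf = 0.7)
#' harmoniseVariants(exp, out)[, c("status", "beta_outcome", "eaf_outcome")]
#' @export
harmoniseVariants <- function(exposure, outcome, palindrome_policy = "infer",
                              eaf_band = c(0.42, 0.58)) {
  palindrome_policy <- match.arg(palindrome_policy, c("infer", "drop"))
  if (!"eaf" %in% names(exposure)) exposure$eaf <- NA_real_
  if (!"eaf" %in% names(outcome)) outcome$eaf <- NA_real_
  oi <- match(exposure$snp, outcome$SNP)
  n <- nrow(exposure)
  res <- exposure
  names(res)[names(res) == "beta"] <- "beta_exposure"
  names(res)[names(res) == "se"] <- "se_exposure"
  names(res)[names(res) == "eaf"] <- "eaf_exposure"
  res$beta_outcome <- NA_real_
  res$se_outcome <- NA_real_
  res$eaf_outcome <- NA_real_
  res$status <- "dropped"
  res$drop_reason <- NA_character_

  for (i in seq_len(n)) {
    j <- oi[i]
    if (is.na(j)) { res$drop_reason[i] <- "missing_outcome"; next }
    ea_x <- toupper(exposure$effect_allele[i])
    oa_x <- toupper(exposure$other_allele[i])
    ea_y <- toupper(outcome$effect_allele[j])
    oa_y <- toupper(outcome$other_allele[j])
    b_y <- outcome$beta[j]; s_y <- outcome$se[j]; f_y <- outcome$eaf[j]
    f_x <- exposure$eaf[i]
    pal <- isPalindromic(ea_x, oa_x)

    if (pal) {
      set_match <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x)
      if (!set_match) { res$drop_reason[i] <- "incompatible_alleles"; next }
      if (palindrome_policy == "drop") {
        res$drop_reason[i] <- "palindromic"; next
      }
      # a swapped palindromic record is indistinguishable from a strand flip:
      # fold the reported orientation into the frequency and infer from it
      if (ea_y == oa_x) { b_y <- -b_y; f_y <- if (is.na(f_y)) NA else 1 - f_y }
      if (is.na(f_x) || is.na(f_y) ||
          (f_x >= eaf_band[1] && f_x <= eaf_band[2]) ||
          (f_y >= eaf_band[1] && f_y <= eaf_band[2])) {
        res$drop_reason[i] <- "palindromic_ambiguous"; next
      }
      if ((f_x < 0.5) != (f_y < 0.5)) { b_y <- -b_y; f_y <- 1 - f_y }
      res$status[i] <- "palindromic_kept"
      res$beta_outcome[i] <- b_y
      res$se_outcome[i] <- s_y
      res$eaf_outcome[i] <- f_y
      next
    }

    status <- NULL
    if (ea_y == ea_x && oa_y == oa_x) {
      status <- "unchanged"
    } else if (ea_y == oa_x && oa_y == ea_x) {
      status <- "swapped"
      b_y <- -b_y; f_y <- if (is.na(f_y)) NA else 1 - f_y
    } else {
      cea <- complementAlleles(ea_y); coa <- complementAlleles(oa_y)
      if (cea == ea_x && coa == oa_x) {
        status <- "strand_flipped"
      } else if (cea == oa_x && coa == ea_x) {
        status <- "swapped"
        b_y <- -b_y; f_y <- if (is.na(f_y)) NA else 1 - f_y
      }
    }
    if (is.null(status)) { res$drop_reason[i] <- "incompatible_alleles"; next }
    res$status[i] <- status
    res$beta_outcome[i] <- b_y
    res$se_outcome[i] <- s_y
    res$eaf_outcome[i] <- f_y
  }
  rownames(res) <- NULL
  res
}
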