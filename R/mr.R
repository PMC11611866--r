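#' @importFrom stats pchisq pnorm lm coef
NULL

Z95 <- 1.96  # 95% CI multiplier, used consistently with the reported CIs

orCi <- function(beta, se) {
  list(odds_ratio = exp(beta), ci_low = exp(beta - Z95 * se),
       ci_high = exp(beta + Z95 * se))
}

#' Wald ratio estimate for a single-instrument exposure
#'
#' Causal log-odds per 1-SD expression: `beta = beta_GY / beta_GX` with
#' first-order delta-method standard error `se = se_GY / |beta_GX|` (the
#' exposure-side uncertainty is ignored by default) and a two-sided normal
#' p-value. Setting `second_order = TRUE` adds the exposure-side variance
#' term to the delta expansion.
#'
#' @param h one-row harmonized data.frame with `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`.
#' @param second_order use the second-order delta-method SE.
#' @return list with `beta`, `se`, `p`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `n_iv = 1`, or `NULL` (with a warning) when `beta_exposure` is 0.
#' @examples
#' h <- data.frame(beta_exposure = 0.5, se_exposure = 0.05,
#'                 beta_outcome = 0.25, se_outcome = 0.10)
#' waldRatio(h)$beta  # 0.5
#' @export
waldRatio <- function(h, second_order = FALSE) {
  bx <- h$beta_exposure; by <- h$beta_outcome
  if (bx == 0) {
    warning("exposure effect is 0; Wald ratio undefined, exposure skipped")
    return(NULL)
  }
  beta <- by / bx
  se <- if (second_order)
    sqrt(h$se_outcome^2 / bx^2 + by^2 * h$se_exposure^2 / bx^4)
  else h$se_outcome / abs(bx)
  p <- 2 * pnorm(-abs(beta / se))
  c(list(beta = beta, se = se, p = p, n_iv = 1L), orCi(beta, se))
}

#' Cochran's Q heterogeneity statistic
#'
#' Per-instrument Wald ratios `r_j = beta_GYj / beta_GXj` with standard
#' errors `s_j = se_GYj / |beta_GXj|` are combined into
#' `Q = sum((r_j - r_ivw)^2 / s_j^2)` around the inverse-variance-weighted
#' mean ratio; the p-value comes from a chi-square with `k - 1` degrees of
#' freedom. Instruments with zero exposure effect are excluded with a
#' warning.
#'
#' @param h harmonized data.frame with at least 2 usable instruments.
#' @return list with `Q`, `Q_p`, `df`.
#' @export
cochranQ <- function(h) {
  ok <- h$beta_exposure != 0
  if (any(!ok)) warning(sum(!ok), " instrument(s) with zero exposure effect excluded")
  h <- h[ok, , drop = FALSE]
  k <- nrow(h)
  if (k < 2) stop("Cochran's Q needs at least 2 instruments")
  r <- h$beta_outcome / h$beta_exposure
  s <- h$se_outcome / abs(h$beta_exposure)
  w <- 1 / s^2
  rbar <- sum(w * r) / sum(w)
  Q <- sum(w * (r - rbar)^2)
  list(Q = Q, Q_p = pchisq(Q, df = k - 1, lower.tail = FALSE), df = k - 1)
}

#' Inverse-variance-weighted estimate for a multi-instrument exposure
#'
#' Zero-intercept weighted regression of outcome on exposure effects:
#' `beta = sum(w b_GX b_GY) / sum(w b_GX^2)` with `w = 1/se_GY^2`. The fixed
#' SE is `(sum(w b_GX^2))^(-1/2)`; the default multiplicative
#' random-effects SE inflates it by `max(1, sqrt(Q / (k - 1)))`.
#'
#' @param h harmonized data.frame with at least 2 instruments.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return list with `beta`, `se`, `p`, `n_iv`, `Q`, `Q_p`, `odds_ratio`,
#'   `ci_low`, `ci_high`.
#' @export
ivwEstimate <- function(h, mode = c("multiplicative_random", "fixed")) {
  mode <- match.arg(mode)
  k <- nrow(h)
  if (k < 2)
    stop("IVW needs at least 2 instruments; use waldRatio() for a single one")
  w <- 1 / h$se_outcome^2
  bx <- h$beta_exposure; by <- h$beta_outcome
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se <- 1 / sqrt(sum(w * bx^2))
  q <- cochranQ(h)
  if (mode == "multiplicative_random")
    se <- se * max(1, sqrt(q$Q / (k - 1)))
  p <- 2 * pnorm(-abs(beta / se))
  c(list(beta = beta, se = se, p = p, n_iv = k, Q = q$Q, Q_p = q$Q_p),
    orCi(beta, se))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Instruments are oriented so every exposure effect is non-negative (both
#' betas negated where needed), then outcome effects are regressed on
#' exposure effects with an intercept, weighted by `1/se_GY^2`. The
#' intercept p-value uses a t distribution with `k - 2` degrees of freedom.
#' Needs at least 3 instruments; returns `NULL` otherwise (sensitivity
#' screening then falls back to Cochran's Q alone).
#'
#' @param h harmonized data.frame.
#' @return list with `intercept`, `se`, `p`, `slope`, or `NULL` when
#'   `nrow(h) < 3`.
#' @export
eggerIntercept <- function(h) {
  k <- nrow(h)
  if (k < 3) return(NULL)
  flip <- sign(h$beta_exposure)
  flip[flip == 0] <- 1
  bx <- h$beta_exposure * flip
  by <- h$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / h$se_outcome^2)
  sm <- summary(fit)$coefficients
  list(intercept = unname(sm[1, 1]), se = unname(sm[1, 2]),
       p = unname(sm[1, 4]), slope = unname(sm[2, 1]))
}

#' Estimate one exposure's causal effect with sensitivity screening
#'
#' Single-instrument exposures use the Wald ratio. Multi-instrument
#' exposures are first screened: Cochran's Q p-value below `q_alpha` or
#' (when computable, i.e. 3+ instruments) an MR-Egger intercept p-value
#' below `egger_alpha` fails the exposure; survivors are estimated by IVW.
#' Failed exposures are returned with `passed_sensitivity = FALSE` and no
#' estimate, so they can be audited but are excluded from multiple-testing
#' denominators.
#'
#' @param h harmonized rows for one exposure (`status != "dropped"` rows of
#'   [harmoniseVariants()]).
#' @param gene,tissue,outcome identifiers copied to the result row.
#' @param q_alpha,egger_alpha sensitivity thresholds (defaults 0.05).
#' @param ivw_mode passed to [ivwEstimate()].
#' @return one-row data.frame (see [bonferroniFilter()] for the significance
#'   columns added later), or `NULL` when no instrument is usable.
#' @export
mrEstimate <- function(h, gene = NA, tissue = NA, outcome = NA,
                       q_alpha = 0.05, egger_alpha = 0.05,
                       ivw_mode = "multiplicative_random") {
  h <- h[h$status != "dropped" & h$beta_exposure != 0, , drop = FALSE]
  k <- nrow(h)
  if (k == 0) return(NULL)
  row <- data.frame(gene = gene, tissue = tissue, outcome = outcome,
                    method = NA_character_, n_iv = k, beta = NA_real_,
                    se = NA_real_, p = NA_real_, odds_ratio = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_, Q = NA_real_,
                    Q_p = NA_real_, egger_intercept_p = NA_real_,
                    passed_sensitivity = TRUE)
  if (k == 1) {
    est <- waldRatio(h)
    if (is.null(est)) return(NULL)
    row$method <- "wald_ratio"
  } else {
    q <- cochranQ(h)
    row$Q <- q$Q; row$Q_p <- q$Q_p
    eg <- eggerIntercept(h)
    if (!is.null(eg)) row$egger_intercept_p <- eg$p
    if (q$Q_p < q_alpha ||
        (!is.null(eg) && eg$p < egger_alpha)) {
      row$method <- "ivw"
      row$passed_sensitivity <- FALSE
      return(row)
    }
    est <- ivwEstimate(h, mode = ivw_mode)
    row$method <- "ivw"
  }
  row$beta <- est$beta; row$se <- est$se; row$p <- est$p
  row$odds_ratio <- est$odds_ratio
  row$ci_low <- est$ci_low; row$ci_high <- est$ci_high
  row
}

#' Bonferroni thresholds and significance flags
#'
#' Within each (tissue, outcome, method) group of sensitivity-passing
#' results, the threshold is `alpha / n_exposures_in_group` (the
#' single-instrument Wald stratum and the multi-instrument IVW stratum are
#' corrected separately); a result is significant when `p < threshold`.
#' Results that failed sensitivity screening get no threshold and are never
#' significant, and do not count in any denominator.
#'
#' @param results data.frame of [mrEstimate()] rows.
#' @param alpha family-wise level (default 0.05).
#' @return `results` with `bonferroni_threshold` and `significant` columns.
#' @export
bonferroniFilter <- function(results, alpha = 0.05) {
  if (!nrow(results)) {
    results$bonferroni_threshold <- numeric()
    results$significant <- logical()
    return(results)
  }
  results$bonferroni_threshold <- NA_real_
  results$significant <- FALSE
  ok <- results$passed_sensitivity & !is.na(results$p)
  grp <- paste(results$tissue, results$outcome, results$method)
  for (g in unique(grp[ok])) {
    sel <- ok & grp == g
    thr <- alpha / sum(sel)
    results$bonferroni_threshold[sel] <- thr
    results$significant[sel] <- results$p[sel] < thr
  }
  results
}

#' Run MR for every exposure against one outcome GWAS
#'
#' Harmonizes each exposure's instruments with the outcome records, applies
#' the sensitivity gate, estimates Wald-ratio / IVW effects and attaches
#' Bonferroni significance flags per stratum.
#'
#' @param instruments instrument table from [selectInstruments()].
#' @param gwas outcome GWAS data.frame ([readGwas()] layout).
#' @param outcome outcome label for the result rows.
#' @param palindrome_policy,eaf_band passed to [harmoniseVariants()].
#' @param q_alpha,egger_alpha,mr_alpha sensitivity and significance levels.
#' @param ivw_mode passed to [ivwEstimate()].
#' @return list with `results` (estimates with significance flags),
#'   `harmonised` (the full harmonization audit including dropped rows).
#' @export
mrAnalysis <- function(instruments, gwas, outcome = "outcome",
                       palindrome_policy = "infer",
                       eaf_band = c(0.42, 0.58),
                       q_alpha = 0.05, egger_alpha = 0.05, mr_alpha = 0.05,
                       ivw_mode = "multiplicative_random") {
  harmonised <- harmoniseVariants(instruments, gwas,
                                  palindrome_policy = palindrome_policy,
                                  eaf_band = eaf_band)
  rows <- list()
  for (g in unique(harmonised$gene)) {
    hg <- harmonised[harmonised$gene == g, , drop = FALSE]
    r <- mrEstimate(hg, gene = g, tissue = hg$tissue[1], outcome = outcome,
                    q_alpha = q_alpha, egger_alpha = egger_alpha,
                    ivw_mode = ivw_mode)
    if (!is.null(r)) rows[[g]] <- r
  }
  results <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
    else data.frame(gene = character(), tissue = character(),
                    outcome = character(), method = character(),
                    n_iv = integer(), beta = numeric(), se = numeric(),
                    p = numeric(), odds_ratio = numeric(),
                    ci_low = numeric(), ci_high = numeric(), Q = numeric(),
                    Q_p = numeric(), egger_intercept_p = numeric(),
                    passed_sensitivity = logical())
  results <- bonferroniFilter(results, alpha = mr_alpha)
  list(results = results, harmonised = harmonised)
}
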