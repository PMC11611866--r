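hrow <- function(bx, by, sx = 0.05, sy = 0.05) {
  data.frame(beta_exposure = bx, se_exposure = sx, beta_outcome = by,
             se_outcome = sy, status = "unchanged")
}

test_that("Wald ratio follows the delta-method formula", {
  w <- waldRatio(hrow(0.5, 0.25, sx = 0.05, sy = 0.10))
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$p, 2 * pnorm(-2.5))          # ~0.0124

  expect_equal(waldRatio(hrow(0.5, 0))$beta, 0)
  expect_equal(waldRatio(hrow(0.5, 0))$odds_ratio, 1)
  expect_equal(waldRatio(hrow(-0.5, 0.25))$beta, -0.5)
  expect_warning(expect_null(waldRatio(hrow(0, 0.25))), "skipped")

  # second-order delta method adds the exposure-side variance
  w2 <- waldRatio(hrow(0.5, 0.25, sx = 0.05, sy = 0.10), second_order = TRUE)
  expect_equal(w2$se, sqrt(0.10^2 / 0.25 + 0.25^2 * 0.05^2 / 0.5^4))
  expect_gt(w2$se, w$se)
})

test_that("IVW equals weighted least squares through the origin", {
  h <- rbind(hrow(0.2, 0.08), hrow(0.4, 0.18), hrow(0.5, 0.21))
  est <- ivwEstimate(h, mode = "fixed")
  # independent route: weighted zero-intercept regression
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = h,
            weights = 1 / h$se_outcome^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(sum(h$beta_exposure^2 / h$se_outcome^2)),
               tolerance = 1e-12)

  # two identical instruments degenerate to the single-IV Wald ratio
  h2 <- rbind(hrow(0.5, 0.25), hrow(0.5, 0.25))
  expect_equal(ivwEstimate(h2)$beta, waldRatio(hrow(0.5, 0.25))$beta)

  # noise-free identity: all ratios equal theta
  h3 <- rbind(hrow(0.2, 0.2 * 0.4), hrow(0.4, 0.4 * 0.4), hrow(0.5, 0.5 * 0.4))
  e3 <- ivwEstimate(h3)
  expect_equal(e3$beta, 0.4, tolerance = 1e-12)
  expect_equal(e3$Q, 0, tolerance = 1e-12)

  # multiplicative random effects never shrinks the fixed SE
  set.seed(9)
  h4 <- rbind(hrow(0.2, rnorm(1, 0.08, 0.1)), hrow(0.4, rnorm(1, 0.16, 0.1)),
              hrow(0.5, rnorm(1, 0.2, 0.1)))
  expect_gte(ivwEstimate(h4, "multiplicative_random")$se,
             ivwEstimate(h4, "fixed")$se)

  expect_error(ivwEstimate(hrow(0.5, 0.25)), "waldRatio")
})

test_that("Cochran's Q matches the hand-computed two-instrument case", {
  q0 <- cochranQ(rbind(hrow(0.2, 0.2 * 0.3), hrow(0.4, 0.4 * 0.3)))
  expect_equal(q0$Q, 0, tolerance = 1e-12)
  expect_equal(q0$Q_p, 1)

  # ratios (0.1, 0.3) with ratio SEs (0.1, 0.1): weighted mean 0.2, Q = 2
  h <- rbind(hrow(1, 0.1, sy = 0.1), hrow(1, 0.3, sy = 0.1))
  q <- cochranQ(h)
  expect_equal(q$Q, 2)
  expect_equal(q$Q_p, pchisq(2, 1, lower.tail = FALSE))  # ~0.157

  expect_warning(cochranQ(rbind(hrow(0, 0.1), hrow(1, 0.1), hrow(1, 0.2))),
                 "zero exposure")
})

test_that("Cochran's Q rejects at its nominal rate under homogeneity", {
  set.seed(314)
  reject <- vapply(seq_len(2000), function(i) {
    k <- sample(3:6, 1)
    bx <- runif(k, 0.3, 0.8)
    h <- data.frame(beta_exposure = bx, se_exposure = 0.05,
                    beta_outcome = 0.4 * bx + rnorm(k, 0, 0.05),
                    se_outcome = 0.05, status = "unchanged")
    cochranQ(h)$Q_p < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("Egger intercept matches a normal-equations oracle and detects pleiotropy", {
  set.seed(11)
  bx <- c(0.2, -0.4, 0.5, 0.35)
  by <- 0.02 + 0.4 * abs(bx) + rnorm(4, 0, 0.03)
  by <- by * sign(bx)       # orientation-consistent outcome effects
  se <- c(0.05, 0.04, 0.06, 0.05)
  h <- data.frame(beta_exposure = bx, se_exposure = 0.05, beta_outcome = by,
                  se_outcome = se, status = "unchanged")
  got <- eggerIntercept(h)
  want <- eggerOracle(bx, by, se)
  expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
  expect_equal(got$se, want$se, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(got$slope, want$slope, tolerance = 1e-10)

  # exactly collinear, zero-intercept data: intercept estimate is 0
  bx2 <- c(0.2, 0.3, 0.5, 0.6)
  h2 <- data.frame(beta_exposure = bx2, se_exposure = 0.05,
                   beta_outcome = 0.4 * bx2, se_outcome = 0.05,
                   status = "unchanged")
  expect_equal(eggerIntercept(h2)$intercept, 0, tolerance = 1e-10)

  expect_null(eggerIntercept(h[1:2, ]))   # k < 3 not computable

  # directional pleiotropy (+0.05 shift) at large k: near-certain rejection
  set.seed(21)
  rej <- vapply(1:100, function(i) {
    k <- 50
    bx <- runif(k, 0.2, 0.8)
    by <- 0.05 + 0.4 * bx + rnorm(k, 0, 0.01)
    h <- data.frame(beta_exposure = bx, se_exposure = 0.05,
                    beta_outcome = by, se_outcome = 0.01,
                    status = "unchanged")
    eggerIntercept(h)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.9)
})

test_that("sensitivity gate and Bonferroni stratification work as documented", {
  # heterogeneous exposure fails Q and is excluded from the denominator
  het <- data.frame(gene = "gBad", tissue = "t", snp = c("a", "b"),
                    effect_allele = "A", other_allele = "G",
                    beta_exposure = c(1, 1), se_exposure = 0.05,
                    beta_outcome = c(0.1, 1.5), se_outcome = 0.05,
                    status = "unchanged", drop_reason = NA)
  r_bad <- mrEstimate(het, gene = "gBad", tissue = "t", outcome = "o")
  expect_false(r_bad$passed_sensitivity)
  expect_true(is.na(r_bad$beta))

  res <- rbind(r_bad,
               mrEstimate(cbind(hrow(0.5, 0.25), gene = "g1"), gene = "g1",
                          tissue = "t", outcome = "o"),
               mrEstimate(cbind(hrow(0.4, 0.02), gene = "g2"), gene = "g2",
                          tissue = "t", outcome = "o"))
  res <- bonferroniFilter(res, alpha = 0.05)
  wald <- res[res$method == "wald_ratio", ]
  # two Wald exposures: threshold 0.05 / 2; the failed IVW exposure has none
  expect_equal(unique(wald$bonferroni_threshold), 0.025)
  expect_true(is.na(res$bonferroni_threshold[!res$passed_sensitivity]))
  expect_false(res$significant[!res$passed_sensitivity])

  many <- do.call(rbind, lapply(1:100, function(i)
    mrEstimate(cbind(hrow(0.5, 0.25), gene = paste0("g", i)),
               gene = paste0("g", i), tissue = "t", outcome = "o")))
  many <- bonferroniFilter(many)
  expect_equal(unique(many$bonferroni_threshold), 5e-4)
})

test_that("odds ratios and confidence intervals are internally consistent", {
  set.seed(3)
  for (i in 1:20) {
    r <- waldRatio(hrow(runif(1, 0.2, 0.8), rnorm(1, 0.1, 0.2)))
    expect_equal(log(r$ci_high / r$ci_low) / (2 * 1.96), r$se,
                 tolerance = 1e-9)
    expect_equal(sqrt(r$ci_low * r$ci_high), r$odds_ratio, tolerance = 1e-9)
    expect_equal(r$odds_ratio, exp(r$beta), tolerance = 1e-12)
    expect_true(r$ci_low < r$odds_ratio && r$odds_ratio < r$ci_high)
  }
})
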