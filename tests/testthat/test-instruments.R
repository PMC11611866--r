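test_that("panel r2 matches hand-computed correlations", {
  H <- rbind(a = c(0L, 0L, 1L, 1L),
             b = c(0L, 0L, 1L, 1L),
             c = c(1L, 1L, 0L, 0L),
             d = c(0L, 1L, 0L, 1L),
             e = c(1L, 1L, 1L, 1L))
  p <- makePanel(H)
  expect_equal(panelR2(p, "a", "b"), 1)
  expect_equal(panelR2(p, "a", "c"), 1)   # complementary rows, r = -1
  expect_equal(panelR2(p, "a", "d"), 0)   # hand-computed Pearson r = 0
  expect_warning(r <- panelR2(p, "a", "e"), "monomorphic")
  expect_equal(r, 0)
  expect_error(panelR2(p, "a", "zz"), "not in panel")
})

test_that("greedy clumping keeps the smallest-p variant of a correlated set", {
  H <- matrix(rep(c(0L, 1L, 1L, 0L, 1L, 0L), 3), nrow = 3, byrow = TRUE)
  rownames(H) <- c("s1", "s2", "s3")
  p <- makePanel(H, pos = c(1000, 2000, 3000))
  cand <- data.frame(snp = c("s1", "s2", "s3"), chrom = "chr1",
                     pos = c(1000, 2000, 3000), pval = c(1e-8, 1e-7, 1e-6))
  kept <- clumpVariants(cand, p, window_kb = 10, r2_max = 0.001)
  expect_equal(kept$snp, "s1")

  # r2 = 0 between the two: both retained
  H2 <- rbind(s1 = c(0L, 0L, 1L, 1L), s2 = c(0L, 1L, 0L, 1L))
  p2 <- makePanel(H2, pos = c(1000, 2000))
  cand2 <- data.frame(snp = c("s2", "s1"), chrom = "chr1",
                      pos = c(2000, 1000), pval = c(1e-6, 1e-8))
  expect_equal(sort(clumpVariants(cand2, p2)$snp), c("s1", "s2"))

  # outside the window nothing is retired even at r2 = 1
  H3 <- rbind(s1 = c(0L, 1L, 1L, 0L), s2 = c(0L, 1L, 1L, 0L))
  p3 <- makePanel(H3, pos = c(1000, 5e7))
  cand3 <- data.frame(snp = c("s1", "s2"), chrom = "chr1",
                      pos = c(1000, 5e7), pval = c(1e-8, 1e-6))
  expect_equal(nrow(clumpVariants(cand3, p3, window_kb = 10000)), 2)

  # input order never matters (canonical sort first)
  expect_equal(clumpVariants(cand2[2:1, ], p2)$snp,
               clumpVariants(cand2, p2)$snp)
})

test_that("clumping matches the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    n_hap <- 40
    # blocky haplotypes so some pairs are strongly correlated
    base <- matrix(rbinom(3 * n_hap, 1L, 0.5), nrow = 3)
    H <- base[sample(1:3, n, replace = TRUE), , drop = FALSE]
    noise <- matrix(rbinom(n * n_hap, 1L, 0.1), nrow = n)
    H <- (H + noise) %% 2L
    rownames(H) <- paste0("v", seq_len(n))
    pos <- sort(sample.int(2e6, n))
    p <- makePanel(H, pos = pos)
    cand <- data.frame(snp = rownames(H), chrom = "chr1", pos = pos,
                       pval = 10^-runif(n, 2, 10))
    for (r2max in c(0.001, 0.1, 0.5)) {
      got <- suppressWarnings(
        clumpVariants(cand, p, window_kb = 1000, r2_max = r2max)$snp)
      want <- suppressWarnings(clumpOracle(cand, H, 1000 * 1000, r2max))
      expect_equal(sort(got), sort(want))
    }
  }
})

test_that("retained instrument count responds monotonically to the knobs", {
  set.seed(77)
  n <- 10; n_hap <- 60
  H <- (matrix(rbinom(2 * n_hap, 1L, 0.5), nrow = 2)[
          sample(1:2, n, TRUE), ] +
        matrix(rbinom(n * n_hap, 1L, 0.15), nrow = n)) %% 2L
  rownames(H) <- paste0("v", 1:n)
  pos <- sort(sample.int(5e6, n))
  p <- makePanel(H, pos = pos)
  cand <- data.frame(snp = rownames(H), chrom = "chr1", pos = pos,
                     pval = 10^-runif(n, 2, 10))
  kept_by_window <- vapply(c(10, 100, 1000, 10000), function(w)
    nrow(clumpVariants(cand, p, window_kb = w, r2_max = 0.01)), numeric(1))
  expect_true(all(diff(kept_by_window) <= 0))
  kept_by_r2 <- vapply(c(0.001, 0.1, 0.5, 0.99), function(r)
    nrow(clumpVariants(cand, p, window_kb = 10000, r2_max = r)), numeric(1))
  expect_true(all(diff(kept_by_r2) >= 0))
})

test_that("proxy search applies the r2 threshold, argmax and orientation rules", {
  # v1 missing from outcome; v2 a perfect proxy; v3 anticorrelated perfect
  # proxy; v4 weak (r2 = 0.25); v5 strong (r2 under 0.6 excluded case below)
  H <- rbind(v1 = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L),
             v2 = c(0L, 0L, 1L, 1L, 0L, 1L, 0L, 1L),
             v3 = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L),
             v4 = c(0L, 1L, 1L, 1L, 0L, 1L, 1L, 0L))
  p <- makePanel(H, pos = c(1000, 2000, 3000, 4000),
                 ref = c("A", "A", "A", "A"), alt = c("G", "G", "G", "G"))
  iv <- list(snp = "v1", beta = 0.5, se = 0.05, pval = 1e-8)

  px <- findProxy(iv, c("v2", "v4"), p)
  expect_equal(px$snp, "v2")
  expect_equal(px$proxy_r2, 1)
  expect_equal(px$effect_allele, "G")   # positive correlation: alt carries
  expect_equal(px$beta, 0.5)

  # anticorrelated proxy: the carried effect maps to the reference allele
  px3 <- findProxy(iv, c("v3", "v4"), p)
  expect_equal(px3$snp, "v3")
  expect_equal(px3$effect_allele, "A")

  # best available below threshold: no proxy, exposure dropped upstream
  expect_null(findProxy(iv, "v4", p, r2_min = 0.6))
  # argmax among qualifying proxies
  px_best <- findProxy(iv, c("v2", "v3"), p)
  expect_equal(px_best$snp, "v2")

  # proxy exposure effect re-looked-up from the eQTL table when present
  eq <- data.frame(snp = "v2", gene = "g1", tissue = "t",
                   beta = 0.33, se = 0.04, pval = 1e-9)
  px_eq <- findProxy(c(iv, gene = "g1", tissue = "t"), c("v2"), p, eqtl = eq)
  expect_equal(px_eq$beta, 0.33)
})

test_that("instrument selection drops exposures with no usable instrument", {
  cfg <- smallNullConfig(seed = 31, prop_causal = 0.25)
  s <- simulateStudy(cfg)
  grn <- buildGrn(s$genome, s$contacts, s$eqtl, fragments = s$fragments)
  sel <- selectInstruments(grn, s$panel, outcome_snps = character(0))
  # no outcome variant at all: every exposure needs a proxy and none exists
  expect_equal(nrow(sel$instruments), 0)
  expect_true(all(sel$audit$status == "dropped_no_instrument"))

  sel2 <- selectInstruments(grn, s$panel, outcome_snps = s$gwas$outcome1$SNP)
  expect_gt(nrow(sel2$instruments), 0)
  expect_true(all(sel2$instruments$pval < 1e-5))
})
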