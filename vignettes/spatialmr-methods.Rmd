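---
title: "Methods: spatial-eQTL-instrumented Mendelian randomization"
author: "spatialmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial-eQTL-instrumented Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one defensible option
existed. No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The causal model

The pipeline estimates the effect of a gene's expression on a binary
outcome using genetic variants as instrumental variables, in the standard
two-sample summary-statistic setting. For instrument $j$ of gene $g$,
let $\hat\beta_{GX,j}$ be the variant's effect on expression (from a
tissue eQTL study) and $\hat\beta_{GY,j}$ its effect on the outcome's
log-odds (from a GWAS in a non-overlapping sample). Under the usual IV
assumptions — relevance, no confounding of the variant–outcome
relationship, and effect on the outcome only through the exposure —
a linear structural model gives

$$\hat\beta_{GY,j} \approx \theta_g\, \hat\beta_{GX,j},$$

where $\theta_g$ is the causal log-odds per 1-SD change in expression.
A single instrument yields the Wald ratio
$\hat\theta = \hat\beta_{GY}/\hat\beta_{GX}$ with first-order
delta-method standard error $se_{GY}/|\hat\beta_{GX}|$; exposure-side
uncertainty is ignored by default (the convention of the established
two-sample MR toolchain; a second-order option exists behind the
`second_order` flag of `waldRatio()`). Multiple instruments are combined
by inverse-variance weighting, algebraically the zero-intercept weighted
regression of $\hat\beta_{GY}$ on $\hat\beta_{GX}$ with weights
$1/se_{GY}^2$. The default standard error is *multiplicative random
effects*: the fixed-effect SE inflated by $\max(1, \sqrt{Q/(k-1)})$, so
under-dispersion never shrinks the SE below the fixed-effect one.

Reported effects are odds ratios per 1-SD expression,
$\mathrm{OR} = e^{\hat\theta}$, with 95% CI
$e^{\hat\theta \pm 1.96\,se}$. The multiplier is exactly 1.96, so the
identities $\sqrt{\mathrm{CI_{lo}}\,\mathrm{CI_{hi}}} = \mathrm{OR}$ and
$\ln(\mathrm{CI_{hi}}/\mathrm{CI_{lo}})/(2 \times 1.96) = se$ hold to
numerical precision; both are asserted in the test suite and the second is
used to reconstruct published ORs from their printed intervals.

### Sensitivity screening

Horizontal pleiotropy — an instrument affecting the outcome through a
path other than the exposure — is the main threat to validity. Two gates
run before estimation for multi-instrument exposures, in this order:

1. **Cochran's Q** on the per-instrument ratios: with
   $r_j = \hat\beta_{GY,j}/\hat\beta_{GX,j}$ and
   $s_j = se_{GY,j}/|\hat\beta_{GX,j}|$,
   $Q = \sum_j (r_j - \bar r)^2 / s_j^2$ around the
   inverse-variance-weighted mean $\bar r$, referred to
   $\chi^2_{k-1}$. Exposures with $Q_p < 0.05$ are excluded.
2. **MR-Egger intercept** (computable for $k \ge 3$; the regression has
   two parameters): instruments are oriented so all exposure effects are
   non-negative, then $\hat\beta_{GY}$ is regressed on
   $\hat\beta_{GX}$ *with* an intercept, weighted by $1/se_{GY}^2$; an
   intercept significantly different from zero ($t$ test with $k-2$ df,
   $p < 0.05$) signals directional pleiotropy and excludes the exposure.
   For $k = 2$ the Egger test is not computable and screening falls back
   to Q alone, which is logged.

Exposures failing either gate are retained in the output with
`passed_sensitivity = FALSE` and no estimate; they never enter the
multiple-testing denominator. Bonferroni correction is applied within
each (tissue, outcome, method) family — the single-instrument Wald
stratum and the multi-instrument IVW stratum separately, mirroring how
the two estimator families are conventionally reported. Each family
controls its own FWER at $\alpha = 0.05$; the union over the two
families is correspondingly larger, which the calibration test accounts
for by asserting the guarantee per family.

## The spatial GRN

Instruments are restricted to *spatial* eQTLs: variants whose restriction
fragment physically contacts a fragment of their target gene in
chromatin-contact data. The construction is purely set-algebraic:

- `digest()` cuts each chromosome at its restriction sites; $n$ internal
  sites give $n+1$ fragments, zero-length fragments are suppressed.
  Coordinates are GRanges (1-based closed) internally and 0-based
  half-open at the BED boundary.
- A variant maps to exactly one fragment; a gene maps to **all**
  fragments overlapping its transcript span (promoter-only assignment was
  rejected as stricter than the fragment-contact evidence warrants).
- A `(variant, gene)` pair is *spatial* iff some contact links the
  variant's fragment to any of the gene's fragments. Contacts are
  unordered. A variant inside one of the gene's own fragments counts only
  if the self-pair $(f, f)$ is explicitly present — the conservative
  reading; co-location alone is not physical-contact evidence.
- Pairs are joined to the tissue eQTL table and Benjamini–Hochberg
  correction is applied *within each variant chromosome* (grouping by the
  variant's chromosome, since instruments are variant-centric); edges with
  adjusted $p \le 0.05$ survive. With a single chromosome this reduces to
  classic BH, which the tests verify, alongside a fixture where grouped
  and pooled BH disagree.
- Each edge is classified by the variant-to-TSS distance: same chromosome
  and $\le$ 1 Mb (inclusive — the boundary case is deliberately `cis`)
  is cis; beyond 1 Mb trans-intrachromosomal; different chromosomes
  trans-interchromosomal. The TSS anchor follows the GTEx convention.
- An optional MAF filter (default threshold 0.05, applied when
  frequencies are supplied) mirrors the usual restriction of the source
  variant set to common variants.

## Instrument selection parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `iv_p` | 1e-5 | eQTL nominal p | instrument-relevance threshold |
| `clump_kb` | 10,000 | kb | clumping window; 10,000 is interpreted in kb (±10 Mb), the convention of the standard clumping tool |
| `clump_r2` | 0.001 | r² | near-independence of retained instruments |
| `proxy_r2` | 0.6 | r² | minimum LD for a substitute instrument |
| `proxy_kb` | 1,000 | kb | proxy search window (a documented knob; proxies in practice lie within the same LD block) |
| `grn_alpha` | 0.05 | adjusted p | GRN edge significance |
| `q_alpha`, `egger_alpha`, `mr_alpha` | 0.05 | p | screening and family-wise levels |

Clumping is greedy: candidates are canonically sorted by (p, chromosome,
position) — making the result independent of input order — and the
smallest-p open variant repeatedly becomes an index, retiring every open
variant within the window at $r^2 \ge$ `clump_r2`. r² is the squared
Pearson correlation of 0/1 haplotype rows in the reference panel;
monomorphic variants get r² = 0 with a warning rather than an error, so
clumping is total. Clumping is performed per exposure gene (the
exposure-wise workflow of the standard toolchain), not genome-wide.

A proxy's exposure effect is re-looked-up from the eQTL table when the
proxy itself has an association for the same gene and tissue; otherwise
the original instrument's effect is carried over with its effect allele
mapped through the *sign* of the haplotype correlation (positive: the two
alternate alleles co-occur).

## Harmonization

Outcome records are aligned to the exposure's effect allele: identical
alleles pass; swapped alleles negate $\hat\beta_{GY}$ and complement the
outcome frequency; complement-strand matches are recoded and re-matched.
Palindromic variants (A/T, C/G) are strand-ambiguous by construction; the
default policy `"infer"` keeps them only when both effect-allele
frequencies fall outside the ambiguity band [0.42, 0.58] (the de-facto
default of the established harmonization tool) and flips the outcome when
the two frequencies disagree about which allele is minor. Missing
frequency on either side, or `palindrome_policy = "drop"`, drops the
variant. Harmonization is involutive — re-harmonizing an aligned pair is
a no-op — and the tests assert that no combination of allele-role swaps
and strand recodings ever changes a downstream estimate.

## What the generator emulates — and what it does not

`simulateStudy()` produces all pipeline inputs under a known ground
truth. Reference study conditions (the generator defaults): 2
chromosomes × 10 Mb, 1000 variants, 200 genes, 1000 haplotypes, 10% of
genes causal at $\theta = 0.4$, outcome standard errors 0.05
(UK-Biobank-scale), no pleiotropy.

- **Haplotypes** follow a block-LD model: each `ld_block_length_bp`
  (20 kb) block has a latent Bernoulli signal per haplotype with block
  frequency uniform on 0.1–0.9, and each variant copies it with per-entry
  flip probability $(1-\sqrt\rho)/2$, giving expected within-block
  correlation $\approx \rho$ (default 0.9) and independence across
  blocks. This is sufficient for clumping and proxy logic; it is *not* a
  demographic model — no recombination maps, no ancestry structure.
- **Truth assignment** gives each gene 1–3 instrument variants within
  1 Mb of its TSS, at most one per LD block and never shared between
  genes, so clumping retains multi-instrument exposures by design (chance
  inter-block correlation in a finite panel still prunes some, which is
  realistic and harmless).
- **eQTLs** for true pairs draw $|z|$ uniform on 6–12 (nominal
  $p \le 2\times10^{-9}$, safely instrument-grade); every emitted p
  equals the two-sided normal tail of its own beta/se to 1e-12. Decoy
  eQTL rows with no supporting contact, and decoy contacts between
  variant-free fragments, are constructed so that neither can form an
  edge — making the GRN stage's recovery of exactly the true pairs a
  sharp closed-loop test rather than a statistical one.
- **Outcome GWAS**: $\hat\beta_{out,j} = \theta_g \hat\beta_{exp,j} +
  \eta_j + \varepsilon_j$ for instrument variants ($\eta$ the optional
  pleiotropy term, off by default), null draws elsewhere; the generative
  model is linear on the log-odds scale, as two-sample summary MR
  assumes — no individual-level binary-trait simulation, and outcomes are
  generated independently (no shared-control correlation). A configurable
  fraction of rows is written allele-swapped or strand-flipped so
  harmonization is exercised end to end, and a fraction of variants can
  be withheld from the outcome to exercise proxy search.
- Effect sizes are shared verbatim across tissue labels, so one outcome
  model is simultaneously consistent with every tissue's exposure data;
  cross-tissue *heterogeneity* (the interesting discordance patterns) is
  therefore exercised with fixtures, not simulation.

Consequently, passing tests demonstrate the pipeline's algebra,
bookkeeping and statistical calibration under its own assumptions. They
do not demonstrate robustness to real-data pathologies: assortative
ancestry, weak-instrument bias with noisy exposure estimates, sample
overlap, or mis-specified LD panels.

## Numerical choices and problem sizes

- Restriction sites sit on a half-spacing-offset grid
  ($(k-\tfrac12)\cdot$spacing), keeping all $\lfloor L/\text{spacing}
  \rfloor$ sites strictly internal so digestion always yields one more
  fragment than sites.
- Clumping tie-breaks: equal p-values resolve by (chromosome, position)
  ascending; proxy ties by higher r², then position.
- The Egger intercept on exactly collinear data has a 0/0 t-statistic in
  floating point; the implementation reports the (zero) intercept and its
  test asserts the estimate, not the p-value, in that degenerate case.
- Monte-Carlo problem sizes were chosen to make sampling error a small
  fraction of the tested margins: 2000 replicates for Q calibration
  (binomial SE ≈ 0.005 on a 0.03–0.07 acceptance band), 500 end-to-end
  global-null replicates for the FWER guarantee (asserted at
  0.05 + 2·binomial SE per Bonferroni family), 50 study replicates for
  effect recovery (asserted at twice the Monte-Carlo SE of the mean,
  ≈ 0.006 on effect scale), and 1000 random instances for the clumping
  oracle. The FWER and recovery suites run on reduced study dimensions
  (12 genes / 120 variants / 200 haplotypes, and the reference conditions
  respectively).

## Known limitations

- Correlated-instrument (LD-aware) IVW, weighted-median/mode estimators,
  MR-PRESSO and Steiger filtering are out of scope.
- Multi-allelic variants and indels are skipped at the VCF boundary.
- The Bonferroni denominator is per tissue and per outcome; no pooling
  across tissues is attempted.
- Gene sets and biotype annotations are user-supplied files; no external
  databases are queried.
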