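---
title: "Methods: dosage-series analysis of homoeolog expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-series analysis of homoeolog expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosageseries)
```

## The design and its central quantity

The package analyses a serial allopolyploid design: two diploid parents (AA,
CC) and four derived genotypes (AC, AAC, CCA, CCAA) combining the A and C
subgenomes in different doses, with two biological replicates per genotype.
The central covariate is the **relative dosage** of a subgenome,

$$d_X(G) = \frac{\text{copies}_X(G)}{\text{copies}_A(G) + \text{copies}_C(G)},$$

which for the A subgenome over its five carrier genotypes (AA, AAC, AC,
CCAA, CCA) equals exactly $(1, 2/3, 1/2, 1/2, 1/3)$; the C series is
symmetric. Relative rather than absolute dosage is what expression responds
to under a fixed transcriptional economy: transcripts compete for a fixed
sequencing library (and, approximately, for a fixed cellular mRNA pool), so
a gene transcribed at a constant per-copy rate occupies a library share
proportional to $d$. This is why AC and CCAA — different absolute copy
numbers, identical relative dosage — are expression-equivalent for
dosage-tracking genes, and the package's generator reproduces that
equivalence by construction.

## Dosage classification

For each gene we correlate its replicate-averaged FPKM across the five
carrier genotypes with the dosage series (Pearson), take the two-sided
p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ degrees of freedom,
and adjust by Benjamini–Hochberg **within each subgenome** (the two
subgenomes are separate test families; their gene sets and dosage series are
distinct). A gene is *dosage dependent* when $p_{adj} < \alpha$ (default
0.05) **and** $r > 0$. Significant negative correlations are biologically a
different phenomenon — inverse dosage effects, attributed to negatively
acting regulators — and are flagged separately while remaining in the
independent class, so that dependent + independent always partition the
genes.

Choices worth making explicit:

* **Genotype means, not replicate-level points.** The correlation uses one
  value per genotype (5 points, 3 degrees of freedom). With two replicates
  the replicate-level alternative (10 points) mixes within- and
  between-genotype variance into a single correlation and overstates the
  effective sample size; the genotype-mean convention matches how the
  five-value expression series is conventionally reported.
* **Constant expression** has an undefined correlation; we define $r = 0$,
  $p = 1$. A perfectly flat profile is the idealised compensated gene, so it
  belongs in the independent class rather than in an error path.
* **The r² cutoff is emergent, not a constant.** With $n = 5$ the plain
  $\alpha = 0.05$ critical value is $r^2 = 0.771$; the adaptive BH threshold
  moves the effective cutoff with the proportion of true signals in the
  dataset. We therefore report, per subgenome, the minimum $r^2$ among
  dependent genes as the dataset's empirical cutoff instead of hard-coding
  any value.
* **Numerical details.** The vectorised screen clamps $r$ to $[-1, 1]$,
  assigns $p = 0$ at exactly $|r| = 1$, and agrees with `cor.test()` to
  $10^{-10}$ (tested). BH goes through `p.adjust()`, with inputs validated
  to $[0, 1]$ modulo a $10^{-8}$ tolerance for floating-point overshoot from
  upstream exact tests.

Homoeolog pairs are then grouped as AdCd/AdCi/AiCd/AiCi. The expected group
proportions under independent assortment are products of the two marginal
dependent fractions, tested by a df = 3 chi-square goodness of fit without
continuity correction.

## Mid-parent fold change

`MPV = (FPKM_AA + FPKM_CC)/2` is the additivity baseline; `FC = FPKM/MPV`
per gene and hybrid genotype. For a subgenome-specific gene the non-carrier
parent contributes whatever the matrix holds (zero in synthetic data; no
masking or special-casing is applied), so MPV is about half the
carrier-parent level and a noise-free dependent A gene in AAC has
$FC = (2/3)/(1/2) = 4/3$ exactly — the analytic anchor used in the tests.
Zero-MPV genes are flagged and excluded from summaries rather than erroring.
Summaries use the linear-interpolation (type 7) quantile convention,
recorded in the output metadata, so medians are bit-reproducible. The
fold-change band is the **closed** interval $[0.5, 1.5]$; the complement is
strictly outside. Subgenome comparisons use the Wilcoxon rank-sum test
(unpaired) or signed-rank test (paired homoeologs); a paired comparison of
identical vectors has no non-zero differences and is reported as $p = 1$
rather than an error.

## Cis/trans partitioning

For a pair with parental expression PA (A homoeolog in AA), PC (C homoeolog
in CC) and hybrid expression F1A, F1C:

$$A = \log_2(PA/PC), \quad B = \log_2(F_1A/F_1C), \quad A - B = \text{trans},$$

because in the common hybrid nucleus both homoeologs see identical trans
factors, so any retained ratio is cis. Two significance calls drive the
four-way classification: `A != B` (Fisher's exact test on the 2×2
replicate-summed count table) and `B != 0` (exact binomial), each BH-adjusted
within the genotype, with "equal" meaning not significant at $\alpha$:

| `A != B` | `B != 0` | category    |
|----------|----------|-------------|
| no       | yes      | only_cis    |
| yes      | no       | only_trans  |
| no       | no       | no_effect   |
| yes      | yes      | cis_trans   |

Design decisions here:

* **Counts for tests, FPKM for estimates.** Exact tests need integer
  counts; point estimates of A and B use genotype-mean FPKM with a
  pseudocount of 0.5 substituted for zeros only (non-zero values are never
  shifted, so exact ratios like 8:2 give exactly $A = 2$).
* **Library normalisation.** PA and PC come from different libraries;
  groups are replicate-summed and scaled to the smallest group total before
  rounding, since unnormalised cross-library counts would bias A.
* **Length correction of the balance test.** Read counts scale with
  transcript length, so "equal expression" corresponds to an expected A
  fraction of $\ell_A/(\ell_A+\ell_C)$, not $1/2$; the balance test uses
  this per-pair fraction. The Fisher test needs no correction because the
  length factors cancel between its two rows. (Omitting this correction
  misroutes most truly trans-divergent pairs whose homoeologs differ in
  length — measurable against the generator's ground truth.)
* **Copy correction is optional and off by default.** In triploids the
  homoeolog copy ratio is 2:1, so `B = 0` can be read either as "equal
  output" (raw, default) or "equal output per copy" (`copy_correct = TRUE`,
  which rescales the null fraction by the copy ratio). Which convention the
  classical analysis used in triploids cannot be determined from how it is
  usually stated; both modes are provided and the mode is echoed into every
  output.
* **Degenerate inputs.** A pair with both hybrid counts zero gets $p = 1$
  and a flag; a Fisher table with a zero margin has $p = 1$.

Categories are cross-tabulated against the AdCd/AiCi pair groups (observed
vs marginal-product expectation, 2×2 chi-square per cell, enrichment
direction flagged); empty categories are omitted with a warning.

## The synthetic-data generator

The generator emulates the study conditions: six genotypes, two replicates,
and a mixture of regulatory classes assigned independently to the A and C
member of each pair — 60% dependent, a 0.5% inverse-dosage sub-fraction, the
rest compensated. Expected expression of a gene with per-copy rate $k$ in a
genotype with relative dosage $d$:

* dependent: $k \cdot d$;
* compensated: $k \cdot c$ with $c = 0.5$, constant in every carrier
  genotype (so a fully compensated gene in a hybrid expresses at its
  parental level);
* inverse: $k \cdot (1.5 - d)$ — strictly decreasing in dosage, always
  positive; the floor 1.5 is the smallest half-integer exceeding the maximum
  dosage of 1;
* absent subgenome: 0.

Per-copy rates are lognormal (meanlog 0.6, sdlog 1.2, FPKM units), shared
within a pair. The meanlog is set so that the parental-expression filter
(FPKM > 1 in both parents) removes roughly half of the pairs, as in typical
leaf transcriptomes; the sdlog gives a realistic four-orders-of-magnitude
dynamic range. Cis-divergent pairs (10%) split the rate symmetrically in
log2 (offset 2, random sign) in every genotype; trans-divergent pairs (10%)
carry the same split in the parents only and collapse to the shared rate in
hybrids, which is exactly the "A ≠ B, B = 0" pattern. Gene lengths are
uniform on 500–5000 bp and enter only through the FPKM formula.

Counts are sampled per library by a gamma-mixed multinomial: each gene's
expected library share (expression × length / 10⁹) is jittered by an
independent Gamma(1/φ, 1/φ) factor (variance φ, the `dispersion` parameter)
and a multinomial of the configured library size (default 2×10⁷, a
scaled-down stand-in for tens of millions of mapped reads) is drawn.
Marginally each count is gamma-Poisson (negative-binomial-like); conditioning
on the library total keeps the fixed-library competition exact, which is the
property that makes FPKM track relative dosage. The pair genes occupy only
part of the library; the remainder is an implicit background transcriptome,
and the sample sheet carries the genome-wide mapped total (`total_reads`) as
the FPKM denominator — exactly the situation in real data, where the
homoeolog-pair matrix is a subset of the library. Without this background,
compensated genes would absorb spurious dosage correlation from
genotype-dependent normalisation. The default dispersion 0.05 reproduces a
between-replicate FPKM correlation of about 0.93, the conventional quality
level for biological replicates; `dispersion = 0` gives pure multinomial
sampling, and `exact = TRUE` skips sampling entirely for analytic checks.

What the generator deliberately does **not** emulate: read-level artefacts
(mapping bias, positional coverage), partial compensation (classes are
discrete; real dosage response is a continuum with no obvious generative
form), expression-level dependence of dispersion, homoeolog cross-mapping,
and any genotype-specific trans networks beyond the simple parental-offset
model. Passing recovery tests therefore demonstrates that the statistics
recover the idealised signal classes, not that they are robust to every
artefact of real RNA-seq.

## Interactions the idealised model makes visible

Three model consequences are worth knowing when reading test output:

* **Compensated genes sit at FC = 2.** Constant expression across carrier
  genotypes, divided by a mid-parent value that is half the carrier-parent
  level, gives fold change 2 — so simulated fold-change medians in mixed
  populations sit above the value real data shows, where independence means
  decorrelation rather than strict constancy.
* **Discordant pairs are composite signals.** A pair whose members differ
  in dosage class (e.g. AdCi) has a genuine parent-vs-hybrid ratio change
  even without regulatory divergence; cis/trans recovery is therefore
  measured on divergent pairs whose members share a dosage class.
* **Trans-divergent compensated genes look dependent.** Their parental rate
  differs from their hybrid rate, and the diploid parent is the dosage-1
  endpoint of the series, so the class labels genuinely conflict; they are
  counted as disagreements in the recovery figures.

Two further caveats are statistical rather than generative. Conditioning on
a noisy parental FPKM exceeding the filter threshold slightly biases the
dosage-1 endpoint upward for genes near the threshold; at the default noise
level the effect on the null type-I rate is negligible, but it grows with
dispersion. And the exact tests assume counting noise only: at deep coverage
with biological overdispersion, Fisher and binomial p-values are
anticonservative, which inflates the cis_trans category — the reason the
recovery checks run at low dispersion (0.01) and the cis/trans null check at
dispersion 0.

## Problem sizes and reproducibility

The test suite exercises the pipeline at 50–800 pairs for unit and property
checks, and at 5,000 pairs (the scale of a filtered homoeolog-pair set,
order-of-magnitude-matched to real designs) for recovery and calibration:
dependence-label agreement ≥ 90% at dispersion 0.01, cis/trans recovery
≥ 80% on concordant divergent pairs, raw-p null calibration inside the exact
binomial 99% CI, and the analytic zero-noise limits ($FC = 4/3$, $r = 1$)
exactly. Every simulation is seeded; identical configuration and seed give
bit-identical datasets, summaries and reports.
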