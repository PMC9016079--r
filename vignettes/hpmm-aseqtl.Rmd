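---
title: "Hierarchical Poisson mixed models for allele-specific eQTL analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Poisson mixed models for allele-specific eQTL analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asehpmm)
```

## The model and its assumptions

Allele-specific expression (ASE) compares the read counts attributable to
the two alleles of a heterozygous subject at a transcribed SNP. Because
both counts come from the same library, sample-level technical noise and
confounders cancel, which makes allelic imbalance a sensitive readout of
cis-regulation. The cost of classical ASE tests is that homozygous
subjects -- often the majority -- contribute nothing.

The hierarchical Poisson mixed model (HPMM) implemented here unifies both
kinds of subjects. For subject $i$ and allele pattern $j$,

$$y_{ij} \sim \mathrm{Pois}\!\left\{\exp(\mu + X_{ij}\beta +
  C_{ij}\gamma + b_i + \varepsilon_{ij})\, K_{ij}\right\},$$

with $b_i \sim N(0, \sigma_b^2)$ shared within subject and
$\varepsilon_{ij} \sim N(0, \sigma_\varepsilon^2)$ independent per
observation. A heterozygous subject is split into the patterns $j = A$
and $j = a$ ($X = 1$ and $0$), each carrying half the library size as
offset ($K = l_i/2$); a homozygous subject contributes one observation
($j = AA$ or $aa$, $X = 1$ or $0$, $K = l_i$). Halving the offset and
sharing $b_i$ makes the two allelic counts of a heterozygote paired
samples: their *difference* is informative about $\beta$ free of $b_i$,
while homozygous subjects inform $\beta$ through their genotype-level
expression, shrunk by the between-subject variance $\sigma_b^2$. The
observation-level effect $\varepsilon_{ij}$ absorbs allele-level
overdispersion relative to the Poisson; when there is no sign of
overdispersion it can be omitted (`include_eps = FALSE`) for extra power.

Assumptions worth keeping in mind: counts are conditionally Poisson given
the log-normal random effects; the random effects are Gaussian on the log
scale; library sizes are known constants; and the allelic split of a
heterozygote is measured without mapping bias (upstream filtering, e.g.
WASP-style, is assumed to have been applied before counts reach this
package -- alignment and bias correction are outside its scope).

### Testing a non-transcribed variant through a phased proxy

GWAS variants are usually not transcribed, so their allelic expression is
not directly observable. With phased genotypes, an exonic proxy SNP
(alleles $B/b$) inside a nearby gene links each GWAS allele to an
observable allelic count, but only in *double-heterozygous* subjects
(heterozygous at both loci): the haplotype carrying the GWAS effect
allele $A$ contributes the count of its phased exonic allele with
$X = 1$, the other haplotype the remaining count with $X = 0$, each with
offset $l_i/2$. All other subjects contribute their total exonic count as
a single observation with $X = 1, 0.5, 0$ for GWAS genotypes AA, Aa, aa.
Subjects heterozygous at the exonic SNP but homozygous at the GWAS SNP
also enter as one total-count observation -- their allelic split cannot
be attributed to GWAS alleles without double heterozygosity.

The interaction model adds $D_i\alpha + X_{ij} D_i \delta$ for a binary
group $D_i$ (diagnosis, dichotomized age, sex); testing $\delta = 0$
detects a differential allelic effect between groups
(`fit_interaction()`).

### The beta-binomial comparator

Restricted to heterozygous subjects and conditioning on each pair total
$n_i = y_{iA} + y_{ia}$, the HPMM reduces to a binomial model for
$y_{iA}$ with $\mathrm{logit}$ mean $\beta$ and overdispersion driven by
$\varepsilon_{iA} - \varepsilon_{ia}$. `fit_betabin()` implements the
classical beta-binomial version (mean $\pi = \mathrm{logit}^{-1}\beta$,
precision $\theta$) by direct likelihood maximization with a Wald test.
It is the package's built-in representative of heterozygous-only methods
for power comparisons. The reduction is exact only in the large-count
limit: at finite depth a small amount of information about $\beta$ flows
through the pair totals, and the Laplace geometries of the two
parameterizations differ by $O(1/\text{count})$. The test suite therefore
checks the equivalence of estimates on a deep-coverage data set (about
$5\times 10^3$ expected reads per allelic observation), where agreement
is within $10^{-3}$, and checks *power* equivalence at ordinary depth.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `library_size` ($l_i$) | per-subject normalizing constant | sum of the subject's counts in the table | the usual library-size convention; a user-supplied normalizing factor column overrides it |
| `include_eps` | keep $\varepsilon_{ij}$ | `TRUE` | overdispersion is the norm in RNA-seq counts |
| `min_double_het` | minimum split subjects before flagging | 3 | below this the allelic part of the design is too thin to interpret |
| `r2_min` | imputation quality threshold (strict `>`) | 0.96 | phasing errors corrupt the allele-to-haplotype link; directly genotyped loci bypass the filter since it exists to control imputation phasing error |
| `min_mean` | mean raw count below which a locus is dropped | 2 | barely covered loci carry no power |
| `window` | TSS window around the tested variant | 500 kb (inclusive) | standard cis-window |
| `alpha`, `fdr_threshold` | test level / BH significance | 0.05 | convention |
| `ld_threshold` | \|r\| above which two SNPs count as high LD | 0.8 | conventional high-LD cutoff used in the three-way interpretation |

## Numerical choices

*Estimation.* The marginal likelihood factorizes over subjects; each
factor is a $(1+m_i)$-dimensional integral over $(b_i,
\varepsilon_{i\cdot})$ approximated by Laplace's method. The negative
Hessian at the joint mode is an arrowhead matrix, so the inner Newton
solve and log-determinant are $O(m_i)$ (compiled code, warm-started
between likelihood evaluations). The outer optimization over $(\mu,
\beta, \gamma, \log\sigma_b^2, \log\sigma_\varepsilon^2)$ uses `nlminb`
(relative tolerance $10^{-10}$, 500 iterations) followed by a short
fixed-Hessian Newton polish; the polish matters because exact likelihood
symmetries -- relabelling alleles negates $\beta$, rescaling all $l_i$
by $c$ shifts $\mu$ by $-\log c$ -- are verified to $10^{-6}$ in the
tests, finer than a finite-difference stopping rule alone delivers.

*Variance boundaries.* Variance components are bounded below at
$10^{-10}$; estimates at the boundary are reported as 0. When
$\hat\sigma_\varepsilon^2$ hits the boundary the model is refitted
without $\varepsilon_{ij}$ and the refit is what is reported
(`eps_dropped`). Standard errors come from the observed information of
the free parameters; if a boundary makes it singular, the fixed-effect
block is inverted with the variances held fixed.

*Tests.* Wald is the default (`test_beta()`), matching common
mixed-model practice; the likelihood-ratio test against the nested
$\beta = 0$ fit is available by flag. Which test produced a p-value is
recorded in the fit object.

*Degenerate inputs.* A design with constant $X$ is an error ("not
testable"); a double-heterozygous subject without phase is an error;
beta-binomial pairs with $n_i = 0$ are dropped with a warning;
correlations of zero-variance vectors return `NA` with a warning rather
than a number.

## The UMI pipeline

For droplet snRNA-seq, molecules rather than reads must be counted. Per
cell and exonic locus: reads not assigned to a transcript are discarded;
each UMI's remaining reads must agree on the allele (a conflicted UMI is
removed as a likely sequencing error); surviving UMIs within Hamming
distance 1 are collapsed *directionally* -- visited in decreasing order
of read support, ties broken lexicographically, each UMI absorbed into
the first established cluster seed within distance 1. Directional,
count-ordered merging is the standard deterministic choice for
single-mismatch collapsing; the source text of the procedure specifies
only "at most one mismatch", so the order rule is a design decision here,
as is removing a collapsed cluster whose members disagree on the allele
(the same error rationale extended to the collapsed level). Pseudo-bulk
counts then sum collapsed UMI calls per subject, cell type and allele;
UMI identity is per cell, so equal UMI strings in different cells are
distinct molecules.

## What the simulation generator emulates

`simulate_genotypes()` draws Hardy-Weinberg genotypes;
`simulate_haplotypes()` draws two-SNP haplotypes with a chosen
allele-indicator correlation (`ld_r`), erroring when the implied
haplotype frequencies are infeasible; `simulate_counts()` draws counts
from the HPMM itself. Defaults mirror the reference study conditions: 500
subjects, $\sigma_b^2 = 1$, $\sigma_\varepsilon^2 = 0.5$, $\beta \in
[0, 0.3]$, MAF $\in [0.1, 0.4]$, 5% level, 2000 replicates. The baseline
$\mu$ and library size are not dictated by those conditions; they are set
so the expected count per allelic observation is about 50 at $l_i =
10^6$ -- a moderate sequencing depth -- and both are configurable.

The generator produces counts *from the model*: it emulates the paired
allelic structure, between-subject variability and allele-level
overdispersion, but not mapping bias, reference bias, genotyping error,
phasing error, or cell-type mixtures. Passing simulation-based tests
therefore demonstrates calibration and power of the inference machinery
under the model's own data-generating process, not robustness to those
artifacts -- which the QC layer is designed to filter out upstream.

Grid sizes used in the automated checks are deliberately smaller than a
publication-grade study (250 replicates per grid cell, 500 for the null
calibration in the test suite; 2000 replicates in
`scripts/acceptance.R`); every comparison carries a Monte-Carlo
standard-error band computed from the replicate count actually used, so
the conclusions scale with the budget chosen.

## Interpreting significant associations

For a significant (GWAS SNP, exonic SNP) pair, the package computes the
whole-sample genotype (dosage) correlation and the *allelic* correlation
across the phased chromosomes of double-heterozygous subjects. The two
can diverge sharply: with no population LD and a small minor-minor
haplotype frequency $P_{ab} = P_a P_b$, double heterozygotes may contain
no $ab$ haplotype at all, forcing the phase configuration $(A\!-\!b,
a\!-\!B)$ in every such subject and hence allelic correlation exactly
$-1$ while the population correlation is near 0. The
`complete_allelic_corr` fixture constructs this degenerate case exactly,
and the test suite reproduces the qualitative contrast at low MAF.

Significant associations are classified three ways: (1) the exonic SNP is
*less* significant than the GWAS SNP (imbalance not mediated by the
proxy); (2) otherwise the two SNPs are in high LD, $|r| > 0.8$ (driver
indistinguishable); (3) otherwise (the exonic SNP is the more likely
driver, and the GWAS association may reflect the inflated conditional
correlation above). "Less significant" compares raw p-values with a
strict inequality, so ties fall into the LD branch; the correlation used
is the Pearson dosage correlation, chosen (and documented here) because
the alternative -- a reference-panel haplotype $r$ -- is not computable
from the cohort itself.

## Design decisions in the open

* The imputation filter uses strict $R^2 > 0.96$ and exempts directly
  genotyped loci.
* The genotype-vs-RNA-seq consistency ratio is min/max of the two allele
  counts, making the homozygous (ratio > 10%) and heterozygous
  (ratio < 2%) rules symmetric and monotone; with $\le 20$ reads the
  imputed call is retained. When the rules fire, the RNA-seq-implied call
  (heterozygous when the ratio is at least 2%, otherwise homozygous)
  replaces the imputed genotype.
* The $\pm 500$ kb TSS window is inclusive at both boundaries and
  coordinates are 1-based throughout.
* Subject-level covariates are replicated across a subject's two allelic
  rows.
* Both random effects are always retained for single-observation
  subjects even though they are not separately identifiable row-wise;
  they are identified through the paired rows, and no special-casing is
  applied.

## Known limitations

* Laplace accuracy degrades for very small counts (a handful of reads
  per observation); the low-expression filter (mean count < 2) removes
  the worst cases, but estimates at minimal depth should be treated with
  care.
* Haplotype-level ASE aggregating several exonic SNPs per gene is not
  implemented; the unit of analysis is one exonic SNP.
* The package consumes tabular allelic counts; producing them (alignment,
  mapping-bias filtering, pileups, cell calling) is upstream.
* The beta-binomial comparator is intercept-only; covariates belong in
  the HPMM, which is the recommended analysis path.
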