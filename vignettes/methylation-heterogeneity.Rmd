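---
title: "Epiallele-based methylation heterogeneity: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epiallele-based methylation heterogeneity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(epipoly)
```

# The measurement model

Bisulfite sequencing reads phase the methylation states of nearby CpGs on the
same DNA molecule. For every run of 4 adjacent CpGs close enough to be
covered by single reads (an *e-locus*), each read exhibits one of $2^4 = 16$
binary *epiallele* patterns. Two summary statistics are computed from the
pattern counts $c_0, \dots, c_{15}$ (frequencies $p_i = c_i / d$ at depth
$d$):

* **epipolymorphism** $E = 1 - \sum_i p_i^2$, the probability that two
  epialleles drawn at random (with replacement) from the locus differ. $E = 0$
  when every read shows the same pattern and $E = 15/16 = 0.9375$ when all 16
  patterns are equally frequent. Sampling *with* replacement matches the
  $1-\sum p^2$ form; the package's test oracle samples pairs the same way.
* **average methylation** $\bar m = \sum_i p_i\,\mathrm{popcount}(i)/4$,
  identical to the read-weighted mean of the four per-CpG methylated
  fractions.

Two samples can share $\bar m$ yet differ strongly in $E$; the package exists
to quantify that disorder dimension and its downstream consequences.

A locus with zero depth in a sample is *missing*, never $E = 0$: conflating
the two would leak unmeasured loci through the coverage filter.

## E-locus enumeration

CpGs are collapsed to the plus-strand C coordinate, CpGs at C/T and G/A SNP
sites are removed, and every 4-CpG window with span at most `max_span` becomes
an e-locus. Two choices here are genuinely open:

* `max_span` defaults to **100 bp**. Patterns must be phased within single
  reads, so the span limit is the read-length scale of short-read bisulfite
  protocols.
* Windows **slide by one CpG** and may overlap. Overlapping windows are the
  superset of any tiling; a disjoint tiling can be thinned downstream, the
  reverse is impossible.

The coverage filter retains an e-locus when at least 75% of samples (boundary
inclusive) reach depth $\ge 10$; samples without a profile row count as
failing.

# Differential epipolymorphism

Per retained locus, a two-sample test compares epipolymorphism between groups
(tumour minus normal when those labels are present), with
Benjamini–Hochberg adjustment over all loci that produced a valid p-value
(at least two non-missing values per group). A locus is called significant
only when **both** $|\Delta E| > 0.1$ and adjusted $p < 0.01$ hold — an
effect-size guard against the large-sample regime where trivial differences
reach significance.

The underlying two-sample test is not dictated by the analysis itself, so
both **Welch's t** (default) and the **Wilcoxon rank-sum** test are exposed;
the choice is recorded in the result's attributes. Multi-region samples from
the same patient are *not* collapsed by default — the sample, not the
patient, is the analysis unit — but a per-patient-mean mode exists for
sensitivity analyses.

One calibration property is worth knowing. Epipolymorphism values are bounded
and, at mostly-concordant loci, zero-inflated and heavily tied; at 10 vs 10
samples both shipped tests are measurably *conservative* (empirical
false-positive rates a few relative percent below nominal at all usual
$\alpha$, as the acceptance checks compute). Type-I error remains controlled;
what is lost is exactness of the nominal level, which no rank or t statistic
can restore on such data at these group sizes.

Annotation enrichment between the two direction sets (more disordered in
tumour vs in normal) uses the two-proportion chi-squared test (continuity
correction off by default, matching the large-count regime), with an exact
Fisher fallback whenever an expected cell drops below 1. A locus carries an
annotation flag when any of its four CpGs falls in the interval set; loci,
not genes, are counted.

# Expression linkage: nested linear models

For (promoter e-locus, gene) pairs — promoter window **TSS −1000/+500 bp,
strand-aware** by default, since "promoter" has no canonical width — the
package fits, on identical samples,

$$\text{reduced: } y = a + b\,\bar m, \qquad
  \text{full: } y = a + b\,\bar m + c\,E,$$

with $y$ log2 expression, and tests the epipolymorphism term by a likelihood
ratio test with statistic $\Lambda = n \ln(\mathrm{RSS_r}/\mathrm{RSS_f})$.

**Calibration of the LRT p-value.** Under Gaussian errors $\Lambda$ is a
monotone function of the partial F statistic, so its exact finite-sample null
distribution is available through the $F(1, n-3)$ pivot:
$p = P\!\left(F_{1,n-3} \ge (n-3)(e^{\Lambda/n} - 1)\right)$. The asymptotic
$\chi^2_1$ reference is noticeably anticonservative at the cohort sizes this
analysis runs at (its CDF deviates by ≈0.05 from uniform at $n = 20$), so the
exact pivot is the default and `p_method = "chisq"` preserves the asymptotic
form. Collinear regressors ($|r| = 1$, including constant epipolymorphism)
yield $\Lambda = 0$, $p = 1$ and a `collinear` flag rather than an error.

BH adjustment runs over *pairs* (a gene with several promoter e-loci is
tested once per locus), and the gene count filter (total counts < 5 removed;
a per-sample mode is optional since the rule's granularity is a judgement
call) is applied upstream on raw counts. Expression is assumed
log2-normalized upstream; the package does not normalize counts.

# Heterogeneity indices and trees

* **APITH** is the mean distance over all $\binom{n}{2}$ pairs of one
  patient's tumour samples. Averaging over pairs is what makes the index
  comparable across patients with different region counts — the package
  property-tests that the expectation is identical across subsample sizes.
  The default distance is the mean absolute beta difference (per-feature,
  scale-free); Euclidean is available.
* **PCAR** = DNAm age / chronological age. Per patient, homogeneity is
  declared when the maximum relative PCAR difference among tumour samples,
  $(\max - \min)/\min$, is *strictly* below 0.30. The denominator is a
  choice (a bare "difference < 30%" does not fix one); the relative form is
  used and recorded. Single-sample patients are homogeneous by convention.
* **Phylo-epigenetic trees** are built by neighbor joining on distances over
  the top 10% most variable CpGs (variance computed across tumour samples
  only; ties broken by coordinate then id so selection is deterministic).
  NJ is the standard distance-matrix method and exactly inverts additive
  matrices; average-linkage clustering is offered as an alternative. Negative
  NJ branch lengths (non-additive input only) are clamped to zero with the
  deficit moved to the adjacent branch.
* **Robinson–Foulds** comparison counts bipartitions present in exactly one
  tree, on *unrooted* topologies (rooting on the normal sample would add an
  assumption the comparison does not need), normalized by $2(n-3)$.

# Regularized NMF deconvolution

Bulk methylomes mix cell types. The package factorizes the loci × samples
beta matrix $D \approx T A$ with $T \in [0,1]^{m \times k}$ (latent
methylation components, LMCs) and $A \ge 0$ with simplex columns (per-sample
proportions), minimizing

$$\|D - TA\|_F^2 \;+\; \lambda \sum_{j,c} T_{jc}(1 - T_{jc}),$$

where the penalty pulls component methylomes toward the biologically
plausible fully-(un)methylated poles.

Numerical design:

* **T-step**: with $A$ fixed, rows of $T$ decouple per component, leaving a
  scalar quadratic on $[0,1]$ per entry. It is minimized in closed form
  (interior stationary point when convex, else the better endpoint), which
  handles the non-convexity the penalty introduces for large $\lambda$
  exactly and keeps the objective monotone.
* **A-step**: each column is a convex simplex-constrained quadratic, solved
  by projected gradient steps at the global Lipschitz bound $2\|T^\top T\|_2$
  (which dominates every masked column problem too), so every step descends.
* The objective is asserted non-increasing at each iteration; a violation
  above $10^{-9}$ aborts. Ten random restarts (Dirichlet(1) columns for $A$,
  uniform $T$), seeds fanned out per restart, best final objective wins.
* Missing rows are dropped by default; a masked-objective mode fits only
  observed entries.

**Model selection** hides a random 10% of entries per fold, fits on the rest,
and scores RMSE on the hidden entries. Because reconstruction RMSE flattens
once $k$ reaches the true rank, RMSE values within 1% (relative) of the
minimum are treated as ties and resolved toward smaller $k$, then larger
$\lambda$ — a parsimony rule, declared rather than inferred. Component
identity is resolved only up to permutation (the simplex constraint fixes
scale), so recovered factors are compared to references or to ground truth
after optimal permutation / by correlation matching with BH-adjusted
correlation tests.

# What the synthetic data do and do not show

The generator reproduces the statistical structure the analysis assumes:
two groups with multi-region patients (defaults 18 patients × 6 tumour
regions + 28 normals = 136 samples, the scale of the motivating study
design); per-locus 16-pattern probability vectors (non-differential loci
share one vector across groups, 75% concordant-pole / 25% disordered —
concordant loci are the genomic majority, but real tissue shows a spread;
differential loci pair a near-uniform disordered vector with a pole vector,
poles split 50/50 between all-methylated and all-unmethylated, direction of
disorder split 50/50 between groups); negative-binomial depth (mean 30,
dispersion 5) with depth-0 loci emitted as missing, so the 75%/10x filter
has real work to do; expression as an affine function of methylation and
epipolymorphism with Gaussian noise; near-pole Beta component methylomes
with Dirichlet mixing and technical noise SD 0.02 (array-scale); random
trees with Brownian-evolved features.

It deliberately omits: genomic sequence context and realistic coordinates
(loci sit on an ordered synthetic chromosome), linkage between neighbouring
e-loci, SNPs, batch effects, purity gradients, and count-level expression
noise. Passing tests therefore demonstrate that the estimators and tests do
what they claim under their own model — not that the model captures every
property of patient methylomes.

Problem sizes used by the test suite and the acceptance script (2,000 loci ×
20 samples × 20 seeds for null calibration; 500 × 30 mixtures; 50 trees up
to 12 leaves; 2,000 nested-model pairs) were chosen as the smallest scales at
which the targeted properties are statistically identifiable.

# Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42, n_patients = 4, regions_per_patient = 3,
                         n_normal = 8, n_eloci = 300, frac_differential = 0.2)
sim <- simulate_epiallele_data(cfg)
prof <- elocus_profiles(sim$counts)
keep <- filter_eloci(prof, samples = sim$samples$sample_id)
de <- diff_epipolymorphism(prof[prof$elocus_id %in% keep, ],
                           stats::setNames(sim$samples$group, sim$samples$sample_id))
table(de$direction)

mix <- simulate_mixture(cfg, m = 400, n = 24)
fit <- deconvolute(mix$D, k = 3, lambda = 1, seed = 42)
round(fit$A[, 1:4], 3)
```

# Known limitations

* The differential test's nominal level is conservative on tied/bounded
  epipolymorphism values at small group sizes (see above); confidence
  statements inherit that conservatism.
* The NMF objective is non-convex; restarts mitigate but do not eliminate
  local minima, and $k$ or $\lambda$ far from the data-supported range can
  absorb noise into extra components.
* APITH assumes exchangeable regions within a patient; spatially structured
  sampling violates that silently.
* The LRT's exact calibration assumes Gaussian residuals on the log2 scale;
  heavy-tailed expression noise shifts it toward the asymptotic behaviour.
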