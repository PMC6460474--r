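---
title: "Edge-level shrunken-centroid classification of a dual-omics plasma secretome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-level shrunken-centroid classification of a dual-omics plasma secretome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsPAM)
```

# The problem

Circulating microRNAs and plasma proteins are secreted from many organ
systems, and in an insulin-resistance phenotype contrast the two secretomes
carry complementary signal: miRNAs that are secreted *less* by a tissue
leave more head-room for the synthesis and secretion of their target
proteins, so a repressive miRNA-target relation should show *negative*
co-expression across subjects, while two physically interacting proteins
should show *positive* co-expression.  omicsPAM implements this
integration: it overlays the two abundance matrices on a signed interaction
network, scores every edge per sample, and asks which edges jointly predict
the phenotype groups.

# The model

## Edge co-expression scores

Both matrices are log2-scaled, preprocessed to completeness, and converted
per feature to Z-scores, $z_{ij} = (x_{ij} - \bar x_i)/s_i$ (sample SD with
$n-1$ denominator by default; an $n$ denominator is available).  For sample
$j$:

* repressive edge (miRNA $m$, protein $p$, sign $-1$):
  $e_j = z_{pj} - z_{mj}$;
* cooperative protein pair ($p_1, p_2$, sign $+1$):
  $e_j = z_{p_1 j} + z_{p_2 j}$.

A repressive edge is therefore large and positive exactly when the protein
sits above and the miRNA below their respective means — the expected
pattern in the insulin-resistant group.  The plain difference/sum is used
by default; `scale = TRUE` divides by $\sqrt 2$ so that independent
unit-variance endpoints give unit-variance edges, which makes edge
variances comparable before shrinkage but departs from the plain formulas,
so it is off by default.

## Nearest shrunken centroids on edges

The classifier is the prediction-analysis (PAM) family model, fitted on the
edge-score matrix.  With overall centroid $\bar x_i$, class centroids
$\bar x_{ik}$, pooled within-class SD $s_i$ (within-class sum of squares
over $n-K$), fudge constant $s_0 = \mathrm{median}(s_i)$ and
$m_k = \sqrt{1/n_k - 1/n}$ (the exact standard-error factor of
$\bar x_{ik} - \bar x_i$; some implementations use $\sqrt{1/n_k + 1/n}$,
available via `mk_variant = "plus"`):

$$d_{ik} = \frac{\bar x_{ik} - \bar x_i}{m_k\,(s_i + s_0)}, \qquad
  d'_{ik} = \mathrm{sign}(d_{ik})\,\max(|d_{ik}| - \Delta,\ 0),$$

$$\bar x'_{ik} = \bar x_i + m_k\,(s_i + s_0)\,d'_{ik}.$$

Classification uses
$\delta_k(x) = \sum_i (x_i - \bar x'_{ik})^2/(s_i+s_0)^2 - 2\log\pi_k$
with empirical priors $\pi_k = n_k/n$ by default, and posteriors
$\propto e^{-\delta_k/2}$.  Every quantity is checked against a naive
loop-based reference implementation in the test suite (200 random small
instances, agreement to $10^{-10}$).

## Threshold selection by repeated cross-validation

$\Delta$ is tuned on a 30-point grid from 0 to $\max|d_{ik}|$ by 10
independent sets of stratified fivefold cross-validation, choosing the
smallest mean misclassification error.

**Plateau ties.**  With 17 samples and strong edges the zero-one CV error
is exactly zero over a wide $\Delta$ plateau: one sufficiently strong edge
already separates the groups, so the error alone cannot locate the right
sparsity, and "largest threshold with minimal error" collapses the model
onto a handful of strongest edges while "smallest" keeps thousands.  We
therefore record the cross-validated posterior log-loss alongside the
error and, among the minimum-error thresholds, keep those whose mean CV
posterior for the true class is at least 0.95 (mean log-loss
$\le -\log 0.95$), i.e. thresholds at which classification is not just
correct but essentially certain, then take the largest of these for
parsimony.  When no tied threshold reaches that confidence — weak or null
signal — the rule falls back to the plain largest-threshold tie-break
(`tie_break = "largest"` forces it).  The 0.95 level is the conventional
"95% certain" operating point; results are insensitive to it across the
zero-error plateau's steep log-loss rise.

The predictive subnetwork is the set of edges with $d'_{ik} \ne 0$ for at
least one class at the chosen threshold, reported with the split into
miRNA-protein regulation versus PPI edges.

## Differential abundance, q-values, enrichment, origin

Per-feature two-sample tests are Welch by default (`"pooled"` optional).
Multiple testing uses Storey q-values: $\hat\pi_0(\lambda)$ on the grid
$0.05, \dots, 0.95$, cubic-smoother extrapolation at $\lambda \to 1$,
clipped to $[0,1]$.  When the raw $\hat\pi_0$ falls below 0.05 the p-value
distribution is dominated by the alternative and cannot be decomposed; the
estimator then emits a structured warning (`omicsPAM_pi0_unstable`) and
the recommended fallback is nominal-p selection — this is why the default
candidate rule is p < 0.01 for miRNAs (where a third of the panel can
shift) and q < 0.05 (strict) for proteins.  Forcing $\pi_0 = 1$
(`pi0_method = "bh"`) reproduces Benjamini-Hochberg exactly.

Enrichment of subnetwork proteins is an upper-tail hypergeometric test
against gene sets intersected with the universe of all quantified proteins
(not the genome; the analysis is protein-level throughout), reported at
nominal p < 0.05 with optional BH adjustment.  Tissue-of-origin calls
require joint mRNA *and* protein evidence in a tissue; a gene whose origin
set contains adipose tissue is an obesity-dependent candidate, a non-empty
non-adipose origin set is obesity-independent, and empty or
vocabulary-wide origin sets stay unresolved.

# Raw-layer preprocessing

*RT-qPCR*: duplicate Ct values are averaged; a per-miRNA least-squares
line $Ct = a + b\log_{10}(\text{copies})$ is fitted on the six-point
10-fold standard series and inverted; samples with averaged Ct later than
the earliest no-template control are undetectable.  Undetected cells are
imputed at the miRNA's minimum detected copy number (rank-preserving, no
fabricated between-group signal; a half-minimum option exists) before
per-sample affine normalization that equalizes the median and SD of log2
copy numbers across samples.  Nonnegative standard-curve slopes or
degenerate series abort with an error — they indicate a broken assay, not
a data point.

*LC-MS peptides*: peptides with $\ge 25\%$ missing cells are removed (the
boundary is inclusive), remaining gaps are filled by distance-weighted
K-nearest-neighbour imputation ($k = 6$ by default, root-mean-square
Euclidean distance over jointly observed samples, only neighbours observed
in the target sample are eligible), samples are median-scaled on the
linear scale, and protein intensity is the sum of its peptides' linear
intensities, stored as log2.  The order — filter, impute, normalize, roll
up — is fixed.  Both normalizations are idempotent by construction (the
targets are the means of the per-sample statistics), which the tests
assert.

# The synthetic cohort generator

No subject-level data are distributed with studies of this design, so the
generator is a first-class module that emulates the study conditions: 9
lean insulin-sensitive versus 8 obese insulin-resistant subjects, 374
miRNAs, 1,499 proteins, a miRNA-target map with a truncated power-law
out-degree distribution (most miRNAs hit few targets, a few are hubs;
$P(d) \propto d^{-2}$, $d \le 50$) plus 1,500 background PPIs.  Twenty
planted miRNA-protein signal edges and five planted co-elevated PPI pairs
carry the group effect: the miRNA falls by `delta_mirna` and the target
protein rises by `delta_protein` (2.5 log2 units each by default, i.e.
2.5 residual SDs at the default $\sigma = 1$) in the OIR-like group —
effects in the middle of the 2-3 SD range that a clearly separable
secretome shift represents.  Planted edges use reserved nodes that carry
no other edges, so each planted edge is an independently verifiable truth
unit; background edges touching planted nodes would otherwise carry
half-strength signal and make edge-level recall/false-discovery
accounting ambiguous.

Raw layers are generated downstream of the true abundances: qPCR plates
(Ct line with intercept 30 at one copy, slope $-\log_2 10 \approx -3.32$
per decade, Gaussian Ct noise SD 0.15, duplicates, six-point standards,
NTC at Ct 38) and peptide tables (each protein split into
$\mathrm{Poisson}(3)+1$ peptides with fixed ionization weights that sum
exactly to the protein intensity; 10% of cells missing completely at
random by default, with an intensity-dependent mechanism behind a flag
since the true mechanism is unknown).  Clinical records draw
insulin/glucose around the two groups' typical means and compute HOMA-IR
$= \text{insulin} \times \text{glucose}/22.5$ exactly per subject.  Note
that group-mean HOMA-IR is *not* the HOMA-IR of the group-mean inputs
(mean of ratios versus ratio of means): for the OIR-like group,
$21.9 \times 4.71 / 22.5 = 4.58$, while a cohort's reported group mean can
legitimately differ (4.53 in the motivating data); only the per-subject
identity is asserted.

All layers are deterministic given the config seed (each generator uses a
fixed offset from it), and subject-level random effects default to off
(additive log2 group effects only), with a `random_effect_sd` flag for
robustness checks.

**What the generator does not emulate**: correlated feature blocks beyond
the planted edges, batch effects, heavy-tailed or intensity-dependent
measurement noise, informative missingness (except behind the flag), and
compositional constraints of qPCR panels.  Passing tests on this cohort
therefore demonstrate correctness of the algorithms and calibration under
the stated model, not robustness to every artefact of real plasma data.

# Numerical choices and degenerate inputs

* Zero-variance features are dropped from Z-scoring with a counted
  warning; zero-variance within both groups yields $p = 1$ (equal means)
  or $p = 0$ with a warning (unequal means) in the t-test.
* Sample Ct ties with the NTC are *not* censored (censoring requires
  strictly later Ct); the 25% peptide missingness boundary *is* removed
  (the rule is "25% or higher").
* Classifier discriminant ties (a sample exactly between two shrunken
  centroids) resolve to the first class level; posteriors report the
  genuine 50/50 split.
* Posterior computation subtracts the row maximum before exponentiation
  (log-sum-exp), and log-loss floors posteriors at $10^{-300}$.
* Edge identifiers are canonical `node1|node2|sign` strings with PPI
  endpoints sorted lexicographically, so positive edges are
  orientation-free and outputs are byte-stable.
* Cross-validation folds are stratified per class with a deterministic
  shuffle from the seed and exported in the result for reproducibility;
  classes smaller than the fold count reduce the fold count with a
  warning.

# Problem sizes used in the checks

The test suite runs the full 374 x 1,499 cohort once for the
planted-subnetwork recovery check (10 x 5-fold CV over 30 thresholds,
about 2,500 edges) and uses cohorts of 40-150 miRNAs and 120-1,500
proteins elsewhere; these sizes were chosen so every property is exercised
at full fidelity while the whole suite stays interactive.  Null
calibration pools 2,000 features, matching the scale at which a
Kolmogorov-Smirnov test is informative.

# Known limitations

* The classifier assumes exchangeable edge noise after standardization;
  strongly dependent edges (shared hub nodes) violate the independence
  heuristic behind the discriminant, which is inherited from the PAM
  family.
* With strong signal the zero-one CV error is uninformative over a wide
  threshold range; the confidence-restricted tie-break above is a
  pragmatic, documented choice, not the only defensible one.
* Tissue-of-origin triage is only as good as the annotation table;
  evidence flags are treated as boolean and unweighted.
* The q-value smoother needs a non-degenerate $\lambda$ grid; with fewer
  than four usable grid points it falls back to the fixed
  $\lambda = 0.5$ estimator.
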