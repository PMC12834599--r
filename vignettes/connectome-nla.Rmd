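---
title: "Network-level inference on parcellated connectomes: models, conventions and design"
author: "nlaconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-level inference on parcellated connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlaconn)
```

# The problem

Population neuroimaging studies relate a predictor (a medication, a
behavioral score) to functional connectivity (FC) measured between all
pairs of regions in a fixed parcellation. With 394 parcels there are
(394² − 394)/2 = 77,421 edges, effect sizes are small, and subjects are
not exchangeable: they cluster by acquisition site and by family.
`nlaconn` implements inference for this setting at three levels —
edges, networks, and cortical maps — plus the power analysis for the
network-level test and a synthetic-data generator that reproduces the
statistical structure the analysis assumes.

# Edgewise marginal model

At each edge \(e\) the Fisher-Z connectivity \(z_{ie}\) of subject
\(i\) is modeled by ordinary least squares on a shared design matrix
\(X\) (intercept, predictor of interest, nuisance covariates — age,
sex, mean framewise displacement by default). Rather than fitting
random effects for site and family — prohibitively expensive across
77k edges — the model is *marginal*: OLS point estimates with standard
errors corrected post hoc for within-cluster dependence by the
Huber–White sandwich estimator

\[ V = (X'X)^{-1}\Big[\sum_g X_g' e_g e_g' X_g\Big](X'X)^{-1}, \]

summed over clusters \(g\). The cluster-robust t-value is
\(\hat\beta / \sqrt{V_{jj}}\). Conventions:

* **Clustering variable.** The reference analysis corrects "for site
  and family" without stating the estimator's exact grouping. The
  package defaults to *site*, the coarsest level of the site/family
  nesting: robust variances at the coarser level absorb dependence at
  every nested level, so family dependence is covered. `"family"` and
  `"family_within_site"` are available (`build_design(cluster_by = )`).
* **Small-sample factor.** CR0 (no correction) is the default, matching
  the classic estimator; CR1 (\(G/(G-1)\cdot(n-1)/(n-p)\)) is available.
  At cohort scale (thousands of subjects, ~20 sites) the factor is
  immaterial; at test scale it is exercised explicitly.
* **Degenerate designs** (rank deficiency, a single cluster, \(n \le p\))
  are typed errors, not warnings.

## Wild cluster bootstrap

Edgewise and network-level inference share one null distribution,
generated by the *restricted* (null-imposed) wild cluster bootstrap:
fit the model without the interest column, then form bootstrap outcomes
\(y^* = X_r\hat\beta_r + v \odot \hat e_r\) with Rademacher signs
\(v_g \in \{-1, +1\}\) drawn once per *cluster* (per-subject signs
would destroy exactly the within-cluster dependence the procedure must
preserve), refit the full model and record the cluster-robust t of the
interest coefficient. Two contracts matter:

* **Shared signs across edges.** Within a replicate the same cluster
  signs apply to every edge, so the \(B \times E\) null matrix carries
  the true between-edge dependence — this is what makes the
  Westfall–Young correction below valid.
* **Closed form.** The per-replicate refit reduces algebraically to
  products of per-cluster score matrices with the sign matrix (the
  restricted fitted values are annihilated by the full-model residual
  projection), so no replicate ever refits anything. The test suite
  asserts bitwise-level agreement (1e-10) with a literal
  refit-every-replicate oracle.

Bootstrap p-values use the as-printed convention \(p = \#\{|t^*| \ge
|t|\}/B\): ties count against rejection, and \(p = 0\) is possible. A
\((k+1)/(B+1)\) estimator is available everywhere the convention
appears (edgewise, network, spin).

# Network Level Analysis

Edge-level signals are aggregated into canonical networks. Small
related networks are merged first (five motor-related systems into SM;
salience + parietal memory into SAL/PMN; lateral + medial visual into
VIS), because the enrichment test is biased toward families with many
edges. For every unordered pair of merged networks (within-network
pairs included) the pair's edgewise t-values are compared with the
whole connectome's by Welch's t

\[ t_W = \frac{\bar a - \bar b}{\sqrt{s_a^2/n_a + s_b^2/n_b}}; \]

positive values mean enrichment, negative depletion. Separately, each
whole network is tested one-sidedly on \(|t|\) over its edges.
Conventions and decisions:

* **Reference group.** The connectome-wide comparison group *includes*
  the pair's own edges, exactly as the procedure is described in the
  source analyses; validity rests on the bootstrap null (the observed
  statistic is exchangeable with null statistics computed identically),
  not on two-sample independence. A disjoint-complement option exists.
* **Whole-network edge set.** "Edges in a network" is read as edges
  *incident* to the network's parcels (consistent with row-wise RMS
  maps); a within-only variant is provided
  (`whole_network_enrichment(edges = "within")`).
* **Two families.** Pairs (two-sided on the Welch statistic) and whole
  networks (one-sided, since depletion of \(|t|\) is not interpreted)
  are corrected separately — they are reported as separate analyses.
* **Degenerate cases.** Pairs with fewer than two edges are excluded
  from the correction family (statistic `NA`). If all values in group
  and reference are identical (0/0), the statistic is 0 by convention.

FWER control is the Westfall–Young step-down (maxT): hypotheses ordered
by decreasing statistic; the adjusted p at rank \(r\) is the fraction of
null replicates whose maximum over hypotheses ranked \(\ge r\) reaches
the observed value; monotonicity is enforced down the ordering, and
ties in observed statistics are broken by hypothesis index. The null
statistics are the pair/network Welch statistics recomputed on every
bootstrap replicate's edge t-vector.

# Brain maps and spin tests

From an edge statistic vector the package derives per-parcel maps: the
RMS magnitude map (root mean square of the \(n-1\) incident edge
values — even in the statistic's sign), seed maps (one parcel's matrix
row, seed entry masked), and row-wise FC correlation maps (per-parcel
Pearson correlation of incident rows from two analyses, constant rows
masked rather than fatal). Maps are computed on the full parcel set;
cortex-only views are masks applied afterwards. Display thresholding
(e.g. 50th–95th percentile) is strictly cosmetic and never precedes
statistics.

Map similarity is tested against a rotational null: random rotations
(Haar-uniform via sign-corrected QR) applied to the cortical parcel
centroids, the right hemisphere receiving the left's rotation mirrored
through the sagittal plane; each parcel takes the value of the nearest
original centroid (great-circle distance, per hemisphere, repeats
allowed — this is how missing-data regions are absorbed). Subcortical
parcels are excluded: the comparisons are cortex-only. The two-tailed p
counts \(|r| < |r_\emptyset|\) strictly, over N = 2,000 rotations by
default.

Whether the original procedure rotated one map or both per iteration is
ambiguous in its description ("correlations between each pair of null
maps"); the package defaults to rotating both independently and exposes
`mode = "rotate_one"`. One implementation subtlety: so that
`spin_test(a, b)` and `spin_test(b, a)` are exactly identical under the
same seed, the two per-iteration rotations are assigned to the maps in
a canonical order based on their affine-normalized values rather than
argument order (Pearson correlation is symmetric, so nothing else
changes; the canonical form is z-scored with a fixed overall sign, so
the ordering — and hence the p-value — is invariant to affine
rescaling of either map).

# Power analysis

The power of the network-level test to detect a standardized effect
\(d\) concentrated in a network of \(n_{net}\) edges is forecast by

\[ t_{net} = \frac{d/\sigma_{stim} - \bar t}{\sigma_t/\sqrt{n_{tot}} +
\sigma_t/\sqrt{n_{net}}} \]

with \(\sigma_{stim}\) the design SE of the interest coefficient (the
square root of its \((X'X)^{-1}\) diagonal element), \(\bar t\) and
\(\sigma_t\) the mean and SD of connectome t-values. The default
constants are the reference cohort's: \(\sigma_{stim} = 0.058\),
\(\bar t = 0.031\), \(\sigma_t = 1.35\), \(n_{tot} = 77{,}421\), with
the attention/control family DAN/VAN/FPN = 496/253/276 within-network
edges. Decisions:

* The printed expression is typeset ambiguously; the denominator is
  implemented token-for-token as the *sum* of the two standard-error
  terms, with a quadrature variant behind
  `denominator = "quadrature"`.
* \(t_{net}\) is ranked one-sided against a null family of Welch
  statistics with Westfall–Young correction; "power = 1 − P" is a
  rank-based surrogate for power, implemented exactly as described and
  documented as such (it is not a classical power integral).
* The conversion \(d = t/\sqrt{n}\) reproduces the reference value
  (d = 0.89 from t = 4.35 at n = 24) and is used for effect-size input.
* Since the original data-derived bootstrap null is not distributable,
  `welch_null_synthetic()` draws edge t-values i.i.d. with mean
  \(\bar t\) and SD \(\sigma_t\) and computes within-network Welch
  statistics per replicate. It matches the null's first two moments but
  not its spatial dependence, so tabulated minimum detectable effects
  from the original cohort are not expected to be reproduced digit for
  digit — the package's power claims are made against its own
  explicitly-constructed null.
* `min_detectable_d()` bisects the (non-decreasing) power curve to a
  1e-4 tolerance and signals unattainable targets.

```{r power}
n_nets <- c(DAN = 496, VAN = 253, FPN = 276)
nul <- welch_null_synthetic(n_nets, B = 2000, seed = 7)
c(t_net = t_net_formula(0.89, 496),
  power = power_at_effect(0.89, n_nets, nul, network = "DAN"))
```

# The synthetic-data generator

The generator is not a fixture factory: it defines the study conditions
under which the pipeline's statistical guarantees are tested.

* **Parcellation.** 333 cortical + 61 subcortical parcels by default.
  Cortical parcels live on a unit sphere per hemisphere (as after
  spherical registration), placed on a Fibonacci lattice; the right
  hemisphere mirrors the left. Networks are Voronoi caps of random seed
  directions — *contiguous*, so network membership carries spatial
  autocorrelation. Independent random labels would make spin nulls
  trivially exchangeable and network tests unrealistically easy; caps
  are the honest regime. Subcortical parcels have no centroids and are
  excluded from spin tests.
* **Cohort.** Subjects nested in families nested in sites (a family
  never straddles sites; uneven site sizes). Stimulant prevalence
  defaults to 5.8% — the day-of-scan prevalence in the cohort being
  emulated, ~337 takers among 5,795 — and sleep is an ordinal 1–5
  score. Nuisance covariates (age in months, sex, mean FD, a
  socioeconomic z-score) have plausible but arbitrary marginals.
* **Connectivity.** \(z_{ie} = \mu_e + \beta^{stim}_e stim_i +
  \beta^{sleep}_e sleep_i + \beta^{int}_e stim_i sleep_i + a_{site(i),e}
  + b_{fam(i),e} + \epsilon_{ie}\), with within-network baseline 0.30
  and between-network baseline 0.05 (Fisher-Z). The default truth
  plants the reference sign pattern: −0.030 on within-SM edges and
  +0.030 on SM–SAL/PMN for stimulant, −0.011 per sleep unit on
  within-SM. Those blocks cover a small fraction of edges, so the
  planted magnitude sits at the upper tail (≈98th percentile) of
  |β| across edges, anchoring recovery tests to reported effect sizes.
* **Free parameters.** Intra-site/intra-family dependence magnitudes
  are not reported anywhere usable; the defaults `site_sd = 0.04`,
  `family_sd = 0.04`, `noise_sd = 0.17` give an intraclass correlation
  of ≈10% and, at the reference prevalence, edgewise |t| of ~2 for the
  planted effects at n = 2,000 — individually marginal, clearly
  detectable only by network aggregation, which is the scientific
  regime of interest. `noise_sd = 0.17` makes β = −0.030 correspond to
  a Cohen's d of ≈0.17, matching the reported d for the 98th-percentile
  stimulant effect.
* **Time series.** Per subject, Gaussian series whose population
  correlation is the inverse Fisher-Z of the subject's target
  connectivity, so `fisher_fc()` recovers targets at the
  \(1/(n_{frames}-3)\) Fisher rate; FD traces carry Bernoulli motion
  spikes above the 0.2 mm threshold. Non-positive-definite targets are
  a typed error with shrinkage as the documented remedy. The generator
  makes no attempt at realistic BOLD spectra, drift or respiration —
  it exists to exercise censoring and correlation, not to simulate
  physiology.
* **Reference maps.** Network indicators plus smooth noise built from
  random spherical bumps evaluated at left-equivalent coordinates, so
  maps are bilaterally symmetric and their per-hemisphere law is
  rotation invariant — the exchangeability regime the mirrored-rotation
  spin test assumes (real cortical maps are approximately bilaterally
  symmetric in the same way).

What passing tests on this generator do **not** show: robustness to
non-Gaussian edge noise, heavy-tailed motion, site-by-effect
interactions, spatially graded (rather than block) effects, or real
parcellation geometry. They do show that the estimators, bootstrap,
step-down correction and spin test are correctly implemented and
calibrated under the dependence structure the methods were designed
for.

# Preprocessing conventions

Framewise displacement is the L1 norm of the six rigid-body parameter
steps, rotations converted at the field-standard 50 mm head radius;
the first frame's FD is 0. Respiratory filtering of motion parameters
is deliberately out of scope (its design is unspecified in the source
analyses); FD is computed on parameters as given. Censoring drops
frames with FD strictly above 0.2 mm (a frame exactly at threshold is
retained — exclusion is stated as "FD > 0.2 mm"), with no
interpolation, and subjects retaining fewer than 600 frames (8 min at
TR 0.8 s) are flagged excluded via a typed signal, never silently
truncated. Correlations with |r| = 1 (collinear parcels) and constant
series are errors, not NaNs.

# Problem sizes in the test suite

The statistical suites run at sizes chosen to give stable Monte-Carlo
estimates while keeping the default test run in minutes: calibration
under a global null uses 200 simulations of 300 subjects × 60 parcels
(1,770 edges) at B = 500, with a binary predictor at prevalence 0.2 —
at n = 300 the study-condition prevalence of 5.8% would leave ~17
positive subjects, too few to probe calibration rather than sparsity;
recovery uses 50 simulations of 2,000 subjects at the study prevalence;
spin calibration uses 200 experiments of 200 rotations. The closed-form
bootstrap makes these sizes cheap: a full B = 500 bootstrap over 1,770
edges costs well under a second.

# Known limitations

* The marginal model assumes cluster-level exchangeability is fully
  captured by the chosen clustering variable; crossed (non-nested)
  dependence is not supported.
* The bootstrap p floor of 0 (as-printed counting) understates evidence
  near the resolution 1/B; use `p_method = "plus_one"` when that
  matters.
* The spin test inherits the usual caveats of rotational nulls:
  nearest-parcel reassignment duplicates sources, and calibration is
  approximate for maps whose spatial law is far from isotropic.
* `welch_null_synthetic()` ignores spatial dependence between edges;
  power against it is a forecast, not a reanalysis of any cohort.
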