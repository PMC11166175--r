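---
title: "Dose-response phMRI and resting-state network analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response phMRI and resting-state network analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

phbold implements the two arms of an awake-rodent pharmacological MRI
(phMRI) study design: an *activation arm* that maps acute dose-dependent
BOLD signal changes after drug injection, and a *resting-state arm* that
maps changes in inter-regional functional connectivity. Because raw scanner
data for such studies is rarely distributable, the package ships a phantom
generator that simulates both session types over a synthetic atlas with
known ground truth, so that every downstream stage can be tested as a
parameter-recovery problem.

## The activation arm

### Percent change and the windowed t-test

A phMRI session is a 4D BOLD series of `NR` acquisitions (default 350 at
TR 6 s, a 35-minute session). The drug is injected after scan 50: scans
1–50 form the **control window**, scans 51–350 the **stimulation window**.
For each voxel with control-window mean $b$, the per-scan percent change is

$$\Delta_t = 100\,(s_t - b)/b,$$

and the per-voxel summary is the mean of $\Delta_t$ over the stimulation
window. Voxels with numerically zero baseline are flagged and excluded
rather than propagating NaN.

Each voxel is then tested with a two-sample Welch *t*-test
(heteroscedastic, two-tailed) between its control-window and
stimulation-window samples, with Welch–Satterthwaite degrees of freedom.
Two modelling caveats are deliberate and documented rather than "fixed":
the sampling unit is the scan, and temporal autocorrelation is ignored, to
match the source procedure this pipeline reproduces. The permutation-test
oracle in the test suite quantifies how closely the parametric p-values
track an exchangeability-based reference on white-noise voxels.

### The rank-based false-positive filter

With roughly $V$ in-brain voxels tested per subject, per-voxel p-values are
screened with a step-up rule: sort the p-values ascending and find the
largest rank $i$ such that

$$P_{(i)} \le \frac{i}{V}\,\frac{q}{c(V)},$$

then declare every test with $p \le P_{(i)}$ significant. With $c(V)=1$
and $V$ equal to the number of tests this is the Benjamini–Hochberg
procedure at level $q$; the shipped defaults are $q = 0.2$ and $c(V) = 1$.
Tied p-values are evaluated at their highest applicable rank, so ties enter
or leave the significant set together. `V` defaults to the in-brain voxel
count for voxel maps and to the number of atlas regions (173) for region
tables; both are configurable, and per-region filtering is available by
passing a per-region `V`.

Significant voxels retain their percent-change values (`filtered_pct`);
everything else is set to zero. A voxel enters the **positive** tally iff
it is significant *and* its percent change is at least the baseline
threshold (+1% by default); **negative** analogously. The 1% threshold is
interpreted as a minimum percent-change magnitude for classification — the
same role the ±1% guide lines play in drug-vs-vehicle time-course figures.

### Volume-of-activation tables

Per-region activated-voxel counts (one arm at a time) are compared across
dose groups with Kruskal–Wallis tests (tie-corrected H, chi-square
p-values; an exact exhaustive-permutation p is available for total
N ≤ 8). Regions with p < 0.05 are retained and ranked ascending by
p-value, with per-group medians and a direction symbol. Group medians are
reported as the *lower* middle value for even group sizes, matching
integer medians in published count tables. Pairwise tables (vehicle vs one
dose) use the two-group test; a three-group omnibus is available.

Alongside each table the package reports the **descriptive FDR critical
value** $i\,q/(V\,c(V))$, where $i$ is the number of retained rows — the
critical p-value the step-up rule would use at that rank. This descriptive
quantity is distinct from the per-voxel step-up mask; both are exposed
separately to avoid conflation.

### Composite maps and time courses

Group composite percent-change maps are built in the atlas frame. Each
subject stores a 4×4 affine (translation·rotation·scale) that maps
*composite coordinates into the subject's frame* — the direction implied by
filling the composite through the inverse of the subject-to-atlas
registration. For every composite voxel, each subject is sampled at the
transformed coordinate with trilinear interpolation and the available
contributions are averaged. Out-of-volume samples contribute *nothing*
(averaging in zeros would bias composites toward null); the contributor
count is recorded per voxel. Coordinates are 0-based continuous voxel
indices, which avoids any world-coordinate convention the inputs do not
carry; points within 1e-9 of the volume boundary are clamped onto it so
that numerically-composed transforms (e.g. $T T^{-1}$) round-trip.

Pooled regional time courses are compared with a two-way mixed ANOVA
(between factor: treatment; within factor: scan; subjects nested in
treatment); the interaction F is the statistic of interest. An optional
binning factor averages consecutive scans first — useful because a
350-level time factor is both slow and noisy; the package leaves the
choice to the caller. If the within-cell error sum of squares is
numerically zero the F statistic is defined as 0 (identical traces) or
infinity (planted divergence with no noise).

## The resting-state arm

Sessions are 200 scans at TR 1 s. The processing chain is: zero-phase
(forward–backward) 4th-order Butterworth band-pass at 0.01–0.1 Hz →
nuisance regression (intercept + six motion parameters + mean white-matter
and CSF traces + per-scan spike indicators for motion outliers, ordinary
least squares) → node averaging over atlas regions → all-pairs Pearson
correlation → Fisher Z ($\mathrm{atanh}$, with |r| clipped to
$1 - 10^{-7}$).

Each series is demeaned before filtering. DC is in the filter's stopband,
so this changes nothing in exact arithmetic — but with a large common
baseline the forward–backward filter's edge transients are otherwise
shared across every series and can correlate all node pairs at $r \approx
1$. Band-passing a TR 6 s phMRI series at 0.1 Hz is rejected (Nyquist is
1/12 Hz).

Group edge maps are one-sample t-tests of the subjects' Fisher-Z values
against zero, per edge. The conversion from t to the reported **Z score**
is not standard across tools; phbold uses the inverse-normal of the
two-tailed p-value with the t's sign restored, which puts edges on the
common standard-normal scale the fixed threshold |Z| = 2.3 expects. |Z| is
capped at 8 (edges with zero cross-subject variance and nonzero mean hit
the cap and are flagged degenerate).

Thresholding keeps $A_{ij} = |Z_{ij}|$ where $|Z_{ij}| \ge 2.3$ (edges are
undirected; negative couplings count through their absolute value), or 1/0
when binarised. **Degree centrality** is the binarised row sum
$C_D(j) = \sum_i A_{ij}$ — the number of connections a node has — with the
weighted row sum (strength) exposed as a secondary output.

"K-nearest-neighbour clustering" of a connectivity matrix is
underdetermined as a phrase; phbold implements the deterministic
mutual-kNN variant: each node's matrix row is its feature vector, cosine
similarity ranks neighbours, an edge survives only if both endpoints rank
each other within the top k (ties at the k-th similarity are included, so
block-constant matrices behave sensibly), and clusters are the connected
components. k defaults to ⌈√n⌉. There is no random initialisation, so
results are exactly reproducible.

Subnetwork analyses mirror the two published figure types: set-to-set edge
counts (e.g. thalamic nuclei × sensory cortices) and first-neighbour sets
of a seed group (e.g. the cerebellar nuclei), reported as a fraction over a
supplied union node list. Degree vectors are compared across conditions
with a Shapiro–Wilk-gated branch: normality not rejected → paired t-test,
otherwise Wilcoxon signed-rank (exact for n ≤ 25 after dropping zero
differences). Pairing is **by region**: the dose groups are independent
animals with unequal n, so subject-wise pairing does not exist; this is an
explicit interpretation of "paired" comparisons between groups over a
common region set.

### Node-count bookkeeping

The published description of this analysis is internally inconsistent
about the node count: 173 atlas regions, "166 × 166" matrices, and
"14 535 pairs" — the last corresponds to 171 nodes, since
$\binom{171}{2} = 14535$ while $\binom{166}{2} = 13695$. phbold makes the
node list configurable (the default excludes the "other" macro region,
standing in for non-neural regions excluded from connectivity analyses),
and `n_node_pairs()` exposes the bookkeeping so both published counts can
be checked explicitly.

## The phantom

### What it emulates

- **Atlas**: `generate_atlas()` grows compact contiguous regions from
  seeded voxels (nearest-seed assignment) inside an ellipsoidal brain mask;
  region count defaults to 173. Macro-region labels (cortex, olfactory,
  thalamus, …, cerebellar_nuclei, other) cycle across regions so every
  downstream grouping is exercised.
- **phMRI sessions**: every voxel starts at a baseline (1000 a.u.);
  affected regions follow a linear ramp from the injection (end of the
  control window) to a plateau of sign × magnitude × dose-multiplier
  percent change. The linear-ramp-to-plateau shape is the simplest
  response with a controllable plateau, enabling exact recovery tests; the
  published time courses constrain a sustained post-injection shift but
  not its kinetics. Defaults: 32 negative regions at −3%, 6 positive at
  +2%, dose multipliers 0 / 0.4 / 1 for Veh / LSD10 / LSD100, Gaussian
  noise of 1.5% of baseline with AR(1) autocorrelation ρ = 0.3, and a
  small linear drift. The vehicle multiplier is pinned at exactly 0.
- **Resting-state sessions**: latent node signals are drawn from a
  multivariate normal with the spec's target correlation matrix (validated
  symmetric, unit-diagonal, positive semi-definite; the offending
  eigenvalue is named otherwise), written into every voxel of the node's
  region, plus nuisance structure with known loadings and independent
  voxel noise. Population correlations equal the target exactly;
  common linear filtering preserves them.
- **Cohorts**: group sizes default to 10 / 9 / 12 (vehicle / low / high),
  the post-exclusion sizes of the study design this mirrors, with unique
  per-subject seeds. All generators are bit-reproducible given a seed.

### Planted connectivity conditions

The default resting-state targets hold two planted contrasts:
thalamo-cortical coupling (5 + 5 nodes, within-set r = 0.7; cross-set 0.7
/ 0.45 / 0.2 for high / low / vehicle) and a cerebellar-nuclei hub (2
nuclei, mutual r = 0.7, coupled 0.35 / 0.2 / 0.1 to 6 brainstem partner
nodes). Two of these numbers deserve justification:

- *Hub coupling 0.35*: a star of 2 hubs coupled equally to 6 independent
  partners is positive semi-definite only while the coupling stays below
  ≈ 0.36; 0.35 is the strongest feasible planted hub at these set sizes.
- *Voxel noise sd 4* (latent amplitude 1): after node averaging this
  attenuates observed correlations by roughly a third. The choice puts the
  vehicle-level coupling near the detection limit of the n = 10 one-sample
  group test at |Z| = 2.3 while leaving drug-level coupling comfortably
  above it — the regime in which the fixed threshold actually
  discriminates conditions. With low noise, even r = 0.2 is detected at
  every edge and both groups saturate, which would make any planted
  *difference* unrecoverable in principle, not just in practice. The
  resulting voxel-level contrast-to-noise (≈ 0.25) is in the low range
  realistic for single-shot rodent EPI.

### What it does not emulate

No k-space or acquisition physics, no motion (inputs are pre-aligned by
contract), no slice timing, no physiological (cardiac/respiratory) noise
spectra, no haemodynamic response convolution, no registration estimation
(transforms are inputs), and no spatial noise correlations beyond those
introduced by smoothing. Passing recovery tests on this phantom therefore
demonstrates that the statistics recover what they are defined to recover —
not that the pipeline is robust to every artefact of real awake-rodent
data.

## Numerical choices

- Welch t degenerate cases: zero variance in both windows gives t = 0,
  p = 1 for equal means, and p = 0 with a degeneracy flag otherwise.
- Step-up ties share their maximum rank; the mask is reported in input
  order; NA p-values are never significant.
- Fisher Z clips |r| at $1 - 10^{-7}$; group Z caps |Z| at 8.
- Trilinear sampling is strict outside $[0, d-1]$ per axis (missing, not
  extrapolated), with a 1e-9 boundary clamp for transform round-off;
  singleton axes are handled by clamping the upper neighbour (its weight
  is zero).
- Gaussian smoothing uses a separable kernel truncated at 3σ and
  renormalised (unit mass), zero-padded at boundaries; FWHM 0 disables it.
- AR(1) noise starts from its stationary distribution, so the marginal
  variance is exact at every scan.
- Detrending removes the full-series linear fit and re-adds the
  control-window mean, keeping percent change interpretable.

## Problem sizes

The package's stated simulation scale is a 20 × 20 × 12 grid (≈ 2000
in-brain voxels) with 173 regions — the voxel count is ~6% of a real
whole-brain session, chosen so that full-cohort simulations (31 subjects ×
350 scans) and replicated recovery studies run on a laptop. The test suite
uses this scale for cohort-level checks and smaller grids for unit tests;
the analysis scripts under `analysis/` run the same scale end-to-end.

One consequence of shrinking the grid is that atlas regions span only
about 3 voxels per axis (vs ≈ 6 in a real whole-brain session), so a
spatial smoothing kernel of realistic physical width mixes region signal
into background far more aggressively than in real geometry — enough to
push a −1.2% low-dose plateau below the 1% classification threshold. The
desk-scale default profile therefore disables smoothing
(`smoothing_fwhm_mm = 0`); the smoothing operator itself (separable
Gaussian, stated FWHM) remains available and is tested independently, and
callers analysing realistically sized volumes should set the kernel to
the acquisition's value (0.8 mm is typical here).

## Known limitations

- The per-voxel t-test ignores temporal autocorrelation (by design, to
  match the reproduced procedure); its p-values are anti-conservative on
  strongly autocorrelated data, which the step-up filter only partially
  absorbs.
- The mixed ANOVA uses Type I sums of squares via `aov()`; with unequal
  group sizes the interaction test is the standard but not unique choice.
- The mutual-kNN clustering is one of several defensible readings of
  "k-nearest-neighbour clustering"; results depend on k.
- Region-paired degree comparisons inherit the usual caveat that regions
  are not independent observations.
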