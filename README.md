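# phbold

Pharmacological MRI (phMRI) activation mapping and resting-state network
analysis for awake-rodent dose-response studies, with synthetic phantoms.

## What problem this addresses

In an awake-rodent phMRI experiment a drug (here, vehicle vs a low and a
high dose) is injected mid-session while BOLD signal is recorded
continuously, and a separate resting-state session measures
inter-regional functional connectivity afterwards. The analysis questions
are: *which atlas regions show dose-dependent positive or negative BOLD
changes*, and *which inter-regional couplings change with dose*. phbold
implements the full analysis chain for both arms, and — because animal
imaging datasets are usually unavailable — a phantom generator that
simulates both session types over a synthetic atlas with known ground
truth, so the whole pipeline is testable as parameter recovery.

The package is aimed at imaging methodologists who want a reproducible,
scriptable version of this analysis style, and at anyone who needs a
ground-truthed 4D BOLD phantom to exercise region-level statistics.

## The statistics at the core

**Activation arm.** Per voxel, percent change
`Δ_t = 100·(s_t − b)/b` against the pre-injection baseline `b`
(control window, scans 1–50 of a 350-scan TR 6 s session), a two-tailed
Welch *t*-test between the control and stimulation windows, then a
rank-based step-up false-positive filter over the V in-brain voxels:
significant are the tests at ranks up to the largest *i* with

    P_(i) ≤ (i/V) · q / c(V),        q = 0.2, c(V) = 1.

Significant voxels keep their percent change, all others are zeroed, and a
voxel counts as activated (positive/negative) only if its percent change
also exceeds the ±1% baseline threshold. Per-region activated-voxel
counts ("volume of activation") are compared across dose groups with
Kruskal–Wallis tests and ranked by p-value; each table carries the
descriptive FDR critical value `i·q/(V·c(V))` for its row count `i` out of
V = 173 regions. Group composite maps are assembled by sampling each
subject through its affine registration transform with trilinear
interpolation; group time courses are compared with a mixed
treatment × scan ANOVA.

**Resting-state arm.** 0.01–0.1 Hz zero-phase Butterworth band-pass,
nuisance regression (motion, white matter, CSF, spike indicators), node
averaging over atlas regions, all-pairs Pearson r → Fisher Z, one-sample
group t-tests per edge converted to signed Z scores, |Z| ≥ 2.3
thresholding into an undirected graph, degree centrality
`C_D(j) = Σ_i A_ij`, mutual-kNN clustering, subnetwork edge counts and
first-neighbour fractions, and Shapiro-gated paired-t / Wilcoxon degree
comparisons.

See `vignettes/phmri-pipeline.Rmd` for the model assumptions, parameter
defaults and numerical choices.

## Worked example

```r
library(phbold)

atlas  <- generate_atlas(dims = c(20, 20, 12), n_regions = 173, seed = 1)
design <- scan_design()          # 350 scans, TR 6 s, windows 1-50 / 51-350
print(design)

effect <- default_effect_spec(atlas)   # 32 regions -> -3%, 6 -> +2%, noise 1.5%
series <- simulate_phmri(atlas, design, effect, group = "LSD100", seed = 42)
map    <- activation_analysis(series, atlas, design)
print(map)

counts <- classify_and_count(map, atlas, design)
head(counts[counts$negative_count > 0, ], 3)

x <- fdr_critical_value(18, fdr_params(q = 0.2, c_V = 1, V = 173))
sprintf("descriptive FDR critical value for 18/173 rows: %.3f",
        attr(x, "rounded"))
```

This prints:

```
phMRI scan design: 350 reps, TR 6 s (35 min session)
  control window: scans 1-50; stimulation window: 51-350
  baseline threshold: 1%
Activation map 'LSD100': 2000 in-brain voxels tested (V=2000, q=0.2), 1299 significant (115+, 503-)
  region_id positive_count negative_count
1         1              0             29
2         2              0             14
3         3              0             22
descriptive FDR critical value for 18/173 rows: 0.021
```

Reading it: the simulated high-dose subject has 2000 in-brain voxels; the
step-up filter at q = 0.2 passes 1299 of them, of which 503 are also below
−1% percent change (negative BOLD) and 115 above +1%. The planted negative
regions (ids 1–32) collect those negative voxels — region 1 has 29 of
them. A ranked group table with 18 significant rows out of 173 regions
would be annotated with the descriptive FDR critical value 0.021.

The end-to-end study lives in `analysis/`:

```sh
Rscript analysis/01_simulate.R            # phantom cohort -> scratch/phantom
Rscript analysis/02_activation_voa.R      # activation maps + ranked VOA tables
Rscript analysis/03_composite_timecourse.R# composites + interaction ANOVA
Rscript analysis/04_rsfc_networks.R       # connectivity, graphs, degrees
```

Tables land under `results/`, volumes and other bulky artifacts under
`scratch/`.

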