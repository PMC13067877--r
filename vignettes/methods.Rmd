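---
title: "Methods: in silico proarrhythmia risk scoring with arscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico proarrhythmia risk scoring with arscore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Drug-induced Torsades de Pointes and related ventricular arrhythmias are a
leading cause of compound attrition in drug development. QT-interval or
hERG-block screening alone misclassifies compounds such as amiodarone that
prolong repolarization without being torsadogenic. `arscore` implements a
composite, population-based in silico assessment: a virtual population of
human ventricular cardiomyocyte models is exposed to a compound at
multiples of its effective free therapeutic plasma concentration (EFTPC),
eight action-potential instability biomarkers are detected per cell, and a
weighted Arrhythmic Risk Score (ARS) per compound is classified into low,
borderline or high risk by two optimized thresholds.

# Cellular model

The cellular substrate is the O'Hara–Rudy (2011) dynamic model of the
undiseased human ventricular endocardial myocyte:

$$C_m \frac{dV_m}{dt} = -I_{tot} + I_{stim},$$

with $I_{tot}$ the sum of INa, INaL, ICaL, Ito, IKr, IKs, IK1, INaCa,
INaK, IpCa and the background currents, $C_m = 1\,\mu F/cm^2$ (currents
per unit capacitance). Nine maximal conductances (the eight drug-target
currents plus INaL) carry multiplicative scale factors, the hooks used by
both the population sampler and the pore-block drug model.

Integration is fixed-step at $\Delta t = 0.02$ ms with Rush–Larsen
exponential updates for all 31 gating variables (each obeys
$dx/dt = (x_\infty - x)/\tau_x$) and forward Euler for voltage,
concentrations and CaMKII. The implementation was validated against the
published model's operating point: after pacing to the limit cycle the
state matches the canonical values (diastolic $V_m \approx -88.0$ mV,
$[K^+]_i \approx 144.8$ mM, $[Ca^{2+}]_i \approx 8\times10^{-5}$ mM,
APD90 $\approx 268$ ms at a basic cycle length of 800 ms), the diastolic
$|dV/dt|$ at the limit cycle is below $10^{-3}$ mV/ms, and the NCX cycle
satisfies detailed balance at its reversal potential (the four King–Altman
occupancy sums were re-derived from the transition graph and checked
against a direct master-equation solve).

**Pacing protocol.** A rectangular 2-ms stimulus at twice the excitation
threshold, delivered at 75 bpm (BCL 800 ms). The threshold is bisected per
model from the published resting state (`find_stimulus_amplitude`), giving
about 28.5 µA/µF for the baseline cell; a fixed-amplitude mode exists for
speed. The full protocol is a train of 500 stimuli; the desk-scale default
is 50 beats with a drift guard that records the APD90 spread over the last
beats (about 0.07 ms for the baseline cell, so limited pre-pacing is
auditable rather than silent). All results in the test-suite and the
acceptance script use these desk-scale sizes; they are the package's
default study conditions, and the 500-beat protocol remains one argument
away.

# Virtual population

Conductance factors for the nine scaled currents are sampled by Latin
hypercube over $[0.2, 3.0]$ (−80% to +200% of reference). Each model is
paced, then passed through two filters **in order**:

1. **Stability** — exclusion reasons `alternans` (one of the last three
   APD90s deviating more than 5% from both others), `repolarization
   abnormality` (an EAD on the last beat, or failure to repolarize below
   −50 mV), `self_stimulation` (diastolic $dV/dt$ above 0.01 mV/ms).
   These reuse the B6, B7/B3 and B1 detectors in a drug-free context.
2. **Calibration** — the five features RMP, APA, APD20, APD50, APD90 must
   lie inside the experimental 5th–95th percentile bands
   (RMP −95..−85 mV, APA 102.7..116.4 mV, APD20 138..188 ms,
   APD50 181..251 ms, APD90 250..331 ms), inclusive at both ends.

**A caveat the user should know.** With the standard amplitude convention
APA = peak − RMP, the unscaled endocardial O'Hara–Rudy model has
APA ≈ 127 mV, above the experimental band, and a grid scan shows the
five bands are jointly satisfiable only in a small corner of the scaling
cube (roughly INa and ICaL near 0.2–0.4 of reference with moderate IKr
reduction). A desk-scale population therefore accepts very few (often
zero) models under the default bands. The package reports the strict
filter verdict rather than adopting an unpublished amplitude convention
that would pass the baseline; users calibrating against their own
recordings can supply any bands via `calibration_ranges()`. Tests that
exercise the population→drug→detector mechanics use explicitly supplied
wider bands for exactly this reason.

# Pharmacology

Drug action is the static pore-block model: at concentration $C$ the
remaining conductance fraction is

$$B_k = \frac{1}{1 + (C/IC_{50})^n},$$

applied multiplicatively to each target current's scale factor
(`apply_drug` is pure; repeated application composes multiplicatively in
the factors, not additively in concentration). The packaged library
(`drug_library()`) carries the ten reference compounds' per-current
IC50/Hill pairs, EFTPCs and risk labels (proarrhythmic: amiodarone,
bepridil, dofetilide, flecainide, moxifloxacin, quinidine;
non-proarrhythmic: diltiazem, mibefradil, verapamil; borderline: sotalol);
"∞" entries (no measured block) round-trip as the string `"inf"`. Each
compound is probed at 1×, 3×, 10×, 30× and 100× EFTPC.

# Biomarkers B1–B8

Per cell and concentration, eight detectors flag instability on the
recorded beats (all inequalities strict; boundaries do not flag):

| Flag | Event | Rule (defaults) |
|------|-------|-----------------|
| B1 | diastolic depolarization | max diastolic $dV/dt$ > 0.01 mV/ms |
| B2 | APD90 prolongation | > 20% over the same cell's drug-free APD90 |
| B3 | elevated resting potential | RMP > −50 mV |
| B4 | low peak (understimulation) | peak < 0 mV |
| B5 | high peak (overstimulation) | peak > 50 mV |
| B6 | alternans | one of last-3 APD90s deviates > 5% from both others |
| B7 | early afterdepolarization | sustained positive $dV/dt$ in late repolarization of the last beat |
| B8 | triangulation | APD90 − APD30 above threshold |

Measurement conventions: APDx runs from the maximum-upstroke time to the
*last* downward crossing of the x% repolarization level (so EADs and
notch-dome morphologies lengthen rather than truncate durations); RMP is
the diastolic minimum before the stimulus; a captured beat that never
reaches the 90% level counts as prolonged (B2).

Two detector details are deliberate design choices where no published
constant exists:

* **B7 window.** The EAD search window opens at the last crossing of 25%
  repolarization rather than at the AP peak: the ORd spike–notch–dome
  morphology has physiological positive $dV/dt$ after the peak that would
  otherwise flag every cell. Threshold (0.01 mV/ms), minimum duration
  (2 ms) and window fraction are all configurable.
* **B8 threshold.** Defined per run as the drug-free population's 95th
  percentile of triangulation (logged in the population object), with a
  fixed-ms override. The default `detector_thresholds()` value is `Inf`
  (B8 disabled) until a population supplies the percentile.

The synthetic waveform generator (`make_ap_trace`) builds piecewise traces
whose APD30/APD90/RMP/APA are exact by construction and can inject each
perturbation independently; the detector suite demonstrates a one-hot
sensitivity matrix (each perturbation fires exactly its own detector). The
generator is a measurement fixture, not an electrophysiological model:
passing these tests shows the detectors implement their rules, not that
the rules capture every real-cell morphology.

# Tissue mode (electrotonically coupled cell model)

The monodomain equation

$$\nabla\cdot(D\,\nabla V) = \beta\left(C_m \frac{\partial V_m}{\partial t} + I_{tot} + I_{stim}\right)$$

is discretized with trilinear hexahedral finite elements on a structured
cuboid (reference geometry 1.8×1.8×18 mm³ at h = 0.3 mm: 2,160 elements,
2,989 nodes, one cell model per node), fibers along +z, transversely
isotropic conductivity $D = \sigma_L[(1-r)\,n\otimes n + r I]$ with
$\sigma_L = 0.0023$ S/cm and $r = 0.35$. Time stepping is operator
splitting: the single-cell ionic step per node, then a backward-Euler
diffusion solve $(M + c K)V = MV^*$ with lumped mass, solved by
Jacobi-preconditioned conjugate gradients with warm start (the system is
a small perturbation of the identity at $\Delta t = 0.02$ ms, so a few
iterations reach $10^{-9}$). Zero-flux boundaries are natural in the FEM
formulation (stiffness rows sum to zero), and pacing is applied to the
z = 0 face so a planar wave travels along the fibers.

**Units and β.** Closing the units between S/cm, µF/cm² and ms requires
the surface-to-volume ratio β: the effective diffusivity is
$\sigma/(\beta C_m)$. β is configurable; β = 1 recovers the raw
reaction–diffusion form. The default β = 900 cm⁻¹ (within the ventricular
range) is calibrated so the default conductivities give a longitudinal
conduction velocity of ≈ 49 cm/s on the reference mesh — mid-physiological
— because the coarse 0.3-mm grid numerically depresses CV (the textbook
β ≈ 1400 cm⁻¹ yields ≈ 36 cm/s here).

Desk-scale tissue runs embed isolated-cell limit-cycle states and run a
few coupled beats (the full 500-beat coupled protocol is supported but
cluster-scale). The tissue stimulus default is a fixed 100 µA/µF on the
paced face. Node-to-model assignment is a seeded random permutation of the
accepted population, recycled if the population is smaller than the mesh.
Boundary-face nodes are excluded from biomarker analysis by default
(`analysis_nodes`).

# Risk score and classification

Per drug, the count matrix $M_{j,k}$ (cells flagged by biomarker *j* at
concentration *k* out of *N*) aggregates to

$$p_j = \frac{\sum_k M_{j,k}/C_k}{N \sum_k 1/C_k},$$

weighting events near therapeutic exposure most (the $1/C_k$ weights use
the concentration multiples 1, 3, 10, 30, 100 by default; an alternative
"index" variant uses $1/k$ — rank weights — and the variant in force is
recorded in every result). Biomarker weights are normalized ROC-AUCs of
the binary pro-vs-non-pro separation (borderline grouped with pro;
rank-based Mann–Whitney AUC with midranks), the ARS is
$x = \sum_j w_j p_j \in [0,1]$, and classes follow
$x \le \ell \to$ low, $\ell < x \le h \to$ borderline, $x > h \to$ high.

Thresholds are grid-searched: 40 candidates for $\ell$ spanning
[min, median] of the scores and 40 for $h$ spanning [median, max], all
pairs with $\ell < h$ evaluated by Macro-F1 (unweighted mean of the three
one-vs-rest F1 scores; a class absent from truth and prediction
contributes F1 = 0), ties broken toward smallest $\ell$ then smallest
$h$.

**A structural property worth knowing.** When more than half of the drugs
are high-risk — as in the ten-compound reference panel (6/10) — the score
median lies inside the high-risk group, so the grid cannot place $h$
below the weakest high-risk score and the best attainable confusion
pattern calls exactly one high-risk compound borderline: Macro-F1
= (1 + 2/3 + 10/11)/3 ≈ 0.859. The package's planted demonstration panel
(`planted_demo_panel`, 3 low / 1 borderline / 6 high) reproduces this
pattern deterministically; `planted_separable_panel` (4/2/4) has a
composition the grid can classify perfectly and is used for the
Macro-F1 = 1 recovery checks. Similarly, the smallest-$\ell$/$h$
tie-break parks thresholds exactly on training scores, so leave-one-out
folds that hold out the extreme member of a class can misclassify it even
with wide inter-class margins; the LOOCV tests use class clusters tighter
than the grid spacing for this reason, and `loocv` reports both the
pooled Macro-F1 and the mean per-fold Macro-F1 (a single held-out drug
makes the latter low-information; neither is privileged).

Validation utilities: `loocv` (per-fold weight and threshold
recomputation), `permutation_test` (label permutation with the add-one
p-value $(1 + \#\{perm \ge obs\})/(B+1)$), `bootstrap_thresholds`
(drug-set resampling with replacement, redrawing single-class resamples,
percentile 95% CIs), and `compare_models` (two-sided Wilcoxon signed rank
on paired per-drug scores, zeros dropped; all-zero differences return
statistic 0 and p = 1 with a warning).

# Robustness: subsampling and biomarker reduction

`subsample_probs` draws T independent without-replacement subsets of n
cells per drug (independent across iterations; the replacement convention
is not fixed by the source description, and without-replacement subsets of
a fixed population are the natural reading) and recomputes $\hat p_j$ and
the score matrix $R_{d,t}$. On i.i.d. Bernoulli synthetic cells the score
variance follows the Monte-Carlo $1/n$ law; the log–log OLS slope is
−0.97 on the default check (sizes 25–400, T = 200, pool 8,000 cells — the
pool is sized so the largest subsample is ≈ 5% of it and the
finite-population correction cannot bias the slope away from −1).
`iteration_sensitivity` estimates the variance of the mean ARS for
N ∈ {10, 50, 100, 200, 400} iterations over 30 outer replicates (the
outer count is the package's choice; the source reports single variance
values without the replicate convention).

All 28 two-biomarker pairs are scored as
$r = \alpha p_i + (1-\alpha)p_j$ with α = 0.5; `rmse_alpha` and
`optimal_alpha` quantify the (small) gain from tuning α, and
`pair_analysis` emits the plot-ready table: per-pair RMSE against the
8-biomarker reference score (same subsample draws), median bias
(median₂ − median₈ across drugs), and %FP/%FN for the high class under
the reference-derived thresholds. The 8-biomarker ARS is an internal
reference, not clinical ground truth; outputs label it "reference".
`biomarker_correlation` gives the pairwise Spearman matrix (midranks;
constant columns yield missing entries).

# Numerical and interface choices

* Deterministic everywhere: every stochastic operation takes a seed, and
  RNG state is saved/restored so library calls do not perturb user code.
* CG tolerance 1e-9 (relative), lumped mass, 2×2×2 Gauss quadrature.
* GHK driving forces are guarded at |V| < 1 µV (removable singularity).
* The CLI (`ars_cli`, with the `inst/cli/arscore.R` wrapper) accepts YAML
  or JSON configuration (a TOML reader is not among the package's
  dependencies; YAML offers the same comments-and-nesting ergonomics),
  validates keys before any compute, and writes a `run_config.json`
  provenance log (command, seed, options, package version) next to every
  artifact set.
* Exports are plain text: CSV event tables (one row per drug ×
  concentration × cell), CSV populations and meshes with JSON metadata
  sidecars, JSON risk reports.

# Problem sizes used by the checks

Unit and acceptance checks run at desk scale: 50-beat baseline pacing,
60-model populations at 30 beats, a 7×7×21-node tissue smoke test over
2 beats, a 135-node heterogeneous strip over 3 beats against 40
stability-filtered isolated cells, and subsampling studies on planted
populations of 400–8,000 synthetic cells. These sizes are the package's
default study conditions; every routine accepts the full-scale settings
(500 beats, 10⁵ models, the 2,989-node mesh) unchanged.

# Known limitations

* Endocardial variant only; no epi/mid-myocardial cells, no dynamic
  (Markov) drug binding, no calcium-transient or contractility
  biomarkers, no pseudo-ECG.
* The static pore block ignores state-dependent binding and trapping;
  compounds whose risk hinges on kinetics can be misrepresented.
* qNet is provided as the standard net-charge integral of the six major
  currents over one beat and is flagged as an interpretation (the exact
  published variant differs in protocol details).
* Synthetic fixtures validate detector and scoring mechanics; they do not
  certify behavior on real optical-mapping or microelectrode recordings.
* The experimental calibration bands and the canonical model's amplitude
  are in tension under the peak-minus-RMP convention (see above); strict
  filtering is reported as-is.
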