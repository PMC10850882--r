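---
title: "Methods: image-based planning of leadless LV endocardial pacing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based planning of leadless LV endocardial pacing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wiseplan)
```

## The planning problem

Leadless left-ventricular (LV) endocardial pacing systems (WiSE-CRT) pace
the LV through an ultrasound link: a transmitter in an intercostal space
(ICS) powers an electrode implanted on the LV endocardium. Two coupled
siting decisions must be made before the procedure:

* **Electrode**: pace where resynchronization helps most — a late
  mechanically and electrically activating segment — while avoiding wall
  thinner than 5 mm (perforation risk) and scar (poor capture, poor acute
  response).
* **Transmitter**: the acoustic link degrades with depth and angle, so the
  ICS must be chosen *for* the chosen electrode segment, and the electrode
  segment is only reachable if some ICS covers it.

`wiseplan` implements this planning computation desk-scale: every stage of
the imaging pipeline is reproduced on seeded synthetic patients with known
ground truth, so the selection rules, the quantification steps and the
acute-hemodynamic evaluation are all testable without imaging data.

## Pipeline stages and their models

### Anatomy and parcellation

The synthetic LV is a truncated prolate ellipsoid (endocardial semi-axes
25 × 25 × 80 mm, base truncation at 70 % of the long axis, apex at the
origin, long axis +z). The AHA 16-segment parcellation divides the
normalized long-axis coordinate into thirds and the azimuth into 6/6/4
sectors anchored to the septal direction; the apical cap is excluded. The
anchor is a stored landmark for generated anatomies; for meshes without
one it is synthesized from the RV pacing site, which assumes that site is
mid-septal.

Wall thickness is measured per endocardial vertex by casting a ray along
the outward normal to the epicardium (nearest hit); the per-segment
summary is the **median** of vertex values, robust to basal-rim ray
artifacts (a `min` summary is available for conservative screening).
A segment is *thin* when its summary is strictly below 5 mm.

The generator draws the per-patient thin-segment count from a normal
distribution with mean 4.8 and SD 3.5, rounded and clipped to 0–16 (the
clipping raises the realized mean to ≈ 4.9). Thin segments draw a true
thickness of 2.5–4.2 mm, others 6.5–12 mm. The margins around the 5 mm
threshold are deliberate: at segment boundaries the epicardial offset
blends neighbouring segments' thickness, which biases a thin segment's
median upward by a few tenths of a millimetre; at the default mesh
resolution (72 × 28, ≈ 2000 endocardial vertices) the interior vertices
dominate the median and the drawn margins keep every realized median on
the correct side of the threshold, so the thin ground truth is exactly
recoverable. At much coarser resolutions boundary blending can push an
isolated thin segment above 5 mm — a documented limit, not a target of the
tests.

### Perfusion quantification

Regional time–attenuation curves (TACs) are modelled as a
single-compartment system: the tissue enhancement is the arterial input
function (AIF) convolved with an exponential residue,

$$C(t) = \frac{\mathrm{MBF}}{6000}\,\int_0^t \mathrm{AIF}(u)\,
  e^{-(t - t_0 - u)/T_c}\,du,$$

with MBF in mL/100 mL/min, $T_c$ the compartment mean transit time (s)
and $t_0$ an arrival delay. Derived quantities: perfused capillary blood
volume $\mathrm{PCBV} = \mathrm{MBF}\cdot T_c/60$ (mL/100 mL) and average
enhancement (time-mean of the baseline-subtracted curve). The vendor
software behind the original measurements implements an unpublished
intravascular/extravascular compartment model; the single-exponential
residue is this package's documented simplification.

Fitting profiles MBF out (the model is linear in flow) and searches
$(T_c, t_0)$ by coarse grid plus refinement. Two numerical choices
matter:

* The convolution quadrature runs on a 10× refined time grid with a
  linearly interpolated AIF. At the acquisition sampling rate alone, a
  sub-sample delay shift merely rescales the basis by $e^{\delta/T_c}$
  and is *exactly confounded* with flow.
* Even on the refined grid that confound survives below the quadrature
  step, so $t_0$ is resolved on a 0.1 s grid (bounded to 0–5 s) rather
  than continuously; $T_c$ is refined by golden-section search. With the
  generator's delay on that grid the noiseless round trip recovers MBF and
  $T_c$ to well under 1 % across MBF 20–120; an off-grid delay costs up to
  ≈ 3 % of flow.

*Hypoperfusion as scar:* a segment is flagged when its MBF falls below a
fraction (default 0.6) of the median MBF of unflagged segments, iterated
to a fixpoint so large scars cannot drag the reference down. The study
reports only "significant hypoperfusion", so the fraction is
config-exposed rather than asserted as the study's criterion. Delayed-phase
late enhancement (flag above remote median + 50 %) is advisory only — it
is an insensitive scar marker (the generator reproduces that: scar shows
late enhancement with probability 1/3).

The synthetic ischemic phenotype (probability 6/11) carries a contiguous
2–4-segment scar territory with flow reduced to 35 % of the healthy draw
(N(80, 8) mL/100 mL/min). TAC noise defaults to 0.65 HU — 5 % of the
≈ 13 HU peak healthy tissue enhancement, the regime the robustness
property targets; segment-mean curves that average thousands of voxels
plausibly reach sub-HU noise. A further fitting safeguard matters at the
scar segments' low SNR: the bolus reaches the whole myocardium within a
fraction of a second, so after a first unconstrained pass the per-region
delay is re-anchored to the median delay of the well-enhanced regions
(± 0.3 s) and outlying regions are refit. Without it, a low-enhancement
curve occasionally admits a *lower-residual* spurious fit that trades
flow against transit time and delay (high flow, short T_c, late t_0). At
these settings hypoperfusion classification reproduces the scar ground
truth with sensitivity = specificity = 1, mirroring the perfect
per-patient detection rate the perfusion criterion showed.

### Mechanics

With vertex correspondence given by the generator (the image-registration
tracking of the clinical pipeline is out of scope), per-segment curves are
computed per phase: local area change (segment area / reference − 1) and
circumferential/longitudinal strain from mean relative edge-length change,
edges binned by reference orientation to the long axis (|cosine| ≤ 0.5 ⇒
circumferential). "Volume curves" are interpreted as segmental
area-change curves — the endocardial-surface proxy.

Time-to-peak (TTP) contraction is the phase of the most negative area
change, localized below the frame step by quadratic interpolation around
the discrete minimum (the contraction waveform is asymmetric, so a plain
argmin can err by a full frame). Segments whose peak-to-peak area change
is below 0.05 are excluded as *flat* — the akinetic-scar exclusion; the
0.05 default is a config value, not a claim about the study's threshold.
The latest mechanical segment is the non-flat argmax of TTP, ties broken
basal-then-lateral (the posterolateral implant preference; inferolateral
before anterolateral).

The motion generator displaces vertices radially with a single-peak
envelope — a baseline-shifted Gaussian bump (σ = 0.05 cycle), zero at
phase 0 and *symmetric about its peak* — peaking exactly at each
segment's drawn TTP (viable amplitude 0.12–0.18, scar 0.01 — akinetic
and below the flat threshold). Two generator-design points matter for the
recovery contract. First, envelope symmetry: with an asymmetric
contraction/relaxation waveform, both the discrete argmin and its
quadratic refinement land systematically late — up to a full frame — of
the nominal peak, an estimator-independent skew. Second, vertices on
segment boundaries are shared, so each vertex blends its incident
segments' envelopes with sharpened (cubed-count) weights: even blending
drags a segment's measured area-curve peak towards its neighbours'
phases, while a hard per-vertex assignment makes the displacement jump
across boundaries by more than a face width and grossly shears boundary
faces. With the final design the TTP recovery error is typically below
0.01 cycle and bounded by half a frame at the tested conditions (a
boundary-pollution residual can very rarely exceed it by ~0.001 when a
segment's neighbours all peak a few frames away). The generated target
pair receives the two latest TTPs, so mechanical lateness is present by
construction; 20 frames per cycle at a 857 ms cycle length (≈ 70 bpm).
One related caveat: the measured peak-to-peak area change carries a
neighbour-phase alignment gain of roughly 0.5–1.2× (a segment whose
neighbours peak with it keeps its boundary contraction, one whose
neighbours peak elsewhere loses it), so amplitude *ordering* across
segments is only recovered for well-separated amplitudes; peak *phase*
recovery is unaffected, and the scar-versus-viable amplitude separation is
categorical.

### Electrical activation

Activation from the RV pacing site is a first-arrival (eikonal) problem
on the endocardial surface with isotropic conduction velocity: healthy
endocardium 0.6 m/s, scar 0.2 m/s (slow-conducting, never blocking, so no
artificial unreachability; both config-exposed, literature-typical). It is
solved as shortest paths on the triangulation augmented with edge-midpoint
Steiner nodes, all six nodes of every face fully chorded at the face's
velocity — this bounds the angular discretization error to ≈ 3.5 %
($1/\cos 15° - 1$), verified against exact geodesics (flat sheet,
sphere great circles) within the 5 % contract. Velocity scaling is exact
by construction. QLV at a site is the arrival time at the nearest vertex,
measured from the pacing stimulus (the clinical QLV references ECG QRS
onset — a documented simplification). The latest electrical segment is the
argmax of per-segment *mean* activation (the study does not say mean or
max; max is available via `latest_stat`).

### Target selection and transmitter ranking

A segment is *viable* when neither thin nor hypoperfused. Each viable
segment with a defined TTP is scored by the **sum of its lateness ranks**
across the mechanical and electrical maps; the primary target is the best
score and the second target its best-scoring viable neighbour on the AHA
adjacency graph (shipped as version-controlled CSV and unit-tested
against the bull's-eye overlap rule), so the pair is always adjacent and
never thin or scarred. Rank-sum is the fusion rule chosen for the cases
where the two maps disagree; `fusion = "mechanical"` or `"electrical"`
restricts the score to one map. Ties resolve basal-then-lateral.

Acoustic intensity from a transmitter candidate to a segment centroid is
the point-source surrogate

$$I(\theta, d) = \cos\theta \, e^{-\mu d}, \qquad
  I = 0 \text{ for } \theta \ge 30° \text{ or } d \ge 12\ \mathrm{cm},$$

with $\theta$ at the skin entry point between beam axis and
entry-to-segment line, $d$ the entry-to-segment distance and
$\mu = 0.1\ \mathrm{cm}^{-1}$. The study states only that intensity was
computed from depth and distance; this form is a surrogate chosen for
monotonicity in both variables and for the hard acoustic-window
admissibility bounds (< 30°, < 12 cm). Its testable contract is
qualitative: a candidate with zero intensity at the target is never ranked
first, and rankings are invariant to candidate order and joint rigid
motion. Candidates are sorted by mean intensity over the two target
centroids; a single available ICS yields a coverage report rather than a
choice, and "no adequate coverage" is flagged rather than silently
accepted. Per-patient ICS availability follows the cohort distribution
36 % / 37 % / 27 % for 1/2/3 spaces.

### Hemodynamic evaluation

dP/dt_max is the per-beat maximum of the centered-difference pressure
derivative over a ≥ 10 s window (500 Hz default sampling). Beats are
delimited by pressure-minimum detection (mid-level upcrossings refined to
the intervening minimum; the mid-level uses 5th/95th percentiles so one
huge ectopic beat cannot lift it above normal systolic peaks). Ectopic
beats are rejected at 3 robust standard deviations — median-centred,
MAD-scaled, with a 0.2 %-of-median floor for noise-free windows. A plain
mean/SD 3-sigma filter (and its leave-one-out variant) is masked when two
or three large ectopics land in one short window, which at the 5 %
ectopy rate happens in roughly one window per cohort and inflated a paced
dP/dt_max by a factor 2; the robust scale is this package's deliberate
deviation from a naive 3-SD rule, at the same nominal 3-sigma level.

AHR is the percent change from reference to mean biventricular paced
dP/dt_max. Group comparison: two-sided Welch t test target vs non-target
(paired available via `paired = TRUE`, pooled segments is the default unit
of analysis), Fisher exact test on the 2 × 2 table of group × (AHR > 10 %),
and the scarred and viable non-target subgroups reported separately.

The pressure generator writes raised-cosine systolic upstrokes on a
diastolic floor, so the trace realizes a prescribed dP/dt_max exactly up
to per-beat jitter (1.5 %); the paced trace scales the upstroke so the
realized AHR is a class-conditional normal draw: target 25.5 ± 8.8 %,
viable non-target 15.4 ± 8.0 %, scarred 5.9 ± 4.0 % (the scarred SD is
unprinted in the source statistics and 4.0 % is a documented free
calibration). Scarred segments fail to capture with probability 0.1, in
which case AHR is missing, matching the no-capture-or-minimal-response
phenotype. Ectopics are isolated 5× amplitude outliers at a 5 % beat rate.

### Tested-segment protocol

Per-patient segment-tested counts are not reported in the source
statistics; the default protocol tests the 2 planner-selected targets
plus 2–4 non-target segments (4–6 total). In ischemic patients each
non-target slot probes a scar segment with probability 0.48. That number
is *derived*, not free: with pooled non-target mean 12.9 %, viable
non-target 15.4 % and scarred 5.9 %, the scarred share of non-target
tests must be (15.4 − 12.9)/(15.4 − 5.9) = 0.263, which at 6/11 ischemic
prevalence is 0.48 per ischemic slot. The AHR class of a tested segment
is procedural: scar segments always draw the scarred distribution, and a
segment draws the target distribution when the planner selected it —
the group statistics being emulated are defined by the selection, not by
the generator's private labels.

## What the generator does and does not emulate

It emulates: the statistical structure the analysis consumes — thin-count
and scar prevalence, class-conditional AHR, ICS availability, TAC forward
physics with noise, akinetic scar motion, septal-paced lateral-late
activation. It does not emulate: real CT physics (beam hardening, motion
artifact), image registration and segmentation error, papillary anatomy,
the right ventricle, fibre anisotropy, or rib shadowing of the acoustic
path. Passing tests therefore demonstrate the correctness and calibration
of the *computation*, not the clinical accuracy of the imaging chain
upstream of it.

## Problem sizes and reproducibility

Default sizes, chosen as desk-scale study conditions: cohorts of 10
patients (mirroring the implanted cohort) with 4–6 tested segments each;
200 patients for the thin-count calibration; meshes of ≈ 2000 endocardial
vertices; 20 cycle phases; 40 TAC time points at 1 s; 12 s pressure
windows at 500 Hz. Every generator takes an explicit seed and all cohort
seeds derive from one base seed, so identical configurations are
byte-identical; `scripts/acceptance.R` re-derives everything from a single
`--seed`.

## Known limitations

* The acoustic model is a monotone surrogate; absolute intensities are
  not calibrated to any device.
* The eikonal solver is surface-only and isotropic; no transmural or
  Purkinje physiology.
* Perfusion delay below 0.1 s is unidentifiable at 1 s sampling (see
  above); real dynamic-CT fitting faces the same trade-off.
* QLV on the synthetic ellipsoid (≈ 150–200 ms at 0.6 m/s) runs longer
  than typical clinical QLV, because the idealized anatomy has a longer
  endocardial path from the septal pacing site than a dilated human LV
  with faster preferential conduction; the package reports it but no
  calibration claim is attached.
* With ~20 target and ~30 non-target segments per cohort, the
  target-vs-non-target Welch test at the calibrated effect size yields
  p < .001 in about 90 % of cohorts (exact noncentral-t computation); in
  the remaining cohorts the separation is still significant at
  conventional levels. Summaries across replicate cohorts should expect
  that rate rather than certainty.
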