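---
title: "Head models, eLORETA and the infant N290: methods behind erpsource"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Head models, eLORETA and the infant N290: methods behind erpsource}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpsource)
```

## The problem

Cortical source analysis projects scalp-recorded ERP data back into the
brain through a *head model*: a geometric and electrical description of
the tissues between the sources and the electrodes. The gold standard is
a head model built from the participant's own structural MRI, but infant
MRIs are expensive and often unobtainable, so substitute head models
built from averaged MRI templates are used instead. `erpsource`
implements, on fully synthetic data, the complete machinery needed to ask
*which substitute is least bad*: cohort simulation, conductivity-based
head models, average-template construction, N290 peak measurement,
eLORETA current-density reconstruction (CDR) summarized per region of
interest (ROI), and the substitution comparison (difference scores,
pattern correlations, mixed ANOVA, and a ranking).

The scientific context is infant face processing in groups at elevated
likelihood of autism: infant siblings of children with ASD (ASIB),
infants with fragile X syndrome (FXS), and low-risk controls (LRC). The
N290 — a negative, face-sensitive component peaking near 290 ms at
posterior electrodes — is enhanced in FXS and muted in ASIBs, and its
generators are expected in fusiform and parahippocampal cortex, with
greater activation to faces than toys. The synthetic cohort generator
injects exactly this structure so that every downstream claim of the
pipeline is testable end to end.

## The synthetic cohort

Head geometry is a stack of concentric ellipsoidal layers (white and
gray matter, CSF, skull, scalp) on an isotropic voxel grid, default 2 mm
voxels on a 91^3 grid. This is deliberately *not* anatomy: the
comparison framework only needs geometry that varies between subjects
and templates in a controlled way. Fixed per-axis multipliers (0.95,
1.06, 0.99) keep the principal axes distinct so that rigid alignment is
well posed.

Per-group mean shell radii differ slightly (ASIB largest, encoding
reported early brain overgrowth in elevated-likelihood infants), and the
per-subject jitter SD is largest for ASIB (3 mm vs 1.5 mm for FXS and
2 mm for LRC), encoding the greater geometric heterogeneity of that
group. Jitter is drawn as one shared head-size deviate (full SD) plus
small independent per-shell deviates (SD/4), both truncated at two SDs:
head size covaries across shells in real heads, and the shared deviate
keeps the shell ordering valid with overwhelming probability. Draws that
compress a shell below ~70% of a voxel are rejected and redrawn a
bounded number of times. The 6 mm gaps between mean shell radii are
wider than an infant skull or CSF layer; they keep each tissue band
resolvable on the coarse grid and after occupancy averaging.

The 18-ROI atlas carves spheres (7 mm radius, centred at 65% of the
brain extent along canonical anatomical directions) out of the
gray-matter rim; bilateral ROIs carry one label with mirrored centres,
so the atlas is exactly symmetric under left-right grid reflection.
ROI placement is qualitative — fusiform ROIs are posterior-inferior,
cingulate ROIs midline — not stereotaxic.

ERP averages are generated through each subject's own lead field from
Gaussian-bump dipole time courses: a positive P1 component (bilateral
medial inferior occipital, 130 ms, outward orientation) and a negative
N290 component (bilateral middle fusiform, anterior fusiform and
parahippocampal sources, 290 ms, inward orientation so nearby posterior
electrodes see a negativity). Gaussians are used because the source
waveform is not constrained by data and they make latency assertions
exact. Condition effect sizes (mother face 1.05, stranger face 0.95,
own toy 0.65, novel toy 0.55) and group multipliers (FXS 1.4, LRC 1.0,
ASIB 0.7) scale the N290 sources only, giving faces > toys in every
group and FXS > LRC > ASIB overall. Sensor noise is white across
channels (default 0.5 uV SD); there is no 1/f background, blink or
artifact model — preprocessing is upstream of this package — so passing
tests demonstrate the pipeline's internal consistency, not robustness
to real EEG noise. Defaults not fixed by the study context (250 Hz
sampling, -100 to 600 ms epochs) are configuration, not claims.

## Head models and the forward problem

Tissue conductivities follow the standard nine-class table (S/m): scalp
0.35, skull 0.0132, CSF 1.79, white 0.2, gray 0.33, dura 0.33, muscles
0.35, eyes 0.5, nasal cavity 0.0048. `assignConductivities` maps any
label volume through this table and refuses unmapped labels by name.

The voxelwise finite-element forward solution used with realistic
anatomy is replaced by an analytic four-shell concentric-sphere model:
`fitShellModel` reduces a label volume to brain/CSF/skull/scalp shells
(centre = scalp centroid; radius = mean distance of each compartment's
outer boundary voxels plus half a voxel, since boundary voxel centres
sit on average half a voxel inside the interface), and
`computeLeadField` evaluates the Legendre-series potential of a dipole
in a piecewise-homogeneous concentric conductor. Per degree, the radial
profile solves a 7-unknown boundary-value system (continuity of
potential and radial current at the three interfaces, insulation at the
scalp); each shell uses basis functions scaled by its own outer radius
so the system stays well conditioned to order 150 and beyond. The
default truncation order is 60; order 80 agrees with the closed-form
single-sphere solution to better than 1e-4 when all conductivities are
equal, and the deepest admissible sources have decayed series terms well
below double precision at order 40. Non-shell tissues (dura, muscles,
eyes, nasal cavity) are accepted in volumes but collapse into their
enclosing shell — they do not form closed shells in the synthetic
geometry. Units are fixed throughout: mm, S/m, nA*m, uV.

Electrodes are a 64-channel montage: the 26 numbered electrodes of the
12 posterior measurement clusters (PO7/PO8, PO9/PO10, P7/P8, P9/P10,
TP7/TP8, TP9/TP10) at hand-set, exactly mirror-symmetric directions,
plus filler electrodes on a Fibonacci lattice over the upper head, plus
nasion/preauricular fiducials. `placeElectrodes` projects the
unit-sphere template radially onto the scalp radius after rotating the
fiducial frame onto the head frame. Cluster membership is exact and
validated against the montage by name.

## Template construction

`buildAverageTemplate` iterates align-average-relabel: every input is
rigidly aligned (centroid + principal axes of the head region; an
optional uniform scale is available but off by default) to the current
reference, per-label occupancy fractions are averaged, and the average
is re-labelled by argmax with ties broken toward the outermost tissue
(deterministic labelling). The RMS occupancy difference between
successive references is tracked; iteration stops when the trace
*levels* (|change| < tol, default 1e-3 occupancy units) or vanishes, or
at max_iter = 10. The stopping threshold is an operational choice — the
leveling criterion itself has no canonical constant. RMS is computed on
label occupancy of the whole volume; computing it on extracted-brain
intensity is the main alternative and would need real MRI intensities.
Nearest-neighbour label resampling is used throughout; nonlinear
registration is deliberately out of scope (with ellipsoidal synthetic
geometry it would add engineering weight without changing what the
comparison tests), and `rigidAlign` is the injection point where a
richer registration could be substituted.

## Peak detection

The N290 is measured on the mean of the 12 posterior clusters (with
per-cluster values available as diagnostics): first the P1 — the largest
positive local extremum in 80-200 ms — then the N290 — the most negative
local extremum after the P1 and at or before 400 ms. A local extremum
must dominate a full +/- 3-sample neighbourhood inside the search
window (ties resolve to the earlier latency, and the twin samples of a
peak centred between samples count once); a window with no extremum
falls back to the sample at 290 ms and sets a machine-readable flag —
the deterministic replacement for manual peak adjustment. The reported
N290 amplitude is the P1-to-N290 peak-to-peak change, which cancels
slow baseline shifts.

## Inverse solution and ROI summaries

`buildEloretaOperator` implements the standard eLORETA iteration: with
sensor-space matrix C = L W^-1 L' + alpha * mu * H (H the
average-reference centering operator, mu the mean sensor-space
eigenvalue, alpha relative and default 0.05), each source's 3x3 weight
is replaced by the symmetric square root of L_j' C^+ L_j until the
largest relative weight change drops below 1e-6 (max 100 iterations;
non-convergence is an error carrying the trace). The defining property —
exact localization of noiseless point sources as alpha goes to 0 — is
asserted directly in the tests over the full source grid at
alpha = 1e-4. The pseudo-inverse truncates eigenvalues below 1e-12 of
the largest, which removes exactly the average-reference null space.

The CDR is the time-mean of the per-sample moment norms over the 20 ms
window centred on the detected N290 peak (time-max is available via an
argument; "surrounding the peak" does not pin down either choice, and
the mean is the more stable summary). Free orientation is kept because
orientation handling is otherwise unconstrained. ROI values are
(sum of source amplitudes in the ROI) / (ROI volume in mm^3) — average
current per mm^3; empty ROIs are NA, never zero. When the source grid is
strided, the sum covers fewer sources and the values shrink accordingly;
all comparisons use a common grid, so this cancels in every contrast the
package computes.

## The substitution comparison

Per subject, each alternative head model is compared with the Self model
by per-ROI difference scores (Self minus alternative, with faces/toys
class means) and by the Pearson correlation of the ROI activation
patterns. Correlations concatenate the faces and toys ROI vectors (36
pairs) by default — pooling stimulus classes is the reading that uses
all information; a `roi_only` switch (18 pairs) covers the other
reading. Correlations are averaged per head model with SDs, overall and
by group; missing ROI values are excluded pairwise.

The mixed ANOVA is the classical univariate decomposition with error
strata subject-within-group crossed with the within factors, computed
via `stats::aov` with the corresponding `Error()` term. No sphericity
correction is applied to the primary table — the integer df pairs of the
published design (head model (5, 85); group x head model x ROI
(85, 1445)) only arise uncorrected — but a Greenhouse-Geisser epsilon
and corrected p are attached as diagnostic columns whenever the contrast
covariance is estimable.

The ranking orders alternatives by mean absolute difference score
(ascending), breaking ties by mean correlation (descending). This is an
explicit formalization of what is otherwise an informal multi-criteria
judgment; making it a total order is what renders the "best substitute"
claim machine-checkable.

One property of the synthetic world deserves emphasis. A study-specific
template built *from the analyzed subjects themselves* is an in-sample
mean, and an in-sample mean of n draws is on average *closer* to those
draws than the population mean is — so under purely geometric variation
the study-specific template can legitimately out-rank a large external
pool. The headline phenomenon this package demonstrates — the large-pool
template winning — therefore requires the small pool to be drawn from a
(mildly) perturbed population, as `headModelRankingExperiment` does
(small pool of 4 at 1.05x radii; mismatched "older-age" pools at 1.15x
and 1.3x; large pool of 12 from the subjects' own population). That
experimental design, not the in-sample default, is the synthetic
analogue of the empirical finding.

## Problem sizes and runtime

The single-run defaults (2 mm voxels, 91^3 grid, full atlas source
grid) suit one-off analyses. The replicate experiments and the
acceptance checks run at deliberately coarser settings chosen once as a
desk-scale compromise: 3-3.5 mm voxels on ~61^3 grids, strided source
grids of a few hundred sources, cohorts of 2-3 subjects per replicate,
50 replicate cohorts for the ranking study and 500 replicates for the
null calibration. The full default cohort (21/15/21 subjects) runs end
to end in well under a minute at the coarse settings; the ranking study
is the most expensive piece at a few minutes on one CPU.

## Known limitations

- Geometry, atlas and sources are schematic; nothing here validates
  anatomical accuracy, tissue anisotropy, or real electrode geometry
  beyond the printed clusters.
- The forward model is spherical; skull thickness variation, sutures and
  fontanelles — all plausibly important in infants — are absent.
- Sensor noise is white; robustness claims to structured EEG noise are
  out of scope.
- The ANOVA is the uncorrected univariate decomposition by design;
  epsilon-corrected p values are diagnostics, not the primary output.
- Only eLORETA is implemented; no sLORETA/beamformer baselines.
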