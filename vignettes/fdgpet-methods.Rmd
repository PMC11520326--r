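---
title: "Quantifying regional FDG uptake in rodent brain PET: models, phantom, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying regional FDG uptake in rodent brain PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fdgpet` implements a complete quantification and inference chain for
dynamic [^18^F]fluorodeoxyglucose (FDG) PET of the rat brain: alignment of
reconstructed dynamic images to a label atlas, regional standardized uptake
values (SUV) and whole-brain-normalized SUVr, and repeated-measures
mixed-effects inference on a two-genotype, two-timepoint cohort. Because no
raw images of the motivating study design are publicly deposited, the
package ships a digital phantom that generates cohorts with known ground
truth, so every stage can be validated quantitatively. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the phantom does and does not establish about real data.

## The quantification model

A dynamic scan is a 4D array of radioactivity concentration (Bq/mL) with a
frame schedule (by default 90 one-minute frames) and a decay-correction
flag; frames are corrected to scan start with the F-18 half-life
(109.77 min), applied at each frame midpoint. Regional time-activity curves
(TACs) are unweighted voxel means over atlas regions. The uptake window is
30-60 min post injection, where FDG is effectively trapped and the TAC has
plateaued; frames partially inside the window are weighted by overlap
duration. Then

* `SUV = mean concentration(30-60 min) / (injected activity / body weight)`
  in g/mL, and
* `SUVr = SUV(region) / SUV(whole brain)`, which cancels injected dose and
  body-weight errors (and any global administration/distribution/
  metabolism/excretion variation). Whole-brain SUVr is identically 1 on
  every scan — the suite asserts this exactly.

## Atlas operations

Label volumes use a right-handed world frame in mm; the center of voxel
(1,1,1) sits at the volume origin, and all transforms act on world
coordinates. Downsampling a high-resolution atlas uses a majority vote per
output block with ties broken toward the lowest label id — this preserves
region volumes better than nearest-neighbor picking and makes the loss of
small regions deterministic; a nearest-source-voxel fallback covers
non-integer grid ratios. The registration target is the brain mask (union
of all labels) smoothed with an isotropic Gaussian of sigma 0.85 mm, whose
full width at half maximum, 2*sqrt(2 ln 2)*0.85 = 2.0 mm, matches the
scanner's point-spread function — so the blurred edge of a real scan and
the mask edge have the same profile, which is what makes mask-based
registration accurate.

## Registration

Transforms are 6-df (3 shifts in mm, 3 rotations in degrees) or 9-df
(plus 3 axis scales). Rotations are extrinsic about the fixed world x, y, z
axes in that order, centered on the geometric center of the target volume;
results are invariant to re-expressing the same matrix. The similarity
metric is normalized cross-correlation (NCC), which is invariant to global
intensity scaling; a coarse multi-start grid over shifts then rotations
(an automated stand-in for manual initial placement, with an `init`
argument to mimic a manual start) seeds a Nelder-Mead simplex search —
which only ever accepts non-worsening steps — run at two resolutions
(block-2 downsampled, then full), 6 df first, then 9 df seeded by the 6-df
result. Within-subject pairs are first aligned to each other by 6 df and
share a single 9-df transform to the atlas, estimated from the pair mean.
A study template (voxelwise mean of aligned images, polished by one 9-df
alignment to the mask) can serve as the target of a second fine-alignment
pass, implemented as a refinement with both transform sets retained. Final
transforms are concatenated into one matrix and applied to the 4D data with
a single trilinear interpolation — never stage by stage — to avoid
cumulative blurring.

Two numerical details matter at the sub-voxel level. First, sampling
coordinates that land on lattice points within float round-off are snapped,
so identity resampling is bit-identical. Second, the phantom renderer
antialiases region edges by averaging painted values over sub-voxel
offsets (factor 2 per axis by default; the pose-recovery study uses 3): a
voxel-quantized edge otherwise imprints a grid-aligned staircase that
biases the weakly constrained pose parameters by up to a few degrees, and
its residue is visible in the scale estimate at the fraction-of-a-percent
level. The staircase is an artifact of rendering a discrete label map, with
no counterpart in real reconstructed scans.

## The digital phantom

The phantom brain is a union of ellipsoids (cerebrum, lateral bulges,
cerebellum/brainstem, olfactory bulb) minus carved fissures, clipped by a
flat ventral plane — about 1730 mm^3. The lumps and grooves are not
decoration: aligning a smooth blurred ellipsoid to a mask leaves rotation
about its long axis nearly unconstrained (surface points move tangentially),
and early experiments with a plain ellipsoid showed rotation errors of
2-3 degrees with an NCC surface flat to ~1e-5 over that range. The
asymmetric outline restores rotation sensitivity comparable to shifts and
scales.

Eighteen a-priori regions (five catecholaminergic, four dysarthria-related,
nine Parkinson-disease-related-pattern regions; striatum and caudate
putamen kept distinct) are placed as non-overlapping blobs with exact voxel
counts; the default volume table has a median of 6 mm^3, matching the
downsampled-atlas scale the pipeline is designed for. Kinetics follow the
plateau model `C(t) = A (1 - exp(-t/tau))` with tau = 5 min — rapid uptake,
then sustained trapped activity — integrated analytically over frames.
Scans are rendered by painting per-region TAC levels into the posed label
map, convolving with the 2-mm-FWHM Gaussian PSF, and adding zero-mean
Gaussian noise with sd = `noise_sd_frac` x local mean / sqrt(frame
duration); the default `noise_sd_frac = 0.05` was chosen once to make
registration non-trivial, as no scanner noise magnitudes were available,
and a variance proportional to signal over frame duration is a tractable
stand-in for reconstructed-PET noise statistics.

The cohort generator reproduces the study layout: 12 knockout (KO) and 14
wild-type (WT) subjects in two age groups, baseline and final timepoints,
43 scans total including the missing cells (no younger-group WT baselines,
one KO baseline and one WT final absent). True poses are uniform within
±3 mm / ±5 degrees with per-axis scales drawn around genotype-specific
means (volume products near 1.08 for WT and 1.03 for KO); baseline and
final share the subject pose up to a small motion perturbation (SD 0.3 mm,
0.5 degrees). Regional SUVr levels default to the WT reference values with
KO multipliers in four regions (striatum and prelimbic reduced, nucleus
ambiguus and posterior parietal cortex elevated); the rest-of-brain level
is solved per genotype so the volume-weighted whole-brain mean is exactly
1, which makes expected SUVr computable analytically from the truth file.

For replicate inference studies the generator also draws uptake tables
directly from the truth model: `SUVr_obs = level * (1 + b + e)` with a
subject-by-region intercept `b` (SD 3.5%) shared across timepoints and
scan-level noise `e` (SD 2.5%). These relative SDs sit in the typical FDG
test-retest range, give LS-mean standard errors close to the study-scale
values, and are calibrated so that the generator realizes the design's
stated operating point — at the default striatal effect the genotype test
has power of at least 0.8 at alpha = 0.05. Rendering, registering and
quantifying hundreds of image cohorts would add nothing but partial-volume
blur to that question, and the image route is validated separately. Behavioral tables
draw cell means for the 23-measure catalogue (ultrasonic vocalization,
tapered balance beam, cylinder test, 5-choice serial reaction time task)
with subject intercepts; total SDs derive from the catalogued LS-mean SEs
as `SE * sqrt(n)` split evenly (ICC 0.5) between subject and residual
variance.

## Inference

Regional SUVr and each behavioral measure are analysed with
`value ~ genotype * timepoint + (1 | subject)` fit by REML, with type-III
F tests and Satterthwaite denominator degrees of freedom. Containment-type
df (as used by some commercial software) are not reproduced exactly on
unbalanced designs, so df are always reported alongside F and p. Cell
means are least-squares means with SE; significant interactions are
followed by Tukey-adjusted all-pairwise cell contrasts. On balanced
single-observation-per-cell data the F statistics coincide with the
classical repeated-measures ANOVA — the suite asserts agreement to 1e-6.
Singular random-intercept fits are flagged and refit by ordinary least
squares with a warning.

Brain-behavior association treats behavior as the dependent variable:
`behavior ~ SUVr * genotype + (1 | subject)`, pooling both timepoints with
a subject intercept (the minimal random structure consistent with repeated
measures; a per-timepoint fit is a trivial restriction). Per-genotype
regression lines are returned for plotting. The exploratory screen crosses
all 23 measures with all 18 regions — 414 tests — and reports hit counts at
alpha = 0.05 and at the stricter 0.005 screen alongside the chance
expectation `round(414 * alpha)` (about 2 at 0.005); no further multiplicity
correction is applied, by design, because the screen is explicitly
exploratory.

The voxel-wise map divides each image by its within-mask mean, computes a
pooled-variance two-sample t per voxel (sign convention KO - WT), and
overlays two bands, p in (0, 0.05] and (0.05, 0.10]. The thresholds are
implemented on the p map: the source description of the display threshold
conflates t and p scales ("|t| > 0.05"), and a p-value reading is the only
internally consistent one; a flag can switch to raw-t thresholds.

## Significance levels and defaults

| Parameter | Default | Units | Why |
|---|---|---|---|
| SUV window | 30-60 | min | plateau phase of trapped FDG |
| mask smoothing sigma | 0.85 | mm | matches 2 mm FWHM scanner PSF |
| PSF FWHM | 2 | mm | scanner resolution |
| F-18 half-life | 109.77 | min | physical constant |
| alpha | 0.05 | — | primary tests |
| exploratory screen | 0.005 | — | limits chance hits to ~2 of 414 |
| noise_sd_frac | 0.05 | — | makes registration non-trivial |
| suvr between/within SD | 0.035 / 0.025 | relative | test-retest-like variability at the design's stated power |
| grid for studies | 0.6 | mm | keeps a full registration under ~15 s |

Problem sizes used by the validation studies are the package's own choice
of desk scale: pose recovery uses 20 phantoms per noise condition on the
0.6 mm grid; power and sign use 200 replicate tabular cohorts; type-I error
uses 500 null cohorts; the end-to-end image pipeline runs the full
43-scan cohort at 12 x 5-min frames.

## What passing tests do and do not show

The phantom establishes internal correctness: transform recovery to
0.25 mm / 1 degree / 1% scale without noise, SUVr exactness without PSF and
noise, nominal type-I error, and power with correct effect signs at the
configured effect sizes. It does not emulate attenuation, scatter, randoms,
reconstruction artifacts, anesthesia physiology, inter-animal anatomical
variability, or non-Gaussian reconstructed noise; partial-volume bias is
present (and demonstrably recovered by a convolution oracle) but its
magnitude depends on the simplified geometry. Real-data F and p values of
the motivating design are not reproducible — no raw data are deposited —
so the published effect sizes serve here as generator defaults, not as
targets.

## Known limitations

* Only axis-aligned NIfTI orientations with positive scales are read.
* The two-tissue irreversible kinetic option is not implemented; the
  plateau model is the supported uptake shape.
* Registration is affine (6/9 df) by design; no deformable refinement.
* The phantom's regions are single blobs, not bilateral structures; its
  striatum and caudate putamen are disjoint although anatomically nested.
* Image noise is Gaussian by default (a scaled-Poisson option exists behind
  `noise_model = "poisson"`); projection-space simulation, attenuation and
  scatter physics are out of scope.
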