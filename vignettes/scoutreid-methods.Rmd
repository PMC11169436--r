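---
title: "Patient re-identification from trunk scout CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient re-identification from trunk scout CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scoutreid)
```

## The problem

Medical images carry patient identifiers in their metadata, and those
identifiers are occasionally wrong — a misfiled study, a mix-up at the
console. A radiologist cannot see "wrong metadata" in the pixels, so
misidentified studies can persist in the archive. Biometric patient
re-identification turns the pixels themselves into an identity check: a
*query* image with uncertain identity is compared against a *gallery* of
baseline images with trusted identities, and the metadata of the most
similar gallery patient is proposed (or a mismatch alert is raised).

The scout (localizer) image acquired before every trunk CT is a natural
substrate: it is a 2D frontal projection covering chest, abdomen and
pelvis, acquired for every exam, and it exposes stable patient-specific
structure (body outline, mediastinum, skeleton, implants). Two systematic
nuisances complicate matching across visits:

* **Vendor processing.** Scanner makes apply different contrast and
  dynamic-range processing and acquire at different pixel spacings, so the
  same anatomy looks different between devices (*domain shift*).
* **Table-height geometry.** The X-ray source sits roughly 1 m from the
  detector (SID about 100 cm) with the isocenter at distance `d0` from the
  source. Raising the table by `dh` magnifies the projection *width* by
  `s(dh) = d0 / (d0 - dh)` while the height direction, swept by table
  travel, is unaffected. Table height is set per visit and is not
  reproduced across visits, so the same patient's silhouette width varies
  by a few percent between exams — and systematically between scanners
  whose nominal table heights differ.

The package implements the full method around those observations:
preprocessing, a width-only training augmentation, deep-metric-learning
training with an adaptive cosine classifier, cosine gallery matching, and
the identification evaluation protocol — plus a synthetic scout phantom so
every stage is trainable and testable without clinical data.

## The phantom: what it emulates, and what it does not

`make_patient()` maps `(seed, id)` to stable anatomy: torso half-widths at
shoulder/waist/pelvis, torso height, lung area, spine periodicity, pelvis
aspect, an implant flag and a texture seed. `render_exam()` composes
soft-edged geometric primitives (a body silhouette with a spline
half-width profile, two lung ellipses, a sinusoidal spine band, a pelvic
ring, optional arms/implant/gas) into an anterior projection, scales the
width by `s(dh)`, rasterizes at the vendor's native spacing (S-like:
2.0 x 2.0 mm over a 560 mm field; G-like: 0.55 x 0.60 mm over 530 mm),
applies the vendor's monotone contrast curve, and adds Gaussian noise.

Design choices worth knowing:

* **Anatomy is schematic by design.** The goal is a *controllable identity
  signal* with realistic nuisance structure, not radiographic realism.
  Passing tests on the phantom shows the pipeline learns and evaluates the
  intended invariances; it does not certify accuracy on clinical images.
* **Vendor contrast curves** (log dynamic-range compression vs sigmoid)
  are identity below a low tissue threshold: vendors disagree about
  midtones and highlights, not about air being black. This also makes
  silhouette measurements with a near-background threshold
  contrast-invariant, which the geometry tests exploit.
* **Geometry:** `d0 = 600` mm, SID 1000 mm. A table offset of 23 mm then
  gives `s = 600/577 ~ 1.04`, the same magnitude as the augmentation's
  default scale factor.
* **Table offsets** are drawn per exam (baseline and follow-up
  independent) as `Normal(vendor mean, 14 mm)`. The vendor means differ by
  9 mm (S-like +4.5, G-like -4.5), reflecting reported per-device nominal
  table heights (about 144 vs 135 mm); this makes width magnification a
  *systematic* cross-vendor nuisance in addition to the per-visit spread.
  `nuisance_rates(table_mean_split = 0)` gives a vendor-free
  `Normal(0, 14)`.
* **Intra-patient nuisances** follow the reported relative frequencies of
  error causes: scan-range shift (rate 0.5, SD 25 mm), lung inflation
  (0.4, multiplier 0.85–1.15), intestinal gas (0.325, 1–3 pockets), arms
  raised (0.225). These rates are read from a table of error *reasons*, so
  they are upper-bound-ish occurrence rates — a deliberate, documented
  approximation.
* **Cohort design.** Training-pool patients contribute >= 3 exams with the
  last held out for validation (images used for training or validation,
  never both); test-pool patients contribute one trusted baseline and —
  for a configurable fraction — one follow-up query. Scanner assignment
  per exam is a policy (`random` or `fixed` per patient) because the
  acquisition process behind an archive is rarely known.

## Preprocessing

`preprocess()` is the fixed chain: bicubic resampling to 2.0 x 2.0 mm,
central 256 x 384 (columns x rows) crop with zero padding for deficits,
then a per-image linear rescale to 8 bits. Numerical choices:

* The resampler is the classical cubic-convolution (Keys) kernel with
  `a = -0.5`, separable by axis; output dimensions are
  `round(dim * spacing_in / spacing_target)` and sample positions align
  physical pixel centers, so physical extent is preserved to within one
  target pixel. An image already at target spacing passes through
  unchanged.
* Crop origin uses `floor()` on odd excess (test-pinned); padding is
  symmetric with the extra pixel after.
* The 8-bit rescale is per-image min–max; whether a fixed global window
  would be preferable is a real question for clinical data, but per-image
  scaling is the safe default when acquisition windows are unknown, and it
  is flagged in the configuration. A constant image maps to all zeros
  (avoids 0/0).

## Augmentation

`augment_pipeline()` applies four layers in order: random perspective
(corner displacement up to 10% of half-size, probability 0.5), random
rotation (±3°, probability 0.5), **random transversal scaling**, and a
center crop back to 384 x 256. No flips, ever — mirrored anatomy is a
clinically harmful transformation, and the property suite asserts that no
draw ever mirrors an asymmetric pattern.

Random transversal scaling is the method-specific layer: with probability
`p` (default 0.25) the width is resized to `round(W * s)` by bicubic
interpolation with `s ~ Uniform[1/f, f]` (default `f = 1.04`), the height
untouched, then re-center-cropped. The symmetric range `[1/f, f]` mirrors
tables positioned above or below the isocenter; a one-sided `[2 - f, f]`
variant is available via configuration. Magnitudes for perspective and
rotation are conservative defaults, configurable; augmentation operates on
the preprocessed 8-bit image (applying it before the 8-bit rescale would
be an equally defensible ordering — it is fixed here and flagged in the
configuration).

## The embedder

The training classifier is: backbone features, a projection head
(linear → ReLU → batch norm → linear), L2 normalization, and an adaptive
cosine-softmax (AdaCos) layer with one class per training patient.

* **Backbone contract.** Any deterministic image-to-vector map fits; at
  full scale a large pretrained CNN producing 1280-d features fills the
  slot. The desk-scale reference backbone is four blocks of
  conv(3x3) → channel batch norm → ReLU → avgpool(2x2) over an input that
  is per-image standardized and block-mean downsampled (factor 4), ending
  in global average pooling (64-d by default). The conv hot loops are
  compiled (im2col + BLAS) with hand-derived backward passes, verified
  against finite differences in the test suite.
* **Per-image input standardization** removes the first-order
  brightness/contrast component of the vendor shift. Without it, at desk
  scale, embeddings cluster by vendor and cross-vendor matching collapses.
* **Deployed embedding.** At full scale the natural deployment is the raw
  backbone feature vector (head dropped). At desk scale the pooled
  features of a small, briefly trained backbone retain a dominant
  identity-independent component (all cosines ~0.995, chance-level
  ranking, observed directly on an 8-patient phantom), so the package
  deploys the head output by default (`deploy_head = TRUE`); the
  head-dropped variant remains one flag away.
* **AdaCos.** Cosine logits are scaled by an adaptively chosen `s`:
  initialized at `sqrt(2) log(C - 1)`, then after each step
  `s = log(B_avg) / cos(min(pi/4, theta_med))` where `B_avg` is the batch
  mean of the summed non-target `exp(s cos)` terms and `theta_med` the
  median target angle. Class counts below 3 are rejected (the initial
  scale degenerates). A non-finite or non-positive update is skipped, so
  the scale stays finite and positive — asserted over training in the
  tests.
* **Loss and optimizer.** Label-smoothed cross entropy
  (`t_k = eps/C + (1 - eps)[k = y]`, `eps = 0.05`), momentum SGD
  (momentum 0.8, weight decay 0.002 on weight matrices), cosine-decay
  learning rate 0.005 → 0.0005 without warmup, batch size 20. A generic
  sharpness-aware two-step wrapper (perturb by `rho` along the gradient
  direction, then descend from the perturbed point) is available with
  `sam_rho = 2`; the element-wise adaptive variant of that optimizer is
  not specified precisely enough to reproduce, so plain momentum SGD is
  the desk default.
* **History.** Training records (every epoch, or every `k`-th) the loss,
  the AdaCos scale, validation top-1 accuracy and genuine/impostor
  similarity means ± SDs between validation images and per-class training
  references. The genuine/impostor track is the overtraining diagnostic:
  in the full-scale regime, training far past the optimum drives both
  distributions toward 1.0 as the representation collapses. At desk scale
  that signature does **not** reproduce: a small model trained from
  scratch *starts* with near-collapsed embeddings (an untrained network
  maps all images to almost the same direction) and training moves it
  monotonically toward separation, so extending the run lowers, rather
  than raises, the impostor mean — measured directly by the acceptance
  suite, which reports the mid- and late-checkpoint impostor means of an
  extended run and (honestly) fails the drift assertion. Demonstrating
  the collapse would require the over-parameterized, long-horizon regime
  of a full-scale extractor.

## Matching and evaluation

Enrollment keeps exactly one baseline embedding per patient (earliest
exam), L2-normalized once, so matching a query is a single matrix product;
results are identical to unnormalized cosine similarity, and a brute-force
pairwise loop is the test oracle. Ranking is descending by similarity with
ties broken by ascending gallery index (stable, documented). Multi-image
enrollment with max-score fusion exists behind a flag but is off by
default.

`stratified_eval()` reports acc@K overall, per (baseline vendor, follow-up
vendor) cell with counts, pooled same-/different-vendor groups, the CMC
curve, genuine/impostor score summaries, and the list of queries beyond
the alert rank with their top scores (rank-based alerting; a
similarity-threshold alert would be an alternative deployment rule, not
implemented as the primary because its operational form is
underdetermined). Queries whose patient is not enrolled are excluded from
accuracies, counted and reported. Statistical comparisons use the pooled
two-proportion Z-test (unpaired subsets) and McNemar's chi-squared test on
discordant pairs (paired conditions; continuity correction on by default,
uncorrected and exact-binomial variants reported alongside; the exact
variant engages below 25 discordant pairs). Raw p-values, no
multiple-testing adjustment — noted in the report.

## Problem sizes and the desk-scale experiment

The bundled experiment (`augmentation_experiment()`) uses 60 patients (30
training classes with 2 training + 1 validation images each; 30 test
patients with baseline + follow-up), two vendors assigned per exam at
random, 30 training epochs, and three master seeds — paired runs differing
only in whether the transversal-scaling layer is active. These sizes are
the package's chosen desk-scale study conditions: large enough for a
directional comparison of the augmentation's cross-vendor effect,
small enough to run on one CPU core in minutes. Absolute accuracies at
this scale sit far below published full-scale values (hundreds of training
patients, a large pretrained backbone, hundreds of epochs); the
comparison of interest is directional — cross-vendor accuracy should not
be hurt, and is expected to be helped, by the width-scaling layer, while
same-vendor accuracy should not degrade materially.

```{r, eval = FALSE}
library(scoutreid)
res <- augmentation_experiment(seeds = 1:3)
res
```

## Known limitations

* The phantom's identity signal is stronger and cleaner than clinical
  anatomy; its nuisance model is a handful of parametric toggles. Results
  transfer as *mechanism demonstrations*, not performance estimates.
* The desk backbone is orders of magnitude smaller than a production
  feature extractor; with 30 training classes the AdaCos scale operates
  far from its large-C regime.
* DICOM containers are not read or written; images travel as 16-bit TIFF
  with a JSON metadata sidecar (pixel spacing mandatory, never assumed).
* Verification-mode metrics (ROC/EER) are out of scope; the evaluation is
  identification-only, matching the method's deployment concept.
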