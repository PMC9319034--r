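---
title: "Perceptual colour co-occurrence texture features for dermoscopic BCC triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual colour co-occurrence texture features for dermoscopic BCC triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermccm)
```

## The clinical problem and the model

Basal cell carcinoma (BCC) is the most common non-melanoma skin cancer.
Dermatologists diagnose it from dermoscopic images by recognising seven
characteristic structures: the pigment network (brown reticular lines, the
sole *negative* criterion — its presence argues against BCC), and six
positive criteria — ulceration, blue-gray ovoid nests, multiple blue-gray
globules, maple-leaf areas, spoke-wheel areas and arborizing telangiectasia.
The clinical criterion combines them: BCC is favoured when at least one
positive structure is present and the pigment network is absent.

`dermccm` implements this assessment as a transparent pipeline:

1. **Colorimetry.** Image pixels are mapped from sRGB into a perceptually
   uniform working space — CIELAB or CAM16-UCS, the uniform space derived
   from the CIECAM16 colour appearance model — where Euclidean distance
   approximates perceived colour difference (ΔE*ab and ΔE′ respectively).
2. **Palette learning.** The main colours of each dermoscopic pattern are
   found by Euclidean K-means over the pooled pixels of that pattern's
   training tiles (18 centroids per pattern, 126 in total); near-duplicate
   centroids across patterns are then merged, with the merge threshold
   adjusted automatically so that exactly 20 master colours remain. Every
   tile is quantized by nearest-centroid assignment in the working space.
3. **Texture.** From the quantized index map a colour co-occurrence matrix
   (CCM) is accumulated: `P[i, j]` estimates the probability that palette
   colours *i* and *j* co-occur at a given spatial offset. Five statistics
   are extracted — homogeneity, mean colour, variance, correlation, entropy —
   in which the classical integer level difference `|i - j|` of Haralick
   statistics is replaced throughout by the perceptual colour difference
   ΔE(C_i, C_j) between the palette centroids. The classical GLCM on the L*
   channel is provided for comparison.
4. **Detection and diagnosis.** A small multilayer-perceptron detector maps
   the texture record to seven per-pattern probabilities (multilabel:
   several structures can coexist in a tile), which are thresholded and fed
   to the clinical rule. The output is a BCC/non-BCC call *together with*
   the detected structures — an explanation, not just a label.

### The five CCM statistics

With `P` the joint co-occurrence probability over the `n`-colour palette,
`C_i` the centroid colours, `p_i` the row marginal, `mu = sum_i C_i p_i` the
marginal mean colour and `sigma^2 = sum_i p_i ΔE(C_i, mu)^2` its ΔE
dispersion:

* homogeneity `H = sum_ij P_ij / (1 + ΔE(C_i, C_j)^2)` — 1 for a constant
  image, small when distant colours co-occur;
* mean `mu = sum_ij C_i P_ij` — a working-space 3-vector equal to the
  (offset-weighted) image mean colour;
* variance `sigma^2 = sum_ij ΔE(C_i, mu)^2 P_ij` — perceptual contrast;
* correlation
  `rho = sum_ij ΔE(C_i, mu_i) ΔE(C_j, mu_j) P_ij / (sigma_i sigma_j)` —
  because ΔE is non-negative this is a non-negative co-dispersion index,
  not a signed correlation; it is defined as 0 when either sigma vanishes;
* entropy `S = -sum_ij P_ij ln P_ij` (natural log, with `0 ln 0 := 0`) —
  0 for a constant image, at most `ln(n^2)`.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| working space | `cam16ucs` | CAM16-UCS preserved colour appearance best in our quantization experiments; `lab` is available throughout |
| viewing conditions | D65 white, L_A = 64 cd/m², Y_b = 20, average surround | the de-facto defaults of the colour-appearance literature for display viewing |
| adaptation | full (`discount_illuminant = TRUE`) | forces the degree of adaptation D to 1 so the adopted white is exactly achromatic; with luminance-derived D the white keeps residual chroma (~1.7), breaking the white → (100, 0, 0) contract |
| stage-1 k | 18 per pattern | palette granularity before merging |
| master palette size | 20 | the merged palette over all seven patterns |
| co-occurrence offsets | distance 1 at 0°, 45°, 90°, 135°, symmetric | the classical Haralick set; it is closed under 90° rotation, so direction-averaged features are robust to the rotation augmentation |
| GLCM binning | 32 uniform bins on L* ∈ [0, 100] | a conventional grey-level resolution |
| detector | 7 one-vs-rest MLP heads, 8 hidden units, weight decay 1e-3, ≤ 500 iterations | binary cross-entropy per head; positive case weight n_neg/n_pos (capped at 20) counters class imbalance |
| thresholds | 0.5, or per-pattern Youden's J on a validation set | `youden_thresholds()` maximizes sensitivity + specificity − 1 |
| rule mode | `strict` | see below |

## Design choices made where the design was open

* **Merge semantics.** "Merge pairs below a threshold" is order-dependent if
  applied pairwise; we define it as single-linkage agglomeration (connected
  components of the ΔE-below-threshold graph collapse to weight-weighted
  means). Adjusting the threshold to leave exactly 20 colours is then
  exactly a cut of the single-linkage dendrogram, which we compute with
  `hclust`/`cutree`; this is deterministic and always achieves the target
  count, even across merge-height plateaus.
* **K-means.** Lloyd iterations with random-pixel initialisation, 10
  restarts keeping the best objective, at most 300 iterations; pixels of all
  tiles of a pattern are pooled (with a seeded subsampling cap, 5·10⁴ per
  image and 2·10⁴ per pattern by default) rather than clustered per image.
* **Correlation denominator.** The statistic is normalised by
  `sigma_i * sigma_j`, the standard co-occurrence normalisation that makes
  it scale-free; a `sigma_squared_product` variant is exposed as a config
  switch for sensitivity analyses.
* **Degenerate images.** A constant tile yields the fixed feature vector
  (homogeneity 1, mean = its centroid colour, variance 0, correlation 0 by
  the `sigma = 0` convention, entropy 0). Quantization ties break to the
  lowest palette index; a probability exactly equal to its threshold counts
  as detected.
* **UCS colour difference.** ΔE′ is the Euclidean norm over (J′, a′, b′);
  M′ is retained on the UCS object for traceability but is redundant with
  (a′, b′) by construction.
* **Rule modes.** The clinical criterion reads the pigment network as a
  veto: `strict` calls BCC only when a positive pattern is present *and*
  the network is absent. A `permissive` mode ignores the veto (any positive
  pattern suffices). The two differ only when the network co-occurs with a
  positive pattern; `strict` is the default because it follows the stated
  clinical criterion, and both are exposed because the operational wording
  of a rule-based triage step can legitimately be read either way.
* **Centroid rendering.** Centroids live in the working space; for display
  each keeps the weighted mean sRGB of its member pixels. When no member
  pixels are available (hand-authored palettes), the inverse transform is
  used — analytic for CIELAB, numerical least-squares inversion of the
  forward model for CAM16-UCS (display-only accuracy, ~1e-3 in sRGB).
* **Numerical floor of the saturation correlate.** For exactly achromatic
  stimuli the chromatic components vanish only to machine precision;
  `s = 100 sqrt(M/Q)` amplifies that floor to ~1e-5, so contracts on
  achromatic inputs are asserted on chroma and colourfulness (< 1e-6), with
  a looser 1e-4 bound on saturation.

## The synthetic-data generator

Clinical dermoscopy databases with per-pattern annotations are private, so
the package ships a seeded generator of pattern-labelled tiles:
each pattern is emulated by a simple geometric motif in its characteristic
colours on a skin-toned background — brown jittered mesh (pigment network),
irregular red patch with a pale core (ulceration), few large blue-gray
ellipses (ovoid nests), many small blue-gray discs (globules), brown-gray
lobes along a border arc (maple leaf), tan lines radiating from a hub
(spoke wheel) and red branching curves (telangiectasia). Tiles default to
256 × 256 like clinical pattern tiles; composites superpose several motifs
and pattern-free tiles provide negatives. The augmentation scheme emits, per
tile, the original plus its 90°/180°/270° rotations (exactly ×4), each
variant independently flipped horizontally/vertically with probability ½; no
colour jitter is applied, because the diagnosis is colour-based.

What the generator *does* emulate: planted colour structure, motif-specific
spatial statistics, multilabel composition, class imbalance knobs, seeded
reproducibility. What it does *not*: photorealistic lesion texture, hair and
rulers, illumination drift, inter-device colour shifts, ambiguous boundary
cases. Passing the end-to-end tests therefore demonstrates that the
machinery recovers planted colour-texture structure — not clinical-grade
performance on real lesions, which requires a real annotated database
through the same interfaces (`feature_table()`, `train_pattern_classifier()`).

## Desk-scale study sizes

The end-to-end harness (`run_synthetic_study()`) trains on 50 single-pattern
tiles per pattern (plus 20% composites and 20% pattern-free tiles) at
96 × 96, with stage-1 clustering capped at 2·10⁴ pooled pixels per pattern,
and evaluates on an independently seeded dataset of the same shape. These
sizes are the package's chosen study conditions: large enough that macro AUC
and the binary operating point are stable (≈ 0.99+ across seeds), small
enough to run on a laptop in about a minute.

```{r study, eval = FALSE}
study <- run_synthetic_study(n_per_pattern = 50, size = c(96, 96),
                             train_seed = 1, test_seed = 2)
study$multilabel$macro
study$binary
```

## Known limitations

* The detector consumes the seven averaged CCM scalars only; it is the
  desk-scale stand-in for a deep image branch, and the feature record is the
  plug-in point if one is added.
* CAM16-UCS inversion (display rendering only) is numerical and clips
  out-of-gamut colours.
* ROC/AUC uses threshold sweeps with tie grouping (Mann–Whitney with ½
  ties); no confidence intervals are provided.
* Metrics with empty denominators raise errors by design — silent zeros
  would corrupt macro averages over rare patterns.
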