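---
title: "Dose prediction with hierarchically dense attention U-nets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose prediction with hierarchically dense attention U-nets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hdadose predicts 3D radiotherapy dose distributions for head-and-neck cases
from a CT volume and binary structure masks, in the knowledge-based-planning
tradition: learn from previously delivered plans what dose distribution is
achievable for a new anatomy. This vignette explains the model family, the
training objective, the synthetic phantoms used throughout the test suite,
the evaluation metrics, and the numerical and design choices that are not
obvious from the function documentation.

## Input encoding

A case is a `plan_case`: a CT volume, a `structure_set` of binary masks
(nested target volumes GTV ⊂ CTV ⊂ PTV plus organs at risk), a reference
dose in Gy and a prescription. `assemble_channels()` encodes a case as a
`(nx, ny, nz, 1 + S)` array: channel 1 is the min-max-normalized CT, then
one binary channel per structure in a fixed cohort-wide order. Structures a
case lacks become all-zero channels: clinical cohorts rarely have every organ
delineated for every patient, and a fixed channel count is the only encoding
compatible with a single network. Such structures are likewise excluded from
per-case losses and metrics.

Clinical planning CTs commonly arrive at 512 x 512 in-plane;
`downscale_volume()` reduces the in-plane axes by an integer factor (cubic
spline interpolation for scalar volumes, linear-then-threshold for masks so
they remain binary) because full-resolution 3D training is memory-prohibitive
and patch-based alternatives lose the global context that matters when dose
must anticipate tumor proximity beyond a patch boundary. The cranio-caudal
axis is left untouched. Non-divisible extents resample to `ceiling(n/factor)`
without padding.

Dose is normalized per case by its own maximum (recorded, so evaluation is
always in Gy). The alternative — normalizing by the prescription — is
equally defensible; the per-case maximum was chosen because it bounds the
network target to exactly [0, 1] regardless of hot spots, and the recorded
scale makes the two conventions interconvertible after the fact.

## The architecture family

Three variants share one interface (`arch_config()` + `build_model()`):

* **HD U-net** — a hierarchically dense U-net. Within a resolution level,
  a *dense convolution* applies a 3x3x3 convolution producing `growth_rate`
  (default 16) channels, ReLU, and concatenates the result onto its input,
  so features grow linearly rather than doubling. *Dense downsampling*
  concatenates a stride-2 convolution (again `growth_rate` channels) with
  2x max pooling of the existing features. The encoder applies two dense
  convolutions and one dense downsampling per level; the bottom level uses
  four dense convolutions (cheap at 8 x 8 x 6 resolution). The decoder
  mirrors: trilinear upsampling to the skip's grid, a 3x3x3 convolution to
  64 channels, concatenation with the skip, and two dense convolutions. A
  1x1x1 convolution produces the dose channel.
* **HDA U-net** — the same hierarchy with a soft attention gate on every
  skip connection and batch normalization after each convolution. The gate
  projects skip and gating features (both 1x1x1 convolutions) to a common
  width, sums, applies ReLU, projects to one channel and squashes with a
  sigmoid; the resulting per-voxel coefficients in [0, 1] multiply the skip
  features before concatenation. The gating signal is the decoder's
  post-upsample convolution output.
* **attention U-net** — the standard channel-doubling U-net (base width 32)
  with the same attention gates, as the conventional high-capacity baseline.

Two width conventions deserve a note, because they fix the parameter counts.
First, the post-upsample convolution outputs 64 channels at every decoder
level — the same 64 that enters the attention gate as its gating signal and
serves as the gate's intermediate projection width. With that convention the
HDA variant counts 3,455,386 trainable scalars (3.5M) and the HD variant
3,404,950 (3.4M); the attention baseline is ~26M. Second, batch
normalization is placed convolution → batch norm → ReLU, the common ordering
when the original description does not specify; with batch size 1 it
normalizes over the spatial extent per channel, with running moments used at
evaluation time.

Odd spatial extents are handled by ceiling-mode pooling/striding and by
upsampling *to the skip's grid* rather than by a fixed factor, so any input
with all axes ≥ 2^(levels-1) works; smaller inputs raise an error that
reports the padding required.

The network stack is implemented in the package itself — a small tape-based
reverse-mode autodiff over 4D feature maps with C++ kernels for convolution
(line-blocked im2col + GEMM, sized so the column buffer stays cache-resident),
pooling, trilinear resampling and their adjoints. Backward convolution reuses
the forward machinery by convolving the output gradient with the flipped,
transposed kernel. All kernels are verified against brute-force oracles and
central finite differences in the test suite.

## The training objective

The differentiable DVH replaces the exact threshold indicator with a
sigmoid. For structure $s$ with mask $M_s$ and threshold grid $d_t$
(default 0, 1, …, 80 Gy — 81 values, inclusive endpoints — with bin width
$\beta_t = 1$ Gy):

$$ \tilde v_{s,t}(D) \;=\; \frac{\sum_{ijk} \sigma\!\big(\tfrac{m}{\beta_t}(D_{ijk} - d_t)\big)\, M_s(ijk)}{\sum_{ijk} M_s(ijk)} $$

with steepness $m = 1$: soft enough to keep gradients alive across the whole
dose range (steeper sigmoids approximate the exact DVH better but starve
training of gradient), yet close enough that curve discrepancies are
meaningful. The DVH objective averages squared curve differences over
structures and thresholds,

$$ L_{\mathrm{DVH}} = \frac{1}{n_s n_t} \sum_s \big\lVert \tilde v_s(D_{\mathrm{true}}) - \tilde v_s(D_{\mathrm{pred}}) \big\rVert_2^2, $$

and the total objective is $L = w_1 L_{\mathrm{MSE}} + w_2 L_{\mathrm{DVH}}$
with $w_1 = 1$, $w_2 = 0.1$, weights that put both terms on the same
magnitude for a trained model while keeping the strongly convex MSE in
charge of convergence. All nonempty structures of a case — targets and
OARs — enter the sum; empty masks are skipped and $n_s$ counts only the
structures present.

One subtlety: training runs on normalized dose, but thresholds are stated in
Gy. Because the sigmoid argument is $(m/\beta_t)(D - d_t)$, dividing $D$,
$d_t$ and $\beta_t$ by the same per-case scale leaves every term unchanged,
so the package rescales the threshold grid (and bin width) by each case's
normalization and the loss value is identical to its Gy-space definition.
The gradient of the combined objective is computed in closed form and
injected into the network's tape (`combined_loss_grad()`), and is checked
against central finite differences.

Optimization follows the published protocol exactly: Adam with learning rate
1e-3, $\beta_1 = 0.9$, $\beta_2 = 0.999$, $\varepsilon = 10^{-7}$, batch
size 1 (one volumetric case per step), 200 epochs, no augmentation, schedule
or early stopping; the returned weights are those of the epoch with the
lowest validation loss (first such epoch on ties). Cohorts split
70/15/15 by a seeded shuffle, validation and test sizes rounded and the
remainder assigned to training (150 cases → 106/22/22); explicit id lists
(e.g. the public challenge's fixed 200/40/100 partition) pass through
untouched. Every stochastic ingredient — weight initialization (He), epoch
shuffling, the split — derives from the one configured seed, so runs are
bitwise reproducible.

## Synthetic phantoms

`phantom_spec()`/`generate_cohort()` produce the fully synthetic cohorts the
test suite trains and evaluates on. Each case is an ellipsoidal "head" CT
with air/tissue/bone bands, nested GTV/CTV/PTV ellipsoids (fixed 0.45/0.70/1
semi-axis ratios about a common center, so nesting is exact), and several
disjoint OAR blobs placed inside the head and away from the PTV, with
bounded rejection sampling and a hard error if geometry cannot be placed.

The reference dose emulates a clinically plausible plan:

$$ D(x) = 1.05\,R_x\; \sigma\!\left(\frac{-\,d(x) + 2.5\,\tau}{\tau}\right)\cdot\big(1 - s\,\mathrm{OAR}_\sigma(x)\big) + \epsilon $$

where $d(x)$ is the signed Euclidean distance to the PTV surface (negative
inside, computed by a separable distance transform), $\tau$ is the falloff
scale (default 2 mm), $\mathrm{OAR}_\sigma$ is the union of OAR masks
blurred by a 3-voxel Gaussian, $s$ is the sparing fraction (default 0.3) and
$\epsilon$ is i.i.d. Gaussian noise (default 0.5 Gy), with the result
clipped at zero. Two calibration choices matter. The falloff midpoint sits
$2.5\tau$ *outside* the PTV surface so that the entire PTV interior clears
95% of prescription even at sharp gradients ($\tau \le 2$ mm) — a falloff
centered on the surface itself would leave boundary voxels near half the
prescription, which no acceptable plan does. The modest 1.05 hot-spot factor
makes the prescription isodose surface wrap the PTV tightly, so conformity
measures behave like their clinical counterparts. Under the defaults a
cohort's ground-truth metrics land in the clinically reported regime:
mean D95 ≈ 0.95–1.01 of prescription, H1 ≲ 0.08, van't Riet ≳ 0.6.

What the phantoms deliberately do not model: beam/arc physics and
deliverability, CT Hounsfield calibration, inter-observer contouring
variability, and the anatomical diversity of real patients. Tests passing on
phantoms therefore demonstrate that the machinery (encoding, architecture,
objective, optimization, metrics) is correct and trainable, not that
clinical-scale accuracy transfers to real cohorts; the OAR-sparing dip
exists precisely so the DVH term has a structure-specific signal to improve,
mirroring its intended clinical role.

## Evaluation

All dosimetric measurements treat voxels as equal-volume. $D_p$ is the dose
received by at least $p$% of a structure: masked doses sorted descending,
value at rank $\lceil p n / 100 \rceil$ (the lower empirical quantile — this
convention keeps $D_{99} \le D_{98} \le D_{95} \le D_{50} \le D_2$ exactly
and matches direct rank enumeration). Coverage (D99, D98, D95) and the
global single-voxel Dmax are reported as fractions of prescription;
homogeneity is $H_1 = (D_2 - D_{98})/D_{50}$ and $H_2 = D_{95}/D_{50}$.
With $V_{100}$ the set of voxels at or above prescription, the van't Riet
conformation number is $|PTV \cap V_{100}|^2 / (|PTV|\cdot|V_{100}|)$ (zero
when $V_{100}$ is empty). For the conformity index, which has no single
agreed formula, the package uses target coverage
$|PTV \cap V_{100}|/|PTV|$ — the reading consistent with CI always bounding
the van't Riet number from above, which the factorization
vantRiet = coverage × selectivity guarantees. Per-structure mean dose error
is the mean absolute voxel difference as a percent of prescription, and
method comparisons use the two-tailed equal-variance Student t-test
(Welch optional), with p = 1 by convention for two degenerate equal samples.

## Problem sizes in the test suite

The suite exercises everything at desk scale, chosen once: full-size
networks are built (for parameter counting) but trained networks are tiny
(growth 4, 2–3 levels, gate width 8) on 20^3–32^3 phantoms. The overfit
check trains 200 epochs on one noise-free 32^3 case — the reference dose is
then a deterministic function of the input channels, so driving training MSE
below 5e-3 (and prediction MAE below 5% of prescription) is a sharp
end-to-end test of gradients and optimizer. The DVH-benefit check trains
both objectives on a 20-case spared cohort for 60 epochs at 20 x 20 x 12,
across three seeds, and compares held-out mean absolute exact-DVH-curve
error. It is a directional, stochastic check by nature, and the hardest of
the suite to scale down: with tiny models on small heterogeneous cohorts,
neither objective reaches full convergence and the between-seed spread of
the held-out curve error is of the same order as the effect being measured,
so this check can land on either side of the line at desk scale. The epoch
count is chosen as the largest the default suite can afford, because the
comparison is only meaningful between reasonably converged models; the
result should be read as directional evidence only. Published-scale
training (hundreds of 128 x 128 x [32–96] cases, 200 epochs) is out of scope
for the suite.

## Known limitations

* The trainer is CPU-bound and single-case batched; it is written for
  correctness, reproducibility and desk-scale experiments, not for
  production training throughput.
* Batch normalization with batch size 1 is effectively instance
  normalization with running statistics; at published scale this is the
  faithful reading of the protocol, but small-phantom runs keep it mostly
  redundant (biases preceding it are absorbed, as the parameter-count tests
  acknowledge).
* The OpenKBP-style reader implements the documented sparse-CSV layout with
  a fixed 128^3 grid and a stated index-order convention; it is validated by
  round-trip, not against the original challenge archive.
* Multi-PTV prescriptions (PTV70/63/56) are supported at the metric level by
  evaluating each target against its own level via `prescription_context()`;
  the report's primary row uses the highest-dose PTV.
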