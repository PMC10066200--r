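---
title: "Retinex decomposition and self-supervised enhancement of dental images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinex decomposition and self-supervised enhancement of dental images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lumident)
```

## The model

Intra-oral photographs are frequently under-exposed and unevenly lit.
`lumident` treats an RGB image `S` (unit-interval intensities, `H x W x 3`)
as the pixelwise product of two latent factors,

$$S(x,y) = r(x,y)\,\cdot\,l(x,y),$$

with a 3-channel reflectance map $r \in [0,1]^3$ carrying tissue colour and
texture, and a single-channel illumination field $l \in [0,1]$ that is
spatially smooth except across strong scene boundaries.  Enhancement acts on
the factors separately and recomposes them, so brightness can be changed
without destroying reflectance detail.  The illumination is single-channel
and broadcast over RGB at recomposition, following the retinex lineage.

All internal computation uses unit-interval floats: 8-bit conventions
(white level 255, weighting offsets in (0, 255]) are divided by 255 at the
API boundary, so every formula below is dimensionless.

## The training-free chain

`classic_enhance()` needs no fitted model.  It exploits the observation
that an inverted low-light image, the *residue* $1 - S$, looks like a hazy
image, so dehazing machinery applies:

1. **Dark channel** (`dark_channel()`): per-pixel minimum over channels and
   a 3×3 window, replicate-padded at the borders.
2. **Global light**: the darkest 0.1 % of the dark channel of $S$ marks the
   regions where the residue is most opaque; the residue's global light is
   the per-channel mean of the residue there (i.e. one minus the mean of
   $S$), floored at 0.01 so it is safe to divide by.
3. **Transmission** (`estimate_transmission()`):
   $l = 1 - \min_{\omega}(1 - \max_c (1-S^c)/a^c)$, clipped to $[0,1]$.
   On the residue this map is low exactly where the original scene was
   dark, so it doubles as the illumination proxy.
4. **Radiance recovery** (`recover_radiance()`): inverts the formation
   model $S = r\,l + a(1-l)$ as $r = (S - a(1-l))/\max(l, 0.05)$.  The
   floor keeps the division well-posed where transmission vanishes; the
   round-trip is exact to numerical precision wherever the floor and the
   final clipping are inactive, which the tests verify.
5. **Weighted recomposition**: the recovered residue radiance is inverted
   back into an enhanced reflectance $r = 1 - J$, the transmission map is
   kept as $l$, and the brightness weights below are applied *in the output
   domain* before the product $S_r \cdot S_l$ is clipped once.

A design note on stage order: the ingredients above can be assembled in
more than one order, and the obvious alternative - weighting the residue
components and inverting the composite at the end - reverses the intended
behaviour of the brightness parameter $\eta$ (the weight $w_r \propto
1/\eta$ would brighten the residue and hence *darken* the output).  We
therefore weight in the output domain, which preserves the documented
relation "lower $\eta$, brighter output" and keeps the chain monotone; this
is asserted by the acceptance tests.

## Brightness weighting

Both enhancement paths share the exponential gain maps of
`weight_config()`:

$$w_l = \frac{e^{\,l}}{n}, \qquad
  w_r = \frac{e^{\,(\lambda - r)/m}}{\eta},$$

with $n, \eta, \lambda, m \in (0,1]$.  $w_l$ grows with $l$ and scales as
$1/n$; $w_r$ shrinks with $r$ and scales as $1/\eta$, so dark reflectance
is boosted the most.  Defaults are the mid-range $n = \eta = 0.5$ with
$\lambda = m = 1$ (the normalised top of their 8-bit ranges): the
reflectance gain is then $2e^{1-r}$, strongest for dark tissue and nearly
neutral for bright enamel.  The weighted components $S_l = l\,w_l$ and
$S_r = r\,w_r$ are deliberately *not* clipped where they are formed - the
training losses need the unclipped maps - and clipping happens once at
final image assembly.  The reflectance weight is computed per channel
(rather than on a luminance summary), matching the elementwise form above.

## The learnable branches

`luminet()` fits two small convolutional branches end-to-end:

* **Decomposition branch**: two 3×3 conv+ReLU stages of width 32, then a
  3-channel reflectance head and a 1-channel illumination head, each
  squashed to $[0,1]$ by $(\tanh(\cdot)+1)/2$.
* **Refinement ("edification") branch**: an encoder-decoder on the
  illumination.  Input is the concatenation of $l$ with the brightness
  target $\mathrm{clip}(l\,w_l(l;n)/e)$; two stride-2 conv+ReLU encoder
  stages (widths 16/32), a mirrored decoder with nearest-neighbour
  upsampling, skip connections, multiscale concatenation of the resized
  input at every decoder level, and a stride-1 tanh-squashed head.

Three architecture decisions deserve explanation:

* **Anchored heads.**  Each output head receives an input-derived logit
  offset: the illumination head is anchored at the lightly smoothed
  max-channel map of $S$ (a standard illumination prior), the reflectance
  head at $S$ divided by that anchor, and the refinement head at the
  brightness target.  With zero-initialised head weights, the network
  starts exactly at this classical decomposition and learns residual
  corrections.  This is what makes training effective at a learning rate
  of $10^{-4}$ and desk-scale step counts: a cold-started network cannot
  move its outputs by $O(1)$ in a few hundred Adam steps, whereas the
  anchored network starts from a good decomposition and spends its steps
  refining it (chiefly: smoothing the illumination).  The tanh squashing
  contract is untouched; only the pre-activation gains the offset.
* **Refinement widths 16/32.**  The single-channel refinement task needs
  little capacity, and these widths keep a desk-scale CPU training run in
  minutes.  Both widths are configuration knobs (`de_width`, `ed_widths`).
* **Conditioning signal.**  The refinement branch sees the inference-time
  brightness target, so changing `n` steers its output *without
  retraining*; the monotone steering property is part of the test suite.
  The reflectance map enters the refinement only through the edge-aware
  loss below, not through the forward pass.

## Training objectives

With constants `loss_weights()` ($\alpha_{re} = 0.004$,
$\alpha_{cal} = 0.3$, $\varphi = 10$):

* split loss: $\mathrm{mean}\,|r\,l - S|$;
* reflectance regulariser: $\mathrm{mean}\,|r|$, kept mild;
* edge-aware smoothness:
  $\mathrm{mean}\,|\nabla l \cdot w_l \cdot e^{-\varphi\,\nabla r\cdot w_r}|$,
  with forward differences (zero trailing edge), $\nabla r$ the
  channel-mean gradient magnitude per direction and $w_r$ the channel-mean
  weight, so the gate is a scalar map.  The gate suppresses the
  total-variation penalty exactly where the reflectance carries an edge,
  keeping illumination piecewise smooth without blurring real boundaries;
* composition loss on the refined illumination:
  $\mathrm{mean}\,|r\,\tilde l - S|$.

L1 norms are realised as means so the constants are
resolution-independent.  The decomposition branch minimises
split $+\,\alpha_{re}\,$reg $+\,\alpha_{cal}\,$smooth; the refinement
branch minimises composition $+\,\alpha_{cal}\,$smooth on $\tilde l$; a
single joint Adam step updates both (a `two_phase` option trains them
sequentially instead).  Two pragmatic backprop conventions: the weighting
maps inside the smoothness term ($w_l$ and the exponential gate) are
treated as constants during differentiation (the weighted-TV convention),
and the refinement input is detached from the decomposition branch.  The
data-term gradients are exact; the per-branch backward passes are verified
against central finite differences in the test suite.

Training is fully self-supervised - no reference image is ever read by the
trainer - and fully seeded: parameter initialisation, patch sampling and
shuffling all derive from one integer, and repeated runs are bitwise
identical on the same platform.  The default protocol is 100 epochs,
128×128 patches (one random patch per training image per epoch), batch 16,
learning rate $10^{-4}$.

## Synthetic data

`synth_triple()` generates (degraded, reference, true-illumination)
triples that emulate the statistical structure of intra-oral photographs:
two arcs of bright, slightly warm ellipses ("teeth", intensities
0.85-0.95) over a textured reddish-pink background ("mucosa", base colour
(0.65, 0.35, 0.35)); degradation is multiplicative - a blurred seeded
noise field, min-max normalised, raised to an under-exposure exponent
(default 1.8) and mapped onto $[0.15, 1]$ - plus mild additive Gaussian
noise ($\sigma = 0.01$) in linear intensity.  Defaults are 160×160 pixels
so the standard 128-pixel training patches fit.  Because the degradation
follows the multiplicative formation model exactly, parameter recovery is
well-posed and the recovered illumination can be compared against the true
field.

What the generator does *not* emulate: specular highlights, colour casts,
camera response nonlinearity, compression artefacts, motion blur and real
anatomical variability.  Passing tests on this data therefore demonstrate
the correctness and internal consistency of the pipeline and its
optimisation - not clinical performance on real photographs, which would
require the real image population and expert-validated references.

## Evaluation metrics

* **PSNR**: $10\log_{10}(1/\mathrm{MSE})$ on unit range, `Inf` for
  identical images.
* **SSIM**: the standard 11×11 Gaussian window ($\sigma = 1.5$),
  stabilisers $(0.01)^2$ and $(0.03)^2$, window positions fully inside the
  image, channel-averaged.
* **LOE** (lower is better): lightness is the per-pixel channel maximum;
  on a lattice of at most 50×50 sample points (bounding the quadratic pair
  count), the number of pixel pairs whose relative lightness order differs
  between input and output, divided by the number of sampled pixels.  Any
  strictly monotone tone map scores exactly 0.

All three match independent scalar-loop oracles in the tests.

## Numerical choices and degenerate inputs

* Window minima use replicate padding (avoids spurious dark borders);
  network convolutions use zero padding.
* Global-light selection breaks ties in stable column-major scan order, so
  results are deterministic.
* The global light is floored at 0.01 and the recovery divisor at 0.05.
* Inputs whose size is not a multiple of the refinement branch's
  downsampling factor (4) are reflect-padded and cropped back.
* Constant images pass through every stage without inventing structure
  (all operators are translation-invariant), and grayscale files are
  promoted to RGB by replication.
* Anchor logits are clamped to $[0.005, 0.995]$ before the inverse tanh.

## Desk-scale problem sizes

The shipped evaluation (`scripts/acceptance.R` and the acceptance tests)
uses 40 synthetic 160×160 triples - 32 for training, 8 held out - with 20
epochs, batch 8 and learning rate $10^{-4}$: small enough to run on one
CPU core in minutes, large enough that the decomposition quality
(reconstruction error, illumination correlation) and the enhancement gain
(PSNR over the degraded input) are meaningfully measurable.  The numbers
it reports are computed fresh on every run.

## Known limitations

* The refinement branch's composition loss pulls $\tilde l$ towards the
  observed illumination while the brightness target pulls it brighter;
  with the anchored design the balance is stable at desk scale, but very
  long training would favour reconstruction over steering.
* The reflectance regulariser opposes the split loss by construction; its
  small weight (0.004) keeps the tension mild, and it is implemented as
  specified rather than "repaired".
* LOE is computed on a downsampled lattice; full-resolution LOE values are
  larger by roughly the downsampling factor squared.
* The classical chain can saturate bright regions at aggressive settings
  (low `eta` *and* low `n`); the learned path is gentler because the
  refinement branch, not a second gain map, adjusts the illumination.
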