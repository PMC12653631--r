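---
title: "Lesion-constrained adversarial attacks: models, losses and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion-constrained adversarial attacks: models, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The attack model

`latatk` generates adversarial examples for medical image classifiers under
a hard spatial constraint: the perturbation may only live inside a
segmented lesion region. Given a clean image $x$ with true label $y$, a
frozen surrogate classifier $F$, and a binary attackable mask $M$ (the
lesion support; its complement $\bar M = 1 - M$ is untouchable), the
adversarial image is

$$x_{adv} \;=\; x \odot \bar M \;+\;
  \mathrm{Clip}_{x,\varepsilon}\!\bigl(x + \varepsilon\, G_\theta(x)\odot M\bigr)\odot M ,$$

where $G_\theta$ is a trained encoder–decoder generator whose Tanh head
bounds its raw output to $[-1,1]$, $\varepsilon$ is the perturbation budget
on the $[0,1]$ intensity scale, and $\mathrm{Clip}_{x,\varepsilon}$ clamps
into $[x-\varepsilon, x+\varepsilon]\cap[0,1]$. Two constraints are stated
separately in the underlying method — the Tanh range bound on the raw field
and the $\|\eta\|_p < \varepsilon$ budget on the applied perturbation — but
never connected; we satisfy both constructively by scaling the Tanh output
by $\varepsilon$ *before* masking and clipping. The norm is taken as
$p=\infty$: clip-based enforcement implies a box constraint, and no other
order is ever stated.

The generator is trained by minimising

$$L \;=\; -\,L_{adv} \;-\; \lambda_{CAM}\, L_{CAM} \;+\; \lambda_{LBP}\, L_{LBP},$$

i.e. gradient descent on $L$ *maximises* the classification damage and the
class-activation disruption while *minimising* the texture damage:

* $L_{adv}$ — cross-entropy of the surrogate's logits on $x_{adv}$ against
  the true label.
* $L_{CAM}$ — squared discrepancy between the Grad-CAM maps of $x$ and
  $x_{adv}$ at the surrogate's last convolutional layer. Channel weights
  are spatial means of $\partial \ell_y / \partial A$ with $\ell_y$ the
  pre-softmax logit; the map is the rectified weighted activation sum at
  the layer's native resolution, with no upsampling and no min–max
  normalisation (the defining equations contain neither).
* $L_{LBP}$ — squared discrepancy between local-binary-pattern texture
  maps of the two grayscales (BT.601 luma), which penalises visible
  texture damage.

Default weights are $\lambda_{CAM} = 1$ and $\lambda_{LBP} = 0.5$.

## Parameters that matter

| parameter | default | units / scale | notes |
|---|---|---|---|
| `epsilon` | 0.01 | [0,1] intensity | training default; 0.1 is the bound used in attack experiments, and both are exercised in the tests |
| `learning_rate` | 5e-5 | — | Adam step size for $\theta$ |
| `weight_decay` | 1e-5 | — | L2, folded into the gradient |
| `batch_size` | 32 | samples | |
| `epochs` | 50 | — | |
| `lambda_cam`, `lambda_lbp` | 1, 0.5 | — | |
| `soft_lbp_temperature` | 0.1 | [0,1] intensity | see below |
| `use_mask`, `use_cam`, `use_lbp` | on | — | ablation flags ("w/o Seg", etc.) |
| `normalize_per_channel` | on | — | classifier-input branch only |

## Differentiating the texture term

The hard LBP code thresholds each of the 8 neighbours against the centre
pixel (bit = 1 when the difference is $\ge 0$, so a constant image codes to
255 everywhere) and weights the bits $2^0..2^7$ clockwise from top-left.
As a function of the image this is a step function: its gradient is zero
almost everywhere, so the published objective cannot be optimised by
gradient descent as stated. Training therefore uses a logistic relaxation,
$\mathrm{bit}_q = \sigma\!\bigl((I(q)-I(c))/T\bigr)$, which converges to
the hard code as $T \to 0$ wherever no difference is exactly zero. Hard
codes are used for reporting, the soft map for gradients. The temperature
(default $T = 0.1$ on the intensity scale) sets how sharp the relaxation
is; note that the *strength* of the texture penalty this induces is far
greater than whatever pressure the non-differentiable original exerted —
see "Limitations".

Squared-norm reductions for both discrepancy losses are **means** over
cells (a `reduce = "sum"` mode exists): mean reduction keeps the loss scale
stable across image and layer sizes.

## Gradient flow

Backpropagation runs through the composition chain (clip pass-through where
the box constraint is inactive, zero where it binds), the classifier-input
normalisation, and the surrogate into the generator only; the surrogate is
frozen and verified bit-identical after training. Two one-sided treatments
are deliberate:

* The clean image's CAM and soft-LBP maps are fixed references (cached per
  sample; the mask of a sample is likewise computed once and cached, since
  the segmentation input never changes during attack training).
* The Grad-CAM channel weights of the adversarial branch are treated as
  constants when differentiating $L_{CAM}$. For the classifiers shipped
  here (global-average-pooling heads) the channel weights are
  algebraically independent of the input, so this "first-order" treatment
  is exact, not an approximation.

Every layer primitive and the full composed chain are validated against
central finite differences in the test suite.

## Per-channel normalisation

The classifier-input branch standardises each channel to mean 0 / sd 1
with a small stabiliser (a constant channel maps to zeros); the stored
adversarial images stay on the $[0,1]$ scale. The default uses each
image's own statistics. A fixed-affine alternative using training-set
channel statistics is available
(`build_tiny_classifier(normalize = "dataset")`): per-image statistics
couple every pixel to every other pixel through the image's own mean and
variance, which measurably distorts the decision geometry on small
synthetic problems, and the dataset mode is the appropriate control when
that matters.

## The synthetic data generator

No external data is required: the fixtures module emulates dermoscopy-like
images — an elliptical lesion with sinusoidal texture (amplitude 0.10,
default 12 cycles/image) over a lower-frequency textured background
(amplitude 0.07, 3 cycles/image) around base level 0.55, a mild zero-sum
reddish tint inside the lesion, and Gaussian pixel noise (sd 0.05), all
clipped to $[0,1]$. The class label is carried entirely by the lesion:
by default its mean intensity falls into one of `n_classes` disjoint bands
partitioning $[0.30, 0.80]$ (two classes: dark $[0.33,0.52]$ vs bright
$[0.58,0.77]$ around the 0.55 threshold), with an inner margin of 0.03 so
texture and noise cannot move the masked mean across a band edge — the
label is *recomputed from the finished image*, never assigned. Everything
is a pure function of `(spec, seed, index)`, with balanced classes by
construction.

What these fixtures do **not** emulate: the morphological diversity, hair
and ruler artefacts, vignetting, colour constancy failures and ambiguous
boundaries of real dermoscopy; a real lesion classifier's features are
far richer than a brightness-band rule. Passing tests demonstrate the
machinery — masks restrict perturbations exactly, losses have the stated
geometry, training ascends its objective deterministically — not clinical
attack performance.

## Desk-scale study conditions

The end-to-end checks run, on one CPU, with: 400 64-px two-class samples
(spec seed 101); surrogate (arch A: three conv blocks + GAP head) and
target (arch B: four blocks, different widths) trained 20 epochs with Adam
at lr $10^{-3}$ to holdout accuracy $\ge 0.90$; generator depth 3 / base
width 4 trained 10 epochs at $\varepsilon = 0.1$ with ground-truth masks,
batch 32 and Adam at lr $10^{-2}$. The step size is the one deliberate
departure from the reference recipe (lr $5\times10^{-5}$), which is tied
to 50-epoch training of much larger networks: over the 130 optimiser
steps available here it moves this small generator by $\sim 10^{-2}$ in
weight norm and learns nothing measurable. The segmenter (U-Net, depth 4,
base 4) trains with a soft-Dice loss — the reference reports Dice but
never names a training loss — for 24 epochs at batch 8 on 200 samples,
enough steps to move past the predict-the-average-lesion optimum.

## Numerical and design choices

* Binarisation threshold 0.5 for predicted masks (standard; exposed).
* Dice/IoU of two empty masks defined as 1.0 (perfect agreement, avoids 0/0).
* Max-pooling ties route to the top-left element, keeping backprop
  deterministic; all stochastic steps (init, shuffling, splits) derive
  from explicit seeds, and identical seeds reproduce training bit-for-bit.
* Generator head initialised near zero so training starts from a null
  perturbation field rather than first un-learning random texture damage.
* ASR follows the printed counting rule: numerator = samples the surrogate
  classifies correctly *and* whose adversarial fools the target;
  denominator = the **full** adversarial set (an `"surrogate_correct"`
  denominator mode exists).
* Global-statistics SSIM is the default (the defining formula has no
  windowing); the conventional 11×11 Gaussian-weighted mean-SSIM is the
  `windowed` option. Colour images average per-channel SSIM.
* The "Ensemble" row of a transfer report is the mean of the per-target
  ASRs, and `avg_asr` the mean over target rows — reading "the average of
  the results from all target models" as result-averaging.
* CAM heatmap export min–max normalises the map (a constant map renders
  as the pure image), upsamples to image size, applies a black–red–yellow–
  white ramp and alpha-blends at 0.5.

## Limitations

* **Texture-term strength.** The differentiable texture penalty is a much
  stronger constraint than the published hard-code objective it relaxes
  (whose gradient is zero almost everywhere). On these smooth synthetic
  fixtures its gradient dominates the adversarial term by orders of
  magnitude at the default weights, and the acceptance suite documents the
  consequences: the fully-weighted attack is largely suppressed relative
  to its `use_lbp = FALSE` ablation, and the unmasked (`use_mask = FALSE`)
  variant — where the penalty acts over the whole image — is suppressed
  almost entirely, so its concealment comes out *higher* than the masked
  attack's, inverting the ordering one would expect from masking alone. On richly textured natural images most
  neighbour differences sit in the relaxation's saturated region, so the
  effect is expected to be milder — but it is intrinsic to making this
  loss differentiable.
* **Optimisation at tiny step budgets.** With two perfectly separated
  classes the cross-entropy landscape contains a strong "push every lesion
  in one direction" local maximum; short first-order training reliably
  converges there and the Tanh head then saturates, freezing further
  progress toward input-dependent (signed) attacks. The acceptance suite
  reports the white-box success rate this yields under the fixed desk
  conditions rather than hiding it; per-sample iterative attacks do
  substantially better, which is exactly the transferability-for-strength
  trade a single-forward-pass generator makes.
* The U-Net here is a compact single-conv-per-stage variant; real
  dermoscopy segmentation needs the full-width original and real data.
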