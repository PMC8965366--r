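---
title: "Cross-modality synthesis and diagnosis with a feature-fusion GAN: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modality synthesis and diagnosis with a feature-fusion GAN: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multimodal neuroimaging classifiers — here, distinguishing an early from a
late mild-cognitive-impairment-like class — work best with both structural
(MRI) and metabolic (PET) volumes, but real cohorts are incomplete: every
subject has an MRI, many lack PET. `ffgan` implements a three-stage hybrid
strategy for this situation:

1. **Stage 1 — pretraining.** A dual-branch residual *fusion network* is
   trained on the paired subjects' whole volumes. Everything up to the final
   affine layer is the *fusion feature extractor* `F`; the affine layer is
   the classifier head.
2. **Stage 2 — feature-fusion GAN.** A 3-D U-Net generator `G` learns the
   MRI→PET mapping on cubic patches against a convolutional discriminator
   `D`, with the objective

   `L(G, D) = L_GAN(G, D) + lambda1 * L1(G) + lambda2 * L_fusion(G)`,

   where `L_GAN` is the usual minimax value, `L1` the mean absolute voxel
   error between real and synthesized PET patches, and the feature-fusion
   term `L_fusion = E ||F(x, y) - F(x, G(x))||_1` is computed through the
   *frozen* `F`. The fusion term is the method's core idea: it steers the
   generator toward reproducing exactly those image properties the
   classifier's fused representation is sensitive to.
3. **Stage 3 — fine-tuning.** The training subjects' PET volumes are assumed
   missing, replaced by `G(MRI)`, and the classifier is fine-tuned at a
   reduced learning rate so it adapts to synthesis artifacts. Stages 2 and 3
   can be cycled; `run_hybrid()` keeps the cycle with the best validation
   accuracy (ties broken by validation AUC).

All networks, losses, and the reverse-mode gradient engine behind them are
implemented in base R (`im2col` gathers plus BLAS matrix products; a tape
records operations and plays them backwards). Transposed convolutions are
the exact adjoints of the strided convolutions, so encoder/decoder
geometries agree by construction and the adjoint identity is unit-tested.

## Reference hyperparameters

The package defaults follow the reference configuration: stage 1 Adam with
learning rate 5e-4, batch 8, L2 penalty 1e-3 on all trainable parameters;
stage 2 learning rate 1e-5 with 5 discriminator steps per generator step,
`lambda1 = lambda2 = 100`, and each iteration consuming the full patch grid
of one subject pair (27 MRI + 27 PET patches of 64^3 at stride 32 for
128^3 volumes); stage 3 learning rate 1e-4. The full-width architecture is
a 6-level U-Net (encoder channels 64–1024, decoder 1024–1), a 6-layer
discriminator (32–1024), and Resblocks of 4 convolutions + 2 shortcuts with
batch normalization and 50% dropout after each block.

Choices the reference leaves open, fixed here:

* **Positive class.** Sensitivity is the recall of class 1 (the LMCI-like
  class). This is stated prominently because results are not interpretable
  without it.
* **Generator adversarial term.** Non-saturating `-E log D(G(x))` by
  default; the literal minimax form is available via
  `generator_form = "minimax"`. Both share the same fixed point.
* **Norms as means.** The L1 and fusion norms are per-element means, so the
  lambda weights are comparable across patch and feature sizes.
* **Classification loss.** Softmax cross-entropy; L2 applies to all
  trainable parameters.
* **Patch recombination.** Whole volumes are synthesized patchwise and
  recombined by overlap averaging — the simplest rule for which
  extract→reassemble is exactly the identity (unit-tested bitwise).
  Indivisible patch geometry is an error, never silent truncation.
* **Resblock wiring.** conv(stride 2)–BN–ReLU–conv–BN with a 1×1×1 strided
  projection shortcut, then an identity-shortcut pair; branches do not share
  weights.
* **Discriminator head.** Flatten + single-unit affine + logistic squash;
  no normalization layers in the discriminator. Leaky-rectifier slope 0.2.
* **5 D-steps.** The five discriminator updates of an iteration reuse that
  iteration's subject pair (the alternative — a fresh pair per D step — is
  not described in the reference schedule).
* **Cycling.** Stage-2 training in later cycles resumes the previous
  generator/discriminator parameters (`stage2$resume = FALSE` reinitializes).
* **PSNR convention.** Peak fixed at 1 on [0,1]-normalized volumes,
  `PSNR = 10 log10(1/MSE)`; identical volumes report `Inf`. SSIM uses
  K1 = 0.01, K2 = 0.03, a uniform 7^3 window over valid positions, and
  unbiased covariance scaling (verified against scikit-image to 1e-6).
  Published MSE/PSNR pairs for this family of models are not mutually
  consistent under any fixed peak convention, so no numeric PSNR target is
  asserted — only the package's own convention is.

## The synthetic cohort

Real cohorts of this kind are access-restricted, so the package ships a
generator whose output has the statistical structure the method assumes,
with ground truth retained for oracles:

* a fixed radial "anatomy" plus per-subject Gaussian-smoothed texture
  (smoothness 2 voxels), min–max normalizable to [0, 1];
* a smooth monotone voxelwise cross-modal map
  `PET_clean = gain * g(MRI) + offset` with `g` a logistic squash (an
  identity option exists for exactness tests) — noise-free cohorts make the
  MRI→PET map deterministic, so generator quality has a known ceiling;
* class-dependent signal: class 1 receives `effect_size` (default 0.15)
  added to PET inside two spherical lesion regions, and 25% of it in MRI —
  MRI must carry some class information because an MRI-only classifier is
  expected to work above chance;
* additive Gaussian PET noise (default sd 0.02);
* a paired subset and an MRI-only subset; the unpaired class ratio defaults
  to balanced (matching the 4-per-class desk benchmark) with an
  imbalanced 27:76 option mirroring the reference cohort's composition.

The default scale — 16^3 voxels, 8 paired + 4 unpaired subjects per class —
is the *standard desk benchmark* used by the tests and the acceptance
script. What passing tests on this cohort show is that the pipeline's
mechanics and its qualitative ordering properties hold under the assumed
generative structure; they say nothing about registration error, scanner
physics, partial-volume effects, or real anatomical variability, none of
which are simulated.

## Desk-scale training conditions

Width scale 1/16 shrinks all channel counts (U-Net encoder 4–8, etc.); 16^3
volumes use 8^3 patches at stride 4, preserving the reference 27-patch grid.
Because the paired pool is 8 subjects per class, the fold plan uses k = 4
stratified subsets (the reference 10-subset split needs at least 10 per
class); the last subset is the validation set and the unpaired subjects are
the test set.

Two stage-2 settings differ from the full-scale defaults, deliberately:

* **Learning rate.** At full scale the generator takes hundreds of
  thousands of Adam steps at 1e-5. A desk-scale run has a few hundred
  steps, where 1e-5 cannot move the network measurably; benchmark runs use
  3e-3. This was chosen by watching generator convergence (synthesis MSE
  against the run's own untrained initialization), not downstream metrics.
* **Epochs.** 15 stage-2 epochs for the noise-free learnability check and
  20 for the benchmark (240/320 generator updates); 30 stage-1 and 20
  stage-3 epochs. Under-trained generators are dominated by the transient
  dynamics of the fusion term: at equal loss values its gradient with
  respect to the synthesized patch is roughly an order of magnitude larger
  in RMS than the L1 term's (the Jacobian of a narrow `F` with batch
  normalization amplifies), which distorts comparisons between loss
  variants unless both are trained to reasonable convergence.

The no-signal null check uses `effect_size = 0` with k = 2 folds (4 + 4
validation subjects) and compares the mean validation AUC of five seeds
against the Mann–Whitney null band — with labels independent of images by
construction, the classifier has nothing to find.

## Numerical details

* Probabilities are clamped to [1e-7, 1 - 1e-7] before logarithms; no loss
  evaluates to NaN or Inf on degenerate discriminator outputs.
* Batch-norm running statistics (momentum 0.9) are part of the fusion
  model's state: they are carried by stage-1/3 training and *frozen* (eval
  mode) whenever `F` is used inside the fusion loss. Freeze contracts are
  enforced: a checksum of `F` is verified bit-identical across stage 2 and
  the generator across stage 3, and `stage_artifacts` record the `F`
  checksum they were trained against.
* Min–max normalization of a constant volume is an error, not a silent
  zero; all-zero volumes cannot be cropped.
* AUC uses the rank (Mann–Whitney) formulation with ties counted one half —
  exact for the small subject counts involved, no binning.
* Determinism: every training entry point draws all its randomness from the
  configuration seed; two runs with the same seed produce bit-identical
  artifacts (single-threaded).
* Grad-CAM: weights are spatially averaged gradients of the chosen class
  score at the last convolutional activation of each modality branch,
  rectified, trilinearly upsampled, max-normalized; an all-zero gradient
  yields an all-zero map flagged with a warning rather than an error.

## Known limitations

* The desk-scale fusion network is narrow; its feature Jacobian makes the
  fusion-loss gradient scale differently than at full width (see above), so
  loss-weight intuitions do not transfer across scales unchanged.
* Whole-volume stage-1/3 training at 128^3 with full-width networks is far
  outside single-CPU reach; the full-scale YAML config documents the
  settings but is not exercised by the tests.
* The synthetic cohort's cross-modal map is voxelwise; real MRI→PET
  relations are spatially nonlocal.
* With 8 test subjects, accuracy moves in 12.5% steps; ordering properties
  are therefore asserted on medians across seeds, not per seed.
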