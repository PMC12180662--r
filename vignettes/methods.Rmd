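---
title: "Slice-based anomaly localization with conditional normalizing flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-based anomaly localization with conditional normalizing flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Unsupervised anomaly localization in 3D brain MRI asks for a per-voxel
anomaly score after training on healthy volumes only.  `voxelflow`
implements a slice-based approach: a frozen 2D feature extractor encodes
every axial slice, the per-slice feature maps are aggregated along the
depth axis, and a conditional normalizing flow models the density of the
resulting per-voxel feature vectors.  Scoring inverts the density: a voxel
whose feature vector is unlikely under the model of healthy tissue is
anomalous.

The pieces, in pipeline order:

1. **Preprocessing** (`read_volume()`, `center_crop()`,
   `rescale_intensity()`, `resize_pad()`). Volumes arrive skull-stripped
   and registered (those steps are external tools' business, not this
   package's); here they are center-cropped, min--max rescaled to
   $[0, 1]$ per volume, or isotropically resized and zero-padded.
   The slice axis is canonicalized to the first array axis on read.

2. **Slice encoder** (`encode_slice()`). A backbone CNN is tapped at two
   intermediate stages.  Each tap is smoothed with a $p \times p$
   neighborhood mean ($p = 3$, replicate-padded, the field's usual local
   patch aggregation), all taps are bilinearly upscaled to the first tap's
   resolution and concatenated, and the channel dimension is reduced to a
   target embedding size by adaptive mean pooling over contiguous channel
   windows.  The reference backbone is the ImageNet-pretrained wide
   50-layer residual network (width factor 2, taps at stages 2 and 3,
   embedding dimension 512).  This environment has no runtime that can
   execute pretrained ImageNet weights, so the backbone sits behind a
   pluggable adapter: the functional default is a small fixed
   random-weight CNN (`tiny_cnn_backbone()`; random convolutional features
   are an established lightweight feature extractor), while the wide
   residual architecture is represented as a parameter-accounting table
   (`wide_resnet50_table()`), whose total -- 68,883,240, i.e. 68.88M --
   matches the published parameter budget of that backbone.

3. **Depth aggregation** (`aggregate_volume()`). Per voxel of the
   low-resolution grid, features are averaged over a window of $w$ slices
   (default $w = 3$, replicated at the ends).  The mean is permutation
   invariant within the window; $w = 1$ disables aggregation and
   reproduces the pure 2D slice model.  A whole-depth mean would destroy
   per-voxel maps, so a local window is the only reading of "aggregate
   across slices" that keeps voxel-wise scoring; the window size is
   exposed in the configuration.

4. **Conditional normalizing flow** (`flow_model()`, `train_flow()`).
   RealNVP-style affine coupling layers (default 8; each subnet is two
   linear maps with one ReLU) over the $d$-dimensional feature vectors,
   conditioned on a fixed sinusoidal 2D positional code of the voxel's
   in-plane location (concatenated to every subnet input,
   `positional_condition()`).  The log-likelihood is the change of
   variables
   $\log p(x) = -\tfrac{d}{2}\log 2\pi - \tfrac12\lVert\varphi(x)\rVert^2
   + \log\lvert\det(\partial\varphi/\partial x)\rvert$,
   and training minimizes the mean negative log-likelihood with Adam
   (reference learning rate 0.001), one volume's feature vectors per
   optimization step.

5. **Anomaly synthesis and contrastive boundary losses** (`loss_config()`,
   `synthesize_anomalies()`, `triplet_loss()`, `bgspp_loss()`,
   `prl_loss()`). Anomalous features are synthesized by adding i.i.d.
   Gaussian noise ($\sigma = 0.06$) to the raw embedding vectors --
   before the flow's internal channel standardization, so that the
   perturbation lives in the same space as the extracted features.  The
   default contrastive term is a triplet loss on the scalar
   log-likelihoods, $\sum_i \max(0, \lVert\log p_i - \log p_j\rVert^2 -
   \lVert\log p_i - \log q_i\rVert^2 + \tau)$ with margin $\tau = 1$,
   pulling normal log-likelihoods together while pushing perturbed ones
   at least a margin away.  Two alternatives are provided for ablation: a
   boundary-guided semi-push-pull hinge around the $\beta$-th percentile
   of normal log-likelihoods, and a pairwise ranking hinge.  The total
   training objective is the unweighted sum of the flow objective and the
   selected contrastive term.

6. **Scoring** (`score_volume()`, `normalize_scores()`). Per voxel the
   anomaly score is $s = 1 - \exp(\log p)$; per slice, the image-level
   score is the maximum voxel score.  Pixel-level evaluation normalizes
   scores min--max within each volume, computes metrics per volume and
   averages; image-level evaluation normalizes across the whole test set
   and pools all slices.

7. **Evaluation** (`evaluate_pixel_level()`, `evaluate_image_level()`).
   AUROC (rank form), AUPRC (step-wise PR integration), PRO (mean
   per-connected-region recall integrated over false-positive rate up to
   a 0.3 cap -- the community convention, as no cap is standard-free),
   and maximum Dice, which is asserted at every run to equal the
   independently computed maximum F1.  Specificity, accuracy and
   precision are reported at the F1-optimal threshold, found by an
   exhaustive sweep over the distinct score values with ties broken
   toward the smallest threshold.

## Design choices where the design was open

* **"Aggregate" operators.** Both the in-plane patch aggregation and the
  channel reduction are unspecified beyond their intent; both are
  implemented as means (neighborhood mean with replicate padding;
  adaptive mean pooling over channel windows), matching the
  feature-embedding lineage this method descends from.  Upscaling is
  bilinear.
* **Coupling details.** Affine couplings with a seeded random channel
  permutation per layer; log-scales are soft-clamped
  ($s \leftarrow \alpha \tanh(s/\alpha)$, $\alpha = 1.9$) to keep the
  log-determinant bounded -- standard flow stabilization.  Subnets are
  identity-initialized (last linear map zero), so an untrained flow is
  exactly the standard Gaussian and training starts from a well-defined
  density.
* **Triplet partner.** The positive partner $j$ in the triplet loss is a
  seeded random derangement of the batch: every normal sample is pulled
  toward another normal's likelihood without self-pairing.
* **Pairing in the ranking loss.** Index-aligned pairs by default (cost
  linear in the batch); the full cross-product is available via
  configuration.  The boundary percentile $\beta$ defaults to 10.
* **Noise in raw feature space.** Because the flow standardizes feature
  channels internally, a raw-space $\sigma$ corresponds to a per-channel
  $\sigma / s_c$ in standardized space: channels with tight distributions
  receive relatively stronger perturbations.  This keeps the synthesized
  anomalies in the space the extractor actually produces; synthesizing
  after standardization instead would uniformly under-perturb tight
  channels and render the contrastive hinge inactive.
* **Contrastive scaling during training.** Raw log-likelihoods grow
  linearly with the feature dimension, so the squared/hinge contrastive
  terms would drown the density-fit gradient at realistic $d$.  The
  trainer therefore evaluates the contrastive losses on
  per-dimension-scaled log-likelihoods ($\log p / d$, bits-per-dim
  style) and weights sum-form losses by the batch size.  The loss
  functions themselves are defined (and tested) on raw scalars.
* **Score stabilization.** $1 - \exp(\log p)$ underflows to a constant
  map once $\log p \ll -745$, which any realistic feature dimension
  produces.  `score_volume()` therefore exponentiates
  $(\log p - \max_{\text{vol}} \log p)/d$ instead.  This is a strictly
  increasing reparameterization of the raw score, so every rank-based
  metric and every min--max-normalized map downstream is unchanged; the
  raw form is available via `stabilize = FALSE`.
* **Feature standardization.** `fit_anomaly_model()` standardizes each
  embedding channel by the training set's mean and standard deviation
  (stored in the flow object and re-applied at scoring).  This conditions
  the density estimation problem without affecting what the flow can
  express.
* **Intensity rescaling scope.** Min--max rescaling is per volume,
  consistent with the per-volume score normalization used at evaluation.
* **Odd crop remainders** drop the extra voxel from the high-index side;
  any fixed rule works, this one is documented and tested.
* **Training sign convention.** The objective is the standard negative
  log-likelihood (minimized); a printed form that would maximize NLL
  verbatim is treated as a sign typo and not followed.

## The phantom generator

`phantom_spec()` and friends generate the synthetic study data: a smooth
ellipsoidal "head" with per-subject smooth deformation (Gaussian random
fields, default magnitude 1.5 voxels) and low-frequency texture, additive
voxel noise (default SD 0.02), intensities clipped to $[0,1]$, and -- for
anomalous volumes -- one to three ellipsoidal lesions with an additive
contrast offset (default +0.4, hyperintense, radius 3--7 voxels) smoothed
with a 1-voxel Gaussian border.  The ground-truth mask marks voxels whose
intensity changed by more than half the contrast, so the smoothed lesion
border contributes genuinely ambiguous transition voxels, which is where
localization is hardest.  Every volume has its own RNG substream derived
from `(seed, index)`, so datasets extend without reshuffling.

What the phantoms emulate: smooth subject-to-subject structural
variation, compact hyper-intense lesions with known masks, axial slicing,
$[0,1]$ intensities.  What they do not emulate: MR physics (bias fields,
acquisition noise structure, modality contrast), real anatomy, lesion
texture, or lesion--tissue interaction beyond an additive offset.
Passing the synthetic benchmark therefore demonstrates that the pipeline
recovers compact intensity deviations against smooth structured
variability; it does not certify performance on clinical data.

## Study sizes and numerical settings

The standard desk-scale benchmark (`run_phantom_benchmark()`) trains on
20 normal phantoms of $32 \times 64 \times 64$ voxels and scores 10
anomalous plus 10 normal held-out phantoms, with the small random-CNN
backbone, a 64-dimensional embedding, and a 4-coupling flow (hidden width
128, 32-dim positional code) trained 4 epochs at learning rate 0.003 --
chosen once as the smallest configuration whose density fit visibly
converges (training NLL plateaus) on these phantoms.  Paired-seed
comparisons (loss variants, aggregation windows) reuse the same encoded
features per seed, which is exact because the encoder is frozen.

Degenerate inputs follow documented rules: constant volumes rescale to
zeros, constant score maps normalize to zeros, empty-mask volumes are
excluded from pixel-level averaging (with a message), cropping never
pads, channel reduction never up-projects, and F1/Dice ties resolve
toward the smallest threshold.

## Known limitations

* The random-CNN adapter is a stand-in feature extractor; with a
  pretrained wide residual backbone the encoder contract is identical
  (the adapter interface, tap arithmetic and parameter accounting are
  tested), but absolute performance on real MRI is not reproduced here.
* PRO sweeps subsample to 200 thresholds above that count; the oracle
  tests use exhaustive sweeps on small maps.
* The flow's likelihood is exact, but training length in the benchmark is
  short of full convergence; the benchmark measures recovery under the
  stated conditions, not the method's ceiling.
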