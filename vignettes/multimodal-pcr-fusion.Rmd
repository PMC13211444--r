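---
title: "Multimodal attention fusion for pCR prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal attention fusion for pCR prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pathological complete response (pCR) to neoadjuvant chemotherapy is a
strong prognostic marker in breast cancer, but it can only be confirmed
pathologically after surgery.  Predicting pCR *before* treatment from
pre-therapy DCE-MRI and routine clinical markers (age, race, ER, PR, HR,
HER2 status and molecular subtype) would let non-responders switch
regimens early.  Two obstacles make this hard: imaging and tabular
clinical data live in very different representation spaces, and pCR
cohorts are small and imbalanced (roughly 29% positives), which punishes
models that cannot generalize from scarce hard cases.

`pcrfusion` implements a complete, CPU-scale testbed for one family of
answers: bidirectional cross-modal attention fusion combined with a
contrast-aware feature enhancement module inside a supervised
contrastive framework, trained with a dual loss.  Everything — the 3D
vision-transformer encoder, the fusion and enhancement modules, the
losses, AdamW and the evaluation stack — is implemented from scratch in
R with hand-written backpropagation, because no deep-learning framework
is available in the target environment.  Every backward pass is verified
against central finite differences in the test suite.

## Model

### Encoders

The imaging encoder is a patch-based 3D vision transformer.  A volume of
shape $(H, W, D)$ is cut into non-overlapping cubic patches of edge $p$,
linearly embedded into $C_{hid}$ dimensions, prepended with a learned
CLS token, summed with learned positional embeddings, and passed through
pre-norm transformer blocks (multi-head self-attention plus a GELU MLP).
The imaging feature is the LayerNorm of the final-layer CLS token,
$f_{img} \in \mathbb{R}^{B \times C_{hid}}$.  No pretrained weights are
used: the scale (patch size, depth, heads, $C_{hid}$) is configuration,
with $C_{hid} = 768$ as the paper-scale default.

The clinical encoder maps the encoded clinical vector through two
stages of `Linear -> ReLU -> LayerNorm`, first to 128 and then to 256
dimensions, yielding $f_{clin}$.

### Clinical encoding and missingness

The raw seven features are encoded in a fixed slot order: Z-scored age
(statistics fitted on the training split only, never on test rows),
race one-hot over $K_{race}+1$ slots, the four binary receptor markers
passed through, and subtype one-hot over $K_{subtype}+1$ slots.  Missing
continuous/binary values are encoded as the sentinel $-1$; missing
categorical values map to the extra one-hot index $K$.  $K_{race} = 3$
and $K_{subtype} = 4$ are configuration values (the synthetic generator's
defaults); real datasets may use different counts.

### BiCMA fusion

Both features are projected into a shared $d_{fuse} = 512$ space.  Two
multi-head cross-attention pathways with *independent* parameters then
run in parallel: IGC-Attention uses the imaging projection as query and
the clinical projection as key/value; CGI-Attention mirrors it.  Because
each modality contributes a single pooled vector, each attention
operates on one-token sequences: the softmax over the single-element key
axis is identically 1, so the attended output reduces to
$W_{out}\,\mathrm{concat}_h(W_v^h v)$ and the literal pooled attention
summaries $a_{mri}, a_{clin}$ are constant 1.  We implement this literal
form as the default and additionally offer
`pooled = "pre_softmax_sigmoid"` — the sigmoid of the head-averaged
scaled logit — which makes the summaries sample-dependent.  How the
original formulation obtains non-constant summaries from a $1 \times 1$
post-softmax attention matrix is not explained; we ship both readings
and assert neither as intent.  The fused feature is
$f_{fused} = W_{fusion}[f_{img}^{attn} \,\|\, f_{clin}^{attn}] + b$.

### MCFE and the similarity feedback

The enhancement module chains four stages on the fused vector:

1. **Modal calibration** — scalar sigmoid gates on $a_{mri}, a_{clin}$
   produce weights $w_{mri}, w_{clin} \in (0,1)$; the calibrated feature
   is $(w_{mri} + w_{clin}) \odot f_{fused}$ (the two gated copies
   collapse algebraically into one broadcast scale).  At zero gate
   parameters both weights are $1/2$ and the stage is the identity.
2. **Clinical semantic-guided selection** — a softmax over the 512
   feature slots, driven by $f_{clin}$ through
   `Linear -> LayerNorm -> ReLU -> Softmax`, multiplies the calibrated
   feature element-wise; the weights sum to one per sample.
3. **Dual-path refinement with dynamic activation** — two independently
   parameterized `Linear -> LayerNorm -> ReLU` paths are scaled by
   $(1 - \beta s_{intra}) \alpha$, so samples with low intra-class
   similarity (hard samples) are activated more strongly.  $\alpha$ and
   $\beta$ are learnable scalars initialized at $1.0$ and $0.1$ — close
   to the no-feedback identity regime.  The scale is *not* clamped by
   default: the literal equations allow it to go negative when
   $\beta s_{intra} > 1$; a `clamp_activation` flag floors it at zero.
4. **Projection** — each path is LayerNorm-projected to the
   128-dimensional contrastive embedding and the two are averaged.

The similarity feedback is circular as stated: the activation needs
$s_{intra}$, which is defined on the embedding the activation produces.
We resolve it with a **two-pass detached scheme**: a provisional
embedding is computed with $s_{intra} = 0$, the intra-class similarity
is computed from it and treated as a constant (no gradient flows through
the first pass), and the activation plus projections are recomputed.
This keeps a single forward graph per step and prevents gradient loops;
the detachment contract is asserted by a dedicated test.  At inference
(no labels) $s_{intra} = 0$.  $s_{intra}$ is used raw as printed — it
scales like $1/\tau$ and is unbounded — which is why $\beta$ starts
small.

### Objectives

The supervised contrastive loss over the enhanced embedding uses the raw
scaled dot product $S_{ij} = z_i^\top z_j / \tau$ (no L2 normalization;
a `cosine_similarity` flag provides the SupCon-style alternative):

$$
L_{CL} = -\frac{1}{N'} \sum_i \frac{1}{|P(i)|} \sum_{j \in P(i)}
  \log \frac{\exp(S_{ij})}{\sum_{k \ne i} \exp(S_{ik})}
$$

with positives $P(i)$ the same-label non-self samples and the
denominator running over *all* non-self samples.  Anchors without a
positive are skipped and $N'$ counts the rest; a batch with no valid
anchor contributes 0.  The classification head (MLP
$512 \to 128 \to 2$, softmax) is trained with class-weighted
cross-entropy whose weights are the opposite-class training counts
(`w1 = #non-pCR`, `w0 = #pCR`).  The total loss is
$L_{cls} + \lambda L_{CL}$ with $\tau = 0.1$, $\lambda = 0.9$ as
defaults.

Raw count weights rescale the loss by roughly the cohort size quotient
(86 vs 34 at small-trial scale), which with a fixed learning rate changes the
effective step size.  The `normalize_weights` option divides the weights
by their mean, preserving their ratio but keeping the loss magnitude
comparable across cohorts; the training profile enables it by default,
while `class_weights_from_counts()` itself always returns the raw
counts.

### Optimization

AdamW with decoupled weight decay 0.01; single-cycle cosine annealing of
the learning rate over the total epoch count (the scheduler's period is
not specified upstream; we chose one cycle spanning all epochs, stepped
per epoch).  Paper-scale configuration uses the layer-wise rates
$10^{-5}$ for the imaging encoder and $10^{-4}$ elsewhere; that split
exists to protect *pretrained* encoder weights.  The desk-scale profile
trains the encoder from random initialization, so it uses $10^{-4}$
everywhere — with $10^{-5}$ a from-scratch transformer barely moves in
ten epochs.  Batch size 4; epochs 50 at paper scale, 10 in the desk
profile.

## The synthetic world

No real cohort ships with the package.  `generate_cohort()` emulates the
statistical structure the network assumes:

* **Phantom volumes** — one ellipsoidal tumor per volume at elevated
  mean intensity (`contrast`), with within-tumor heterogeneity noise,
  over a Gaussian background.  Default desk shape is $(32, 32, 16)$;
  the paper-scale $(192,192,112)$ is configuration.  Per-patient
  geometry (radii, center, contrast, heterogeneity) varies around the
  template, with radii clamped so the tumor stays inside the volume.
* **Clinical table** — age $\mathcal{N}(49, 10^2)$, race with 3 levels,
  ER/PR Bernoulli with HR their maximum, HER2 positive in 30%, and the
  four-level subtype derived from HR/HER2 — the standard clinical
  taxonomy.  ER/PR missingness defaults to 66.8%, the rate observed in
  large multi-center clinical tables; missingness is injected *after*
  label generation, so labels always depend on complete features.
* **Label model** — $p = \mathrm{logistic}(\beta_0 + \beta_{img} s +
  \beta_{er}\,\mathrm{ER} + \beta_{her2}\,\mathrm{HER2} + \gamma\, s
  \cdot \mathrm{HER2})$, where the imaging score $s$ is the standardized
  tumor volume fraction plus standardized heterogeneity — two
  interpretable quantities a volumetric encoder can plausibly recover.
  The interaction is planted on HER2 because HER2 status is the clinical
  marker most strongly tied to chemosensitivity.  Defaults
  ($\beta_{img} = 1.2$, $\beta_{er} = -0.8$, $\beta_{her2} = 0.8$,
  $\gamma = 2$; ER negative raising the pCR odds) produce a clearly
  multimodal signal.  The intercept is solved by root finding so the
  *expected* prevalence matches the target (default 0.285, the ~29%
  imbalance of neoadjuvant cohorts) under any coefficient choice.

What the phantoms deliberately do not model: contrast kinetics, bias
fields, scanner artifacts, anatomical background, non-ellipsoidal
morphology.  A green synthetic test therefore establishes that the
implementation is correct and that fusion can exploit a genuine
imaging-by-clinical interaction at desk scale — it does not establish
clinical performance on real DCE-MRI.

## Numerical choices

* LayerNorm uses $\epsilon = 10^{-5}$; an all-constant row maps to the
  shift vector (zeros at initialization), keeping every op total.
* A constant volume Z-scores to all zeros (documented convention), and
  volumes are Z-scored over all voxels — no tumor mask is assumed.
* Symmetric zero padding puts the odd remainder voxel on the high-index
  side; this is arbitrary but fixed, so padding is bit-reproducible.
* Log-sum-exp in the contrastive loss is max-shifted; cross-entropy
  probabilities are floored at $10^{-12}$.
* Age SD uses the sample ($n-1$) convention, the usual feature-scaling
  choice; a flag selects the population convention.
* Fold summaries use the population (denominator $k$) SD because that
  convention reproduces published fold tables of this form
  ($0.8475 \pm 0.0901$ from the five fold AUCs); the sample convention
  is a flag.  Confidence intervals over folds use Student's t with
  $k - 1$ degrees of freedom; test-set intervals use the percentile
  bootstrap (B = 1000) with undefined resamples redrawn and counted.
  Which percentile variant the original evaluation used is unstated;
  plain percentile was chosen.
* DeLong's test uses the midrank $O(n \log n)$ formulation of the
  structural components; identical score vectors return $p = 1$ with a
  `zero_variance` flag.
* Hard labels come from the softmax argmax, i.e. a 0.5 threshold.
* Stratified folds deal each shuffled class round-robin, carrying the
  rotation across classes so fold sizes differ by at most one.

## Ablations and open design points

The `fusion` switch selects `concat` (plain joint projection — the base
model), `igc` / `cgi` (one pathway, the attended feature concatenated
with the other modality's shared projection — the single-direction rows
of the fusion ablation), or full `bicma`.  The `mcfe` switch selects
`full`, `off` (no contrastive branch), `conventional_cl` (SupCon on a
plain linear projection of the fused feature), `no_calibration`,
`no_dual_path`, or `no_dynamic_activation`.  Unimodal baselines
(`modality = "image"` / `"clinical"`) reuse the same encoder and head
codepaths with a linear bridge to the fused width, so multimodality
comparisons are architecture-matched.  Ablation orderings are emitted
for inspection, not asserted: at desk scale they are stochastic.

## Known limitations

* Single-token cross-attention makes the literal pooled summaries
  degenerate (constant 1); see the two shipped interpretations above.
* The from-scratch 3D ViT at $n \approx 500$ and 10 epochs recovers only
  part of the planted imaging signal (an oracle logistic fit on the
  generative score is markedly better); the multimodality ordering holds
  but absolute desk-scale AUCs are modest, and nothing here should be
  read as a reproduction of published real-data AUCs.
* Training is single-threaded and deterministic given a seed; there is
  no GPU path, mixed precision, or data-parallelism.
* The NIfTI reader/writer is minimal (float32, identity affine) — it
  exists for interchange of synthetic phantoms, not for clinical images.
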