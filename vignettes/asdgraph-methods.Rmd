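---
title: "Methods: a two-stream population-graph classifier for multimodal MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stream population-graph classifier for multimodal MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(asdgraph)
```

## The model

`asdgraph` classifies subjects as autism spectrum disorder (ASD) or typical
control (TC) with a semi-supervised graph convolutional network (GCN) on a
*population graph*: one node per subject, node features derived from
resting-state fMRI, edges derived from structural MRI. The premise is that
structural similarity between subjects is a more transferable notion of
"neighbourhood" than phenotype matching, while the functional signal carries
the discriminative information. The two streams are built independently and
meet only in the graph.

### Functional stream: summary derivatives and the 3D CNN

Each subject's 4D volume is reduced to nine voxelwise maps — ReHo, ALFF,
fALFF, binarized/weighted degree centrality, binarized/weighted eigenvector
centrality, LFCD, VMHC — plus one dual-regression map per group template
(10 by default), stacked on a channel axis in a fixed documented order
(19 channels). Definitions and conventions:

* **ReHo**: Kendall's coefficient of concordance over the voxel plus its
  in-mask neighbours (26-neighbourhood by default; 6 and 18 available).
  Ranks over time use mid-ranks; the denominator carries the standard tie
  correction `K²(n³−n) − K ΣT`. A nonpositive denominator (every series
  constant) reports 0 rather than NaN.
* **ALFF/fALFF**: after optional linear detrending (default on), the
  single-sided amplitude spectrum is `a_k = 2|X_k|/n`, so a bin-aligned
  sinusoid of amplitude A reports A at its bin. ALFF averages `a_k` over
  0.01–0.08 Hz (DC excluded); fALFF divides the band amplitude sum by the
  sum over 0 < f ≤ 0.25 Hz, with 0 where the denominator vanishes. The
  low-frequency band is configurable; 0.01–0.08 Hz is the field's standard
  choice. Note that detrending a finite sinusoid leaks a small broadband
  component (the fitted line has a full spectrum), which is why the
  package's own spectral-concentration checks disable detrending — the
  planted tones have no trend.
* **Centralities**: Pearson correlations between all in-mask voxel pairs;
  correlation against a constant series is defined as 0, which keeps maps
  finite and implicitly masks degenerate voxels. Binarized degree counts
  r ≥ 0.25 (self excluded); the weighted variant sums those r. Eigenvector
  centrality applies power iteration (seeded start, tolerance 1e−10,
  maximum 1000 iterations) to the thresholded matrix, rescaled to
  (1 + r)/2 in the weighted case so entries are nonnegative
  (Perron–Frobenius then guarantees a nonnegative leading eigenvector).
* **LFCD**: from each seed, a 6-connected cluster grows by admitting
  neighbours whose correlation *with the seed* passes the threshold; the
  map records cluster size (≥ 1). This is the standard local
  region-growing definition.
* **VMHC**: correlation between voxel (i, y, z) and its first-axis mirror
  (Nx+1−i, y, z); grids with an even first axis have no centre plane.
* **Dual regression**: stage 1 regresses each timepoint's image on the
  template vectors (least squares via QR), stage 2 regresses each voxel's
  series on the stage-1 time courses. Rank deficiency in either design is
  an error naming the stage.

The CNN is a five-block 3D convolutional network: a first block of 16
filters, then four blocks of 32, 64, 128, 256 (doubling), each block being
3×3×3 same-padded convolution, ReLU, batch normalisation, and 2×2×2 valid
max pooling, followed by global average pooling, a 1024-unit ReLU dense
layer, dropout 0.5 and a 2-class softmax. Same-padding with valid pooling
makes five pooling stages feasible on 61-voxel axes (61→30→15→7→3→1). The
first-block width and the training protocol (adaptive-moment optimiser,
learning rate 1e−3, full-batch, seeded initialisation and dropout) are
configuration choices exposed in `cnn_config()`. Node features are the
post-ReLU dense activations with dropout off and batch normalisation in
inference mode (running statistics).

### Structural stream: radiomics, Fisher score, stacked autoencoder

Radiomic features are computed per atlas ROI on all 8 level-1 sub-bands of
an undecimated (stationary) 3D wavelet transform with the 8-tap Daubechies
filter. The undecimated form keeps every sub-band on the input grid so the
atlas mask applies unchanged — decimated transforms would force an
ambiguous mask-downsampling step. Filters are scaled by 1/√2 per axis, so
with periodic boundary extension the 8 sub-band energies sum exactly to the
input energy (a tight frame), which the tests verify as a Parseval
identity. Per ROI and sub-band, 19 first-order features (population-moment
conventions; histogram entropy/uniformity over 32 fixed-count bins) and 22
grey-level co-occurrence features (symmetric matrices over the 13 unique
distance-1 offsets, feature values averaged over offsets, fixed-bin-count
discretization over the ROI's min–max so features are invariant to global
intensity shifts) give 328 features per ROI and 48,544 per subject with the
148-region parcellation.

Fisher's score ranks features by
`F_j = Σ_c n_c(μ_cj − μ_j)² / Σ_c n_c σ²_cj` (population variances;
zero-denominator features score 0, ties break by feature index). The top
2000 features feed a 4-level stacked autoencoder
2000→1024→512→256→150 — the interior widths are a halving-style
interpolation, since only the endpoints are fixed by the design — with
sigmoid activations throughout, so the 150-dimensional embedding is bounded
in [0, 1] and therefore valid input for the sqrt-cosine similarity, which
requires nonnegative vectors. Inputs are min–max scaled per feature.
Training is greedy layer-wise pretraining followed by end-to-end
fine-tuning, both minimising mean squared reconstruction error with Adam
(learning rate 1e−3, 200 + 200 epochs by default). The selector and the
autoencoder are fitted on training-split subjects only and then applied to
all subjects: both consume labels directly (Fisher) or risk memorising
(SAE), and the split protocol is otherwise agnostic to them.

### Graph construction and the GCN

Similarity is `Sim(x, y) = Σ √(xᵢyᵢ) / (√Σxᵢ √Σyᵢ)` — the
Hellinger-affinity ("improved sqrt-cosine") form, which is 1 exactly on
identical direction, 0 on disjoint supports, and bounded in [0, 1] for
nonnegative inputs. A plain-product variant (`method = "literal"`) is
available for comparison. The edge threshold is
τ = minᵢ maxⱼ≠ᵢ S_ij; ties at τ are kept (≥), which by construction leaves
every node with at least one neighbour. Edges are unweighted by default
(the propagation rule uses A + I without weights); a flag preserves
similarities as weights.

The GCN uses the symmetric normalisation
`Â = D̄^{-1/2}(A+I)D̄^{-1/2}`, equivalently entries
`Ā_ij/√((dᵢ+1)(dⱼ+1))`, two 16-unit hidden layers with dropouts 0.005 and
0.4 on the respective layer inputs, ReLU between layers, and a linear layer
plus row softmax at the end. Training is full-batch cross-entropy on the
training-mask nodes with Glorot-uniform initialisation, Adam (learning rate
0.01, weight decay 5e−4 on the first layer) and 200 epochs by default —
the optimisation protocol is a configuration choice, as only the layer
sizes and dropouts are fixed by the design. Node features are
column-standardized before entering the graph: GCN optimisation is
scale-sensitive, and input-feature normalisation is standard practice for
this model class; constant columns stay at zero.

## What the synthetic data emulates

The fixture module generates every input the pipeline consumes, each with a
planted property that a direct test can verify without running the
pipeline:

* a mirrored box-parcellation emulating a Destrieux-style atlas (74 regions
  per hemisphere, contiguous, left–right mirrored across the first axis);
* 4D volumes with exact mirror symmetry, locally homogeneous blocks sharing
  a latent series, known template-mixture structure, bin-aligned pure
  tones, or white noise — all bit-reproducible under a fixed seed;
* disjoint unit-norm group templates standing in for group-ICA spatial
  maps;
* cohorts whose class-1 subjects have per-ROI structural intensity shifts
  (`effect_size`, default 5 intensity units against unit noise, i.e. a
  strong effect) in designated regions, and optionally an amplified
  low-frequency oscillation in those regions (`functional_effect`) that
  ALFF-family derivatives and the CNN can detect.

What it does **not** emulate: scanner physics, motion, multi-site batch
effects, realistic anatomy or haemodynamics, spatial autocorrelation of
noise. Passing tests therefore demonstrate that the implementation computes
the intended quantities and that the pipeline recovers signals of the
planted kind — not that the method attains any particular accuracy on
clinical data.

Two behaviours of the planted-signal experiments deserve honest statement.
First, the undecimated wavelet's 8-tap support means a planted intensity
step bleeds across ROI boundaries: ROIs within ~7 voxels of an affected
region acquire genuinely discriminative edge responses, and GLCM features
under fixed-bin-count discretization are shift-invariant by construction
and cannot respond to a pure mean shift at all. Recovery is therefore
asserted on the features that carry the planted signal — the mean-sensitive
low-pass first-order features of the designated ROIs — which land above the
0.9 score quantile and inside the top-k selection. Second, when the
structural effect is strong the population graph is so class-assortative
that the GCN classifies correctly from edges alone — which is the method's
motivation, but means a feature-randomization control cannot collapse
there. The negative control is therefore run on a cohort with structural
effect 0, where the graph is uninformative by construction and randomized
node features drop accuracy to chance. The complementary observation — with
informative features but an uninformative graph the GCN reaches only ~60%,
because two-hop neighbourhood averaging over a noise graph dilutes node
signal — is a real property of the propagation rule and a known limitation
of this model class.

## Numerical choices and problem sizes

* Voxel indexing is 1-based in R; the channel axis is always last; the
  mirror axis is the first array axis; no silent axis reordering ever
  happens.
* The default brain mask is "voxels with nonzero temporal variance"; an
  explicit mask overrides it.
* Power iteration: tolerance 1e−10, 1000 iterations, deterministic uniform
  start; failure to converge is an error reporting the residual.
* Max-pooling ties route gradients to the first maximum (fixed order);
  odd trailing voxels are cropped.
* Argmax ties in prediction break toward the lower class index.
* All stochastic stages draw from seeds derived deterministically from one
  global seed with stage tags; identical configuration and seed reproduce
  every number bitwise under single-threaded BLAS.

The test suite and the acceptance script run the method at miniature scale
chosen so the full suite completes in minutes on one CPU: grids of
12×14×12 to 20×24×20 voxels, 30–40 timepoints, 6-region parcellations for
end-to-end runs and the full 148-region parcellation for the dimensional
contracts, cohorts of 16–30 subjects, and reduced epoch counts. These sizes
are the package's own study conditions for its synthetic experiments; the
configuration objects accept the full-scale values (61×73×61 grids, 19
channels, 2000/150 selection, 1024-wide CNN features) and the dimensional
contracts are exercised at those widths.

## Known limitations

* The CNN, SAE and GCN are full-batch, dense, CPU implementations: correct
  and reproducible, but not suited to cohorts of thousands of subjects or
  full-resolution training at scale.
* The GCN inherits the usual transductive limitation: adding a subject
  changes the graph and requires re-prediction (though not necessarily
  re-training).
* Feature extraction assumes the atlas and volumes share a grid; no
  registration or resampling is provided.
* ROI-level centrality variants, phenotype-based edges, and alternative
  selectors or autoencoder families are intentionally out of scope.
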