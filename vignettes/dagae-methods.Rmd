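---
title: "Distribution-regularized adversarial generation of brain functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distribution-regularized adversarial generation of brain functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dagae)
```

## The problem

Diagnostic classifiers for dementia built on brain functional networks
(BFNs) — weighted graphs whose nodes are atlas parcels (ROIs) and whose
edges are Pearson correlations between regional BOLD time series — are
starved for data: a typical balanced two-class cohort has on the order of
150 subjects, while a single network already has $N(N-1)/2 = 4005$ free
edges at $N = 90$ ROIs. `dagae` implements a generative augmentation
strategy: an adversarial graph autoencoder learns class-conditional latent
node representations and a transformer-style generator decodes them back
into connectivity matrices, so that synthetic labeled networks can be added
to the training side of a classifier.

## Model

Four networks are trained together.

**Graph encoder.** Two graph-convolution layers map a subject's feature
matrix $F \in \mathbb{R}^{N\times T}$ ($T = 187$ time points) and BFN
$A \in \mathbb{R}^{N\times N}$ to latent node representations
$H = \tanh(\hat A\, \mathrm{ReLU}(\hat A F W_1) W_2) \in (-1,1)^{N\times p}$,
with $p = 32$ and hidden width 64. The propagation operator is the
symmetric normalization $\hat A = D^{-1/2}(A + I)D^{-1/2}$; because Pearson
edges are signed, $D$ is built from row sums of $|A| + I$ (signed degrees
could make $D^{-1/2}$ undefined) while the signed $A$ itself is propagated.

**Label-distribution prior.** Instead of a fixed Gaussian prior, the
latent space is regularized towards a class-conditional kernel density
estimate. Each ROI's time series is reduced to $p$ dimensions by per-ROI
PCA fitted on training subjects only, and a Gaussian KDE with Scott's-rule
bandwidth $b = \hat\sigma\, m^{-1/(p+4)}$ is fitted per class. Two
granularities are available: `per_roi` (default; one KDE per ROI per
class, so sampled latent matrices preserve ROI identity, which the
per-ROI discriminator presupposes) and `pooled` (all $N\,n_Y$ node
features of a class in one density). Sampling draws a center uniformly and
adds isotropic Gaussian noise of standard deviation $b$.

Two choices here deserve emphasis because the architecture forces them.
First, PCA is used as the dimension-reduction operator because the prior
must exist *before* adversarial training starts and must not depend on the
encoder being trained against it; a deterministic, training-only linear
reduction satisfies both. Second, the reduced features are rescaled per
dimension to maximum absolute value 1 on the training set. The encoder
output is $\tanh$-bounded in $(-1,1)$; if the prior lived on a different
scale, the discriminator could separate real from fake by scale alone and
the adversarial game would have no reachable equilibrium. This rescaling is
a modeling necessity, not a cosmetic normalization.

**Discriminator.** $N$ independent sub-networks (three-layer perceptrons
$p \to 32 \to 64 \to 1$, sigmoid output), one per ROI; subnetwork $i$ sees
only row $i$ of its input, and the discriminator output is the mean of the
$N$ subnetwork outputs. It is trained to score KDE samples $X$ as real and
encoder outputs $H$ as fake.

**Classifier.** A five-layer perceptron with softmax output on the
row-wise flattened $H$, adding a cross-entropy term that keeps the latent
space discriminative between the two diagnostic classes. The depth (five
layers) and two-way output are fixed by the architecture; the hidden
widths are free, and we use $256 \to 128 \to 64 \to 16 \to 2$ — sized so the
classifier head has on the order of $10^6$ rather than $10^7$ parameters,
which both regularizes it against cohorts of only $\sim 10^2$ subjects and
keeps a training run at desk scale.

**Transformer generator.** Three connectivity-transformer (CT) layers —
pre-norm multi-head self-attention over the $N$ node tokens with residual
connections, head counts 4, 8 and 11 — interleaved with two
dimension-upscaling (DU) affine+ReLU layers $32 \to 64 \to 187$:
$M' = \mathrm{CT}_3(\mathrm{DU}_2(\mathrm{CT}_2(\mathrm{DU}_1(\mathrm{CT}_1(M)))))$.
Head counts must divide layer widths ($32/4$, $64/8$, $187/11$); the
configuration constructor refuses anything else. Connectivity is decoded
by the inner-product head $A = \tanh(M'M'^\top)$ with the diagonal
overwritten to 1 to match the Pearson convention. Residual wiring and
layer (not batch) normalization are our choices where the layer list is
otherwise fixed; no positional encoding is used because ROI identity is
carried by the features themselves.

Initialization is Glorot-uniform with one deliberate exception: each
attention block's output projection starts at $0.1\times$ Glorot scale, so
every CT layer opens close to its residual identity. This matters
numerically: with full-scale output projections the rows of $M'$ are large
enough that $M'M'^\top$ saturates $\tanh$ to exactly $\pm 1$ in double
precision, the saturated gradient underflows to exactly zero, and the
generator can never move — Adam included, since a literally zero gradient
produces a zero update. Near-zero residual-branch initialization is
standard transformer practice and keeps the decoder inside the active
range of $\tanh$ from the first step.

## Losses and optimization

With $D$ the discriminator, $C$ the classifier, $E$ the encoder and $G$
the generator:

* $L_{enc} = \mathbb{E}[\log(1 - D(H))]$ — encoder fools the discriminator;
* $L_{dis} = \mathbb{E}[-\log(1 - D(H))] + \mathbb{E}[-\log D(X)]$;
* $L_{cla} = -\mathbb{E}[y \cdot \log C(H)]$ — standard negative
  log-likelihood (the minimization of its sign-flipped form would be
  degenerate);
* $L_{rec} = \|A_{rec} - A\|_1 / N^2$ with $A_{rec} = G(H)$;
* $L_{nrc} = \|\hat H - H\|_1 / (Np)$ with $\hat H = E(A_{rec}, F)$ — the
  re-encoding consumes the reconstructed network as adjacency and the
  subject's original features, the minimal reading consistent with the
  encoder's two-argument signature.

Training alternates, per minibatch (size 16), $T_{dis} = 1$ Adam steps on
the discriminator against matched-class KDE samples, then one joint Adam
step of encoder, classifier and generator on
$L_{enc} + L_{cla} + L_{rec} + L_{nrc}$ (all weights 1, configurable).
Learning rates: encoder $10^{-3}$; discriminator, classifier and generator
$10^{-4}$. The matched-class pairing of KDE samples to batch subjects is
required for the prior to stay class-informative. Training runs a fixed
number of epochs and reports equilibrium diagnostics post hoc — the mean
discriminator output on real and fake batches over the final 50 epochs,
converged when both sit within $0.5 \pm 0.15$ — rather than using an early
stopping rule, so runs are exactly reproducible from the seed. Gradients
are computed by hand-written reverse-mode passes through every component,
including the adjacency normalization of the re-encoding path; the test
suite checks all of them against central finite differences.

Probabilities entering a logarithm are clamped one-sidedly away from the
singular end at $10^{-7}$, which keeps closed forms such as
"perfect prediction $\Rightarrow$ loss 0" exact. L1 subgradients use
$\mathrm{sign}(0) = 0$. Parameters are initialized Glorot-uniform from the
run seed. A non-finite loss aborts training and returns the last finite
checkpoint with a diagnostic.

## Augmentation and evaluation protocol

After training, `augment()` draws, per class, `round(k * n_train_class)`
latent matrices from the class-conditional KDE and decodes them with the
generator (default $k = 1$). Evaluation follows a leakage-safe stratified
5-fold cross-validation: for each fold, the model (including its KDE
prior and PCA reducer) is trained on the four training folds only, the
generated networks join the original training networks, and only original
held-out networks are tested; an assertion fails if any test subject
reaches the augmentation input. The GCN classifier follows a two-stage
curriculum: it is first trained on the original training networks alone
and then fine-tuned, from that warm start, on the original-plus-generated
union — the synthetic networks refine an already-sensible decision
boundary instead of shaping it from scratch. The SVM and DNN baselines
fit once on the union. The GCN classifier uses the rows of the
BFN as node features — generated networks have no time series, so
connectivity profiles are the only input available to both kinds of
network — with two graph-convolution layers (32, 16), mean pooling and a
linear softmax head. The SVM (RBF, probability-calibrated) and DNN
($128 \to 32 \to 2$ on standardized upper-triangle vectors) baselines are
deliberately conventional. Prediction quality is reported as ACC, SEN, SPE
(sensitivity and specificity with respect to the patient class) and
rank-based AUC; degenerate denominators yield `NA`, never 0.

Generated-network quality is assessed by six weighted graph metrics
(Onnela clustering, strength, betweenness on $1/w$ distances, Louvain
modularity, local and global efficiency — all on absolute weights with
zero diagonal, since strengths and efficiencies are undefined for signed
edges) and by a 2-D t-SNE embedding of vectorized upper triangles. The
t-SNE here is a compact exact-gradient implementation (perplexity
calibration by bisection, early exaggeration, momentum gradient descent);
it is only used for qualitative overlap pictures of a few hundred
networks, where the $O(n^2)$ exact formulation is appropriate.

## The synthetic cohort generator

No real imaging data ships with the package; cohorts are simulated with a
structure that matches what the model assumes about BFN data:

* a block-modular correlation template (default 5 modules over $N = 90$
  ROIs, within-module correlation 0.5, between-module 0.1) standing for
  functional systems;
* a class effect: class 1 adds `effect_size` to a seeded random subset
  (`effect_edges`, default 20%) of inter-module edges, mimicking
  disease-related abnormal long-range connectivity, clipped to
  $[-0.95, 0.95]$ and repaired to the nearest valid correlation matrix
  (eigenvalue clipping and unit-diagonal renormalization);
* subject-level heterogeneity: Gaussian jitter (sd 0.05) on the template
  before each subject's draw;
* $T = 187$ time points drawn i.i.d. from the subject's multivariate
  normal. Time is white on purpose: Pearson connectivity is invariant to
  temporal ordering, so autocorrelation would add realism without adding
  test power.

Default cohort sizes are 75 subjects per class (150 total), matching the
balanced two-class setting the method targets; the acceptance studies use
60 per class, the per-fold training size of a 5-fold protocol on 150.
What the generator does *not* emulate: hemodynamics, scanner noise,
motion, atlas misregistration, site effects, and the heavy-tailed,
spatially structured dependence of real BOLD. Tests passing on these
cohorts therefore demonstrate that the machinery is correct and that the
method behaves as designed under its own assumptions — not that it
improves diagnosis on real fMRI.

## Reduced problem sizes in the test-suite studies

The equilibrium study runs at the full stated scale (60 subjects per
class, $N = 90$, $T = 187$, 300 epochs). The recovery and utility studies
run on reduced cohorts — $N = 20$ ROIs, $T = 44$ ($44 = 4 \times 11$ keeps
the third CT layer's 11 heads valid), $p = 8$, 12 subjects per class,
5 seeds — chosen so that every architectural constraint (head splits, PCA
rank, KDE center counts) still binds. The cohort difficulty (class effect
0.3 on 30% of inter-module edges, subject jitter 0.05) was fixed by one
criterion: the *un-augmented* cross-validated GCN baseline should sit
around 0.8, i.e., clearly above chance but well below ceiling — the
data-scarce regime augmentation is meant for; a cohort a classifier
already solves perfectly cannot show an augmentation effect in either
direction. The utility comparisons train for 80 epochs; the
template-recovery study trains to the generator's reconstruction plateau
(200 epochs, where the L1 reconstruction loss has flattened near 0.11)
and averages twice the training count of generated networks per class to
reduce the Monte-Carlo noise of the mean-network estimate.

## Ablations

`ablation_run()` reproduces the module-removal studies as configuration:
`no_discriminator` and `no_classifier` drop the module and its loss terms;
`no_du` keeps a CT-only generator at constant width $p$ (the third CT's 11
heads cannot divide 32, so that variant runs heads 4, 8, 8 — divisibility
is a hard constraint); `no_ct` reduces the generator to the two affine DU
layers. `no_encoder` removes the autoencoding path entirely: the scaled
PCA features stand in for $H$ and the generator trains on reconstruction
alone, the one reading of "remove the encoder" that leaves a trainable
model. `k_sweep()` reports `DeltaACC`$(k) = $ ACC$_k - $ACC$_0$ under
identical folds and makes no monotonicity assumption — degradation at
large $k$ is an expected outcome, not an error.

## Known limitations

* Binary classification only; imbalance is out of scope.
* The KDE prior is fitted per training fold from as few as dozens of
  subjects; with `per_roi` granularity and $p = 32$ this is a
  high-dimensional density estimate, and Scott's rule is a blunt
  bandwidth — the prior should be read as a regularization target, not a
  calibrated density.
* Generated networks satisfy the structural contract (symmetry, unit
  diagonal, $[-1,1]$ range) by construction and land on the originals'
  graph-metric scales, but they remain distributionally distinguishable
  from the originals on the reduced synthetic cohorts: two-sample
  Kolmogorov–Smirnov statistics for the six graph metrics range from
  roughly 0.4 (modularity) to 0.9 (efficiencies) after convergence. The
  prior-decoded networks inherit whatever mismatch remains between the
  encoder latents and the KDE prior at the adversarial equilibrium; the
  effect sizes the downstream utility comparisons detect are accordingly
  small.
* Training is CPU-bound and single-threaded by design (deterministic
  given a seed); a full-scale 300-epoch run takes on the order of ten
  minutes.
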