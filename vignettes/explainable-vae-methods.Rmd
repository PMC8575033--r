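---
title: "Explaining a VAE expression classifier: model, attribution engine and validation protocols"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining a VAE expression classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Deep embeddings of bulk expression profiles classify tumour types well, but a
classifier that cannot say *which genes* drove a call is hard to trust and
useless for hypothesis generation. `omixplain` couples a variational
autoencoder (VAE) classifier for sample-by-gene expression matrices with an
activation-level attribution engine, so that every prediction — and the
latent space itself — can be decomposed into per-gene contribution scores.

## Model

The encoder maps a profile $x \in [0,1]^G$ through ReLU hidden layers to a
Gaussian posterior $q_\phi(z \mid x) = \mathcal N(\mu, \mathrm{diag}\,\sigma^2)$.
Sampling uses the reparameterization trick $z = \mu + \sigma \odot \epsilon$,
$\epsilon \sim \mathcal N(0, I)$, so gradients flow through $\mu$ and
$\sigma$. The decoder mirrors the encoder and ends in a sigmoid layer;
because inputs are min–max normalized to $[0,1]$, the reconstruction
likelihood is elementwise binary cross-entropy (a mean-squared-error switch
is available via `recon_loss = "mse"`). The negative ELBO is

$$\mathcal L_{VAE} = \underbrace{\textstyle\sum_g \mathrm{BCE}(x_g, \hat x_g)}_{\text{reconstruction}}
 + \underbrace{\textstyle\sum_j \tfrac12(\sigma_j^2 + \mu_j^2 - 1 - 2\ln\sigma_j)}_{D_{KL}\left(q_\phi \,\|\, \mathcal N(0, I)\right)},$$

both terms summed within a sample and averaged over the batch. A three-layer
classification head (hidden widths 128 and 64, ReLU) consumes **the latent
mean $\mu$ directly** — not a sample $z$ — and produces class logits;
training minimises $\mathcal L_{total} = \alpha \mathcal L_{VAE} + \beta\,
\mathrm{CE}(y, y')$ in two phases: an unsupervised phase
($\alpha = 1, \beta = 0$, default 50 epochs) followed by a joint phase
(default $\alpha = \beta = 1$, 100 epochs). Optimisation is Adam at learning
rate $10^{-3}$ with minibatches of 32; all shuffling, initialisation and
$\epsilon$ noise derive from one integer seed, so a run is exactly
reproducible.

Because the classifier reads $\mu$ only, prediction is deterministic and the
stochastic node sits outside every path the attribution engine explains.
$\sigma$ is parameterized as $\exp(\tfrac12 \log \mathrm{var})$ for
positivity, with the log-variance clamped to $[-10, 10]$ for numerical
safety. The encoder/decoder hidden architecture is configurable
(`encoder_hidden`); the package default is a single hidden layer of 1024
units per side, the smallest shape consistent with compressing tens of
thousands of genes into a 128-dimensional bottleneck. No KL warm-up is used:
with a single weight $\alpha$ on the whole VAE term the two-phase schedule
already separates representation learning from classification.

## The attribution engine

The engine implements difference-from-reference attribution with the
DeepLIFT *rescale rule*, the propagation rule Deep SHAP applies to deep
networks. Given a sample $x$, a reference $r$ and a scalar output $f$, each
feature receives a contribution $C_{\Delta x_i \Delta o}$ such that

$$\sum_{i=1}^{n} C_{\Delta x_i \Delta o} = \Delta o = f(x) - f(r)$$

(*summation-to-delta*). Multipliers start at the target output unit and are
pulled backwards: a dense layer propagates them through its transposed
weights; an elementwise nonlinearity multiplies by the chord slope
$(f(a) - f(a_{ref}))/(a - a_{ref})$, falling back to the local derivative
when $|a - a_{ref}| < 10^{-7}$ (the 0/0 guard). For purely linear networks
this reduces exactly to $w_{\mathrm{eff}} \odot (x - r)$; for ReLU/sigmoid
networks the identity holds to floating-point accuracy, and the engine
records the worst relative violation it observed (`max_rel_error`) so every
result carries its own completeness check.

Three target modes share the machinery:

* **gene → class**: the class's *pre-activation logit* (never the softmax
  probability, which saturates) attributed over the input genes, through the
  encoder-to-$\mu$ trunk and the classifier;
* **latent → class**: the classifier's input layer is intercepted, samples
  and references are encoded to $\mu$, and the logit is attributed over the
  latent dimensions;
* **gene → latent**: one coordinate $\mu_j$ is the explained output.

With $k$ references, attribution runs against each reference separately and
the $k$ score vectors are averaged — not computed against the mean
reference, which differs for nonlinear networks. The default `k_refs = 100`
balances the variance of the reference average against cost. Reference
choice is scientific, not technical: random training samples give a
"versus everything" explanation, while phenotype-matched references (normal
tissue, the opposite sex, a sibling subtype) sharpen the contrast of
interest; both are supported and give partially overlapping gene lists.

Per-sample scores are aggregated over a labelled group by the mean of
absolute values (signed scores would cancel), and features are ranked with a
deterministic tie-break on feature id. Only the rescale rule is implemented;
the RevealCancel rule is out of scope. Three gradient-based baselines
(saliency, input-times-gradient, and expected-gradients/GradientSHAP with
seeded draws) share the same forward machinery for comparison studies; the
saturation fixture in the test suite shows the failure mode that motivates
the rescale rule — a unit pushed past its ReLU hinge has zero gradient but a
nonzero difference-from-reference.

## Latent-space tools

For unsupervised questions ("what separates these two clusters?") each
latent dimension is scored by Welch's unequal-variance $t$-test between the
two groups' $\mu$ values; dimensions are ranked by $p$-value (ties by $|t|$,
then index). Two-sided $p$-values are used. A dimension with zero pooled
standard error is degenerate and is flagged with $p = 1$ rather than ranked.
The top dimension can then be handed to the gene → latent mode to name the
genes that drive the separation.

Necessity is probed by sign-flip ablation: a listed dimension's $\mu_j$ is
replaced by $-1$ if positive and $+1$ if negative (exact zeros are left
unchanged, a case the flip rule does not define), guaranteeing a
perturbation away from the observed value. The ablation battery follows the
per-class framing: each class's own top/bottom dimensions are flipped and
the change in that class's one-vs-rest recall on the held-out split is
summarised across classes. Per-class Deep-SHAP-style rankings are the
default input to the battery (Welch rankings are equally accepted); the
per-class ranking is used because a dimension can matter for a class either
through its own logit or through a competitor's, and the per-class protocol
measures exactly the class it ranks for.

## Synthetic data: what it emulates and what it does not

The generator emulates the *shape* of a preprocessed pan-cancer expression
matrix: far more genes than samples, values in $[0,1]$, a small planted set
of discriminative genes per class, and a binary sex-analogue covariate
driven by one designated gene at extreme values (so latent-space sex
findings have a known driver). Background genes are Gaussian noise around
0.5, clipped to $[0,1]$ (clipping rather than resampling keeps generation
deterministic and cheap); planted genes get a constant $+0.4$ mean shift in
their class at noise sd $0.1$; 2% of cells are masked missing. Defaults are
the package's standard study fixture: 600 samples, 2000 genes, 4 balanced
classes, 25 planted genes per class.

What it deliberately does **not** model: count noise (negative binomial,
library size), correlated co-expression modules, batch effects, unbalanced
class sizes, or label noise. Passing the recovery tests therefore shows the
pipeline is *correct and sensitive* under clean planted signal; it does not
certify performance on real cohorts, where effect sizes are smaller and
correlation structure can spread credit across co-expressed genes.

## Numerical and design choices

* Preprocessing follows the standard expression pipeline: genes on
  chromosome Y, all-zero genes, and genes missing in strictly more than 10%
  of samples are removed (a gene at exactly 10% is kept); remaining missing
  cells are imputed with the per-gene mean — the deterministic reading of
  "replaced by the expression level of the corresponding gene"; min–max
  normalization is per gene over the training set, constant genes map to 0
  (avoiding 0/0), and the per-gene $(\min, \max)$ record is stored so new
  samples are normalized identically.
* Filter precedence (Y, then all-zero, then high-NA) affects only how a
  multiply-matching gene is *reported*; the surviving set is
  order-independent. Unannotated genes are retained and flagged, never
  silently dropped.
* Ranked-list ROC follows the gene-count-threshold construction: ~100
  cutoffs evenly spaced over $1..G$ with both endpoints forced into the
  grid, TPR/FPR per cutoff against the curated set, trapezoid AUC.
* Retraining studies reuse the parent hyperparameters except the input
  width, with a fresh seed per arm; random-gene arms draw uniformly without
  replacement; one-vs-rest metrics (F1, PPV, TPR, rank-statistic AUC) are
  macro-averaged over "other" classes.
* Train/test splits are stratified 80/20 with seeded shuffling.

## Fixture-scale choices

All shipped tests and the acceptance script run on the standard fixture at
sizes a laptop CPU handles comfortably: encoder hidden width 256, latent
width 32, classifier 128/64, the default epoch schedule (50 + 100), batch
32. These sizes are the package's own fixture-scale choices (a latent width
of 32 trains stably at this sample size; thinner encoders occasionally
undertrain); the epoch schedule, batch size, learning rate and classifier
shape are the package defaults at any scale. The genome-wide, 1024-hidden,
latent-128 configuration is supported but not exercised in the test suite.

## Known limitations

* The attribution engine supports dense + elementwise-activation networks
  (the architectures this package trains); convolutional or attention layers
  are out of scope.
* Rescale-rule scores depend on the reference set; there is no single
  "true" ranking, and users should state the reference strategy alongside
  any reported gene list.
* Welch ranking is used for ordering dimensions, not inference; no
  multiple-testing correction is applied across dimensions.
* Sign-flip ablation assumes latent activations of order ±1 (true after KL
  regularisation); grossly mis-scaled latents would make the flip either
  negligible or catastrophic.
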