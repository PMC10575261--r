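---
title: "Methods: conditional diffusion synthesis of multi-lead ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conditional diffusion synthesis of multi-lead ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(diffecg)
```

## The model

`diffecg` generates class-conditional multi-lead ECG records with a
denoising diffusion probabilistic model (DDPM). A forward process corrupts
a clean record $x_0$ over $T$ steps with a linear variance schedule
$\beta_t$,

$$x_t = \sqrt{\bar\alpha_t}\,x_0 + \sqrt{1-\bar\alpha_t}\,\epsilon,
\qquad \alpha_t = 1-\beta_t,\quad \bar\alpha_t = \textstyle\prod_{i\le t}\alpha_i,$$

and a denoiser network $\epsilon_\theta(x_t, t, c)$ is trained by MSE
regression on the injected noise, conditioned on a binary multilabel rhythm
vector $c$. Generation runs the ancestral reverse chain

$$x_{t-1} = \frac{1}{\sqrt{\alpha_t}}\Big(x_t -
\frac{1-\alpha_t}{\sqrt{1-\bar\alpha_t}}\,\epsilon_\theta(x_t,t,c)\Big) +
\sigma_t z,$$

with $z \sim N(0,1)$ for $t>1$ and $z=0$ at the last step. Reference
settings are $T=200$, $\beta$ from $10^{-4}$ to $0.02$, Adam at
$2\times10^{-4}$.

Two textual variants of the forward equation circulate: with and without
the square root on the noise weight. Only the rooted form yields
unit-variance marginals (and matches the $\sqrt{1-\bar\alpha_t}$ appearing
in the training-gradient expression), so the rooted form is the default;
the no-root variant is kept behind `forward_diffuse(no_root_noise = TRUE)`
for audit. Likewise the exact form of the fixed variance schedule
$\sigma_t$ is a genuinely open choice; $\sigma_t^2=\beta_t$ is the default and the
posterior variance $\tilde\beta_t$ is available via
`reverse_sample(variance = "posterior")`.

## The denoiser

The denoiser is a DiffWave-lineage stack: the input is lifted by a width-1
convolution, runs through residual blocks that add a three-level
sinusoidal diffusion-step embedding, apply their diffusion layers, inject
an affine projection of $c$ inside a gated (tanh ⊙ sigmoid) unit, and emit
residual and skip streams; the summed skips pass through one more
diffusion layer (again with label conditioning) and two output
projections. The diffusion layers are SPADE blocks — hybrid global/local
layers:

$$X_{local} = \mathrm{Local}(\mathrm{LN}(X)),\quad
X_{global} = \mathrm{SSM}(\mathrm{LN}(X)),$$
$$X_a = W[\mathrm{LN}(X_{local}), \mathrm{LN}(X_{global})] + X,\qquad
Y = \mathrm{FFN}(\mathrm{LN}(X_a)) + X_a.$$

* **Local branch** — sliding-window multi-head self-attention: position
  $i$ attends to $|i-j|\le w$ ($w$ = `window`, default 8 at desk scale).
  The implementation computes softmax mass only on the visible band, so
  out-of-window weights are exactly zero; it is oracle-checked against
  dense attention with an additive $-\infty$ mask.
* **Global branch** — a structured state-space (S4) convolution per
  channel. Each channel owns a fixed stable HiPPO system $(A, B)$ with a
  log-uniform step size $\delta \in [10^{-3}, 10^{-1}]$ and a trainable
  output map $C$, so its length-$L$ kernel is a trained linear combination
  of $N$ fixed basis kernels. Kernels are materialized directly
  ($K_k = \bar C \bar A^k \bar B$, $O(N^2 L)$) and applied with FFT
  convolution; at desk scale this is faster to verify and fast enough, and
  the $O(L)$ Cauchy-kernel path is deliberately out of scope.
* Local layers (the non-global levels) are the same block with the SSM
  branch disabled.
* The FFN nonlinearity is the sigmoid form of GELU,
  $x\,\sigma(1.702x)$ — a "GELU-like" smooth gate chosen for CPU cost.

### The HiPPO sign question

The printed construction of the base matrix $A^{(ds)}$ (negative
square-root entries on *both* triangles, $+\tfrac12$ diagonal) produces a
symmetric matrix with large positive eigenvalues: the continuous system is
unstable and the discretized kernel overflows for $\delta = 0.1$ at
$L = 1024$. The standard S4 normal form (sign-flipped upper triangle,
$-\tfrac12$ diagonal) has all eigenvalues at real part $-1$ and is stable
for every $\delta \in (0, 2)$. `build_hippo()` exposes both via
`form = c("printed", "s4")`, defaults to the printed formulas for
fidelity, and the model's SSM branches use the stable `"s4"` form. The
stability screen in the test suite therefore runs on the `"s4"` form, and
the instability of the printed form is itself asserted.

### Training and parameterization choices

* **Autodiff**: no deep-learning framework is available in the target R
  environment, so the package ships a small tape-based reverse-mode
  engine (`R/autodiff.R`). Every operator is gradient-checked against
  central finite differences in the test suite, and the training path is
  asserted exactly equal to the plain-numeric and compiled inference
  paths.
* **$\delta$ fixed, $C$ trained**: training $\delta$ would require
  differentiating through the bilinear-transform inverse and the matrix
  powers behind every kernel entry; with per-channel fixed $(A, B,
  \delta)$ the kernel family spanned by $C$ is already $N$-dimensional
  per channel. This is the one deliberate deviation from the suggested
  parameterization, made for CPU tractability.
* The final residual block's residual-stream projection is omitted: its
  output is never consumed, so it would be untrainable dead weight (and
  would break the gradient-coverage audit).
* The last output projection is initialized near zero so the initial loss
  sits at the zero-predictor baseline ($\approx 1$) and training starts
  stably; it is not exactly zero so that every parameter group receives
  gradient from the first step.
* Sampling uses a compiled (RcppArmadillo) replica of the forward pass
  and advances up to 25 reverse chains at once; the noise of record $i$
  is drawn from a counter-derived stream, so results are bit-reproducible
  and independent of batching.

## Lead reconstruction

The generator produces 8 leads: I, aVF and V1–V6. The remaining four limb
leads follow from Einthoven's law and Goldberger's equations. Since those
identities are stated in terms of II, the module first inverts the system
to $II = aVF + I/2$ — the unique solution consistent with all four
identities — then sets $III = II - I$, $aVL = (I-III)/2$,
$aVR = -(I+II)/2$. Round-tripping a consistent 12-lead record through its
8-lead subset reproduces it to $10^{-10}$, and every assembled record
satisfies the identities by construction.

## Evaluation

* **DTW** with squared-difference cost via the standard dynamic program;
  exact against exhaustive enumeration of monotone warping paths for
  short series. Multi-lead records are compared per lead and averaged
  (`dtw_mode = "concat"` is provided because the alternative convention
  cannot be ruled out).
* **MMD** with a Gaussian RBF kernel, unbiased within-set terms and the
  $-2/(nm)$ cross term; the bandwidth defaults to the median pairwise
  distance of the pooled sample and is logged in the report.
* **Multilabel accuracy** (position-wise, scores thresholded at 0.5) and
  **macro AUROC** (Mann–Whitney with ties counted ½, degenerate label
  columns skipped and reported).
* **Authenticity** is classifier transfer: a classifier trained on real
  training data is applied to real and generated test sets; smaller
  accuracy/AUROC gaps mean more authentic samples. The bundled harness is
  a small 1-D residual convolutional multilabel classifier (a stand-in
  for a full ResNet-1D, which is out of scope).

A caveat uncovered during development: "a frozen random classifier scores
AUROC ≈ 0.5" is only true when its scores are independent of the labels.
On class-structured records a random convolutional filter bank correlates
with the class-dependent beat rate, and single-seed AUROCs range from 0.19
to 0.97. The chance-level acceptance check is therefore asserted against
independently permuted labels, which is the null its derivation actually
simulates.

## The synthetic fixture

`generate_dataset()` produces quasi-periodic beat trains: five Gaussian
bumps per beat (P, Q, R, S, T surrogates) tiled at a label-dependent rate
with label-dependent R/T amplitudes, mixed linearly into leads (so
noise-free 12-lead records satisfy the limb identities exactly), plus
seeded Gaussian noise. Label effects are additive on log-rate and
multiplicative on amplitudes, so multilabel combinations compose
predictably.

Desk defaults: $L=128$ at 64 Hz (2 s), 2 leads, 2 one-hot classes at 1.25
and 2.5 Hz, noise SD 0.05 — chosen so one beat class sits well inside a 2 s
window, the classes are a factor 2 apart in rate (trivially separable:
the bundled dominant-frequency detector achieves 100% on clean data), and
the noise floor is visible but small against the unit R wave. The beat
morphology is deliberately smooth (wide R and T bumps) so the spectral
fundamental of a train dominates its harmonics; this is what makes a peak
detector a valid class oracle. None of this emulates physiological ECG:
morphology variability, baseline wander, inter-lead timing and real
arrhythmia signatures are absent. A green end-to-end test therefore
establishes that the pipeline — conditioning, training, sampling, lead
algebra, evaluation — works, not that the model produces clinically
plausible ECG.

## Desk-scale end-to-end run

The acceptance run trains the 2-block / 32-channel model (L = 128, 2
leads) on 2,000 synthetic records for 1,500 steps (inside the stated
2,000-step cap; the count is set by 1-CPU wall time) at learning rate
$10^{-3}$ — scaled up from the reference $2\times10^{-4}$ because the
desk model is two orders of magnitude smaller. It must (a) drive the
eps-prediction loss below the zero-predictor baseline of 1.0 and (b)
generate samples whose dominant frequency matches the conditioning class
for at least 80% of 100 samples per class. The reference-scale
configuration (4 blocks, 256 channels, L = 1000, 12 labels, 8 leads) is
shipped as `dsat_config_reference()` but requires GPU-scale compute to train.

## Known limitations

* Training is single-threaded CPU R; the reference-scale model is
  shipped but not trainable here.
* The S4 branch trains only its output map; `delta`, `A`, `B` are fixed
  at initialization.
* Complex/diagonal S4 parameterizations, DDIM-style fast samplers,
  learned variances and classifier-free guidance are out of scope.
* The WFDB reader/writer covers exactly the single-segment format-16
  subset the package writes; it is not a general PhysioNet client.
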