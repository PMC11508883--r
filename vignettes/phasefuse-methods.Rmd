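---
title: "Split-variable phase retrieval with fusing: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-variable phase retrieval with fusing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasefuse)
```

## The measurement model

Phase retrieval asks for a signal given only the magnitudes of its Fourier
measurements; the detector records intensities and the phase is lost. Under
the coded diffraction pattern (CDP) scheme the real signal
$x \in \mathbb{R}^N$ (a 1-D vector or a vectorized $H \times W$ image) is
modulated elementwise by $K$ random masks $W_j$ before the DFT, and the
observations are the squared magnitudes

$$ y_{ij} \;=\; \lvert f_i^T W_j x \rvert^2 + \eta_{ij},
   \qquad i = 1,\dots,N,\; j = 1,\dots,K, $$

where $f_i^T$ are the rows of the unnormalized DFT matrix (the 2-D DFT for
image layout) and $\eta$ is optional additive white Gaussian noise. Mask
entries are drawn i.i.d. uniformly from $\{1, -1, i, -i\}$ — a physically
realizable phase-shift modulation. This alphabet gives the sensing operator
the moment structure the convergence theory needs: $E\,w = 0$,
$E\,w^2 = 0$ and $\lvert w \rvert^2 = 1$ exactly. The $\{1,-1\}$ and
$\{i,-i\}$ sub-alphabets preserve the zero-mean property and are available
as options. `sampleMasks()`, `forwardIntensity()` and `addAwgn()` implement
this model; by Parseval's identity each mask's column of noise-free
intensities sums to $N\lVert x\rVert^2$, which the tests exploit as an
exact invariant.

Writing $H_{ij} = \mathrm{Re}\{W_j^* \bar f_i f_i^T W_j\}$, each
measurement is the quadratic form $x^T H_{ij} x$. The real part appears
because the signal and both split variables below are real; the package's
conjugation convention is fixed by requiring the diagonal case to
reproduce $\lvert f_i^T W_j x\rvert^2$, and all operators apply $H_{ij}$
matrix-free as $\mathrm{Re}\{z_a \overline{z_b}\}$ with
$z_v = \mathrm{DFT}(W_j \odot v)$ — the $N \times N$ matrices are never
formed.

## The split-variable solver and the fusing step

Lifting interprets the quadratic measurements as linear measurements of
the rank-1 matrix $X = x x^T$. Instead of semidefinite programming over
$X$ (prohibitive beyond toy sizes), the package factorizes $X = b a^T$
with two independent real vectors and solves

$$ \min_{a, b} \;\sum_{ij}\, (a^T H_{ij} b - y_{ij})^2
   \quad \text{s.t.} \quad a = b . $$

For fixed $a$ the objective is an ordinary linear least-squares problem in
$b$: stacking rows $a^T H_{ij}$ gives a $KN \times N$ operator $H_a$, and
the half-step solves the normal equations $H_a^T H_a b = H_a^T y$ by
conjugate gradient, matrix-free (each CG iteration costs $O(KN\log N)$).
Alternating the two half-steps alone does **not** converge: the pair
$(a, b)$ comes to rest on opposing sides of the solution. The algorithmic
contribution is the *fusing* (recombination) step

$$ a_n = b_n = \tfrac{1}{2}\,(a_{n-1} + b_n), $$

which cancels the opposing error components, enforces $a = b$ (hence
positive semidefiniteness of the implied $X$) and makes the iteration
contract. Only one half-step per outer iteration is needed — the analysis
shows the second can be skipped. `phaseRetrieve()` implements exactly this
loop; `recombine = FALSE` exposes the pure alternation for ablation, and
the package's tests confirm that disabling fusing stalls the majority of
otherwise-easy noise-free problems.

The supporting theory tracks the error vectors $d = a - x$, $e = b - x$
and $g = d + e$. In expectation over the masks, the contraction factor is
governed by the scalar function

$$ f(u) \;=\; \frac{u + 1}{1 + 3u^2}, \qquad u = \cos\theta_{gb}, $$

whose maximum over $[-1, 1]$ is $\approx 1.0774$ (attained at
$u = 2/\sqrt 3 - 1$), below the worst-case constant $1.08$ used in the
bounds. Propagating that constant through the geometry yields the
convergence condition $\mu = \lVert e\rVert / \lVert b\rVert \le 1/1.08$
and the basin radius: any initialization with
$\lVert e \rVert \le 0.48\,\lVert x \rVert$ converges. `boundFunction()`,
`boundFunctionMax()` and `convergenceDiagnostics()` expose these
quantities; the concentration slack terms ($\delta$, $\delta_1$) of the
full analysis are *not* estimated from data — the diagnostics use their
zero limit, which is what the flags document.

## Stopping rules and numerical choices

* The outer loop stops when $\lVert a_n - a_{n-1}\rVert / \lVert a_n\rVert
  < \varepsilon$ with $\varepsilon = 10^{-15}$ by default. The stopping
  distance is taken *relative* for amplitude invariance; with the default
  tolerance the rule fires when the iteration reaches a machine-precision
  fixed point. The iteration cap is $q = 2500$.
* CG uses a fixed relative residual tolerance $10^{-12}$ and cap $p = 50$,
  warm-started from the previous half-step solution. A loose
  early-iteration tolerance was deliberately rejected: a fixed tolerance
  keeps runs deterministic and reproducible to the last bit under a fixed
  seed.
* The normal-equations form mirrors the algebra of the half-step
  derivation; its squared condition number is acceptable at these problem
  sizes and the dense-oracle tests bound the CG solution error at
  $10^{-8}$ relative against a QR least-squares solve.
* The global sign ambiguity of real phase retrieval is resolved only in
  the metrics (`normalizedError()` minimizes over $\pm$), never inside
  the solver.
* Degenerate inputs: a zero anchor (or an estimate that collapses to
  zero) raises a degenerate-operator error; all-zero observations yield
  the zero half-step solution exactly; non-convergence within $q$
  iterations is reported as `converged = FALSE`, not as an error.
* The compiled core plans FFTW transforms once per solve and reuses them
  across all iterations; 2-D signals use the 2-D DFT throughout
  (`N = H \cdot W`).

## Initializations

The positive random initialization draws i.i.d. uniform$(0,1)$ entries and
rescales to the Parseval energy estimate
$\lVert \hat x\rVert^2 = \sum_{ij} y_{ij} / (NK)$, which is exact for
noise-free data. Its two load-bearing properties are strict positivity and
a correctly calibrated norm; its error is nearly independent of $K$
(about $0.6$–$0.75$ on natural and phantom images). For *nonnegative*
signals it is remarkably effective — with it the solver recovers
uniform$[0,1]$ signals from as few as $K = 2$ masks.

The spectral initializations power-iterate (50 iterations by default) on
the data-weighted operator $v \mapsto \sum_{ij} w_{ij} H_{ij} v$:

* **wf** — $w = y$ (plain spectral method);
* **twf** — $w = y \cdot \mathbb{1}\{y \le \alpha_y^2 \lambda^2\}$ with
  $\alpha_y = 3$ and $\lambda^2$ the energy estimate, discarding heavy-tail
  samples;
* **taf** — unit weights on the fraction (default $1/6$) of rows with the
  largest amplitudes. The small-amplitude rows are nearly orthogonal to
  $x$, so the kept complement concentrates around it. For CDP masks every
  sampling row has norm exactly $\sqrt N$, so ordering by normalized
  correlation is ordering by amplitude.

All inits are rescaled to the energy estimate, so for noise-free data
their norms match $\lVert x\rVert$ within 1%. Spectral inits need
$K \ge 4$ (TAF) or $K \ge 8$ (TWF) masks to beat a random guess
(normalized error below 1), while the positive random init is informative
at every $K$ — but only encodes nonnegativity, which is why general
(sign-mixed) Gaussian signals at small $K$ favor the TAF start.

## Baselines

`runBaseline()` re-implements the standard comparison methods from their
published descriptions, matrix-free through the same operators:
Wirtinger flow (intensity-residual gradient with the ramped step
$\min(1 - e^{-t/330}, 0.2)$ normalized by the starting norm), truncated
Wirtinger flow (Poisson-type gradient with the $\alpha$ truncation rules,
step $0.2$), truncated amplitude flow (amplitude residuals with the
$1/(1+\gamma)$ truncation, $\gamma = 0.7$, step $0.6$), a
momentum/median-reweighted TAF variant (momentum $0.3$, residuals beyond
3 median absolute residuals down-weighted — the source description calls
these "minor modifications" without constants, so both are exposed in
`baselineConfig()`), and a split-variable ADMM sharing this package's
bilinear formulation but enforcing $a = b$ through a penalty and dual
update rather than fusing (penalty scale exposed as `admmRho`; its
convergence is known to be parameter-sensitive). The TAF family consumes
plain magnitudes; when comparing at a matched SNR the noise is applied to
the magnitudes for those methods and to the squared magnitudes for the
others.

These baselines are held to a *qualitative* fidelity bar — stationarity at
the truth, descent of their own objectives, the success/failure pattern
across $K$, and the ADMM-vs-fusing iteration-count contrast — not to
bit-exactness against the original MATLAB releases. One known divergence:
this package's WF is a real-variable rewrite and achieves exact noise-free
recovery at $K = 4$, where the original complex implementation is reported
to plateau near $0.03$.

## What the synthetic generator emulates

`generateSignal()` reproduces the study conditions: $32 \times 32$ signals
with i.i.d. uniform$[0,1]$ entries (nonnegative case) or i.i.d. standard
Gaussian entries (general real case), plus a deterministic
piecewise-constant phantom in $[0,1]$ standing in for natural test images
so nothing needs downloading. Success-rate experiments run 100 trials per
cell by default with per-trial signal/mask/noise seeds derived
deterministically from one master seed, success meaning normalized error
below $10^{-5}$ (the source table does not state its threshold; this
choice sits three orders below the noise-free error floor and three above
typical failures, so rates are insensitive to it). Mask sets are redrawn
per trial.

Real detector data differ from this generator in ways the tests cannot
probe: Poisson rather than additive Gaussian counting noise, partial
coherence and model mismatch in the optics, correlated mask imperfections,
and nonnegativity priors that real images satisfy only approximately.
Passing tests therefore demonstrate correctness of the algorithmic claims
under the stated random model, not end-to-end performance on an
instrument.

Desk-scale experiment sizes used throughout the suite — $N = 64$ vectors,
$32\times32$ to $64\times64$ images, $K \in \{2,\dots,16\}$, 100-trial
success tables, 50-trial basin sweeps — were chosen as the smallest sizes
at which the published qualitative behavior (success-rate table, basin,
trend curves) is already stable.

## Known limitations

* Real signals only: the complex case changes both the algorithm and the
  analysis and is out of scope.
* Success rates for general (sign-mixed) Gaussian signals at small $K$
  are sensitive to implementation details that published tables for this
  algorithm family rarely pin down — the initialization's norm
  calibration, the exactness of the inner least-squares solves, and the
  outer iteration budget. With this package's Parseval-exact init and
  tight CG tolerances, the measured success rates at $K = 4$ sit near
  100% rather than in the middle of the transition region; the
  transition across $K$ keeps its shape but can sit one mask count lower
  than under looser settings.
* The lifted matrix is never materialized, so nothing here addresses the
  semidefinite-programming route.
* AWGN on intensities is a simplification of detector physics.
* Image experiments use the built-in phantom by default; absolute
  PSNR/SSIM values on natural images depend on the image and are checked
  as orderings, not absolutes.

## A worked example

```{r example, eval = FALSE}
x <- phantomImage(32)                       # ground truth in [0, 1]
masks <- sampleMasks(dim(x), K = 4, seed = 1)
y <- addAwgn(forwardIntensity(x, masks), snrDb = 24, seed = 2)
x0 <- randomPositiveInit(y, masks, seed = 3)
fit <- phaseRetrieve(y, masks, x0, groundTruth = x)
normalizedError(estimate(fit), x)
imageQuality(estimate(fit), x)
```
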