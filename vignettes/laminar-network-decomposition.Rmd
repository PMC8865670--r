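---
title: "Decomposing laminar directed connectivity into concurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing laminar directed connectivity into concurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`laminet` estimates how cortical areas influence each other, layer by
layer, as a function of time and frequency, and decomposes that
connectivity into a small number of concurrent directed networks. This
vignette explains the models behind each stage, the parameters that
matter, the synthetic ground-truth generator used to validate the chain,
and the numerical and design choices that were genuinely open.

## The model chain

### Time-varying MVAR and the adaptive estimator

Epoched multichannel LFPs $x(t) \in \mathbb{R}^n$ are modelled as a
time-varying vector autoregression of order $p$,
$$x(t) = \sum_{k=1}^{p} A_k(t)\, x(t-k) + w(t), \qquad w(t) \sim (0, \Sigma_w).$$
`fit_tvmvar()` estimates $A_k(t)$ with an adaptive recursive
least-squares scheme: at each time step every trial enters as a repeated
measurement of the same regression, and past time steps are
exponentially down-weighted by the filter factor $c \in (0, 1]$. The
accumulated regressor covariance is inverted through an eigenvalue
decomposition with components below $10^{-8}$ of the largest eigenvalue
truncated (a warning reports when truncation is active). With $c = 1$
the estimate at time $t$ is exactly the cumulative ordinary
least-squares solution — the property the test suite uses as an oracle.
The residual covariance is estimated from one-step-ahead prediction
errors, both as a per-time exponential average and as a global average
(the global average feeds the connectivity normalization; whether the
original adaptive filter keeps a time-resolved residual covariance is
not documented, so both are retained).

Parameters: `p` (samples; default 15 at 250 Hz = 60 ms) and `c`
(default 0.98). The first `p` samples carry initialization values and
are flagged as burn-in; baseline windows should exclude them.
`select_model_order()` picks `p` by comparing the model's parametric
spectra against nonparametric Morlet-wavelet reference spectra. The
comparison is made on log spectra with each channel's mean log offset
removed: log spectra balance the contributions of the 1/f range, and
the offset removal makes the criterion invariant to the arbitrary
scale of the wavelet estimate. Ties go to the smallest order.

### iPDC and the five-way tensor

With $\bar{A}(f, t) = I - \sum_k A_k(t) e^{-i 2 \pi f k / f_s}$, the
information partial directed coherence from channel $j$ to channel $i$
is
$$\iota_{ij}(f,t) = \frac{|\bar{A}_{ij}(f,t)|\; \sigma_{ii}^{-1/2}}
  {\sqrt{\bar{a}_j(f,t)^{\mathsf H}\, \Sigma_w^{-1}\, \bar{a}_j(f,t)}},$$
where $\bar{a}_j$ is column $j$ and $\sigma_{ii}$ the $i$-th residual
variance. With diagonal $\Sigma_w$ this reduces to the generalized PDC
and $\sum_i \iota_{ij}^2 = 1$ for every (source, frequency, time) — an
identity the tests verify to $10^{-10}$. Magnitudes (not squares) are
stored; because the normalization is per source, time, and frequency,
the measure is insensitive to 1/f power gradients and to common channel
rescaling. Per-animal arrays are reorganized into a five-way tensor —
source layer × target layer × time × frequency × between-area
connection (within-area blocks dropped; 30 ordered connections for 6
areas) — and averaged element-wise over the animals that provide each
connection.

### Nonnegative PARAFAC

The group tensor is decomposed as
$$X_{s,t,\tau,f,c} \approx \sum_{k=1}^{K}
  a_{s,k}\, b_{t,k}\, c_{\tau,k}\, d_{f,k}\, e_{c,k}, \qquad
  a, b, c, d, e \ge 0,$$
fitted by alternating least squares with exact nonnegative column-wise
updates (each column update solves its subproblem in closed form, so
the reconstruction error is monotone non-increasing — a tested
invariant). The first initialization is a deterministic nonnegative
higher-order SVD (the magnitudes of each unfolding's leading singular
vectors); additional starts are random and the best fit is kept.
Random initialization alone regularly stalls in swamps on these
tensors. Stopping: relative fit change below $10^{-8}$ or 2,000
iterations. On exit the layer, frequency, and connection columns are
normalized to unit variance, the scale is carried by the temporal
loadings, and components are ordered by descending amplitude share.

The component number is selected with `select_components()`: for each
of `n_diag_boots` random animal subsets, all candidate K are fitted on
the subset mean and the Corcondia score, fit, convergence, and maximal
between-component loading correlation recorded. K* is the largest K
with median Corcondia ≥ 85, median between-component correlation
< 0.8, and a median fit gain over K−1 of at least one point. Fit is
expressed on the standard PARAFAC percentage-of-norm scale,
$100\,(1 - \lVert X - \hat X\rVert / \lVert X \rVert)$: with a
dominant component holding half the model amplitude, the smallest
component contributes only a fraction of a percent of the *squared*
error, so a squared-scale gate could never detect it; on the norm
scale the fourth network adds ~3–5 fit points and a fifth adds well
under one. All thresholds are arguments, and the full diagnostic table
is attached to the result, so the decision is auditable and
reproducible — the replacement for a by-eye step.

Corcondia computes the least-squares core tensor implied by the fitted
loadings and scores its closeness to the ideal superdiagonal CP core,
$100\,(1 - \sum (g - t)^2 / \sum t^2)$; 100 for an exact CP model,
collapsing (typically far negative) when overfactored.

### Characterization, hierarchy, RF and spiking analyses

Per component: layer loadings are normalized to sum one per bootstrap
and a layer is flagged when the lower bound of the central 95 %
bootstrap interval exceeds the uniform weight $1/n_\text{layers}$;
temporal loadings are converted to percent change from the
pre-stimulus baseline and tested per post-stimulus time point
(one-sided t across bootstraps, Bonferroni over post-stimulus points;
two-sided available); amplitude shares divide each component's mean
temporal loading by the sum over components; frequency loadings are
fitted with power-law $c f^{-\beta}$, lognormal, and exponential
curves by nonlinear least squares in linear space and the family with
the smallest mean squared error wins. The lognormal is fitted as a
curve $c \exp(-(\log f - \mu)^2 / 2\sigma^2)$ — a scale parameter is
required to fit loading amplitudes even though only $(\mu, \sigma)$
describe the shape. Initial values: power law ($c$ = loading at the
lowest frequency, $\beta = 1$), lognormal ($\mu$ = log argmax,
$\sigma = 1$, $c$ = max), exponential ($c$ = max, $\beta = -0.05$).
`modulation_spectrum()` removes a linear trend from the post-stimulus
temporal loading and returns the discrete Fourier amplitude spectrum
(resolution = 1/window length).

Functional hierarchy: $\mathrm{DAI}_{ij} = (e_{ij} - e_{ji}) /
(e_{ij} + e_{ji})$ with $e_{ij}$ the loading of the connection from
area $j$ to $i$; pairs with no connectivity in either direction are
set to 0. The DAI is scaled by the fixed factor 2.5 — mapping the
attainable $[-1, 1]$ range onto six hierarchy levels (range 5, shifted
to $[1, 6]$) — rather than by min–max of the observed values, which
would break antisymmetry; a min–max variant is available. Per target
area the row is shifted so its smallest entry is 1, and the per-area
score $H$ is the row mean (the summed variant is available; rankings
agree on complete matrices). Low $H$ marks the network's driving
areas. Note a structural property of this score: an area is lowest
exactly when its row is uniformly dominated, so a stream's designated
driver separates from the rest only when the remaining pairs carry
heterogeneous or direction-balanced connectivity — pure one-way chains
are degenerate (driver and pure receiver tie).

RF analysis: per site, the observed statistic is the maximum over
stimulus positions of the mean response; the null permutes responses
across trials and positions, $p = (1 + \#\{\text{null} \ge
\text{obs}\}) / (1 + n_\text{perm})$; the centroid is the
response-weighted mean over pixels above half the peak (both the
statistic and the centroid rule are configurable, as the upstream
definition is not fully specified). Connection strengths are
reconstructed from the PARAFAC loadings — by multilinearity the mean
over layers, time, and frequency collapses to
$e_{c,k}\,\bar a_k \bar b_k \bar c_k \bar d_k$, verified against a
brute-force tensor reconstruction — and regressed on RF-centroid
distance with random intercepts for bootstrap and connection
(maximum likelihood; Satterthwaite p for the slope, likelihood-ratio
test against the fixed-effects model, and both a naive adjusted R²
and a marginal/conditional variance-partition R², since "adjusted R²"
is ambiguous for mixed models). Spikes: units with SNR > 3 are pooled
per (area, layer) into 4-ms bins (L1 is excluded by default for lack
of spiking); each bootstrap's temporal loading is correlated with the
raw counts and a site is significant when the central 95 % of the
bootstrap correlation distribution excludes zero.

## The synthetic ground truth

The generator's default configuration (`default_config()`) encodes the
study conditions the analysis assumes: 6 areas (V1, LM, RL, AL, PM,
AM) × 6 layers at 250 Hz, epochs −300…1000 ms, two contrast variants,
and four planted networks —

* **scale-free feedforward**: sources peaking at L4/L5, targets at L5,
  spectrum $f^{-0.4}$, fast transient envelope (onset 50 ms at high,
  80 ms at low contrast, second peak at 300 ms at low contrast),
  broad long-range connections driven by V1; amplitude share 50 %.
* **gamma feedforward**: sources and targets at L2/3, Gaussian
  spectral peak at 38 Hz (high) or 26 Hz (low contrast), sustained
  envelope; at low contrast the envelope carries a 5-Hz modulation;
  short-range V1-driven connections; share 18 %.
* **supragranular feedback**: L1 sources and targets, lognormal
  spectrum peaking at 5 Hz (FWHM ≈ 1–14 Hz), transient envelope,
  AM-driven top-down connections; share 17 %.
* **infragranular feedback**: L6 sources and targets, peak 6 Hz
  (FWHM ≈ 2.5–15.5 Hz); the envelope dips after onset at high
  contrast and rises late at low contrast; connections are
  concentrated on RL broadcasting to all areas over a weak
  direction-balanced residual; share 15 %.

Shares are defined under the model normalization (unit-variance
loadings, scale in the time mode), so recovered amplitude shares
reproduce the planted ordering. The four connection footprints carry
distinct distance decays and driver areas; this is what makes the
planted rank-4 model identifiable — with near-proportional connection
columns the CP decomposition of the resulting tensor is not unique and
no method could recover it.

Two routes realize the configuration:

* `simulate_group_tensors()` builds per-animal five-way tensors
  directly from the loadings, with two stochastic layers: a per-animal
  lognormal amplitude factor per component (SD 0.2, the first-order
  model of between-animal variability; it reproduces bootstrap share
  SDs of a few points on the dominant network) and additive Gaussian
  measurement noise specified per epoch (default 7.5 % of the tensor
  RMS) and scaled by $1/\sqrt{n_\text{trials}}$, since a per-animal
  tensor is an average over trials. Noise is rectified at zero to keep
  the tensor nonnegative.
* `simulate_epochs()` realizes the configuration generatively: each
  planted coupling becomes a band-shaped FIR kernel (frequency-sampling
  design, 12 lags by default) between the designated layer channels,
  scaled by the component's connection weight, laminar weights, and
  temporal envelope; channels have weak self-dynamics (lag-1
  coefficient 0.3, kept weak so the iPDC column normalization leaves
  the planted cross-spectral shapes undistorted) and unit-variance
  innovations. Coupling amplitudes follow the component shares
  directly. The assembled coefficient array is globally rescaled until
  its companion spectral radius is at most 0.95 at every time point,
  and simulation refuses to run if any time point is unstable. The
  realized spectra (the FIR magnitude responses) are stored next to
  the design spectra and are the ground truth for generative-route
  recovery scoring.

`reduced_config()` is a 3-area × 3-layer variant for fast tests:
layers collapse to supragranular/granular/infragranular, the feedback
spectral peaks move to 5 and 12 Hz and the infragranular driver to the
middle area — at this scale the six-area defaults would leave the two
feedback streams spectrally and topologically collinear, i.e.
unidentifiable rather than merely harder.

`run_recovery()` chains epochs → tvMVAR → iPDC → group tensor →
PARAFAC and scores recovery per mode. It fits one component more than
planted: the estimation floor of finite-trial iPDC (the nonzero
magnitudes that zero couplings produce) is itself structured, and
giving it its own component prevents it from merging with the weakest
planted network. Recovery is scored by loading correlations per mode
(layers, frequency, connection); the time mode carries the model scale
and is validated instead through the temporal statistics and
modulation analyses.

## What the tests show — and what they do not

The synthetic data match the statistical structure the analysis
assumes: linear time-varying couplings, Gaussian innovations,
rank-structured connectivity with smooth envelopes and spectra,
Poisson spiking tied to network envelopes, Gaussian RF bumps. Passing
recovery tests therefore demonstrate that the estimators and
decompositions are implemented correctly and are identifiable under
these conditions. They do not show that real recordings satisfy those
conditions: real LFPs have nonstationary noise, volume conduction,
non-Gaussian artifacts, imperfect layer assignment, and animal
variability richer than amplitude scaling. Two procedural caveats are
worth stating explicitly. The bootstrap-interval significance rule for
spike-network correlations is calibrated only when the bootstrap
spread of the loadings is at least as large as the loading's own
sampling uncertainty; when bootstraps are nearly shape-identical and
the envelope is smooth, it is anticonservative against rate noise. And
the hierarchy score's per-row shift makes pure one-way structures
degenerate, as noted above.

## Numerical choices and problem sizes

Degenerate inputs: all-zero tensors, zero baselines, constant rate
series, missing RF centroids, non-antisymmetric DAI matrices, and
unstable coefficient arrays are rejected with explicit errors; pairs
with no connectivity get DAI 0; zero-variance loading columns are left
in place (a dead component) rather than reinitialized, preserving the
monotonicity of ALS.

The test suite and the acceptance script run everything at reduced
problem sizes chosen to keep the full validation on a single CPU in
minutes: the reduced 3×3 configuration with 200 trials for
generative-route recovery (three seeds), tensors subsampled to ~17–66
time points and ~13–34 frequencies for decomposition studies, 6–12
bootstraps where the full analysis would use 500, and 1,000-repetition
null simulations for the error-rate checks. The planted structure is
smooth on all axes, so the subsampling does not remove information
that the full grids carry.
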