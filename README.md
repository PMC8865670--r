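# laminet

Decompose time- and frequency-resolved directed cortical connectivity into
concurrent feedforward and feedback networks.

`laminet` is an R toolbox for laminar local field potential (LFP) studies of
the visual cortical hierarchy. Visual stimulation engages several
interareal processing streams at once — a broadband feedforward stream over
granular/infragranular layers, a gamma-band feedforward stream over layers
2/3, and low-frequency feedback streams over layer 1 and layer 6 — and the
package provides the full chain needed to separate them from multichannel
recordings:

1. **Preprocessing** — stimulus-locked epoching, bipolar re-referencing at
   layer-representative channels (80 µm span on 40-µm probes), anti-aliased
   downsampling to 250 Hz, current source density (CSD) from the second
   spatial derivative, and prior-guided layer assignment
   (`epoch_signals()`, `bipolar_reference()`, `downsample()`,
   `compute_csd()`, `assign_layers()`).
2. **Time-varying MVAR modelling** — an adaptive recursive least-squares
   estimator with a forgetting ("filter") factor fits a time-varying
   multivariate autoregressive model across trials; the model order is
   selected against nonparametric Morlet-wavelet reference spectra
   (`fit_tvmvar()`, `select_model_order()`, `parametric_psd()`).
3. **Directed connectivity** — the Fourier-transformed coefficients are
   normalized into the information partial directed coherence (iPDC), a
   frequency-domain Granger-causal measure; per-animal arrays are unfolded
   into a five-way tensor: source layer × target layer × time × frequency ×
   between-area connection (`ipdc()`, `build_group_tensor()`,
   `morlet_psd()`).
4. **Tensor decomposition** — nonnegative PARAFAC (canonical polyadic)
   decomposition by alternating least squares separates the tensor into K
   rank-one networks; the component number is chosen with core-consistency
   (Corcondia), fit, convergence, and between-component correlation
   diagnostics over animal-subset bootstraps (`fit_parafac()`,
   `corcondia()`, `select_components()`, `bootstrap_decompose()`,
   `match_components()`).
5. **Characterization** — laminar significance of loadings, baseline
   percent-change dynamics with Bonferroni control, amplitude shares,
   power-law / lognormal / exponential spectral model comparison, and
   modulation spectra of the temporal loadings
   (`laminar_significance()`, `temporal_stats()`, `amplitude_share()`,
   `fit_frequency_models()`, `modulation_spectrum()`).
6. **Functional hierarchy** — the directed-influence asymmetry index
   `DAI_ij = (e_ij − e_ji) / (e_ij + e_ji)` (with `e_ij` the loading of the
   connection from area *j* to area *i*), scaled onto ±2.5, shifted per
   target area, and averaged into a per-area hierarchy score `H`; lower `H`
   means the area drives the rest of the network more strongly
   (`dai_matrix()`, `hierarchy_scores()`, `component_hierarchy()`).
7. **Receptive fields and spiking** — permutation tests and centroids for
   RF maps, Kronecker reconstruction of per-connection strengths,
   mixed-effects regression of strength on RF-centroid distance, 4-ms
   spike binning with SNR filtering, and bootstrap correlation of network
   amplitudes with laminar firing (`detect_rf()`, `rf_distance()`,
   `reconstruct_connection_strength()`, `regress_rf()`, `bin_spikes()`,
   `correlate_networks_spikes()`).

Every stage is testable without any external recordings: the synthetic
module plants four ground-truth networks (with configurable laminar
profiles, coupling spectra, envelopes, and connection footprints) and
generates laminar LFP epochs, spike trains, RF maps, and group tensors from
them, so the whole pipeline is validated by parameter recovery
(`default_config()`, `reduced_config()`, `simulate_epochs()`,
`simulate_spikes()`, `simulate_rfs()`, `simulate_group_tensors()`,
`run_recovery()`).

## A worked example

Simulate laminar recordings from the reduced three-area configuration,
estimate directed connectivity, and recover the planted networks:

```r
library(laminet)

cfg <- reduced_config("high")
cfg
#> <planted_networks> 3 areas x 3 layers @ 250 Hz, contrast high
#>   scalefree_ff      share   50%, spectrum argmax 1 Hz
#>   gamma_ff          share   18%, spectrum argmax 38 Hz
#>   supragranular_fb  share   17%, spectrum argmax 5 Hz
#>   infragranular_fb  share   15%, spectrum argmax 12 Hz

rec <- run_recovery(cfg, n_trials = 200, seed = 11)
rec$scores
#> # A tibble: 4 × 7
#>   component        matched source_layer target_layer  freq connection min_cor
#>   <chr>              <int>        <dbl>        <dbl> <dbl>      <dbl>   <dbl>
#> 1 scalefree_ff           4        0.993        1.000 0.994      0.985   0.985
#> 2 gamma_ff               2        0.999        0.992 0.973      0.967   0.967
#> 3 supragranular_fb       3        0.999        1.000 0.990      0.999   0.990
#> 4 infragranular_fb       1        1.000        0.987 0.997      0.997   0.987
```

Each row matches one planted network to a fitted PARAFAC component and
reports the correlation between planted and recovered loadings per mode —
here every network is recovered with correlations above 0.96 in all modes.
(One extra component absorbs the estimation noise floor of finite-trial
iPDC; it matches no planted network.)

Characterize a component's spectrum and hierarchy on the full six-area
configuration (tensor route):

```r
cfg6 <- default_config("high")
tensors <- simulate_group_tensors(cfg6, n_animals = 8, seed = 1,
  time_grid = cfg6$time[seq(1, 326, by = 20)], freq_grid = seq(1, 100, by = 6))
fit <- fit_parafac(mean_tensor(tensors), K = 4, seed = 1)

tidy(fit_frequency_models(fit$loadings$freq[, 1], fit$axes$freq))[1:2, ]
#> # A tibble: 2 × 5
#>   family   term  estimate      mse best
#>   <chr>    <chr>    <dbl>    <dbl> <lgl>
#> 1 powerlaw c0       4.95  5.28e-10 TRUE
#> 2 powerlaw beta     0.400 5.28e-10 TRUE

component_hierarchy(fit, 1)
#> <hierarchy_result>
#>   hierarchy (bottom first): V1 < AM < LM < RL < AL < PM
```

The dominant recovered component has a power-law (scale-free) frequency
profile — the planted exponent 0.4 comes back exactly — and a functional
hierarchy with V1 at the bottom: a feedforward stream driven by the primary
visual area. `tidy()`, `glance()`, and `autoplot()` methods
are available for the fitted objects, and `run_pipeline()` orchestrates all
stages from a single (YAML-configurable, fully seeded) run configuration.

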