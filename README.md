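# spasmpipe

Quantitative analysis of spasm-related spinal recordings after sacral spinal
cord injury, for electrophysiologists and imaging labs studying spasticity:
motor-unit firing phenotypes on EMG, motor-neuron plateau properties from
current ramps, synaptic excitation/inhibition balance, reflex and spasm
quantification on root recordings, and peri-event time normalization of
interneuron calcium peak times — plus a synthetic-session generator that
emulates every modality with known ground truth so each stage has a
parameter-recovery test.

## The analyses

A spasm-evoking trial has four epochs — stimulation, pre-spasm silence,
spasm, post-spasm silence — and the package's core quantities live on that
skeleton:

* **Firing phenotypes.** Motor-unit spikes are sorted by amplitude template
  matching (a spike joins a unit only if `|a − A|/A < 0.20`); each unit's
  instantaneous frequency `f_k = 1/(t_k − t_{k−1})` is labeled
  *long_lasting* (significant negative trend), *bimodal* (Hartigan dip test
  p < 0.05, implemented from first principles with a bootstrap uniform
  null), *high* or *low* (30 Hz boundary).
* **Plateau properties.** From a triangular current ramp, the recruitment
  and de-recruitment currents give `ΔI = I_De − I_Re`; counter-clockwise
  f–I hysteresis with ΔI < 0 marks a full plateau, linear f–I with ΔI < 0 a
  partial plateau, ΔI ≥ 0 no plateau.
* **E/I balance.** `Inhibition = IPSPs/(IPSPs+EPSPs)`,
  `Excitation = EPSPs/(IPSPs+EPSPs)` from events detected in 20 s windows
  around stimulation.
* **Root responses.** Rectified-signal areas over a 10 ms monosynaptic
  window and a 50–4000 ms long-lasting window; stimulus–response threshold
  and rising-phase slope; envelope-threshold segmentation into the four
  epochs.
* **Calcium peak times.** `ΔF/F = (Ft − Fo)/Fo × 100`; the peak is the
  maximum of a 500 ms moving average; peaks map onto the canonical axis
  `[−1, 3]` (one unit interval per epoch, 100 bins each) and population
  distributions are fitted as Gaussians (acute) or two-component mixtures
  (chronic).

All user-facing functions take a data frame first and return tibbles, so
stages chain with the pipe; fitted objects have `tidy()`/`glance()` methods
and `plot_*()`/`autoplot()` companions.

## Worked example

Assess a plateau motor neuron from a synthetic ramp programmed with the
full-plateau class means (recruitment 4.0 nA, de-recruitment 2.5 nA):

```r
library(spasmpipe)
rec <- gen_ramp_recording(i_re = 4.0, i_de = 2.5, hysteresis = "ccw")
assess_plateau(rec)
#> # A tibble: 1 × 10
#>    i_re  i_de delta_i i_de_censored n_spikes hysteresis index_hz epsilon_hz
#>   <dbl> <dbl>   <dbl> <lgl>            <int> <chr>         <dbl>      <dbl>
#> 1     4   2.5    -1.5 FALSE              130 ccw            23.0      0.203
#> # i 2 more variables: mean_rate_hz <dbl>, plateau_class <chr>
```

`delta_i = −1.5` nA with counter-clockwise hysteresis classifies the cell as
a full-plateau motor neuron: it keeps firing 1.5 nA below the current that
recruited it, the signature of a persistent inward current.

Recover the chronic excitatory-interneuron peak-time distribution from a
simulated population (198 cells, the published chronic eIN sample size):

```r
seg <- epoch_segmentation(5, 6.5, 8.5, 28.5, 48.5)   # the session epochs
set.seed(1)
pop   <- gen_calcium_population(chronic_peak_specs(), seg,
                                n_cells = c(eIN = 198, iIN = 184))
peaks <- recover_peak_times(pop$traces[grepl("eIN", pop$traces$cell_id), ], seg)
fit   <- fit_peak_distribution(peaks, n_components = 2,
                               cell_class = "eIN", condition = "chronic")
fit
#> Peak-time fit: 2 component(s), n = 198, BIC = -29.3
#> # A tibble: 2 × 4
#>   component   mean     sd weight
#>       <int>  <dbl>  <dbl>  <dbl>
#> 1         1 -0.330 0.0753  0.500
#> 2         2  1.17  0.197   0.500
```

The early component peaks during stimulation (mean −0.33 on the normalized
axis) and the delayed excitatory component at the start of the spasm
(mean 1.17) — the full chain (transient synthesis, ΔF/F, 500 ms-average peak
detection, four-epoch normalization, mixture fit) recovers the programmed
distribution. `autoplot(fit)` overlays the fitted density on the peak-time
histogram; `plot_population_raster()` shows the dorsoventrally ordered
population raster.

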