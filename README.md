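# plastidyn

Light-driven chloroplast morphodynamics in the dinoflagellate
*Pyrocystis lunula*: a two-sensor viscoelastic response model with
fitting and filter analysis, plus the full 4D microscopy pipeline —
segmentation, skeleton-to-graph extraction, node tracking, mean squared
displacement and binary-mask topology — validated end to end against a
seeded synthetic-data generator.

*P. lunula* carries one net-like ("reticulated") chloroplast that
contracts toward the cytoplasmic core within minutes under strong light
and slowly re-expands under dim light, modulating how much light the
cell absorbs. The package is for quantitative biologists who want to
(i) model projected-area traces `A(t)/A0` under arbitrary
piecewise-constant light protocols and fit the response timescales, and
(ii) turn brightfield or confocal time series into area/loss traces,
spatial network representations, topology (Betti number, Euler
characteristic, genus) and node kinematics.

## The model

The relative contraction `x(t)` (projected area `A/A0 = 1 - x`) is a
Kelvin–Voigt element driven by two photosensory signals:

    tau_KV  dx/dt + x = p(t)            (tau_KV* when expanding)
    tau_i  dc_i/dt + c_i = s_i(I(t)),   i = 1, 2
    s1 = alpha1 * I                     (avoidance sensor)
    s2 = alpha2 * H(I_th - I)           (sub-threshold repressor)
    p  = clip(beta * (c1 - c2), 0, x_max)

Contraction is fast (`tau_KV` = 2.25 min), expansion slow
(`tau_KV*` = 7.2 min), signaling sits near 1.7–1.8 min, and the cap
`x_max = 0.4` encodes the cytoplasmic core area the chloroplast cannot
vacate. Above threshold the chain acts as a Butterworth-like two-pole
low-pass filter of environmental light with a −3 dB cutoff near
0.3 min⁻¹.

## Worked example

```r
library(plastidyn)

p <- lunula_params()
p
#> Two-sensor Kelvin-Voigt light-response parameters
#>   tau_kv   2.250 min   tau_kv*  7.200 min
#>   tau1     1.740 min   tau2     1.760 min
#>   alpha1  0.0333 (mW/cm2)^-1   alpha2 0.0800   beta  1.000
#>   i_th     2.800 mW/cm2       x_max   0.400

# low-pass cutoff of the light-to-area cascade
cutoff_frequency(p)
#> [1] 0.3215051     # min^-1: flicker above this is filtered out

# response to a 2.5 min pulse of strong light, then dim recovery
pulse <- light_protocol(c(7.6, 0.4), c(2.5, 10))
resp  <- simulate_response(pulse, p)
max_contraction(resp)
#> [1] 0.08481295    # the short pulse shaves ~8% off the projected area

# fit timescales to a noisy synthetic trace (5% multiplicative noise)
pr  <- light_protocol(10, 30)
tr  <- simulate_area_trace(p, pr, noise_sd = 0.05, seed = 42)
fit_trace(tr, pr, free = c("tau_kv", "tau1"), n_boot = 50)
#> Viscoelastic model fit (61 samples, RSS = 0.09674)
#>   tau_kv         1.9787  +/- 0.6052 (bootstrap)
#>   tau1           2.3249  +/- 0.6342 (bootstrap)

# order-of-magnitude diffusivity of the internal trigger signal
estimate_signal_diffusion(90, 30)$diffusion_um2_s
#> [1] 270           # um^2/s, for a 90 um cell responding within 30 s
```

The imaging side follows the same pattern: `run_synthetic()` writes a
complete synthetic dataset (confocal volumes, brightfield series,
ground-truth tables), `run_confocal()` chains attenuation correction →
segmentation → skeleton graph → tracking → MSD, and `run_fit()` fits
measured trace CSVs and summarizes a population. See the vignette
(`vignettes/chloroplast-morphodynamics.Rmd`) for the science and every
default.

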