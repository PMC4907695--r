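# lgfret

Quantitative analysis of single-molecule FRET experiments on the
SecYEG–SecA protein translocation machine, and of the ensemble and
kinetic measurements that surround them.

The SecYEG channel's *lateral gate* opens and closes as the SecA motor
ATPase cycles through its nucleotide states. A dye pair across the gate
reports this as a per-molecule FRET efficiency: E ≈ 0.76 with the gate
closed, ≈ 0.59 part-open, ≈ 0.45 open. `lgfret` implements the full
analysis chain for such data:

* **Trace analysis** — selection of valid single-donor/single-acceptor
  TIRF traces by sequential single-step photobleaching (acceptor first,
  with an anti-correlated donor rise), and the acceptor-photobleaching
  estimator `E = 1 − (I_DA − I_bck)/(I_D − I_bck)`.
* **Histogram fitting** — FRET-efficiency histograms, bin-by-bin
  replicate averaging with SEM, and a four-stage constrained
  three-Gaussian global fit across experimental conditions (high peak
  anchored on the channel-alone sample; shared positions/widths;
  unshared per-replicate amplitudes; over-constraint check), with
  orientation correction for inward-facing channels and one-way ANOVA
  errors on amplitudes.
* **Model selection** — SVD component counting against a replicate-noise
  edge, and residual comparison of k-component fits.
* **Ratchet kinetics** — Gillespie simulation of the two-state
  (closed/open) channel at the measured cycle rates
  (k_cat = 0.27 s⁻¹ ADP release, k_cleave = 11.5 s⁻¹ hydrolysis), TIRF
  sampling emulation (noise, then 200 ms window averaging), dwell-time
  maximum-likelihood rate recovery.
* **Ensemble assays** — quadratic tight-binding (ligand-depletion)
  titration fits, single/double stopped-flow exponentials with t½,
  proximity ratio, ATPase turnover conversion, Förster distance
  conversion (R₀ = 6 nm).
* **Structure metrics** — Cβ–Cβ label distances, lateral-gate widths and
  minimum side-chain distances on PDB coordinate files.
* **Synthetic data** — seeded generators for every input above, so the
  entire pipeline runs and is tested without experimental downloads.

## Worked example

Simulate a six-condition experiment (three replicates of 200 molecules
per condition), fit the staged three-Gaussian model, and check the
kinetic and binding modules:

```r
library(lgfret)

hs <- list()
conds <- lateral_gate_conditions()
for (j in seq_along(conds)) {
  reps <- sample_mixture(lateral_gate_mixture(weights = conds[[j]],
                                              seed = 100 + j))
  for (r in seq_along(reps))
    hs[[length(hs) + 1]] <- build_histogram(reps[[r]],
                                            condition = names(conds)[j],
                                            replicate = r)
}
fit_staged_mixture(hs, seed = 1)
#> Staged three-Gaussian global fit
#>       state  mean width se_mean se_width
#> 1    closed 0.755 0.227 0.00000   0.0000
#> 2 part_open 0.578 0.167 0.00857   0.0173
#> 3      open 0.390 0.240 0.02843   0.0299
#>
#> Condition amplitudes (areas):
#>          closed part_open  open
#> ADP      157.88     33.02  9.10
#> alone    199.40      0.60  0.00
#> AMPPNP    93.56     62.54 43.89
#> ATP       75.01     80.25 44.74
#> ATP_high  41.89     91.97 66.15
#> ATP_pOA   59.80     90.60 49.60
#>
#> RSS per stage: stage1=27.95, stage2=419.2, stage3=3144, stage4=419.2
```

The fixed closed peak sits at 0.755 (true 0.76); the shared part-open
and open means for this single simulated experiment land at 0.578 and
0.390 — the open component is broad and its mean scatters by ±0.04 from
one 600-event experiment to the next, which is why recovery analyses
average several simulated experiments. The amplitude table shows the
expected biology: the channel alone is purely closed, ADP keeps it
mostly closed, and ATP/substrate shift weight to the open states.

```r
traj <- simulate_two_state(two_state_model(total_time = 2000), seed = 1)
estimate_dwell_rates(traj)
#>   state       rate         se   n
#> 1  high  0.2649948 0.01165446 517
#> 2   low 11.0652141 0.48664756 517
```

Both cycle rates are recovered within two standard errors of 0.27 and
11.5 s⁻¹ from 517 complete dwells.

```r
ser <- generate_titration(titration_spec(F0 = 1, Bmax = 0.47, E0 = 10,
  KD = 23.5, concentrations = c(0, 2, 5, 10, 20, 40, 80, 160, 320, 640),
  noise_sd = 0.005, seed = 2))
fit_tight_binding(ser)
#> Tight-binding fit (E0 = 10 nM)
#>   KD   = 23.2 +/- 1.2 nM
#>   Bmax = 0.466 +/- 0.0048
#>   F0   = 1 +/- 0.0036
#>   RSS  = 0.000197
```

A 0.5% noise titration returns the dissociation constant within its
standard error.

The same stages can be driven from one seeded configuration:

```r
res <- run_pipeline(run_config(seed = 1,
                               stages = c("simulate", "histograms",
                                          "fit", "svd")))
```

which is fully reproducible (identical seeds give byte-identical JSON
output). See the vignette `vignettes/lateral-gate-smfret.Rmd` for the
models, conventions (all Gaussian widths are FWHM) and numerical choices.

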