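# SSBrecycle

Stochastic simulation and analysis of single-stranded DNA-binding protein
(SSB) recycling at the *E. coli* replisome.

During coupled DNA replication, SSB coats the ssDNA transiently exposed on
the lagging strand. Two pathways supply each new Okazaki-fragment gap:
**internal transfer** — a tetramer displaced by the lagging-strand
polymerase rebinds newly exposed ssDNA behind the helicase without
dissociating — and **external exchange** — concentration-dependent
replacement by SSB from solution, with effective rate

&nbsp;&nbsp;&nbsp;&nbsp;*k*<sub>ex</sub>(*c*) = *k*<sub>intr</sub> + *k*<sub>fac</sub>·*c*,&nbsp;&nbsp;&nbsp;&nbsp;τ = 1/*k*<sub>ex</sub>.

The balance is quantified by single-molecule FRAP: recovery traces are
fitted with the photobleach-corrected model

&nbsp;&nbsp;&nbsp;&nbsp;*I*(*t*) = *a*·e<sup>−*t*/τ<sub>b</sub></sup> + *I*₀·(1 − e<sup>−*t*/τ</sup>)

(combined single-step fit in vitro; two-step control-corrected fit in
vivo), and interpreted through the recycling metrics
*n*<sub>cycles</sub> = τ·*v*/*L*<sub>OF</sub> and the per-cycle retained
fraction e<sup>−1/*n*<sub>cycles</sub></sup>.

The package is for single-molecule biophysicists who want to re-derive
these quantities end to end on synthetic data with known ground truth, or
to drop real kymographs (TIFF + JSON sidecar) and traces (CSV) into the
same analysis chain. It provides:

- `sim` core: event-driven fork/SSB simulator with dye photophysics, FRAP
  pulses, chase mode and an in-vivo variant with finite cytosolic pools
  (`simulateReplisome()`, `simulateInVivoScene()`);
- rendering: two-channel rolling-circle kymographs and cell movies as
  16-bit TIFF (`renderKymograph()`, `renderCellMovie()`);
- trajectory analysis: spot detection, tracking, BIC-penalized
  piecewise-linear rate segmentation, focus co-localization;
- FRAP inference: phase extraction, ensemble averaging, the combined fit
  and the two-step bleach-corrected fit (`fitRecoveryEq1()`,
  `fitBleachControl()`, `bleachCorrectAndFit()`);
- Okazaki-fragment lengths two ways: truncated-exponential MLE on SSB
  inter-spot spacings and emulated alkaline-gel densitometry with
  intensity-per-length normalization;
- recycling metrics and per-concentration reports
  (`cyclesPerExchange()`, `countTetramers()`,
  `concentrationSeriesReport()`).

## Worked example

Inject a known exchange time (10 s, the 10 nM regime) into the generator,
simulate 24 replisomes with three FRAP pulses each, average the recovery
phases and fit:

```r
library(SSBrecycle)
ex <- frapInVitroExperiment(cSSB = 10, tauTrue = 10, nReplisomes = 24,
                            seed = 1)
ex$fit
#> RecoveryFit: tau = 9.62 +/- 0.084 s, I0 = 0.975, a = 0, tau_b = NA s
#>   flags: tauB_unidentifiable
```

The fitted exchange time (9.62 s) recovers the injected 10 s; the bleach
amplitude is negligible because FRAP acquisition is stroboscopic, so the
term is dropped and flagged. Feeding measured exchange times, fragment
lengths and the shared ~750 bp/s rate into the recycling report:

```r
rep <- concentrationSeriesReport(data.frame(
    concentration = c(2, 10, 20, 100), tau = c(20, 10, NA, 2.9),
    L_of = c(1.4, 1.5, 2.0, 2.8), v = 750))
rep$table
#>   concentration tau_exch L_of   v t_of n_cycles retained_fraction_per_cycle
#> 1             2     20.0  1.4 750 1.87   10.714                       0.911
#> 2            10     10.0  1.5 750 2.00    5.000                       0.819
#> 3            20       NA  2.0 750 2.67       NA                          NA
#> 4           100      2.9  2.8 750 3.73    0.777                       0.276
```

At 2 nM the same SSB pool supports ~10.7 Okazaki-fragment cycles (91%
retained per cycle); at 100 nM external exchange dominates. The 20 nM
exchange time was never measured, so that row carries an explicit missing
value. The two-fold length change (2.8/1.4) across a 100-fold
concentration range and the 35 tetramers × 35 nt ≈ 1.2 kb fork footprint
(`countTetramers(35, 1)`) come out of the same primitives.

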