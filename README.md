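# metquant

Quantitative analysis of cochlear hair-cell mechanotransduction
experiments, for auditory physiologists and the analysts who work with
them. The package implements, as tested reusable R functions, the four
measurement pipelines such studies rest on:

1. **MET current trace analysis** — cycle-averaging of sinusoidally
   stimulated patch-clamp recordings, peak-to-peak mechanoelectrical
   transducer (MET) current extraction, current–voltage curves with
   interpolated reversal potential, saturation detection for
   gradually-increased stimuli, and the resting open probability

   *P*<sub>open</sub> = (*I*<sub>hold</sub> − *I*<sub>inhib</sub>) / *I*<sub>max</sub>,

   the fraction of the maximal (excitatory-minus-inhibitory) MET current
   flowing with the bundle at rest.
2. **Hair-bundle motion and stiffness** — kymograph reslicing, per-frame
   min–max profile normalization, sub-pixel localization by Gaussian
   amplitude fitting, displacement tracking relative to the pre-stimulus
   baseline, and the apparent overall steady-state bundle stiffness
   *k* = *F*/*x*<sub>steady</sub> from fluid-jet force steps.
3. **Ratiometric confocal quantification** — MYO7A immunofluorescence
   normalized to F-actin in anisotropic Gaussian volumes (truncated at
   ±4 SD, renormalized) at five anatomical landmarks along the hair cell,
   with group summaries and percent reduction versus control.
4. **Gene-set overlap arithmetic** — differential-expression filtering at
   |log2FC| > 0.5, lfcSE < 0.5, adjusted *p* < 0.01 (strict), Venn
   partitions, overlap percentages, and curated-panel overlaps with
   direction splits; plus two-group statistics (Welch *t*, exact
   small-sample Mann–Whitney by full enumeration).

Every modality has a synthetic-data generator with exact ground truth
(Boltzmann-gated channel population on an overdamped bundle spring,
shot-noise movies, two-channel voxel stacks, gene universes with known set
structure), so each analysis stage — and the whole pipeline — is testable
without any raw recordings. See `vignettes/metquant-methods.Rmd` for the
models and the reasoning behind the defaults.

## Worked example

```r
library(metquant)

# -- resting open probability from a simulated recording ------------------
ch   <- channel_model(p_rest = 0.5)        # unadapted P_open 0.5
jet  <- fluid_jet_model()                  # 3 mN/m bundle, 0.5 ms jet lag
prot <- trace_protocol(voltage_steps = -84)  # 50 Hz sinusoid, 1 mM EGTA
rec  <- simulate_met_traces(ch, jet, prot, seed = 1)
est  <- resting_open_probability(rec$traces[[1]])
round(c(estimate = est$p_open, truth = rec$truth$p_open_rest[1]), 3)
#> estimate    truth
#>    0.139    0.135

# -- I-V curve and reversal potential -------------------------------------
iv <- build_iv_and_reversal(simulate_met_traces(ch, jet, trace_protocol(),
                                                seed = 1))
round(iv$reversal_mV, 2)
#> [1] 0.71      # model reversal potential is 0 mV

# -- bundle stiffness from a 900-frame movie ------------------------------
mv <- simulate_bundle_movie(movie_spec(), fluid_jet_model(k_true = 3),
                            list(list(amplitude = 0.3, onset = 40,
                                      duration = 120)), seed = 1)
bundle_stiffness_pipeline(mv)$stiffness[c("x_steady_nm", "k_mN_per_m")]
#> $x_steady_nm
#> [1] 100.1496   # 0.3 nN / 3 mN/m -> 100 nm
#> $k_mN_per_m
#> [1] 2.995518

# -- published overlap arithmetic from synthetic tables -------------------
sim <- simulate_gene_tables(fig_overlap_spec(), seed = 1)
ko  <- filter_degs(sim$tables$ko_p30)
panel_overlap(sim$sets$bundle_panel, ko)[c("overlap_count", "percent_int",
                                           "n_down")]
#> $overlap_count
#> [1] 16         # of a 64-gene hair-bundle panel
#> $percent_int
#> [1] 25
#> $n_down
#> [1] 14
```

The estimate/truth gap in the first block is the expected effect of
extremum noise on a cycle-averaged trace; the recovery error stays below
0.01 at default noise (see below).

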