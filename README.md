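# fmdestain

Quantification of FM-dye destaining ("unloading") kinetics at presynaptic
terminals, with a synthetic-experiment simulator that makes every stage of
the analysis verifiable against ground truth.

## The problem

FM styryl dyes (FM 5-95, FM 4-64, ...) label recycling synaptic vesicle
membranes. When terminals are field-stimulated, vesicle fusion releases the
dye and the fluorescence of each presynaptic punctum decays. Two quantities
summarize presynaptic function per imaging field:

* the **fraction of responsive puncta** — a punctum is responsive if it
  unloads more than 5% of its normalized fluorescence within 60 s of
  stimulation onset;
* the **decay time constant τ** of each responsive punctum, from a
  least-squares fit of

  ```
  F(t) = C + A · exp(−(t − t_stim) / τ),   A ≥ 0, C ≥ 0, τ > 0
  ```

  to the normalized unloading trace from stimulation onset onwards. τ is
  inversely related to release probability; puncta with τ > 360 s are
  flagged non-releasing and excluded from τ statistics.

The package implements the full measurement chain used for such
experiments: sum projection of confocal z-stacks, global-range 8-bit
conversion, rigid (translation) registration by windowed cross-correlation,
background subtraction using the frame ~3 min after stimulation onset,
punctum segmentation at an 8-bit threshold of 15 with a 0.4–10 µm² area
gate, colocalization with an eGFP dendrite outline and with immunomarker
channels (vGLUT1/GAD67/vGAT-type), per-punctum trace extraction and
normalization to the last pre-stimulation frame, responsiveness
classification (on non-background-subtracted stacks), single-exponential τ
fitting, per-field summaries, and Welch-test comparisons between
conditions. Small closed-form quantifications used alongside such
experiments (percent cell viability `[(Hoechst − Sytox⁺)/Hoechst]×100`,
spine density `(#spines/dendrite length)×10`) are included.

Because public image data for this protocol is typically unavailable, the
`sim_field` module simulates complete experiments — T×Z×Y×X stacks at 15 s
cadence (1 min baseline, 1 min stimulation, 2 min post), Gaussian puncta
with known per-punctum τ, Poisson + read noise, bounded rigid stage drift,
an eGFP dendrite channel, and marker channels — with an exhaustive truth
table, so segmentation, registration, classification and τ estimation can
all be scored against known answers.

## Worked example

```r
library(fmdestain)

cfg <- sim_config(n_z = 5, marker_positive_frac = c(synapsin1 = 0.93),
                  rng_seed = 7)
ex  <- simulate_experiment(cfg)
an  <- run_analysis(ex, condition = "control")
print(an)
#> <fm_analysis>
#> <fm_field_summary> [control]
#>   puncta: 40 total, 30 responsive / 10 unresponsive (75.0%)
#>   tau: 112.8 +/- 9.8 s (mean +/- s.e.m., n = 30; 0 excluded)
#>   marker-positive fractions: synapsin1 = 0.90

seg <- evaluate_segmentation(an, ex,
         drift_ref_yx = ex$applied_drift[an$reference_frame, ])
kin <- evaluate_kinetics(an, ex, seg$matches)
cat(sprintf("precision %.2f, recall %.2f, median relative tau error %.1f%%\n",
            seg$precision, seg$recall, 100 * kin$median_rel_tau_error))
#> precision 1.00, recall 1.00, median relative tau error 2.8%
```

The field summary reads: all 40 simulated puncta were detected and gated,
the 30 truly destaining puncta were classified responsive (75% of the
field), their fitted decay constants average 112.8 s (the simulated
population is centred on 124.8 s with a long right tail; fits are accurate
to ~3% per punctum), and 90% of in-gate puncta colocalized with the
simulated synapsin-type marker channel (36/40 were truly marker-positive at
the configured rate of 0.93).

Per-punctum tables are in `an$kinetics$results` (unloading fraction at
60 s, responsive flag, τ, fit diagnostics, inclusion flag) and
`an$rois$table` (centroid, area, gate and colocalization flags);
`run_analysis(..., out_dir = "out")` writes them as CSV with a JSON run
log. A thin command-line wrapper with `simulate` / `analyze` / `compare`
verbs is in `inst/scripts/fmdestain-cli.R`.

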