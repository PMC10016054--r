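# duetsync

Simulation and analysis of interpersonal keystroke timing in piano duet
performance.

When two pianists play together, each keystroke pair carries a signed
**asynchrony** (melody onset minus bass onset, in ms) and each player's
**inter-keystroke intervals** (IKIs) carry the trace of who adapts to
whom. `duetsync` implements the behavioral machinery of a duet paradigm
that crosses **TEMPO congruency** (the two players are cued to the same
or opposite second-phrase tempo change, 150 vs 96 bpm, inducing
anticipatory micro-asynchronies in the jointly played 120 bpm first
phrase) with **motor FAMILIARITY** (whether a player practiced the
partner's part), for researchers in sensorimotor synchronization and
joint action who need a fully testable, data-free reimplementation of
this analysis stack.

The package provides:

* **A coupled-timekeeper simulator** (`simulate_dataset()`): each player
  is a linear phase-correcting timekeeper,
  `t_i(n+1) = t_i(n) + T_i(n) − α_i (t_i(n) − t_j(n)) + η`, with an
  anticipation ramp toward the cued tempo, a familiarity-dependent
  timing-signature offset, a segregation parameter λ that reduces the
  melody player's gain under familiar–incongruent cueing, and injected
  wrong-note / wrong-tempo / outlier trials with a ground-truth log.
* **Event I/O** (`read_events()`, `write_events()`,
  `read_midi_events()`): a documented keystroke CSV dialect with strict
  validation, plus a Standard MIDI File (format 0/1) reader/writer.
* **Trial QC** (`run_qc()`): wrong-note exclusion against scores, tempo
  goodness of fit by MSE against the 400/625/500 ms IKI templates, and
  whole-trial removal of pooled 1%/99% IKI outliers.
* **Synchronization metrics** (`condition_summary()`): mean-centered
  asynchronies, accuracy (|mean asynchrony|), stability (asynchrony SD),
  and lag −1/0/+1 IKI cross-correlations with Fisher z, per participant
  and condition.
* **Inference** (`rm_anova()`, `paired_t()`, `pearson_cor()`,
  `fisher_z_compare()`): exact contrast-based repeated-measures ANOVA
  for 2-level within designs with partial eta squared
  (`η_p² = F/(F + df₂)`), Cohen's `d_z = t/√n`, and the Fisher r-to-z
  comparison of two correlations.
* **Cluster-extent Monte Carlo** (`estimate_extent_threshold()`): the
  smallest cluster size k such that smoothed Gaussian null volumes,
  thresholded voxelwise at p < 0.001, produce a cluster ≥ k in fewer
  than 5% of iterations — whole-volume FWE control for statistical maps.

The numbered scripts in `analysis/` run these stages as a workflow
(simulate → QC → metrics → inference → MC threshold), writing their
tables under `results/`.

## Worked example

```r
library(duetsync)

params <- dyad_params(seed = 42)
design <- design_spec(n_pairs = 10, trials_per_condition = 32)
sim <- simulate_dataset(params, design)

qc <- run_qc(sim$events, sim$meta)
print(qc)
#> Duet trial QC: 950 of 1280 trials retained
#>   wrong note: 61 | wrong tempo: 34 | technical: 0 | IKI outlier: 237
#>   pooled IKI bounds: [466.3, 533.9] ms (n = 14244)
#>  condition retained
#>         FC      226
#>         FI      235
#>         UC      245
#>         UI      244

cs <- condition_summary(qc$events, sim$meta)
round(tapply(cs$mean_abs_async, cs$condition, mean), 2)
#>   FC   FI   UC   UI
#> 3.86 9.28 3.33 5.89

cs$familiarity <- substr(cs$condition, 1, 1)
cs$tempo <- substr(cs$condition, 2, 2)
rm_anova(cs, "mean_abs_async", c("familiarity", "tempo"), "participant")
#> Repeated-measures ANOVA (n = 20)
#>             effect     F df1 df2     p eta_p2
#>        familiarity  5.46   1  19 0.031   0.22
#>              tempo 24.03   1  19 0.000   0.56
#>  familiarity:tempo  3.04   1  19 0.098   0.14
```

Reading the output: QC retained 950 of 1,280 simulated trials (the
pooled 1%/99% IKI trim is the largest filter, as whole trials are
dropped for any outlying interval). Mean absolute asynchronies are
higher in the incongruent conditions (FI, UI) than the congruent ones —
the anticipation-drift effect — and the repeated-measures ANOVA across
the 20 participants shows the corresponding TEMPO main effect
(F(1,19) = 24.0, η_p² = 0.56) with this run's familiarity effect
reflecting the simulator's familiar-trial timing signatures.

The methods vignette (`vignettes/duet-synchronization.Rmd`) documents
the generative model, every tunable parameter, the numerical
conventions, and what the simulator does and does not emulate.

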