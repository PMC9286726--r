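# trinetdyn

Dynamic time-varying interaction analysis for the brain's triple network —
salience (SN), left/right frontoparietal (LFPN, RFPN) and default mode
(DMN) — from per-subject component time series. The package is aimed at
researchers studying cognitive-control network dynamics in clinical
cohorts (e.g. ADHD treatment studies) who need a tested, reusable
implementation of the standard windowed-connectivity brain-state pipeline
together with a ground-truth synthetic generator to validate it.

## What it computes

For each subject's T × 4 time series:

- **Tapered sliding-window correlations** — weighted Pearson correlations
  under an exponentially decaying causal taper
  `w_t ∝ exp(-(L-1-t)/θ)`, Fisher-z transformed:
  `f(cc) = ½ ln((1+cc)/(1−cc))`.
- **Latent brain states** — group-wise consensus k-means on the pooled
  6-dimensional Fisher-z window vectors, with the number of states chosen
  by majority vote of cluster-validity indices.
- **Dwell time** — mean contiguous run length per state (windows and
  seconds) and the subject's unweighted mean over visited states.
- **Network Interaction Index** —
  `NII = ½{f(cc_SN,LFPN) + f(cc_SN,RFPN)} − f(cc_SN,DMN)` per window:
  positive when the SN engages the FPN while disengaging from the DMN.
  Per-subject mean, variability (SD), per-state means and the static
  (full-session) NII.
- **Inference** — paired and Welch t-tests with Cohen's d and Bonferroni
  correction, brain–behavior Pearson correlations, OLS prediction of
  treatment response, and CART classification of group pairs under
  leave-one-out cross-validation with an exact binomial test against the
  no-information rate.
- **Synthetic cohorts** — hidden-Markov generators with state covariances
  whose NII is known in closed form, plus linearly coupled behavioral
  scores, so every stage can be validated against ground truth.

See `vignettes/triple-network-dynamics.Rmd` for the model, parameter
rationale, and the limits of what the synthetic world establishes.

## Worked example

```r
library(trinetdyn)

# closed-form NII of a constructed state
s <- make_state_covariance(0.5, -0.5)
s$true_nii
#> [1] 1.098612       # = atanh(0.5) - atanh(-0.5)

# three simulated groups, full pipeline
cfg <- pipeline_config(seed = 7, n_mph = 12, n_placebo = 12, n_td = 12,
                       T = 200, window_length = 10, window_theta = 10/3,
                       k_range = 2:4, n_resamples = 20)
res <- run_pipeline(cfg, out_dir = "demo_out", verbose = FALSE)

res$comparisons[["mean_dwell_s: ADHD-MPH vs ADHD-Placebo"]]
#> mean_dwell_s: ADHD-MPH vs ADHD-Placebo: t(11) = 2.558, p = 0.02661
#>   (Bonferroni 0.07982), d = 0.738
res$comparisons[["nii_sd: ADHD-Placebo vs TD"]]
#> nii_sd: ADHD-Placebo vs TD: t(21.38) = -6.570, p = 1.519e-06
#>   (Bonferroni 4.558e-06), d = -2.682
res$classification[[2]]
#> ADHD-Placebo vs TD: LOOCV accuracy 87.5% (NIR 50.0%, p vs NIR = 0.0001386)
```

The simulated placebo group dwells longer in its states than the treated
group (positive paired t on mean dwell) and shows lower NII variability
than controls (negative Welch t), and the two groups separate well above
chance — the qualitative pattern the generator plants. At this demo scale
the validity-index vote tends to overestimate the number of states for the
weakly separated default covariances (`res$partitions$TD$k_selected`);
the acceptance suite demonstrates reliable state-count recovery with
well-separated states at n = 20, T = 300.

Per-stage artifacts (time series TSVs, manifest CSV, ground-truth JSON,
windowed z matrices, partition JSON, metrics/comparisons CSV,
classification/regression JSON) land under `demo_out/`, each with a
provenance header. The same stages are scriptable via the CLI:

```sh
Rscript inst/cli/trinetdyn simulate --seed 1 --out sim
Rscript inst/cli/trinetdyn windows --in sim --out win --length 10 --theta 3.3
Rscript inst/cli/trinetdyn run-all --seed 1 --out full_run
```

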