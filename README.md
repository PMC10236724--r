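# rxseq — clustering biologic DMARD prescription sequences

Many rheumatoid arthritis (RA) patients cycle through several biologic or
targeted-synthetic DMARDs (b/tsDMARDs) before their disease is controlled.
The *order* of classes tried — persisting on a TNF inhibitor, switching to
and remaining on abatacept, staying on rituximab, cycling through many
classes — is a treatment-history phenotype in its own right. rxseq is an R
package for deriving and analysing these phenotypes from EHR-style data:

1. **Sequence construction** — apply cohort-inclusion filters (first
   b/tsDMARD on/after a study start, an RA ICD code ≥ 90 days prior, two
   prescriptions ≥ 90 days apart) and convert prescription events into
   per-patient drug-class sequences over 91-day windows with
   zero/single/multiple-encounter rules (within a window,
   `A → A → C → C` collapses to `A → C`).
2. **Mixture Markov clustering** — model sequences as draws from a
   K-component mixture of first-order Markov chains over the 5-class state
   space {TNFi, CTLA4-Ig, IL6R, JAKi, anti-CD20},

   P(s) = Σₖ πₖ αₖ(s₁) Πₜ Pₖ(sₜ₋₁, sₜ),

   fitted by EM with random restarts; patients are assigned to their
   highest-posterior cluster.
3. **Model selection** — AIC (2p − 2 log L, with
   p = (K−1) + K(S−1) + KS(S−1)) across K = 2..5, with the
   Calinski-Harabasz index of yearly class-encounter rates as a
   concordance check.
4. **Cluster profiling** — composition summaries, yearly mean CDAI
   trajectories (years −1..6 from the first biologic), one-way ANOVA and
   Kruskal–Wallis comparisons across clusters.

A synthetic-cohort generator (`simulate_cohort()`, preset
`"paper_default"`) emulates an EHR extract from a known ground-truth
mixture — drug names, dates, duplicate prescriptions, multi-drug windows,
gaps, RA diagnosis codes, CDAI visits — so the full pipeline is testable
without protected health data.

## Worked example

```r
library(rxseq)

cfg    <- preset_scenario("paper_default", seed = 42)   # 2000 patients
cohort <- simulate_cohort(cfg)
built  <- build_all(cohort$prescriptions, cohort$diagnoses)
built$summary
#> n_patients: 2000, n_prescriptions: 33865, n_unique_sequences: 566

sel <- select_k(built$sequences, 2:5, n_restarts = 10, seed = 1)
sel
#>  K log_likelihood   p      aic ch_score selected ch_agrees
#>  2      -7172.015  49 14442.03 2018.283    FALSE      TRUE
#>  3      -6985.735  74 14119.47 3159.752    FALSE      TRUE
#>  4      -6936.924  99 14071.85 3232.417     TRUE      TRUE
#>  5      -6920.529 124 14089.06 2708.870    FALSE      TRUE
#> selected K = 4 (AIC), C-H score agrees
```

AIC bottoms out at K = 4 and the C-H score peaks there too: four
treatment-trajectory clusters. Assign and profile:

```r
fit <- sel$fits[[as.character(sel$selected_k)]]
asg <- posterior_assign(built$sequences, fit$params)
for (p in profile_clusters(built$sequences, asg))
  cat(sprintf("cluster %d: n=%4d share=%.3f single-class=%.2f\n",
              p$cluster, p$n, p$share, p$single_class_frac))
#> cluster 1: n= 179 share=0.089 single-class=0.17
#> cluster 2: n=1328 share=0.664 single-class=0.94
#> cluster 3: n= 224 share=0.112 single-class=0.03
#> cluster 4: n= 269 share=0.135 single-class=0.54
```

Cluster 2 here is the TNFi-persister group (66% of the cohort, 94% never
leave one class), cluster 1 the TNFi→abatacept switchers, cluster 3 the
multi-class/tocilizumab cyclers, cluster 4 the rituximab-dominant group —
recovering the generator's mixing proportions (0.65 / 0.08 / 0.13 / 0.14);
adjusted Rand index against the generating labels is 0.93. CDAI
trajectories per cluster:

```r
head(cdai_yearly_means(cohort$visits, built$sequences, asg), 4)
#>   cluster year mean_cdai   n
#>         1   -1  23.02159 179
#>         1    0  20.48086 179
#>         1    1  17.55346 179
#>         1    2  15.80317 179
```

(the switcher cluster's disease activity falls after the first biologic).

## End-to-end pipeline and CLI

```r
run_pipeline(pipeline_config(
  simulate = list(preset = "paper_default", n_patients = 500),
  k_candidates = 2:5, n_restarts = 10, seed = 3, out_dir = "out"))
```

writes `sequences.csv`, `selection.csv`, `model.json`, `assignments.csv`,
`profiles.json`, `cdai_trajectories.csv`, `tests.csv` and a reproducible
`manifest.json`. The same stages are scriptable:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/rxseq.R", package="rxseq"))') \
    simulate --preset paper_default --n 2000 --seed 1 --out data/
```

with subcommands `simulate`, `build-sequences`, `fit`, `assign`,
`select-k`, `profile`, `run`.

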