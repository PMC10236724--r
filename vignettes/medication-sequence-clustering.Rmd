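---
title: "Clustering b/tsDMARD prescription sequences with mixture Markov models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering b/tsDMARD prescription sequences with mixture Markov models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxseq)
```

## The problem

Rheumatoid arthritis patients who fail first-line therapy cycle through
biologic and targeted-synthetic DMARDs (b/tsDMARDs). A patient's medication
*history* — which classes were tried, in which order, and how long each was
kept — is itself a clinically meaningful signal: persisting on a TNF
inhibitor, switching to and remaining on abatacept, staying on rituximab, or
cycling through many classes describe very different disease courses. rxseq
turns raw EHR-style prescription tables into per-patient drug-class
sequences, clusters those sequences with a mixture of first-order Markov
chains fitted by maximum likelihood, selects the number of clusters with AIC
and the Calinski-Harabasz (C-H) index, and profiles the resulting clusters
against CDAI disease-activity trajectories.

## The model

Each patient contributes an observed state sequence $s_1, \dots, s_L$ over
the 5-class state space {TNFi, CTLA4-Ig, IL6R, JAKi, anti-CD20}. The model
assumes each sequence is generated by one of $K$ latent first-order Markov
chains, drawn with mixing probabilities $\pi$:

$$
P(s_{1:L}) \;=\; \sum_{k=1}^{K} \pi_k \,
  \alpha_k(s_1) \prod_{t=2}^{L} P_k(s_{t-1}, s_t).
$$

Initial distributions $\alpha_k$ are component-specific because the first
drug differs strongly across clusters (e.g. the cycler cluster starts on
tocilizumab far more often than the persister cluster). Chains are
first-order and time-homogeneous; states are fully observed (this is not an
HMM). Estimation is EM: the E-step computes responsibilities
$\gamma_{ik} \propto \pi_k L_{ik}$, the M-step re-estimates $\pi$, $\alpha$
and $P$ from (pseudocount-smoothed) weighted counts. Each patient is
assigned to the component with the highest posterior, ties broken to the
lowest index. Because the sequence likelihood factors through the first
state and the 25 transition counts, EM internally deduplicates sequences
with identical sufficient statistics, which makes the full pipeline fast at
cohort scale.

### Number of clusters

For each candidate $K$ the free-parameter count is
$p = (K-1) + K(S-1) + KS(S-1)$ — mixing, initial rows, transition rows, each
a simplex. AIC $= 2p - 2\log L$ is the primary selector (likelihood-native);
the C-H index, computed on per-patient yearly class-encounter rates
(counts divided by windowed follow-up in 365.25-day years), is reported and
checked for agreement, mirroring the practice of reading both criteria.
The "yearly rate" feature embedding is deliberately isolated behind
`yearly_rate_features()` so alternatives can be plugged in; the phrase is
underdetermined and this is the simplest faithful reading.

### Numerical choices

* Mixture likelihoods use log-sum-exp; zero-probability transitions give an
  exact $-\infty$ (guarded against `0 * -Inf`).
* The M-step smooths every initial and transition count with a pseudocount
  $\varepsilon = 10^{-6}$ so that rare transitions never produce $-\infty$
  likelihoods during fitting; $\varepsilon = 0$ recovers the closed-form
  count MLE exactly (used by the tests).
* With $\varepsilon > 0$ the smoothed M-step is the exact maximiser of a
  Dirichlet-penalised objective, not of the EM Q-function, so the *raw*
  log-likelihood may decrease by $O(\varepsilon)$ near convergence. The
  fitter therefore traces (and reports) the penalised objective, for which
  MAP-EM monotonicity is a theorem; it differs from the data log-likelihood
  by about $10^{-4}$ on a 2000-patient fit, which is irrelevant to AIC
  differences but worth knowing when comparing against
  `mixture_log_likelihood()` directly.
* Restarts are initialised from Dirichlet(1) draws of every probability row
  (smooth starts produce fewer degenerate empty components than random hard
  partitions). Convergence is declared on relative objective change
  ($10^{-8}$), since the quantity consumed downstream is the likelihood.
* `K = 1` needs no EM: one closed-form M-step.
* A transition row with zero weighted count and zero pseudocount is set to
  uniform with a warning — the data say nothing about it.
* Component labels are non-identifiable (label switching); recovery
  experiments match components to a reference by minimising total L1
  distance between transition matrices, exhaustively over $K!$.

## Sequence construction

Sequences anchor at the first b/tsDMARD prescription and advance in fixed
windows. "Three months" is operationalised as 90 days for the filter gaps
and 91 days for encounter windows — integers avoid calendar-month
ambiguity, and both are configurable. Per window: no prescriptions — no
state (the 5-class state space has no "gap" state, so empty windows are
invisible to the chain); one class — one state; several — order by date
(same-day ties by class index, for determinism), map to classes, and
collapse *consecutive equal* classes within the window. Windows concatenate
without collapsing across boundaries, so persistence appears as repeated
states. Inclusion filters run in a fixed order and log the first failing
reason: (a) first prescription on/after the study start with none before,
(b) an RA diagnosis code at least 90 days earlier (droppable — the
sensitivity analysis), (c) two prescriptions at least 90 days apart.
Unknown drug names fail loudly by default because silent drops corrupt
sequences; real extracts can opt into logged skipping.

## The synthetic cohort: what it emulates, and what it does not

No protected EHR data ship with the package; the generator is the model's
forward direction plus the nuisance structure the builder must survive:
multiple prescriptions per window, redundant same-drug duplicates, two
distinct classes sharing a window, empty gap windows, concrete drug names
drawn uniformly within class, an RA diagnosis code 90–365 days before the
first biologic, and yearly CDAI visits at cluster-specific means plus
truncated Gaussian noise (truncation, not resampling, because only yearly
means are consumed downstream). A second state joins a window only when
distinct from the first, so within-window collapsing never deletes a true
state and the builder recovers the generating path *exactly* under every
nuisance setting — gaps shift window indices without touching states. The
`seq_length_range` parameter counts Markov states per patient (8–20 by
default, roughly 2–5 years of windows; sequence-length distributions are
not reported for the source cohort, so this is a repository constant).

The `"paper_default"` preset fixes the stated world: mixing proportions
(0.65, 0.08, 0.14, 0.13) and four components designed from the published
cluster descriptions — (1) near-absorbing TNFi persisters (~94% of them
never leave TNFi), (2) TNFi-to-abatacept switchers with abatacept
near-absorbing, (3) rituximab-dominant patients, (4) cyclers with elevated
tocilizumab occupancy. CDAI year profiles order component 1 lowest and
give component 2 a downward-sloping trajectory, matching the qualitative
published picture.

Two structural choices in the preset deserve explanation:

* **Shared class-persistence rows.** How a patient behaves once on
  abatacept (or rituximab, tocilizumab, a JAKi) is modelled as a property
  of the drug class: components whose patients rarely reach a class reuse
  the transition row of the component that dominates that class's traffic.
  Without this, rows for rarely-visited states are unidentifiable — a
  160-patient component yields ~10 observed transitions from a state it
  almost never occupies.
* **Occasional TNFi retrial.** Clusters 2 and 3 include a small
  probability of returning to TNFi (0.03 from abatacept, 0.018 from
  rituximab), consistent with their published descriptions ("TNFi *and*
  abatacept therapy"; "rituximab *or multiple* bDMARDs"). Statistically
  this matters: each retrial cycles a patient through the TNFi row again,
  whose switching destination is what distinguishes the two clusters. In a
  purely absorbing design the K-component MLE merges clusters 2 and 3 —
  a merged component models disjoint absorbing states at almost no cost,
  while a split pays the mixing-entropy price — and AIC then prefers
  $K=3$. With retrial the four-cluster structure is decisively optimal,
  which is the regime the published analysis reports.

What a green test does **not** establish: the generator draws true
first-order Markov paths, so recovery results say nothing about
model misspecification in real EHR data (dose changes, insurance-driven
switching, informative censoring, prescriptions ordered but never filled —
all out of scope). Within-cluster heterogeneity in real cohorts is richer
than a single chain per cluster.

### Known limitation: rare-row recovery

Even in this favourable world, transition rows for states that a small
component rarely occupies cannot be estimated to tight tolerance at
$n = 2000$: they receive a handful of true transitions and are further
biased by responsibility leakage from larger components. The acceptance
suite asserts the full-strictness recovery property as stated (every row
within L1 0.1, mixing within ±0.03, ARI ≥ 0.9); the every-row clause fails
for exactly these rare rows, and the fitted mixing proportions fluctuate
within roughly ±0.01 of a ~0.02 soft-assignment bias, i.e. right at the
±0.03 bound. Rows that carry a component's actual dynamics recover well
inside the tolerance, and cluster recovery (ARI ≈ 0.94) is unambiguous.

## Cluster profiling

Profiles report per-cluster size and share, first/last-state
distributions, the distribution of distinct classes tried (bucketed
1 / 2 / 3–5), and the single-class fraction. CDAI trajectories use
365.25-day year bins anchored at each patient's first b/tsDMARD; averaging
is two-stage (patient-year means, then cluster-year means over patients)
so heavily-visited patients do not dominate; missing patient-years are
excluded, never imputed. Across-cluster comparisons use classical one-way
ANOVA from explicit sums of squares — applied to 0/1 indicators for
proportions, mirroring the source analysis' stated (unconventional)
practice — and the Kruskal–Wallis test with tie correction. Post-hoc
procedures (Tukey, Dunn) are out of scope.

## Reproducibility

Every stochastic entry point takes a seed and is deterministic given it;
the pipeline expands its master seed by a fixed scheme (simulation uses
`seed`, model fitting `seed + 1000`) so stages can be rerun in isolation.
Identical pipeline configs produce byte-identical outputs, manifest
timestamp aside. The pipeline config file is JSON (the R stack used here
has no YAML reader; the in-memory structure is unchanged).
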