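# vocrank

Grunt-call acoustics and dominance-hierarchy analysis for hierarchically
organised mammal herds.

Many group-living mammals — peccaries, suids, several primates — emit short,
noisy grunt-like calls around agonistic interactions. Two questions recur in
studies of such systems: *does the herd have a linear dominance hierarchy*,
and *do the grunts carry information* about the caller's rank, identity or
sex? `vocrank` packages the full analytical chain for both questions so it
can be run end to end on interaction logs and call recordings, or on fully
synthetic herds for method validation:

* **Dominance inference** from winner/loser records: Landau's linearity
  index *h* = 12/(N³−N) · Σₐ (Vₐ − (N−1)/2)², its correction *h′* for
  unknown relationships (random completion of undirected dyads, with a
  10,000-randomisation significance test), the I&SI rank order (minimise
  the number of inconsistencies *I*, then their total strength *SI*), and
  the directional consistency index DCI = Σ(H−L)/Σ(H+L).
* **Acoustic measurement** of grunt elements in 48 kHz mono WAV recordings:
  two-threshold (−9/−10 dB) hysteresis detection with a 50 ms hold time on
  a 1024-point/87.5%-overlap Hamming spectrogram, then twelve parameters
  per element — duration plus peak/min/max frequency, bandwidth and
  spectral entropy at the call centre and as frame means, and an
  autocorrelation harmonic-to-noise ratio at the centre.
* **Preprocessing** for multivariate analysis: per-variable Yeo-Johnson
  transformation (maximum-likelihood λ), robust Mahalanobis/MCD outlier
  removal at the χ²₀.₉₇₅ cutoff, and stepwise variance-inflation-factor
  elimination (drop the higher-VIF member of the most correlated pair until
  all VIF ≤ 2).
* **Discriminant analysis** of caller identity and sex: Fisher DFA with
  Wilks' Λ = Π 1/(1+λₖ), balanced subsampling, held-out cross-validation,
  exact binomial tests against chance, and permuted DFA (pDFA) with
  restricted permutation for identity (within sex) and a nested design for
  sex (whole individuals reassigned, controlling for caller).
* **Conflict statistics**: per-individual grunt counts, Spearman rank
  correlations, χ² goodness-of-fit on conflict outcomes, grunt-to-outcome
  latency summaries, and a per-individual acoustic report table.
* **A synthetic-herd generator** producing interaction logs, per-call
  feature tables and grunt waveforms with known hierarchy steepness,
  rank-dependent grunt rates and rank-dependent acoustic signatures — every
  generator parameter is recoverable by the downstream estimators, which is
  how the package tests itself.

## Worked example

A complete synthetic study — 19 animals (9 M / 10 F), 1,880 agonistic
interactions, 50 calls per caller (the top-ranked animal never grunts) —
runs in a few seconds:

```r
library(vocrank)
res <- run_pipeline(pipeline_config(seed = 11), out_dir = "run1")
cat(readLines("run1/summary.txt"), sep = "\n")
```

```
== vocrank pipeline summary ==
[dominance] h' = 1.000 (p = 9.999e-05), DCI = 0.900, I&SI: I = 0, SI = 0
[preprocess] 170 outliers removed; retained: duration_s, peak_freq_mean_hz, min_freq_centre_hz, bandwidth_centre_hz, entropy_centre, hnr_centre_db
[dfa] Wilks Lambda = 0.427 (chi2 = 402.1, df = 102, p = 3.05e-37); CV accuracy = 17.2% (chance 5.6%, binomial p = 7.91e-11)
[dfa] first two functions explain 74% of variance
[pdfa identity] original 15.2% vs permuted 6.7%, p = 0.009901
[pdfa sex] original 61.6% vs permuted 56.0%, p = 0.07843
[conflict] grunts ended 569 conflicts vs 16 continued (chi2 = 522.75, df = 1, p = 1.07e-115)
[rank] Spearman rank~grunt count: r_s = 0.99 (p = 1.45e-16); rank~mean min freq: r_s = 0.84 (p = 1.49e-05)
```

Reading the output: the simulated herd is perfectly linear (*h′* = 1) and
almost fully unidirectional (DCI = 0.90); grunts end conflicts far more
often than aggression continues (χ² = 522.75, df = 1); callers are
individually distinguishable well above the 5.6% chance level for 18
callers (cross-validated 17.2%, pDFA original 15.2% vs 6.7% permuted), while
the sexes are not reliably separable once caller identity is controlled
(nested pDFA p = 0.078). Every intermediate (dominance matrix, rank order,
feature tables, VIF trace, DFA coefficients, confusion matrix,
per-individual report) is written to the run directory as CSV, and
`run_log.txt` records the package version and every stage seed, so a run
can be reproduced exactly.

The stages are plain functions if you prefer to drive them directly —
`build_matrix()`, `landau_h_prime()`, `isi_rank()`, `dci()`,
`detect_elements()`, `measure_element()`, `preprocess_features()`,
`fit_dfa()`, `pdfa_identity()`, `pdfa_sex()`, `spearman()`, `chisq_gof()` —
and a thin command-line front end with per-stage subcommands lives at
`inst/scripts/vocrank.R`.

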