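---
title: "Methods: grunt calls, dominance hierarchies, and permuted discriminant analysis"
author: "vocrank"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grunt calls, dominance hierarchies, and permuted discriminant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocrank)
```

`vocrank` analyses the social function of grunt-like calls in herds with a
dominance hierarchy. This vignette is the package's account of its methods:
the statistical models, their assumptions, the tunable parameters, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Dominance hierarchy

The raw material is a log of agonistic interactions in which each decided
conflict names a winner and a loser (conflicts without a clear outcome are
excluded before any index is computed). `build_matrix()` tabulates these
into the win-count matrix $X$, with $X_{ij}$ the number of times $i$ beat
$j$.

**Linearity.** Landau's index summarises how close the dominance relations
are to a strict linear order:

$$h = \frac{12}{N^3 - N} \sum_a \left(V_a - \frac{N-1}{2}\right)^2,$$

where $V_a$ is the number of individuals that $a$ dominates, the direction
of each dyad being the strict majority of its wins. $h = 1$ for a perfect
linear order and $h = 0$ when every animal dominates exactly half the
others (e.g. a circular triad). Real datasets contain dyads that never
interacted ("unknown relationships") or are exactly tied; the corrected
index $h'$ assigns every such undirected dyad a random direction and
averages $h$ over `n_random` completions (default 10,000). Its significance
is the proportion of *fully random* tournaments of the same size whose $h$
reaches the observed $h'$, reported as $(\mathrm{count}+1)/(n+1)$ so a
p-value is never exactly zero. Exactly tied dyads are treated like unknown
ones in the randomisation: a tie carries no directional information, and
this keeps $h'$ a smooth extension of $h$ (when no dyad is undirected,
$h' = h$ identically).

**Rank order.** `isi_rank()` seeks the order minimising first the number of
inconsistencies $I$ (dyads whose majority direction points up the order)
and then their total strength $SI$ (the summed rank distances of the
inconsistent dyads). Finding the exact optimum is combinatorial; the
package uses pairwise-swap hill climbing from a deterministic start (the
order of descending win proportion), restarted from random perturbations
(`n_tries`, default 20). On every 4- and 6-individual instance in the test
suite the heuristic attains the exhaustive-search optimum; on larger herds
optimality is not guaranteed, which is inherent to the method, and the
result flags when several inspected orders tie. One point worth noting:
a *single* flipped adjacent dyad does not create an inconsistency in the
optimal order — swapping the two animals restores transitivity — so
irreducible inconsistencies require a cycle, and the tests exercise exactly
that case.

**Directionality.** The DCI is $\sum_d (H_d - L_d) / \sum_d (H_d + L_d)$
over dyads with at least one decided interaction, where $H_d$ and $L_d$
count the more and less frequent direction: 1 means fully unidirectional
submission, 0 complete bidirectional exchange.

## Acoustic measurement

Analysis settings follow common automatic-measurement practice for short
noisy calls at 48 kHz: 1024-point FFT, 87.5% overlap, Hamming window,
giving 46.875 Hz frequency resolution and a 2.67 ms time step. Recordings
are normalised to −1 dBFS and band-passed to 30 Hz–8 kHz before
measurement. (A literal "above 30 kHz and below 8 kHz" filter band is
impossible at a 48 kHz sampling rate; the retained 30 Hz–8 kHz band is the
reading consistent with grunt energy, whose minimum frequencies sit around
330–450 Hz.) The band-pass is a zero-phase third-order Butterworth
high-pass combined with a 511-tap linear-phase FIR low-pass applied with
group-delay compensation.

**Element detection** runs on an RMS envelope computed on 128-sample
(2.67 ms) frames, in dB relative to the recording's own peak. Two-threshold
hysteresis opens an element above −9 dB and closes it below −10 dB; gaps
shorter than the 50 ms hold time are merged. The envelope frames are one
*time step* long, not one FFT window: a 1024-sample RMS window would smear
a sharp onset by roughly 8 ms, while hop-length frames keep measured
durations within two time steps (±5.3 ms) of truth on constructed bursts —
the resolution bound the tests enforce.

**Per-element parameters.** Within a detected segment, per-frame magnitude
spectra give: peak frequency (bin of maximum magnitude); minimum and
maximum frequency (lowest/highest bin within −9 dB of that frame's peak
bin — the same threshold that defines the element, reused as the spectral
extent criterion); bandwidth (their difference); and spectral entropy
(Shannon entropy of the normalised power spectrum divided by
$\log(\text{bins})$, 0 for a pure tone and 1 for flat noise). Each is
reported at the *centre* (the frame nearest the segment midpoint — grunts
have little frequency modulation, so the centre frame is representative)
and as the *mean* over frames; whether a published "mean" is a frame
average or a single whole-call measurement is often ambiguous in tool
documentation, and frame averaging is adopted here. The
harmonic-to-noise ratio is measured only at the centre:
$\mathrm{HNR} = 10\log_{10}(r/(1-r))$ with $r$ the highest non-zero-lag
normalised autocorrelation peak over lags corresponding to 50–1500 Hz in a
4096-sample window. For a periodic signal in additive noise, $r$ estimates
the periodic power fraction, so 1% relative noise power gives ≈20 dB — the
analytic anchor used in the tests. $r$ is clamped to $[10^{-6},
1-10^{-6}]$, capping the report at ±60 dB. All frequency-domain parameters
are invariant under uniform gain, and every row satisfies
min ≤ peak ≤ max.

Fundamental-frequency tracking and formant measurement are deliberately out
of scope: grunts are atonal enough that an F0 contour is not reliably
defined, and formant interpretation requires vocal-tract information the
package does not model.

## Preprocessing

The pipeline order is fixed and logged: Yeo-Johnson transform → outlier
removal → collinearity elimination.

* **Yeo-Johnson.** The standard piecewise power transform defined on all
  reals; $\lambda$ is fitted per variable by profile maximum likelihood
  (golden-section search on $[-5, 5]$) on the full table before any row is
  removed, so the transform does not depend on which rows are later
  flagged. $\lambda = 1$ is the identity; mirroring a sample maps
  $\lambda \mapsto 2 - \lambda$. The transform is exactly invertible
  (round-trip error below $10^{-9}$ in the tests).
* **Outliers.** Rows are flagged when their squared robust Mahalanobis
  distance — from a minimum-covariance-determinant location/scatter
  (`MASS::cov.rob`) — exceeds $\chi^2_{0.975}$ on $d$ degrees of freedom.
  This is a documented stand-in for compositional-data outlier tools whose
  internals are not published; the flagging quantile and the MCD coverage
  fraction are both exposed. The coverage default is 0.75: on clean
  multivariate normal data the flag rate stays near the nominal 2.5%,
  while the maximal-breakdown 0.5 coverage flags the tails of a
  multi-individual mixture very aggressively (one-third of all calls in
  the default synthetic herd). Call tables *are* mixtures across callers,
  so a screening step should not treat caller-level spread as
  contamination wholesale.
* **Collinearity.** Variance inflation factors $1/(1-R^2_j)$; while any
  VIF exceeds 2, the pair of variables with maximum |Pearson correlation|
  is found and its higher-VIF member dropped, ties broken by column order.
  The loop terminates in at most $p-1$ steps and the trace records every
  drop. On the twelve measured parameters the centre/mean pairs are nearly
  collinear by construction, so roughly half the columns are eliminated,
  mirroring the five-of-twelve retention typical of such tables.

## Discriminant analysis and permutation tests

`fit_dfa()` is a Fisher discriminant analysis built from the pooled
within-class scatter $W$ and between-class scatter $B$: axes are the
eigenvectors of $W^{-1}B$ (computed by symmetric whitening), scaled to unit
pooled within-class variance, ordered by eigenvalue, and sign-fixed so each
axis's largest-magnitude standardized coefficient is positive — this makes
coefficient tables reproducible. Wilks' $\Lambda = \prod_k 1/(1+\lambda_k)$
with Bartlett's $\chi^2$ approximation provides the multivariate test.
Classification assigns a call to the nearest class mean in discriminant
space with equal priors (all designs here are balanced); a near-singular
$W$ receives a ridge of $10^{-8}\,\overline{\mathrm{diag}(W)}$ and the fit
records it.

Calls are repeated measures of their caller, so conventional DFA p-values
are not valid for caller- or sex-level questions. The permuted DFA wraps
the whole procedure in a permutation test:

* **Identity** (`pdfa_identity`): the statistic is the mean held-out
  accuracy over `n_selections` balanced subsamples (default 37 training
  calls per caller). The null repeats the *identical* procedure after
  permuting caller labels across calls within each level of the
  restriction factor (sex by default). Because each permutation redraws
  both the labels and the balanced selections, the original and permuted
  statistics are exchangeable under the null — without this, the original
  (a mean of many selections) would be more concentrated than the permuted
  values and the test would be badly miscalibrated. The test suite checks
  the type-I error at $\alpha = 0.05$ over 200 null simulations. Note that
  restricted permutation deliberately *retains* any sex-level signal in
  the null, so the permuted accuracy can sit above naive $1/g$ chance;
  that is what "controlling for sex" means.
* **Sex** (`pdfa_sex`): a nested design — calls never leave their caller;
  the null reassigns whole individuals to sexes. Each statistic draws 8
  individuals per sex and 36 calls per drawn individual by default.
* p-values are always $(\mathrm{count} \ge \mathrm{obs} + 1)/(n+1)$.
  Published descriptions of such analyses sometimes mix 100 and 1000
  permutations; the default here is 1000, configurable.

A one-sided exact binomial test (`binomial_vs_chance`) compares held-out
accuracy with the $1/g$ chance level (5.6% for 18 callers).

## The synthetic herd generator

The generator exists so every estimator above can be validated by parameter
recovery. Its defaults describe one fixed study condition: 19 adults (9
males, 10 females), 1,880 interactions, 50 calls per caller, with the
top-ranked animal never calling.

* **Conflicts.** Dyads are sampled uniformly; the higher-ranked member
  wins with probability $\mathrm{logistic}(k \cdot \text{rank gap})$. No
  generative model for wins is canonical; logistic in the rank gap is the
  minimal monotone choice. The default $k = 0.9$ was set a priori so that
  the expected directional consistency over uniformly sampled dyads of a
  19-animal herd is about 0.9, a typical value for a strict captive
  hierarchy.
* **Grunts.** Only losers grunt, with probability
  $p = \text{base} + \text{slope}\cdot(\text{rank}-1)$ (default base 0,
  slope 0.025): submission calling that worsens down the hierarchy, with
  the alpha structurally silent. Because low-ranked animals also *lose*
  more often, raw grunt counts correlate with rank even at zero slope; the
  zero-slope null is therefore tested on the per-loss grunt rate.
* **Outcomes and latencies.** After a grunt the conflict ends with
  probability 400/413; latencies are lognormal with medians 1.3 s (end)
  and 6.8 s (continuation) and log-SDs 0.45 and 0.6 — medians chosen to
  match the characteristic short-end/long-continuation separation, shapes
  free.
* **Acoustic signatures.** Per individual, the mean minimum frequency is
  $330 + 5 \cdot \text{rank}$ Hz plus between-individual noise (SD 25 Hz),
  so lower-status animals call at higher pitch; duration, peak frequency,
  bandwidth and HNR vary around herd means (0.10 s, 800 Hz, 1650 Hz,
  28 dB) with diagonal between/within covariance. Within-individual SDs
  (0.05 s, 400/110/600 Hz, 12 dB) are of the magnitude seen in published
  per-caller tables for calls of this type. Feature tables can be drawn
  directly on the feature scale (fast, used for the multivariate tests),
  including the centre/mean pairing that makes automatic-measurement
  tables collinear.
* **Waveforms.** A grunt is synthesised as a harmonic stack with
  fundamental at the signature minimum frequency under a band-limited
  spectral envelope with a +6 dB bump at the peak frequency, plus
  spectrum-shaped noise mixed to the target HNR, under a fast-attack
  envelope (3 ms attack, 4 ms release). The spectral peak is therefore
  realised on the harmonic grid; the realised value is attached to the
  waveform and is the reference for round-trip checks. This design is what
  makes the measurement contract satisfiable: with a single tone at the
  peak, the −9 dB spectral-extent criterion would collapse minimum and
  maximum frequency onto the tone bin at any realistic HNR. Bouts
  concatenate elements with silent gaps; element counts follow
  $1+\mathrm{Poisson}(2.5)$ truncated to $[1, 20]$, mode 3.

**What the generator does not emulate:** background noise and reverberant
field recordings, overlapping callers, amplitude cues (everything is
re-normalised), vocal-tract resonances/formants, age or weight effects, and
temporal dynamics of the hierarchy. Passing round-trip tests therefore
shows the estimators are correct and calibrated on clean, stationary,
single-caller data — not that detection would survive a noisy field
recording.

## Numerical choices and degenerate inputs

* Seeds: every stochastic function takes an explicit seed; child seeds are
  derived by integer sampling, and the pipeline logs all of them. Identical
  config + seed gives byte-identical outputs.
* Amplitude dB are $20\log_{10}$ re full scale; power ratios use
  $10\log_{10}$.
* Degenerate inputs are rejected with informative errors rather than
  guessed at: all-zero signals, all-zero dominance matrices, segments
  shorter than one analysis frame, constant vectors in `fit_lambda`/
  `spearman`, herds below a triad, insufficient rows per class.
* `landau_h` on a matrix with undirected dyads refers the caller to
  `landau_h_prime` instead of silently picking directions.
* Pipeline balanced designs cap the per-class subsample at the smallest
  class remaining after outlier removal, so the default 37 calls per
  caller is used whenever the data allow it and reduced (and logged)
  otherwise.
* Problem sizes in the shipped tests are chosen for fast, deterministic
  feedback: exhaustive oracles run at 4–6 individuals where enumeration is
  exact; Monte-Carlo checks use 30–200 replicates with fixed seeds; the
  full pipeline example runs a complete 19-animal study in seconds with
  10 selections × 100 permutations for the identity pDFA (production
  analyses should use 100 × 1000, one argument away).

## Known limitations

* $h'$ adopts the random-completion definition of the unknown-relationship
  correction; closed-source implementations of the same index may differ
  in detail.
* The I&SI search is heuristic beyond small herds, as is every practical
  implementation of the method.
* The HNR definition (autocorrelation peak) is documented but not
  identical to proprietary tools' unstated formulas; comparisons across
  tools should be by rank, not absolute dB.
* The outlier stand-in (MCD Mahalanobis) will not reproduce the flag count
  of any specific compositional-data tool.
* Measured minimum/maximum frequencies depend on the −9 dB spectral-extent
  threshold by construction; they are threshold-relative quantities, not
  physical band edges.
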