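---
title: "Methods: MEA phenotyping of neuronal cultures and organoids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MEA phenotyping of neuronal cultures and organoids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meapheno)
```

This vignette documents the models, conventions and numerical choices behind
`meapheno` — what each stage assumes, which parameters matter and why their
defaults are what they are, what the synthetic generator does and does not
emulate, and where the design was genuinely open.

## Recording model and windows

A recording is a set of per-electrode spike trains (strictly increasing times
in seconds from recording start, with amplitudes in µV as the negative
waveform trough) plus metadata and stimulation epochs. All windows are
half-open `[start, end)`, with time 0 at recording start, so a spike on a bin
edge is counted exactly once. The analysis compares the `window_s` (default
300 s) span ending at the first stimulation epoch with the equal span
starting after the last one — two 5-minute windows separated by the
stimulation block.

The active set — electrodes firing strictly above `inactive_rate_max`
(default 2 spikes/min) — is determined on the pre-stimulation window and held
fixed for all of that session's post-window metrics. The stimulation effect
would otherwise change the denominator population mid-comparison; holding the
pre-window set fixed keeps pre/post contrasts interpretable. The inactivity
rule is applied to the window-average rate (the simplest reading), not to
per-minute bins.

The recording-level mean firing rate is the *two-step* mean: per-electrode
rate first, then an unweighted mean over active electrodes, so arrays with
many weakly active electrodes are not dragged down mechanically. Zero active
electrodes yield `NA`, never 0. Amplitude is summarized the same two-step way
by default; whether a pooled per-spike mean would be preferable is genuinely
open, so the pooled value is always returned alongside. Amplitude is never
used for plasticity classification.

## Burst detection

A single-channel burst is triggered when at least `burst_min_spikes` (5)
spikes fall within a *sliding* `burst_window_s` (30 ms) window. Sliding, not
fixed, bins: fixed bins would miss bursts straddling a bin edge, and the
sliding reading is the stricter and standard one. The trigger is evaluated as
"any 5 consecutive spikes spanning at most 30 ms", which is equivalent to the
sliding-window formulation; overlapping qualified windows are merged into one
maximal event whose boundaries are the first and last spike of the merged
run. The burst rule defines only the trigger, so event extent (maximal merge)
is this package's convention. The implementation is tested for exact
agreement with an exhaustive window-enumeration oracle.

Network bursts use the hybrid electrode threshold
`T = max(nb_min_electrodes, ceiling(nb_min_fraction * n_active))` — a fixed
floor of 5 electrodes or 30% of the active set, whichever is larger, with the
fraction rounded up ("at least 30%" cannot be satisfied by a fractional
electrode). Clustering is greedy left-to-right over sorted SCB *onsets*: the
earliest unassigned onset opens a candidate window of `nb_window_s` (500 ms);
if it gathers at least `T` distinct electrodes, a network burst is emitted
and the onsets are consumed. Onset proximity (rather than burst-interval
overlap) was chosen as the reading of "co-occurring within a 500 ms window";
the overlap variant would require an additional extent convention on top of
the trigger-only burst definition.

## Short-term plasticity

Each active electrode's pre and post windows are split into
`plasticity_bin_s` (30 s) bins — 10 per 5-minute window — and the binned
counts are compared with a two-sided Mann–Whitney U test at `alpha` (0.05).
The choice of test is a design decision: the window-level comparison needs a
per-electrode significance call, and a rank test matches the non-parametric
stance of the rest of the pipeline while being robust to bursty, non-Poisson
count distributions. Under the generator's null (post/pre effect exactly 1)
the classifier's empirical type-I rate is within sampling error of `alpha`
(validated over 500 simulated null electrodes in the test suite).

The summary reports class fractions, the mean |relative change| within each
class, and a signed ratio built from summed magnitudes:
`+S_STP/S_STD` when potentiation dominates, `-S_STD/S_STP` otherwise, where
`S_x` sums `|post - pre|/pre` over class `x`. Magnitude sums (not electrode
counts) are used because the ratio is a rate-based quantity; an empty
denominator is capped at ±10 and flagged so downstream embeddings stay
finite; equal sums give the boundary value +1. Relative (not absolute) rate
changes are used throughout, with the absolute variant available from the
per-electrode table.

## Connectivity

For an ordered electrode pair, delays `t_j - t_i` within
`[0, xcorr_max_lag_s)` (500 ms) are binned at `xcorr_bin_s` (5 ms — fine
enough to resolve the generator's 0–20 ms coupling jitter while keeping
per-bin counts stable) and normalized by `sqrt(N_i N_j)`. The geometric-mean
normalization is symmetric under exchanging the trains and is the standard
choice for count-normalized correlation; product and minimum normalizations
would only rescale the threshold calibration. The pair strength is the peak
normalized bin, maximized over the two orderings; the counting kernel is
compiled (two-pointer sweep) and tested against a brute-force delay
enumeration.

Because no fixed threshold is defensible across firing-rate regimes, the
default edge threshold is calibrated per recording: `n_surrogates` (20)
surrogates jitter every spike uniformly by ±`surrogate_jitter_s` (50 ms) —
destroying millisecond-scale coupling while preserving rates and slow
structure — and the threshold is the `surrogate_quantile` (0.95) of the
pooled surrogate pair strengths. With coupling absent this yields a
false-edge rate near the nominal 5% (validated at <= 7.5% pooled over 20
seeded runs). A fixed numeric `edge_threshold` can be supplied instead for
exact reproducibility.

Graphs are undirected and simple; network size counts nodes with degree
>= 1; density is `2E/(N(N-1))` over all `N` active nodes; clustering is the
mean local clustering coefficient with degree < 2 nodes contributing 0.
Degenerate graphs (< 2 active electrodes) report all metrics as 0, flagged.

Temporal dynamics build an independent graph in each `dynamics_bin_s` (30 s)
bin over `dynamics_span_s` (60 s) on each side of the stimulation block — a
symmetric 120 s window, the span being centred on stimulation by choice since
nothing dictates an asymmetric one. One numerical subtlety: the sampling
fluctuation of a correlogram peak grows as the window shrinks, so a threshold
calibrated on the 5-minute window is anticonservative in a 30 s bin. The bin
series therefore rebuilds its surrogate null from the pre-stimulation bins
themselves (pooled), holding the resulting threshold and the pre-window
active set fixed across all bins. The stimulation effect on any metric is
reported as `(post - pre)/pre * 100`, with a zero pre-value flagged `NA`.

## The 18-feature phenotype

The per-organoid feature vector spans every quantity the upstream stages
produce: pre-window MFR, two-step mean amplitude, active-electrode count, SCB
rate, mean burst duration, mean spikes per burst, NB rate, mean NB size,
pre-window network size/density/clustering, post-window network
size/density/clustering, STP and STD fractions, the signed STP/STD ratio, and
the relative change of binned network size across stimulation. The exact
composition of such feature panels varies between studies, so the registry is
data-driven: `extract_features()` accepts any subset or reordering, and the
default is simply this package's definition of a full panel.

Before embedding, features are standardized to zero mean and unit variance.
Missing values are median-imputed (rows with more than 30% missing are
dropped) — imputation keeps a few degenerate recordings from deleting whole
cohorts, and the medians are robust to the heavy tails of rate features.
Constant features are dropped with a warning since they carry no variance to
decompose. The embedding is an ordinary PCA (`prcomp`); component signs are
fixed by making each component's largest-magnitude loading positive, so runs
are deterministic and comparable. Three components are retained to match how
such phenotypes are visualized and tested; explained-variance ratios are
reported over all components. Patients are summarized by the mean and SEM
(`sd/sqrt(n)`) of their organoids' scores, with single-organoid patients
flagged (`NA` SEM).

## Group statistics

*PERMANOVA* operates on Euclidean distances between score rows: pseudo-F from
the between/within sum-of-squares partition of the squared distance matrix,
with `p = (1 + #(F_perm >= F_obs)) / (1 + n_permutations)` — the +1
correction avoids p = 0 and keeps the test exact. Labels permute freely at
the organoid level by default; whether organoids of one patient are
exchangeable across groups is debatable (pseudo-replication), so a `strata`
argument restricts permutations to within-stratum swaps when desired. The
pseudo-F agrees with `vegan::adonis2` to machine precision (test-suite
cross-check), and the null distribution of p-values is uniform (KS-validated).
Pairwise group contrasts rerun the test per pair and adjust with Holm
(`stats::p.adjust`), which dominates the raw p-values and never exceeds
Bonferroni.

*Kruskal–Wallis* (tie-corrected, via `stats::kruskal.test`) is paired with
Dunn's z post-hoc comparisons on mean ranks, implemented here with the
standard tie-corrected variance and a configurable adjustment (Holm by
default, recorded in the output). Per-patient means are the intended unit for
these univariate comparisons, mirroring how such results are displayed.

*Per-bin Fisher tests* compare a group against the control at each dynamics
time bin on the 2x2 table of (connected, unconnected) node counts pooled over
each group's organoids. The contingency construction is this package's
interpretation — an exact test needs counts, and connected-node counts are
the per-bin quantity of interest; it is flagged as such. Degenerate margins
give p = 1, flagged. The implementation (`stats::fisher.test`) is verified
against full hypergeometric enumeration for every table with margins up to
12.

*Radar tables* divide each group's feature means by the control's, so the
control row is exactly 1; features with a zero or missing control mean are
flagged and omitted rather than silently producing infinities.

## The synthetic generator

`simulate_recording()` produces data matching the analysis assumptions, with
full ground truth:

* baseline firing is homogeneous Poisson per electrode, with per-electrode
  rates log-normal around the profile mean (`rate_dispersion` on the log
  scale, mean-preserving);
* single-channel bursts are injected as blocks of >= 5 spikes at a fixed 4 ms
  inter-spike interval, so every injected burst satisfies the 5-in-30-ms
  criterion *by construction* and ground truth is usable for recall scoring;
* network bursts inject near-simultaneous bursts (onset jitter 0–100 ms,
  well inside the 500 ms rule) on a sampled electrode subset;
* coupled pairs copy each source spike to the target with probability
  `coupling_strength` and uniform 0–20 ms jitter, producing a correlogram
  peak inside the first bins by construction;
* each electrode draws a stimulation label (STD/STP/none) from the profile
  mixture; its multiplicative rate effect applies to the whole post window
  (no decay — the analysis is window-level, and decay dynamics would add
  unidentified parameters). Because the normalized correlogram peak is
  invariant to common rate scaling, a rate effect alone cannot decouple the
  graph, so the profile also carries `post_coupling_factor` (< 1 emulates
  stimulation-induced decoupling, default 1);
* amplitudes are negative with log-normal magnitude
  (`amplitude_mean_uV`, `amplitude_cv`);
* `simulate_cohort()` adds log-normal patient- and organoid-level rate
  effects (sd 0.15 and 0.10 on the log scale) over groups -> patients ->
  organoids -> 2 sessions, everything deterministic given one seed.

The stimulation timeline is the protocol's cycles (default three 20 s
cycles) between 5-minute pre and post segments; pulse-level parameters
(100 µA, 66.7 µs phase width, 10 ms, 100 Hz) are stored verbatim for
provenance but do not shape the spike data — the stated pulse count,
frequency and cycle length are mutually inconsistent at face value, so the
simulator deliberately does not resolve pulse timing.

What the generator does *not* emulate: raw voltage traces (beyond the
optional threshold-detection fixture in the tests), electrode drift, spike
sorting and unit identity below the electrode level, rate non-stationarity
within windows, refractory structure of baseline spiking, and stimulation
artifacts. Passing tests therefore demonstrate that the pipeline recovers
known structure of this statistical form — they do not certify behaviour on
pathologies real MEAs can show (e.g. strongly non-Poisson interval
statistics or drifting baselines).

The three shipped profiles (`default_profiles()`) span a control, a
hypoactive group (fourfold reduced rate, smaller amplitudes, sparse
bursting), and a hyperactive, strongly depression-biased group with
pronounced post-stimulation decoupling. The paper-style study reports only
significance orderings, not effect sizes, so these magnitudes are fixed
design choices selected once to reproduce the qualitative orderings
(hypoactivity, hyperactivity, STD bias, stimulation-induced network-size
reduction); they are synthetic and labelled as such.

## Problem sizes and runtime choices

The validation suite runs at desk scale by design: 10–50 electrodes per
simulated array, 5-minute windows, 20-seed replication for recovery rates,
500 null electrodes / 500 replicates for calibration checks, 200 replicates
at 99 permutations for the PERMANOVA null, and 20 cohorts of 12 recordings
(three groups x two patients x two organoids) at 999 permutations for the
end-to-end discrimination check. The shipped profiles default to 12-electrode
arrays for the same reason; `default_profiles(n_electrodes = 60)` restores a
full-size array when runtime is no concern. Connectivity cost is dominated by
surrogate calibration (`n_surrogates` x all pairs) and scales quadratically
in electrode count.

## Degenerate inputs and edge conventions

Empty trains give empty burst lists and zero, flagged correlograms; zero
active electrodes give `NA` metrics and empty NB lists; graphs with < 2
active nodes are flagged degenerate with zero metrics; all-equal paired
differences give a degenerate paired test (statistic 0, p 1 when identically
zero); all-identical values give the Kruskal–Wallis H = 0, p = 1 convention;
a zero pre-value makes the relative change `NA`; duplicated
(electrode, time) rows are deduplicated with a warning on read, while
out-of-range times are an error naming the row. Spike times are written with
6 decimal places (microsecond precision), which bounds round-trip error at
0.5 µs — far below the 4 ms scale of any analysis constant.

## Known limitations

* Unit identity: everything is per electrode; multi-unit activity on one
  electrode is not resolved.
* The burst and network-burst rules are the fixed thresholds above; adaptive
  detectors (ISI-histogram or MaxInterval families) are out of scope.
* Connectivity is undirected and binarized; no directed or weighted-graph
  inference.
* The Fisher contingency construction and the exact 18-feature composition
  are this package's documented interpretations, configurable where
  reasonable.
* PERMANOVA on organoid-level rows treats organoids as exchangeable under
  the null; use `strata` when patient-level dependence is a concern.
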