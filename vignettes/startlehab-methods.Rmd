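---
title: "Models and methods behind startlehab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind startlehab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(startlehab)
```

# The assay model

Larval zebrafish respond to strong acoustic/vibrational stimuli with a
Mauthner-cell-driven escape maneuver, the short-latency C-bend (SLC);
weaker stimuli evoke slower long-latency C-bends (LLC). `startlehab`
encodes the two protocols this behavior is probed with:

* the **habituation assay** — 10 sub-threshold stimuli at 30 s ISI
  (sensitivity phase), 10 high-intensity stimuli at 30 s ISI
  (pre-habituation baseline), 30 high-intensity stimuli at 3 s ISI
  (habituation phase), with a 30 s break between phases;
* the **multi-intensity assay** — 5 trials at each of 6 intensities
  (0.3–35 dBu) at 40 s ISI.

Stimulus intensity is carried in dBu, the decibel scale referenced to
0.775 V (`dbuFromVolts()`), because rigs are calibrated from accelerometer
voltages. The low/high/intermediate intensities are *empirical* rig
calibrations — chosen to elicit SLCs in roughly 10%, 80% and 25% of
wild-type trials — so `ProtocolConfig` treats them as configuration, not
constants. Inter-phase breaks are represented as gaps in `time_s`, never as
sentinel rows, so stimulus indices 1–50 line up with phase language such as
"stimuli 41–50"; the break *replaces* the ISI at a phase boundary, making
the gap between stimuli 20 and 21 exactly 30 s.

# Behavioral statistics

**Classification.** Response class is a pure function of latency:
SLC for latency ≤ 15 ms, LLC in (15, 100] ms, `none` otherwise. The 15 ms
cutoff is the conventional boundary for Mauthner-driven responses at
standard temperatures and is configurable (`classifyResponses()`); all
"startle responsiveness" statistics count SLCs only, matching how such
data are reported.

**Habituation.** Per larva, `100 * (1 - f(41-50)/f(11-20))` over SLC
frequencies. Two deliberate readings are encoded:

* the group statistic is the *mean of per-larva percentages*, not the
  ratio of group means — per-larva normalization is what makes the
  statistic robust to baseline differences;
* the non-responder filter (`< 40%` baseline responsiveness) is a strict
  inequality: a larva at exactly 4/10 is retained.

The filter applies to habituation and kinematic summaries only; the
sensitivity-phase rate is unfiltered, because hypersensitivity is precisely
the phenotype that phase measures. Larvae tracked on fewer than 80% of the
required stimuli are dropped with a warning (tracking dropouts are a fact
of life in plate-based assays; the choice of 80% is ours).

**Sensitivity index.** Trapezoidal area under percent-startle vs. intensity
(%·dBu). The trapezoid makes the index additive over adjacent intensity
sub-ranges and monotone in every frequency, both of which are tested as
properties. Duplicate intensity points with equal frequencies are collapsed
so repeated levels cannot inflate the area; conflicting duplicates are an
error rather than silently averaged.

**Kinematics.** Mean SLC latency/duration per larva over the baseline
phase (stimuli 11–20) — the habituation phase is excluded because response
probability is changing there, and the sensitivity phase because
sub-threshold responses are a latency mixture. Latency-by-intensity tables
flag levels with fewer than 3 SLCs as too sparse to report.

# The synthetic-data generator

The generator exists so the pipeline is testable end to end: it produces
event tables with the statistical structure the analysis assumes, with
every preset calibrated once against a published group statistic.

**Response model.** Each larva × stimulus is an independent Bernoulli
draw. Probability is `p_sensitivity` in the sensitivity phase, `p_baseline`
in pre-habituation, and decays geometrically through the habituation phase
toward a plateau, reaching within 1% of it by the 21st habituating stimulus
(stimulus 41) — the data constrain the plateau (stimuli 41–50), not the
decay shape, so the rate is fixed by that "converged by 41" requirement.

**Plateau calibration.** A preset's `habituation_pct` is defined as the
*measured* cohort statistic to be recovered, and the measured statistic is
not a plain ratio of probabilities: it divides by each larva's noisy
baseline frequency and conditions on the non-responder filter, so its
expectation exceeds `plateau / p_baseline` (Jensen's inequality; about
2–3 pp at `p_baseline = 0.8` with 10 baseline stimuli). The generator
therefore inverts the measurement model — the plateau solves
`E[100(1 − late/pre) | pre ≥ 0.4] = habituation_pct`, using the exact
binomial expectation `E[10/X | X ≥ 4]` and the residual decay-tail
amplitude — rather than using `p_baseline (1 − habituation_pct/100)`
directly. One consequence: a non-habituating preset
(`habituation_pct = 0`) plateaus slightly below `p_baseline` (0.778 at
0.8), because a cohort holding its baseline frequency exactly would
*measure* slightly negative habituation.

**Presets.** Calibration values are taken from the published group
statistics: habituation 83.3 (wild-type TL), 5.4 (p177 homozygote), 12.4
(sa16189), 19.9 (sa16051), 39.5/39.0 (trans-heterozygotes), 32.6
(sa16051 under reduced intensity); sensitivity-phase rates 9.3, 52.4, 70,
60, 38.2, 42.4, and 16/11% for heterozygote-sibling pools; psychometric
anchors (7.6 dBu, 0.334) and (13 dBu, 0.888) for sa16189 homozygotes and
(7.6, 0.024), (25.6, 0.888) for their heterozygous siblings. Baseline
responsiveness is 0.80 for all standard-intensity presets (the stimulus is
calibrated to ~80% in wild-types and per-genotype baselines are only shown
graphically); the reduced-intensity mutant preset uses 0.65 — no published
number exists, and hypersensitive mutants must sit well above the ~25%
wild-type calibration at the intermediate intensity. Kinematic parameters
(median latency 6 ms wild-type, sdlog 0.25, mutant latency factors
0.8–0.9, duration 9 ± 1.5 ms) are plausible values on the SLC scale chosen
once; only their *ordering* (mutant < wild-type, duration unchanged) is
meaningful, and that is what tests assert.

**Psychometric curves.** A two-parameter logistic with floor 0 and fixed
ceiling 0.95 (full-population responsiveness is never observed), fitted by
least squares on the logit scale through the preset anchors; with two
anchors the curve interpolates them exactly. The latency shift of mutants
is disabled at the lowest anchor intensity, reproducing the observed
pattern that latency and hypersensitivity unlink at weak stimuli.

**Crosses and pools.** `mate()` is plain Mendelian segregation.
`simulateMutantPool()` gives every pooled chromosome the mutagenized-strain
(TL) allele at the causal locus; at `d` cM it keeps the TL allele with
probability `1 − r(d)` under the Haldane map `r = (1 − e^(−2d/100))/2`
(no-interference assumption), with unlinked chromosomes at 0.5. Depth is
Poisson around the mean coverage, reads are binomial in the realized pool
allele fraction, and each read miscalls with the error rate. A uniform
1.25 cM/Mb map is the default since no genetic map is modeled.

**Reproducibility.** Every larva (and each pool) draws from a substream
seeded by a counter-based hash of the master seed and its index, so event
tables are byte-identical under the same seed and individual larvae are
stable when the cohort grows.

**What the generator does not emulate.** Within-larva correlation beyond
the phase structure (real larvae have stable individual thresholds),
spontaneous movement superimposed on responses, LLC probability as an
independent channel (only the latency mixture), tracking dropouts, linkage
disequilibrium structure or marker ascertainment bias. Passing recovery
tests therefore validates the *pipeline arithmetic and its statistical
contracts*, not the biological realism of any preset.

# Homozygosity mapping

The score is the TL read fraction `tl/(tl+wik)` — the caption semantics of
such scans (1.0 = linked to the mutagenized strain, 0.0 = mapping strain,
0.5 = unlinked) fix this definition; the original method's exact statistic
lives in its own reference and is not reproduced here. Numerical choices:

* markers with coverage < 4 reads are masked before smoothing
  (low-information sites);
* smoothing is a running median over 51 markers per chromosome — robust to
  miscalled markers and matching the noisy-but-plateaued look of real
  scans. The window shrinks symmetrically at chromosome ends (we do not
  use `runmed`'s Tukey end rule, which disagrees with the symmetric
  contract at boundaries); medians ignore `NA`s from masked markers;
* the interval call is the maximal contiguous run of smoothed scores
  ≥ 0.95 containing the genome-wide maximum, closed on both ends, 1-based;
  BED output converts to 0-based half-open at write time. Ties at the
  maximum break toward the first marker in genome order.

With 64 pooled larvae (128 chromosomes), binomial noise at realistic
coverage (30–50×) leaves the smoothed track maximal at the causal locus
essentially always; the test suite checks ≥ 90% interval recall over 50
seeded pools at coverage 30 and 1% read error.

# Genotyping

`DigestAssay` stores per-template amplicon lengths and cut offsets; the
three shipped assays encode their published fragment arithmetic, including
the deliberately mirrored conventions (p177: wild-type template cleaved;
sa16051: mutant template cleaved — each dCAPS mismatch primer creates the
site on a different template). Amplicon sequences are not published, so cut
positions come from the fragment arithmetic, not from genomic sequence;
`findCutSites()` exists for assays defined from sequence and is verified
against a brute-force substring scan. Calls compare observed band
multisets against wild-type, mutant, and their union (heterozygote) with a
±5 bp tolerance reflecting agarose resolution; sub-20 bp fragments are
flagged as unresolvable on gel but kept in predictions, since the p177
assay's informative 16 bp band shows such fragments are still meaningful
in silico.

# Group comparisons

The test-selection logic is deliberately mechanical: D'Agostino–Pearson
normality per group at α = 0.05 (implemented in-package from the standard
skewness/kurtosis Z transforms, verified against an independent
implementation), then Welch t / ANOVA + Dunnett for normal data and
Mann-Whitney / Kruskal-Wallis + Dunn otherwise, always versus a designated
reference group. Normality is judged per group (not on pooled residuals),
and a single non-normal group sends the whole comparison down the
nonparametric branch — the conservative reading. Groups under n = 8 cannot
be tested for normality and force the nonparametric branch with a warning.
Dunn's comparisons are Bonferroni-adjusted over the reference comparisons
only; Dunnett uses the joint multivariate-t distribution via `multcomp`.
The suite checks type-I error of the full select-then-test pipeline over
1000 null simulations (n = 30 per group), requiring the rejection rate to
stay in [0.03, 0.07].

# Problem sizes and determinism

All simulation-backed checks run at the reported group sizes (n = 20–148
larvae, 50-stimulus protocol) averaged over 10 seeds, pools of 64 larvae
over a few hundred to 10⁴ markers, and 50–1000 replicate property
simulations — sizes chosen so the whole suite and the acceptance script
each complete in well under a minute of compute per check while leaving
Monte-Carlo error small against every stated tolerance. All randomness
flows from explicit integer seeds; nothing numeric reads the clock or OS
entropy.

# Known limitations

* Presets inherit every simplification above; they are calibration
  vehicles, not digital twins of mutant lines.
* The habituation statistic is undefined for larvae with zero baseline
  responsiveness; the non-responder filter removes them, which means
  cohorts with baseline probability near the 40% threshold estimate a
  *conditional* habituation (the reduced-intensity protocol flirts with
  this; its preset baseline of 0.65 keeps exclusion modest).
* The mapping stage starts from allele counts: alignment artifacts,
  reference bias and marker ascertainment are upstream of this package.
* Latency cutoffs are fixed per analysis, not fitted; borderline responses
  near 15 ms flip class with the cutoff, which is why it is exposed as a
  parameter everywhere.
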