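---
title: "Methods: quantification model for 15N metabolic labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantification model for 15N metabolic labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silia)
```

## The quantification model

In a metabolic ¹⁵N labeling experiment every nitrogen position of an
expressed protein is subject to labeling, so a heavy peptide with
*n* labelable nitrogens sits *n*·(m(¹⁵N) − m(¹⁴N)) above its light twin.
Two properties of this design drive everything in this package:

1. **Labeling is incomplete.** Enrichment *p* — the fraction of labelable
   positions actually occupied by ¹⁵N — typically lands between 0.93 and
   0.99 for plate-grown Arabidopsis after two weeks, and is close to
   constant across proteins within one experiment. The number of residual
   ¹⁴N atoms in a heavy molecule is Binomial(*n*, 1 − *p*), so the heavy
   isotope cluster develops satellite peaks at M−1, M−2, … below the
   all-¹⁵N monoisotopic species M.
2. **Only the monoisotopic peak is measured.** Reading a single peak per
   channel keeps quantification robust against cluster overlap, but the
   heavy M peak then carries only a fraction
   *f*<sub>M</sub>(*p*) = P(zero residual ¹⁴N) × (natural-abundance
   mono fraction of C/H/O/S and unlabeled N) of the channel's total
   abundance, while the light M peak carries a larger (and
   *p*-independent) fraction. The uncorrected monoisotopic ratio is
   therefore biased toward the light channel by
   *f*<sub>L</sub>/*f*<sub>H</sub>(*p*) — a factor of ~2 at *p* = 0.95 for
   a typical tryptic peptide.

The corrected ratio is

L/H = (I<sub>L</sub> / *f*<sub>L</sub>) / (I<sub>H</sub> / *f*<sub>H</sub>(*p*)),

with I the measured monoisotopic intensity (or area) per channel. The
acceptance suite demonstrates both halves: at *p* = 0.95 the uncorrected
log₁₀ ratios of 200 simulated pairs carry a systematic bias above 0.1
while the corrected ones recover truth with RMSE below 0.05.

### Envelope computation

Envelopes are aggregated by nominal-mass bin (unit-mass isotopologues):
at Orbitrap resolutions the ¹³C/¹⁵N/²H fine structure inside a bin is not
resolved, and the M−1…M+2 peaks the workflow operates on are unit-spaced.
Each bin carries an intensity-weighted centroid mass. The distribution is
an iterated polynomial convolution of single-atom isotope vectors —
natural abundance for C, H, O, S and unlabeled nitrogen, the two-point
(1 − *p*, *p*) vector for each labeled nitrogen — using binary
exponentiation per element. Heavy offsets are anchored at the all-¹⁵N
species, so incomplete labeling shows up at negative offsets, matching the
field's "M−1 satellite" naming.

An exact enumeration oracle (`brute_force_envelope`, ≤ 12 atoms)
aggregates every isotopologue combination by exact mass and is the
independent check: the suite requires agreement below 10⁻⁹ on 50 random
small compositions per run.

Numerical choices: per-step truncation of convolution terms below 10⁻¹²
(bounded error far under test tolerances at peptide scale); final
truncation of the envelope tail once cumulative abundance reaches
1 − 10⁻⁶, followed by renormalization to sum 1. Internally envelopes are
sum-normalized; the display/CLI convention reports the largest peak as
100%, which is how isotope-plot tools present clusters.

The one caveat of unit-mass aggregation: at *p* < 1 the offset-0 bin of a
heavy envelope mixes the pure all-¹⁵N species with rare cancellation
species (e.g. one ¹³C plus one residual ¹⁴N), so its centroid can sit a
few mDa off the exact monoisotopic mass. The centroid-vs-mass invariant is
therefore asserted on the clean anchors (light envelopes, and heavy at
*p* = 1), where the bin is pure.

### Efficiency estimation

M−1/M is strictly decreasing in *p* (more label, fewer residual ¹⁴N), so
an observed satellite ratio inverts to an enrichment estimate. Inversion
is by bisection on *p* ∈ [0.5, 0.9999] to |Δp| < 10⁻⁵: below 50%
enrichment heavy and light clusters overlap and the whole workflow is
invalid, so the bracket doubles as a sanity bound; observations outside it
clamp to the ends with a warning. Per-peptide estimates are averaged
unweighted (the spread is reported as an SD so non-constant labeling is
visible); peptides under 1500 Da are preferred — their M peak is the
cluster's largest, making the satellite ratio the most reliable
measurement — but the filter is overridable and ignored when nothing
passes it.

### Spectrum measurement

MS¹ scans inside an asymmetric retention-time window (default −5 s/+15 s
around the identifying MS² scan) are averaged: chromatographic peaks run
~30 s wide here, and a narrow window nearly always contains the elution
apex while limiting exposure to co-eluting interference; column/gradient
changes warrant re-examining it. Pooled peaks are clustered on the m/z
axis and matched to targets with one coherent resolution model: tolerance
= FWHM/2 with FWHM = m/z / R, default R = 240,000 (a deliberately tight
matching setting for high-resolution MS¹ data). Cluster intensity is the
mean over all scans in the window; areas are trapezoidal integrals of
per-scan heights. Two peaks inside tolerance resolve to the nearer one,
exact distance ties to the taller.

The **zero-noise contract**: a target with no peak inside tolerance
contributes exactly 0 — never an imputed noise floor. This is what makes
one-sided (bait-IP) quantifications meaningful: a missing channel is a
clean `Inf`/`0` sentinel, not a ratio against noise. Sentinels are
retained at peptide level and excluded from log-space protein statistics
(their counts are reported per protein).

### Quality scoring and aggregation

The CS score is the cosine similarity of observed vs theoretical M, M+1,
M+2 vectors, per channel, with the theoretical pattern taken at the
run's enrichment — at low *p* the heavy pattern changes dramatically, and
an enrichment-blind score would flag correct measurements. Scores below
the threshold (default 0.9) flag the pair; nothing is auto-removed. Scores
within 10⁻¹² of 1 snap to exactly 1 so proportional vectors score 1.0
despite floating-point rounding; an all-zero observed vector yields `NA`
(undefined), deliberately distinct from a genuine mismatch of 0. Because
only three points enter the cosine, contamination on a peak that already
dominates the pattern has a score floor (≈ *b*₀/‖*b*‖); the score is also
least reliable at very low signal, so each quant carries its summed
observed intensity for down-weighting. Both limitations are inherent to a
3-point pattern statistic, and the interference test asserts what the
statistic can deliver: contaminated peptides score below clean ones
essentially always, and excluding flagged peptides moves protein medians
strongly toward truth without false flags — not that every contaminated
peptide crosses the threshold.

Protein statistics are Q1/median/Q3 of log ratios, back-transformed
(base-independent; quartiles by linear interpolation of order statistics,
the `stats::quantile` type-7 default, as no convention is canonical
here). The median resists the outlier ratios that interference produces.
Normalization divides all ratios by the median of the top-100 most
abundant proteins' medians — samples are never mixed at exactly 1:1 —
with "abundant" ranked by summed cluster intensity by default (peptide
count available as an alternative; no abundance metric is canonical), or
by user-named housekeeping proteins. Normalization runs on unflagged
quantifications.

### Deduplication and channels

One quantification per (sequence, modifications, charge, file). When both
channels were identified independently, the higher-score identification
anchors the RT window. The reported ratio is always L/H regardless of
which search identified the peptide. Per-channel FDR splits the
target/decoy counts of the ¹⁴N and ¹⁵N searches after combined
thresholding.

## The simulator: what it emulates and what it does not

`sim_config()`/`simulate_scans()` generate centroided MS¹ scans containing
paired clusters built from the same envelope engine at a configured
enrichment, Gaussian elution (FWHM 30 s), 1% multiplicative peak noise
(typical centroid-height reproducibility at good signal), charges 2–3,
co-eluting single-peak interference, missing-heavy proteins and unlabeled
(seed-storage) proteins. Sequences come from a bundled list of real
Arabidopsis tryptic peptides plus random tryptic-like strings (the
`SYNTH*` accessions in the bundled table mark constructed sequences). The
seed fully determines the output.

Defaults are the study conditions, chosen once: *p* = 0.97 (a good
two-week labeling), 20 proteins × 5 peptides for routine runs; the test
suite scales problem sizes to its purpose — 200 pairs for ratio-recovery
RMSE, 100 interference injections, 10 peptides per efficiency point —
sizes at which the stochastic tolerances above are comfortably
discriminating.

Passing against this simulator shows the *computational* chain is
correct and unbiased under its stated model. It does not demonstrate
robustness to what the simulator omits: profile peak shapes and
centroiding artifacts, chromatographic drift between runs, charge-state
envelopes sharing elution, electrospray saturation, or real co-isolation
landscapes denser than the injected single-peak contaminants. Envelope
correctness is anchored independently of simulation by the enumeration
oracle and the worked composition example.

## Known limitations

- Low-incorporation studies (protein turnover) produce heavy clusters that
  overlap the light cluster; this package does not deconvolve overlapping
  distributions and its ratios are invalid there (the bisection bracket's
  0.5 floor encodes this boundary).
- Only ¹⁵N labeling is wired, though the envelope engine is parameterized
  by element tables; ¹³C/²H metabolic labels would need their own labeled
  positions bookkeeping.
- Profile-mode mzML is rejected, not centroided; MS² search, decoy
  construction and protein inference are upstream concerns consumed via
  the ID table.
- Statistical testing across biological replicates is out of scope; the
  protein table is the input to such downstream analysis.
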