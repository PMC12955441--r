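---
title: "Counting rare transcripts by duplex RT-ddPCR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting rare transcripts by duplex RT-ddPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cifquant)
```

## Scope

cifquant analyzes duplex droplet digital PCR experiments in which a rare
target transcript — the motivating case is *Wolbachia* *cifA*/*cifB* mRNA
from *Drosophila* testes — is counted on the FAM channel while a spike-in
RNA or an endogenous reference gene (*β-Spectrin*) is counted on HEX in
the same droplets. This vignette documents the statistical models, the
simulator's assumptions, the defaults and why they were chosen, and the
limits of what the test suite demonstrates.

## The partition model

A 20 µL reaction is partitioned into droplets of volume $V_d$ (default
0.85 nL). Copies land in droplets independently, so the occupancy of a
droplet for a target at concentration $c$ copies/µL is Poisson with mean
$\lambda = c \, V_d$ (volumes in µL). Endpoint PCR saturates, so any
droplet with occupancy $\ge 1$ reaches the positive amplitude cluster;
amplitude does not encode the within-droplet copy number. Inverting the
zero class gives the estimator

$$\hat\lambda = -\ln(1 - \hat p), \qquad \hat p = x/n,$$

which corrects for multiple occupancy, and
$\widehat{\text{copies/reaction}} = \hat\lambda \, V_r / V_d$.

**Confidence intervals.** The delta method gives
$\mathrm{SE}(\hat\lambda) = \sqrt{\hat p / (n(1-\hat p))}$; the 95% CI on
$\lambda$ is scaled to copies/reaction. When either class is nearly empty
($x \le 5$ or $n - x \le 5$) the normal approximation is poor and exact
Clopper–Pearson bounds on $p$ are transformed through $-\ln(1-p)$
instead. A fully positive well has no finite estimate and is returned
flagged `saturated` rather than as an error. Simulation at
$\lambda = 0.2$ (the acceptance suite, 1,000 wells of 15,000 droplets)
shows empirical coverage within the 94–96% band.

**Dead volume.** All of a well's read droplets are taken to represent the
reaction, and copies/reaction scales by the full $V_r = 20$ µL regardless
of the fraction actually partitioned. This matches how copies-per-20 µL
is conventionally reported but means the "per reaction" quantity refers
to the assembled mix, not to molecules actually cycled; a documented
limitation, not a correction we attempt.

**QC.** Wells with fewer than 10,000 droplets are excluded (flag
`qc_pass`); the boundary count passes. The floor is configurable.

## Droplet classification

Each droplet gets exactly one of four labels: `negative`, `fam_only`,
`hex_only`, `double`. FAM positivity is raw amplitude versus a single
cutoff and never depends on the HEX state — intermediate HEX clusters
must not perturb target counting.

Thresholds are fitted deterministically per well:

1. **FAM cutoff** — a 1-D two-cluster split (Lloyd's k-means, $k = 2$,
   initialized at the 5th/95th amplitude percentiles, 100 iterations
   max); the cutoff is the midpoint of the two cluster means. If the
   means are closer than 4× the pooled within-cluster SD the channel is
   declared single-cluster and the cutoff is placed at mean + 5 SD, so an
   all-negative well yields zero positives. The factor 4 separates true
   bimodality from the ~1.6σ split k-means produces on unimodal data;
   the 5-SD offset makes a false positive on a clean negative well a
   ≪ 10⁻⁶ event per droplet.
2. **HEX cutoff** — the same split applied to the FAM-negative droplets,
   which carry essentially no crosstalk (falling back to all droplets
   when that stratum has under 100 members).
3. **Crosstalk coefficient** — among FAM-positive droplets, a two-cluster
   split of HEX identifies the FAM-only cloud; the coefficient
   $\hat\alpha$ is the least-squares slope of HEX on FAM within that
   cloud (≥ 50 members required, else 0, the spec of a clean assay).
   Classification then compensates every droplet's HEX amplitude by
   $\hat\alpha \max(0, \text{FAM} - \widehat{\text{FAM}}_{neg})$.
4. **Competition-aware HEX cutoff** — duplex chemistry lets the two
   targets compete for reagents in double-positive droplets, pulling
   their HEX amplitude toward the baseline (an intermediate cluster). A
   single HEX cutoff fitted on the whole well sits *above* that cluster
   and would misclassify most double positives, so the HEX boundary for
   the FAM-positive stratum is fitted separately: the midpoint of the two
   compensated HEX cluster means within that stratum
   (`hex_cutoff_fampos`). When there is no competition the two cutoffs
   coincide, recovering the plain quadrant rule. This stratified design
   is what lets label accuracy stay above 99.5% with both artefacts at
   their default strengths.

Degenerate inputs are handled explicitly: user-supplied cutoffs outside
the observed amplitude range are rejected unless the channel is flagged
single-cluster (an out-of-range cutoff is then the point); a FAM-positive
stratum whose HEX side is unimodal (target absent, or everything double)
falls back to the global HEX cutoff after compensation.

One known failure mode remains: a well in which *all* FAM-positive
droplets are double-positive *and* competition is strong can classify
those droplets HEX-negative, because nothing in the well reveals where
the competed cluster should sit. This requires HEX occupancy near 1 with
moderate FAM occupancy and does not arise in the study designs simulated
here.

## The simulator

`simulate_reaction()` draws per-droplet occupancies independently per
channel (`rpois`), maps occupancy ≥ 1 to the positive cluster, and draws
amplitudes from Gaussian clusters. Defaults place FAM negatives at 700
a.u. and positives at 9,603 a.u., HEX negatives at 1,032 a.u. and
positives at 4,284 a.u. — the amplitude regime of the cifA/spike duplex
on a QX200 reader — with SDs of 3% of each mean (cluster means are
well-characterized in such data; dispersions are not, and 3% reproduces
the tight, clearly separated clouds seen in practice). Two artefacts are
modelled:

- **competition** multiplies the HEX positive mean by $\kappa$ (default
  0.5) in double-positive droplets only;
- **crosstalk** adds $\alpha \max(0, \text{FAM} - \mu^{FAM}_{neg})$
  (default $\alpha = 0.05$) to every droplet's HEX amplitude.

The defaults keep both artefacts active simultaneously, which is the
harder classification problem; $\kappa = 0.5$ and $\alpha = 0.05$ are
chosen so the intermediate clusters sit well inside the gap between the
HEX negative and positive clouds, qualitatively matching observed duplex
2-D plots (the magnitudes of these artefacts are not quantified in the
literature; they are simulator conventions, exposed in
`simulation_params()`).

Droplet volume is 0.85 nL, the QX200 convention; copies/µL scales
linearly in it, so it is a visible parameter rather than a constant.
Droplet count defaults to 15,000 (mid-range of the 10,000–20,000 a QX200
well yields). No-template controls carry a small background contamination
(default 0.005 copies/µL, ~0.06 expected positive droplets per well) so
LOD machinery sees realistic occasional single-positive NTCs. "Rain" —
droplets at intermediate amplitudes — is off by default and available as
`rain_fraction` for threshold robustness testing only.

Determinism: identical `(params, truth, seed)` give bit-identical wells.
Dilution series sub-seed replicate $r$ at level index $i$ as
`seed + 1000 i + r` so any single well can be regenerated. The series
helper scales both targets by $b^k$; `hold_hex_constant` exists for
designs that re-add spike per reaction, but defaults to off because a
spike added before extraction dilutes along with the cDNA.

**What the simulator does not emulate** — and hence what passing tests do
not show about real data: droplet volume variability, rain from partial
inhibition, day/operator effects, pipetting error between replicates
beyond Poisson sampling, template degradation, and reverse-transcription
efficiency (concentrations are of cDNA, not mRNA). Tests against the
simulator certify the statistics, not the chemistry.

## Detection limits

The LOD is the upper 95% confidence bound of the no-template controls on
the copies/reaction scale, rounded up to whole copies (`ceiling`) —
reporting convention for a threshold below which a signal is
indistinguishable from background. "95% CI of the no-template controls"
is read as *across replicate wells*: with $\ge 2$ NTCs the bound is
$\bar x + t_{0.975, n-1} s / \sqrt n$; with one NTC the well's own CI
upper bound is used. When every NTC measures exactly zero the
across-replicate interval degenerates to zero, so the wells are pooled
and the Clopper–Pearson upper bound on the pooled positive fraction is
converted to copies/reaction — the LOD is never exactly zero, which is
the scientifically meaningful behavior (absence of observed background is
not evidence of zero background).

## Normalization

- `spike_recovery()` = measured/expected spike; values above 1 are
  permitted but warn, since they indicate a suspect expected-input
  calibration. The expected input is a configuration value (absolute
  calibration), or the batch-mean recovery in relative mode — which of
  the two a given lab uses depends on whether its spike stock is
  absolutely quantified, so both are supported and neither hard-coded.
- `correct_by_efficiency()` divides the raw count by the efficiency.
  Compensating a loss requires scaling *up* a count measured after that
  loss; division by the recovery fraction is the operation with that
  property (multiplying a raw count by an efficiency < 1 would shrink
  it further).
- `normalize_to_reference()` is a guarded ratio with a delta-method CI
  for a ratio of independent estimates; a zero reference returns an
  undefined-result flag rather than an infinity.

## Validation statistics

- **Dilution linearity** is computed on the log-log scale:
  $\log_{10}(\text{copies})$ against $\log_{10}(b^k)$. A 1:5 series over
  six levels spans nearly four orders of magnitude, and a raw-scale
  Pearson statistic there is dominated entirely by the top level; the
  log-log statistic weights levels evenly and has slope exactly 1 under
  perfect proportionality. The raw-scale least-squares slope is reported
  alongside for transparency. Levels containing any zero estimate cannot
  enter a log fit and are excluded from it (and reported); at least three
  zero-free levels are required.
- **Replicate CV** is $100 \, s/\bar x$ with the $n-1$ SD (two technical
  replicates is the common design, where the $n$ denominator would
  noticeably understate dispersion). CV of an all-zero level is
  undefined and flagged, not zero.
- **Yield slope test**: least-squares slope of RNA concentration on
  testis-pair count, tested against the mean per-pair yield by a
  one-sample t-test of the per-sample ratios; exactly constant ratios
  short-circuit to p = 1 with a zero-variance flag.
- **Amplitude separation** (positive-mean minus negative-mean per
  channel) ranks annealing temperatures; empty classes yield NA flags.

Display rounding is two decimals where such values are conventionally
printed; full precision is always retained in returned objects.

## Oligo design QC

`melting_temperature()` implements the unified nearest-neighbor model:
stacking ΔH/ΔS sums with terminal initiation terms and the
self-complementary symmetry correction,
$T_m = \Delta H / (\Delta S_{salt} + R \ln(C_T/4)) - 273.15$, with the
entropy salt correction $0.368 (N-1) \ln[\mathrm{Na}^+_{eq}]$ and the
divalent-to-monovalent conversion
$\mathrm{Na}^+_{eq} = \text{mono} + 120\sqrt{\max(0, \text{divalent} - \text{dNTP})}$
(mM). It agrees with an independent nearest-neighbor implementation to
well under 0.01 °C on the test oracles. Two condition presets exist
because Tm is convention-dependent: `thermo_conditions()` reflects the
assembled reaction (3 mM Mg, 900/250 nM oligos) and
`primer3_conditions()` the design-time convention (1.5 mM divalent,
0.6 mM dNTP, 50 nM oligo) that primer design windows such as 58–62 °C
refer to. Window verdicts are reported as measured — some published
primers sit a degree outside their nominal window under either preset,
which the report states rather than hides; Tm checks are
window-membership questions, never point equalities, because the exact
ion conditions behind any published window are rarely stated.

Other rules: the "GC clamp of 2" is read as *both* of the two 3′-terminal
bases G or C (the common design-tool meaning); poly-X is the longest run
of identical consecutive bases; verdicts are case-invariant; oligos with
ambiguous bases get `NA` (not evaluable) Tm verdicts rather than errors.

`insilico_pcr()` finds exact forward matches and downstream
reverse-complement matches; the product length spans both primers
inclusive. A mismatch-tolerant mode (≤ 2 mismatches, 3′-terminal 3 bases
anchored exact) supports cross-strain checks and is clearly an
extension, not the default. The bundled *β-Spectrin* template is a
synthetic stand-in embedding the primer sites at the declared 107 bp
spacing — the product-size logic is what it exercises, not sequence
provenance.

`consensus_with_n()` masks variable alignment columns as N, drops
gap-majority columns, and ignores minority gaps when comparing residues
(a single gapped sequence should not erase an otherwise-conserved
column). `filter_alignment_genes()` keeps a gene only when every gap run
is a multiple of three and at most one sample has gaps — a frameshift and
pseudogene guard for codon alignments.

## Problem sizes

The test and acceptance simulations use 15,000-droplet wells throughout:
100 wells per occupancy level for estimator recovery, 1,000 wells for CI
coverage, 100 seeded series (six levels × two replicates) for linearity
and precision, and 200 runs for spike-recovery coverage. These sizes give
Monte-Carlo error comfortably below the margins being tested (e.g.
binomial SE ≈ 0.7 percentage points on the coverage estimate) while
keeping the full suite in the low minutes on one core.

## Known limitations

- Occupancy→amplitude is binary; partial amplification ("rain") is not
  produced by the default generative model.
- The classifier assumes at most two HEX clusters per FAM stratum; exotic
  multi-target chemistry would need a different geometry.
- Copies/reaction refers to the assembled 20 µL mix (no dead-volume
  correction).
- Reference-gene stability across biological conditions is assumed, not
  tested here.
- The spike-in's absolute input is a calibration parameter; absolute
  efficiencies are only as good as that calibration (relative mode
  avoids this at the cost of absolute interpretability).
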