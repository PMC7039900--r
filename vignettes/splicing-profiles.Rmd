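---
title: "Splicing profiles and aberrant splicing calls from targeted RNA-seq"
author: "spliceprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing profiles and aberrant splicing calls from targeted RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceprofiler)
```

## The problem

Germline variants that disrupt splicing of tumor suppressor genes are a
recognized blind spot of DNA-only panel testing: many land outside the
canonical dinucleotides, receive an inconclusive in-silico prediction, and
stay classified as variants of unknown significance. Targeted (capture)
RNA-seq of whole blood gives direct evidence of the transcript each allele
actually produces, at depths far above whole-transcriptome sequencing.

The difficulty is that "abnormal" splicing is only meaningful against a
baseline: healthy blood expresses a reproducible repertoire of alternative
junctions in these genes, mostly at low levels. `spliceprofiler` implements
the corresponding analysis: it classifies non-canonical splice junctions
relative to one designated reference isoform per panel gene, quantifies each
event as percent spliced in (PSI), aggregates a healthy-control cohort into a
reference splicing profile, and tests each patient sample's events against
that profile, reporting calls that survive effect-size, direction, coverage
and multiple-testing gates.

## Inputs and coordinate conventions

Four inputs drive the pipeline:

1. a GTF/GFF annotation containing, for every panel gene, the single
   reference isoform that defines "canonical" (read with `rtracklayer`);
2. per-sample splice-junction count tables in the familiar 9-column
   aligner dialect (chromosome, first/last intronic base, strand code,
   motif, annotated flag, unique and multimapped read counts, overhang);
3. per-sample per-exon mean-coverage tables (TSV);
4. cohort metadata (sample id, control/patient role, demographics, batch).

All coordinates are 1-based inclusive end to end. Both input dialects (GTF
and the junction tables) already use that convention, so the package performs
no base-shifting at I/O boundaries; junction matching is exact integer
equality on intron endpoints. Exons are numbered 1..n along the reference
isoform in transcript orientation (for minus-strand genes exon 1 is the
interval with the highest genomic coordinate). Where a panel gene has exons
that cannot be analyzed — the classic case is a gene with a nearly identical
processed pseudogene that contaminates short-read alignments — those exons
are listed in the panel configuration as excluded: they remain in the model,
so transcript coordinates are unchanged, but every event whose footprint
touches them is dropped from quantification.

Only uniquely mapping junction reads are counted. The multimapper column is
carried through unmodified but never feeds PSI; uniqueness is the
conservative choice for a clinical assay, where a multimapped split read is
as likely to be pseudogene noise as signal.

## Event taxonomy

Each junction observed in a sample is compared with the reference isoform's
canonical junction set (one junction per adjacent exon pair):

* **ESF** (full exon skipping): both junction ends coincide with canonical
  donor/acceptor boundaries of non-adjacent exons; all intervening exons are
  skipped.
* **ESP** (partial exon skipping): one end canonical, the other strictly
  inside an exon; the truncated portion (plus any fully spanned exons) is
  deleted.
* **IP** (partial intronic insertion): one end canonical, the other strictly
  inside the adjacent intron; the remainder of the intron is retained,
  extending the neighboring exon.
* **IC** (cryptic exon): two junctions within one intron — one leaving the
  canonical donor, one arriving at the canonical acceptor — delimiting a
  non-empty intronic segment included as a novel exon.
* **ES**: a reporting aggregate combining the ESF and ESP events of one exon.

One geometric ambiguity deserves a note: a single junction anchored at a
canonical boundary with its far end inside the intron is indistinguishable
from one half of a cryptic-exon pair. The engine therefore collects such
junctions per host intron first, pairs donor-anchored with acceptor-anchored
candidates whenever the implied exon is non-empty (greedily, in coordinate
order, each junction used at most once), and only the unpaired remainder is
reported as IP. Junctions with both ends inside exons (exitron-like) or with
no canonical anchor at all are set aside as unassigned with a reason — the
taxonomy above has no category for them, and guessing would do more harm
than a logged skip.

Ties always resolve toward the canonical interpretation: a junction end that
coincides exactly with a canonical boundary is treated as canonical, never as
a zero-length truncation.

Frame status is pure arithmetic: an event is in-frame if and only if its net
length change (inserted minus deleted nucleotides) is a multiple of 3.

Events carry deterministic r.-style names: deletions are
`r.<first>_<last>del` over the deleted transcript positions; insertions are
`r.<left>_<right>ins<start>_<end>`, with intronic bases labeled by their
offset from the nearest exon boundary in transcript space (`80+12`,
`81-8`; ties at an intron midpoint take the upstream `+` form). This scheme
reproduces the labels clinicians expect for these events without attempting
full HGVS compliance (no uncertainty syntax, no protein-level consequences).

## PSI

For an event with alternative junction read count $a$ and replaced canonical
junctions with unique counts $c_1, \dots, c_k$,

$$\mathrm{PSI} = 100 \cdot \frac{a}{a + \mathrm{round}\left(\tfrac{1}{k}\sum_i c_i\right)}.$$

"Reads in the region" is the one genuinely under-specified quantity in this
kind of assay, and the choice matters, so it is isolated behind two small
functions (`event_alt_reads()`, `region_reads()`) that can be swapped
wholesale. The mean over the replaced canonical junctions avoids
double-counting canonical molecules that traverse several junctions of a
multi-exon skip, and reduces to the natural $a/(a+c)$ for single-junction
events. For a cryptic exon, $a$ is the rounded mean of its two supporting
junctions and the denominator junction is the host intron's canonical
junction. A denominator of zero reads marks the event not assessable (PSI
`NA`) rather than silently zero. Counted alternatives to this definition —
for example counting every read overlapping the genomic region, including
non-junction exonic reads — would need BAM access, which this package
deliberately does not require.

## The control profile

Samples enter the profile only after coverage QC: at least 85% of the
panel's non-excluded exons must have mean coverage of at least 50 reads
(both thresholds inclusive and configurable; a 17-of-20 sample passes).
Sequencing-run metrics (Q30 fraction > 0.75, mean base quality > 30,
perfect-index fraction > 0.85) are gated from a precomputed metadata table
when available; the package does not recompute them from reads.

Per event, two control summaries are kept, because they answer different
questions:

* **detected-only** median and interquartile range (controls with PSI > 0),
  the natural display statistic for "how strong is this event when it
  occurs";
* **zero-assigned** mean and SD over *all* QC-passing controls (PSI 0 where
  the event was not called), the vector the patient test runs against, since
  absence of the event in a control is evidence, not missing data.

The zero-assigned PSI matrix itself is exported for external clustering or
heatmaps; the package draws nothing.

An event is *common* when its PSI reaches 5 in at least
`floor(0.05 * n_controls)` controls — with 345 controls that is a threshold
of 17 carriers. The floor rule is the default because 17/345 is in fact
4.93%: a strict reading (ceiling, 18 carriers) is available via an argument.
Common-event reporting also includes per-sample event counts (events with
PSI ≥ 5 and region coverage ≥ 50), the Pearson correlation between a gene's
median event count and its exon number (`stats::cor.test`), and pairwise
Welch t tests of event counts between metadata groups — the standard sanity
checks that cohort structure, not biology, is not driving the profile.

## Testing a patient

Each event detected in a patient (PSI > 0) is tested with the one-sample
two-sided t test

$$t = \frac{\bar{x}_{\mathrm{ctrl}} - \mathrm{PSI}_{\mathrm{pat}}}{s_{\mathrm{ctrl}}/\sqrt{n}},\qquad
p = 2\,P\!\left(T_{n-1} \le -|t|\right),$$

against the zero-assigned control vector. An event absent from every control
is tested against an all-zero vector; its variance is zero, and the
degenerate branch reports $p = 0$ with an explicit flag (equality with a
constant control vector reports $p = 1$). This mirrors how control-absent
events are treated as the strongest findings rather than as undefined.

Raw p values are adjusted with the Holm–Šidák step-down: sort ascending,
apply $1-(1-p_{(i)})^{m-i+1}$, enforce monotonicity with a running maximum,
cap at 1, restore input order. The implementation uses
`-expm1(k * log1p(-p))` for numerical stability at small p and is tested to
1e-12 against the naive formula.

The tested family is per patient sample — the clinical reporting unit — and
comprises the events eligible to be reported at all: patient PSI above the
control mean (events *below* control levels are never considered), PSI ≥ 5,
and region coverage ≥ 50 reads. Events outside the family get `NA` adjusted
p. A call is **significant** when all four criteria hold: PSI ≥ 5, PSI above
the control mean, adjusted p < 0.05, region reads ≥ 50.

Cohort-level reporting closes the loop with the diagnostic-yield arithmetic:
with $n_\mathrm{before}$ patients positive on DNA evidence alone and
$n_\mathrm{after}$ after adding RNA evidence, the relative increase is
$100\,(n_\mathrm{after}-n_\mathrm{before})/n_\mathrm{before}$, e.g.
`diagnostic_yield(77, 84)` prints a 9.1% relative increase. Which variants
count as "positive" (and which moderate-risk genotypes are excluded from the
numerator and denominator) is a clinical-judgment input, not something this
package decides.

## The synthetic cohort generator

Because real control cohorts of this kind are access-controlled, every
pipeline stage is validated on synthetic cohorts with known truth
(`simulation_config()`, `simulate_cohort()`). The generator emulates the
structure such data actually has:

* gene models with 8–12 exons of 80–250 nt and introns of 300–3000 nt, one
  gene per chromosome, alternating strands;
* per-region junction depth that is negative-binomial (default mean 500,
  size 8) — overdispersed capture depth is the realistic stressor for the
  50-read coverage gate;
* a common-event catalog of four events per gene on disjoint exons/introns:
  a ubiquitous in-frame 42-nt partial exon skip whose Beta(12, 19) PSI
  distribution has mean ≈38.7% (the "always present, clearly non-zero"
  pattern real panels show), a 30%-frequency full exon skip, a
  15%-frequency frameshifting 8-nt intron retention and a 10%-frequency
  in-frame 63-nt cryptic exon, all at low PSI;
* patient spike-ins: a frameshifting 17-nt partial exon skip absent from
  the control catalog, at true PSI drawn uniformly from 20–60% — the range
  a heterozygous splice-disrupting variant produces in blood;
* carriers drawn per event (Bernoulli in the event frequency), alternative
  reads Binomial(D, PSI/100) in the region depth D, canonical junctions
  receiving D − alt, so the quantifier's estimate is binomial around the
  truth by construction;
* exon coverage tables consistent with junction totals, and optional
  QC-failing samples with 20% of exon depths zeroed.

Random streams are split per sample and per event from the master seed, so
enlarging a cohort never perturbs existing samples, and the same seed always
reproduces byte-identical files. Templates are *realized* by running the
package's own event engine on the implied junctions, so the truth table and
the detector agree on names by construction.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: alignment artifacts and soft-clipping noise,
pseudogene cross-mapping (exclusion lists are applied, not stress-tested),
correlated depth along a transcript, batch effects, degraded-RNA 3' bias,
and events sharing junctions with one another. Results on synthetic cohorts
validate the statistics and the bookkeeping, not the aligner upstream.

## Validation studies and their outcomes

Three seed-reproducible studies ship as package functions:

* `psi_recovery_study()` — 200 controls × 20 events at 500× negative-
  binomial depth: the PSI estimate falls within two binomial standard
  errors of the truth in ≈98% of quantifiable event-sample cells (≈95% of
  carrier cells alone, i.e. nominal two-sigma coverage).
* `spikein_power_study()` — spiked events at true PSI 30 and 200× coverage
  against 100 controls lacking the event are called significant in
  effectively every replicate; detectability is monotone in coverage and
  true PSI.
* `null_calibration_study()` — patients drawn from the same population as
  the controls. Here the measured significant-call rate among gate-passing
  events is far above the nominal 0.05 (≈0.5 in the default
  configuration), and this is a property of the published statistic, not of
  the implementation (which matches `stats::t.test` to 1e-10): the
  one-sample t test treats the patient's measured PSI as a fixed
  hypothesized mean. When the patient is in truth exchangeable with the
  controls, the numerator of $t$ carries the patient's own sampling noise,
  while the denominator scales it by $\sqrt{n}$ — so $t$ has standard
  deviation near $\sqrt{n+1}$ under the null, and grows *less* calibrated
  as the control cohort grows. See Limitations.

## Numerical and design choices

* Coordinates are kept 1-based inclusive internally (the convention of both
  input dialects and of R's genomic ecosystem) rather than converting to
  0-based half-open and back; with exact integer matching on intron
  endpoints there is no interval arithmetic left to get wrong.
* Canonical support is `round(mean(...))` of the replaced junctions; R's
  banker's rounding is applied and PSI is compared unrounded downstream
  (tables print 2 decimals).
* `floor` vs `ceiling` for the common-event carrier threshold: floor by
  default, as discussed above.
* Quantile type for the detected-only IQR is R's default (type 7).
* Degenerate inputs: single-exon genes load with a warning and produce no
  junctions; profiles require ≥ 2 controls; zero-variance control vectors
  take the flagged degenerate branch; a zero-read region is `NA`, never 0.
* Events supported by fewer than one unique read are not emitted (PSI 0 is
  equivalent to absence).
* The tested family includes the PSI and coverage gates (not only the
  direction filter): adjusting over events that could never be reported
  would only dilute the correction.
* Problem sizes in the validation studies (200×20 recovery cells, ~1200
  gate-passing null tests, 200 power replicates, 100 random models) were
  chosen so each study's Monte-Carlo error is small relative to the margin
  being checked while the full suite stays interactive.

## Limitations

* The aberrant-splicing test is an outlier test dressed as a location test.
  A calibrated alternative would compare the patient value against the
  control *predictive* distribution — e.g.
  $t = (\bar{x} - x_{\mathrm{pat}})/(s\sqrt{1 + 1/n})$ — or model counts
  directly (beta-binomial). This package implements the published
  procedure; in practice its specificity comes from the effect-size gates
  and from true pathogenic events lying far outside the control range
  (degenerate $p \approx 0$), not from the nominal type-I error of the t
  test. Treat adjusted p values as a ranking, not a calibrated error rate.
* Only one reference isoform per gene defines "canonical"; junctions of
  other annotated isoforms are deliberately reported as events with
  measurable PSI.
* The PSI denominator counts junction reads only, not all reads overlapping
  the region; with capture data and the mean-of-replaced-junctions rule the
  two differ little, but they are not identical.
* No batch correction is applied; the group-comparison utilities are meant
  to *demonstrate* its absence of need on a given cohort, not to fix it.
* Multimapped junction reads are ignored by design; genes with pervasive
  pseudogene homology need exclusion lists, as the panel configuration
  supports.
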