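---
title: "Detecting pre-accommodation ribosome pausing from length-stratified footprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pre-accommodation ribosome pausing from length-stratified footprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribopause)
library(data.table)
```

## The model

Ribosome profiling footprint length reports the conformational state of the
elongating ribosome. A ribosome whose A-site is empty — waiting for
aminoacyl-tRNA delivery — protects a short fragment with a mode near 21 nt;
after accommodation the same ribosome protects a long fragment with a mode
near 29 nt. The dwell time of a ribosome at a codon is proportional to the
number of footprints sampled there, so a shortage of one aminoacyl-tRNA
species raises the A-site frequency of its cognate codons *specifically in
the short-footprint population*: the ribosome waits longer pre-accommodation
but is unaffected once the tRNA is bound. The analysis chain in this package
is built around that contrast.

The occupancy statistic is deliberately simple. For reads of an admitted
length $L$, the P-site nucleotide is the 5′ end plus a per-length offset;
the P-site codon index is the floor of $(\text{P-site nt} -
\text{cds\_start})/3$ and the A-site codon is the next one. Counts over the
64 codons are normalized within each (site, length, sample) stratum to
frequencies $f_c = n_c / \sum_{c'} n_{c'}$, replicate frequencies are
averaged per condition, and conditions are compared as per-codon ratios.
Since codon usage appears in both numerator and denominator, it cancels: a
codon family with dwell multiplier $f$ and aggregate A-site usage $u$ has
expected frequency ratio

$$ \frac{f}{1 + u\,(f-1)} , $$

which for $f = 2$, $u = 0.01$ is $2/1.01 = 1.9802$ — the analytic anchor
used throughout the tests.

Choices worth making explicit:

* **P-site, not A-site, offsets.** One offset convention (5′ end to first
  P-site nucleotide) serves both footprint populations, because the
  open-A-site species loses nucleotides at its 3′ end — its 5′ geometry is
  unchanged. The A-site codon is always P + 1.
* **Floor-division assignment, no frame rejection.** Out-of-frame reads are
  assigned to the codon containing their P-site nucleotide. Periodicity is
  enforced upstream, by admitting only read lengths whose frame structure
  is clean; re-filtering per read would double-count the same evidence.
* **Stop codons count in the A-site only.** The last admitted P-site index
  is $n_\text{codons} - 2$, so the A-site ranges over all 64 codons
  (terminating ribosomes exist) while the P-site is always a sense codon.
  Tables still span 64 rows in both sites; stop P-site rows are
  structurally zero.
* **Ratios with zero denominators are flagged `undefined`, not padded.**
  At the read depths this package targets every observable codon is
  observed; epsilon-padding would silently bias rare strata.
* **Replicate aggregation** defaults to the arithmetic mean of
  per-replicate frequency vectors (a mean of triplicates); pooling counts
  across replicates before normalizing is available as
  `aggregate_condition(..., method = "pooled_counts")`. Both keep each
  stratum summing to 1; with balanced replicates they differ negligibly.

## P-site offset calibration

Offsets are inferred from start-codon metagenes: initiating ribosomes
pile up with the AUG in their P-site, so for each read length $L$ the
count of 5′ ends at relative position $-o$ peaks at the true offset. The
inferred offset is the $\arg\max$ over candidates $o \in [6, L-6]$ (edge
offsets are geometrically impossible for genuine footprints), with ties
broken toward the smaller offset so the rule is deterministic. Lengths with
fewer than `min_reads` (default 200) reads in the $[-40, -1]$ upstream
window are omitted rather than guessed; any downstream lookup of an omitted
length is a hard error. "CDS-mapped" is operationalized as: histogram reads
whose 5′ end lies in $[\text{cds\_start} - 30, \text{cds\_end})$; occupancy
reads whose P-site nucleotide lies inside the CDS.

## What the simulator emulates

`simulate_library()` draws each footprint in three steps, per condition:

1. **(position, state)** sampled with probability proportional to
   $\text{prior}(s) \times \text{pause factor}(s, \text{A-site codon})
   \times \text{start enrichment}$, where the open-state prior `p_open`
   defaults to 0.4 (a visibly bimodal length histogram) and positions run
   over every P-site sense codon of every transcript.
2. **length** from the state-conditional distribution: 20–22 nt (mode 21)
   open, 27–30 nt (mode 29) occupied.
3. **5′ end** at P-site codon start − 12 nt, then ±1-nt jitter with
   probability 0.1 (split evenly), giving ~90% in-frame reads. Reads
   falling outside their transcript are resampled, not clamped, to avoid
   boundary pile-ups.

Two modelling choices go beyond that skeleton, both motivated by features
every real Ribo-seq library shows:

* **Start-codon enrichment** (`start_enrichment`, default 5) multiplies the
  dwell weight of the position with the start codon in the P-site. Without
  it a uniform-position sampler spreads upstream metagene mass equally over
  $-12, -9, -6$ and the offset $\arg\max$ is undefined up to noise; real
  metagenes have a dominant initiation peak, and the offset-calibration
  module needs one to be meaningfully exercisable. The analytic oracle
  enumerates the same weights, so no test silently benefits.
* **End-trimming heterogeneity for non-modal lengths.** A 20-nt open-state
  footprint is a 21-mer trimmed by one extra nucleotide, equally likely at
  either end (binomial split of the length difference). Consequently only
  the modal lengths — 21 and 29 nt — have single-frame 5′ ends; the
  flanking lengths carry ~50/50 frame mixtures and are correctly rejected
  by periodicity selection at the default dominance threshold of 0.6,
  mirroring the decision to analyze exactly 21- and 29-nt fragments in
  practice. Had all lengths shared the clean 5′ model, every length would
  pass selection and the length filter would be vacuous.

The simulated stop codon is always TAA; TAG and TGA therefore have zero
frequency in every stratum (their table rows exist, their ratios are
flagged undefined). Size selection defaults to the 15–35 nt window used at
library preparation.

**What the simulator does not emulate:** sequencing errors, ligation and
nuclease sequence biases, multi-isoform genes, uneven transcript abundance
beyond uniform coverage, contaminant reads, and any initiation/termination
kinetics beyond the single start-enrichment factor. Passing tests therefore
demonstrate that the analysis chain recovers known parameters from data
generated under its own assumptions — a necessary, not sufficient,
condition for correctness on biological libraries.

## The analytic oracle

`expected_site_frequencies()` enumerates every candidate (position, state)
pair with its exact sampling weight and applies the jitter model
analytically: a −1 nt shift moves the assigned P-site codon one codon
upstream under floor division (reads jittered upstream of codon 0 are
excluded, exactly as assignment excludes them), while 0/+1 shifts leave the
assignment unchanged. Length strata mix the two states through the
state-conditional length distributions. The result is exact for the modal
lengths — the strata that survive periodicity selection — and is the
reference for the simulator's parameter-recovery tests: empirical
frequencies are multinomial around the oracle values, so agreement within
4 Monte-Carlo standard errors for ≥95% of codons is the acceptance
property.

## Numerical and degenerate-input behaviour

Probability vectors must sum to 1 within $10^{-9}$; stratum frequencies sum
to 1 within $10^{-12}$ by construction. Empty libraries give empty
histograms with absent modes; empty strata are excluded from normalization
(never divided); an empty periodic-length selection is a hard error with
advice rather than a silent empty analysis. All randomness flows through
explicit seeds (`withr::local_seed`), so identical (inputs, config, seed)
give byte-identical outputs, including written TSVs.

## Problem sizes

The defaults — 50 transcripts × 300 sense codons, $10^5$ reads per library
— were chosen so that every per-codon stratum count is large enough for
stable frequencies (rare glycine codons at usage 0.01 still collect
hundreds of reads per stratum) while a full 6-sample experiment at
$5 \times 10^5$ reads per sample runs in well under a minute on one CPU.
The parameter-recovery analyses in the test suite use those sizes; the
glycine-pause experiment is simulated once and shared across its
assertions.

## Orchestration

`run_pipeline()` is a single-command driver over the exported functions:
simulate or load, size-select, histogram, calibrate offsets on the pooled
library, compute frame fractions, select periodic lengths, assign sites,
count, normalize, aggregate, compare — writing TSVs, a JSON summary and a
YAML config snapshot when an output directory is given, and a per-sample
read-accounting table in which every discarded read is attributed to
exactly one filter (checked, not assumed: non-monotone or non-balancing
counts are errors). The package deliberately ships no shell executable:
its users drive analyses from R, and the function surface plus this
vignette are the interface; `scripts/acceptance.R` shows the canonical
end-to-end invocation.

## Known limitations

* One transcript model per gene; no genome-space coordinates, spliced
  mapping, or multi-mapping disambiguation (uniquely mapped transcript-space
  input is assumed).
* Offsets are calibrated from the pooled library, not per sample; samples
  with genuinely different digestion geometries would need per-sample
  calibration.
* No significance testing of per-codon ratios — the statistic is the ratio
  itself, with Monte-Carlo envelopes available from the simulator when
  needed.
* The two-state model is a deliberate simplification: real libraries
  contain intermediate lengths from partial digestion that are neither
  state cleanly.
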