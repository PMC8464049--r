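# ribopause

Read-length-stratified codon occupancy analysis for ribosome profiling
(Ribo-seq), built to detect codon-specific ribosome pausing and to tell
*pre*-accommodation from *post*-accommodation pausing.

## The science

During elongation, a ribosome waiting for its aminoacyl-tRNA (an **open
A-site**) protects a short mRNA footprint (~21 nt), while a ribosome that has
already accommodated the tRNA (**occupied A-site**) protects a long footprint
(~29 nt). If a specific aminoacyl-tRNA is scarce — e.g. glycyl-tRNA when a
mutant glycyl-tRNA synthetase sequesters it — ribosomes pause with the
cognate codons in the A-site *before* accommodation, and the enrichment
appears specifically in the A-site of short footprints.

The core statistic: footprints are assigned P- and A-site codons via
per-length P-site offsets calibrated from start-codon metagene peaks; codon
counts are normalized **within each (site, read length, sample) stratum**,

&nbsp;&nbsp;&nbsp;&nbsp; f<sub>c</sub> = n<sub>c</sub> / Σ<sub>c′</sub> n<sub>c′</sub> ,

averaged across replicates per condition, and compared between conditions as
per-codon frequency ratios f<sub>c</sub><sup>mut</sup> / f<sub>c</sub><sup>wt</sup>.
Because codon usage cancels in the ratio, a codon family with an elevated
dwell time of factor *f* and aggregate A-site usage *u* has expected ratio
*f* / (1 + *u*(*f* − 1)).

The package also ships a two-state dwell-time footprint **simulator**:
(position, state) pairs are sampled proportionally to
`state prior × dwell multiplier of the A-site codon`, footprint lengths come
from state-conditional distributions (modes 21/29 nt), 5′ ends sit at
`P-site − 12 nt` with 1-nt jitter, and an analytic oracle
(`expected_site_frequencies()`) gives the exact expected occupancy tables
for any configuration — so pause recovery is testable against ground truth.

## Worked example

Simulate a glycine-shortage experiment (3 wild-type + 3 mutant replicates;
glycine-family usage 0.01; mutant doubles the open-state glycine dwell) and
run the full pipeline:

```r
library(ribopause)
gly <- codon_family("G")                      # GGA GGC GGG GGT
sim <- sim_config(
  n_reads      = 5e5,
  codon_usage  = codon_usage_with_family(gly, 0.01),
  pause_factors = pause_factors("G240R", "open", gly, 2))
design <- data.frame(condition = rep(c("WT", "G240R"), each = 3),
                     replicate = rep(1:3, 2))
run <- run_pipeline(run_config(design, sim = sim, seed = 1))
run$group_ratios
#>      site length group_mean_ratio group_mean_diff
#>    <char>  <int>            <num>           <num>
#> 1:      A     21        1.9672122    2.187029e-03
#> 2:      A     29        1.0084571    4.041479e-05
#> 3:      P     21        0.9598158   -8.644789e-05
#> 4:      P     29        0.9811624   -3.322036e-05
```

Reading the output: the glycine-family mean frequency ratio (mutant/WT) is
**~2 in the A-site of 21-nt footprints** — ribosomes pause about twice as
long at glycine codons pre-accommodation — while 29-nt footprints and both
P-site strata stay at ~1: the pause is localized to the open-A state, the
signature of an aminoacyl-tRNA supply defect. The four top-shifted codons
are exactly the glycine family:

```r
rank_codon_shifts(run$ratios[["A_21"]], 4)[, .(codon, ratio)]
#>     codon    ratio
#> 1:    GGT 2.021829
#> 2:    GGA 2.015201
#> 3:    GGC 1.989544
#> 4:    GGG 1.842275
```

QC outputs: `length_histogram()` (bimodal 21/29 peaks),
`metagene_start_profile()` (peak at −12 → P-site offset),
`frame_fractions()` / `select_periodic_lengths()` (only 21 and 29 nt show
clean 3-nt periodicity and are admitted).

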