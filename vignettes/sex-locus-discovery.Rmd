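---
title: "Locating a young sex locus: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating a young sex locus: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexscan)
```

## The problem

In many fish, sex chromosomes are evolutionarily young: X and Y recombine
over almost their whole length and differ only in a small region around
the master sex-determining gene. Standard karyotyping or coverage-based
sex-chromosome detection fails there — the Y is neither degenerate nor
large. What remains detectable is (i) a local excess of positions
heterozygous in all males but homozygous in all females, (ii) a short
stretch of Y-only sequence with no female coverage and half-normal male
coverage, and (iii) RAD markers that co-segregate with phenotypic sex in
a family. `sexscan` implements these three detectors plus the simulator
used to validate them.

## Pool-seq model

Both sexes are sequenced as pools (defaults assume 30 + 30 individuals).
At a site with per-pool depths $d_m, d_f$ and allele read counts, the
male pool of an XY species is a 1:1 mixture of X and Y haplotypes, so a
site divergent between X and Y has expected alternative-allele frequency
$0.5$ in the male pool and $0$ (or $1$) in the female pool. The
classifier calls a *male-specific SNP* (MSS) when

* both pools reach `min_depth` (default **10** reads);
* the male pool carries exactly two alleles, each at frequency within
  `freq_het ± range_het` (default **0.5 ± 0.15**);
* the female pool's majority allele has frequency within
  `[freq_hom − range_hom, freq_hom]` (default **[0.95, 1]**; the window
  is truncated at 1 because frequencies cannot exceed it).

Two choices here were genuinely open and are resolved as follows. The
"exactly two alleles" rule is strict: a single read of a third allele
disqualifies the site. This costs a little sensitivity at high depth
(an error-bearing read vetoes an otherwise clean site) but is exactly
reproducible and keeps the false-positive rate of the scan near zero,
which matters more for a region-delimitation method than per-site power.
Second, N and deletion counts are carried through the sync records but
never enter depth or frequency arithmetic, matching the usual semantics
of pooled count files.

Per-base differentiation is summarised by a Nei-type fixation index on
the two pools' allele-frequency vectors,
$F_{ST} = (H_t - H_s)/H_t$ with $H_s$ the mean within-pool expected
heterozygosity and $H_t$ that of the averaged frequencies, clamped to
$[0,1]$ and defined as 0 when $H_t = 0$. No pool-size correction is
applied: within this pipeline $F_{ST}$ ranks windows and flags outliers
rather than estimating demographic parameters, and an uncorrected
estimator keeps the statistic a deterministic function of the counts.
`classify_sites(..., fst_fun = )` accepts any replacement estimator with
the same signature, so a pool-size-corrected variant can be swapped in.

Windows tile each contig from position 1; the genome-wide scan uses
50-kb non-overlapping windows and the fine pass 2.5-kb windows. When a
step smaller than the window is requested, the step must divide the
window size (the implementation aggregates step-sized bins and
rolling-sums them; the standard configurations are non-overlapping
anyway). Terminal windows keep their true width, so density comparisons
should divide by `width`. Ties for "window of maximum count" resolve to
the smallest (contig, start).

Region delimitation (`delimit_enriched_region`) merges runs of windows
with at least `threshold` sex-specific SNPs, tolerating up to `max_gap`
consecutive sub-threshold windows inside a run; bounds span from the
first to the last above-threshold window. The scan defaults used in the
validation are threshold 5 with `max_gap` 1 at 50 kb, and threshold 3
with `max_gap` 2 at 2.5 kb: at 50× depth and divergent-site density
0.005/bp a 2.5-kb window inside the locus carries ≈ 11 detectable MSS,
so threshold 3 keeps single-window dropouts rare while background
windows (which essentially never reach 2 MSS) stay excluded; the larger
gap tolerance at fine resolution bridges the occasional Poisson-thin
window without extending boundaries by more than one window.

## Y-specific coverage model

Sequence present only on the Y haplotype shows two coverage signatures
when pools are aligned to a male-derived assembly: windows covered by
male reads only (male mean depth strictly above 10, female depth exactly
zero — "MR1k" at the 1-kb scan size), and hemizygous windows at half
coverage (male relative coverage within the closed interval
$[0.3, 0.7]$, female absolute coverage below 1). "No aligned reads in
females" is evaluated as zero female depth summed over the window; with
per-position count input, zero total depth is equivalent to no
overlapping read. Relative coverage divides by the pool's genome-wide
mean depth over all tiled positions, zero-depth positions included, so a
contig-scale duplication inflates the denominator rather than silently
rescaling single windows. Flagged windows merge into segments within
`max_gap` bp and the segment lengths sum to the Y-specific total. The
method presumes the alignments feeding the sync file were filtered to
proper pairs of decent mapping quality; with permissive mapping,
cross-mapped female reads will erase MR1k calls.

## RAD family panel

Markers are groups of reads with identical sequence — deliberately no
similarity clustering, so a polymorphic locus splits into one marker per
allele and every marker is non-polymorphic, making presence/absence
comparable across individuals. Presence requires depth ≥ 5 (inclusive;
the same threshold applies to parents and offspring). The sex bias of a
marker is $S = M/M_{TOTAL} - F/F_{TOTAL}$; in a family design (metadata
declaring a sire and a dam) the totals count offspring only, so $S$
measures segregation: a fully Y-linked marker has $S = 1$. Parental
origin is assigned for markers present in at least 10 individuals:
dam-only → maternal, sire-only → paternal, both → nonspecific. Each
marker is tested against sex with a two-sided Fisher's exact test;
a Bonferroni-adjusted column accompanies the raw p-values, as is
conventional for marker tables, with the raw values retained for
plotting. Genomic positions for the segregation profile are supplied
externally (marker alignment is upstream of this package).

## 2×2 tests

`fisher_exact` uses the point-probability two-sided convention — the sum
of hypergeometric probabilities of all tables (margins fixed) no more
probable than the observed one, with a relative tie tolerance of 1e-7 —
computed entirely in log space, so tables like 157/4/0/60 yield usable
log-p (≈ −49) instead of underflow. `chisq_yates` applies the
continuity correction with the $\max(|O-E| - 0.5,\, 0)$ floor and
reports the upper chi-square tail with 1 df, also as log10; the
correction is on by default because 2×2 phenotype tables at these sample
sizes are exactly where it matters, and `correct = FALSE` is available.
Bounds such as $p < 2.2\times10^{-16}$ are checked on log-p.
`manhattan_table` transforms p to $-\log_{10} p$ and caps underflowed
values at 320 with an explicit flag.

## The simulator

`sim_config()` fixes the study conditions the detectors are validated
under: a 10-Mb genome (two 4-Mb autosomes plus a 2-Mb sex contig), a
300-kb differentiated interval at LG24:720,001–1,020,000 with
divergent-site probability 0.005/bp, pools of 30 + 30 at mean depth 50×
per pool, shared-SNP density 0.002/bp with population frequency uniform
on (0.05, 0.95), and sequencing error 0.002 per read base landing
uniformly on the other three nucleotides. The coverage validation plants
a 180-kb Y insertion on a 2-Mb scaffold at 40× with female depth zero
inside it. The family panel has 37 male and 41 female offspring; Y-linked
paternal markers sit at recombination fractions 0–0.5 from the sex locus
(200 markers per distance), with 300 maternal and 200 nonspecific
markers; marker depth is Poisson with mean 10, so a carrier drops below
the presence threshold with probability ≈ 0.03 — visible as
$\bar{|S|} \approx 0.97$ rather than 1 at zero recombination. Where the
data the package emulates did not pin a value (error rate, SNP density,
marker depth) these defaults were chosen once as typical of Illumina
pool-seq and RAD experiments in fish and are not tuned thereafter.

By default the male pool's Y-divergent allele frequency is exactly 0.5
(pool composition, not sampled); `finite_pool = TRUE` adds a binomial
resampling layer over the 2n chromosomes of each pool for studying
pool-size noise. Read-level realism is intentionally minimal — no
quality strings, indels or PCR duplicates — because every in-scope
method consumes counts or exact sequences; simulating alignment would
validate nothing this package does. Consequently, passing recovery tests
demonstrates correctness of the statistics and window logic under the
stated sampling model, not robustness to mismapping, reference bias,
batch effects or allele-specific amplification in real libraries.

Map-filter validation needs exact, not probabilistic, truth:
`simulate_map_loci` therefore fixes the genotype-class counts of each
tagged locus deterministically (a 1:1 locus in 78 offspring is exactly
39/39) and randomises only the assignment of genotypes to individuals.
Each tag then has a provable fate under the six-rule filter, and the
per-rule removal counts must match truth exactly — which the acceptance
checks assert.

One root seed drives everything; per-generator streams derive as
`seed*7 + offset` (pools 0, family 1, map loci 2) so datasets can be
regenerated independently.

## Numerical and degenerate-input choices

* Sync positions are 1-based inclusive; window arithmetic is internally
  0-based half-open; BED export converts explicitly.
* A window with no sites reports zero coverage and undefined (NA) mean
  $F_{ST}$; low-depth sites never contribute to $F_{ST}$ averages.
* `fisher_exact` on an all-zero table returns 1; `chisq_yates` with a
  zero expected count returns an undefined statistic with p = 1 and a
  warning.
* Rule 3's heterozygosity bounds are exclusive ("higher than 0.66 or
  lower than 0.33"), so boundary values survive; rule 5's windows are
  inclusive. Heterozygosity uses non-missing offspring only. A
  homozygote-class count of zero fails rule 5's ratio window outright.
* "Fewer than half the offspring" uses strict inequality on the declared
  offspring count (78 → dropped when < 39).
* Mapping exports are byte-stable: individuals sorted by id, missing
  token fixed, no timestamps (provenance headers carry the version and a
  parameter hash instead).

## Problem sizes used in validation

The shipped checks run the pool scan at 10 Mb / 50× (about a minute of
simulation plus classification), the coverage scan at 10 Mb / 40×, the
family panel at 1,400 markers × 80 individuals, the exact-test
enumeration over all 46,375 tables with $N \le 30$, and the map filter
at 280 loci × 78 offspring — sizes at which every stochastic acceptance
property has comfortable statistical margin while a full run stays
within a few minutes on one CPU.

## Known limitations

* The scan assumes one male pool and one female pool; designs with
  replicate pools need external merging.
* Grouping of adjacent sex-specific SNPs (an option in some pool-seq
  scanners) is not implemented: every qualifying site counts once.
  Counts made with SNP grouping enabled will differ slightly.
* The strict third-allele veto makes per-site sensitivity fall slowly
  with depth at realistic error rates (≈ 10% of truly divergent sites
  are vetoed at 50× and error 0.002); window-level recovery is
  insensitive to this, but per-site MSS totals are conservative.
* Fisher tests are on marker presence, not allelic counts; with
  genotype-level SNP data an allelic test will give different p-values.
* The simulator's uniform error and coverage models do not emulate GC
  bias, repeats or paralogy — the classic sources of false MR1k windows
  in real assemblies.
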