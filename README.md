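# sexscan

Sex-locus discovery from pooled and RAD sequencing data, for geneticists
working on species with young, largely undifferentiated sex chromosomes
(male-heterogametic XY systems). The package locates the small genomic
region where X and Y differ by combining three signals, each computable
from short-read data without a phased assembly:

1. **Pool-seq sex-specific SNP scan.** From a male pool and a female pool
   aligned to a reference, a position is a *male-specific SNP* (MSS) when
   the male pool is heterozygous — exactly two alleles, both with
   frequency in 0.5 ± 0.15 — while the female pool is homozygous
   (majority-allele frequency in 1 ± 0.05), at a minimum depth of 10 per
   pool. MSS density and a per-base between-sex
   F<sub>ST</sub> = (H<sub>t</sub> − H<sub>s</sub>)/H<sub>t</sub>
   (Nei-type, on pool allele frequencies) are aggregated in genomic
   windows (50 kb genome-wide, 2.5 kb for fine delimitation) and enriched
   regions are merged and delimited.
2. **Y-specific coverage scan.** On a male-derived assembly, 1-kb windows
   with male mean depth > 10 and *no* female reads (MR1k), and windows
   with male relative coverage in [0.3, 0.7] and female absolute coverage
   < 1 (the hemizygous half-coverage signature), mark Y-specific
   sequence; merged segments are totalled into an estimate of the
   Y-specific length.
3. **RAD marker segregation in a family panel.** Reads with identical
   sequence form non-polymorphic markers; a marker's sex bias is
   S = M/M<sub>TOTAL</sub> − F/F<sub>TOTAL</sub> (presence = depth ≥ 5),
   with parental origin assigned from presence in sire/dam, and a
   two-sided Fisher's exact test per marker against sex.

A six-rule filter prepares polymorphic RAD loci for linkage-map building,
and exact/χ² 2×2 association tests (log-space tails, Yates correction)
cover genotyping and phenotype tables. A seeded simulator
(`simulate_pools()`, `simulate_family()`, `simulate_map_loci()`)
generates all of these inputs with planted sex-locus structure and
machine-readable truth, so the whole pipeline is validated by parameter
recovery without any external data.

## Worked example

Plant a 300-kb X/Y-differentiated region in a 10-Mb genome, scan it, and
delimit it:

```r
library(sexscan)

cfg <- sim_config()            # 10 Mb; locus at LG24:720,001-1,020,000
sim <- simulate_pools(cfg, seed = 1)
calls <- classify_sites(sim$sites)          # per-site MSS/FSS calls + FST
w <- window_scan(calls, window_config(50000),
                 contig_lengths = sim$contig_lengths)
w[which.max(w$n_mss), c("contig", "start", "end", "n_mss")]
#>    contig  start    end n_mss
#> 1:   LG24 750001 800000   241

delimit_enriched_region(w, "n_mss", threshold = 5, max_gap = 1)
#>    contig  start     end n_windows total
#> 1:   LG24 700001 1050000         7  1354
```

The peak 50-kb window (241 MSS against a genome background of ~0) falls
inside the planted locus, and the delimited region 700,001–1,050,000
brackets the true 720,001–1,020,000 interval to within one window; a
2.5-kb rescan (`window_config(2500)`, threshold 3, max_gap 2) recovers
the boundaries exactly. For the association side:

```r
chisq_yates(matrix(c(10, 0, 5, 19), 2, byrow = TRUE))$p.value
#> [1] 0.0001147543
fisher_exact(c(157, 4, 0, 60), log10_p = TRUE)
#> [1] -49.09957
```

the first being a Yates-corrected χ² on a 10-vs-24 phenotype table, the
second the log10 Fisher p of a 161-male/60-female presence table.

## Scope

Upstream steps (demultiplexing, alignment, stack building, sync
generation from BAM) and downstream map ordering or annotation are out of
scope: the package starts from sync files, read files plus metadata, and
genotype tables, and ends at window/region tables, BED segments,
sex-bias profiles, map-ready genotype exports and Manhattan tables. See
`vignettes/sex-locus-discovery.Rmd` for the models, parameter choices and
limitations.
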