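# nomepipe

Downstream analysis of **NOMe-seq** (nucleosome occupancy and methylome
sequencing) with companion RNA-seq procedures, for researchers studying
epigenetic regulation — originally motivated by multi-omics profiling of
hypertrophic myocardium, but applicable to any NOMe-seq experiment.

NOMe-seq treats nuclei with the GpC methyltransferase M.CviPI before
bisulfite conversion, so a single molecule reports two signals that separate
purely by trinucleotide context:

* **WCG** (W ∈ {A,T}) — endogenous CpG methylation;
* **GCH** (H ∈ {A,T,C}) — M.CviPI footprints, i.e. chromatin accessibility;
* **GCG** / **CCG** — ambiguous or off-target-prone, excluded from both.

On top of that separation the package implements:

* **DMR calling** — 300 bp windows, per-sample mean WCG level (≥ 3 sites at
  ≥ 3× coverage), two-tailed Student's *t* test, Benjamini–Hochberg FDR;
  windows with |Δ| > 0.20, p ≤ 0.05 and FDR ≤ 0.05 merge within 300 bp into
  directional DMRs.
* **NDR calling** — 100 bp windows sliding by 20 bp, pooled GCH counts
  tested against the genomic background by a 1-df chi-squared
  (χ² = Σ (Oᵢ−Eᵢ)²/Eᵢ, p ≤ 10⁻¹⁰); merged candidates need ≥ 5 GCH sites and
  ≥ 140 bp; multi-intersection group merging with 10 bp connection;
  promoter-proximal (TSS −1 kb/+0.5 kb) vs distal classification.
* **Expression procedures** — RPKM, a documented NB-Wald stand-in for the
  (log2FC, p) contract of count-based DE tools, biotype-aware DEG gates
  (|log2FC| > 0.5, FDR ≤ 0.05, RPKM > 1 coding / > 0.1 lncRNA), lncRNA–coding
  *cis*-pairs (r ≥ 0.6, p ≤ 0.05, ≤ 100 kb), isoform ratios (e.g.
  MYH7/MYH6), fetal-gene-program construction and drug-reversal fractions.
* **A seeded synthetic-data generator** producing genomes, per-cytosine call
  tables and expression counts with truth tables for every planted feature.

## Worked example

Simulate a 0.5 Mb genome with 30 planted accessible regions and 25 planted
methylation shifts, then call NDRs and DMRs:

```r
library(nomepipe)

cfg <- sim_config(seed = 42, genome_length = 5e5, n_ndr = 30, n_dmr = 25,
                  depth = 20, n_per_group = 4)
sim <- simulate_genome(cfg)
calls <- simulate_calls(cfg, sim)

s1 <- calls$samples$group1[[1]]
gch <- filter_sites(s1, "GCH")
cat("GCH sites at >=3x:", nrow(gch),
    " global accessibility:", round(global_level(gch), 3), "\n")
#> GCH sites at >=3x: 32094  global accessibility: 0.157

head(call_sample_ndrs(s1, c(chrS = cfg$genome_length)), 3)
#>   chrom start   end n_gch_sites     level background       chi2_p
#> 1  chrS 11460 11740          20 0.3762188   0.157281 1.255065e-32
#> 2  chrS 18340 18800          28 0.3953351   0.157281 2.456573e-56
#> 3  chrS 46740 47200          26 0.4681223   0.157281 6.160763e-83

res <- call_dmrs(calls$samples$group1, calls$samples$group2,
                 c(chrS = cfg$genome_length))
head(res$dmrs, 3)
#>   chrom start   end n_windows      delta direction
#> 1  chrS 17100 17700         2 -0.2903162      hypo
#> 2  chrS 26700 27600         3  0.2748260     hyper
#> 3  chrS 53100 54000         3 -0.3009728      hypo
```

Each NDR row is a merged accessible region: its mean GCH site level
(`level`) against the sample's global background, the pooled-count
chi-squared p over the merged span, and the distinct GCH site count. Each
DMR row spans its constituent significant windows with their mean level
difference (group 1 − group 2) and direction. All coordinates are 0-based
half-open.

Real data enter through `read_cytosine_report()` (Bismark cytosine-report
or `.cov` dialects), `annotate_contexts()` with a reference FASTA via
`classify_contexts()`, and `read_genes()` (BED-like TSV or GTF).

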