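---
title: "Methods: separating methylation from accessibility in NOMe-seq and the downstream callers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: separating methylation from accessibility in NOMe-seq and the downstream callers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The measurement model

NOMe-seq treats intact nuclei with the GpC methyltransferase M.CviPI before
bisulfite conversion. After conversion, a single molecule carries two
orthogonal signals, separable purely by trinucleotide context:

* **WCG** (A/T, then C, then G): CpG sites that no GpC overlaps. Methylated
  calls here report endogenous DNA methylation.
* **GCH** (G, then C, then A/T/C): GpC sites that no CpG overlaps.
  Methylated calls report M.CviPI activity, i.e. chromatin accessibility —
  nucleosome-free DNA is methylatable, wrapped DNA is not.
* **GCG** is ambiguous between the two signals, and **CCG** is prone to
  M.CviPI off-target activity at CC dinucleotides. Both are classified but
  excluded by every downstream filter. We classify rather than drop them so
  QC can report class counts per sample.

Classification uses only the reference trinucleotide (the standard choice
for Bismark-derived call tables); both strands are classified, a reference
guanine being a reverse-strand cytosine read through the reverse-complement
trinucleotide. Cytosines adjacent to `N` or a contig end go to `OTHER`. The
level of a covered site is `meth / (meth + unmeth)`; sites below **3x
coverage** are discarded, and any region-level quantity is defined only when
the region holds at least **3 qualifying sites** — below that the level is
reported as missing, never imputed.

All tables inside the package use 0-based half-open (BED-compatible)
coordinates; the readers in `read_cytosine_report()` are the only place
on-disk conventions (1-based cytosine reports) are translated.

# Differentially methylated regions

The genome is tiled into **300 bp windows**; each sample's window value is
the unweighted mean of its per-site WCG levels (at least 3 sites, else
missing). Windows are tested between the two groups with a two-tailed
equal-variance Student's *t* test, dropping missing samples per window and
requiring at least two values per group (a *t* test needs a variance; a
Welch variant sits behind `var_equal = FALSE`). Benjamini–Hochberg
adjustment runs over all windows with a valid test — untested windows have
no p-value and do not enter the FDR universe. A window is differentially
methylated when the absolute group difference **exceeds 0.20** (strict
inequality), **p ≤ 0.05** and **FDR ≤ 0.05**; same-direction windows within
**300 bp** merge into DMRs. Opposite directions never merge, so hyper- and
hypomethylated DMR sets are disjoint by construction.

Mean-of-site-levels (rather than pooled count ratios) is the primary region
statistic because site levels are defined first and regions are described as
averages of them; a pooled mode exists behind `mode = "pooled"` for
sensitivity analysis. Degenerate windows with zero pooled variance are
treated as non-evidence when the group means agree (p = 1) and as the limit
of the *t* statistic (p = 0) when they differ; the latter cannot arise under
the binomial noise of the generator except at negligible depth.

# Nucleosome-depleted regions

NDR calling scores **100 bp windows sliding by 20 bp**. Within a window the
GCH calls are pooled (sum of methylated and total counts over its sites) and
tested against the whole-genome background with a one-degree-of-freedom
chi-squared goodness-of-fit; the background is the sample's unweighted mean
GCH site level. Pooling counts for the test while describing regions by the
site-mean level follows the asymmetry of the procedure itself: the test is
count-based, the descriptive level is an average. The chi-squared is
two-sided, so callers add an explicit `level > background` gate, which at
the calling threshold (**p ≤ 1e-10**) is equivalent to a one-sided test.

Significant windows that overlap or book-end are merged into candidates;
candidates must hold **≥ 5 distinct GCH sites** and span **≥ 140 bp**. Both
gates apply to the merged candidate, not to single windows — a lone 100 bp
window can never satisfy the 140 bp rule. Region statistics are then
recomputed over the merged span and regions whose site-mean level does not
exceed the background are dropped, so no reported NDR ever has
`level ≤ background`.

Cross-sample merging follows multi-intersection semantics: the union of all
samples' NDRs is partitioned by support count, segments supported by at
least `min_samples` sets are kept (default 1 = union, because the original
procedure's choice between union and intersection is not decidable; the
parameter is exposed), and kept segments within **10 bp** are connected.
NDRs overlapping a promoter — **1 kb upstream to 0.5 kb downstream of the
TSS**, strand-aware — by at least 1 bp are *proximal*, all others *distal*.

The sliding-window generator emits a window at every 20 bp offset up to the
contig end, truncating the final windows; the alternative of stopping the
last full-width window early changes nothing downstream because sub-140 bp
tails cannot survive the NDR gates, and we prefer windows that tile the
whole contig.

# Expression procedures

RPKM is `counts / (length_bp/1000) / (library/1e6)`; gene length is the
supplied exonic length when the annotation carries one, else the TSS–TES
span. The two-group test behind `diff_test()` is a deliberate, documented
stand-in for the output contract of count-based DE tools (per-gene log2
fold change and p-value), so externally computed tables can be gated
identically: median-of-ratios size factors, pseudocount-1 log2 fold change
of normalized group means, method-of-moments NB dispersion pooled over the
two groups and floored at 0.01, and a Wald statistic for the log fold
change referred to a *t* distribution with `n1 + n2 - 2` degrees of
freedom. The *t* reference (rather than normal) is the package's choice for
small-sample calibration; the test suite checks that the null p ≤ 0.05
fraction stays within [0.03, 0.07] on 2,000 simulated null genes.

DEG gating is `|log2fc| > 0.5` (strict), `FDR ≤ 0.05`, and a biotype
expression floor: mean RPKM **> 1** for protein-coding genes, **> 0.1** for
lncRNAs. Cis-pair annotation tests every same-direction (lncRNA, coding)
DEG pair within **100 kb** — distance is the nearest-end gap of the gene
spans, 0 when they overlap, since the procedure's anchor points are
unspecified — and keeps pairs with Pearson **r ≥ 0.6** and test
**p ≤ 0.05**, computed across the pooled samples of both groups (a flagged
choice; the sample universe of the original correlation is unstated).

The fetal program is pure set logic: `co_up` is the intersection of genes
up-regulated in disease-vs-control and fetal-vs-control, `co_down` the
analogous down-set. A program gene is *reversed* when both
treated-vs-disease contrasts call it in the opposite direction; fractions
are reported per program side as percentages rounded half-up (base R's
round-half-even would misprint exact halves).

# What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: genome GC fraction 0.40,
WCG background 0.72 (adult myocardium scale), GCH background 0.15 with
planted accessible regions at 0.45, mean coverage 10x (20x in the NDR
recovery runs), 6 methylation samples per group, and an expression design
of five groups with 4 samples each carrying an 88 + 275-gene program with
reversal fractions 0.84/0.79 and a 3-fold planted effect. Methylation calls
are binomial at the site's true level with Poisson depth — no extra
overdispersion by default (`bb_theta` enables a beta-binomial stress mode).
Hypermethylated plants at background 0.72 with delta 0.30 would exceed 1,
so simulated levels clamp to [0.01, 0.99] and hyper plants realize a delta
of about 0.27, still above the 0.20 calling gate. Only WCG/GCH/GCG/CCG
cytosines are emitted (OTHER-context cytosines carry no downstream
information); GCG/CCG are simulated at the methylation background so the
exclusion filters are exercised. The generator's context truth is derived
by literal pattern matching of the eight class trinucleotides — an
independent route from the classifier it cross-checks.

Plants are placed one per equal-width slot with margins, so they never
overlap and never straddle a merge gap; real NDRs cluster and real DMRs
have ragged boundaries. The generator also has no mappability bias, no
bisulfite conversion failure, no copy-number structure and no batch
effects. Passing recovery tests therefore demonstrates the correctness of
the calling logic under the stated noise model, not performance on real
tissue.

Two emergent properties of the expression design are worth knowing. First,
recovering a *reversal* requires DEG calls in four contrasts; with 4
samples per group the down-program side (whose disease-state counts are
low) loses measurable power, so the end-to-end reversed percentage
recomputed by `scripts/acceptance.R` falls below the planted fraction while
the up side tracks it closely. Second, the latent factor that correlates a
planted cis-pair also adds within-group variance, which costs those genes
DEG power; the acceptance script therefore reports cis recovery both
end-to-end and conditional on the pair's members being called DEGs.

# Problem sizes and determinism

The recovery suites run on a 2 Mb single-contig genome: 150 planted NDRs of
200–500 bp at 20x for sensitivity/precision by 50% reciprocal overlap, the
same genome without plants for specificity, and 100 planted 900 bp DMRs at
10x, 6 vs 6, for DMR sensitivity; null calibrations use a 0.3 Mb genome
(about 1,000 tested windows) and 2,000 null NB genes. These sizes put every
property in its asymptotic regime while keeping the full suite under a
minute. One integer seed pins every draw; each simulator writes plain-text
outputs (FASTA, cytosine-report TSV, BED truth tables, counts TSV, JSON)
that are byte-identical across runs with the same seed.

# Known limitations

* The NDR caller fragments plants that span runs with no GCH sites (the
  window test has nothing to pool); fragments shorter than 140 bp are
  dropped and longer fragments may fail reciprocal-overlap matching. This
  is inherent to fixed-threshold window testing at sparse site density.
* The NB Wald stand-in is not a shrinkage estimator; at 2 samples per group
  its dispersion estimate is noisy, and externally computed DE tables are
  the recommended input for real data.
* Enrichment of regions in genome elements is base-pair based (counted per
  region base against the element's merged footprint); a count-based
  definition would differ for many short regions.
* Group NDR merging defaults to union semantics; intersection-like behavior
  is available via `min_samples` but the two can differ substantially when
  sample depth varies.
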