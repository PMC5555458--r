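# ripseed

Target calling for RIP-Seq experiments, and miRNA seed-site enrichment in
the 3′ UTRs of the called targets.

RIP-Seq identifies the RNAs bound by an RNA-binding protein by sequencing
three kinds of libraries: an immunoprecipitation of the tagged protein
(IP), a tag-only control immunoprecipitation (CTRL), and pre-IP total RNA
(Total). `ripseed` takes transcript-level count tables from such a design
— typically a handful of replicates, e.g. 3 IP / 2 CTRL / 2 Total — calls
bound transcripts, and then asks a follow-up question that matters when
the protein is suspected to share targets with microRNAs: are the 3′ UTRs
of the bound mRNAs unusually dense in conserved miRNA seed-match sites?

The package is aimed at people analysing RIP-Seq (or similar
IP-vs-control count) experiments in organisms with compact, well-annotated
3′ UTRs, and at anyone who wants a fully simulated version of such an
experiment with known ground truth.

## What it computes

**Adjusted counts.** Each transcript's raw mapped reads divided by the
library's total reads — a within-library proportion, so every library
column sums to 1.

**IP enrichment score.** With adjusted counts averaged across replicates
within each class,

```
score = (AdjustedCounts(IP) − AdjustedCounts(CTRL)) / AdjustedCounts(Total)
```

positive when the IP captures more of a transcript than the tag-only
control, relative to its abundance in the input.

**Differential enrichment.** A self-contained moderated negative-binomial
Wald test of IP vs CTRL: median-of-ratios size factors, per-transcript
method-of-moments dispersion (variance = μ + αμ²) shrunk 50/50 toward a
fitted mean–dispersion trend, and a Wald test of the log ratio of group
means. P-values get Benjamini–Hochberg q-values; a transcript is a target
when q < 0.1 (configurable) and its fold enrichment is positive, and a
gene is a target if any of its isoforms is.

**Seed sites and density.** Canonical seed matches (8mer, 7mer-m8,
7mer-A1: complementarity to miRNA positions 2–8, with or without the A
opposite position 1) are scanned in each UTR; for a gene with several UTR
isoforms the median site count and the median UTR length are taken
separately and combined as

```
density per kb = (median sites / median UTR length) × 1000
```

Target-set density is compared to an expression-filtered background, both
for all miRNA families and for a designated subset (e.g. families known to
interact genetically with the protein).

**Set and phenotype statistics.** Hypergeometric overlap tests
(P[X ≥ k]), two-sided Fisher exact tests, the standard error of a
proportion, and an enhancer-screen wrapper that flags genotypes whose
arrest penetrance significantly exceeds every reference.

**Synthetic data.** `sim_config()` / `simulate_annotation()` /
`simulate_counts()` / `simulate_phenotypes()` generate the whole
experiment — NB libraries with a planted bound set, UTRs with planted seed
sites recorded in an exact ground truth, family tables, expressed-gene
lists, penetrance tables — so every stage of the analysis can be validated
against known truth.

## Worked example

```r
library(ripseed)

cfg    <- sim_config(rng_seed = 1)          # 500 genes, 50 bound, 4x IP effect
ann    <- simulate_annotation(cfg)
counts <- simulate_counts(cfg, ann$truth)

fit <- rip_enrichment(counts, ann$gene_map, q_threshold = 0.1)
summary(fit)
#> RIP-Seq enrichment summary
#>   1004 transcripts, 96 called (q < 0.1), 54 target genes
#>   fold enrichment (IP/CTRL)  targets: median 3.93 mean 3.94
#>                              all:     median 0.98 mean 1.26

sites   <- scan_seed_sites(ann$utrs, ann$families)
tab_sub <- utr_density_table(sites, ann$utrs, ann$gene_map,
                             families = ann$interacting_families)
density_comparison(fit$targets, unique(ann$gene_map$gene_id),
                   tab_sub, ann$expressed_genes)
#> interacting-family density: targets 14.85 vs background 6.26 per kb (2.37-fold)
```

The 54 called target genes recover all 50 planted bound genes
(sensitivity 1.00 at this seed); their median IP/CTRL fold enrichment
(3.93) sits near the planted 4-fold effect while the bulk of transcripts
stays at 0.98; and their UTRs carry a 2.4-fold excess of
interacting-family seed sites over the expressed background, reflecting
the 3× planting rate after dilution by background sites and UTR-length
variation.

`run_pipeline(pipeline_config(out_dir, sim = cfg))` chains all stages
(simulate → enrich → seedscan → overlap → screen), writes every
intermediate as TSV/FASTA plus a `report.json`, and is byte-for-byte
reproducible for a given config and seed. A thin command-line wrapper
with the same stages as subcommands lives in `inst/cli/ripseed.R`.

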