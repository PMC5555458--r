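---
title: "Methods: RIP-Seq target calling and seed-site density in ripseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RIP-Seq target calling and seed-site density in ripseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripseed)
```

## The problem

A RIP-Seq experiment immunoprecipitates a tagged RNA-binding protein and
sequences the co-purified RNA, alongside a tag-only control IP and pre-IP
total RNA. The analytical questions are (i) which transcripts are
enriched in the IP beyond the non-specific background captured by the
control, and (ii) — when the protein is suspected to act alongside the
miRNA pathway — whether the 3′ UTRs of the bound mRNAs carry an excess of
miRNA seed-match sites. `ripseed` implements both stages, plus the
overlap and penetrance statistics used around them, and a synthetic-data
generator that makes the whole chain testable against planted ground
truth.

The package operates strictly at the count-table level. Read-level
processing (adapter/quality trimming, spliced alignment, read counting)
is out of scope and assumed done by standard tooling.

## Enrichment model

**Adjusted counts.** For transcript $i$ in library $s$,
$a_{is} = c_{is} / \sum_j c_{js}$: a within-library proportion. Columns
of the adjusted matrix sum to 1 by construction (the tests check this to
$10^{-9}$), and the proportions are invariant to rescaling a library's
depth.

**IP enrichment score.** With $\bar a^{IP}, \bar a^{CTRL}, \bar a^{TOT}$
the adjusted counts averaged across replicates within each class,

$$ E_i = \frac{\bar a^{IP}_i - \bar a^{CTRL}_i}{\bar a^{TOT}_i}. $$

Averaging replicates before applying the formula is a deliberate choice:
the formula is defined on one value per class, and the arithmetic mean is
the symmetric minimum-variance way to get there. The score is
antisymmetric under swapping IP and CTRL. When $\bar a^{TOT}_i = 0$ the
score is undefined; `ripseed` reports `NA` (and a message with the count
of such transcripts) rather than propagating infinities into medians, and
returns 0 for the 0/0 case. `NA` scores are excluded from all summaries.

**Differential test.** The IP-vs-CTRL comparison is a self-contained
moderated negative-binomial Wald test:

1. *Size factors*: median-of-ratios across the IP and CTRL columns
   (geometric-mean reference over transcripts observed in every library;
   total-count scaling as fallback when fewer than ten such transcripts
   exist).
2. *Dispersion*: per-transcript method of moments on normalized counts
   under the NB parameterisation $\mathrm{Var} = \mu + \alpha\mu^2$,
   pooled within groups, clamped at 0; a mean–dispersion trend
   $\alpha(\mu) = a_0 + a_1/\mu$ is fitted by least squares across
   transcripts and the final dispersion is the 50/50 blend of the raw
   estimate and the trend, floored at $10^{-8}$. The equal blend keeps
   per-transcript information while taming the very noisy 2–3 replicate
   moment estimates.
3. *Wald test*: the statistic is
   $\log(\hat q^{IP}) - \log(\hat q^{CTRL})$ over its model-based
   standard error (delta method on NB means, using the moderated
   dispersion), referred to the standard normal. A pseudocount of 0.5 on
   the group means stabilises the log at low counts; it biases fold
   changes of near-zero transcripts toward 0, which is the conservative
   direction. All-zero transcripts get $p = 1$, $\log_2 FC = 0$, and a
   flag. With a single replicate in a class the dispersion must be pooled
   across classes — this absorbs real signal into the noise estimate, so
   those results are flagged and the function warns.

The choice of a normal reference rather than a small-$\,df$ t is part of
the estimator design: because half the dispersion weight comes from the
trend, the variance estimate is far more stable than a raw 3-degree
moment estimate, and the t reference would double-count that
uncertainty. The test suite quantifies the resulting calibration under
the generator's null (2000 transcripts, 3v2 replicates, dispersion 0.05):
the fraction of $p < 0.05$ is required to fall in $[0.03, 0.07]$ and the
KS distance from uniform below 0.05. The test is mildly anticonservative
(fractions near 0.06–0.08 across seeds); with BH correction at
$q < 0.1$ the realised false-positive *gene* rate under the null is far
below the nominal level, which is what matters for target calling.

**Targets.** $q$-values are Benjamini–Hochberg; a transcript is called at
$q < 0.1$ (configurable) *and* positive fold enrichment — only "enriched"
transcripts can be targets; significant depletion is not a binding call.
Gene-level calls use the any-isoform rule. The IP enrichment score can be
enabled as an additional filter (`score_filter`), but is off by default:
the score and the differential test answer overlapping questions, and
stacking them silently would make the effective threshold opaque.
Fold-change summaries (median and mean for targets vs all transcripts)
are computed on the ratio scale $2^{\log_2 FC}$.

## Seed sites and density

Seeds are nucleotides 2–8 of the mature miRNA; families are groups of
miRNAs sharing the seed (checked on load; a family table whose members
disagree is an error). On the UTR sense strand the three conserved site
classes are: 8mer (reverse complement of the seed followed by A), 7mer-m8
(reverse complement of the seed), 7mer-A1 (reverse complement of seed
positions 2–7 followed by A).

The matcher anchors on the 6-nt core (reverse complement of seed
positions 2–7) and classifies each core match once by its two flanking
positions, 8mer taking precedence over the 7mers. This is the TargetScan
counting convention: a window is never double-counted across classes, but
core matches in different registers — including overlapping ones — are
all reported. Coordinates are 0-based half-open on the UTR. UTRs may be
given as DNA or RNA (`T` ≡ `U`); non-IUPAC characters are an error naming
the offending position. The matcher is validated against a brute-force
window scan (an explicitly independent formulation that tests every 7-
and 8-nt window against literal pattern strings) on 1000 random UTRs.

**Density.** For a gene with isoform site counts $k_1..k_m$ and UTR
lengths $l_1..l_m$,

$$ \text{density} = \frac{\mathrm{median}(k)}{\mathrm{median}(l)} \times 1000 $$

— the two medians are taken independently and then paired, not averaged
per-isoform ratios. The median of an even number of isoforms is the mean
of the middle two, so `median_sites` can be half-integer. The statistic
is invariant under duplicating a gene's isoform set. Within a family (and
for totals across families) sites are deduplicated by `(start, end)`, so
a window claimed by two families with colliding patterns counts once.

**Comparison.** Target and background gene sets are intersected with an
expressed-gene list before comparing mean densities (an empty filtered
set is an error, not a silent 0); the fold change is reported for all
families and for a designated "interacting" subset. One semantic
difference from TargetScan-style analyses is deliberate and worth
knowing: conservation is *not* computed here. The scanner finds all seed
matches for the families it is given; "conserved" is a property of the
supplied family list, not of the site. Users who need conservation-level
filtering should supply only conserved families.

## Set and phenotype statistics

The overlap test is the upper-tail hypergeometric $P[X \ge k]$ including
the observed value — the over-representation convention — with expected
overlap $ab/N$ and fold enrichment $k/(ab/N)$. The universe size $N$ is a
required explicit input: it changes the answer and no default is
defensible. Fisher's exact test is two-sided by the minimum-likelihood
rule. Both are validated against exhaustive enumeration (all
$\binom{N}{b}$ draws for $N \le 12$; all tables with fixed margins) in
the test suite. The enhancer screen reports arrest proportion,
$\sqrt{\hat p(1-\hat p)/n}$, and Fisher p-values against every reference,
flagging a genotype when it beats $\alpha = 0.001$ against all references
with a higher proportion than each; no multiple-testing correction is
applied across genotypes by default (screens conventionally report raw
Fisher significance at a fixed $\alpha$), with BH available as an option.

## The synthetic generator

The generator emulates the experimental design the analysis assumes:
three IP, two CTRL and two TOTAL libraries (1e6 expected reads each) over
`n_genes = 500` genes with 1–3 UTR isoforms, of which `n_bound = 50` are
bound with `ip_effect = 4`; NB counts at dispersion 0.05 around
log-normal baseline abundances ($\sigma_{\log} = 1$, normalised to
proportions); UTR lengths normal (mean 200 nt, sd 60, truncated at
40 nt); 8 miRNA families of which 5 form the interacting subset; planted
site counts per UTR Poisson with mean 3 (interacting families, bound
genes) versus 1 (everything else); and 90% of genes on the expressed
list. These defaults are the study conditions of the package's validation
suite, chosen once as a realistic desk-scale stand-in for a compact
invertebrate transcriptome; none of them is tuned to any particular
outcome.

Design choices that matter:

* UTRs are emitted as DNA in FASTA (the common convention for UTR
  annotation files); the matcher normalises internally.
* Planted sites are 8mers, inserted at non-overlapping positions by
  replacement. Placement uses the classic gap construction (sample the
  slack, then offset), which always succeeds when $8n \le L$; an exact
  site request that cannot fit is an error naming the gene, while
  Poisson draws that do not fit are redrawn (an upper-tail truncation
  with negligible effect at the default means).
* Ground truth is exact by construction: after planting, the generator
  re-scans and re-randomises any background bases that happen to form
  additional seed matches, and family seeds are rejection-sampled so that
  no family's core occurs inside another family's site pattern. The
  round-trip property — scanner output equals the planted truth exactly —
  is asserted in the tests.
* Determinism: each generator entry point seeds the RNG from
  `rng_seed` (with fixed offsets for the counts and phenotype stages), so
  identical configs give byte-identical FASTA/TSV output and pipeline
  reports.

What the generator does *not* emulate, and hence what passing tests do
not show about real data: positional or structural preferences of
binding, correlated replicates or batch effects, isoform-level expression
differences within a gene, UTR base composition (background is uniform),
site conservation, GC or length biases of library preparation, and any
read-level artefact. Results on real libraries depend on upstream mapping
quality in ways the synthetic path cannot probe.

## Numerical conventions and degenerate inputs

* Adjusted-count columns sum to 1 within $10^{-9}$; a zero-total library
  is an error naming the sample.
* Enrichment score: 0/0 → 0; $x$/0 → `NA` + message; `NA` excluded from
  summaries.
* Dispersion estimates are clamped to $[10^{-8}, \infty)$; the trend
  intercept to $\ge 10^{-4}$ and slope to $\ge 0$.
* `nb_dispersion = 0` selects exact Poisson sampling in the generator.
* Empty target set: fold-change summaries return `NA` markers;
  `call_targets` on empty results warns and returns an empty set.
* Site sorting is by `(start, end)`; ties cannot occur within a family
  scan.
* The pipeline aborts with the failing stage's name; all thresholds are
  validated to lie in $(0,1)$.

## Problem sizes

The unit suite runs generators at 15–150 genes; the validation suite uses
the full default conditions (500 genes, ~1000 isoforms), a 2000-transcript
null calibration, 1000 random UTRs for matcher–oracle equivalence, and
500 random configurations for the enumeration checks — a few minutes of
CPU in total, single-threaded.

## Limitations

The differential engine is a deliberately transparent moment-based test,
documented and calibrated here; it is not a reimplementation of DESeq2 or
CuffDiff and will not reproduce their numerics. Site scanning covers the
three canonical ≥7mer classes only — no 6mers, 3′-compensatory sites, or
context scoring. The density comparison is a mean contrast without a
significance test (the overlap test covers set-level significance).
Confidence tiers among targets are user-supplied subsets, not derived by
the package.
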