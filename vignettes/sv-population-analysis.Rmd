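---
title: "Population-genomic analysis of insertions and deletions with svscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-genomic analysis of insertions and deletions with svscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svscape)
```

# What the package computes

`svscape` implements the downstream half of an indel / structural-variant
population-genomics study: it starts from a merged multi-sample VCF of
biallelic SNPs, insertions and deletions (variant calling itself is out of
scope) and carries the cohort through quality control, genomic
characterisation and selection scans. The stages, in dependency order:

1. **QC and size classing** — GATK-style hard filters, removal of indels
   within 10 bp of a higher-confidence indel, cohort missingness/MAF
   filters, and the three-way size stratification (Small 1–10 bp, Medium
   11–50 bp, Large >50 bp) that every later stage conditions on.
2. **Region annotation** — each variant is assigned to exactly one of six
   genomic region groups (exonic/splicing, UTR5/UTR3, intronic, ncRNA,
   upstream/downstream, intergenic) by feature precedence.
3. **Hotspot detection** — breakpoints are counted in non-overlapping
   100 kb bins; bins in the genome-wide top 1% are hotspots, cross-tabulated
   against QTL trait categories.
4. **Overlap enrichment** — a permutation Z-score test of variant overlap
   with labelled interval tracks (QTLs, regulatory elements).
5. **Repeat content** — the fraction of each Medium/Large variant covered
   by annotated repeat bases; variants covered by more than 80% are
   classified as TE-driven or simple-repeat-driven.
6. **Fst selection scans** — Weir–Cockerham per-site estimates aggregated
   in 50 kb windows stepped by 20 kb for Small/Medium indels, and a
   frequency-based Hudson estimate per Large variant; top-1% outliers and
   the genes they overlap, including genes shared across breed pairs.
7. **LD tagging** — composite r² between each variant and nearby
   eQTL/sQTL-flagged SNPs, with the high/medium/low LD categories and a
   tissue-resolved summary.

Because the real cohorts such analyses run on are not redistributable, the
package ships a synthetic-cohort generator that produces every input the
pipeline consumes, with planted ground truth for closed-loop validation.

# Statistical models and estimators

## Population model

Genotypes are simulated under the Balding–Nichols model: each locus has an
ancestral frequency $p \sim U(0.05, 0.95)$; each population $k$ draws

$$p_k \sim \mathrm{Beta}\!\left(\frac{p(1-F)}{F},\ \frac{(1-p)(1-F)}{F}\right),$$

so $\mathrm{E}[p_k] = p$ and $\mathrm{Var}(p_k) = F\,p(1-p)$, and diploid
genotypes are $\mathrm{Binomial}(2, p_k)$. The dispersion $F$ is the
quantity the Fst estimators are supposed to recover, which is why this
model (rather than a coalescent simulator) drives the generator: it
parameterises the estimand directly and runs in seconds. The default
background is $F = 0.02$, the weak differentiation typical of related
indigenous breeds (pairwise Fst of a few times $10^{-2}$ down to
$10^{-3}$).

## Fst

Two estimators are implemented, matching the two data situations:

* **Weir–Cockerham (1984)** variance components $a$ (among populations),
  $b$ (among individuals within populations, with the observed
  heterozygosity correction) and $c$ (within individuals), with
  $\hat F_{ST} = a/(a+b+c)$ per site. This is the estimator VCFtools
  computes from genotypes; it is used for Small/Medium indels. Negative
  per-site estimates are retained, not clamped.
* **Hudson (Bhatia form)** for allele frequencies alone, used for Large
  variants whose Fst is computed from SV frequencies:
  $N = (p_1-p_2)^2 - \frac{p_1(1-p_1)}{n_1-1} - \frac{p_2(1-p_2)}{n_2-1}$,
  $D = p_1(1-p_2)+p_2(1-p_1)$, $\hat F_{ST} = N/D$.

Genome-wide and windowed aggregates are **ratios of sums** —
$\sum a / \sum (a+b+c)$ and $\sum N / \sum D$ — not means of per-site
ratios. The distinction matters: averaging per-site ratios is biased
toward zero (we measure ≈0.149 for a generating $F = 0.2$ under the
package's own recovery conditions), while the ratio-of-sums aggregate
recovers $F$ within ±0.01 at $F \in \{0.02, 0.05, 0.2\}$ with 2
populations × 50 diploids × 5000 loci. Windows report both
(`fst_weighted`, `fst_mean`); `fst_weighted` is primary.

Sliding windows are anchored at position 0 of each chromosome, 50 kb wide
with a 20 kb step; the last partial window is kept; windows with no
defined site are omitted. Top-1% selection candidates use
$k = \max(1, \lfloor 0.01\,n \rfloor)$ with ties at the threshold
included, ranked genome-wide.

## Permutation enrichment

The overlap statistic (count of query elements with ≥1 bp overlap, or
total overlapping bases against the merged reference) is compared with its
distribution under 100 independent re-placements of each query element,
uniformly on its original chromosome with length preserved — the simplest
null consistent with a region-permutation test. $z = (\mathrm{obs} -
\bar{x}_{perm})/s_{perm}$, with a one-sided empirical p in the direction
of departure using the $+1$ correction so p is never 0. When the
permutation sd is 0 the result is flagged degenerate rather than given an
infinite z. Under the null (query itself produced by the randomizer) the z
distribution is calibrated: mean within ±0.15, sd within [0.7, 1.3] over
200 replicates.

## LD

r² is the squared Pearson correlation of unphased genotype dosages over
jointly non-missing samples (composite LD) — the default when phase is
unavailable, and consistent with haplotype r² under random mating: on
simulated haplotype blocks with known $D$, dosage r² converges to
$D^2/(p_A p_a p_B p_b)$ within ±0.02. Category boundaries are closed
exactly as conventionally printed: high $r^2 \ge 0.8$, medium
$0.2 \le r^2 < 0.8$, low $r^2 < 0.2$. The e/sQTL search window is ±1 Mb
(configurable); a variant's tissue list is the union of tissues of all
SNPs achieving the maximum r² within $10^{-9}$.

## Breakpoints and hotspots

A deletion has two reference junctions, an insertion one; so a DEL
contributes 2 breakpoint counts (start bin and end bin — two increments
even if they land in the same bin) and an INS 1. Bins are 100 kb,
non-overlapping, partial terminal bins kept, counts not length-normalised.
Hotspots are the genome-wide top 1% of bins by count (ties included; a
count of at least 1 is always required, so an empty genome yields no
hotspots).

## Repeat content

Coverage uses union (merged-interval) semantics: overlapping repeat hits
are counted once, so the covered fraction never exceeds what summing raw
element lengths would suggest. The "driven" call requires strictly more
than 80% of the variant length covered. TE and simple-repeat membership
are mutually exclusive, resolved by which category contributes more bases;
the driver is the single element contributing the most bases (ties broken
lexicographically and flagged). Deletions are assessed on their reference
span; insertions need a parallel RepeatMasker annotation of the inserted
(ALT) sequences — without it they are skipped and tallied, since the
package does not run RepeatMasker. Small variants are excluded from this
module by construction.

## Region precedence

Classification follows the ANNOVAR convention: a variant touching several
features takes the highest-precedence one, with precedence
exonic/splicing > UTR5/UTR3 > intronic > ncRNA > upstream/downstream >
intergenic; the splice window is 2 bp into the intron at each exon
junction and the upstream/downstream flank is 1 kb (both configurable,
both the ANNOVAR defaults). Insertions are assessed at their anchor point;
a deletion spanning several categories takes its highest-precedence touch.

# Coordinate conventions and numerical choices

* All internal interval arithmetic is 0-based half-open. VCF (1-based),
  GFF3 and RepeatMasker .out (1-based inclusive) are converted exactly
  once, at ingest; BED passes through unchanged. An insertion is a
  zero-width anchor $[p, p)$; for overlap queries the anchor behaves as
  point-in-interval.
* Strict vs non-strict inequalities in all filters are taken literally
  from the conventional phrasing they implement: QD < 2.0 removes, FS
  exactly 200.0 is retained, missing rate exactly 0.1 (or 0.3 for SVs)
  removes, MAF exactly 0.01 fails "greater than 0.01".
* Proximity dedup measures distance between VCF POS anchors, per
  chromosome, and resolves clusters greedily: QUAL descending, ties by
  position ascending then DEL before INS; an indel is discarded iff its
  start lies within 10 bp of an already-accepted start. The pairwise
  "remove the lower-QUAL one" rule is ambiguous for chains of 3+; the
  greedy order makes it deterministic and order-independent.
* Hard-filter rules whose INFO key a record lacks are skipped, not
  failed — merged SV records carry no GATK annotations.
* Randomization, simulation and permutation all run off explicit integer
  seeds; the pipeline derives per-stage seeds from one run seed, and two
  runs of the same configuration produce byte-identical stage outputs
  (verified by md5 in the run manifest).

# The synthetic generator: what it emulates, what it does not

The generator produces a five-breed cohort of 20 diploids per breed on a
2 × 5 Mb genome with ~3,000 variant loci — deliberately desk-scale. It
plants, and records as truth: the region class of every INS/DEL (placed
inside pure single-class pools derived from the generated gene models),
breakpoint hotspot bins (1% of bins at a 20× breakpoint rate), TE-driven
variants (44% of Large, echoing the ~42–46% seen in cattle SV studies,
with a SINE/Core-RTE length component peaked near 150 bp and mostly named
BOV-A2), simple-repeat variants (unit-length mixture peaking at
dinucleotides), low-quality records violating one hard-filter rule each,
selection loci with locus-specific $F = 0.5$, and e/sQTL-tagged variants
(a nearby SNP whose dosages copy the variant's with 3% per-sample error,
giving r² ≈ 0.9) alongside untagged controls with independent nearby SNPs.

Two generator choices deserve emphasis:

* **Planted sweeps are conditioned on divergence.** A symmetric
  Balding–Nichols draw at $F = 0.5$ leaves the two populations on the
  same side of the ancestral frequency about half the time — such a locus
  is simply not differentiated and no scan could (or should) find it.
  Selection-locus frequencies are therefore redrawn under the same Beta
  model until the across-population range is ≥ 0.4: a planted sweep is,
  by construction, a differentiated locus. With that definition the
  top-1% scan recovers the planted locus in ≥95% of replicates.
* **No linkage structure.** Loci are exchangeable draws; there is no LD
  decay along the chromosome, no demographic history, no sequence-level
  realism (REF/ALT strings are random bases, symbolic alleles above
  100 bp). Planted LD exists only where the generator fabricates it
  (variant–SNP tag pairs).

Passing the closed-loop tests therefore demonstrates that each stage
recovers exactly the signal the generator planted under its stated model —
correctness of the estimators and bookkeeping — not that the pipeline is
robust to the messiness of real resequencing data (caller-specific biases,
genotyping error correlated with depth, reference gaps, segmental
duplications).

# Problem sizes

The bundled analyses and tests use: default cohorts of ~3,300 loci × 100
samples; Fst recovery at 5,000 loci × 2 × 50 diploids per $F$ level;
selection-scan recall over replicate cohorts of 1,000 loci × 2 × 25
diploids; null calibration of the permutation test over 200 replicates of
100 permutations on 40-element queries. These sizes make every stochastic
check stable at the tolerances tested while keeping a full run in minutes
on one core.

# Known limitations

* The X chromosome is treated like an autosome (all samples diploid
  everywhere); sex-aware allele counting is out of scope.
* Insertions' repeat content depends entirely on a supplied ALT-sequence
  annotation; there is no built-in masking.
* Enrichment p-values are reported raw, per track label, with no
  multiple-testing correction across labels — matching how such screens
  are conventionally reported, but worth remembering when many labels are
  tested.
* Multiallelic records are rejected (or skipped on request), never split.

# A worked example

```{r example, eval = FALSE}
library(svscape)

sim <- simulate_cohort(sim_config(seed = 1), out_dir = "cohort")
vt <- read_vcf(sim$paths$vcf, layout = sim$layout)
qc <- filter_cohort(apply_hard_filters(vt)$variants)

pair <- c("Wuling", "Dabieshan")
sites <- wc_fst(qc, sim$pops, pair)
win <- windowed_fst(sites, sim$layout)
top <- top_selection_regions(win, "fst_weighted", 0.01)
genes_in_regions(top, sim$genes)
```

The numbered scripts under `analysis/` run the same stages end-to-end and
write every table under `results/`.
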