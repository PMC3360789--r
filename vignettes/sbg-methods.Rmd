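---
title: "Sequence-based genotyping at desk scale: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based genotyping at desk scale: models, thresholds and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

sbgtools implements a complete sequence-based genotyping (SBG) workflow for
mapping populations: restriction-digest complexity reduction, inline-barcoded
multiplexed sequencing, reference construction by clustering unique reads,
diploid genotype calling, parent-based co-dominant A/B/H scoring, frequency
filtering, and linkage mapping. Because real reduced-representation datasets
are hundreds of millions of reads, the package ships a first-class simulator
that reproduces the structure of such an experiment at desk scale, with full
truth tables, so every downstream stage is testable end to end. This vignette
explains the models, the tunable parameters and their defaults, and the design
decisions taken where more than one reasonable construction exists.

## The simulated experiment

**Founders and populations.** `make_founders()` draws a background genome
(default: 5 chromosomes of 1 Mb and 125 cM each, GC 0.36 — an
arabidopsis-like shape) and a SNP table at which a second founder differs by
single-nucleotide substitutions. The default density of 6 SNPs/kb is on the
scale of two well-diverged accessions of a selfing plant (roughly one
polymorphism per 170 bp) and is chosen so that the default design yields at
least ~500 informative markers after all downstream filters, enough to build
a dense map. `simulate_cross()` produces BC1 populations (one F1 gamete plus
one recurrent-parent gamete; offspring are only heterozygous or homozygous
for the recurrent allele) or selfed RILs (the F1 selfed `generations - 1`
times; residual heterozygosity at F8 is \(0.5^7 \approx 0.78\%\)).

**Recombination model.** Meiosis follows Haldane's model: crossover counts
per chromosome are Poisson(\(L_{cM}/100\)) with positions uniform on the cM
scale and no interference. This is deliberately matched to the Haldane
mapping function used at the mapping end (\(d = -\tfrac{1}{2}\ln(1-2r)\),
in cM), so map-length recovery is unbiased in expectation: simulating with
interference but mapping with Haldane would build a known bias into every
end-to-end check.

**Digest and library structure.** `digest_select()` cuts at every rare-site
and frequent-site occurrence (all default sites are palindromic, so a
single-strand scan suffices) and keeps only fragments flanked by one rare
and one frequent cut: with two-adapter AFLP-style chemistry only those
fragments carry both PCR primer sites and amplify. Fragments containing an
optional excluder site (MseI in the three-enzyme PstI/TaqI/MseI scheme) are
removed — the in-silico equivalent of letting the third enzyme destroy
P–M/M–T fragments. A length window (default 80–2000 bp for EcoRI/MseI,
200–2000 bp for the paired-end scheme, where removing everything under
200 bp is also what eliminates adapter dimers) models size selection. One
window is applied per library; the two reads of a pair are not
size-selected independently.

**Reads.** Read 1 is `[5-nt tag][fragment from the rare-cut end]` truncated
to the read length (default 76 nt); with `paired = TRUE`, read 2 is the
reverse complement from the frequent end (100 nt, untagged). Remnant
conventions are the standard AFLP ones (EcoRI `AATTC`, PstI `TGCAG`, TaqI
`CGA`, MseI `TAA`). Depth per fragment per individual is Poisson with mean
20 by default (a negative-binomial option exists to stress the coverage
threshold); a heterozygote's reads are split Binomial(d, 1/2) between
haplotypes. Substitution errors are applied per base at the rate implied by
a constant Phred profile (Q30 → \(10^{-3}\)); quality strings are constant,
the simplest model that still exercises the likelihood caller. Inserts
shorter than the read are padded with Illumina-style adapter read-through.
What the simulator does *not* model — position-dependent quality decay,
indels, PCR duplicates, chimeras — bounds what passing tests say about real
data: they validate the algorithmic pipeline, not robustness to every
instrument artifact.

## Demultiplexing and read QC

Tags are a distance-2 code: `design_tags()` scans all \(4^L\) candidates in
lexicographic order, greedily accepting tags at Hamming distance ≥ 2 from
all accepted ones (this attains the maximal \(4^{L-1}\)-word code), then
issues a seeded random subset. Distance 2 cannot correct single errors
unambiguously, so `classify_read()` matches tags exactly and rejects
otherwise — rescue would risk misassignment, and with 5-nt tags at Q30 the
loss is ~0.5% of reads. Checks run in a fixed order (tag, expected remnant,
N count, homopolymer run, mean quality, blocklist k-mer), so every read
lands in exactly one category and the demultiplexing report partitions the
input exactly. Defaults: homopolymer runs over 10 rejected, no Ns allowed,
mean Phred ≥ 20, blocklist screening by exact 31-mer membership against a
user-provided organelle/repeat FASTA (an aligner-free stand-in for a
contaminant-database hit). The remnant is *retained* on the trimmed read:
it is part of the locus sequence and keeps otherwise-similar loci
distinguishable.

## Reference construction

All full-length trimmed reads (length exactly `read_length - 5`; shorter
reads come from sub-read-length inserts) are deduplicated exactly; each
unique sequence is its own 100%-identity cluster and its own
representative. Sequences seen more than 100,000 times (repeats, organelle
leftovers) or fewer times than the population size (mostly error variants —
a real locus should be seen about once per sample or more) are discarded;
the lower default is `n_samples`. A consequence of exact clustering is that
the two alleles of a polymorphic locus form *separate* contigs; this is
intentional and is resolved at calling time.

## Read assignment and genotype calling

Fragments have fixed starts and uniform length, so assignment is ungapped:
`assign_read()` takes the unique best Hamming match with at most `max_mm`
(default 3) mismatches and discards ties (paralog/allele conflation guard).
The bulk path adds an exact-match shortcut and a pigeonhole index (split
the read into `max_mm + 1` chunks; any read within budget must match one
chunk exactly), and is property-tested to agree with the per-read scan.

Contigs within `max_mm` of each other are merged into one locus before
pileup (reuniting allele contigs; the highest-count contig becomes the
locus reference) — without this, a SNP whose alleles split across two
contigs would be invisible. Per locus, candidate sites are positions with
two or more observed alleles; the two most frequent alleles are kept and
sites with a third allele above 5% of the pileup are dropped as unresolved.

Genotypes come from a flat-prior diploid likelihood: per read with base
\(b\) and error \(e = 10^{-Q/10}\) (floored at \(10^{-4}\) to avoid
overconfident qualities), \(P(b\mid \text{hom-}X) = 1-e\) if \(b = X\),
else \(e/3\); the heterozygote averages the two homozygous models.
Log-likelihoods sum over reads, are Phred-scaled and normalized to PL
(minimum 0); GQ is the second-smallest PL capped at 99. A flat prior keeps
GQ interpretable and lets an independent brute-force oracle check every
small pileup exactly. Genotypes are set missing below **7× coverage** or
**GQ 20**; site quality (SNPQ) is defined constructively as the summed
per-sample evidence against the all-major-homozygote configuration (capped
at 9999) and sites below **SNPQ 30**, or with no non-missing non-major
genotype, are dropped. The 7/20/30 defaults are the classical validated
operating point for this assay class; all are configurable. At 7×
coverage, a true heterozygote loses one allele with probability
\(2 \cdot 0.5^7 \approx 1.6\%\) per exactly-7× genotype — the reason the
coverage threshold matters, and the only mechanism by which a noise-free
BC1 simulation can produce (rare) pedigree-impossible calls.

## A/B/H scoring and SNP filtering

Parent-based genotyping keeps sites where both parents are called, both
homozygous, for different alleles; offspring are then coded A (parent-1
homozygote), B (parent-2 homozygote), H (heterozygote). A is anchored to
the parent given first — which founder is "A" is a labeling convention,
not inferable from data. Without parents, raw biallelic calls can be
exported unlabeled (`to_abh()` is simply skipped).

The filter presets encode the expected segregation: BC1 — more than 60%
missing, B or H frequency outside 25–75%, or A frequency above 3% removes
the SNP; RIL — A and B bounded to 25–75%, H capped at 15%. In BC1 the A
class is pedigree-impossible, so its frequency is a direct error-rate
proxy and the 3% cap guarantees ≥97% per-SNP accuracy by construction.
Frequencies are computed over non-missing calls (the missingness rule
handles absent data separately); range bounds are inclusive and "more
than" thresholds strict, read literally. The three rules are evaluated
jointly and verdicts record every violation (sequential application would
remove the same SNPs).

## Linkage mapping

Pairwise recombination fractions: in BC1, informative pairs are jointly
non-missing B/H calls; \(\hat r = R/N\) (capped at 0.4999) with
\(LOD = R\log_{10}\hat r + (N-R)\log_{10}(1-\hat r) - N\log_{10}0.5\).
When observed discordance reaches 0.5 the LOD is set to exactly 0. In
RILs, residual heterozygotes are phase-uninformative and treated as
missing, and the observed discordance \(\hat R\) is corrected to a map rf
by \(r = \hat R / (2(1-\hat R))\), treating F8 as effectively fixed
(F∞); the LOD is computed on \(\hat R\). Estimates above 0.4 barely
separate linkage from independence, so they are re-estimated through
shortest paths: edges with \(\hat r \le 0.4\) are weighted by Haldane
distance, and the shortest-path distance maps back through the inverse
Haldane function (pairs with no path keep 0.5).

Grouping is single-linkage over edges with rf ≤ 0.4 and LOD ≥ 4. The rf
bound is the re-estimation threshold; LOD 4 is a conventional grouping
stringency (the assay's own grouping threshold is not fixed by the
protocol) and is exposed in `map_config()`. As a light merge/split
optimization, the partition is evaluated at LOD 3/4/5 and the one
maximizing mean within-group LOD is kept. Leftover markers are anchored to
the group holding their minimum-rf partner, only when that best rf is
within bounds *and* beats the second-best group by a margin (default
0.05) — ambiguity leaves a marker unplaced. For heavy missingness, a
two-step mode groups on markers with ≤30% missing data and anchors those
between 30% and 60%.

Ordering generates 150 candidate orders per group (seeded multi-start
greedy nearest-neighbor chaining refined by 2-opt local search) and
selects the one minimizing the sum of adjacent recombination fractions
(SARF), ties broken by maximal sum of adjacent LOD. The original
assay's five proprietary ordering algorithms are not published; the
multi-start + 2-opt generator is this package's replacement, while the
selection rule (min SARF, max SALOD) and the stability machinery — the
fraction of candidate orders in which a marker's rank moves by at most one
position relative to the best map — follow the published procedure.
Orientation is normalized (first marker id sorts before the last), cM
positions accumulate Haldane distances along adjacent pairs, and
exhaustive enumeration verifies optimality for groups of up to 8 markers.

## Numerical and degenerate-input choices

* rf estimates are capped at 0.4999 so LOD and Haldane transforms stay
  finite; pairs with fewer than 2 informative individuals report rf 0.5,
  LOD 0.
* Contig ids are assigned by descending abundance with lexicographic
  tie-breaks; candidate tags, greedy starts and 2-opt improvements all have
  deterministic tie rules, so every stage is reproducible bit-for-bit
  under a seed. The pipeline fans one global seed out to per-stage child
  seeds, so any stage can be re-run standalone.
* Reads at equal distance from two contigs, sites with a third allele
  above 5%, and markers with ambiguous anchor fits are all *dropped*, not
  guessed at.
* Empty inputs (no reads, empty A/B/H matrix, single-marker groups) return
  empty results or trivial orders rather than erroring, except where a
  result would be meaningless (mapping fewer than 2 markers).

## Problem sizes used in the checks

The bundled verification runs use the default BC1 design (220 offspring
plus parents, ~6.2 M simulated reads, ~510 informative SNPs) for the
end-to-end properties; 10,000 individuals for the unlinked-rf consistency
check; 2,000 F8 RILs × 500 SNPs for segregation frequencies; 1,000 SNPs ×
220 offspring with 5% injected genotype errors for the filter guarantee;
and exhaustive enumeration up to 8 markers (40,320 permutations) for
ordering optimality. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances (e.g. ±2 percentage points on
class frequencies).

## Known limitations

* Exact (100%-identity) clustering means high error rates fragment loci
  into many low-count variants; the abundance floor absorbs this at Q30
  but the design has not been stressed beyond ~1% per-base error.
* Ungapped assignment presumes fixed-start, uniform-length reads; indels
  are out of scope end to end.
* The RIL rf correction treats F8 as fully inbred; at F8 the residual
  heterozygosity (~0.8%) makes this bias negligible, but the correction is
  not exact for early generations.
* Two-point (not multipoint) estimation throughout; no interference
  (Kosambi) option.
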