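---
title: "Curating multi-study mtDNA data for skyline inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating multi-study mtDNA data for skyline inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtcurate)
```

## The problem

Public sequence repositories hold decades of mitochondrial DNA deposited by
many independent studies. Pooling those records can produce datasets large
enough for coalescent demographic reconstruction — Bayesian skyline plots
(BSPs) of effective population size (*N*~e~) through time — for species no
single study has sampled adequately. But the pooled records are not
comparable as deposited: organism fields mix species and subspecies ranks,
the same gene is annotated under many names and misspellings, RefSeq
re-publications duplicate source records, studies sequenced different spans
of the gene to different standards, and some studies deposited one record
per *haplotype* rather than one per *individual sampled*. Because haplotype
frequencies drive skyline estimates, any of these left uncorrected biases
the inference.

mtcurate is a pipeline that makes these corrections explicit, logged and
reproducible:

parse GenBank flat files → remove RefSeq duplicates → standardise organism
and gene nomenclature → restrict to the gene of interest → drop short
sequences → align → crop to the maximum overlap → strip ambiguous columns →
collapse haplotypes → audit per-study deposition style → magnify
representative haplotypes to sampled frequencies → build a haplotype
network → drop divergent singleton outliers → apply information-content
filters → emit BEAST2 skyline XML.

## Stage-by-stage rationale

### Records and RefSeq deduplication

RefSeq accessions are recognisable by the underscore in the accession
number; plain repository accessions never contain one. A RefSeq record is
removed when its declared source accession (the DBSOURCE cross-reference)
is present in the set, or when a non-RefSeq record with an identical
sequence and organism is present. A RefSeq record with no identifiable
original is **retained**: dropping it would silently lose the only copy of
the data. Accession collisions on input keep the first occurrence and log
the rest. Study identity is derived from a hash of the first reference
block's title and authors; records with no reference get
`unknown:<accession>` so that per-study audits still function.

### Nomenclature

Gene names are matched to a conversion table after case-folding and
stripping `".,-_"` and whitespace, so `nad2`, `NADH2`, `ND-2` and
`NADH dehydrogenase subunit 2` all standardise to `ND2`. This is exact
matching over a curated synonym list, not fuzzy matching: edit-distance
matching would silently conflate `ND4` and `ND4L`-type near-collisions. The
shipped table covers 18 commonly sequenced mitochondrial genes
(13 protein-coding, 2 rRNAs, the control region, 2 tRNAs) and is
user-replaceable for non-mitochondrial work. Organism names with three or
more tokens are truncated to the binomial by default, since subspecies
should usually pool under the species for demographic work; explicit map
entries override truncation, and hybrid / open-nomenclature markers
(`x`, `sp.`, `cf.`) suppress it and flag the record for manual review
instead of guessing.

### Alignment, cropping, cleaning

Same-gene mtDNA fragments from different studies are near-identical over
the region they share; they differ mostly in *which span* of the gene was
sequenced. The built-in aligner is therefore a center-star: the longest
sequence (ties broken by smallest accession) is the center, every other
sequence is aligned to it by dynamic programming, and the pairwise
alignments are merged under once-a-gap-always-a-gap. Scoring is
+1 match / −1 mismatch / −2 gap (linear, configurable), with **free end
gaps** (overlap alignment). Free end gaps matter: under fully global
scoring, the tail of a short fragment admits co-optimal "weaves" — chance
matches scattered across the center's unshared tail — and any fixed
traceback tie-break can pick one, inflating the fragment's apparent
coverage and shrinking the cropped block below the shortest input. With
terminal gaps free and internal gaps charged, the contiguous placement is
strictly optimal and the crop window is exact. Fill ties are resolved
diagonal > up > left. Users preferring a full progressive MSA can import
its aligned FASTA via `import_alignment()`.

Cropping removes columns outside the window covered by every row
(1-based, inclusive), and records the bp each sequence loses; losses above
500 bp are flagged, because a single short deposit can silently cost every
other sequence most of its length — the user should see that and decide
whether to drop the short record instead. Cropping happens **before**
ambiguity cleaning (window semantics on coverage, then content filtering):
afterwards every column holding a gap, `N`, `?` or any non-ACGT code in any
row is deleted, so downstream analyses see a gap-free unambiguous block.
The diagnostic length histogram (`summarise_lengths()`, `plot()`) shows the
original length distribution with the overlap length marked in red.

### Haplotypes, deposition audit, magnification

Identical cleaned rows collapse into haplotypes whose frequency is the
member count. A study is flagged when *every* sequence it contributed
occurs exactly once within its own contribution: either it genuinely
sampled all-distinct haplotypes (common at small sample sizes) or it
deposited one representative record per haplotype. Only the source
publication can say which, so the pipeline treats unresolved flags as a
**hard stop**: it continues only if a magnification table covers the
flagged study's accessions or the user sets
`acknowledge_unique_only = TRUE` after review. Silent continuation would
push biased frequencies straight into the skyline. A magnification table
(accession → number of individuals represented) raises each listed
accession's contribution; totals update accordingly, and lowering a
contribution is an error.

### Networks and outliers

The haplotype network is a minimum spanning tree over pairwise Hamming
distances (Kruskal, deterministic weight-then-lexicographic tie-break);
each node's `min_dist` — distance to its nearest other haplotype — comes
from the full distance matrix, not just tree edges. The network and a
crude clade-size summary (component sizes after cutting the longest MST
edge) are *reported only*: deciding whether apparent clades reflect
population sub-structure, and whether to split a dataset, is left to the
user, because over-splitting homogeneous data manufactures star-like
clusters that mimic expansions.

An "extreme outlier" is a haplotype represented by a single sample whose
`min_dist` strictly exceeds a threshold (default 30 bp). Such sequences may
be genuine, but more often are immigrants, mislabelled samples, nuclear
copies of mitochondrial genes, or bad sequencing, and they distort
coalescent inference. Outliers are removed most-divergent-first with
`min_dist` recomputed after each removal, so the result does not depend on
processing order; a post-removal FASTA is written for downstream use.

### Information-content filters

A single-gene skyline needs enough signal. Species datasets are dropped
when they have fewer than 6 haplotypes, fewer than 20 samples, or fewer
than 600 cleaned bp; each dropped species carries *all* failing reasons.
Boundary semantics are strictly-less-than, so exactly 6/20/600 passes. The
three predicates commute, so filter order cannot change the outcome. These
defaults suit a single mitochondrial gene and are deliberately exposed:
there is no out-of-the-box value that fits every gene, mutation rate and
sample size.

### BEAST2 XML and run diagnostics

`setup_basic_xml()` writes a skyline-ready BEAST2 (2.6-layout) skeleton:
the cleaned alignment verbatim, a strict clock at the user's mutation rate,
a coalescent Bayesian skyline tree prior with a configurable group count
(default 5), HKY with empirical base frequencies by default (JC69
available; the default is a package choice, not a claim about the best
model), and trace/tree loggers named from the output stem. The mutation
rate is a plain user input — taxon-specific calibration (e.g. from body
mass) is out of scope and left to the user's judgement. The XML is
validated by parse-ability and exact round-trip of sequences, taxa, rate
and chain length, not byte equality, since element layout varies across
BEAST 2.x versions. Running the MCMC itself is out of scope.

For run diagnostics, `effective_sample_size()` implements
ESS = *n* / (1 + 2 Σ ρ~k~), truncating the autocorrelation sum by the
initial-positive-sequence rule (consecutive autocorrelation pairs are added
while their sum stays positive; autocorrelations via FFT). The integrated
autocorrelation time is clamped to ≥ 1 so ESS never exceeds *n*, and a
constant series returns ESS = 1 by convention. Estimates below 200
(configurable) are flagged: such chains need more states before their
skyline output should be trusted. Default burn-in is 10%.
`parse_skyline_summary()` reads Tracer-style exports (case-insensitive
time/median/upper/lower columns), validates lower ≤ median ≤ upper and
strictly increasing times, and `plot()` draws the median (dashed) inside
the 95% HPD envelope.

## The synthetic-data generator

`generate_records()` emits GenBank-style flat files whose ground truth is
known by construction, so every pipeline stage can be checked exactly. It
emulates: subspecies name variants (default rate 0.2), inconsistent
gene-name spellings drawn from a variant pool, RefSeq duplicate accessions
with DBSOURCE back-references, heterogeneous record lengths
(suffix-truncation of full haplotypes; default 600–700 bp, a typical
single-gene deposit range), study-structured haplotype frequencies
(decreasing-weight spectrum over a default 8 haplotypes and 40 samples,
every haplotype guaranteed ≥ 1), unique-haplotypes-only deposition styles
with the true counts written to a magnification table, and divergent
singleton outliers (default 35 bp, comfortably beyond the 30 bp removal
threshold). Haplotypes are made by mutating a random ancestor at recorded,
pairwise-disjoint positions inside the guaranteed overlap window, so all
Hamming distances and post-crop identities are known a priori; frequencies
are drawn, not evolved — no coalescent realism is attempted.

What passing the generator-based tests shows: the bookkeeping — parsing,
deduplication, standardisation, collapse, magnification, outlier removal,
filtering — reproduces a known truth exactly under realistic record
pathologies. What it does not show: behaviour on real data with genuine
indels, recombination-free but NUMT-contaminated amplicons, re-sequenced
museum specimens deposited under multiple accessions, or deeply structured
populations. Those require the user's eyes, which is why the pipeline
reports and halts rather than auto-resolving.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere.
* Alignment fill ties: diagonal > up > left; center ties: smallest id.
* An empty overlap window (non-overlapping fragments) is an error advising
  removal of the offending sequences, not a silent empty alignment.
* Zero unambiguous columns after cleaning is an error.
* A single haplotype yields a one-node network with `min_dist` undefined;
  outlier removal needs ≥ 2 haplotypes and otherwise does nothing.
* ESS needs ≥ 10 retained samples; a zero-variance series returns 1.
* All iteration orders are deterministic, and generators take explicit
  seeds, so re-running a configuration reproduces its report byte-for-byte.

## Known limitations

* **Near-threshold outliers.** The outlier rule compares post-alignment
  Hamming distance with a strict threshold. For divergences within a few
  bases of the threshold, an optimal-score alignment can legitimately trade
  a dense mismatch cluster for an indel pair, and column cleaning then
  erodes the measured distance by 2–3 bases — enough to flip a 31–33 bp
  outlier below a 30 bp threshold. The decision boundary should not be
  treated as sharp at that resolution; the validation suite exercises
  divergences of 35 bp and above.
* Re-sequenced individuals deposited under different accessions (museum
  specimens sampled by several studies) are not detectable from record
  content and are not handled.
* The center-star aligner is adequate for near-identical same-gene
  fragments but is not a substitute for progressive MSA on diverged or
  indel-rich data; import an external alignment in that case.
* Network construction is a plain MST; reticulations (alternative equally
  parsimonious edges) are not drawn.
* Live repository retrieval is out of scope; records are read from local
  flat files.

## Validation problem sizes

The shipped checks run, among others: exhaustive-enumeration agreement of
pairwise alignment scores (500 random pairs up to 8 bp, where enumeration
over all monotone matchings is feasible); brute-force minimum spanning
tree agreement over all labelled trees (1,000 random tables of up to 6
haplotypes, via Pruefer enumeration); end-to-end ledger recovery on 50
randomised generator specifications (20–40 samples, 4–8 haplotypes,
300–510 bp, 1–3 studies, optional RefSeq duplicates, unique-only studies
and 35–45 bp outliers); ESS calibration on 10,000 i.i.d. draws and an
AR(1) series of 50,000 states with lag-1 autocorrelation 0.9; and exact
XML round-trips for 20 random toy alignments. These sizes were chosen so
the whole suite completes in about a minute on a laptop while still
enumerating the oracle spaces exhaustively.
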