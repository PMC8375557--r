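---
title: "Sex-specific marker discovery from 2b-RAD tags: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific marker discovery from 2b-RAD tags: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rad2b)
```

## The problem

Many gonochoristic aquaculture species — sea urchins prominently among
them — show no external sexual dimorphism, yet growth, immunity and
product value differ by sex. With no heteromorphic sex chromosomes to
karyotype, the practical route to genetic sexing is reduced-representation
sequencing of a known-sex panel: find sequences present in every
individual of one sex and absent from the other (sex-limited tags), and
sites at which one sex is constitutively heterozygous while the other is
homozygous (gametolog SNPs). The direction of both signals identifies the
heterogametic sex: female-limited markers and female-only heterozygosity
imply ZW/ZZ; the mirror implies XY/XX.

This package implements that whole analysis chain at desk scale, together
with a synthetic-data generator that plants a known sex-linked
architecture, so every inference step can be validated against ground
truth without any sequencing download.

## 2b-RAD tag model

Type IIB restriction enzymes cut on both sides of their recognition site,
releasing a uniform short fragment. We model BsaXI by its interrupted
recognition motif `AC(N5)CTCC` and fixed retention offsets: 9 nt retained
5' of the motif and 7 nt 3', giving a 27-nt tag core
(9 + 11 + 7), with 3 further terminal bases on each side in the 33-nt
sequenced read. The enzyme's physical cut-offset chemistry is not modelled;
the motif-plus-offsets abstraction reproduces the observable object — the
tag — exactly, and the published candidate-tag sequences shipped in
`inst/extdata/table3.tsv` all match this structure (one forward motif at
core offset 9), which is how the geometry was fixed. Custom enzymes can be
described with `recognition_spec()`.

Because tags are double-stranded, tag identity is the lexicographic
minimum of a core and its reverse complement (`canonicalize()`). The
scanner (`scan_motif()`) matches the IUPAC motif on both strands
(motif-side ambiguity codes expanded; subject-side `N` never matches,
and any `N` inside a core window skips that site with a logged count),
reports all overlapping sites, and uses 0-based half-open BED-compatible
coordinates throughout.

## Read quality control

Reads are filtered in a fixed, documented order:

1. `wrong_length` — not the expected 33 nt;
2. `n_excess` — ambiguous-base fraction strictly above 8% (so 3 Ns in
   33 nt fail, 2 do not);
3. `low_quality` — mean Phred below 20. The upstream filtering criterion
   this mirrors is stated only as "poor-quality reads", so the threshold
   is an explicit, exposed assumption;
4. `no_motif` — no recognition-site match on either strand with a full
   core window.

Survivors are trimmed to the 27-nt core with the motif at offset 9,
reverse-complementing minus-strand matches rather than discarding them
(this maximizes usable data; the alternative is a parameter away), and
canonicalized. The accounting invariant `raw = clean + sum(reasons)` is
enforced and tested.

## Catalog clustering and genotyping

Clean cores are clustered into tag loci the way stacks-family pipelines
do, but with a deterministic, order-free rule: sequences are processed by
descending total abundance (lexicographic tie-break); each joins the
nearest existing locus whose founder is within 2 substitutions (in either
orientation — a variant can flip a tag's canonical strand, so both are
tried and alleles are stored in the founder's frame), otherwise it founds
a new locus. A pigeonhole chunk index (a sequence within *m* mismatches
of a founder must share one of *m*+1 exact chunks) keeps this near-linear.

Genotypes are called by depth thresholds rather than a likelihood model —
adequate and fully deterministic at 2b-RAD depths of ~30–40x:

* total depth < 3 → **absent** (the "fewer than three reads are
  precluded" rule; the same threshold defines presence/absence in the
  screening matrix);
* second allele with ≥ 2 reads and a minor fraction strictly above 0.1 →
  **het**;
* otherwise **hom** for the major allele.

Loci with more than two call-supported alleles are flagged multiallelic
and excluded from SNP association. SNP rows report 1-based positions on
the 27-nt tag with the major allele as reference, matching the published
table schema.

## K-mer genome survey

`count_kmers()` builds the canonical 17-mer multiplicity spectrum (the
jellyfish `-m 17 -C` behaviour) with a single rolling 2-bit pass over the
N-joined read concatenation. `estimate_genome_size()` is a deliberately
simplified single-peak estimator, not a mixture model: the error cutoff
is the first local minimum of the window-3 smoothed spectrum; the
homozygous peak is the raw argmax of multiplicity x count within 2 of the
smoothed argmax (the raw refinement makes degenerate single-multiplicity
spectra exact); genome size is the k-mer mass above the cutoff divided by
the peak depth.

Heterozygosity comes from the half-depth band (multiplicities between the
cutoff and 0.75 x peak): each diverged locus contributes two distinct
half-depth k-mers, so with `het` and `hom` the distinct counts in the two
bands, the fraction of affected loci is
$h = \frac{het/2}{het/2 + hom}$, and the per-base rate is
$r = 1 - (1-h)^{1/k}$, inverting the probability that a k-mer overlaps at
least one diverged site. On simulated diploid reads with 1% planted
divergence this recovers estimates within the tested [0.5%, 2%] band; the
band is wide because Poisson tails leak between the two bands at 30x
total depth.

## Sex screening and system inference

The default tag criterion is strict, matching how candidate sex markers
are nominated in practice: present in **all** individuals of one sex and
**none** of the other (`min_present_fraction = 1`,
`max_absent_sex_presence = 0`; both relaxable for missing data). Every
marker additionally carries a two-sided Fisher exact p-value from its
presence (or het/hom) 2x2 table. The association test is not named in the
analysis this package re-implements; Fisher's exact test was chosen
because it is exact at n = 20 and reproduces the natural extreme-table
benchmark: a perfect 10-female vs 10-male split gives
p = 2/184756 ≈ 1.08e-5. The implementation enumerates the hypergeometric
support in log space and sums probabilities at most (1 + 1e-7) times the
observed table's; `stats::fisher.test` and a direct enumeration oracle
serve as independent cross-checks in the tests, and an allele-count model
is available as an alternative.

Multiple testing: raw p is reported alongside Bonferroni and
Benjamini-Hochberg columns, but candidate selection uses rank (top-N),
as marker panels are selected in this field; ranking ties break
lexicographically on marker id for reproducibility. Absent calls are
dropped per marker, never imputed.

`classify_pattern()` labels each SNP `female_heterogametic`
(all non-absent females het, all males hom for one shared allele),
`male_heterogametic`, `fixed_difference`, or `uninformative`. Applied to
the shipped 10-SNP candidate fixture this yields 7 / 2 / 1 of the first
three classes — notable because the accompanying text describes all ten as
female-heterozygous while three printed rows are not; the classifier
follows the printed genotypes, and this discrepancy is surfaced rather
than resolved. `infer_system()` calls ZW only when female-specific tags
strictly outnumber male-specific ones **and** female-heterogametic
patterns are at least as common as male-heterogametic ones among the
top-ranked SNPs (mirrored for XY, anything else undetermined).

## What the simulator emulates — and what it does not

`sim_config()` defaults encode the emulated study design: 10 females and
10 males, a ZW system, per-tag depths near 37x, 33-nt reads. The
generator builds a motif-free random autosomal/Z contig (accidental
recognition sites, including those straddling planted-window junctions,
are disrupted by point changes at non-wildcard motif positions), plants
tag windows with exactly one motif occurrence each, and adds a single
separate W (or Y) contig for sex-limited tags — one contig rather than
scattered regions purely for truth bookkeeping. Gametolog loci make the
heterogametic sex ref/alt heterozygous; autosomal loci draw Hardy-Weinberg
genotypes at allele frequency 0.5. Reads are Poisson per haploid tag copy
(`coverage_mean` is per copy, so a homozygous diploid locus sequences at
about twice it), with iid substitution errors, random strand and constant
Phred 'I' qualities.

Deliberately not modelled: indels (tags are too short for meaningful
indel handling), PCR duplicates, realistic base-quality profiles, paired
read merging (reads are emitted already merged), enzyme star activity and
methylation sensitivity, and repeat content in the survey genome. The
per-locus depth distribution of real libraries is unknown; Poisson is an
assumption. Passing tests therefore demonstrate correctness of the
inference machinery under this generative model, not robustness to
artifacts real libraries may carry (allele dropout, depth overdispersion,
paralogy).

## Problem sizes and numerical choices

The reference validation runs use a 100 kb genome with 213 planted loci
(3 W-limited, 10 gametolog, 200 autosomal), 30 reads per copy and 1%
error — a scale a desk machine simulates and analyses in seconds while
leaving every statistical signal at its study-design strength; the null
(no sex linkage) behaviour is checked across dozens of smaller seeded
replicates (20 kb, 50 loci, error-free). The k-mer survey checks use
100 kb genomes at 30x. All randomness flows from a single integer seed
per simulation product, so every output is byte-reproducible; fixtures
transcribing published tables are frozen by checksum so tests anchored to
published values cannot drift silently.

## Known limitations

* The genotype caller is threshold-based; at depths well below ~15x a
  likelihood model would behave better.
* The survey estimator is single-peak; heavily repetitive or very
  heterozygous genomes need a proper mixture model.
* Catalog clustering is ungapped; indel-bearing alleles would split loci.
* The headline counts of the motivating study (tens of thousands of real
  SNPs, its genome size, its alignment rates) depend on its deposited
  raw data and are out of scope here; the package reproduces the
  printed-table arithmetic, the marker structure, and the inference
  logic, validated on synthetic truth instead.
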