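---
title: "Methods: small-RNA miRNA discovery and expression profiling with mirfruit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA miRNA discovery and expression profiling with mirfruit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirfruit)
```

# Scope

`mirfruit` re-implements, as a tested desk-scale pipeline, the classical
small-RNA sequencing analysis used to profile miRNAs across plant fruit
development: library cleaning and categorization, conserved miRNA
identification against a miRBase-style reference, novel miRNA prediction
from genomic hairpins, TPM-based differential expression across staged
libraries with a digital-count significance test, rule-based miRNA
target prediction, genomic cluster detection, annotation-term enrichment
factors, and comparative ddCt qPCR quantification. A synthetic-data
generator plants every signal the pipeline is meant to detect, so all
stages are testable end to end without any sequencing download.

# Read cleaning and categorization

Cleaning applies, in order: 3' adapter removal (leftmost exact
occurrence of an adapter prefix with at least 6 nt of overlap; reads
without a located adapter retain their full length and are usually
removed by the length filter), poly-A removal, a mean-Phred quality
filter, and an 18–30 nt length window. Survivors are collapsed to unique
sequences with read counts; everything downstream consumes this
collapsed representation.

Three cleaning parameters are stated nowhere in the protocol this
pipeline descends from and are therefore package choices, fixed once:
poly-A means at least 80% A in the trimmed insert; "low quality" means
mean Phred below 20; the adapter must overlap by at least 6 nt. All
three are exposed as arguments.

Categorization assigns each unique sequence exactly one category by a
fixed priority: ncRNA (rRNA/snRNA/snoRNA/tRNA) > known miRNA > repeat >
exon_sense > exon_antisense > intron_sense > intron_antisense >
unannotated. The priority order itself is a design choice (the common
exclusion order of small-RNA pipelines) because the source protocol
never states one; fixing it makes the partition reproducible, and the
partition property (categories sum to clean reads) is asserted in the
tests. Matching is exact search — equality against mature references,
substring against ncRNA references, exact genome mapping plus interval
overlap for repeat/exon/intron — rather than BLAST: at desk scale exact
search is deterministic and the search backend is not the scientific
content. Per-category averages over libraries are rounded half-up to
integers; that convention is what reproduces published per-category
averages ending in .5.

# Folding model

Hairpin evaluation needs a secondary-structure folder. The built-in
backend minimises an additive pair-energy proxy (GC = −3.0, AU = −2.0,
GU = −1.0 kcal/mol) over nested structures with a minimum hairpin loop
of 3 nt and **no isolated base pairs**, by interval dynamic programming
(in C++) with full traceback to dot-bracket. The no-lonely-pair
constraint is the one refinement over the plain maximum-stability
recursion: without it, any two complementary bases 4 nt apart form a
spurious one-pair "hairpin", littering real stem-loops with phantom
terminal loops and making loop-counting criteria meaningless. With it,
the model recovers clean hairpins for planted precursors while staying
simple enough to verify by exhaustive structure enumeration (the test
suite does exactly that at small lengths, plus an independently coded
interval recursion up to 30 nt).

Energies from this model are comparable only within the model: they are
not Turner free energies and will not reproduce published RNAfold
values. The backend is pluggable — any function returning a balanced
dot-bracket of equal length and a non-positive energy can be
substituted — so a thermodynamic folder can be wired in without touching
the criteria code. Mean folding energies reported by the pipeline are
therefore data- and backend-dependent outputs, not constants to compare
across tools.

# Conserved and novel miRNA identification

A clean sequence counts toward a known miRNA if and only if it equals
the reference mature sequence (T/U equivalent) — exact matching, no
mismatch tolerance, following the "perfectly matched" convention.
Families derive from reference names by stripping species prefixes,
variant letters, arm suffixes and star marks.

Novel prediction takes the unannotated unique sequences with a summed
read count of at least 3 (a MIREAP-style floor), maps them exactly to
the genome on both strands, and excises two windows around each locus
(150 nt upstream or downstream, window capped at 374 nt). Each window is
folded; the star arm is located as the largest contiguous cluster of
partners of the mature region (stray long-range pairs into flanking
sequence are ignored, and the star-side bound is padded so mature edge
positions recover their true complement); the candidate is trimmed to
the mature–star span and refolded; and the hairpin criteria are
evaluated on the trimmed precursor:

* precursor length 64–374 nt, mature length 18–25 nt;
* a single mature/star junction: every terminal loop lies between the
  two arms. Micro-stems *inside* the junction loop are tolerated — under
  a naive energy model the junction of a genuine hairpin frequently
  carries a small extra stem, and rejecting those would reject real
  precursors; loops inside either arm remain disqualifying;
* at least 16 mature nucleotides paired to the star, at most 4 unpaired
  mature positions in the duplex, no asymmetric bulge larger than 2 nt;
* folding energy at or below −18 kcal/mol (configurable).

The numeric thresholds follow the community (Meyers-style) criteria;
the protocol this descends from cites them without printing numbers
beyond the length range and the hairpin requirement. Accepted
candidates are deduplicated by mature sequence; known and novel sets
are disjoint by construction and by test.

# Differential expression

Counts are normalised as TPM = count × 10⁶ / clean-read total of the
library — no pseudocounts. Comparisons are pairwise against the control
stage (15 DAF by default): a TPM of zero on either side is revised to
0.01, and a pair with both adjusted values below 1 is excluded as too
low to compare. The zero/low rules are interpreted pairwise per
comparison, matching the pairwise fold-change definition
log2(treat / control).

The significance test is the exact conditional digital-count test:
conditional on the total *x* + *y*, the count *y* from the library of
*N₂* reads follows a binomial with size *x* + *y* and probability
*N₂*/(*N₁* + *N₂*); the p-value doubles the smaller tail (observation
included) and caps at 1. This is the conditioned, symmetric form of
the classical Audic–Claverie digital-expression comparison: the raw
Audic–Claverie conditional (negative binomial in *y* given *x*) is not
invariant under swapping the two libraries — even at equal depths its
doubled-tail p-values differ between orientations — whereas the
conditional form satisfies
`de_test(x, y, N1, N2) = de_test(y, x, N2, N1)` exactly, which is the
behaviour a two-sided comparison of two libraries should have. The
choice is a documented assumption either way: the protocol this
descends from promises a formula it never prints, and the digital
exact test is the standard of that pipeline generation. The test runs on raw counts with library totals
(any count-based exact test requires them); TPM is reported alongside.
Raw p-values are labelled at 0.05/0.01, the reporting convention of
such studies; Benjamini–Hochberg adjustment is available but off by
default. Trends across stages are classified as increasing/decreasing
only when non-strictly monotone with at least one strict step —
deliberately strict, so a peak followed by a decline is "other".

qPCR validation support computes comparative ddCt relative expression:
dCt = Ct(target) − Ct(reference), ddCt relative to the control stage,
relative expression 2^(−ddCt) (1 at the control stage by definition).

# Target prediction and enrichment

A target site is an ungapped duplex: miRNA position *i* (numbered from
the miRNA 5' end) faces site position *L* − *i* + 1. Five rules decide
acceptance: total mismatches ≤ 4 with G:U wobbles counting 0.5; no more
than two adjacent full mismatches; no adjacent full mismatches within
positions 2–12; no full mismatch at positions 10–11; weighted
mismatches within positions 1–12 ≤ 2.5. Wobbles neither form nor break
adjacency — they are weighted only in the sum rules; that reading is
isolated behind one predicate so it can be flipped if a different
convention is wanted. Gapped duplexes are out of scope (the printed
rules mention only mismatches). The rule kernel is checked exhaustively
against an independently coded string-based checker over all status
vectors with up to six altered positions.

Enrichment of an annotation term among target genes is the enrichment
factor (k/n)/(K/N) with a hypergeometric upper-tail p-value,
BH-adjusted by default (enrichment screening is where the false
discovery rate control belongs).

# Genomic mapping and clusters

Mature sequences map to the genome by exact search on both strands
(occurrences of the reverse complement are minus-strand loci); all
overlapping occurrences are reported and the occurrence count is the
transcript-site count. Clusters are single-linkage chains per
chromosome, strand-agnostic: sort by start, chain while the inter-locus
gap is at most *d*, keep chains with at least two loci. *d* is always
an explicit parameter — published cluster counts at nominal distances
are input-dependent and internally inconsistent in the literature this
follows, so the package asserts nothing about any particular pairing of
distance and count. Coordinates are 1-based inclusive internally
(GFF3-native); BED export would convert at the boundary.

# The synthetic study generator

`sim_config()` defaults define the simulated study: six libraries
labelled 15/36/81/110/145/167 DAF; 50,000 reads per library (the
sequenced study ran ~20M reads per library; depth is scaled down
explicitly and configurable); four 500-kb chromosomes with uniform
background composition; 30 known matures and 20 novel precursor
hairpins planted at recorded loci; 3 clusters planted as locus pairs
within 10 kb; 60 transcripts with 25 planted target sites spanning
perfect, wobbled and rule-violating edit sets; 25% contaminant reads
split among ncRNA decoys, repeat, exon/intron and intergenic fragments,
poly-A reads and sub-18-nt fragments. Mature lengths are drawn so
21–24 nt dominate with 24 nt most frequent, and first bases are
U-biased (37% U / 31% A / 18% G / 14% C) — the canonical plant
small-RNA profile. Counts are negative binomial (dispersion size 5 by
default) around per-miRNA log-normal baselines; ten known miRNAs carry
a planted monotone 8-fold trend (five up, five down) implemented as a
geometric ramp across stages. Novel precursors are built as arm + A/C
loop + noisy reverse-complement arm, so they genuinely fold under the
package's own energy model; the A/C loop cannot pair internally, which
keeps the planted hairpin's junction clean. Generated inserts are
rejection-sampled against containing the adapter seed, so simulated
reads trim unambiguously. Base qualities are constant high by default;
a degraded-quality mode exists solely to exercise the quality filter.

What the generator does **not** emulate: sequencer error models, PCR
duplication, isomiR heterogeneity, non-uniform genomic base
composition, and real ncRNA family structure. Passing the recovery
tests therefore demonstrates that the pipeline's logic is correct under
its stated assumptions, not that it would achieve the same sensitivity
on real libraries.

Determinism: `generate_genome()` seeds the RNG with the config seed;
`simulate_libraries()` and `generate_transcripts()` use seed + 1 and
seed + 2, so each stage is reproducible standalone and the whole bundle
is byte-identical across runs.

# Problem sizes and numerical choices

The test suite and the acceptance script run the full pipeline on the
default 6 × 50,000-read study (a few minutes on one CPU); module tests
use a 2 × 150-kb genome with 2,000-read libraries. Exhaustive fold
enumeration is limited to 14 nt (structure counts explode beyond that);
an independent memoised recursion covers lengths to 30 nt. The
digital-count test is computed through the negative-binomial tail
(`pnbinom`) rather than explicit summation, and its test oracle sums
log-gamma terms directly. Ties in folding are broken toward the
unpaired/leftward option by strict-improvement comparison, making
tracebacks deterministic. Degenerate inputs are defined, not crashed: an
empty length class yields an NA bias vector, an empty locus set an empty
table, and a candidate window whose mature region cannot find a star is
rejected with all flags populated.

# Known limitations

* The folding proxy has no stacking, dangles or loop-size terms;
  absolute energies are not comparable to thermodynamic folders.
* Exact matching defines "known": isomiRs and near-matches flow into
  novel prediction instead of being grouped with their family.
* Ungapped duplexes only in target prediction.
* The Audic–Claverie choice for the significance test is an assumption
  (documented above), and raw p-values are the default reporting.
* Cluster detection is purely positional; it does not model polycistron
  transcription.
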