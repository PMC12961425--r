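---
title: "Curating TE consensus libraries with mycomob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating TE consensus libraries with mycomob}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycomob)
```

## The problem

De novo transposable-element (TE) discovery tools emit libraries of
consensus sequences that mix three things: genuine autonomous TEs whose
open reading frames betray their identity, genuine but protein-less
(non-autonomous or degraded) repeats, and multicopy *host genes* that were
captured only because they are repetitive. Before such a library can be
used for homology-based annotation — let alone merged across thousands of
genomes — the host genes have to go, poor-quality consensus sequences have
to be flagged or removed, redundant family variants have to be collapsed,
and every surviving sequence needs a stable, information-bearing name.

mycomob implements that curation pipeline for fungal TE libraries at desk
scale, together with a base-pair-resolution comparison of competing TE
annotation sets of the same genome. It does not run any search tool
itself: users supply the outputs of their protein searches (tabular
BLAST/DIAMOND against a reference proteome and against a TE-peptide
library, and a HMMER domain table against TE profile HMMs), and the
package makes the decisions.

## The decision core

### One coordinate axis

Protein hits arrive in the residue coordinates of one of six translated
frames. All downstream logic works on a single shared axis — the forward
strand of the consensus, 0-based half-open. A residue span $[s, e)$ of
forward frame $f \in \{1,2,3\}$ projects to nucleotides
$[3s + f - 1,\; 3e + f - 1)$; for a reverse frame $f \in \{4,5,6\}$ the
span is projected on the reverse complement and mirrored through the
consensus length $L$. Every projected interval has length $3(e-s)$ and
lies inside $[0, L)$; these two facts are enforced by property tests.

### Hit hygiene

Hits are first filtered with inclusive per-category thresholds:
reference-proteome and TE-peptide hits at e-value $\le 10^{-3}$, profile
hits at full-sequence e-value $\le 10^{-3}$ *and* full-sequence bit score
$\ge 50$. Within one consensus and category, *nested* hits (one span fully
contained in another) are resolved by keeping the higher-quality hit —
quality ordered by bit score, then e-value, then span length, then subject
id. The resolution is applied greedily in quality order, which guarantees
the output contains no containment pair and makes the outcome
deterministic even when several removal orders would be admissible.
Surviving spans are then coalesced into coverage intervals; spans
overlapping, touching, or separated by at most `gap_max_nt` (default
30 nt, i.e. 10 residues) become one interval. The gap default bridges
short indels or frameshifts that split one protein alignment into several
HSPs, while staying far below the typical distance between distinct
domains; it is exposed in the configuration.

### The host-gene rule

With RefSeq coverage $R$ and TE-protein coverage $T$ (the union of the
peptide and profile coverage) on the shared axis, a consensus is a
putative host gene if

1. $R \ne \emptyset$ and $T = \emptyset$, or
2. both are non-empty and
   $\lfloor |R \setminus T| / 3 \rfloor \ge 90$ residues.

The floor-of-thirds conversion is used because $R$ and $T$ may come from
different frames, so residues are only comparable after projection to
nucleotides. By default the exclusive count is taken on the union of all
RefSeq subjects; this is the conservative reading (more sequences
removed) of "at least 90 residues aligned to a reference query". The
alternative reading — a *single* reference protein must contribute the 90
exclusive residues — is available as
`exclusive_mode = "per_subject"`, which takes the maximum over subjects.
Union mode removes at least as many sequences as per-subject mode; the
difference only matters when several distinct host proteins each cover a
different part of the consensus.

Consensus sequences with no hits at all are retained and marked
non-autonomous: absence of protein evidence is not evidence of host-gene
origin.

### Quality filtering and genome flags

Host-gene removal runs first; quality filtering second. A record that
fails both is accounted as a host gene, never double-counted. The quality
rules are exactly the printed boundaries: removed when shorter than
120 bp (strict) or when the N fraction is at least 5% (inclusive — a
200 nt sequence with 10 N is removed). Records from assemblies with N50
below 50 kb *and* BUSCO completeness below 90% — a conjunction — carry an
`LQGenome` flag in their headers rather than being removed; a missing
BUSCO value is an error because the conjunction cannot be evaluated.

### Evidence labels

Each retained consensus is labelled with the relationship between its
assigned classification and its TE-protein hits, after resolving hit
subjects through a domain-to-classification mapping table (exact match
first, then prefix match): `PE` when mapped evidence is concordant and
nothing conflicts, `DA` when any mapped hit conflicts, `NE` when no hit
maps to an informative classification (which includes all non-autonomous
records). Three decisions close gaps the rule statement leaves open:

* a hit that matches at the high level but conflicts at a defined
  sub-level (e.g. *LTR/Copia* evidence on an *LTR/Gypsy* consensus)
  counts as a conflict — conflict is exactly the signal `DA` exists to
  carry;
* a consensus classified `Unknown` is compatible with any evidence, so
  mapped hits yield `PE` (the evidence supports, and cannot contradict, a
  vacuous claim); this keeps the invariant that `NE` holds exactly when
  no mapped evidence exists;
* mapping rows with an empty classification mark uninformative domains
  and never count as evidence.

Evidence is computed per record; the family's label (its representative's)
is propagated to member names in the unclustered library.

## Family clustering

Families follow the 80-80-80 rule: two sequences belong together when
they align at $\ge 80\%$ identity over $\ge 80\%$ of the shorter sequence
and are at least 80 bp long. `greedy_cluster()` is a reference
implementation in the greedy longest-first style of CD-HIT: candidates
join the first cluster whose *representative* they match, on either
strand. This approximates — deliberately, and only at desk scale — the
cascaded clustering of dedicated tools; the two are interchangeable
through the shared two-column cluster table, and everything downstream
depends only on the acceptance rule, not on how clusters were found.
Clustering operates on nucleotide sequences (the rule's identity is a
nucleotide identity). Alignment uses local alignment with match $+1$,
mismatch $-1$, gap open $-2$, gap extend $-1$ (a gap of length $k$ costs
$2 + k$); identity is matches over alignment columns including gaps, and
coverage is the aligned span of the shorter sequence over its length.
`N` never counts as a match. An independent full-matrix Gotoh aligner
with traceback (`dp_align_stats()`, implemented in C++) serves as the
brute-force cross-check: tests verify score agreement with the production
aligner and re-verify every cluster member against its representative.

Ties in the production aligner's traceback (alternative optimal
alignments) can shift identity by a column or two; tests that demand
exact identity agreement therefore use end-anchored substitution-only
pairs, for which the optimal alignment is unique, while rule-level checks
always operate with a margin well away from the 0.80 threshold.

## Naming

Names follow the two grammars

```
MycMob<release>_family-<n>-<CODE>_<PE|DA|NE>[_LQGenome]#<high>[/<sub>] @<Genus> <epithet>
MycMob<release>_family-<n>_member-<m>-<CODE>_<EV>[_LQGenome]#<high>[/<sub>] @<Genus> <epithet>
```

with the six-letter species code in the family block for clustered
families and in the member block for unclustered members, following the
printed templates literally. Family numbers are assigned by descending
cluster size with ties broken by representative id — any deterministic
order would do, since only uniqueness and persistence matter; the chosen
order is recorded in the emitted name map so future releases can keep
numbers stable through an identity mapping. The species code itself is a
convention (the grammar names it but not its construction): first three
letters of genus and epithet, initial capitals, non-alphabetic characters
dropped, parts shorter than three letters padded with `x`
("Zymoseptoria tritici" → `ZymTri`). Code collisions across species are
tolerated because the family/member number is the unique key. The
`LQGenome` token is placed directly after the evidence code. Parsing and
formatting are exact inverses on grammar-valid names, enforced by a
round-trip property test over generated headers.

## Comparing annotation sets

`compare_annotations()` quantifies the agreement of two TE annotation
sets of one genome in two accountings, both reported:

* **position-level** — genomic positions covered by both methods are
  shared, positions covered by one are unique to it; the three categories
  partition all annotated positions, so per-method coverage is conserved
  (`covered = shared + unique`) and percentages sum to 100;
* **width-level at shared loci** — for the shared category each method's
  own annotation widths are summed separately, because two methods
  rarely agree on the extent of the same element.

Strand is ignored: repeat annotations are compared as genomic extents.
Within a method, overlapping same-class features are merged on read;
features of *different* classes are left as they are, so the per-class
breakdown sums exactly to the category totals only when a method's
classes do not overlap each other — the situation the synthetic generator
plants, and the common case for defragmented annotations.

## The synthetic generator

`make_fixture()` builds the entire input side — library FASTA, hit tables
in the real external formats, genome metadata, mapping table, and an
annotation pair — with planted outcomes, and computes the expected
verdict of every record with an *independent* per-position brute-force
routine (boolean coverage arrays, re-stated thresholds, re-stated
projection arithmetic) at generation time. The default composition: three
clean TEs exercising all three evidence labels, two branch-(i) host
genes, two branch-(ii) host genes at 149 exclusive residues, one
borderline record at exactly 89 exclusive residues (retained — one
residue short of removal), records of 119 and 60 nt (119 probes the
strict length boundary), and a 200 nt record with exactly 10 N (the
inclusive 5% boundary). One genome in the metadata is planted below both
LQ thresholds. All randomness flows from one seed and output is
byte-identical per seed.

What the generator does *not* emulate: realistic TE sequence evolution
(LTR structure, target-site duplications, nesting), realistic protein
similarity (hit tables are constructed geometrically, not by running a
search), or fragmented multi-HSP alignments. Tests passing on fixtures
therefore demonstrate that the decision rules are implemented exactly —
not that the thresholds are biologically optimal for any particular
genome.

`make_family_set()` plants families by mutating a random 300–2000 nt
ancestor per family at a per-position substitution rate, reverse
complementing every second copy. At rate 0.05 within-family identity is
about 0.90 — comfortably above the 0.80 threshold — and clustering must
recover the planted families; at rate 0.35 pairwise identity between
copies falls to roughly 0.46, far below threshold, and every sequence
must found its own cluster.

## Problem sizes and numerical choices

The shipped test-suite scales are: 1000 random interval geometries each
for the host-gene, interval-merge, and comparison oracles; 20 seeded
replicates per clustering regime with families of four copies at 300–1200
nt; 1000 generated headers for the grammar round trip. These sizes give
every property enough room to fail while keeping a full run in minutes on
one core.

Degenerate inputs are defined, not accidental: empty hit sets yield
retained non-autonomous `NE` records; an empty RefSeq coverage can never
produce a host-gene call; empty cluster input yields empty named output;
zero-score alignments report identity and coverage 0. Interval sets are
normalized (sorted, overlapping-or-touching merged) at construction, so
all set algebra operates on canonical forms. All threshold comparisons
are inclusive exactly as written above; none has a hidden epsilon.

## Limitations

Domesticated transposases and TE-derived host genes sit exactly on the
boundary this pipeline draws; conservative host-gene filtering will
remove some genuine TE-derived sequences, and no attempt is made to
recognize them. The greedy clusterer is quadratic in the worst case and
is not intended beyond roughly $10^4$ sequences — delegate larger
libraries to an external clusterer and import its cluster table. The
80-80-80 rule itself over-merges young families and over-splits ancient
ones regardless of implementation. Evidence labels inherit every bias of
the supplied mapping table; an incomplete mapping inflates `NE`.
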