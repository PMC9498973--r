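---
title: "Methods: ITS barcoding analysis with barcodekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ITS barcoding analysis with barcodekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodekit)
```

## The problem

Closely related congeneric plants — the motivating case is *Actinidia
eriantha* and seven relatives whose dried roots are traded as traditional
medicine — are hard to tell apart morphologically, especially as powdered or
dried material, which invites adulteration. The nuclear ribosomal internal
transcribed spacer (ITS: ITS1–5.8S–ITS2, roughly 620–640 bp in these taxa) is
a standard plant DNA barcode for this situation: it is near-invariant within a
species, clearly divergent between species, short, and easy to amplify.

`barcodekit` implements the complete analysis such a study runs after
sequencing: build a master alignment, partition it into ITS1/5.8S/ITS2 and
summarise per-region length and GC content, collapse samples into haplotypes,
classify variable sites and call species-diagnostic ("specific") sites,
compute the Kimura 2-parameter (K2P) distance structure within and between
species, and build neighbor-joining (NJ) or K80 maximum-likelihood (ML) trees
with bootstrap supports to assess whether each species is recovered as a
clade. A seeded simulator generates datasets with the same statistical
structure plus machine-readable ground truth, so every stage is testable
without any downloads.

## Data model

Everything flows through *sequence tables*: tibbles with `id` and `seq`
columns (uppercase `A,C,G,T`, IUPAC ambiguity codes, `-` for gaps; `U` and
`.` are normalised on input). `join_metadata()` attaches `species`,
`locality`, `accession` and `is_outgroup` from a five-column TSV, and the
join is total — a sequence without metadata is an error, not a silent drop.
All reported coordinates are 1-based column indices on the master alignment:
that is the only frame in which positions are comparable across samples, so
coordinates from differently-built alignments are not directly comparable
(counts and states are).

## Alignment

Barcode sequences within a genus are typically >90% identical, so a simple
deterministic aligner is preferable to a heuristic black box. We use
Needleman–Wunsch/Gotoh global alignment with affine gaps (default `match = 5`,
`mismatch = -4`, `gap_open = -10`, `gap_extend = -0.5`; a gap of length *k*
costs `gap_open + k*gap_extend`) and center-star progressive merging: the
center is the sequence minimising the summed alignment-free 5-mer distance to
all others, every other sequence is aligned to it, and pairwise gap patterns
are merged under "once a gap, always a gap" with new gap columns padded at the
right of each inter-residue slot. Dynamic-programming ties are broken
diagonal-first, then up (gap in the second sequence), then left, so scores
*and* layouts are reproducible byte for byte. Center-star was chosen over
guide-tree progressive alignment because at barcode-level identity the two
give essentially the same answer and center-star is far easier to verify
against a brute-force optimum (the test suite enumerates all alignments for
short sequences and cross-checks scores against an independent implementation).

Datasets aligned externally enter through `load_prealigned()` /
`align_sequences(prealigned = TRUE)`; equal-length gapless inputs are treated
as stacked but still pass through the aligner in `build_msa()`.

One consequence worth knowing: with clustered substitutions the optimal
affine-gap alignment can open compensating gaps that a human (or a different
scoring scheme) would not, shifting downstream column coordinates. Counts and
(species, state) content of downstream results are robust to this; absolute
positions are alignment-frame quantities by design.

## Region partition

The 5.8S gene is strongly conserved while the spacers are not, so its
placement is inferred without an rDNA model: among all runs of `window_len`
(default 164, the canonical plant 5.8S length) consecutive gap-free columns,
`infer_58s_window()` picks the run minimising total column diversity (summed
count of rows carrying a non-modal state), ties going leftmost. ITS1 is
everything left of the window and ITS2 everything right. Boundaries can also
be supplied explicitly. Per-record lengths count non-gap characters only and
are *reported*, never asserted equal — real datasets contain the occasional
haplotype whose 5.8S deviates from 164 bp. GC is `100*(G+C)/(A+C+G+T)`,
excluding gaps and ambiguity codes from numerator and denominator alike
(a conservative choice that moves GC by well under half a percent), rounded
half-away-from-zero to two decimals at the reporting layer only.

## Haplotypes

Haplotype identity is exact string equality of aligned rows after trimming
columns that are gaps in every row: indels separate haplotypes (two published
*A. eriantha* haplotypes differ by a single 1-bp deletion, and collapsing
them would be wrong), and IUPAC ambiguity codes are distinct states rather
than being expanded — expanding them would merge haplotypes that the
underlying chromatograms distinguish. The default scope collapses within
species, mirroring the species-prefixed haplotype names used in field
surveys; a global scope is available. Identifiers are deterministic:
species-initial prefix plus rank of first occurrence, so permuting input rows
relabels but never repartitions.

## Variable and diagnostic sites

`classify_sites()` labels every column invariant, variable (two or more
distinct bases, but not parsimony-informative) or parsimony-informative, with
gaps and ambiguity codes flagged but not counted as states; `is_variable`
(any column with ≥2 distinct bases) is the "variation sites" count barcoding
studies report. A `(position, state)` pair is *diagnostic* for species X iff
every row of X carries exactly that state and no row of any other ingroup
species does. Policy decisions, all configurable:

* a gap or ambiguity code among X's own rows disqualifies the position for X;
* a gap in another species counts as a different state (it cannot match a base);
* an ambiguity code in another species disqualifies the site whenever its
  base set contains the candidate state — conservative, trading recall for
  zero false diagnostics;
* fixed gaps may serve as diagnostic states only behind
  `allow_indel_diagnostics` (off by default: published diagnostic sites are
  bases, and indel coding is alignment-sensitive).

`identify_sample()` operationalises the key: a query matches a species when
it carries that species' full diagnostic set by exact character equality (an
`N` matches nothing), returning one species, `"ambiguous"`, or `"no-call"`.

## K2P distances

For two aligned rows, columns where either carries a gap or ambiguity code
are deleted pairwise (complete deletion would discard far more signal; the
desktop tools these studies use default to pairwise deletion too). With
transition proportion *P* (A↔G, C↔T) and transversion proportion *Q* over the
remaining sites,

d = −½·ln[(1 − 2P − Q)·√(1 − 2Q)].

When the log argument is non-positive (saturation) or no sites remain, the
pair is flagged undefined instead of yielding `NaN`, and undefined pairs are
excluded from group means with a warning. Within-species means average over
unordered conspecific pairs and between-species means over all cross pairs.
The default averages over unique haplotypes — published summary tables are
built from haplotype-level matrices — with sample-frequency weighting
available via `freq` (identical samples then contribute zero-distance pairs).
The outgroup is excluded from these summaries. Internal values are kept at
full precision; percentages are rounded (half away from zero, two decimals)
only in reporting columns. `barcode_gap()` reports the extremes and each
species' nearest neighbour; a negative gap is a result, not an error.

## Trees

`neighbor_joining()` is the standard agglomerative algorithm, exact on
additive matrices (property-tested against random additive matrices and, for
quartets, an exhaustive least-squares oracle), with negative branch lengths
clamped to zero and Q-criterion ties broken by the lexicographically smallest
pair of cluster labels (a cluster is labelled by its alphabetically first
leaf) — determinism again.

`k80_loglik()` is Felsenstein pruning under K80 with equal base frequencies,
the likelihood counterpart of the K2P distance; gaps and ambiguity codes
become (partial) missing data at that leaf and site, and unique site patterns
are compressed. K80 rather than GTR+Γ keeps the model matched to the distance
analysis and verifiable against closed forms (the two-taxon likelihood, the
κ=1 Jukes–Cantor reduction). `ml_search()` alternates per-branch univariate
optimisation (branch lengths bounded to [0, 10], tolerance 1e-6, κ
initialised at 2 and optimised on [0.02, 100]) with a
nearest-neighbour-interchange hill-climb accepting strict improvements, from
an NJ start by default. NNI-only search is adequate at a few dozen leaves
with strong signal; SPR is out of scope.

`bootstrap_support()` resamples columns with replacement, rebuilds per
replicate, and maps the percentage of replicates containing each bipartition
onto the internal edges of the *point-estimate* tree (not a consensus tree —
a stated convention, since tools differ silently here). All randomness flows
from one master seed from which per-replicate sub-seeds are pre-drawn, so
replicate r is reproducible in isolation. Replicates with undefined distances
are dropped and counted. `root_and_monophyly()` roots on the outgroup and
reports, per species, whether its samples form a clade; region-restricted
trees (ITS1-only, ITS2-only) run the same machinery on column slices, giving
the per-region discrimination table.

## The simulator

`simulate_dataset()` emulates the data-generating structure the analysis
assumes, with defaults fixed at the study conditions of an eight-species ITS
survey: 8 ingroup species plus one outgroup; per-species sample counts
`c(59, 19, 14, 18, 27, 16, 15, 17)` (185 samples); haplotype counts
`c(9, 5, 4, 6, 6, 5, 3, 8)` (46 haplotypes); 630 bp structured as
ITS1 245 / 5.8S 164 / ITS2 221; between-species K2P path lengths rescaled
into 0.0228–0.11 substitutions/site and per-species within-species divergence
caps drawn from 0.0035–0.0226 (the observed inter- and intra-specific ranges
in such surveys — the ranges keep a positive barcoding gap by construction);
κ = 4, a typical ITS transition bias; 7 implanted diagnostic sites per
species; the 5.8S block evolving at 0.1× the spacer rate; an outgroup on a
0.25 substitutions/site basal branch, long enough to exercise rooting without
saturating; a 0.2 per-species chance of one 1–12 bp deletion (matching the
~12 bp length spread seen across such datasets), confined to the spacers and
away from diagnostic columns; and a 0.002 per-site ambiguity rate on
non-dominant haplotypes, mimicking the occasional ambiguous GenBank record.
Within each species one dominant haplotype carries all non-singleton samples,
the skew field surveys show. Species trees are pure-birth (`ape::rphylo`),
rescaled so the extreme pairwise path lengths hit the configured range ends.

Diagnostic sites are implanted post hoc at columns invariant across all
species consensuses rather than waiting for drift to fix them — this
guarantees a known-truth key exists, mirroring the fixed differences real
surveys report. Within-species mutations, deletions and ambiguity codes all
avoid diagnostic columns, so the planted key is exactly recoverable.

What the simulator does *not* emulate: insertion events (only deletions, so
the truth alignment is always a sub-pattern of the root coordinate frame),
alignment uncertainty arising from repeats or microsatellites, rate
heterogeneity across spacer sites, coalescent within-species genealogy,
recombination, and sequencing error beyond ambiguity codes. Passing recovery
tests therefore demonstrates correctness of the analysis machinery under the
model's assumptions, not robustness to real-data pathologies such as
ambiguous alignment regions.

Everything is deterministic per seed: the same `sim_config()` yields a
byte-identical dataset, and the pipeline's outputs are pure functions of
(inputs, config, seed).

## Numerical and design choices

* Sample counts exclude the outgroup by default (survey sample tables often
  list the outgroup inside the sample table; ours is flagged and excluded
  from "sample" and haplotype counts, configurable).
* Tolerances: branch-length and κ optimisation to 1e-6; alignment traceback
  tie comparisons at 1e-9; NJ tie detection at 1e-12 relative.
* Degenerate inputs are defined results, not crashes: all-identical
  alignments give zero variable sites and a star-like tree; all-gap regions
  report length 0 and missing GC; saturated pairs are flagged undefined.
* Test problem sizes are deliberately desk-scale — 4–6 species, 420–800 bp,
  tens of samples, bootstrap replicates in the tens — chosen so the whole
  suite exercises every stage end-to-end in minutes while the same code paths
  scale to full survey sizes (185 samples, 1000 replicates).

## Reproducing the published survey

The full 185-sample *Actinidia* dataset is reconstructable from the shipped
haplotype-frequency table (`inst/extdata/actinidia_haplotype_counts.tsv`)
plus the 47 GenBank haplotype sequences, which are not redistributed:
`inst/scripts/fetch_accessions.R` caches them (network required), after which
`load_published_dataset()` expands the samples and the dataset-reproduction
tests run. Known caveat: the survey's own alignment is not recoverable from
the desktop software it used, so absolute site coordinates (e.g. "85 bp")
are checked as counts and per-species states, not positions; the published
coordinate lists also contain internal inconsistencies (the same site given
two states in different sections, one listed coordinate beyond the sequence
length), which is why no coordinate-level check is tied to them.

## Limitations

Single-locus barcoding cannot detect hybridisation or introgression — the
two species that fail monophyly in the motivating survey plausibly share
recent ancestry, and no ITS analysis will separate them. The ML search is a
local NNI optimum from an NJ start; the aligner is not suited to sequences
below ~70% identity; and `identify_sample()` requires the query to be in the
master alignment's frame (align it jointly first).
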