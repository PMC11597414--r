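---
title: "Methods: comparative analysis of F and M mitogenomes in DUI bivalves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of F and M mitogenomes in DUI bivalves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duimito)
```

## The problem

Bivalves with doubly uniparental inheritance (DUI) carry two sex-linked
mitochondrial genomes: an F type transmitted through eggs to all offspring
and an M type transmitted through sperm and retained in the male germ line.
Comparing the two genomes of a species — and the F and M lineages across
species — answers several recurring questions: how divergent the two
genomes are, whether their protein-coding genes remain under purifying
selection, whether the *cox2* gene carries the lineage-specific insertions
and 3′ extensions repeatedly observed in DUI taxa, where the control region
hides among the unassigned (intergenic) regions, how conserved the gene
arrangement is, and whether the phylogeny groups genomes by species
("taxon-joining") or by transmission route ("gender-joining").

duimito implements this comparative pipeline for annotated mitogenomes,
plus a synthetic-data generator that plants known structure so every stage
can be validated end-to-end without any external data.

## Data model and conventions

A genome is a `mito_genome`: sequence, species, sex type (F/M/unknown),
topology, and an ordered feature table over the closed symbol vocabulary
`cox1..cox3, cob, nad1..nad6, nad4l, atp6, atp8, rrnS, rrnL,
trnA..trnY` (with `trnL1`/`trnL2` and `trnS1`/`trnS2` as distinct
isoacceptor identities). Coordinates are 0-based half-open internally;
GenBank's 1-based inclusive convention is converted at the file boundary,
which keeps unassigned-region arithmetic free of off-by-one errors. On
circular genomes a feature with `end <= start` spans the origin, and all
length arithmetic is modulo the genome length. Completeness means all 13
protein-coding gene (PCG) identities, both rRNAs, and all 22 tRNA
identities are present; duplications are reported, not penalized.

Annotation spellings are normalized through a synonym table
(`inst/extdata/gene_synonyms.tsv`, editable) plus built-in rules for tRNA
isoacceptor tags; unmappable names are kept as `unknown:<raw>` with a
warning rather than dropped.

## Composition and codon usage

AT skew is (A − T)/(A + T) and GC skew is (G − C)/(G + C). Ambiguity codes
are excluded from every count and denominator, and a skew whose denominator
is empty is undefined (NA), never zero. Start/stop tabulation honors
`codon_start` and flags incomplete stop codons (a CDS whose length is not a
multiple of three and ends in T or TA, completed by polyadenylation).
Because "ATD" start-codon summaries are ambiguous in practice (IUPAC D
excludes C), the tabulator reports both readings — `atd_fraction` (ATA,
ATT, ATG) and `atn_fraction` (any AT·) — and labels them.

## Divergence statistics

*p*-distances are uncorrected mismatch proportions over comparable columns;
columns containing a gap or ambiguity are excluded (pairwise deletion).
Whole-genome distance is offered in two modes because the right choice
depends on the data: `align` (global nucleotide alignment first) and
`positional` (site-by-site, exact for substitution-only comparisons).
Under the default scoring (match +1, mismatch −1, gap open 2, extend 0.5 —
a gap of length *k* costs 2 + 0.5(*k* − 1)), global alignment of highly
divergent sequences converts some mismatch runs into paired gaps, which
biases the aligned-mode distance downward by roughly 0.02 at 20%
divergence. This is a property of parsimony-style affine-gap alignment,
not a bug; recovery experiments therefore use substitution-only pairs and
positional measurement, and real-data users should prefer per-gene
distances where orthology is clean.

dN/dS uses Nei–Gojobori (1986) counting: per-codon synonymous site
fractions (changes to stop codons counted as nonsynonymous) averaged over
the two sequences; codon differences resolved by averaging synonymous and
nonsynonymous steps over all minimal mutational pathways, excluding
pathways through stop codons (if every pathway is blocked, all are used);
Jukes–Cantor correction d = −(3/4)·ln(1 − (4/3)p), undefined at p ≥ 0.75.
The counting path is verified against an independent brute-force pathway
enumeration over all 61 × 61 sense-codon pairs. NG86 is a deliberate,
documented method choice: it is fully specified and oracle-checkable,
whereas maximum-likelihood codon models (the usual alternative) are not
desk-verifiable; comparisons with ML estimates should be qualitative
(e.g. both < 1 under purifying selection), not digit-exact.

*cox2* modification scanning aligns translated query against translated
reference; a run of ≥ 30 consecutive non-reference codons internal to the
alignment is an insertion (a duplication when the inserted peptide matches
the reference at ≥ 50% identity), and such a run past the reference 3′
terminus is a 3′ coding extension. The 30-codon threshold sits well below
the smallest event reported in DUI venerids (86 codons) and well above
ordinary indel noise. Transmembrane helices use a Kyte–Doolittle sliding
window (window 19, mean hydropathy > 1.6, overlapping windows merged) — a
standard heuristic standing in for HMM-based predictors, adequate for the
qualitative question "does the modified region add helices?".

## Unassigned regions

URs are maximal spans not covered by any feature; the gap spanning the
origin is a single UR; flanking genes name each UR. URs > 150 nt are
"principal", and the single longest (LUR) is the prime control-region
candidate (ties go to genome order and are flagged). The composite
characterization runs, per principal UR: composition, tandem repeats,
G-strings, conserved-element similarity, homopolymer runs (≥ 8 nt,
configurable), and a secondary-structure inventory, emitting a
control-region summary table (flanks, length, A–T%, repeat unit count,
copy numbers joined by `+`, other characteristics).

**Tandem repeats** are found by a simplified re-implementation of the
Tandem Repeats Finder scoring scheme (weights 2/7, minimum score 50,
maximum period 500): positions matching one period ahead (or two periods
ahead, where the array is long enough — this rescues arrays below ~92%
identity, whose single-lag signal drifts negative) seed maximal-scoring
segments; boundaries are then refined against the majority consensus of
the seed and trimmed until the outermost positions are match-dense;
candidate periods are collapsed to the smallest sub-period their consensus
repeats, and overlapping calls are resolved by consensus fidelity, then
smaller period, then score. Indels inside arrays are not modelled. The
detector is calibrated so that i.i.d. random sequence yields no calls
(measured 0/100 nulls at the default score threshold), planted arrays at
the generator's defaults are recovered with period ±1 and copy number
±0.2, and across a stress envelope spanning unit lengths 4–200 and
identities down to 85% detection stays above 90% — exact copy numbers for
very short units are boundary-limited, since ±0.2 copies of a 4-mer is
sub-nucleotide precision no detector can promise.

**G-strings** (the ~20-nt G-rich string marking the sea-urchin control
region) are all windows of length 18–23 with G fraction ≥ 0.8, merged to
the best window per overlap group. **Element similarity** slides each
control-region element (TAS, CSB1, mTF1, mt3, mt4) over both orientations
and reports the best window above 50% identity. The shipped element
library is an explicitly synthetic stand-in (the reference elements come
from mammalian/sea-urchin control regions that are not redistributed
here); real analyses should supply their own FASTA, which the loader
accepts unchanged.

**Secondary structure** uses Nussinov base-pair maximization
(Watson–Crick + GU, minimum hairpin loop 3, C++ dynamic programming;
verified against exhaustive enumeration for short sequences). Sequences
longer than 3.5 kb are folded in overlapping 1-kb windows. Stems are runs
of ≥ 5 nested contiguous pairs; `stem_loop` marks any stem, `hairpin`
additionally a hairpin-closing stem of ≥ 10 pairs with loop ≤ 10 nt. These
labels are explicit heuristics for inventory purposes — base-pair
maximization is not a thermodynamic model, and the labels should not be
read as minimum-free-energy structures.

## Gene order

Circular orders are canonicalized by rotation to cox1; reflection is *not*
identified because all genes of the study system sit on the forward strand,
making orientation meaningful. Duplications and absences come from the
multiset difference; on the shared single-copy set, breakpoint distance
counts orientation-respecting adjacencies of one order absent from the
other (verified against an adjacency oracle on random permutations), and a
minimal transposition set is searched exactly for up to two moved genes —
every single-tRNA transposition reported in the study system falls in this
range, and minimal transposition distance is NP-hard beyond it, so larger
rearrangements report breakpoints without a minimal-move claim.

## Phylogenetic patterns

Classification operates on a rooted labelled tree (tips
`<species>__<F|M>`): "sister group" is root-dependent, so NJ trees must be
rooted on an explicit outgroup. For each species with both tips, in order:
(a) **taxon_joining** if the smallest clade containing its F and M tips
holds no other F/M tips; (b) **gender_joining** if the F tip's sister group
is all other-species F tips and the M tip's sister group all other-species
M tips; (c) **masculinization_signature** if another species' M tip lies
inside the smallest clade containing the two species' F tips while this
species' M tip attaches outside — the footprint of a recently
re-masculinized F lineage; (d) **indeterminate** otherwise, rather than
forcing a label. Branch supports are carried but never change calls.
Neighbor-joining itself is plumbing (ape's Saitou–Nei implementation,
negative branches clamped to zero); the package's contribution is the
classification logic.

## The synthetic-data generator

The generator emulates the study conditions: circular genomes built from
the canonical 13 + 2 + 22 template (all forward strand), PCGs as random
in-frame CDSs under NCBI translation table 5, three planted URs (a 1.1-kb
LUR carrying a tandem repeat of unit 80 at 2.5 copies and 95% identity, a
20-G string, TAS/CSB1 plants at 85%/75% identity and a stem-loop; two
smaller principal URs with stem-loops), small 2–20 nt intergenic gaps, and
an M genome whose LUR is 1200 nt longer than the F one — echoing the
observed F/M length asymmetry. Default pair divergence is 0.20
(mid-range of the observed 4.2–38.7%) and default omega is 0.1 for every
PCG (inside the observed 0.001–0.43, firmly purifying).

Divergence is controlled by realized p-distance, not by rate parameters:
single-site substitutions are proposed uniformly, accepted always at
synonymous and non-coding sites, with probability omega at nonsynonymous
sites and never when they create a stop, until the proportion of differing
ancestral positions first crosses the target (landing within 1/L of it).
This direct calibration makes recovery tests exact. Two consequences are
worth knowing. First, because coding proposals are mostly rejected,
unassigned regions absorb substitutions at roughly twice the genome-wide
rate — a realistic fast-evolving-UR property. Second, planted UR features
are masked from substitution, so both emitted genomes carry them at the
identity the plan declares: they model conserved functional elements
against fast background turnover, and recovery tests measure scanner
sensitivity at a known identity rather than an unknown degraded one.

Clade scenarios share one ancestral genome evolved along the implied tree:
`taxon_joining` gives each species its own recent F/M split;
`gender_joining` has one ancient F/M split predating speciation;
`masculinization` (two species by construction — the diagnostic topology
only exists for a pair) replaces the first species' M with a recent copy of
its F, yielding `(((A_F,A_M),B_F),B_M)`, where the classifier calls A
taxon_joining (its cherry is genuinely species-joined) and B the
masculinization signature. An outgroup genome is emitted for rooting.
Everything is deterministic under the mandatory seed.

What the generator does *not* emulate: indels and alignment ambiguity
(except the single M-LUR insertion), rate heterogeneity among sites,
substitution saturation and base-compositional drift between lineages,
annotation error, and recombination. Tests passing on these synthetics
therefore validate the statistics and the bookkeeping, not robustness to
real-data mess; per-gene analyses on real genomes still depend on the
quality of the input annotation.

## Problem sizes and numerical choices

The validation experiments run at desk scale, chosen so the whole suite
completes in a few minutes while keeping every estimate's Monte-Carlo error
well inside its tolerance: divergence recovery on full ~17-kb pairs at
targets {0.05, 0.20, 0.35}; omega recovery at 1000 codons, 20 replicates
per omega ∈ {0.05, 0.5, 1.0} (median within 25% of truth; the small
downward bias at omega = 1 comes from stop-codon exclusion and Jukes–Cantor
saturation, and is well inside that band); planted-feature recovery over
25 pairs (50 repeat plants, 50 G-strings, 100 motifs); pattern
classification over 51 seeded end-to-end runs (17 per scenario, two
species each). Oracle equivalences are exhaustive where the space is small
(all 61 × 61 sense-codon pairs; all structures of sequences ≤ 14 nt) and
sampled (1000 cases) where it is not.

Tie-breaks and degenerate inputs are decided explicitly: LUR ties go to
genome order and are flagged; motif ties go to the plus orientation, then
leftmost; all-ambiguous composition yields NA skews; a featureless genome
is one UR with a warning; an empty pattern-call set tallies to an empty
summary. The Nussinov traceback prefers closing a pair over skipping a
base and pairs outermost-first, so optimal helices are traced as
contiguous stems.

## Pipeline and reproducibility

`run_pipeline()` drives the full analysis from one YAML config (genome
files with species/sex metadata, optional tree and outgroup, every
threshold overridable in one place) and writes the report tables
(composition, divergence, dN/dS, cox2, UR table + JSON details, gene
orders, rearrangements, pattern calls) plus a provenance block (package
version, seed, config hash) and a log that records each step. Reruns under
the same config and seed are byte-identical apart from the log. A thin
command-line wrapper (`inst/cli/duimito.R`) exposes `analyze`, `simulate`,
`urscan` and `patterns` subcommands; `scripts/acceptance.R` recomputes the
headline validation quantities from scratch for a given seed.
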