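---
title: "Methods: intron evolution analysis of nematode GHF5 cellulase gene families"
author: "engevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intron evolution analysis of nematode GHF5 cellulase gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(engevo)
```

# The problem

Plant-parasitic nematodes of the order Tylenchida carry glycoside hydrolase
family 5 (GHF5) endoglucanases (cellulases), most likely acquired from a
prokaryote by lateral gene transfer. Because prokaryotic genes have no
spliceosomal introns, the exon–intron structure these genes have accumulated
since their acquisition is itself a phylogenetic character: intron positions
are gained rarely and lost more readily, so the presence or absence of an
intron at a homologous position can diagnose clades of catalytic-domain
sequences where the underlying alignment is saturated or ambiguous.

`engevo` implements the computational chain needed to do this analysis
reproducibly, from degenerate-primer design through in-silico PCR, intron
inference, canonical numbering and phase statistics, to parsimony mapping of
intron presence/absence onto a phylogeny — plus a simulator that generates
gene families with a *known* intron history so that every stage can be
validated against ground truth.

# Degenerate primer design

Six peptide motifs (`r paste(names(ghf5_motifs()), collapse = ", ")`) are
conserved across nematode GHF5 catalytic domains; `ghf5_motifs()` ships them
and `ghf5_domain_protein()` carries a representative full catalytic-domain
scaffold with all six at their natural spacing.

`back_translate()` turns a motif into an oligonucleotide pattern under a
*codon policy*:

* `full_degenerate` uses every sense codon per residue. Expansion
  (`expand_pattern()`) enumerates codon *combinations*, so six-codon residues
  (L, S, R) contribute exactly six alternatives even though no single IUPAC
  triplet can express them; the rendered IUPAC string is then a cover and the
  object's `exact` flag records this.
* `inosine_at_4fold` writes residues whose codons form one four-fold box (A,
  G, P, T, V) as two fixed bases plus inosine.
* fixed choices pin individual positions to one codon, which is how the
  published species-specific primer variants arise.

Inosine semantics are split deliberately: for *hybridisation* inosine matches
any base (it behaves like N in searches); for *synthesis degeneracy* it is a
single molecular species and contributes factor 1 by default
(`degeneracy(count_inosine_as = "one")`), configurable because conventions
differ between vendors.

The shipped primer table (`primer_presets()`) keeps the published patterns
verbatim, including fixed-base choices (recorded in a `fixed_positions`
column) and two species-specific presets whose fixed residues deviate from
the consensus motif at one position each — their targets genuinely differ
there, so the table must not be "corrected". Presets that are shortened or
frame-shifted relative to a clean codon grid are stored as literals and are
not regenerated by `back_translate()`.

# In-silico PCR

`find_sites()` scans both strands of a template for primer matches under
IUPAC set-intersection semantics (two symbols match when their base sets
intersect; inosine matches anything), with a configurable mismatch budget
and an optional requirement that the three 3'-terminal primer bases match
exactly — a standard PCR-extension constraint, off by default because
mismatch tolerance itself defaults to zero. The search is backed by
`Biostrings::matchPattern(fixed = FALSE)`; the test suite and the acceptance
script verify it position-by-position against an independent brute-force
O(nm) scan.

One convention worth stating: when a primer's reverse complement matches the
forward strand over exactly the footprint of a forward match (a
self-complementary footprint, e.g. a palindromic pattern), that is a single
duplex site and is reported once, on the `+` strand.

`amplify()` pairs every forward site with every downstream reverse site and
reports products *including both primer footprints*, because sequenced clone
lengths run primer to primer; a size range filters the cross product, and
order (by start, then length) is deterministic. Zero products is a valid
result, as is a primer longer than its template.

# Intron inference by protein-anchored spliced alignment

The historical workflow located introns by manual comparison with the
exon–intron structure of homologous public sequences. `engevo` formalises
that step as a dynamic programme (`infer_introns()`, C++ core):

* the genomic fragment is modelled as a chain of ungapped coding exons
  separated by introns with canonical `GT..AG` boundaries (optionally `GC`
  donors, flagged in output);
* coding base *c* of the fragment is collinear with reference coding
  coordinate *c*, with a free start offset (semi-global in the reference,
  global in the fragment);
* the score is the BLOSUM62 sum over translated codons against the reference
  protein minus a fixed penalty per intron; split codons are scored at the
  junction from the donor-side and acceptor-side bases;
* ties are broken towards the leftmost donor, making results deterministic.

Parameters and defaults:

| parameter | default | why |
|---|---|---|
| `min_intron` | 20 bp | these families contain introns down to 27 bp, so the usual 40+ bp floors of gene finders would silently merge exons |
| `intron_penalty` | 15 (BLOSUM62 half-bits) | roughly the score of 4–5 identical residues: an intron must "pay for itself", preventing spurious GT..AG pairs from fragmenting well-aligned exons |
| `identity_floor` | 0.40 amino-acid identity | catalytic domains are strongly conserved; below this there is no defensible homology-based splice solution, and the error raised (`engevo_no_splice`) carries the best partial score |
| `allow_gc_donor` | `FALSE` | canonical boundaries only, unless explicitly relaxed |

When several references are supplied the highest-scoring one is used and
recorded (`ref_id`) — the analysis does not require the user to know in
advance which public sequence is closest.

**Phase anchoring.** Intron phase (0 between codons, 1 after the first, 2
after the second base) is computed in the *reference* reading frame:
`coding_offset` is measured from a frame-anchored origin so that
`phase == coding_offset %% 3` always holds. A consequence we consider a
feature: phases are invariant to *any* shift of the fragment start, not only
codon-preserving shifts, because the anchor comes from the reference rather
than from the fragment's first base. The test suite asserts invariance under
1-, 2- and 3-nt truncations.

Two approximations are documented rather than hidden. First, codon scoring
at the very edge of a fragment that starts mid-codon can mis-score one
boundary codon; semi-global alignment edges are always fuzzy and this never
moves an intron. Second, the dynamic programme assumes internal exons of at
least a few bases (a split codon's bases must not span two junctions);
biologically meaningful exons are far above this.

`splice()` performs the excision with validation (sorted, non-overlapping,
in range) and conserves length by construction:
`nchar(genomic) == nchar(cds) + sum(intron lengths)` is asserted on every
output. `verify_against_cdna()` compares a splice product with an
experimentally derived cDNA over their best ungapped overlap, with optional
end trims for primer-derived ends.

# Canonical numbering and phase statistics

Positional homology is established on a protein multiple alignment:
`project_to_alignment()` maps each intron to the alignment column of the
codon it interrupts (phase > 0) or immediately precedes (phase 0).
`assign_identifier()` then matches positions against a canonical map with a
tolerance of ±1 alignment column *and required phase compatibility*; the
window is deliberately tight and prominently configurable, because no
community standard defines when two intron positions are "the same" — a
mixed-phase canonical position (one observed in phases 0 and 1) is treated
as a single identifier with a phase multiset, matching how such positions
are book-kept in practice.

Novel positions between canonical *k* and *k+1* mint the half-integer
*k*+½ (0½ before the first position, *n*+½ after the last), rendered as
`"4.5"` in machine outputs and `"4½"` for display. Assignment is monotone —
larger columns never receive smaller identifiers — and two distinct novel
positions in the same gap receive letter suffixes with a warning rather than
silently colliding.

`summarize_phases()` reports per-position phase counts, flags mixed
positions, and reports the fraction of pure phase-0 positions as a
percentage rounded **down** to an integer. Floor rounding is a deliberate
choice so that a 16-of-24 dataset renders as 66%, the convention used in the
literature this package accompanies.

Fragments that do not span a canonical position contribute **unknown** — not
absent — to downstream matrices (`catalog_to_matrix()`); a 256-bp amplicon
simply cannot testify about most of the domain. This distinction is critical
and is carried through parsimony.

# Parsimony superposition

`superpose()` maps each presence/absence character onto the tree:

* **Fitch** mode (default, because the real families show both gains and
  losses): minimum number of state changes, computed by a binary Sankoff
  dynamic programme in which unknown tips are free variables — they take
  whatever state minimises the count, which is exactly the right treatment
  of a fragment that cannot testify. Counts are invariant under re-rooting.
* **Dollo** mode (single-origin hypothesis): at most one gain per character,
  unlimited losses; the event count is the gain plus the minimum losses,
  found by enumerating the gain branch with a per-subtree loss DP. The Dollo
  count can never be below the Fitch count.

Both modes return a branch-level event labelling achieving the minimum, with
deterministic tie-breaking (the root prefers absence; children keep the
parent's state on ties). Correctness is established in the test suite by
exhaustive enumeration over all ancestral and unknown-tip labellings on
trees of 4–8 tips, and independently cross-checked against
`phangorn::parsimony` for Fitch scores.

`diagnostic_characters()` classifies each character per clade as
perfectly diagnostic (uniform inside, complementary outside),
shared-not-exclusive, or non-diagnostic, ignoring unknowns.
`classify_type()` assigns catalytic-domain type labels (A/B/C) by nearest
labelled reference under normalised local alignment score (a reference
scores 1 against itself); it is a reference-based classifier, not a
phylogenetic placement, and queries below the threshold (default 0.4) stay
unassigned rather than being forced into a type.

# The simulator and what passing tests mean

`simulate_family()` generates gene families with known history: a coalescent
tree (or a user tree) scaled so that `subst_rate` is the expected root-to-tip
substitutions per coding site; uniform (Jukes–Cantor-like) substitution
outside protected positions; intron gain/loss at canonical slots as Poisson
events per branch with recorded branch labels; intron lengths of
`min + geometric` form; `GT..AG` boundaries always.

Default scale — 12 taxa, a 230-codon CD1..CD6 catalytic domain on a
307-residue scaffold, an 18-slot canonical map whose phase pattern mirrors
the phase-0 bias of real catalytic-domain introns (12 of 18 slots phase 0),
introns of 25 bp minimum and 60 bp mean, root occupancy 0.35 — was chosen
once to emulate the data regime of single-nematode catalytic-domain
amplicons (fragments of roughly 0.25–1.5 kb carrying zero to about seven
introns).

Three protections make ground truth exact. Motif codons and primer
footprints are excluded from substitution, so the designated preset primers
bind every simulated taxon with zero mismatches. Substitutions that would
create a stop codon are reverted. And newly gained introns are rejected if
their insertion would admit an equivalent shifted splice (identical splice
product with valid boundaries a few bases away) — such configurations are
unresolvable *by any homology method*, so leaving them in would make "exact
boundary recovery" an ill-posed target rather than a property of the
algorithm.

What the simulator does **not** emulate — and therefore what passing tests
cannot show about real data: codon-usage bias, indels within exons
(alignment gaps between orthologs), splice-site motifs beyond the boundary
dinucleotides, rate heterogeneity across sites and branches, and boundary
sliding of introns. The recovery rates quoted by the acceptance machinery
(100% at zero divergence, ≥95% at 20% root-to-tip divergence) are therefore
statements about homology-constrained splicing under clean divergence, not
about arbitrary genomic input.

Problem sizes used by the automated checks — 100 simulated families of 4
taxa for recovery, 200 random 2-kb templates for the PCR oracle, all
random trees of 4–8 tips with 200 characters per size for the parsimony
oracle — are the package's own choice of a thorough-but-routine validation
batch.

# Known limitations

* Exons are ungapped against the reference: a genuine coding indel between
  fragment and reference will degrade the alignment around it rather than
  being modelled. Choosing the closest reference (automatic) mitigates this.
* The positional-homology window (±1 column, equal phase) is a convention;
  datasets with sloppy alignments may need a wider window, at the cost of
  merging nearby positions.
* Dollo mode assumes the character can be gained once; characters that
  plausibly arose twice should be read in Fitch mode.
* The type classifier is only as good as its labelled references; borderline
  sequences are left `unassigned` by design.
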