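---
title: "Screening and typing aryl-alcohol oxidase candidates with aaoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening and typing aryl-alcohol oxidase candidates with aaoscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaoscan)
```

## The problem

Aryl-alcohol oxidases (AAOs, EC 1.1.3.7) are FAD-dependent members of the
glucose-methanol-choline (GMC) oxidoreductase superfamily.  They oxidise
activated primary alcohols to aldehydes while reducing O2 to H2O2, which
makes them both key players in fungal lignocellulose degradation and
attractive green-chemistry biocatalysts.  Long known only from
wood-decaying fungi, AAOs have recently been characterised in bacteria
and arthropods, and candidate sequences can now be mined from genome
databases at scale.

`aaoscan` packages the desk side of that mining exercise: given candidate
protein sequences and a homology-search hit table, it screens for the
conserved hallmarks of the family, types the survivors by their
active-site composition, summarises motif conservation as sequence-logo
statistics, assesses whether the resulting types are coherent on a
phylogeny, and compares structures by C-alpha superposition.  A seeded
synthetic-data generator with known ground truth makes every stage
testable without network access or external databases.

## The screening model

A putative AAO candidate must display, simultaneously:

1. a homology hit with percent identity strictly above 35 and e-value
   strictly below 1e-10 (both inequalities are strict, read literally
   from the selection thresholds; sequences with no hit at all are
   screened on features alone and flagged `no_hit_evidence`);
2. the ADP-binding fingerprint of the Rossmann beta-alpha-beta element,
   `G-x-G-x(2)-G-x(18)-E`, in the N-terminal region;
3. the GMC PROSITE signature PS00623 in the N-terminal region and
   PS00624 in the central portion;
4. histidine at both catalytic positions, located by global alignment to
   a kingdom reference (PeAAO H502/H546 for fungi; ShAAO H456/H500 for
   bacteria).

The source material constrains the signatures only to the "N-terminal
region" and "central portion", without numeric windows.  We operationalise
these as the first 40% of the sequence and the 30--75% band respectively
(`region_windows()`), deliberately permissive: in PeAAO (~593 residues)
PS00623 sits near residue 100 and the catalytic core far downstream, so
genuine instances fall well inside these windows while random matches in
the wrong region are rejected.  Both fractions are configurable.
Signature matching is exact (mismatch-free); no mismatch allowance is
stated for the original screen, and the signatures' own alternative sets
already encode the permitted variation.

The PROSITE engine supports residue literals, `x` wildcards, bracket
alternative sets, `{...}` exclusion sets, `<`/`>` terminal anchors and
fixed or ranged repeats.  Two semantics choices are fixed and tested:
matching reports, at each matching start, the leftmost-shortest match
(non-greedy; screening needs existence and location, not extent), and a
sequence `X` matches only the wildcard element.  A brute-force scanner
(`brute_force_scan()`) that enumerates repeat widths by depth-first
search is kept in the package as an independent oracle; a property test
holds the fast scanner equal to it on random pattern/sequence pairs.

## Reference anchoring

Residue equivalences ("the PeAAO Y92-equivalent position") are resolved
by global pairwise alignment of each query to its kingdom's reference
enzyme (Needleman-Wunsch with Gotoh's three-state affine-gap recursion;
BLOSUM62, gap open 10, gap extend 0.5 — common protein defaults, all
configurable).  Traceback tie-breaking is fixed (diagonal, then up, then
left), making every result reproducible.  Reference numbering is taken
on the sequence exactly as supplied: whether a published residue number
counts from the initiator methionine or the mature chain is not always
stated, so the package performs no signal-peptide arithmetic and expects
callers to supply consistently numbered references.  A query whose
alignment places a gap at an anchor position is reported as UNMAPPED at
that position and the downstream type call becomes `unclassified` rather
than a guess.

Anchoring is pairwise (query vs reference), not through the multiple
alignment: it is order-independent, cheaper, and sufficient for reading
two residues per sequence.  The progressive multiple aligner (guide tree
from 3-mer distances + neighbor joining, then profile-profile alignment
up the tree, implemented in C++) is used only where column context
matters: logo statistics and phylogeny.  An externally computed MSA can
be supplied instead at both places.

## Typing rules

Two active-site positions carry the classification: position a (PeAAO
Y92 / ShAAO F92 / CpAAO Y128 equivalents) and position b (PeAAO F501 /
ShAAO F455 / CpAAO Y535).  Position a is the primary classifier;
position b only sets a consistency flag, because the source describes
per-type residue *distributions* at b rather than a second independent
rule.  The residue classes are fixed as AROMATIC = {F,W,Y}, ALIPHATIC =
{A,V,L,I,M} (glycine excluded — it anchors fungal type III by itself),
UNCHARGED_POLAR = {S,T,N,Q,C}, POSITIVE = {K,R,H}.

* **Fungi** — aromatic a: type I (all classical Basidiomycota AAOs);
  glycine: type III (the Ascomycota / MtAAO group); aliphatic or
  uncharged polar: type II.  Types I/II expect aromatic b; type III
  expects loss of aromaticity at b.
* **Bacteria** — ordered rules: A or G: type I; F (or Y, which covers
  the Geminicoccaceae variant without needing taxonomy input): type II;
  V/L/I/M: type III.  Expected b residues are Y (I), F (II), Y or F
  (III).  ShAAO (F,F) types as II and SdAAO (V,F) as III, matching
  their reported assignments.
* **Arthropods** — a single type: aromatic a gives `arthropod`, with the
  consistency flag set when b is tyrosine or positively charged.

Rule order resolves class overlaps deterministically (bacterial A
belongs to both {A,G} and ALIPHATIC; type I is tested first because A/G
are named explicitly for it).  Leucine at the fungal a position is a
known ambiguity — it occurs in basidiomycete AAOs yet is not aromatic —
and is assigned type II by the aliphatic rule; the observed residues are
always recorded in the TypeCall audit columns so such calls can be
revisited.  Every (residue, residue) pair yields exactly one label; a
property test enumerates all 400.

## Logo statistics

Column conservation is the standard information-theoretic quantity
R = log2(20) − (H + e(n)) bits, where H is the Shannon entropy of the
observed residue frequencies and e(n) = (s−1)/(2·ln2·n), s = 20, is the
small-sample correction; letter heights are frequency × R.  Gaps are
excluded from the counts (the common logo convention) rather than
treated as a 21st symbol; the correction defaults to "on below 50
observations".  Columns are numbered by reference residue positions
(PeAAO numbering for fungal logos, ShAAO for bacterial, CpAAO for
arthropod), translated through the reference row of the MSA.  The tested
surface is the numeric TSV; rendering is left to general plotting tools.

## Phylogeny

The pipeline builds distance trees: p-distances over mutually ungapped
columns (optionally Poisson-corrected, d = −ln(1−p)) and Saitou-Nei
neighbor joining with the standard Q criterion.  Ties in Q break to the
lowest (row, column) pair; negative branch-length estimates are clamped
to zero with the deficit moved to the sibling branch (common practice,
preserving path lengths through the parent).  On additive matrices the
generating topology and branch lengths are recovered exactly, which the
tests exercise against path-length matrices from random trees.  NJ was
chosen over maximum likelihood deliberately: it reproduces the
qualitative clade structure of interest at desk scale, is deterministic
and dependency-free, and the pipeline accepts an externally inferred
Newick tree wherever it accepts its own.  Model-based inference,
model selection and bootstrap support are external-tool territory and
out of scope.

Rooting uses a designated outgroup when its leaves are separable by a
single edge (the root splits that edge equally; a non-separable outgroup
is an error, not a silent re-rooting), and midpoint rooting otherwise.
Clade coherence of the type labels is quantified per label as the
smallest clade containing all its leaves: monophyletic if pure, with a
purity fraction otherwise; single-member labels are monophyletic by
convention.

## Structure comparison

`superpose_structures()` pairs C-alpha atoms of two chains through
global sequence alignment (columns with gaps or non-standard residues
excluded), computes the least-squares rigid-body fit by the SVD (Kabsch)
construction with reflection correction (det(R) = +1 always), then
iteratively discards pairs farther than `reject_multiplier` (default 2)
times the current RMSD and refits, up to `max_iterations` (default 5) or
until nothing is discarded.  This mirrors common align-and-refine
superposition protocols; published RMSD figures from other tools should
be treated as approximate benchmarks, since rejection schedules differ
between programs and pair counts are protocol-dependent.  Refinement
stops early once the fit is numerically exact (RMSD below 1e-8 Å), so
perfect superpositions keep all pairs.  PDB and mmCIF files are read
through bio3d, taking the first model, first alternate location, and the
largest (or a named) protein chain.

## The synthetic-data generator

The generator emulates the screened sequence population: GMC-like
proteins carrying all four conserved features with known type labels.
Defaults are fixed once: 560-residue sequences (a typical GMC length;
arthropod AAOs run ~600), uniform background residue frequencies (the
simplest null — real GMC composition is not uniform, and no claim about
composition is tested), per-site substitution `mutation_rate` outside
protected positions with replacement drawn from the other 19 residues,
and `type_divergence` 0.1 separating each type's founder from the
kingdom backbone so that within-type distances stay below between-type
distances.  The feature layout scales with sequence length and mirrors
the PeAAO landmark proportions: ADP fingerprint at [5,30), typing
position a at 0.16L, PS00623 at 0.18L, PS00624 at 0.5L, typing position
b adjacent to the first catalytic histidine at 0.85L, second catalytic
histidine at 0.93L (compare Y92/F501/H502/H546 of ~593).

Choices that matter for what the tests can claim:

* Planted features, typing and catalytic positions are protected from
  background mutation, so ground-truth labels survive any mutation rate;
  type recovery at high mutation rates therefore measures the anchoring
  and rule machinery, not signature robustness to active-site mutation.
* Each member draws its own concrete instance of every signature
  (wildcards uniform over 20 residues, alternative sets uniform over
  their options, the reference backbone keeping one fixed instance), so
  family logos show the signature's conservation profile — invariant
  positions at full information, wildcard columns near zero — rather
  than a cloned instance.
* Decoys ablate exactly one feature: both catalytic histidines to
  alanine, or a motif instance replaced by background residues and
  verified by rescanning to leave no match anywhere in the sequence
  (chance background matches are destroyed by flipping one constrained
  position, avoiding other planted features).
* Kingdom backbones are seeded by (seed, kingdom) alone, so references
  and decoy pairings are stable across family sizes.
* No indel process, no rate heterogeneity, no signal peptides: the
  generator is a screening/typing/clade-structure testbed, not a
  sequence-evolution simulator.  Passing tests demonstrate the
  machinery is correct on data satisfying its assumptions; they do not
  show robustness to alignment-shifting indels in real homologs.

Within each type the simulated genealogy is a star (members radiate
independently from the founder), so the internal edge separating two
types on the NJ tree is the founder divergence alone.  At the default
sequence length this edge comfortably exceeds p-distance sampling noise
and the type clades come out monophyletic; shortening sequences (or
raising the mutation rate) shrinks that margin, and an occasional
non-monophyletic star clade is then expected behaviour of distance
methods on near-star trees, not a defect of the monophyly test.

## Problem sizes and numerical choices

The bundled end-to-end runs use deliberately desk-scale sizes, chosen as
defaults for the package's own verification: screening round-trips on
~300 true sequences plus ~84 single-ablation decoys; type recovery on
105 sequences per condition; 50 random additive matrices of 4--12 taxa
for NJ exactness; a full pipeline bundle of 56 sequences for clade
coherence.  Distance-matrix symmetry is enforced to 1e-12; NJ recovery
and Kabsch invariants are asserted to 1e-9; the logo worked value to
1e-3.  All randomness flows from explicit integer seeds, and rerunning
any stage with the same configuration is byte-identical.

## Known limitations

* The headline discovery counts of the motivating survey (93 fungal,
  259 bacterial, 203 *Mycobacterium*, 91 arthropod sequences) depend on
  the database snapshots searched and are not reproducible offline; the
  package reproduces the *procedure*, and its verification rests on
  worked examples and property suites.
* The progressive aligner is intentionally minimal (no iterative
  refinement, no consistency objective) and is not expected to
  reproduce MUSCLE or MAFFT output; supply an external MSA for
  publication-grade alignments.
* Structure benchmarks against published crystal structures require the
  PDB entries (5OC1, 9AVH, 6O9C, 8RPF, 82PG) to be downloaded by the
  user; `superpose_structures()` accepts them directly, and printed
  RMSDs over hundreds of C-alphas should be matched within a few tenths
  of an Ångström with pair counts within ~10%, given the
  protocol-dependence noted above.
* Hit filtering is per-hit (a subject passes if any of its hits
  passes); whether the original screen filtered per best hit is not
  stated.

## A worked run

```{r, eval = FALSE}
library(aaoscan)

dir <- tempfile("aao_demo_")
bundle <- write_synthetic_bundle(
  synth_config(n_per_type = 4, mutation_rate = 0.05, seed = 11), dir)

summary <- run_pipeline(list(
  sequences        = bundle$sequences,
  hit_table        = bundle$hits,
  references_fasta = bundle$references,
  anchors          = bundle$anchors,
  kingdoms         = bundle$kingdoms,
  phylo_correction = "poisson",
  outdir           = file.path(dir, "out"),
  seed             = 11))

summary$counts       # input / retained / rejected
summary$type_counts  # per-kingdom type tallies
summary$monophyly    # clade coherence of the type labels
```
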