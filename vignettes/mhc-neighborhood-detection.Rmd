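---
title: "Detecting multi-heme cytochrome gene neighborhoods without homology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting multi-heme cytochrome gene neighborhoods without homology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemescan)
```

## The model

Extracellular electron transfer (EET) pathways share a structural signature
rather than a sequence one: a compact run of genes encoding exported
cytochromes that together bind many c-type hemes. `hemescan` operationalizes
that signature in four deterministic stages — motif counting, localization,
neighborhood chaining, and criteria gating — each of which is a pure
function of the input sequences and a small set of documented thresholds.

### Heme motif counting

c-type hemes attach at Cys-Xaa-Xaa-Cys-His sites. The default template set
is `CxxCH` plus the documented spacing variants `CxxxCH` / `CxxxxCH` and the
`CxxCK` variant; users who want the strict canonical motif can pass
`heme_config(motif_patterns = "CxxCH")`. Counting is greedy and
non-overlapping, left to right, shortest template first: a single cysteine
pair cannot anchor two hemes, and the shortest-first tie-break means the
canonical motif wins when a longer-spacer variant starts at the same
residue. Ambiguity codes `X`/`U` satisfy wildcard positions (which are
unconstrained by definition) but never the literal `C`/`H`/`K` anchors.

Three per-protein thresholds matter downstream, all integers in units of
motifs:

* `mhc_min_hemes = 3` — what counts as a *multi-heme* cytochrome. The gate
  exists to exclude the ubiquitous mono- and diheme respiratory proteins;
  the binding criteria below do not depend on its exact value.
* `heme_rich_min = 4` — the *heme-rich* flag used by inclusion criterion 2.
* `high_heme_min = 11` — the *high-heme* flag (strictly more than 10
  motifs), a reporting category for unusually heme-dense enzymes.

### Localization

The inclusion criteria need to know whether a cytochrome leaves the
cytoplasm. External Phobius predictions can be supplied and win wherever
present, but the package also ships a self-contained heuristic so the
pipeline runs with zero external binaries:

1. Hydrophobic segments are maximal unions of 19-residue windows whose mean
   Kyte–Doolittle hydropathy is at least 1.6. The scale has one decimal
   place, so window sums are computed in exact integer deci-units; the
   threshold comparison has no floating-point drift.
2. A segment starting at residue ≤ 10 and ending at residue ≤ 45 is a
   signal-peptide candidate; it is accepted when at least one Lys/Arg lies
   in the first 10 residues. The charge check is anchored to the N-terminal
   10 residues (the positively charged n-region) rather than to "residues
   before the segment", because the 19-residue window smears a hydrophobic
   core backwards: for a classic `MKK` + poly-Leu signal peptide the first
   qualifying window already starts at residue 1, which would leave no room
   for any preceding charge.
3. All other hydrophobic segments are transmembrane helices. A protein with
   a signal peptide *and* a downstream TM helix is classed inner-membrane,
   not exported — it is membrane-anchored, and the neighborhood criteria
   require a cleanly exported MHC. Lipoprotein (lipobox) signals are not
   modeled separately; an N-terminal hydrophobic segment suffices.

The three-way call (`exported` / `inner_membrane` / `cytoplasmic`)
deliberately does not discriminate periplasmic from outer-membrane from
secreted: for EET candidacy they are one class. Proteins with no
localization evidence at all default to cytoplasmic — the conservative
choice, since it can only suppress candidates, never invent them.

### Neighborhoods and the three criteria

A *gene neighborhood* is defined operationally: consecutive genes on one
contig chain while the intergenic distance (next start minus previous end)
is at most `max_intergenic_bp = 500`, a standard operon-context heuristic;
chaining is strand-agnostic because porin–cytochrome modules routinely
include divergently transcribed accessory genes. Every maximal chain
containing at least one *seed* — an exported MHC — is a neighborhood; two
seeds within joining distance therefore merge, neighborhoods are pairwise
disjoint, and the count of neighborhoods needs no tie-breaking.

A neighborhood passes when all three gates hold (each individually
toggleable):

1. at least one MHC with a signal peptide;
2. at least one heme-rich (≥ 4 hemes) MHC;
3. at least `min_cluster_hemes = 15` hemes summed over **all** member
   proteins — hemes in cytoplasmic members still count toward the total,
   since the cluster-level count is what the threshold was calibrated on.

Criteria 1 and 2 are evaluated independently: the signal-peptide MHC does
not itself have to be the heme-rich one.

### Pilins

Type IV aromatic pilins carry no hemes, so they are reported in a separate
table and never contribute to cluster totals. The rule is a transparent
Geobacter-PilA-like stand-in rather than an HMM: full length 50–200 aa, a
class-III (prepilin peptidase) processing site `G-[FMLIV]-x-x-x-E` with the
glycine within residues 2–40 (cleavage after the G, so the mature peptide
begins with the hydrophobic residue), and a mature-peptide aromatic
(F/Y/W/H) fraction of at least 0.09. All thresholds are configurable.

### Protein families

To turn discovered MHCs into searchable profile HMMs, exported MHCs are
clustered greedily: sequences sorted by decreasing length (ties by
identifier, for determinism) either join the first centroid reaching 50%
global identity with 80% coverage of the shorter sequence, or found a new
family. Pairwise alignment is global Needleman–Wunsch under BLOSUM62 with
affine gaps (open 11, extend 1), identity counted over alignment columns
excluding terminal gaps. Families are aligned center-star against the
centroid, columns with strictly more than 50% gaps are masked (the strict
majority is the literal reading of "mostly gaps"; exactly-half columns are
kept), and families with at least three orthologs are exported as Stockholm
alignments. Profile-HMM parameter estimation itself is delegated to an
external `hmmbuild`; the package emits builder-ready alignments rather than
reimplementing HMMER.

The clustering and masking defaults (0.5 identity, 0.8 coverage, 0.5 gap
fraction) are this package's documented choices; the three-ortholog
eligibility floor is the method's stated requirement.

## What the synthetic generator emulates

`make_protein()` builds proteins whose heme count and localization are
analytically forced: motifs are planted on a background alphabet drawn from
{A, G, S, T, P, D, E, N, Q} — no C/H/K, so no accidental motifs; no F/Y/W,
so controlled aromatic densities; none of the strongly hydrophobic
residues, so no spurious membrane segments — with at least five background
residues between motifs. Exported proteins get an `MKK` + 20-Leu
signal-peptide cassette. Two rejection checks (against the motif scanner
and the localization rule) guarantee the construction even in pathological
random draws, e.g. an all-Ala window that would clear the hydropathy
threshold. `simulate_assembly()` lays clusters out on their own contigs
with specified intergenic gaps, interleaves heme-poor unexported decoys
both beyond joining distance on cluster contigs and on dedicated contigs,
and computes its truth table from a literal restatement of the three
criteria — never by calling the pipeline, so recovery tests are a genuine
two-route check.

What the generator does **not** emulate: real amino-acid composition,
nucleotide sequence (coordinates are synthesized as `3 × (length + 1)` bp),
fragmented assemblies, annotation errors, or motif-like sequence noise.
Passing recovery tests therefore demonstrates that the chaining and gating
logic is exact, not that the motif set or the localization heuristic match
any particular external predictor on real proteomes — for real data the
Phobius route and the configurable motif set are the knobs that matter.

## Numerical and degenerate-input choices

* Window means use integer deci-units (exact); all other gates are integer
  comparisons, so the pipeline has no tolerance parameters.
* Empty inputs flow through: an assembly with no genes yields zero
  neighborhoods; a protein shorter than one window is cytoplasmic; an empty
  sequence has zero motifs.
* Identifier collisions (FASTA duplicates, assembly-level duplicates) are
  hard errors naming the identifier; a FASTA/GFF identifier mismatch that
  matches zero CDS rows is a hard error, since it almost always means the
  wrong ID scheme. Matching tries `ID`, then `locus_tag`, then `protein_id`,
  and uses the first scheme with any hit for the whole file — mixing schemes
  within one annotation invites silent misjoins.
* Reports are written with fixed column order, fixed row order (assembly,
  contig, first-gene start) and `\n` line endings, so identical inputs give
  byte-identical files.
* Test-suite and acceptance problem sizes (1,000 random sequences for the
  scanner oracle, 100 assemblies for recovery, 200 random configurations
  for monotonicity) were chosen as the smallest sizes at which the
  property-based checks exercise every code path multiple times while the
  whole suite stays interactive.

## Known limitations

* The motif set of the original heme-counting stage is not published; the
  default here (CXXCH family plus CXXCK) follows the c-type cytochrome
  literature and is fully configurable, but counts on real genomes may
  differ from other scanners for proteins relying on exotic long-spacer
  motifs.
* The built-in localization heuristic is intentionally simple; it has no
  notion of lipoproteins, Tat vs Sec signals, or cleavage-site scoring.
  Where Phobius (or any predictor producing its short format) is available,
  use it.
* The 500 bp / consecutive-gene neighborhood rule is an operational choice;
  operon prediction or transcription-unit evidence could refine membership.
* Greedy centroid clustering is order-dependent by construction (longest
  first); it matches the behavior of standard greedy clusterers but is not
  a globally optimal partition, and center-star alignments degrade for
  families near the identity threshold.
* Cross-contig clusters (split by assembly fragmentation) are not stitched.
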