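# hemescan

Homology-independent detection of multi-heme cytochrome (MHC) gene
neighborhoods in prokaryotic genomes.

## The problem

Extracellular electron transfer (EET) — the movement of electrons between a
cell's membranes and external substrates such as minerals or electrodes —
runs through multi-heme cytochromes: proteins that covalently bind several
c-type hemes at CXXCH-family attachment motifs and pass electrons across the
periplasm and outer membrane (the MtrCAB porin–cytochrome complex of
*Shewanella* is the canonical example). Homology search (BLAST, profile
HMMs) only finds EET machinery related to the handful of characterized
systems. But the defining features of an EET module are structural, not
phylogenetic: a run of neighboring genes encoding exported, heme-dense
cytochromes. `hemescan` looks for exactly that, so it can flag candidate EET
pathways that have no detectable homology to known ones.

## The method

For every protein in an annotated genome (protein FASTA with
Prodigal-dialect headers, or FASTA + GFF3):

1. **Heme-motif scan.** Count c-type heme attachment motifs — CXXCH plus the
   CX3CH / CX4CH spacing variants and CXXCK — with a greedy, left-to-right,
   non-overlapping scan (one heme cannot serve two attachment sites). A
   protein with ≥ 3 motifs is called an MHC; ≥ 4 is *heme-rich*; > 10 is
   *high-heme*.
2. **Localization.** Decide whether each protein leaves the cytoplasm, using
   either a transparent Kyte–Doolittle hydropathy heuristic (19-residue
   windows, mean ≥ 1.6; an N-terminal hydrophobic segment with an upstream
   Lys/Arg is a signal peptide) or external Phobius predictions
   (`--phobius-results`), which take precedence when supplied.
3. **Neighborhoods.** Chain consecutive genes on a contig while the
   intergenic gap is ≤ 500 bp; every maximal chain containing an exported
   MHC seed is a candidate neighborhood. A neighborhood **passes** when it
   has (1) an MHC with a signal peptide, (2) at least one heme-rich (≥ 4
   hemes) MHC, and (3) at least **15 hemes** summed over all member
   proteins.
4. **Pilins.** Type IV aromatic pilin candidates (heme-free, but implicated
   in conduction) are reported separately: prepilin-peptidase site
   `G-[FMLIV]-x-x-x-E` near the N-terminus, 50–200 aa, ≥ 9% aromatic mature
   peptide.
5. **Families.** Discovered exported MHCs can be clustered into protein
   families (greedy centroid clustering, ≥ 50% identity / ≥ 80% coverage),
   aligned center-star, masked (columns > 50% gaps removed), and exported as
   Stockholm alignments ready for `hmmbuild` — families need ≥ 3 orthologs
   to be HMM-eligible.

A fully determined synthetic-assembly generator (`simulate_assembly()`)
plants clusters with exact heme counts and export status, so every stage is
testable without downloads.

## Worked example

```r
library(hemescan)

# a synthetic genome: one MtrCAB-like cluster (two exported decahemes plus a
# heme-free porin stand-in) and one 14-heme cluster that falls short
sim <- simulate_assembly(
  list(cluster_spec(c(10, 10, 0), c(TRUE, TRUE, FALSE)),
       cluster_spec(c(5, 9),      c(TRUE, FALSE))),
  n_decoy_genes = 6, seed = 42
)

res <- scan_genome(sim$genes)
res
#> <mhc_scan>
#>   proteins:        11 (4 MHC, 4 heme-rich, 0 high-heme)
#>   neighborhoods:   2 (1 passing)
#>   pilin candidates: 0

tidy(res)[, c("neighborhood_id", "n_genes", "total_hemes", "passes", "criteria_failed")]
#>     neighborhood_id n_genes total_hemes passes criteria_failed
#> 1 synthetic_nbh_001       3          20   TRUE
#> 2 synthetic_nbh_002       2          14  FALSE     total_hemes
```

The 20-heme cluster passes all three criteria; the 14-heme cluster is found
but rejected by the cluster-heme gate (`total_hemes < 15`). `glance(res)`
gives the one-row per-genome summary and `autoplot(res)` the
hemes-per-neighborhood scatter.

File-level runs (writing `proteins.tsv`, `neighborhoods.tsv`, `pilins.tsv`,
`summary.tsv` and a `run_config.yaml` echo) go through `run_scan()`, or the
bundled CLI:

```sh
Rscript inst/scripts/hemescan simulate --out sim/ --seed 5
Rscript inst/scripts/hemescan scan --faa sim/genome.faa --gff sim/genome.gff --out scan/
Rscript inst/scripts/hemescan families --proteins scan/proteins.tsv --faa sim/genome.faa --out fam/
```

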