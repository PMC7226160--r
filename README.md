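# m5uevo

Comparative genomics of the C5-uracil (m<sup>5</sup>U) methyltransferase
repertoire in *Mollicutes* — the wall-less bacteria (mycoplasmas,
spiroplasmas, acholeplasmas, phytoplasmas) whose strongly reduced genomes
make them a natural laboratory for studying reductive evolution.

Two unrelated enzyme superfamilies put the same methyl group on C5 of
uracil in RNA: the SAM-dependent COG2265 family (TrmA, RlmC, RlmD, RlmCD,
YfjO) and the flavin/folate-dependent COG1206 family (TrmFO and its
paralogs). In mollicutes the COG1206 family has radiated into three
subfamilies: **TrmFO** (m<sup>5</sup>U54 in tRNA), **RlmFO**
(m<sup>5</sup>U1939 in 23S rRNA, a mollicute invention), and the
enigmatic **TrmFO-like** proteins, in which the two catalytic cysteines
(C51/C223, *T. thermophilus* numbering) are replaced by tyrosines. The
package is for molecular evolutionists and RNA-modification researchers
who want to classify these homologs, reconstruct how the repertoire was
gained, lost, duplicated, degraded and horizontally transferred across a
species phylogeny, and validate each step against simulated ground truth.

## What it does

* **Subfamily classification** — global pairwise alignment (BLOSUM62,
  affine gaps) against an annotated TrmFO reference maps the diagnostic
  positions: catalytic C51/C223 (Y/Y ⇒ TrmFO-like), the FAD
  pyrophosphate motif `GAGx[A/S]GxE[A/V]`, the folate triad
  H308/[R,K]309/N310 and the flavin-stacking Y343. Gene-neighbourhood
  (synteny) Jaccard scores separate TrmFO from RlmFO among
  cysteine-bearing homologs; premature stops/truncations flag
  pseudogenes.
* **Ancestral reconstruction** — Sankoff parsimony (Wagner mode), Dollo
  parsimony (single origin at the carrier MRCA, minimum losses), and an
  exact transfer-augmented Dollo search that places one primary origin
  plus any number of HGT re-origins; gains on lineages already carrying
  a sister subfamily are re-typed as duplications, pseudogene leaves
  append decay events. The minimised score is the event cost sum
  `g·(#gains) + l·(#losses) + t·(#transfers)` with defaults
  `g = 2, l = 1, t = 2` (losses cheap: the reductive-evolution prior).
* **Curated reference dataset** — a 39-species mollicute tree (internal
  nodes numbered as cited in the source analysis: 2, 3, 12, 19, 27, 28,
  33, 34, 36, 37, 38), an 11-family phyletic matrix with per-cell
  provenance, gene neighbourhoods, and empirical tRNA/rRNA modification
  phenotypes for 8 assayed species.
* **Simulation** — gene birth/death/transfer/pseudogenization along the
  tree and planted-signature protein/CDS sequences, providing ground
  truth for recall/precision checks of every stage.

## Worked example

```r
library(m5uevo)
ref <- load_reference_dataset()

# repertoire counts
count_species(ref$matrix, c("trmFO", "rlmFO", "trmFO_like"))   # 12
count_species(ref$matrix, "thyA")                              # 16

# Dollo scenario for trmFO on the reference tree
sc <- sankoff_reconstruct(ref$tree, family_leaf_states(ref$matrix, "trmFO"),
                          cost_model(mode = "dollo"), "trmFO")
sc$events
#>   type             edge family donor
#> 1 gain               38  trmFO  <NA>
#> 2 loss                2  trmFO  <NA>
#> 3 loss               28  trmFO  <NA>
#> 4 loss              n42  trmFO  <NA>
#> 5 loss Mycoplasma_auris  trmFO  <NA>
#> 6 loss               33  trmFO  <NA>
```

Reading: the tRNA-methylating *trmFO* was present in the mollicute
ancestor (origin on the root, node 38) and was lost by the Phytoplasma
ancestor (node 2), the Hominis/Pneumoniae ancestor (node 28) and the
Mycoides-cluster ancestor (node 33), plus two smaller lineage-specific
losses. The transfer-aware search on the TrmFO-like pattern returns

```r
dollo_with_transfers(ref$tree, family_leaf_states(ref$matrix, "trmFO_like"),
                     cost_model(mode = "dollo_with_transfers"))$events
#>       type edge     family donor
#> 1     gain   34 trmFO_like  <NA>
#> 2 transfer  n51 trmFO_like    34
```

i.e. a duplication origin in the ruminant-mycoplasma ancestor (node 34)
and one horizontal transfer into the *M. agalactiae*/*M. bovis* ancestor
(`n51`) — cost 4, versus 7 for the best vertical-only scenario.

A command-line front end covers the same ground:

```sh
Rscript inst/cli/m5uevo reproduce
Rscript inst/cli/m5uevo reconstruct --tree tree.nwk --matrix matrix.tsv --out-prefix run
Rscript inst/cli/m5uevo classify --fasta proteins.faa --out calls.tsv
```

## Caveats

The packaged matrix and tree are a *curated reconstruction*: every cell
backed by an explicit statement in the source analysis carries
provenance `text`; the remaining cells, the uncited parts of the
topology, the gene neighbourhoods and the reference TrmFO sequence
(filename-tagged `synthetic`) are realistic stand-ins. See the methods
vignette (`vignettes/m5uevo-methods.Rmd`) for what a green test does and
does not establish.
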