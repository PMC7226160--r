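---
title: "Methods: reconstructing the m5U methyltransferase repertoire of mollicutes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing the m5U methyltransferase repertoire of mollicutes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5uevo)
```

## The problem

Mollicutes have shed large parts of the RNA-modification machinery their
Gram-positive ancestors carried. For 5-methyluridine (m⁵U) two unrelated
chemistries coexist: SAM-dependent methyltransferases (COG2265: TrmA,
RlmC, RlmD, RlmCD, YfjO) and flavin/folate-dependent ones (COG1206:
TrmFO and its paralogs). Within the COG1206 family the mollicutes evolved
three subfamilies — TrmFO (tRNA m⁵U54), RlmFO (23S rRNA m⁵U1939) and the
functionally uncharacterised TrmFO-like proteins — through duplications,
a horizontal transfer, and repeated losses and pseudogenizations. The
package turns that narrative into reproducible computation: classify
homologs into subfamilies, reconstruct the event history on a reference
species tree, and check the gene content against empirical modification
phenotypes.

## Subfamily classification

A query protein is globally aligned to an annotated TrmFO reference
(affine Needleman–Wunsch, BLOSUM62, gap open 11 / extend 1, the standard
protein defaults; the engine is `Biostrings::pairwiseAlignment`, and the
test suite verifies its scores against an exhaustive alignment
enumeration oracle on short sequences). The alignment's column map reads
the query residues at reference positions 51 and 223 (the catalytic
cysteines), 308–310 (folate triad H, R/K, N) and 343 (flavin-stacking
tyrosine); the FAD pyrophosphate motif `G A G x [A/S] G x E [A/V]` is
scanned on the full query. Decision rules, in order:

1. Y at both 51 and 223 ⇒ **TrmFO-like** (the subfamily's defining
   substitution);
2. C/C and an RlmFO-type gene neighbourhood (context score ≥ 0.3, TrmFO
   context < 0.3) ⇒ **RlmFO**;
3. C/C and a TrmFO-type neighbourhood (score ≥ 0.3) ⇒ **TrmFO**;
4. C/C and a user-supplied gene-tree clade label ⇒ that label;
5. otherwise **ambiguous** — a valid outcome, not an error.

Sequence alone cannot separate TrmFO from RlmFO (both keep the
catalytic cysteines), which is why synteny or a gene tree must break the
tie; rule 4 is this package's design choice for the case, not described
in the source analysis, where synteny is uninformative. The conserved
cysteine around alignment positions 195–196 is deliberately **not** used
as a diagnostic: it sits far from the active site and is dispensable for
catalysis. Position 309 is matched strictly against R or K; whether
other basic residues would be tolerated is unknown, so the rule stays
conservative.

**Synteny score.** Neighbourhoods are reduced to the set of flanking
ortholog families within ±5 genes of the anchor; the score against a
profile is the maximum Jaccard index over the profile's reference
neighbour sets. Gene order and strand are ignored on purpose — the
comparison mimics region gene-content conservation, which is how synteny
was assessed qualitatively. The 0.3 decision threshold separates
"highly conserved" RlmFO contexts (scores near 1 in the packaged data)
from the "moderate" TrmFO-like contexts (scores below 0.3); it is a
package decision, exposed as a parameter, since no numeric criterion was
published.

**Pseudogenes.** A CDS is flagged when (a) its length is not a multiple
of three (`length_frame`), (b) an in-frame stop occurs at or before 80%
of the reference protein length (`premature_stop`), or (c) it is shorter
than 60% of the reference coding length (`truncation`). The 80%/60%
cutoffs are package choices tuned to the obvious cases (a stop at half
length, a half-length fragment); borderline decayed genes may escape.

## Ancestral reconstruction

Leaf states are binary per family; **pseudogenes count as present**,
because a decaying copy still witnesses historical presence — they are
re-added as terminal-edge pseudogenization events, while mutual
exclusivity and genotype–phenotype checks count them as non-functional.
Copy-number evolution is deliberately decomposed into per-subfamily
binary analyses (no integer-state Sankoff); duplications are recovered
afterwards by `type_events()`, which re-types a gain on a lineage
already carrying a sister subfamily as a duplication (sister recorded,
or `ambiguous` when more than one sister is present — as at node 34,
where the template of the TrmFO-like duplication cannot be decided).

Three engines, all annotating events on the edge above the named child
node:

* **Wagner/Sankoff** — dynamic programming under asymmetric gain/loss
  costs, free root state; ties broken by preferring presence at the root
  and then no-change along each edge, keeping forced events rootward.
  `enumerate_mprs()` lists all co-optimal labelings (with an explosion
  guard).
* **Dollo** — the family originates exactly once. The origin is placed
  at the MRCA of the carrier leaves and charged `gain_cost` even when it
  is the root (the origin is a real event of the model, not a boundary
  condition). This convention makes the MRCA the *unique* optimal
  origin — moving the origin rootward adds at least one loss while the
  gain is constant — so the canonical scenario is deterministic, and it
  places the rlmFO origin on edge 36 where the duplication re-typing
  expects it.
* **Dollo with transfers** — one primary origin plus any number of
  transfer re-origins. The search is exact: carrier-only maximal
  subtrees ("blocks") are covered by origin edges via a set-cover
  dynamic program over block subsets (cost `l·losses + t` per origin,
  constant-shifted so the primary/transfer distinction cannot change the
  argmin); the preorder-first origin is reported as the primary gain and
  the donor of every transfer. Ties prefer fewer transfers. The guard
  (`max_blocks = 20`) bounds the 2^B table. Because the single-origin
  cover is always in the search space, the result never costs more than
  plain Dollo.

Default costs `gain 2 / loss 1 / transfer 2` encode the
reductive-evolution prior: losses are the common currency of mollicute
evolution, novel acquisitions and transfers are rare. All costs are
parameters. Under these defaults the alternative rlmD history (fresh
acquisition by the Hominis ancestor instead of losses in the Spiroplasma
and Pneumoniae groups) loses to the loss scenario; users can explore the
cost ratios under which it wins via `enumerate_mprs()` and cost sweeps —
the package does not hard-code a verdict.

## The curated reference dataset

The published occurrence matrix and tree exist only as a figure, so the
packaged dataset is a curated reconstruction. Every statement made in
text — the all-absent TrmA/RlmC/RlmCD columns, the single Tdk-less
species, the four RlmD paralogs of *A. laidlawii*, the five
TrmFO-subgroup carriers with the *S. citri* pseudogene, the 12 / 10 /
16 counts, the specific pseudogenes, the rlmH predictions of the assayed
species — holds cell-by-cell and is tagged `provenance = "text"`.
Cells and topology not fixed by text are plausible stand-ins tagged
`curated`; acceptance-grade checks restrict themselves to text-anchored
quantities. Two curation decisions deserve flagging: *A. laidlawii* is
given two trmFO copies (the published 12-carriers/10-multi-copy counts
force exactly two single-copy carriers, which the text assigns to the
*M. agalactiae*/*M. bovis* trmFO-like singletons), and *M. leachii* is
left out of the 39-species set (including it would contradict the
carrier count of 12). Internal nodes keep the published numbering for
the eleven nodes cited in text; uncited nodes are labelled `n40`… to
avoid collisions. The reference TrmFO sequence is a **synthetic
stand-in** (the real *T. thermophilus* sequence is not redistributable
here): its background is random, but all annotated coordinates are the
published ones, which is sufficient because every consumer reads
positions, not biochemistry. Gene neighbourhoods are likewise synthetic,
built to honour the qualitative statements (RlmFO contexts highly
conserved across the Spiroplasma group; TrmFO contexts shared with
Gram-positive-like gene order; TrmFO-like contexts moderately conserved
with a folate-transporter *folT* gene immediately downstream).

## The simulator, and what a green test establishes

`simulate_gene_content()` evolves independent gene copies down the tree
with competing Poisson processes per copy per unit branch length
(loss, duplication, pseudogenization, transfer emission). Transfers
insert one copy at the top of a uniformly chosen branch that is neither
ancestral nor descendant to the donor — without branch dates this is the
package's operational reading of "contemporaneous" — and transferred
copies do not re-transfer. Pseudogenized copies stop evolving and are
inherited by all descendant leaves. A fixed seed fully determines a run;
the star-tree survival fraction matches the analytic `exp(-rate)`
expectation within Monte-Carlo error in the test suite.

`simulate_protein()` plants subfamily diagnostics into the reference
template. The non-diagnostic background diverges from the template with
probability `divergence` (default 0.25, i.e. ~75% identity — within-class
homolog distance at which pairwise position mapping is still reliable),
plus an extra `noise` probability for robustness experiments; diagnostic
positions are never mutated. A fully random background (an alternative
reading of "remaining positions random") would make pairwise coordinate
mapping meaningless for *any* method and was rejected; the published
homologs were aligned as a family at ~30% identity to the reference,
which a pairwise classifier cannot emulate. TrmFO-like simulants carry a
20-residue deletion downstream of all diagnostics, mirroring their
shorter length.

Consequently a green recovery test establishes that classification and
reconstruction invert *this* generative model (template-derived
sequences, independent copies, dated-free transfers) — not that they
would recover the history of arbitrarily diverged real proteomes, nor
that the curated cells of the fixture are the paper's figure cells. In
the packaged validation runs, Dollo reconstruction on 200 simulated
replicates (loss rate 0.1/unit length) attains ≥90% loss-edge recall and
precision, the planted transfer is recovered in ≥80% of informative
replicates, and subfamily recovery is 100% noise-free and ≥95% at 10%
extra substitution noise — all recomputed, never asserted, by
`tests/testthat/test-acceptance.R`.

## Numerical and degenerate-input choices

* Alignment gap cost is `open + len·extend` (the Biostrings convention);
  the enumeration oracle uses the same convention.
* Jaccard of two empty neighbour sets is defined as 0.
* An all-absent family yields an empty scenario of cost 0; a
  single-carrier family under Dollo originates on that terminal edge.
* `copy_count = 0 ⇔ status = "absent"` and `mixed ⇒ copy_count ≥ 2` are
  enforced at construction; TSV readers report the offending row.
* Seeds are plain integers; every stochastic routine restores the global
  RNG state after use.

## Known limitations

* TrmFO vs RlmFO separation depends entirely on context evidence; with
  neither synteny nor a gene tree the call is `ambiguous` by design.
* The transfer search has no time calibration: donor–recipient
  contemporaneity is approximated by phylogenetic unrelatedness, and the
  donor of every transfer is reported as the primary origin lineage.
* Wagner-mode MPR enumeration and the transfer set-cover are exponential
  in (respectively) co-optimal nodes and carrier blocks; both are
  guarded, not silently truncated.
* The phenotype table covers only the eight assayed species; the
  genotype–phenotype check is a consistency audit, not a predictor.
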