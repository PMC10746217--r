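---
title: "Calling flagellated species and their signaling systems from genome annotations"
author: "flagscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling flagellated species and their signaling systems from genome annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flagscan)
```

## The problem

Flagellar motility is sparsely and unevenly distributed across
*Actinobacteria*: most well-known members (mycobacteria, streptomycetes,
bifidobacteria) are non-motile, while several basal, mostly aquatic classes
are rich in flagellated species. Deciding from a genome whether a species
is flagellated — and characterizing the chemosensory and c-di-GMP signaling
systems that co-evolve with the flagellum — is a rule-based exercise over
standard annotation products: homology hits against a reference set of
flagellar proteins, gene coordinates, protein-domain hits, and assembly
metadata. `flagscan` implements that exercise as a tested, reusable
pipeline, together with a synthetic-genome generator that plants ground
truth for every quantity the pipeline estimates.

The package deliberately sits *downstream* of homology search and tree
inference: BLAST-style hit tables, domain-hit tables and Newick trees are
inputs, never computed here.

## The reference catalog

The registry ships 50 flagellar query genes in six functional categories
(flagellar type-III export apparatus, MS ring, motor, rod, hook/filament,
regulators), of which 24 form the ancient core set used for the flagellated
call. The underlying query enumeration names 52 symbols: YvyC and FlaG are
the same filament-associated protein under two organism nomenclatures and
are shipped as one entry, and CwlQ — the *B. subtilis* cell-wall hydrolase
queried alongside the rod cap — is carried as a query alias of its
Gram-negative functional analog FlgJ. Both merges are recorded in the
registry documentation because the canonical count of 50 does not uniquely
determine them. All 52 symbols (plus FlhO/FlhP, the *B. subtilis* names for
FlgF/FlgG) are recognized when labeling hits.

```{r}
reg <- loadRegistry()
reg
table(geneCatalog(reg)$category)
```

## The flagellated call

**Label assignment.** Each locus takes the best homology hit with E-value
strictly below `1e-5` (ties broken by bitscore, then lexicographically — a
deterministic rule). FlgE (hook) and FlgF/FlgG (distal rod) cross-react at
their conserved D0/Dc domains, so their labels are provisional until
`disambiguateRodHook()` applies the conserved gene-order cues
*flgD–flgE* and *flgF–flgG*: the candidate nearest a FlgD gene (within 3
intervening genes, configurable) becomes FlgE; a remaining adjacent pair
becomes FlgF then FlgG in transcriptional order; anything else is labeled
`FlgEFG_ambiguous` rather than guessed.

**Four-state matrix.** Presence is recorded per genome and gene as
present / absent / pseudogene / partial, with precedence
present > pseudogene > partial when a gene has several calls. `partial`
marks a coding sequence truncated by a contig edge (within 20 bp by
default), which in a fragmented assembly most likely reflects an intact
gene; it therefore counts as present in all rules.

**The call.** For complete and draft genomes a species is flagellated when
every required core gene is non-absent and at most two core genes are
pseudogenes (the allowance is a parameter). For metagenome-assembled
genomes (MAGs), whose annotations are systematically incomplete, at least
10 of the 24 core genes suffice; a stricter threshold of 20 flags
representative-quality MAGs without affecting the call.

**Why FlgF and FlgG are exempt by default.** The distal-rod pair FlgF/FlgG
(with FlgJ, FlhX, YvyC/FlaG, FlhF and FlgM) was lost wholesale in the later
actinobacterial classes, whose species nonetheless build working flagella
with a simpler rod. A literal all-24 rule would therefore misclassify every
flagellated later-class genome. The default call excludes FlgF and FlgG
from the presence requirement; the strict reading is available via
`core_exempt = character()`. The exemption is unconditional rather than
"only when both are absent" so the call stays monotone: upgrading any cell
toward presence can never revoke a flagellated call. The tests verify the
call against an exhaustive truth-table oracle over all core-state
combinations with up to three non-present cells, in both modes.

## Chemosensory classification

Chemosensory genes (CheA/W/B/R/C/D/X/Y, chemoreceptors) within 5
intervening genes of each other on a contig form a system; isolated
chemoreceptors are recorded but are not systems. Class assignment follows
the phylogenomic scheme's two well-characterized signatures, in precedence
order with conflicts reported in an evidence trail:

* **F1** — auxiliary components CheC and CheD both present (F1 has no
  conserved gene order, so components alone decide);
* **F5** — a CheA kinase carrying an extra CheW domain (`A:W`), with the
  conserved operon order `A:W W … B R`; interleaved chemoreceptor and CheY
  genes are ignored when matching the motif;
* **F7 / F9 / ACF** — the source scheme defers their discrimination to its
  reference classification, so the registry ships editable
  required-component placeholders chosen to be mutually disjoint (F7
  additionally requires CheX; F9 CheC without CheD; ACF CheD without
  CheC). A bare CheA/CheW/CheB/CheR backbone deliberately matches nothing.

Chemoreceptors are typed by the length of their cytoplasmic signaling
domain in 7-residue heptads: the nearest registry class (36H, 38H, 40H,
44H) within a tolerance of 2 heptads wins, otherwise the receptor is
unassigned. This makes typing a step function of length — perturbations
under tolerance × 7 / 2 residues cannot change the class. Each F class has
a cognate receptor type (44H for F1, 38H for F5, 36H for F7, 44H for F9,
40H for ACF); `cognateReport()` checks the modal receptor class of each
genome against the classes of its detected systems. A genome has a
*chemotaxis set* when it encodes the core four — a chemoreceptor, CheA,
CheW and CheY — anywhere, clustered or not.

## Evolutionary screens

**GC screen.** Nearly all flagellar genes sit in one large cluster;
`detectMajorCluster()` merges flagellar-labeled genes within 10 kb and
takes the cluster with the most genes (ties broken by span and reported).
The cluster's GC content (computed over the nucleotide span by default;
N bases excluded from numerator and denominator) is compared with the
whole-genome GC; an absolute difference strictly above 5 percentage points
flags a horizontal-transfer candidate. The supplied metadata GC is
authoritative when present.

**GGDEF census.** The count of distinct proteins with at least one GGDEF
domain hit proxies the size of a genome's c-di-GMP network; a protein with
several hits counts once, and MAGs are excluded by default because
incomplete assemblies undercount. Group comparisons use a Wilcoxon
rank-sum test — the source analysis names no test, and per-genome counts
are heavily right-tailed (0 to 80), which rules out normal-theory
comparisons; the rank test is also invariant under monotone transforms of
the counts. This choice is the package's own.

## Tree concordance and transfer detection

Species trees and flagellar-protein trees are compared unrooted with the
Robinson–Foulds distance (the symmetric difference of non-trivial
bipartition sets, delegated to `phangorn::RF.dist` and cross-checked in
the tests against a brute-force bipartition enumeration; the test suite
verifies the metric axioms exhaustively on the 15-tree space of 5-leaf
topologies). Inter-class transfer detection is the package's
operationalization of a claim the source analysis made by visual clade
inspection: a leaf is reported when the majority class of its sister clade
in the gene tree differs from its own class while the species tree places
it with its kin. Ties in the sister-clade majority are reported as
ambiguous, never silently resolved, and support values are carried but not
thresholded.

## The synthetic-data generator

`generateGenome()` emits one annotation bundle — gene calls, 12-column
hits, domain hits, contig sequence, metadata — with a ground-truth record.
Design choices worth knowing:

* The flagellar cluster is laid out in a fixed conserved order with the
  *flgD–flgE* and *flgF–flgG* adjacencies built in; later-class genomes
  lack the seven-gene FlgFG module (34 vs 41 genes), and 0–2 droppable
  accessory genes are removed per genome, which is what produces the
  32–41 spread of per-genome flagellar gene counts among complete genomes.
* FlgE/FlgF/FlgG loci receive *equally good* hits to all three paralogs
  (E-value 1e-25, equal bitscores), so nothing but the gene-order cue can
  recover their identity — the disambiguation step is genuinely exercised.
* Pseudogenes are planted only among non-core genes, so the planted
  flagellated status is never silently contradicted; MAG truncation drops
  a uniform fraction of annotations (default retention 0.85).
* Chemosensory operons follow per-class templates consistent with the
  registry signatures; receptor signaling-domain lengths are exact heptad
  multiples of the planted class.
* GGDEF counts are negative-binomial per ecology (size 1.5; means 4 for
  host-associated vs 10–14 for free-living ecologies, flagellated genomes
  ×2.5, capped at 80) — a Poisson would be far too thin-tailed for the
  observed 0–80 spread.
* Cluster GC anomalies are planted by offsetting the base-sampling
  probability over the cluster span (+8 points for the single planted
  offender per cohort); at cluster lengths of tens of kb the realized
  offset is within ±0.4 points of the target, far from the 5-point
  threshold on both sides.
* Intergenic spacers are 100 bp; gene lengths are drawn per gene from a
  small table (450–1500 bp; receptors 1950 bp).

The default cohort profiles emulate the published survey's composition:
538 genomes over nine classes, 69 with flagellar gene sets when drawn with
exact counts (6% of Actinomycetia, 41–91% across the basal classes, zero
in Coriobacteriia and Rubrobacteria), basal classes F1 / FlgFG-containing,
later classes F5 / FlgFG-less, and the three novel classes as MAGs. The
per-class genome numbers themselves are not printed in the source text and
are this package's choice, constrained to those totals and ratios.
Flagellated status is drawn per genome (binomially) by default, as an
independent-sampling emulation; `draw = "exact"` plants the profile counts
exactly and is what the acceptance script uses, since there the planted
totals are the input to an arithmetic check.

What the generator does *not* emulate: real sequence evolution (no
substitution model, no codon structure), annotation errors other than the
planted ones, paralogy outside FlgE/F/G, operon rearrangements, and
contamination. Passing recovery tests therefore demonstrate the
correctness of the decision rules under their stated assumptions, not
robustness to every failure mode of real annotation pipelines.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive (GFF3) everywhere.
* All thresholds compare strictly (`evalue < 1e-5`, `difference > 5`).
* Ambiguity is a value, not an error: unresolvable rod/hook candidates,
  unclassified systems, unassigned receptors and tied sister-clade
  majorities are all first-class outcomes.
* Readers reject rather than coerce: out-of-range percents, negative
  scores, malformed GFF3 lines (reported with line numbers) and unbalanced
  Newick parentheses (reported with positions) are errors.
* Empty inputs return empty results where that is meaningful (a genome
  with no flagellar genes has zero clusters) and errors where it is not
  (GC content of an all-N sequence).
* QC removal uses OR-semantics (`completeness < 80` OR
  `contamination > 5`): the two documented whitelist exceptions are
  genomes whose *only* defect is contamination slightly above 5%, which
  only need exempting under OR.

## Problem sizes used in the shipped checks

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: the truth-table oracle enumerates the 17,345
core-state combinations with at most three non-present cells; tree-metric
axioms are verified on all 15 five-leaf topologies (including every
triangle triple); recovery runs use noise-free cohorts of 120–150 genomes
plus a 538-genome survey-scale cohort with default noise; the rank-test
power simulation uses 200 replicates of 50 + 50 genomes with planted means
5 versus 25. These sizes are the package's choices and scale linearly if
enlarged.

## Known limitations

* F7/F9/ACF signatures are placeholders; real discrimination requires the
  external phylogenomic reference scheme, and users can edit the shipped
  signature table without code changes.
* Pseudogene status is taken from the input annotation; the optional
  length-based heuristic mentioned in the flagellar rules is not enabled
  by default, and the package makes no attempt to recognize pseudogenes
  de novo.
* `query_coverage` cannot be derived from 12-column hit tables (no query
  lengths) and is `NA` after reading; only generated bundles fill it.
* Transfer detection reports leaf-level events only; it does not
  reconstruct donors or directions, and clade-level (multi-leaf) transfers
  are outside its design envelope.
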