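---
title: "Methods: pan-genome partitioning, orphan genes and gain-loss reconstruction"
author: "PanGenEvo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome partitioning, orphan genes and gain-loss reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PanGenEvo)
```

# The problem

Genus-scale comparative genomics of fungi asks a recurring set of
questions of a collection of annotated genomes: which gene families are
shared by every species (the core genome), which are confined to one
infrageneric clade or a single species, which genes have no detectable
homolog outside the genus at all (orphans, also called taxonomically
restricted genes), where the orphans sit on the chromosomes, how gene
families were gained and lost along a dated phylogeny, and what selection
pressure acts on individual coding sequences. PanGenEvo implements this
analysis chain for desk-scale data: ortholog clusters built in-package by
reciprocal best hits, or ingested from an OrthoMCL groups file produced by
external clustering at any scale.

The package is organised around a few S4 containers: `Proteome` (an
`AAStringSet` plus a taxon id), `ClusterTable` (a clusters-by-taxa gene
count matrix with optional per-cluster membership), `CladePartition`
(taxon-to-clade labels, ingroup flags, and a strain-to-species map),
`GeneMap` (a `GRanges` of gene loci with chromosome lengths and gene-order
ordinals) and `GainLossMap` (reconstructed ancestral states plus
per-branch change counts). Dated trees are validated `ape::phylo` objects
with branch lengths in million years (Mya).

# Ortholog clustering

Full-scale studies use BLAST E-value cutoffs and Markov clustering.
E-values depend on database size and are meaningless for the small
simulated proteomes this package is validated on, so the in-package
scorer is a normalized global alignment similarity: Needleman-Wunsch with
BLOSUM62 and affine gaps (opening 10, extension 0.5), divided by the
self-alignment score of the shorter sequence and clamped to [0, 1].
Identical sequences score 1 regardless of length; unrelated sequences
score near 0. The default acceptance threshold is 0.5.

`reciprocalBestHits()` reports a pair when each protein is the other's
unique top hit and the score clears the threshold; ties for the top hit
exclude the query, which is the strict reading of reciprocal uniqueness.
Before alignment, an optional shared-k-mer prescreen (4-mers, at least 3
shared) restricts the candidate list, mirroring how BLAST seeds
alignments; pairs failing the screen are treated as score 0. The screen
changes nothing for homologs at the divergences the simulator produces
(sequences at 85% identity share dozens of 4-mers) and removes the
quadratic alignment cost for unrelated pairs. `buildClusters()` takes
connected components of the RBH graph as clusters — with low-noise graphs,
components and Markov clustering coincide, and users with real MCL output
can bypass the whole stage through `readGroups()`. Every protein lands in
exactly one cluster; proteins without edges become singleton clusters.

# Pan-genome partitioning

"Present" always means at least one gene. Two conventions matter and are
fixed package-wide:

* **Species collapse.** When several sequenced strains represent one
  species, presence is OR-combined over strains before core-genome and
  genus-orphan tests (a 13-strain, 12-species ingroup is tested against
  12 species). Copy numbers are collapsed by maximum where counts matter
  (parsimony in count mode).
* **Subset specificity.** A cluster is specific to a taxon subset if it is
  present in at least all-but-one of the subset's members and in no taxon
  outside the subset.

`classifyByClade()` assigns each cluster one category with fixed
precedence `genus_wide > multi_clade > clade_only > species_only`
(clusters with no ingroup member are `outgroup_shared`); the precedence
makes the overlapping column definitions of a clade-distribution summary
table deterministic. The per-species summary column "at least two species
from each clade" is computed, by default, requiring all ingroup clades
simultaneously; a `requireAllClades = FALSE` flag relaxes this to each
clade represented in the cluster, since the table caption reading is
genuinely ambiguous. Reported percentages are integer-rounded, matching
the precision at which such tables are printed.

# Orphan genes and chromosome geometry

Orphans are detected at three scopes: genus (present in every ingroup
species, absent from every outgroup — necessarily a subset of the core
genome), clade (subset-specific to the clade, absent from outgroups) and
species (clusters whose members all belong to one taxon, including
unclustered singletons).

On a `GeneMap`, an orphan cluster is a maximal run of two or more genes
that are consecutive in gene order and all orphans. Published analyses
rarely state whether intervening non-orphan genes are tolerated; the
default here is strict adjacency (`maxGap = 0`), with the looser reading
exposed as `maxGap > 0`. A gene is subtelomeric when its midpoint lies
within 100 kb (configurable) of either chromosome end; using the midpoint
avoids double-counting genes straddling the window boundary, and
coordinates are 1-based inclusive throughout. The subtelomeric fraction
is monotone non-decreasing in the window size by construction.

# SSCP classification

Small secreted cysteine-rich proteins are filtered by three explicit
rules: length strictly below 300 residues, cysteine fraction at least 5%
(inclusive; `X` residues never count as cysteine), and a positive
secretion call. Filter-passing proteins are labelled with precedence
hydrophobin > cerato-platanin > generic SSCP:

* **Class-II-type hydrophobin**: exactly eight cysteines with the 2nd/3rd
  and 6th/7th directly adjacent (the canonical CC doublets). "Occurring
  as pairs" is interpreted as direct adjacency.
* **Cerato-platanin**: exactly four cysteines. The homology confirmation
  used in curated censuses requires external databases and is out of
  scope; a cysteine-spacing profile is emitted for manual inspection, and
  hydrophobin subtypes (class II vs pseudo-class I) are not distinguished
  because no mechanical rule exists for them.

Secretion is decided by a deterministic heuristic modelled on the
tripartite signal-peptide architecture: a K/R within the first five
residues (n-region), an 8-residue window in positions 6-25 with at least
six hydrophobic residues (h-region), and small residues at the -3 and -1
positions of a cleavage site placed three residues after the first
qualifying window (c-region). Sequences shorter than 25 residues are
called non-secreted. This rule is transparent and exactly testable; calls
from any external predictor can override it per protein via
`readSecretionCalls()`, reported with `secretion_source = "external"`.

# Gain-loss reconstruction

Family-size evolution is reconstructed by parsimony rather than by a
stochastic birth-death likelihood: parsimony is deterministic, has no
free rates to estimate from a handful of taxa, and is exhaustively
testable against enumeration. The package therefore reports minimal-change
reconstructions, not significance-filtered family sets; absolute branch
totals are comparable between runs but are not probability statements.

`wagnerParsimony()` runs Sankoff dynamic programming: presence mode uses
binary states with unit change cost; count mode uses states 0..max
observed copy number with linear cost |i − j|. All ties are broken toward
the smaller state, both at the root and during top-down assignment —
a conservative convention that places gains as late as possible and makes
output byte-reproducible. Per-branch gains and losses are parent-to-child
state increases and decreases; `branchRates()` divides total changes by
branch length in Mya, reporting `NA` (never infinity) on zero-length
branches. `dolloParsimony()` restricts each cluster to a single gain at
the most recent common ancestor of its carriers with minimal losses below
— the natural model for single-origin families such as orphans; its cost
can never undercut the Wagner minimum.

# Molecular evolution

Amino-acid divergence is summarised by the p-distance after pairwise
deletion of gap and `X` sites, the Poisson correction
$d = -\ln(1-p)$, and the gamma correction
$d = \alpha\,[(1-p)^{-1/\alpha} - 1]$ with shape $\alpha = 4$ by default
(the value used for distance tables in the motivating study design). The
gamma correction dominates the Poisson correction, which dominates p, and
converges to Poisson as $\alpha \to \infty$. Pairwise deletion is a
deliberate deviation from complete-deletion concatenate analyses: the
pairwise operations only ever see two sequences. Mean ortholog identity
matrices report `100 * (1 - p)` averaged over single-copy clusters and
are labelled as identity-based, not model-corrected, values.

dN/dS is estimated by Nei-Gojobori (1986) counting: fractional
synonymous-site counting per codon under the standard code (changes to
stop codons excluded from the site denominator), observed differences
averaged over all shortest substitution pathways between codons excluding
pathways through stops (with a fallback to all pathways in the degenerate
case where every pathway is blocked), Jukes-Cantor correction
$d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$, and $\omega = dN/dS$ (`NA` when
$dS = 0$; proportions at or above 3/4 are a saturation error). This
replaces codon-model maximum likelihood (PAML M0) deliberately: NG86 is
self-contained and exactly checkable against a naive pathway-enumeration
oracle. Absolute $\omega$ values can differ from M0 estimates, but the
purifying/neutral/diversifying classification — made by
`selectionClass()` with a configurable neutral band of $\pm 0.1$ — is
robust to the estimator choice at the effect sizes of interest.

# The synthetic-data generator

The simulator produces data with the statistical structure the analyses
assume, plus complete truth labels, and its defaults define the
validation conditions used by the test suite and the acceptance script:

* **Tree and taxa.** A 15-leaf ultrametric chronogram mirroring the
  motivating study design: 13 ingroup strains of 12 species in three
  clades (4 + 5 + 4, one species sequenced twice), two outgroups; clade
  crowns 25-35 Mya, genus crown 66 Mya, outgroup splits 120/140 Mya.
* **Family evolution.** 60 root families; new families arrive on each
  branch as Poisson(0.05/Mya x branch length); a present family is lost
  on a branch with probability `1 - exp(-0.002 x length)`, at most once
  per branch — adequate for presence/absence truth, and deliberately
  simpler than multiple-hit birth-death. Planted categories (15 core, 4
  per clade, 6 genus orphans, 6 species orphans) are forced onto their
  defining presence patterns; planted core families are also present in
  the outgroups so that they are disjoint from the genus orphans.
* **Sequences.** Each family has an independent random ancestral protein
  (mean length 120, minimum 60). Leaf copies substitute sites with
  probability `5e-4` per Mya of path from the family's origin — about
  85-93% identity between ingroup orthologs, comfortably above the RBH
  threshold while unrelated families stay far below it. Orphan-family
  ancestors being i.i.d. random guarantees the no-similarity property the
  orphan definition requires. There are no paralogs, indels, domain
  architectures or realistic codon usage; passing recovery tests
  demonstrates correctness of the set algebra and reconstruction on clean
  signals, not robustness to annotation noise or deep divergence.
* **SSCPs.** Planted hydrophobins/cerato-platanins/generic SSCPs carry a
  prefix satisfying the secretion heuristic and controlled cysteine
  patterns (random fill excludes cysteine); decoys each violate exactly
  one filter leg. Planted classes satisfy the 5% cysteine bound by
  construction, which keeps hydrophobins at or below 160 residues and
  cerato-platanins at or below 80.
* **Gene maps.** Genes occupy fixed 2-kb slots (1-kb genes) on three
  chromosomes of 1.2-1.6 Mb. Orphan runs are placed with at least one
  non-orphan gene between placements, whole runs assigned to the
  subtelomeric (midpoint within 100 kb of an end) or interior zone until
  the requested subtelomeric share (default 8%) is met; defaults plant 55
  singletons and clusters of sizes 2, 3 and 8 (about a third of orphan
  genes clustered, under a tenth subtelomeric — the regime reported for
  real fungal chromosomes). The truth records realized, not requested,
  counts, so recovery comparisons are exact.
* **Codon pairs.** Sequences diverge from a random sense-codon ancestor;
  proposals at rate 1 per site per unit time (transitions weighted by
  `kappa`, default 1), stop-creating proposals rejected, nonsynonymous
  proposals accepted with probability `omega`. With `kappa = 1` the NG86
  estimator recovers neutral simulations without bias; transition bias
  would bias NG86 upward, which is why the default is unbiased proposals.

One master seed drives everything; sub-generators use fixed offsets of
it, so a config reproduces every file byte-for-byte.

# Numerical and scale choices

Problem sizes were chosen so the whole validation chain is exact and
quick: the Wagner implementation is compared against exhaustive
enumeration over every rooted topology with up to six leaves (1,069
trees, 200 random patterns each); gain-only recovery uses 50 random trees
of 6-13 leaves; pipeline recovery clusters roughly 75 proteins per taxon
across 15 taxa; NG86 is checked to 1e-9 against naive enumeration on
30-codon pairs and calibrated on 10,000-codon simulations. Degenerate
inputs are handled explicitly: empty ingroups, subsets equal to the full
taxon set, zero-length branches, saturated substitution proportions,
sequences shorter than the signal-peptide rule's scope, and orphan ids
missing from a gene map (warning plus exclusion, listed in the report).

# Known limitations

Connected components can chain clusters through promiscuous hits on noisy
real data where MCL would split them — ingest real MCL output for such
inputs. Parsimony underestimates event counts on branches long enough for
multiple hits, and reconstructs minimal, not probable, histories. The
secretion heuristic is a transparent stand-in, not a trained predictor;
census columns that depend on homology confirmation or hydrophobin
subtyping are out of scope. dN/dS absolute values are estimator-dependent;
only the selection classification is asserted.
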