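---
title: "Reconstructing gene-family ancestry from domain hits, collinearity and gene trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-family ancestry from domain hits, collinearity and gene trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lbdtrace)
```

## The problem

Plant gene families such as the Lateral Organ Boundaries Domain (LBD)
transcription factors expanded from a handful of genes in early land plants
to dozens per angiosperm genome, through stem duplications along the
backbone of land-plant evolution and through whole-genome, tandem, proximal
and dispersed duplications inside individual genomes. Reconstructing that
history means answering three linked questions: *which* genes belong to the
family, *how* each copy arose, and *how many* ancestral genes existed at
key evolutionary depths (early land plants, the seed-plant ancestor, the
angiosperm ancestor). `lbdtrace` implements that reconstruction as a tested
pipeline over standard comparative-genomics artifacts; the heavy external
tools (hmmsearch, BLASTP, MCScanX, tree inference, codeml) are run
upstream, and their outputs are consumed as files.

## Family detection

A protein is a family member iff at least one of its domain hits to the
family profile passes **both** gates on the **same hit**:

* per-domain E-value $\le$ `max_evalue` (default $10^{-5}$, the operational
  reading of the profile's curated gathering threshold), and
* profile coverage $(\mathrm{hmm\_to}-\mathrm{hmm\_from}+1)/L \ge$
  `min_coverage` (default 0.8).

Requiring a single hit to pass both gates treats the hit as the unit of
evidence; two half-passing hits do not add up. Coverage is measured in
profile (HMM) columns, not target-sequence coordinates, because "80% of
the domain" refers to the domain model: this rejects partial matches while
tolerating sequence-divergent members. Which E-value field the gate should
use (per-domain vs full-sequence) is a genuine ambiguity in practice; the
per-domain E-value is used because the coverage gate is also per-domain,
and the threshold is configurable.

Alternative isoforms are collapsed to one representative per locus — the
longest protein, ties broken by the lexicographically smallest gene id — a
deterministic rule that makes reruns reproducible.

## Duplication typology

Genes are ranked 0..n−1 by start coordinate within each (species,
chromosome); rank is derived, never stored. The classifier then applies a
strict priority cascade, mirroring how genome-scale classifiers operate on
whole genomes (the family is subset afterwards):

1. **wgd** — the gene occurs in any collinear-block anchor;
2. **tandem** — some homology partner sits on the same chromosome at rank
   distance exactly 1;
3. **proximal** — a partner at rank distance in (1, `proximal_window`),
   default window 20, exclusive: distance 19 is proximal, 20 is dispersed.
   This is the literal reading of "spanning less than 20 genes";
4. **dispersed** — any homology partner at all;
5. **singleton** — otherwise.

Homology pairs are symmetrized first: BLAST top-k lists are asymmetric but
duplication is a symmetric relation. A gene belonging to both a tandem and
a proximal configuration with different partners takes the higher-priority
label; the cascade is the documented tie-break. Classification is
per-genome, so the pipeline feeds it intra-species pairs and intra-species
blocks only, while collinear-group merging (below) uses all blocks.

## Collinear ortholog groups

Anchors whose both genes are family members are deduplicated as unordered
pairs, and "recursive merging" is formalized as the connected components of
the resulting pair graph — the transitive closure is the only closure
consistent with iteratively clustering collinear genes. Components are
labelled deterministically by their smallest member id. Dicots and monocots
are merged separately (genome rearrangement obscures syntenic blocks
between the clades, so a joint hierarchy is not attempted); a pair spanning
the two scopes is treated as mis-scoped input and raises an error rather
than being silently dropped. Intra-species pairs (e.g. from WGD blocks)
participate in merging when present, since per-clade self-comparison
produces them naturally. Components of size $\ge 2$ are reported, including
intra-species-only ones.

## Ancestral lineages at three depths

All three inferences run on a rooted gene tree whose leaves carry species
labels (`annotated_gene_tree()`); unrooted trees can be rooted on an
outgroup or at the midpoint. Multifurcations are kept as-is — no arbitrary
resolution, for determinism.

The workhorse is `minimal_complete_clades()`: a postorder scan returning
the *minimal* clades whose leaf multiset satisfies every clause of a taxon
requirement (no qualifying strict descendant qualifies). Minimal qualifying
clades are provably pairwise disjoint, which is asserted on every run.

* **Seed-plant ancestors**: $\ge 1$ gymnosperm gene plus $\ge 1$ gene from
  every configured angiosperm species. The all-species requirement is
  deliberately stringent: it guards against long-branch attraction
  producing spurious deep clusters. Whether basal species should also be
  required is ambiguous; the package requires gymnosperm + all angiosperms
  and leaves the clause set configurable.
* **Angiosperm ancestors**: coverage of at least `dicot_min` dicot species
  and `monocot_min` monocot species (defaults: all configured). Leaves of
  other groups are *transparent* — they neither satisfy nor block clauses.
  With stem duplications, gymnosperm orthologs interleave inside angiosperm
  clades; strict exclusion would undercount, transparency keeps the
  arithmetic consistent with the reference topology.
* **Ancient lineages**: maximal clades consisting exclusively of
  bryophyte/lycophyte genes attest an ancient lineage iff their *sister*
  clade contains $\ge 1$ gene from every seed-plant species. "Neighboring"
  seed-plant genes is not otherwise topology-checkable; the sister test is
  the package's formalization and is flagged here so users know exactly
  what is being counted.

Support gating is off by default (`min_support = NULL`, pure topology);
0.95 is recommended when the tree carries SH-aLRT-style supports, applied
at the qualifying node only. A cherry parent with a missing support label
passes the gate (many tree writers omit supports on leaf-parents). Supports
in (1, 100] are read as percentages, in [0, 1] as fractions; both
conventions occur in the wild, values outside [0, 100] are errors, and
missing supports stay missing rather than becoming zero.

An angiosperm cluster is *collinearity-supported* iff its dicot members
that occur in any dicot group all occur in one group, likewise for
monocots, and at least one member is grouped at all; clusters with no
grouped member are flagged unsupported, since massive duplication can
defeat block detection.

`ancestry_report()` nests the depths by clade containment. An ancient
cluster's members are basal genes only, so a seed cluster can never be a
subset of them; containment for the path table is therefore evaluated
against the attesting basal clade's parent (basal clade plus sister), the
smallest clade that actually represents the ancient lineage. Containment
failures are reported as `"unassigned"`, never dropped.

## Branch-model LRT

`likelihood_ratio_test()` computes $2\Delta\ell = 2(\ell_1-\ell_0)$ and the
upper chi-square tail with explicit `df` (the extra omega count; a
consistency warning fires when fits are supplied and the counts disagree).
The alternative nests the null, so $\ell_1 < \ell_0 - 10^{-6}$ signals a
failed optimization upstream and is an error rather than a negative
statistic; deficits within the tolerance clamp to 0. Note that restarting
the upstream optimizer from several initial omega values is codeml's
concern, not this module's — it only does the test arithmetic on the final
likelihoods. P-values are never rounded internally.

## Conservation profiles and motifs

Per alignment column, information content is $\log_2 20 - H$ with $H$ the
Shannon entropy of the gap-excluded residue distribution; gaps are excluded
from the denominator and **no small-sample correction** is applied — the
correction is a logo-rendering presentation choice, and omitting it keeps
the statistic deterministic and exactly testable. All-gap columns get IC 0
with gap fraction 1. Motif scanning is case-insensitive, `x` is the only
wildcard, matches may overlap, and a pattern longer than the sequence is an
empty result, not an error.

## The simulator: what it emulates, and what it does not

`simulate_family()` is the package's study-condition generator. Defaults
are the modelled history: the eleven-species panel (one bryophyte, one
lycophyte, one gymnosperm, five dicots, three monocots), depth counts
(7, 11, 18) with the canonical class layout (two ancient lineages in class
IA; seed lineages 2/2/3/1/1/2 and angiosperm lineages 3/3/5/2/2/3 across
IA, IB, IC1/ID, IC2, IE, II), chromosomes of 200 background genes (5 per
species), WGD block retention 0.5, loss probability 0. Per-angiosperm-
species event counts default to wgd = 5, tandem = 2, proximal = 1,
dispersed = 4 — chosen once as a realistic mix in which WGD and dispersed
duplications dominate and tandem/proximal are minor contributors, as is
typical for regulatory families in angiosperm genomes.

Family genes sit at fixed syntenic slots (30 genes apart), so orthologous
positions align across genomes and inter-species blocks (an 11-anchor
window around each slot, per same-clade species pair) carry the true
ortholog anchors. Tandem copies insert at gene-order offset 1, proximal at
an offset drawn from 2..19, dispersed copies land on another chromosome,
and WGD events copy a ±5-gene window onto another chromosome, emitting the
intra-species block. Each event targets a distinct base gene, so every
truth label is unambiguous. Homology pairs connect genes of the same
ancient lineage, truncated to the top 5 per query by a similarity that
ranks same-species copies first, then phylogenetically near species —
enough to exercise the classifier's reliance on top-k truncation.

Deliberate non-realism: tree supports are emitted as 1 (the simulated
history is certain; noise lives in `perturb_simulation()`, which applies
exactly one perturbation — gene drop, leaf-order shuffle, or support
downgrade); "protein" sequences are per-class consensus strings with 5%
per-site substitution and implanted motifs (`SKYQ` in class IA, `LxLxL` in
class II), not output of a substitution model; simulated E-values are
rank-consistent placeholders; and there is no fractionation bias. Passing
tests on simulated data therefore demonstrates the *logic* of the pipeline
— gate arithmetic, cascade priorities, closure and clade search — under a
known truth, not robustness to alignment error, annotation noise or
incomplete block detection in real genomes.

## Numerical and testing choices

Coordinates are 1-based inclusive throughout (GFF convention). Species is
an explicit column, never parsed from id prefixes. All tie-breaks
(isoform representative, rank order, group labels, majority class of a
cluster with ties broken lexicographically) are deterministic, so byte-
identical reruns are a tested property of both the simulator and the
pipeline manifest. Degenerate inputs have defined behavior: empty hit
tables and empty pair lists yield empty results; zero ancient attestations
is a valid outcome; an anchor line outside a block header, a pair spanning
clade scopes, a member without a locus, or a requirement naming an unknown
species are errors.

The property suite checks the combinatorial kernels against independent
brute-force oracles — exhaustive clade enumeration for
`minimal_complete_clades()`, a graph library for component merging, a
per-gene rule loop for the classifier — on randomized instances (60 trees
of up to 40 leaves across requirement/support settings, 120 random graphs
of up to 100 vertices, 25 random genomes of up to 200 genes, with smaller
replicates inside the per-module tests), and parameter recovery runs the
full pipeline on 100 simulator seeds at the default conditions, sizes
chosen to keep the default suite fast while exercising every branch of the
cascade and clade logic.

## Known limitations

Tree inference, block detection and omega estimation are out of scope by
design; the quality of the reconstruction is bounded by those upstream
artifacts. The native HMMER `--domtblout` layout is not parsed verbatim —
project it to the documented seven-column table first. The ancient-lineage
criterion counts basal clades with fully covered sisters and will
undercount when basal genes are missing from the tree or supports gate out
defining nodes (by construction it never overcounts on the simulator's
histories, a tested monotone-degradation property under gene loss).
Dicot/monocot group hierarchies are intentionally not merged across
clades.
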