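---
title: "Clustering a protein superfamily into functional families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering a protein superfamily into functional families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funfamer)
```

## The problem

A CATH superfamily groups protein domains that share a common evolutionary
ancestor, but its members can catalyse very different reactions. Functional
families (FunFams) subdivide a superfamily into the largest possible groups
in which function — operationally, the EC number and the pattern of
conserved residues — is consistent. `funfamer` implements a
distance-driven version of the classic agglomerate-and-cut approach:

1. **Starting clusters (S90).** Sequences are greedily clustered at ≥ 90%
   pairwise identity; each cluster is represented by one member. Clusters
   with no experimentally supported GO annotation are set aside.
2. **Distance half-matrix.** A condensed matrix of pairwise distances is
   computed *over representatives only*, from embedding vectors (cosine,
   Euclidean or Manhattan distance) or from precomputed structural scores
   (1/bitscore, RMSD). Everything downstream sees only this matrix, so the
   distance source is pluggable.
3. **Relationship tree.** The half-matrix is agglomerated bottom-up
   (average linkage by default) into a binary merge tree.
4. **Refill and cut.** Leaves are refilled with their full cluster
   membership, per-node alignments are built bottom-up by profile–profile
   alignment, and the tree is cut wherever a merge would join two
   sub-alignments showing *differentially conserved positions* (DCPs) —
   columns strongly conserved on both sides but with different consensus
   residues, the signature of diverged specificity.

Three orchestration protocols wrap these stages. The **single pass** runs
them once over the whole superfamily. **MARC** prepartitions sequences by
multi-domain architecture (MDA), runs the stages per partition, then pools
the resulting FunFams as starting clusters (each represented by its
embedding-space medoid member) for a final iteration. **FRAN** deals the
starting clusters at random into fixed-size projects, cuts each
independently, and relies on a merging second iteration to reunite
families split across projects. FRAN's first iteration characteristically
over-fragments — its value is bounding per-project problem size — and the
second iteration can only merge, never split, so its family count is
monotonically non-increasing.

## Scores and rules

**Pairwise identity** is the number of identical aligned residue pairs in
the optimal global alignment divided by the length of the shorter
sequence, the convention of greedy incremental clustering tools. `X`
(unknown residue) never counts as a match.

**Column conservation** for column $j$ with non-gap residue frequencies
$p_i$ and gap fraction $g_j$:

$$s_j = \left(1 - \frac{H_j}{\ln 20}\right)(1 - g_j), \qquad
  H_j = -\sum_i p_i \ln p_i .$$

This entropy score is a deliberate proxy for the scorecons family of
conservation scores: it honours the same contract (an invariant gap-free
column scores 1, a column holding all twenty residues scores 0, gaps
attenuate) without the stereochemical and sequence weighting of the full
trident score. It is the single substitution point if an exact scorecons
implementation is wanted later. Absolute values are therefore not
comparable to published DOPS figures; only ordering behaviour is.

**DOPS** (diversity of positions score) maps the proportion of conserved
columns onto 0–100:

$$\mathrm{DOPS} = 100\left(1 - \frac{|\{j : s_j \ge c_{\mathrm{cons}}\}|}{n_{\mathrm{cols}}}\right)$$

with $c_{\mathrm{cons}} = 0.9$, chosen so an alignment of identical
sequences scores exactly 0 (no variability, uninformative) and a fully
diverse alignment scores 100.

**DCP rule.** After placing two alignments on a common coordinate system
by profile–profile alignment, a merged column is differentially conserved
iff *all* of:

* conservation $\ge c_{\mathrm{high}}$ (default 0.8) on both sides;
* gap fraction $< g_{\max}$ (default 0.5) on both sides;
* at least `min_support` (default 2) non-gap residues on both sides;
* the modal residues differ.

A merge is accepted when both children were accepted, the DCP count is at
most `d_max` (default 0) and, when a `distance_ceiling` is set, the merge
height does not exceed it (the ceiling is off by default: the cut is
driven by differential conservation). FunFams are the member sets of
maximal accepted subtrees, which makes the output a partition by
construction.

The `min_support` condition is this package's own addition to the
otherwise conventional four-part DCP test, and it matters: every column
of a single-sequence alignment is trivially "100% conserved", so without
a support floor each stray point mutation in a singleton cluster
registers as differential conservation and singleton S90 clusters could
never merge with their family. Requiring two observations per side is
the minimal statistically meaningful notion of within-group conservation;
setting `min_support = 1` restores the literal rule.

## Alignment machinery

Starting-cluster members are ≥ 90% identical, so a guide tree adds
nothing: members are aligned progressively in length-descending order
(ties broken by id), each sequence profile-aligned into the growing MSA.
Global alignment is Needleman–Wunsch (Gotoh for affine gaps) with a fixed
traceback preference (diagonal > up > left) so results are bit-reproducible.
The default scheme is BLOSUM62 with gap open 11 / extend 1; a flat
identity scheme (match 1, mismatch −1, linear gap 1) supports
exact-arithmetic testing. Profile–profile column scores are mean pairwise
substitution scores with gap-vs-residue pairs charged the extension
penalty; in affine mode each *run* of inserted gap columns additionally
pays the opening penalty once — without it, a single strong mismatch
(e.g. D vs Y under BLOSUM62) is "cheaper" to stagger into two gap columns
than to align, which would split exactly the specificity columns the cut
is looking for. The two profiles are oriented canonically (by smallest
row id) before the dynamic program so `profile_align(A, B)` and
`profile_align(B, A)` agree up to row order.

## Tree construction choices

The agglomerator merges the minimum-distance pair and updates distances
with the Lance–Williams rule (unweighted average by default; single,
complete and centroid are exposed for experimentation — centroid may
produce non-monotone heights and is not default). Average linkage is the
closest distance-space analogue of comparing merged profiles, which is
what the HMM-based ancestor of this pipeline effectively does. Exact ties
are broken by the lexicographically smallest (left id, right id) pair,
which makes the merge list independent of input ordering; merge heights
are non-decreasing for average/single/complete linkage, and the suite
checks the whole merge list against a naive oracle that recomputes every
inter-cluster distance from scratch after each merge.

## The synthetic test substrate

`generate_superfamily()` plants $K$ families: each family draws a random
ancestor, shares a set of SDP columns at which every family holds its own
fixed residue (distinct between any two families), and members copy the
ancestor with an independent per-site substitution probability μ at
non-SDP sites (uniform over the 19 alternatives — a neutral model;
separability control, not realism, is the goal).
`generate_embeddings()` places family centers at
$N(0, \sigma_b^2 I)$ and members at center $+ N(0, \sigma_w^2 I)$. The
study conditions used throughout the tests and the acceptance script are
$K=6$ families × 40 members, length 80, 3 SDP columns, μ = 0.03,
$\sigma_b/\sigma_w = 6$, embedding dimension 16 — a desk-scale stand-in
for a diverse, well-annotated superfamily that runs end to end in
seconds. Families get ECs `1.1.1.i` (distinct EC4, shared EC3, so the
EC4/EC3 purity distinction is exercised) and every member carries the
family's experimental GO term, making the evidence filter a pass-through
under these fixtures; the filter's discard behaviour is tested
separately on toy clusters.

Two generator regimes matter. With independent ancestors (default),
families differ across most columns and are separable by identity and by
embedding — the regime for end-to-end recovery tests. With
`shared_ancestor = TRUE`, families differ *only* at the SDP columns, the
right regime for checking that DCP detection recovers exactly the
planted columns (at μ = 0 the detected set equals the planted set).

What the generator does **not** emulate: indels (alignments of simulated
members are gap-free), rate heterogeneity across sites, phylogenetic
correlation within families, biased amino-acid composition, and
annotation noise. Passing these tests therefore demonstrates the
machinery is correct and deterministic, not that real superfamilies with
fragmented domains and sparse annotation will be recovered at the same
fidelity.

## Benchmarking

EC purity of a FunFam at level ℓ ∈ {3,4}: each member contributes its EC
numbers truncated to ℓ fields; truncations still containing the `-`
wildcard are excluded at that level (an EC like `3.4.12.-` counts at EC3
but not EC4); a member with several valid keys splits a unit weight
equally among them, so promiscuous annotations cannot dominate. Purity is
the largest key weight over the total; a FunFam with no contributing
member has *undefined* purity — reported as missing and excluded from
averages, never as zero. Threshold proportions ("over 80/90/100%") are
inclusive and reported against both denominators (defined-only and all
FunFams), since the choice is not obvious. Partition agreement with the
planted truth uses the adjusted Rand index.

## Parameter summary

| Parameter | Default | Meaning |
|---|---|---|
| `identity_threshold` | 0.90 | S90 membership: identity to representative |
| `evidence_whitelist` | EXP, IDA, IPI, IMP, IGI, IEP | experimental GO codes |
| `metric` | cosine | representative distance |
| `linkage` | average | Lance–Williams update |
| `c_high` | 0.8 | conservation floor for a DCP side |
| `c_cons` | 0.9 | DOPS conserved-column cutoff |
| `g_max` | 0.5 | max gap fraction for comparable columns |
| `min_support` | 2 | min non-gap residues per side for a DCP |
| `d_max` | 0 | DCPs tolerated per accepted merge |
| `distance_ceiling` | none | optional height gate on merges |
| `mda_min_size` | 1 | sequences for an MDA to separate (scale parameter; production-scale analogues run to the millions) |
| `fran_project_size` | 10 | max starting clusters per FRAN project |

## Known limitations

* The conservation score is an entropy proxy, not scorecons; DOPS values
  are internally consistent but not comparable to published numbers.
* The distance mode replaces profile-HMM comparison with single-
  representative distances; as with the production systems this trades a
  little purity for large speed and memory gains, and cannot see
  within-cluster heterogeneity beyond the refill stage.
* The greedy clusterer is exact (all-vs-representative alignments)
  rather than k-mer-prefiltered, so it is quadratic-ish and meant for
  desk-scale inputs; an external tool's membership TSV can be substituted
  through `read_cluster_membership()`.
* MDA strings are treated as flat ordered lists; discontinuous domains
  have no special handling.
* Whether the production MDA threshold applies per architecture or per
  superfamily is ambiguous in the literature describing it; this package
  applies it per architecture (`partition_by_mda`).
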