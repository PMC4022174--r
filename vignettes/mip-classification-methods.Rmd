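---
title: "Methods: classifying major intrinsic proteins with mipclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying major intrinsic proteins with mipclass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mipclass)
```

## Scope

`mipclass` classifies major intrinsic proteins (MIPs, the
aquaporin/aquaglyceroporin channel family) into subfamilies from three
lines of evidence: the two NPA-like tripeptide boxes on loops B and E,
the four-residue aromatic/arginine (ar/R) selectivity filter, and
distance-based phylogenetic placement. Its particular focus is the LIP
("large intrinsic protein") group of heterokont algae, delineated by a
proline at the first loop-E filter role (LE1) together with leucine or
isoleucine at the second (LE2), typically accompanied by an NPM second
box, tryptophan or tyrosine at the helix-2 role (H2), and a C-terminal
lysine.

Because real heterokont proteomes are out of scope, the package ships a
simulator that generates MIP-like protein sequences with planted,
fully-recorded truth: box variants, filter residues, C-terminal residue,
and an exact alignment back to the generating template. All statistical
claims in the test suite are made against this planted truth.

## Motif model

A candidate box is any occurrence of N-[PG]-X. The scanner scores exact
NPA as 2 and any other candidate as 1, and reports the pair (one start
in the N-terminal 60% of the sequence, one in the C-terminal 60%)
maximising the summed score subject to a minimum separation of 40
residues — roughly the three transmembrane helices between loops B and
E. Ties resolve to the left-most starts, so scanning is deterministic.
Boxes are never fabricated: a sequence with no candidate in a window
yields an absent box plus a warning record. The pair label is one of
`canonical`, `second_NPM`, `first_variant` (covering the NGA- and
NPG-type first boxes seen in the panel), `other_variant`, or
`incomplete`. Variant first boxes other than NGA/NPG are not given
bespoke labels; they fold into the same `first_variant`/`other_variant`
scheme.

## ar/R filter extraction

The four filter roles (H2, H5, LE1, LE2) are read off a global pairwise
alignment between the query and an annotated reference, mapping the
reference's annotated columns onto the query. This replaces the
profile-HMM alignment a full-scale study would use; the mapping
semantics are the same, but a pairwise alignment carries less context
than a profile, which matters at high divergence (see *Limitations*).

Alignment is Needleman–Wunsch with BLOSUM62 and affine gaps (a gap of
length L costs `open + extend * L`, defaults 10 and 1 — conventional
protein-alignment settings, both exposed in the pipeline config). The
packaged reference table contains two entries named `HsAQP1` and
`EcGlpF` carrying the published annotations F56/H180/C189/R195 and
W48/G191/F200/R205 respectively. The underlying residue strings are
**synthetic stand-ins** (the file is named
`mip_references_synthetic.tsv` and says so in its descriptions): real
database sequences could not be bundled, so the stand-ins are built on
the simulator's scaffold coordinate system with edit plans that place
the annotated letters at exactly the published positions, which are
asserted every time the table is loaded. References are auto-selected
per query by alignment score; ties resolve to table order.

Substrate specificity is a lookup against the two experimentally
grounded signatures: H2=W, H5=V, LE1∈{A,G}, LE2=R is a glycerol
permease; H2=F, H5=H, LE1∈{A,C}, LE2=R is a water channel. The two
rules are mutually exclusive (their H2 letters differ). Any other
complete filter is `unknown`, and a filter with any gapped role is
never scored — partial filters get `incomplete`, not a guess.

## Distances and trees

Pairwise distances are maximum-likelihood estimates under the
Jones–Taylor–Thornton (JTT) empirical substitution model. The published
exchangeabilities and equilibrium frequencies are shipped as plain-text
data with md5 checksums asserted at load. The rate matrix is normalised
to one expected substitution per site per unit branch length, and its
reversibility is exploited: symmetrising with the square-root of the
stationary distribution gives a real spectral decomposition, so
transition matrices for any distance cost one matrix product. The
likelihood of an aligned pair (pairwise deletion of gapped columns) is
unimodal in the distance; it is maximised by bracketed 1-D search on
[0, 10] to a tolerance of 1e-6. Identical rows short-circuit to exactly
0; estimates hitting the cap are flagged saturated.

Trees come from a from-scratch Saitou–Nei neighbour-joining
implementation with the Studier–Keppler criterion. Two numerical
choices make it fully deterministic and well behaved: ties in the
join criterion are broken by the lexicographically smallest pair of
cluster representatives (C-locale byte order), and a negative
intermediate branch length is clamped to zero with the deficit
transferred to its sibling edge, preserving the path lengths NJ is
consistent for. On additive matrices the generating tree is recovered
exactly. Bootstrap supports resample alignment columns with
replacement, rebuild the tree, and report for each internal edge of the
full-data tree the percentage of replicates containing the same leaf
bipartition; replicates whose resampled matrix is degenerate are
skipped, and more than 10% skips is an error rather than a silent
bias.

## Classification logic

Evidence is combined with a fixed precedence:

1. the LIP primary criterion (LE1 = P and LE2 ∈ {L, I}) — deliberately
   tree-independent, because the group is *defined* by its filter
   signature; a conflicting tree placement is logged in the evidence
   trail but does not override it;
2. monophyly with exactly one labelled reference group at bootstrap
   support ≥ 50;
3. the glycerol-permease filter rule (→ GIP);
4. the water rule, which alone cannot separate PIP from MIPE — without
   tree evidence the call stays `unclassified` with both candidates
   recorded;
5. otherwise `unclassified`.

Every call carries a non-empty evidence trail; summaries refuse rows
without one.

## The simulator and the packaged panel

All simulated sequences derive from a fixed 300-residue scaffold
template drawn once from the JTT equilibrium frequencies under an
internal seed, with a canonical aquaporin layout planted: NPA boxes at
78 and 185, filter F60/H175/A188/R190. Six design points matter:

* **Protected positions.** The planted boxes, the four filter residues
  and the C-terminal residue never mutate, and indels are re-drawn away
  from windows around them. This is what makes planted truth exact.
* **Conserved cores.** Six column ranges flanking the planted features
  (the transmembrane stretches) are held fixed — no substitutions, no
  indels — in every scaffold-derived template, panel member, and
  synthetic reference. Real MIP families keep exactly these stretches
  recognisably conserved while loops and termini drift; they are also
  what makes reference-anchored extraction well-posed. The `divergence`
  parameter is therefore the expected substitution load on the
  *evolvable* sites.
* **Decoy suppression.** Chance N-[PG] occurrences outside the planted
  boxes are rewritten (never touching protected positions), so the
  planted boxes are the only scanner candidates in generated data. Box
  recovery statistics thus measure coordinate fidelity, not luck.
* **Substitution processes.** The default `uniform` process draws a
  Poisson(divergence) number of hits per site, each replacing the
  residue uniformly among the 19 alternatives; its observed difference
  fraction has the closed form (19/20)(1 − exp(−20d/19)) used by the
  tests. A `jtt` mode samples descendants from the JTT transition
  matrix instead, for distance-recovery checks.
* **Indels.** Event count Poisson(rate × length), insertion or deletion
  with equal probability, lengths 1 + Geometric(1/2). `indel_rate =
  NULL` defaults to divergence/60, so zero divergence is exactly the
  identity.
* **Subfamily structure.** Eight subfamily ancestors sit at 0.5
  expected substitutions per evolvable site from the scaffold, each
  under a fixed internal stream, so families simulated from different
  subfamilies are distinguishable yet alignable in one coordinate
  system.

The packaged 20-protein heterokont panel encodes the published
comparison: the Table-1 filter strings, the eight NPM second boxes, the
NGA and NPG first-box variants, C-terminal lysines on the NPM carriers,
and the published length classes (EsMIP 225, NgMIP 230, other LIP
members 280–317), produced by centred deletions in the flexible
inter-feature regions. Member-level variation (8% of evolvable sites)
comes from the caller's seed, so the panel is deterministic given a
seed and its classification is seed-stable. The published description
enumerates motif variants for only half the panel; the un-enumerated
proteins are carried with canonical NPA pairs, and no statistic is
derived from the count of conserved pairs, since the source is
ambiguous on that point.

## Limitations

* **Pairwise extraction at high divergence.** The published HsAQP1/EcGlpF
  coordinates force both synthetic references to carry private edits in
  the loop-E region (e.g. a four-residue insert between LE1 and LE2 for
  HsAQP1). When a query has drifted enough near those edits, the
  *optimal* global alignment can place its gaps a column or two away
  from the true homology — the score genuinely favours it, so no
  tie-break fixes it. At divergence 0.3 this costs roughly half a
  percent of extractions; the package reports such cases honestly
  rather than repairing them with template knowledge a real query would
  not have.
* **LE2 = V ties.** For panel members whose filter ends in valine
  (the bacterial-type IAGV/TASV filters), BLOSUM62 scores V against R
  no better than the gap continuation the reference insert forces, so
  LE2 maps to a gap. These extractions are flagged `low_confidence` and
  get specificity `incomplete`; the affected proteins carry no scored
  specificity either way. The behaviour is deterministic and asserted
  in the tests as a documented operating characteristic.
* **Water rule ambiguity.** The FHAR/FHCR signature is shared between
  PIP- and MIPE-type channels; filter evidence alone cannot separate
  them, and the classifier says so instead of guessing.
* The simulator generates protein sequences only — no gene structure,
  no nucleotide-level processes, no attempt to mimic real heterokont
  proteomes beyond the panel's published feature table.

## Reproducibility

Every random stage takes an explicit integer seed, and the pipeline
writes its outputs deterministically (C-locale sorts, fixed number
formatting): two runs with the same config are byte-identical. The run
manifest records the config echo, package version, md5 checksums of the
packaged data files, per-stage record counts, warnings, and — on
failure — the failing stage.
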