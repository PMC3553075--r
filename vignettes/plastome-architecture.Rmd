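---
title: "Plastome architecture, structural characters and Dollo placement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome architecture, structural characters and Dollo placement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Most land-plant plastid genomes are quadripartite: a large and a small
single-copy region (LSC, SSC) separated by two identical, oppositely
oriented copies of an inverted repeat (IRa, IRb). Genome content and
architecture evolve slowly, so the rare changes that do happen — junction
shifts that capture single-copy genes into the IR, block inversions, and
losses of individual genes or introns — behave like low-homoplasy
characters. In groups where sequence-based phylogenetics is unstable
(horsetails are the canonical case: an ancient lineage with no close living
relatives and an elevated substitution rate, a recipe for long-branch
artifacts), these structural characters can carry the decisive signal.

This package implements that workflow end to end: detect the IR and derive
the partition, describe the four junctions, score genes and introns into a
presence/absence matrix with positional intron names, and map the implied
gains and losses onto candidate topologies with Fitch and Dollo parsimony,
including a regraft scan that asks how many extra events an alternative
placement of a clade would cost.

## Inverted-repeat detection

`detect_ir()` looks for the longest pair of disjoint, reverse-complementary
segments on the circle. Exact k-mer seeds shared between the sequence and
its reverse complement are grouped on anti-diagonals (the invariant of a
common substring between the sequence and its reverse complement), extended
into maximal runs circularly, and optionally merged across a bounded number
of substitutions.

Tunable parameters, with defaults:

* `min_length = 1000` bp. Real plastome IRs are 9–25 kb; 1 kb excludes
  dispersed repeats while catching every IR in scope.
* `max_mismatch = 0`. The two IR copies are homogenized by recombination
  and are typically identical; mismatch tolerance exists for partially
  degraded repeats but is off by default. Only substitutions are modeled —
  indel-tolerant extension is out of scope.
* `k = 31`. Seeds must be long enough that chance matches are negligible
  (4^-31) and short enough to subdivide any real IR.

Degenerate outcomes are explicit: a sequence with no qualifying repeat
returns a "no IR" partition (`found = FALSE`) rather than an error, and
equal-length candidates are tie-broken to the smallest start coordinate
with a warning, so results are deterministic. The SSC is the shorter
single-copy gap by definition; IRa is the copy that follows the LSC in
circle order, matching conventional map presentation. A gene counts as "in
the IR" only when fully contained in one copy — genes cut by a border
belong to the junction report, which records them with a truncated-copy
flag, mirroring how border-straddling genes leave a fragmented second copy
in real genomes.

## Structural characters

The packaged ten-taxon matrix (`content_matrix()`) covers two lycophytes
and eight ferns with five states: present (`1`), absent (`0`), pseudogene
(`P`), trans-spliced (`T`) and unknown (`?`). Counting and parsimony work
on recoded binary views (`recode_binary()`); the stored grid is never
mutated. Two policies exist:

* `strict` (default): pseudogenes count as absent. This reproduces the
  curated per-taxon totals (genes 116–122, introns 17–22) exactly.
* `pseudo_as_present`: pseudogenes count as present. A pseudogene is
  physical evidence that the locus was present on that lineage, which is
  the relevant reading for Dollo arguments.

The trans state is display-only and maps to present in every computation
(the trans-spliced rps12 first intron is still an intron).

Intron characters use positional nomenclature: an intron is named
`<gene>i<position>` by the nucleotide position immediately 5' of its
insertion site in a reference copy of the host gene. `name_intron()`
aligns the host exon concatenation to the reference globally (match 1,
mismatch −1, gap open −4, gap extend −1), maps the insertion coordinate
through the alignment, resolves gap columns to the nearest aligned
reference position 5' of the site, and refuses to name anything aligning
below 50% identity — misnaming against the wrong reference is worse than
no name. tRNA intron labels drop the anticodon hyphen (`trnKUUUi37`).

Two characters cannot be derived from a plastome annotation and ship as
fixture-only "extrinsic" characters: the mitochondrial atp1i361 intron and
the LSC-side IR expansion that captured the 3'-rps12/rps7/ndhB/trnL-CAA
block. Both are gain-direction characters in the event mapping.

One curated-data caveat is flagged rather than resolved: the source
literature states rpl16 is wholly absent from several fern lineages while
its content table scores the gene present throughout (only the rpl16i9
intron varies); the packaged matrix follows the table.

## Parsimony and the placement scan

Characters are directional. Loss characters (almost everything) use
root-present Dollo: the state is ancestrally present and the reconstruction
is the minimal set of edges whose subtrees contain all absent tips —
computed exactly by a single traversal that descends only into subtrees
still containing present tips. Gain characters use either single-gain
Dollo (`dollo_reconstruct(..., "single_gain")`: the gain sits above the
smallest clade containing all present tips, losses explain absences inside
it) or, in `map_events()`, the minimal set of independent gains with no
losses; a character needing more than one independent event of the same
type is flagged homoplasious. Unknown states never force an event. The
generic Fitch engine (`fitch_min_changes()`) backs the property tests and
ties are broken toward the parent state, so labelings are deterministic.

`placement_scan()` prunes a clade, reattaches it on every edge of a scope
subtree, and counts per-character Dollo events for each placement.
Two choices deserve justification:

* **Scope**: the scan defaults to the fern subtree. Placements outside the
  ingroup are not biologically entertained and would only pad the report.
* **Group monophyly**: the scan keeps the recognized major groups
  (Psilotopsida, Equisetales, Marattiales, Polypodiopsida, the lycophyte
  outgroup) monophyletic. The hypothesis space is "which group is this
  clade sister to", not "break another group apart"; an attachment inside
  Psilotopsida, for example, is no longer an alternative *group*
  relationship. This constraint is what makes the one-loss-versus-two
  contrast well defined.
* **Policy**: the placement argument for rps16 is run with
  `pseudo_as_present`, because the lycophyte rps16 pseudogene witnesses
  presence on that branch; under the strict recode the column would carry
  an extra outgroup pendant loss that has nothing to do with the fern
  question. rps12i346 has no pseudogene states and is unaffected.

With the packaged matrix and reference topology this yields: one loss each
for rps12i346 and rps16 on the Psilotopsida+Equisetales stem on the
favored topology, a minimum of two independent losses each under every
alternative Equisetum attachment, a single atp1i361 gain on the
Marattiales+Polypodiopsida stem with zero losses, and a homoplasious
IR-expansion character (Psilotum and Marattiales+Polypodiopsida
independently). The clpPi363 loss maps to the Equisetum stem, rpl16i9 to
the *E. hyemale* pendant edge.

`reversal_scenario()` handles the inversion side: breadth-first search over
signed block reversals, exhaustive and therefore bounded (≤ 12 genes,
configurable depth). It reports the reversal list or an explicit
"unsolved" beyond the depth bound; it is intended for the short
IR-adjacent gene orders where inversion scenarios are argued, not for
genome-wide rearrangement distances.

## What the simulator emulates — and what it does not

`make_ancestor()` builds a compact quadripartite genome (~47 kb by
default): an LSC roster of 20 canonical plastid genes, a 7-gene SSC, the
nine-gene ancestral IR complement (four rRNAs, five tRNAs), thirteen
introns at their canonical host positions (including both clpP introns and
rps16i40, so the loss characters the event mapping reasons about exist in
simulation), uniform 120–280 bp intergenic spacers, and IRb as the exact
reverse complement of IRa. The compact scale keeps the default test and
acceptance runs fast while preserving every structural property the
pipeline measures; region proportions and gene length scales are realistic
even though the total size is about a third of a real plastome.

Sequence content is random with per-feature seeds derived from the master
seed, so genomes are reproducible and non-repetitive (no accidental
secondary IRs at k = 31). One deliberate nudge: a random single-copy base
immediately flanking a junction has a 1-in-4 chance of extending the
repeat pairing by chance, so the generator adjusts up to two spacer bases
to make the planted IR the exact maximal repeat — otherwise "planted
interval recovered exactly" would be false for one run in two for reasons
that have nothing to do with the detector.

`simulate_history()` draws per-branch Poisson event counts (defaults: 0.2
gene losses, 0.2 intron losses, 0.1 pseudogenizations, 0.1 IR expansions,
0.1 inversions per branch — the "few lineage-specific changes" regime) with
uniform targets among currently eligible features, and maintains Dollo
coherence along every path. In `no_homoplasy` mode a character hit
anywhere becomes ineligible everywhere, including the implicit case where
losing a host gene would re-hit its intron characters. Replay is exact:
`emit_genomes()` edits the ancestor's blueprint (splice out genes/introns,
plant an in-frame stop for pseudogenes so coordinates stay stable, slide
junctions for expansions, reverse-complement inversion blocks) and
re-renders; IRb always remains the exact mirror of IRa.

The simulator does **not** model nucleotide substitution, branch lengths
in time units, IR contraction (expressible as the mirror expansion in
tests), indels, or rearrangements spanning region boundaries. Passing the
plant-and-recover suite therefore demonstrates that the pipeline's logic
is correct on clean annotations; it says nothing about robustness to
annotation error or sequence divergence in real data, where the
alignment-based intron naming and the mismatch-tolerant IR extension do
the corresponding work.

## Numerical and engineering choices

* Internal coordinates are 0-based half-open everywhere; GenBank I/O
  converts at the boundary, and an origin-spanning `join` folds into a
  single wrapping interval (`end < start`) that every length/containment
  operator understands.
* Problem sizes in the default test suite: planted circles of 2–8 kb,
  synthetic plastomes of ~47 kb, ten-tip trees, Fitch oracle sweeps over
  all labelings of 4–7-tip trees, reversal oracles on 8-element signed
  orders scrambled by three reversals.
* Records lacking an explicit circular topology flag are treated as
  circular with a warning — everything in scope maps circularly.
* Gene symbols are folded into one symbol space
  (`normalize_symbol()`): tRNA anticodon canonicalization, lowercase
  `ycf`/`rrn`/... prefixes, and the known content-table typo
  `cplPi363` → `clpPi363`.
* The ordering of successive IR expansions at one junction is *not*
  inferred — only net gained/lost sets relative to the ancestral
  complement. Ordering arguments require outgroup reasoning that is out of
  scope here.

## A worked fixture run

```{r}
library(plastomes)

tree <- reference_tree()
m <- content_matrix(extrinsic = TRUE)
defs <- dplyr::bind_rows(character_definitions(), extrinsic_characters()$defs)

count_all_taxa(content_matrix())          # totals: genes 116-122, introns 17-22

scan <- placement_scan(tree, major_groups()$Equisetales, m,
                       c("rps12i346", "rps16"), defs,
                       policy = "pseudo_as_present", scope = fern_taxa(),
                       keep_monophyletic = major_groups())
glance(scan)                              # original 2 events, alternatives >= 4

map_events(tree, m, defs, policy = "pseudo_as_present")
autoplot(scan)
```

## Known limitations

GenBank writing is out of scope (the simulator's minimal flat-file writer
exists for round-trip testing only). IR detection tolerates substitutions
but not indels between copies. The regraft scan is exhaustive over edges,
which is fine for tens of taxa but not hundreds. Support values on input
trees are carried, never interpreted: topology assessment by resampling or
likelihood is a different tool's job, and this package deliberately takes
the topology as an input.
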