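# plastomes

Comparative plastome architecture and rare genomic structural changes, for
plant molecular systematists working where sequence-based phylogenetics
gives unstable answers.

Land-plant plastid genomes are quadripartite — a large and a small
single-copy region (LSC, SSC) separated by two identical inverted-repeat
copies (IRa, IRb) — and both the architecture and the gene/intron
complement evolve very slowly. When a lineage is prone to long-branch
artifacts (horsetails are the textbook case), the few structural changes
that did happen — IR junction shifts, block inversions, losses of single
genes or introns, rare intron gains — can be treated as low-homoplasy
characters and mapped onto candidate topologies directly.

The package covers that workflow end to end:

* **Architecture** — `read_genbank()` parses annotated flat files
  (compound locations, pseudogene and trans-splicing flags, derived
  introns); `detect_ir()` finds the maximal pair of disjoint
  reverse-complementary segments by seeded anti-diagonal extension on the
  circle and derives the LSC/IRa/SSC/IRb partition; `summarize_plastome()`,
  `junction_map()` and `compare_boundaries()` produce the per-genome
  summary, the four junction adjacencies (with truncated-copy flags) and
  the gained/lost IR complement relative to the ancestral nine-gene set;
  `reversal_scenario()` finds minimal signed-inversion scenarios between
  short gene orders by exhaustive breadth-first search.
* **Characters** — a curated ten-taxon (two lycophytes, eight ferns)
  gene/intron matrix over states {present, absent, pseudogene (Ψ),
  trans-spliced, unknown} ships as `content_matrix()`; `extract_states()` /
  `build_matrix()` score annotated genomes; `name_intron()` implements
  positional intron nomenclature (`rps12i346` = intron inserted after
  nucleotide 346 of the reference host copy) via global alignment.
* **Parsimony** — `fitch_min_changes()` (minimum free reversals),
  `dollo_reconstruct()` (root-present Dollo for loss characters,
  single-gain Dollo for gains), `map_events()` (per-branch event ledger
  with homoplasy flags), and `placement_scan()` (prune a clade, reattach
  on every edge of a scope subtree, count the Dollo events each placement
  forces).
* **Simulation** — `make_ancestor()`, `simulate_history()` and
  `emit_genomes()` generate annotated circular plastome-like genomes along
  a known tree with planted losses, pseudogenizations, IR expansions and
  inversions plus a replayable truth log, so every stage is testable
  without downloads.

Results are tibbles (with `tidy()`/`glance()`/`autoplot()` methods), so
everything composes with the usual dplyr/ggplot2 verbs.

## A worked example

The question the toolkit was built around: where do the horsetails
(*Equisetum*) attach among ferns? Two structural characters — the loss of
the *rps16* gene and of the rps12i346 intron — are shared by Psilotopsida
(*Ophioglossum* + *Psilotum*) and *Equisetum*:

```r
library(plastomes)

tree <- reference_tree()                  # ten-taxon topology, lycophyte-rooted
m    <- content_matrix(extrinsic = TRUE)  # curated matrix + extrinsic characters
defs <- dplyr::bind_rows(character_definitions(), extrinsic_characters()$defs)

bin <- recode_binary(m, "pseudo_as_present")
dollo_reconstruct(tree, setNames(bin$rps12i346, bin$taxon), "root_present")
#> <dollo_result> mode=root_present gain=root-ancestral losses=1
#>    node edge
#> 1    14 Equisetum_arvense+Equisetum_hyemale+Ophioglossum_californicum+Psilotum_nudum
```

One loss, on the stem of Psilotopsida + *Equisetum*. Is any other
placement as cheap? Prune the *Equisetum* clade and reattach it on every
edge of the fern subtree (keeping the recognized major groups intact):

```r
scan <- placement_scan(tree, major_groups()$Equisetales, m,
                       c("rps12i346", "rps16"), defs,
                       policy = "pseudo_as_present", scope = fern_taxa(),
                       keep_monophyletic = major_groups())
glance(scan)
#>   n_placements original_total alternative_min_total alternative_max_total
#> 1            5              2                     4                     4
```

The favored topology needs one loss per character (total 2); every
alternative attachment forces at least two independent losses of each
(total ≥ 4). The same machinery shows the mitochondrial atp1i361 intron as
a single gain on the Marattiales + Polypodiopsida stem with zero losses,
and flags the IR expansion shared by *Psilotum* and
Marattiales + Polypodiopsida as homoplasious (`map_events()`).

Counts from the curated matrix reproduce the published per-taxon totals —
deduplicated gene counts 116–122 and intron counts 17–22, e.g. 17 introns
for *Equisetum hyemale* and 122 genes for *Angiopteris evecta*:

```r
count_all_taxa(content_matrix())
#>    taxon                     genes trnas rrnas proteins introns
#>  5 Equisetum_hyemale           121    33     4       84      17
#>  7 Angiopteris_evecta          122    33     4       85      22
#>  9 Adiantum_capillus_veneris   116    28     4       84      20
```

And the simulator round-trips: a seeded ancestor's planted IR is recovered
exactly by detection,

```r
detect_ir(make_ancestor(ancestor_spec(), seed = 1))
#> <quadripartite_partition> genome 48,770 bp
#>   LSC [0,26400) 26400 bp | IRa [26400,33060) | SSC [33060,42110) 9050 bp | IRb [42110,48770)
#>   IR 6660 bp, 0 mismatch(es) between copies
```

A thin command-line wrapper (`inst/cli/plastomes-cli.R`) exposes the
stages as subcommands (`summarize`, `junctions`, `matrix`, `scan`,
`map-events`, `simulate`, `all`) over YAML/flag configuration, writing
stamped CSVs plus a MANIFEST.

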