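#' Read a rooted tree from a Newick file or string
#'
#' Thin wrapper over [ape::read.tree()] that validates the properties the
#' parsimony machinery relies on: unique tip labels and a rooted, binary
#' topology. Internal node labels (e.g. support values) are retained as
#' annotations and never interpreted; branch lengths are kept but ignored by
#' all parsimony operations.
#'
#' @param x path to a Newick file, or a Newick string.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(x) {
  tree <- if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
  if (is.null(tree)) abort("could not parse Newick input")
  validate_tree(tree)
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @param path output file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_tree <- function(tree) {
  if (anyDuplicated(tree$tip.label)) abort("duplicate tip label in tree")
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (!ape::is.binary(tree)) abort("tree must be binary")
  invisible(tree)
}

#' The packaged ten-taxon reference topology
#'
#' Rooted on the two lycophytes; ferns comprise (Psilotopsida + Equisetum)
#' sister to (Marattiales + Polypodiopsida). This is the maximum-likelihood
#' topology the event mapping and placement scans are evaluated on.
#'
#' @return a `phylo` object with the ten matrix taxa as tips.
#' @export
reference_tree <- function() {
  read_newick(path_package_file("reference_tree.nwk"))
}

#' Major-group membership of the ten matrix taxa
#'
#' @return named list of tip-label vectors (Lycophytes, Psilotopsida,
#'   Equisetales, Marattiales, Polypodiopsida).
#' @export
major_groups <- function() {
  list(
    Lycophytes    = c("Isoetes_flaccida", "Huperzia_lucidula"),
    Psilotopsida  = c("Ophioglossum_californicum", "Psilotum_nudum"),
    Equisetales   = c("Equisetum_hyemale", "Equisetum_arvense"),
    Marattiales   = "Angiopteris_evecta",
    Polypodiopsida = c("Alsophila_spinulosa", "Adiantum_capillus_veneris",
                       "Pteridium_aquilinum"))
}

#' @rdname major_groups
#' @export
fern_taxa <- function() {
  unname(unlist(major_groups()[c("Psilotopsida", "Equisetales", "Marattiales",
                                 "Polypodiopsida")]))
}
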