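#' Structural character definitions
#'
#' The closed list of gene and intron characters scored across the ten
#' packaged taxa: symbol, kind (`gene`/`intron`), functional class
#' (`tRNA`/`rRNA`/`protein`/`intron`), the intron host gene and its reference
#' insertion position (positional nomenclature: `<gene>i<position>` where the
#' position is the nucleotide in a reference copy of the host gene
#' immediately 5' of the insertion site), the parsimony direction
#' (`loss`/`gain`) and the trans-splicing flag. User-supplied definition
#' files with the same columns extend the list.
#'
#' @param path optional path to a definitions CSV; defaults to the packaged
#'   set.
#' @return a tibble with one row per character.
#' @export
character_definitions <- function(path = NULL) {
  path <- path %||% path_package_file("character_definitions.csv")
  defs <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(position = "i"))
  req <- c("symbol", "kind", "class", "host", "position", "direction", "trans")
  if (!all(req %in% names(defs))) {
    abort(sprintf("definitions file must have columns: %s", paste(req, collapse = ", ")))
  }
  defs$symbol <- normalize_symbol(defs$symbol)
  defs
}

#' Extrinsic structural characters
#'
#' Characters that cannot be derived from a plastome annotation but belong in
#' the event-mapping ledger: the mitochondrial atp1i361 intron gain shared by
#' Marattiales and Polypodiopsida, and the inverted-repeat expansion that
#' captured the 3'-rps12/rps7/ndhB/trnL-CAA block from the LSC. Their states
#' are fixture-only.
#'
#' @return list with `defs` (definition rows) and `states` (a taxa-by-symbol
#'   state tibble ready to join onto a character matrix).
#' @export
extrinsic_characters <- function() {
  raw <- readr::read_csv(path_package_file("extrinsic_characters.csv"),
                         show_col_types = FALSE)
  state_cols <- grep("^state_", names(raw), value = TRUE)
  taxa <- sub("^state_", "", state_cols)
  states <- tibble(taxon = taxa)
  for (i in seq_len(nrow(raw))) {
    states[[raw$symbol[i]]] <- as.character(unlist(raw[i, state_cols],
                                                   use.names = FALSE))
  }
  defs <- select(raw, "symbol", "kind", "class", "host", "position",
                 "direction", "trans")
  list(defs = defs, states = states)
}

#' The packaged ten-taxon content matrix
#'
#' Curated gene and intron presence/absence states for ten lycophyte and fern
#' plastomes. States: `1` present, `0` absent, `P` pseudogene, `T`
#' trans-spliced (present), `?` unknown.
#'
#' @param extrinsic if `TRUE`, append the [extrinsic_characters()] columns.
#' @return a character-matrix tibble (one row per taxon, `taxon` column first,
#'   one column per character).
#' @export
content_matrix <- function(extrinsic = FALSE) {
  m <- readr::read_csv(path_package_file("content_matrix.csv"),
                       show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  if (extrinsic) {
    m <- left_join(m, extrinsic_characters()$states, by = "taxon")
  }
  validate_matrix(m)
  m
}

#' Curated per-taxon summary reference
#'
#' Published architecture and content summaries for the ten packaged taxa
#' (accession, region lengths, GC, and deduplicated gene/tRNA/rRNA/protein/
#' intron counts), used to check matrix-derived counts.
#'
#' @return a tibble with one row per taxon.
#' @export
summary_reference <- function() {
  readr::read_csv(path_package_file("summary_reference.csv"), show_col_types = FALSE)
}

#' Ancestral single-copy membership of the gene roster
#'
#' Reference table assigning each gene character to the region (LSC, SSC or
#' IR) it occupied in the ancestral land-plant plastome; used to split
#' boundary-classification gained/lost sets by origin.
#'
#' @return tibble with columns `symbol`, `region`.
#' @export
region_membership <- function() {
  readr::read_csv(path_package_file("region_membership.csv"), show_col_types = FALSE)
}

#' The nine-gene ancestral inverted-repeat complement
#' @return character vector of gene symbols.
#' @export
ancestral_ir_genes <- function() {
  c("rrn4.5", "rrn5", "rrn16", "rrn23", "trnA-UGC", "trnI-GAU", "trnN-GUU",
    "trnR-ACG", "trnV-GAC")
}

matrix_states <- c("1", "0", "P", "T", "?")

validate_matrix <- function(m) {
  if (!"taxon" %in% names(m)) abort("character matrix needs a 'taxon' column")
  if (anyDuplicated(m$taxon)) abort("duplicate taxon name in character matrix")
  vals <- unlist(m[setdiff(names(m), "taxon")], use.names = FALSE)
  bad <- setdiff(unique(vals), matrix_states)
  if (length(bad)) abort(sprintf("unknown state symbol(s): %s", paste(bad, collapse = ", ")))
  invisible(m)
}

#' Score one genome against the character list
#'
#' A gene character is `1` when a non-pseudo feature with the normalized
#' symbol exists, `P` when only pseudo-flagged copies exist, `0` otherwise.
#' An intron character is scored on the host gene's derived intron features:
#' each intron's positional name is computed against the reference copy of
#' the host coding sequence ([name_intron()]) and matched to the character's
#' reference position; `T` marks an intron whose host is trans-spliced at
#' that site. Without a reference sequence for the host, intron identity
#' falls back to matching the definition order (ordinal within the host).
#'
#' @param record a [genome_record()].
#' @param defs a [character_definitions()] tibble.
#' @param references named character vector of reference coding sequences for
#'   intron-bearing hosts (names are host symbols); optional.
#' @return a one-row character-matrix tibble.
#' @export
extract_states <- function(record, defs = character_definitions(),
                           references = NULL) {
  feats <- record$features
  states <- character(nrow(defs))
  intron_names <- genome_intron_names(record, defs, references)
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    if (d$kind == "gene") {
      hit <- feats$name == d$symbol & feats$kind != "intron"
      states[i] <- if (any(hit & !feats$pseudo)) "1"
        else if (any(hit)) "P" else "0"
    } else if (d$kind == "intron") {
      host_present <- any(feats$name == d$host & feats$kind != "intron")
      if (!host_present) { states[i] <- "0"; next }
      hit <- intron_names$label == d$symbol
      states[i] <- if (!any(hit)) "0"
        else if (isTRUE(d$trans) || any(intron_names$trans[hit])) "T" else "1"
    } else {
      states[i] <- "0"   # extrinsic/structure characters are fixture-only
    }
  }
  out <- tibble(taxon = record$taxon)
  for (i in seq_len(nrow(defs))) out[[defs$symbol[i]]] <- states[i]
  out
}

# positional labels of every derived intron in a record
genome_intron_names <- function(record, defs, references) {
  introns <- filter(record$features, .data$kind == "intron",
                    grepl("host=", .data$note))
  if (nrow(introns) == 0) {
    return(tibble(label = character(), trans = logical()))
  }
  info <- stringr::str_match(introns$note,
                             "host=([^;]+);ordinal=(\\d+);offset=(\\d+)")
  hosts <- info[, 2]
  ordinals <- as.integer(info[, 3])
  offsets <- as.integer(info[, 4])
  labels <- rep(NA_character_, nrow(introns))
  for (j in seq_len(nrow(introns))) {
    ref <- references[[hosts[j]]] %||% NULL
    if (!is.null(ref)) {
      host_row <- filter(record$features, .data$name == hosts[j],
                         .data$kind != "intron")[1, ]
      exons <- feature_sequence(record, host_row)
      nm <- try(name_intron(exons, offsets[j], ref, host = hosts[j]),
                silent = TRUE)
      if (!inherits(nm, "try-error")) labels[j] <- nm$label
    } else {
      # ordinal fallback: k-th intron of the host in the definition list
      cand <- defs$symbol[defs$kind == "intron" & defs$host == hosts[j]]
      cand <- cand[order(defs$position[match(cand, defs$symbol)])]
      if (ordinals[j] <= length(cand)) labels[j] <- cand[ordinals[j]]
    }
  }
  host_rows <- match(hosts, record$features$name)
  tibble(label = labels,
         trans = record$features$trans_spliced[host_rows] %in% TRUE)
}

#' Build a character matrix from annotated genomes
#'
#' One row per taxon via [extract_states()]. Use [content_matrix()] for the
#' packaged curated matrix.
#'
#' @param records list of [genome_record()] objects.
#' @inheritParams extract_states
#' @return a character-matrix tibble.
#' @export
build_matrix <- function(records, defs = character_definitions(),
                         references = NULL) {
  if (length(records) == 0) abort("need at least one record")
  taxa <- map_chr(records, "taxon")
  if (anyDuplicated(taxa)) abort("duplicate taxon name among records")
  m <- bind_rows(map(records, extract_states, defs = defs,
                     references = references))
  validate_matrix(m)
  m
}

#' Recode character states to binary under a counting policy
#'
#' The default (`"strict"`) policy counts present and trans-spliced states as
#' 1 and absent/pseudogene as 0; unknown becomes `NA`. The
#' `"pseudo_as_present"` policy treats pseudogenes as witnesses of past
#' presence (1), which matters for Dollo arguments.
#'
#' @param m a character-matrix tibble.
#' @param policy `"strict"` or `"pseudo_as_present"`.
#' @return a tibble of the same shape with integer 0/1/`NA` states.
#' @export
recode_binary <- function(m, policy = c("strict", "pseudo_as_present")) {
  policy <- match.arg(policy)
  map_state <- function(x) {
    out <- dplyr::case_when(
      x %in% c("1", "T") ~ 1L,
      x == "P" & policy == "pseudo_as_present" ~ 1L,
      x %in% c("0", "P") ~ 0L,
      TRUE ~ NA_integer_)
    out
  }
  mutate(m, across(-"taxon", map_state))
}

#' Deduplicated feature counts for one taxon
#'
#' Counts characters scored present (`1` or `T`) under the recode policy,
#' split by functional class. Duplicated IR copies are already collapsed
#' because characters are symbols, not feature instances.
#'
#' @param m a character-matrix tibble.
#' @param taxon taxon name present in `m`.
#' @param defs matching [character_definitions()].
#' @inheritParams recode_binary
#' @return tibble with columns `taxon`, `genes`, `trnas`, `rrnas`,
#'   `proteins`, `introns`.
#' @export
count_features <- function(m, taxon, defs = character_definitions(),
                           policy = "strict") {
  if (!taxon %in% m$taxon) abort(sprintf("unknown taxon '%s'", taxon))
  bin <- recode_binary(m, policy)
  row <- bin[bin$taxon == taxon, , drop = FALSE]
  n_class <- function(cl) {
    syms <- intersect(defs$symbol[defs$class == cl], names(row))
    sum(unlist(row[, syms]) == 1L, na.rm = TRUE)
  }
  tibble(taxon = taxon,
         trnas = n_class("tRNA"), rrnas = n_class("rRNA"),
         proteins = n_class("protein"), introns = n_class("intron")) |>
    mutate(genes = .data$trnas + .data$rrnas + .data$proteins, .after = "taxon")
}

#' @rdname count_features
#' @export
count_all_taxa <- function(m, defs = character_definitions(), policy = "strict") {
  bind_rows(map(m$taxon, count_features, m = m, defs = defs, policy = policy))
}
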