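#' Specification of the ancestral synthetic plastome
#'
#' Defines the quadripartite architecture the simulator emits: gene rosters
#' (symbol, kind, coding length, strand) for the LSC, SSC and IR, intron
#' placements (host, coding position, length), and the intergenic spacer
#' length range. The default is a compact plastome-like genome (~47 kb) with
#' the nine-gene ancestral IR complement, single-copy rosters drawn from the
#' canonical plastid roster at realistic length scales, and ten introns
#' (including the two clpP introns and rps16i40) so that the loss characters
#' the event mapping reasons about exist in the simulation.
#'
#' @param spacer_range integer bounds of the uniform intergenic spacer length.
#' @param size_target optional total size floor in bp; extra length is added
#'   to one LSC spacer. Infeasible targets (below the realized size) error.
#' @return an `ancestor_spec` list.
#' @export
ancestor_spec <- function(spacer_range = c(120L, 280L), size_target = NULL) {
  g <- function(symbol, kind, length, strand = "+") {
    tibble(symbol = symbol, kind = kind, length = as.integer(length),
           strand = strand)
  }
  lsc <- bind_rows(
    g("trnH-GUG", "tRNA", 74), g("psbA", "protein", 1062, "-"),
    g("trnK-UUU", "tRNA", 74, "-"), g("matK", "protein", 1500, "-"),
    g("rps16", "protein", 261, "-"), g("psbK", "protein", 186),
    g("atpA", "protein", 1524, "-"), g("atpF", "protein", 555, "-"),
    g("rpoB", "protein", 1200, "-"), g("rpoC1", "protein", 1600, "-"),
    g("psbC", "protein", 1386), g("psbD", "protein", 1062),
    g("ycf3", "protein", 507, "-"), g("rbcL", "protein", 1428),
    g("clpP", "protein", 591, "-"), g("petB", "protein", 648),
    g("petD", "protein", 483), g("rpl2", "protein", 825, "-"),
    g("trnL-CAA", "tRNA", 74), g("ndhB", "protein", 1530, "-"))
  ir <- bind_rows(
    g("rrn16", "rRNA", 1491), g("trnI-GAU", "tRNA", 74),
    g("trnA-UGC", "tRNA", 74), g("rrn23", "rRNA", 2700),
    g("rrn4.5", "rRNA", 97), g("rrn5", "rRNA", 121),
    g("trnR-ACG", "tRNA", 74), g("trnN-GUU", "tRNA", 74),
    g("trnV-GAC", "tRNA", 74))
  ssc <- bind_rows(
    g("ndhF", "protein", 2200, "-"), g("chlL", "protein", 873),
    g("chlN", "protein", 1389), g("rpl21", "protein", 360),
    g("rpl32", "protein", 171), g("ndhA", "protein", 1080),
    g("ccsA", "protein", 960))
  introns <- tibble(
    host = c("trnK-UUU", "rps16", "atpF", "rpoC1", "ycf3", "ycf3",
             "clpP", "clpP", "petB", "petD", "rpl2", "ndhB", "ndhA"),
    position = c(37L, 40L, 145L, 432L, 124L, 354L, 71L, 363L, 6L, 8L,
                 397L, 726L, 556L),
    length = c(420L, 500L, 480L, 520L, 450L, 440L, 460L, 430L, 470L,
               410L, 490L, 455L, 445L))
  structure(list(lsc = lsc, ir = ir, ssc = ssc, introns = introns,
                 spacer_range = as.integer(spacer_range),
                 size_target = size_target),
            class = "ancestor_spec")
}

# --- description layer: an editable, replayable genome blueprint ----------

# element: list(type = "spacer", seq) or
#          list(type = "gene", symbol, kind, strand, coding, introns =
#               tibble(position, seq))
build_description <- function(spec, seed) {
  if (any(duplicated(c(spec$lsc$symbol, spec$ir$symbol, spec$ssc$symbol)))) {
    abort("gene rosters must be disjoint")
  }
  idx <- 0L
  feat_seed <- function() {
    idx <<- idx + 1L
    as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483647)
  }
  mk_gene <- function(row) {
    set.seed(feat_seed())
    coding <- random_dna(row$length)
    placements <- filter(spec$introns, .data$host == row$symbol)
    intr <- tibble(position = integer(), seq = character())
    if (nrow(placements)) {
      placements <- arrange(placements, .data$position)
      if (any(placements$position >= row$length)) {
        abort(sprintf("intron position beyond host %s", row$symbol))
      }
      intr <- tibble(position = placements$position,
                     seq = map_chr(placements$length, function(L) {
                       set.seed(feat_seed()); random_dna(L)
                     }))
    }
    list(type = "gene", symbol = row$symbol, kind = row$kind,
         strand = row$strand, coding = coding, introns = intr)
  }
  mk_spacer <- function() {
    set.seed(feat_seed())
    n <- sample(spec$spacer_range[1]:spec$spacer_range[2], 1)
    list(type = "spacer", seq = random_dna(n))
  }
  region <- function(roster) {
    elems <- list()
    for (i in seq_len(nrow(roster))) {
      elems <- c(elems, list(mk_spacer()), list(mk_gene(roster[i, ])))
    }
    c(elems, list(mk_spacer()))
  }
  desc <- list(lsc = region(spec$lsc), ira = region(spec$ir),
               ssc = region(spec$ssc))
  if (!is.null(spec$size_target)) {
    realized <- rendered_length(desc)
    if (spec$size_target < realized) {
      abort(sprintf("infeasible size target: %d < realized %d",
                    spec$size_target, realized))
    }
    pad <- spec$size_target - realized
    if (pad > 0) {
      set.seed(feat_seed())
      desc$lsc[[1]]$seq <- paste0(desc$lsc[[1]]$seq, random_dna(pad))
    }
  }
  desc
}

elem_text <- function(el) {
  if (el$type == "spacer") return(el$seq)
  pre <- el$coding
  if (nrow(el$introns)) {
    pieces <- character(); last <- 0L
    for (i in seq_len(nrow(el$introns))) {
      p <- el$introns$position[i]
      pieces <- c(pieces, substr(el$coding, last + 1, p), el$introns$seq[i])
      last <- p
    }
    pre <- paste0(paste(pieces, collapse = ""),
                  substr(el$coding, last + 1, nchar(el$coding)))
  }
  if (el$strand == "-") revcomp(pre) else pre
}

rendered_length <- function(desc) {
  one <- function(elems) sum(map_int(elems, ~ nchar(elem_text(.x))))
  one(desc$lsc) + 2L * one(desc$ira) + one(desc$ssc)
}

# render a region's elements starting at `at`; returns list(text, features)
render_region <- function(elems, at) {
  feats <- list(); texts <- character(length(elems)); pos <- at
  for (i in seq_along(elems)) {
    el <- elems[[i]]
    txt <- elem_text(el)
    texts[i] <- txt
    if (el$type == "gene") {
      feats[[length(feats) + 1]] <- gene_features(el, pos)
    }
    pos <- pos + nchar(txt)
  }
  list(text = paste(texts, collapse = ""), features = bind_rows(feats),
       end = pos)
}

# exon/intron feature rows for one gene element placed at genomic `at`
gene_features <- function(el, at) {
  n_int <- nrow(el$introns)
  clen <- nchar(el$coding)
  # piece lengths in coding order: exon0, intron1, exon1, ...
  cuts <- el$introns$position
  exon_lens <- diff(c(0L, cuts, clen))
  piece_len <- integer(0); piece_is_exon <- logical(0)
  for (i in seq_len(n_int)) {
    piece_len <- c(piece_len, exon_lens[i], nchar(el$introns$seq[i]))
    piece_is_exon <- c(piece_is_exon, TRUE, FALSE)
  }
  piece_len <- c(piece_len, exon_lens[n_int + 1])
  piece_is_exon <- c(piece_is_exon, TRUE)
  if (el$strand == "-") {         # genomic order is reversed coding order
    piece_len <- rev(piece_len); piece_is_exon <- rev(piece_is_exon)
  }
  starts <- at + cumsum(c(0L, head(piece_len, -1)))
  ends <- starts + piece_len
  exon_iv <- cbind(start = starts[piece_is_exon], end = ends[piece_is_exon])
  rows <- new_feature(el$symbol, el$kind, el$strand, exon_iv,
                      pseudo = isTRUE(el$pseudo))
  if (n_int > 0) {
    int_starts <- starts[!piece_is_exon]; int_ends <- ends[!piece_is_exon]
    ord <- if (el$strand == "-") rev(seq_len(n_int)) else seq_len(n_int)
    for (k in seq_len(n_int)) {
      ordinal <- ord[k]
      rows <- bind_rows(rows, new_feature(
        el$symbol, "intron", el$strand,
        cbind(start = int_starts[k], end = int_ends[k]),
        note = sprintf("host=%s;ordinal=%d;offset=%d", el$symbol, ordinal,
                       el$introns$position[ordinal])))
    }
  }
  rows
}

render_genome <- function(desc, identifier, taxon) {
  lsc <- render_region(desc$lsc, 0L)
  ira <- render_region(desc$ira, nchar(lsc$text))
  ssc <- render_region(desc$ssc, nchar(lsc$text) + nchar(ira$text))
  irb_at <- nchar(lsc$text) + nchar(ira$text) + nchar(ssc$text)
  ira_len <- nchar(ira$text)
  irb_text <- revcomp(ira$text)
  # mirror IRa features into IRb
  irb_feats <- ira$features
  if (nrow(irb_feats)) {
    base <- nchar(lsc$text)
    irb_feats$intervals <- map(irb_feats$intervals, function(iv) {
      rel <- iv - base
      mirrored <- cbind(start = ira_len - rel[, "end"],
                        end = ira_len - rel[, "start"])
      mirrored[rev(seq_len(nrow(mirrored))), , drop = FALSE] + irb_at
    })
    irb_feats$strand <- ifelse(irb_feats$strand == "+", "-", "+")
  }
  seqs <- paste0(lsc$text, ira$text, ssc$text, irb_text)
  seqs <- break_junction_extensions(seqs, nchar(lsc$text), ira_len,
                                    nchar(ssc$text))
  feats <- bind_rows(lsc$features, ira$features, ssc$features, irb_feats)
  rec <- genome_record(identifier, taxon, seqs, feats, circular = TRUE)
  rec$references <- description_references(desc)
  rec$ir_interval <- list(ira = c(nchar(lsc$text), nchar(lsc$text) + ira_len),
                          irb = c(irb_at, irb_at + ira_len))
  rec
}

# a random base just outside a junction can accidentally extend the
# repeat pairing; nudge the flanking single-copy base so the planted IR is
# the exact maximal repeat (the substituted bases sit in spacers)
break_junction_extensions <- function(seqs, lsc_len, ira_len, ssc_len) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  pick_other <- function(bad) setdiff(c("A", "C", "G", "T"), bad)[1]
  a1 <- lsc_len                      # 1-based index of last LSC base
  a2 <- lsc_len + ira_len            # last IRa base; first SSC base is a2+1
  b1 <- a2 + ssc_len                 # last SSC base; IRb starts at b1+1
  # left of IRa pairs with the base after IRb (the first LSC base)
  if (substr(seqs, a1, a1) == comp(substr(seqs, 1, 1))) {
    substr(seqs, a1, a1) <- pick_other(comp(substr(seqs, 1, 1)))
  }
  # right of IRa pairs with the base before IRb (the last SSC base)
  if (substr(seqs, a2 + 1, a2 + 1) == comp(substr(seqs, b1, b1))) {
    substr(seqs, a2 + 1, a2 + 1) <- pick_other(comp(substr(seqs, b1, b1)))
  }
  seqs
}

description_references <- function(desc) {
  refs <- character()
  for (reg in desc) {
    for (el in reg) if (el$type == "gene") refs[el$symbol] <- el$coding
  }
  refs
}

#' Generate the ancestral synthetic plastome
#'
#' Builds a circular record with LSC + IRa + SSC + IRb layout; IRb is the
#' exact reverse complement of IRa and every feature is annotated on both
#' copies. Deterministic for a fixed seed (per-feature seeds are derived
#' from the master seed). The returned record carries `$references` (coding
#' sequences for intron naming) and `$ir_interval` (the planted IR, for
#' recovery tests).
#'
#' @param spec an [ancestor_spec()].
#' @param seed integer master seed.
#' @return a [genome_record()].
#' @export
make_ancestor <- function(spec = ancestor_spec(), seed = 1) {
  desc <- build_description(spec, seed)
  rec <- render_genome(desc, "SYNTH-ANC", "ancestor")
  rec$description <- desc
  rec
}

# --- event simulation -----------------------------------------------------

#' Simulate structural events along a tree
#'
#' Draws per-branch event counts from a Poisson distribution with the given
#' per-event-type means and uniform targets among currently eligible
#' features, maintaining Dollo coherence (a character lost on a path is
#' never regained). In `no_homoplasy` mode a character already hit anywhere
#' in the tree is no longer eligible, so every planted event is unique.
#' Events with no eligible target are logged as skipped.
#'
#' @param tree rooted binary `phylo`; branches are identified by the child
#'   node's clade.
#' @param spec an [ancestor_spec()].
#' @param rates named expected event counts per branch; names from
#'   `gene_loss`, `intron_loss`, `pseudogenize`, `ir_expand`, `inversion`.
#' @param seed integer seed.
#' @param no_homoplasy reject repeated hits on the same character.
#' @return an `event_log` tibble: `branch` (edge label), `node`, `order`,
#'   `type`, `target`, `detail`, `skipped`; attributes `seed` and `rates`.
#' @export
simulate_history <- function(tree, spec = ancestor_spec(),
                             rates = c(gene_loss = 0.2, intron_loss = 0.2,
                                       pseudogenize = 0.1, ir_expand = 0.1,
                                       inversion = 0.1),
                             seed = 1, no_homoplasy = FALSE) {
  if (any(rates < 0)) abort("rates must be >= 0")
  set.seed(as.integer(seed))
  intron_labels <- paste0(gsub("-", "", spec$introns$host), "i",
                          spec$introns$position)
  root_state <- list(
    lsc = spec$lsc$symbol, ssc = spec$ssc$symbol,
    introns = setNames(spec$introns$host, intron_labels),
    pseudo = character())
  used <- character()     # characters hit anywhere (no_homoplasy mode)
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  pre <- ed[rev(seq_len(nrow(ed))), , drop = FALSE]
  states <- list(); states[[tree_root(tree)]] <- root_state
  rows <- list()
  types <- intersect(names(rates), c("gene_loss", "intron_loss",
                                     "pseudogenize", "ir_expand", "inversion"))
  for (r in seq_len(nrow(pre))) {
    parent <- pre[r, 1]; child <- pre[r, 2]
    st <- states[[parent]]
    n_events <- setNames(rpois(length(types), rates[types]), types)
    order_i <- 0L
    for (ty in types) {
      for (e in seq_len(n_events[[ty]])) {
        order_i <- order_i + 1L
        drawn <- draw_event(ty, st, used, no_homoplasy)
        rows[[length(rows) + 1]] <- tibble(
          branch = edge_label(tree, child), node = as.integer(child),
          order = order_i, type = ty,
          target = drawn$target %||% NA_character_,
          detail = drawn$detail %||% NA_character_,
          skipped = drawn$skipped)
        if (!drawn$skipped) {
          st <- drawn$state
          if (no_homoplasy) used <- c(used, drawn$character)
        }
      }
    }
    states[[child]] <- st
  }
  log <- if (length(rows)) bind_rows(rows) else
    tibble(branch = character(), node = integer(), order = integer(),
           type = character(), target = character(), detail = character(),
           skipped = logical())
  attr(log, "seed") <- seed
  attr(log, "rates") <- rates
  class(log) <- c("event_log", class(log))
  log
}

draw_event <- function(type, st, used, no_homoplasy) {
  block <- function(x) if (no_homoplasy) setdiff(x, used) else x
  skipped <- list(state = st, skipped = TRUE, character = NA_character_)
  if (type == "gene_loss" || type == "pseudogenize") {
    elig <- block(setdiff(c(st$lsc, st$ssc), st$pseudo))
    if (type == "gene_loss" && no_homoplasy) {
      # losing a host would silently re-hit its intron characters
      used_hosts <- unique(st$introns[names(st$introns) %in% used])
      elig <- setdiff(elig, used_hosts)
    }
    if (length(elig) == 0) return(skipped)
    target <- sample(elig, 1)
    hit <- target
    if (type == "gene_loss") {
      hit <- c(target, names(st$introns)[st$introns == target])
      st$lsc <- setdiff(st$lsc, target); st$ssc <- setdiff(st$ssc, target)
      st$introns <- st$introns[st$introns != target]
    } else {
      st$pseudo <- c(st$pseudo, target)
    }
    return(list(state = st, skipped = FALSE, target = target,
                detail = NA_character_, character = hit))
  }
  if (type == "intron_loss") {
    elig <- block(names(st$introns))
    if (length(elig) == 0) return(skipped)
    target <- sample(elig, 1)
    st$introns <- st$introns[names(st$introns) != target]
    return(list(state = st, skipped = FALSE, target = target,
                detail = NA_character_, character = target))
  }
  if (type == "ir_expand") {
    sides <- block(c("LSC", "SSC"))
    sides <- sides[(sides == "LSC" & length(st$lsc) > 3) |
                     (sides == "SSC" & length(st$ssc) > 3)]
    if (length(sides) == 0) return(skipped)
    side <- sample(sides, 1)
    n <- sample(1:2, 1)
    moved <- if (side == "SSC") head(st$ssc, n) else tail(st$lsc, n)
    if (side == "SSC") st$ssc <- setdiff(st$ssc, moved)
    else st$lsc <- setdiff(st$lsc, moved)
    return(list(state = st, skipped = FALSE, target = side,
                detail = paste(moved, collapse = ","),
                character = paste0("ir_expand_", side)))
  }
  if (type == "inversion") {
    if (length(st$lsc) < 4) return(skipped)
    len <- sample(2:min(4, length(st$lsc) - 1), 1)
    from <- sample(seq_len(length(st$lsc) - len + 1), 1)
    blockv <- st$lsc[from:(from + len - 1)]
    key <- paste0("inv_", paste(blockv, collapse = ","))
    if (no_homoplasy && key %in% used) return(skipped)
    st$lsc[from:(from + len - 1)] <- rev(blockv)
    return(list(state = st, skipped = FALSE,
                target = paste(blockv[1], blockv[len], sep = ".."),
                detail = paste(blockv, collapse = ","), character = key))
  }
  skipped
}

#' Replay an event log and emit tip genomes
#'
#' Each tip genome results from replaying its root-to-tip event prefix on
#' the ancestor's blueprint: gene losses splice the gene out, intron losses
#' splice the intron, pseudogenization plants an in-frame stop (coordinates
#' stable) and sets the pseudo flag, `ir_expand` slides the junction past
#' the adjacent single-copy genes (duplicating them into both IR copies),
#' and inversions reverse-complement the block and flip contained strands.
#' Each record carries its implied truth states in `attr(, "truth")`.
#'
#' @param tree rooted binary `phylo`.
#' @param ancestor a [make_ancestor()] record (with `$description`).
#' @param log an event log from [simulate_history()].
#' @return named list of [genome_record()]s, one per tip.
#' @export
emit_genomes <- function(tree, ancestor, log) {
  if (is.null(ancestor$description)) abort("ancestor lacks its blueprint")
  paths <- tip_event_paths(tree, log)
  out <- list()
  for (tip in tree$tip.label) {
    desc <- ancestor$description
    evs <- paths[[tip]]
    if (!is.null(evs) && nrow(evs)) {
      for (i in seq_len(nrow(evs))) desc <- apply_event(desc, evs[i, ])
    }
    rec <- render_genome(desc, paste0("SYNTH-", tip), tip)
    attr(rec, "truth") <- description_truth(desc, ancestor$description)
    out[[tip]] <- rec
  }
  out
}

tip_event_paths <- function(tree, log) {
  ed <- tree$edge
  parent_of <- setNames(ed[, 1], ed[, 2])
  root <- tree_root(tree)
  out <- list()
  for (t in seq_len(ape::Ntip(tree))) {
    path_nodes <- integer(); v <- t
    while (v != root) { path_nodes <- c(v, path_nodes); v <- parent_of[[as.character(v)]] }
    evs <- filter(log, .data$node %in% path_nodes, !.data$skipped)
    evs <- evs[order(match(evs$node, path_nodes), evs$order), , drop = FALSE]
    out[[tree$tip.label[t]]] <- evs
  }
  out
}

apply_event <- function(desc, ev) {
  if (ev$type == "gene_loss") {
    for (reg in c("lsc", "ssc")) {
      desc[[reg]] <- purrr::discard(desc[[reg]], ~ .x$type == "gene" &&
                                      .x$symbol == ev$target)
    }
  } else if (ev$type == "pseudogenize") {
    desc <- edit_gene(desc, ev$target, function(el) {
      el$pseudo <- TRUE
      cod <- floor(nchar(el$coding) / 6) * 3 + 1
      substr(el$coding, cod, cod + 2) <- "TAA"
      el
    })
  } else if (ev$type == "intron_loss") {
    desc <- edit_gene_all(desc, function(el) {
      if (el$type != "gene" || nrow(el$introns) == 0) return(el)
      labels <- paste0(gsub("-", "", el$symbol), "i", el$introns$position)
      el$introns <- el$introns[labels != ev$target, , drop = FALSE]
      el
    })
  } else if (ev$type == "ir_expand") {
    moved <- strsplit(ev$detail, ",")[[1]]
    if (ev$target == "SSC") {
      take <- take_genes(desc$ssc, moved, from_front = TRUE)
      desc$ssc <- take$rest
      desc$ira <- c(desc$ira, take$taken)
    } else {
      take <- take_genes(desc$lsc, moved, from_front = FALSE)
      desc$lsc <- take$rest
      desc$ira <- c(take$taken, desc$ira)
    }
  } else if (ev$type == "inversion") {
    moved <- strsplit(ev$detail, ",")[[1]]
    idx <- which(map_lgl(desc$lsc, ~ .x$type == "gene" && .x$symbol %in% moved))
    if (length(idx)) {
      span <- min(idx):max(idx)
      blockv <- rev(desc$lsc[span])
      blockv <- map(blockv, function(el) {
        if (el$type == "gene") el$strand <- if (el$strand == "+") "-" else "+"
        else el$seq <- revcomp(el$seq)
        el
      })
      desc$lsc[span] <- blockv
    }
  }
  desc
}

edit_gene <- function(desc, symbol, f) {
  for (reg in names(desc)) {
    desc[[reg]] <- map(desc[[reg]], function(el) {
      if (el$type == "gene" && el$symbol == symbol) f(el) else el
    })
  }
  desc
}

edit_gene_all <- function(desc, f) {
  for (reg in names(desc)) desc[[reg]] <- map(desc[[reg]], f)
  desc
}

# remove the named genes (plus their leading/trailing spacer) from one end
take_genes <- function(elems, symbols, from_front) {
  is_target <- map_lgl(elems, ~ .x$type == "gene" && .x$symbol %in% symbols)
  gene_idx <- which(is_target)
  taken_idx <- integer()
  for (gi in gene_idx) {
    taken_idx <- c(taken_idx, if (from_front) c(gi - 1L, gi) else c(gi, gi + 1L))
  }
  taken_idx <- sort(unique(taken_idx[taken_idx >= 1 & taken_idx <= length(elems)]))
  list(taken = elems[taken_idx], rest = elems[-taken_idx])
}

# truth character states implied by a blueprint (relative to the ancestor's)
description_truth <- function(desc, ancestor_desc) {
  anc_genes <- character(); anc_introns <- character()
  for (reg in ancestor_desc) for (el in reg) {
    if (el$type == "gene") {
      anc_genes <- c(anc_genes, el$symbol)
      if (nrow(el$introns)) {
        anc_introns <- c(anc_introns,
                         paste0(gsub("-", "", el$symbol), "i", el$introns$position))
      }
    }
  }
  genes <- character(); pseudo <- character(); introns <- character()
  for (reg in desc) for (el in reg) {
    if (el$type == "gene") {
      if (isTRUE(el$pseudo)) pseudo <- c(pseudo, el$symbol) else
        genes <- c(genes, el$symbol)
      if (nrow(el$introns)) {
        introns <- c(introns,
                     paste0(gsub("-", "", el$symbol), "i", el$introns$position))
      }
    }
  }
  states <- setNames(rep("0", length(anc_genes) + length(anc_introns)),
                     c(unique(anc_genes), unique(anc_introns)))
  states[intersect(names(states), unique(genes))] <- "1"
  states[intersect(names(states), unique(pseudo))] <- "P"
  states[intersect(names(states), unique(introns))] <- "1"
  states
}

#' Character matrix implied by a set of emitted genomes' truth attributes
#'
#' @param genomes named list from [emit_genomes()].
#' @return a character-matrix tibble of the planted truth.
#' @export
truth_matrix <- function(genomes) {
  rows <- map(names(genomes), function(tx) {
    st <- attr(genomes[[tx]], "truth")
    out <- tibble(taxon = tx)
    for (s in names(st)) out[[s]] <- st[[s]]
    out
  })
  bind_rows(rows)
}

#' Character definitions matching a synthetic ancestor
#'
#' @param spec an [ancestor_spec()].
#' @return a definitions tibble usable with [extract_states()].
#' @export
synthetic_definitions <- function(spec = ancestor_spec()) {
  genes <- bind_rows(spec$lsc, spec$ir, spec$ssc)
  gene_defs <- tibble(symbol = genes$symbol, kind = "gene",
                      class = ifelse(genes$kind == "tRNA", "tRNA",
                              ifelse(genes$kind == "rRNA", "rRNA", "protein")),
                      host = NA_character_, position = NA_integer_,
                      direction = "loss", trans = FALSE)
  intr_defs <- tibble(symbol = paste0(gsub("-", "", spec$introns$host), "i",
                                      spec$introns$position),
                      kind = "intron", class = "intron",
                      host = spec$introns$host, position = spec$introns$position,
                      direction = "loss", trans = FALSE)
  bind_rows(gene_defs, intr_defs)
}

#' Write a record as a minimal GenBank-style flat file
#'
#' Emits LOCUS/ORGANISM headers, gene-level features (CDS/tRNA/rRNA with
#' join/complement locations and pseudo flags; derived introns are omitted
#' and re-derived on read) and the ORIGIN sequence, readable by
#' [read_genbank()].
#'
#' @param record a [genome_record()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_flatfile <- function(record, path) {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     record$identifier, record$length),
             sprintf("DEFINITION  synthetic plastome of %s.", record$taxon),
             "SOURCE      synthetic",
             sprintf("  ORGANISM  %s", record$taxon),
             "FEATURES             Location/Qualifiers")
  f <- filter(record$features, .data$kind != "intron")
  for (i in seq_len(nrow(f))) {
    iv <- f$intervals[[i]]
    n <- record$length
    parts <- apply(iv, 1, function(r) {
      if (r["end"] > r["start"]) sprintf("%d..%d", r["start"] + 1, r["end"])
      else sprintf("join(%d..%d,1..%d)", r["start"] + 1, n, r["end"])
    })
    loc <- if (length(parts) == 1) parts else
      sprintf("join(%s)", paste(parts, collapse = ","))
    loc <- gsub("join\\(join\\((.*)\\)\\)", "join(\\1)", loc)
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    key <- switch(f$kind[i], protein = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "gene")
    lines <- c(lines, sprintf("     %-16s%s", key, loc),
               sprintf("                     /gene=\"%s\"", f$name[i]))
    if (f$pseudo[i]) lines <- c(lines, "                     /pseudo")
    if (f$trans_spliced[i]) {
      lines <- c(lines, "                     /trans_splicing")
    }
  }
  lines <- c(lines, "ORIGIN")
  s <- record$sequence
  for (start in seq(1, nchar(s), by = 60)) {
    chunk <- substr(s, start, min(start + 59, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", start, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}
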