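# --- tree helpers on ape 'phylo' objects --------------------------------

tree_root <- function(tree) ape::Ntip(tree) + 1L

tree_children <- function(tree) {
  nt <- ape::Ntip(tree); nn <- tree$Nnode
  kids <- vector("list", nt + nn)
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]
    kids[[p]] <- c(kids[[p]], tree$edge[r, 2])
  }
  kids
}

node_tipsets <- function(tree) {
  nt <- ape::Ntip(tree); nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- i
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  for (r in seq_len(nrow(ed))) {
    sets[[ed[r, 1]]] <- c(sets[[ed[r, 1]]], sets[[ed[r, 2]]])
  }
  sets
}

#' Human-readable label for the edge above a node
#'
#' Pendant edges are labeled by the tip; internal edges by the sorted tip set
#' of the clade the edge subtends.
#'
#' @param tree a `phylo` object.
#' @param node node id (edge = the branch above this node).
#' @return a string.
#' @export
edge_label <- function(tree, node) {
  if (node == tree_root(tree)) return("root")
  tips <- sort(tree$tip.label[node_tipsets(tree)[[node]]])
  paste(tips, collapse = "+")
}

check_column <- function(tree, states) {
  if (is.null(names(states))) abort("character column must be named by taxon")
  missing <- setdiff(tree$tip.label, names(states))
  extra <- setdiff(names(states), tree$tip.label)
  if (length(missing) || length(extra)) {
    abort(sprintf("column taxa do not match tree tips (missing: %s; extra: %s)",
                  paste(missing, collapse = ","), paste(extra, collapse = ",")))
  }
  states[tree$tip.label]
}

# --- Fitch ----------------------------------------------------------------

#' Fitch small parsimony for a binary character
#'
#' Two-pass Fitch algorithm: minimal number of freely reversible state
#' changes on the rooted tree, plus one deterministic optimal internal
#' labeling. Unknown tip states (`NA`) carry the full state set. Ties in the
#' traceback prefer the parent's state; a tie at the root is resolved by
#' `root_preference`.
#'
#' @param tree rooted binary `phylo` object.
#' @param states named integer vector of tip states (0/1/`NA`).
#' @param root_preference state chosen when the root set is ambiguous.
#' @return list with `count` and `labeling` (states for all nodes, tips
#'   first, in ape node order).
#' @export
fitch_min_changes <- function(tree, states, root_preference = c(0, 1)) {
  root_preference <- root_preference[1]
  states <- check_column(tree, states)
  nt <- ape::Ntip(tree); nn <- tree$Nnode
  sets <- integer(nt + nn)                 # bitmask: 1 = {0}, 2 = {1}, 3 = both
  sets[seq_len(nt)] <- ifelse(is.na(states), 3L, ifelse(states == 1, 2L, 1L))
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  count <- 0L
  seen <- logical(nt + nn)
  for (r in seq_len(nrow(ed))) {             # children are final before parents
    p <- ed[r, 1]; ch <- ed[r, 2]
    if (!seen[p]) {
      sets[p] <- sets[ch]; seen[p] <- TRUE
    } else {
      inter <- bitwAnd(sets[p], sets[ch])
      if (inter != 0L) {
        sets[p] <- inter
      } else {
        sets[p] <- bitwOr(sets[p], sets[ch])
        count <- count + 1L
      }
    }
  }
  labeling <- integer(nt + nn)
  root <- tree_root(tree)
  pick <- function(set, want) {
    wantbit <- if (want == 1) 2L else 1L
    if (bitwAnd(set, wantbit) != 0L) want else (if (set == 2L) 1L else 0L)
  }
  labeling[root] <- pick(sets[root], root_preference)
  pre <- ed[rev(seq_len(nrow(ed))), , drop = FALSE]   # preorder
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    labeling[ch] <- pick(sets[ch], labeling[p])
  }
  list(count = count, labeling = labeling)
}

# --- Dollo ----------------------------------------------------------------

#' Dollo reconstruction of a directional character
#'
#' In `"root_present"` mode the character is ancestrally present and only
#' losses are allowed: the result is the minimal set of edges whose removal
#' of the state explains every absent tip. In `"single_gain"` mode the gain
#' is placed on the edge above the smallest clade containing all present
#' tips and losses are the minimal edge set explaining absences inside that
#' clade. Unknown tips never force an event.
#'
#' @inheritParams fitch_min_changes
#' @param gain_mode `"root_present"` or `"single_gain"`.
#' @return a `dollo_result`: `gain_edge` (label, or `"root-ancestral"` /
#'   `NA`), `gain_node`, `losses` (tibble `node`, `edge`), `loss_count`,
#'   `feasible`, `mode`.
#' @export
dollo_reconstruct <- function(tree, states,
                              gain_mode = c("root_present", "single_gain")) {
  gain_mode <- match.arg(gain_mode)
  states <- check_column(tree, states)
  nt <- ape::Ntip(tree)
  kids <- tree_children(tree)
  sets <- node_tipsets(tree)
  present_below <- map_lgl(sets, ~ any(states[.x] == 1, na.rm = TRUE))
  absent_below <- map_lgl(sets, ~ any(states[.x] == 0, na.rm = TRUE))
  collect_losses <- function(start) {
    losses <- integer()
    walk <- function(v) {
      for (ch in kids[[v]] %||% integer()) {
        if (present_below[ch]) walk(ch)
        else if (absent_below[ch]) losses <<- c(losses, ch)
      }
    }
    walk(start)
    losses
  }
  present_tips <- which(states == 1)
  if (gain_mode == "single_gain" && length(present_tips) == 0) {
    return(new_dollo(NA_character_, NA_integer_, integer(), tree, gain_mode))
  }
  if (gain_mode == "single_gain") {
    gain_node <- if (length(present_tips) == 1) present_tips else
      ape::getMRCA(tree, tree$tip.label[present_tips])
    gain_edge <- if (gain_node == tree_root(tree)) "root-ancestral"
      else edge_label(tree, gain_node)
    losses <- if (gain_node > nt) collect_losses(gain_node) else integer()
  } else {
    gain_node <- tree_root(tree)
    gain_edge <- "root-ancestral"
    losses <- if (present_below[gain_node]) collect_losses(gain_node)
      else if (absent_below[gain_node]) gain_node  # everything lost at once
      else integer()
  }
  new_dollo(gain_edge, gain_node, losses, tree, gain_mode)
}

new_dollo <- function(gain_edge, gain_node, loss_nodes, tree, mode) {
  losses <- tibble(node = as.integer(loss_nodes),
                   edge = map_chr(as.integer(loss_nodes), edge_label, tree = tree))
  structure(list(gain_edge = gain_edge, gain_node = gain_node,
                 losses = losses, loss_count = nrow(losses),
                 feasible = TRUE, mode = mode, tree = tree),
            class = "dollo_result")
}

#' @export
print.dollo_result <- function(x, ...) {
  cat(sprintf("<dollo_result> mode=%s gain=%s losses=%d\n",
              x$mode, x$gain_edge, x$loss_count))
  if (x$loss_count > 0) print(x$losses)
  invisible(x)
}

#' Replay a Dollo reconstruction to tip states
#'
#' Applies the gain and the loss edges along the tree and returns the
#' implied tip states; used to verify that a reconstruction explains the
#' observed column.
#'
#' @param x a `dollo_result`.
#' @return named integer vector of implied tip states.
#' @export
replay_dollo <- function(x) {
  tree <- x$tree
  nt <- ape::Ntip(tree)
  sets <- node_tipsets(tree)
  tips <- setNames(rep(0L, nt), tree$tip.label)
  if (!is.na(x$gain_node)) tips[sets[[x$gain_node]]] <- 1L
  for (v in x$losses$node) tips[sets[[v]]] <- 0L
  tips
}

# --- regrafting -----------------------------------------------------------

#' Enumerate regraft placements of a clade
#'
#' Prunes a monophyletic clade and reattaches it to every candidate edge of
#' the backbone (optionally restricted to the subtree spanned by `scope`
#' tips), excluding reattachments that reproduce the input topology and,
#' optionally, placements that break a protected clade. Trees are handled on
#' their unrooted equivalent for duplicate detection and re-rooted as given.
#'
#' @param tree rooted binary `phylo`.
#' @param clade character vector of tip labels forming a monophyletic group.
#' @param scope optional tip labels (in the backbone) delimiting the subtree
#'   scanned for attachment edges.
#' @param keep_monophyletic optional list of tip-label vectors that must stay
#'   monophyletic in every returned tree.
#' @return tibble with `placement` id, `edge` (backbone attachment edge
#'   label) and a `tree` list-column.
#' @export
regraft_placements <- function(tree, clade, scope = NULL,
                               keep_monophyletic = list()) {
  if (!all(clade %in% tree$tip.label)) abort("clade tips not all in tree")
  if (length(clade) > 1 && !ape::is.monophyletic(tree, clade)) {
    abort("clade is not monophyletic in the input tree")
  }
  sub <- if (length(clade) == 1) NULL else ape::keep.tip(tree, clade)
  backbone <- ape::drop.tip(tree, clade)
  backbone$edge.length <- rep(1, nrow(backbone$edge))
  sets <- node_tipsets(backbone)
  candidates <- backbone$edge[, 2]
  if (!is.null(scope)) {
    scope <- intersect(scope, backbone$tip.label)
    keep <- map_lgl(candidates, function(ch) {
      all(backbone$tip.label[sets[[ch]]] %in% scope)
    })
    candidates <- candidates[keep]
  }
  out <- list()
  for (ch in candidates) {
    cand <- attach_clade(backbone, sub, clade, ch)
    if (topo_identical(cand, tree)) next
    ok <- all(map_lgl(keep_monophyletic, function(g) {
      g <- intersect(g, cand$tip.label)
      length(g) < 2 || ape::is.monophyletic(cand, g)
    }))
    if (!ok) next
    out[[length(out) + 1]] <- tibble(edge = edge_label(backbone, ch),
                                     tree = list(cand))
  }
  res <- if (length(out)) bind_rows(out) else tibble(edge = character(),
                                                     tree = list())
  # drop duplicate topologies (possible at the root trifurcation)
  if (nrow(res) > 1) {
    dup <- rep(FALSE, nrow(res))
    for (i in seq_len(nrow(res) - 1)) {
      if (dup[i]) next
      for (j in (i + 1):nrow(res)) {
        if (!dup[j] && topo_identical(res$tree[[i]], res$tree[[j]])) dup[j] <- TRUE
      }
    }
    res <- res[!dup, , drop = FALSE]
  }
  mutate(res, placement = row_number(), .before = 1)
}

attach_clade <- function(backbone, sub, clade, where) {
  if (is.null(sub)) {
    sub <- structure(list(edge = matrix(c(2L, 1L), 1, 2), tip.label = clade,
                          Nnode = 1L, edge.length = 1), class = "phylo")
  } else {
    sub$edge.length <- rep(1, nrow(sub$edge))
    sub$root.edge <- 1
  }
  out <- ape::bind.tree(backbone, sub, where = where, position = 0.5)
  out$edge.length <- NULL
  out
}

topo_identical <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  ape::dist.topo(ape::unroot(a), ape::unroot(b)) == 0
}

# --- placement scan -------------------------------------------------------

#' Dollo event counts across alternative placements of a clade
#'
#' For the input topology and every alternative regraft placement of
#' `clade`, counts the Dollo events each selected character requires:
#' root-present losses for loss-direction characters, single-gain-mode
#' losses for gain-direction characters. The original placement is included
#' and marked.
#'
#' @inheritParams regraft_placements
#' @param m a character-matrix tibble.
#' @param characters character symbols to score.
#' @param defs matching [character_definitions()] (supplies direction).
#' @param policy recode policy (see [recode_binary()]).
#' @return a `placement_scan` tibble: `placement`, `edge`, `original`,
#'   one count column per character, `total`.
#' @export
placement_scan <- function(tree, clade, m, characters,
                           defs = character_definitions(),
                           policy = "strict", scope = NULL,
                           keep_monophyletic = list()) {
  if (length(characters) == 0) abort("empty character subset")
  bin <- recode_binary(m, policy)
  missing <- setdiff(characters, names(bin))
  if (length(missing)) abort(sprintf("characters not in matrix: %s",
                                     paste(missing, collapse = ", ")))
  placements <- regraft_placements(tree, clade, scope, keep_monophyletic)
  all_trees <- c(list(tree), placements$tree)
  edges <- c("original", placements$edge)
  rows <- list()
  for (i in seq_along(all_trees)) {
    tr <- all_trees[[i]]
    counts <- map_int(characters, function(ch) {
      col <- setNames(bin[[ch]], bin$taxon)[tr$tip.label]
      dir <- defs$direction[match(ch, defs$symbol)] %||% "loss"
      mode <- if (identical(dir, "gain")) "single_gain" else "root_present"
      dollo_reconstruct(tr, col, gain_mode = mode)$loss_count
    })
    row <- tibble(placement = i - 1L, edge = edges[i], original = i == 1L)
    for (j in seq_along(characters)) row[[characters[j]]] <- counts[j]
    row$total <- sum(counts)
    rows[[i]] <- row
  }
  out <- bind_rows(rows)
  class(out) <- c("placement_scan", class(out))
  out
}

# --- event mapping --------------------------------------------------------

#' Map most-parsimonious structural events onto a tree
#'
#' For every informative character, infers the event edges under its
#' direction: loss characters use root-present Dollo (minimal loss edges);
#' gain characters use the minimal set of independent gains with no losses
#' (each gain covers a maximal clade of present tips). Characters whose
#' minimal reconstruction needs more than one independent event of the same
#' type are flagged homoplasious.
#'
#' @param tree rooted binary `phylo`.
#' @param m a character-matrix tibble covering the tree tips.
#' @param defs matching [character_definitions()].
#' @param policy recode policy.
#' @return an `event_map` tibble: `character`, `direction`, `event`
#'   (`gain`/`loss`), `edge`, `n_events`, `homoplasious`; one row per event.
#' @export
map_events <- function(tree, m, defs = character_definitions(),
                       policy = "strict") {
  bin <- recode_binary(m, policy)
  characters <- intersect(defs$symbol, setdiff(names(bin), "taxon"))
  kids <- tree_children(tree)
  sets <- node_tipsets(tree)
  rows <- list()
  for (ch in characters) {
    col <- setNames(bin[[ch]], bin$taxon)[tree$tip.label]
    dir <- defs$direction[match(ch, defs$symbol)]
    if (identical(dir, "gain")) {
      nodes <- minimal_gain_nodes(tree, col, kids, sets)
      ev <- "gain"
    } else {
      nodes <- dollo_reconstruct(tree, col, "root_present")$losses$node
      ev <- "loss"
    }
    if (length(nodes) == 0) next
    rows[[length(rows) + 1]] <- tibble(
      character = ch, direction = dir, event = ev,
      edge = map_chr(as.integer(nodes), edge_label, tree = tree),
      n_events = length(nodes), homoplasious = length(nodes) > 1)
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(character = character(), direction = character(),
           event = character(), edge = character(), n_events = integer(),
           homoplasious = logical())
  class(out) <- c("event_map", class(out))
  out
}

# minimal independent gains, no losses: edges above maximal clades whose
# tips are all present (unknowns are free riders)
minimal_gain_nodes <- function(tree, states, kids, sets) {
  present_below <- map_lgl(sets, ~ any(states[.x] == 1, na.rm = TRUE))
  absent_below <- map_lgl(sets, ~ any(states[.x] == 0, na.rm = TRUE))
  gains <- integer()
  walk <- function(v) {
    if (!present_below[v]) return()
    if (!absent_below[v]) { gains <<- c(gains, v); return() }
    for (ch in kids[[v]] %||% integer()) walk(ch)
  }
  walk(tree_root(tree))
  gains
}
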