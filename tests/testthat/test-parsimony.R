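tip_states <- function(tree, ...) {
  v <- c(...)
  setNames(as.integer(v), tree$tip.label)
}

test_that("Fitch counts match hand-checked cases", {
  t4 <- read_newick("((A,B),(C,D));")
  expect_equal(fitch_min_changes(t4, tip_states(t4, 1, 1, 1, 1))$count, 0)
  expect_equal(fitch_min_changes(t4, tip_states(t4, 1, 1, 0, 0))$count, 1)
  expect_equal(fitch_min_changes(t4, tip_states(t4, 1, 0, 1, 0))$count, 2)
  # unknowns carry the full state set
  expect_equal(fitch_min_changes(t4, tip_states(t4, 1, NA, 0, 0))$count, 1)
  expect_error(fitch_min_changes(t4, c(A = 1, B = 0, C = 1, X = 0)),
               "match tree tips")
})

test_that("Fitch equals the exhaustive-labeling oracle on random trees", {
  set.seed(202)
  for (case in 1:60) {
    nt <- sample(4:7, 1)
    tree <- ape::rtree(nt)
    states <- setNames(sample(c(0L, 1L), nt, replace = TRUE), tree$tip.label)
    if (case %% 10 == 0) states[sample(nt, 1)] <- NA   # sprinkle unknowns
    got <- fitch_min_changes(tree, states)$count
    expect_equal(got, fitch_oracle(tree, states),
                 label = sprintf("case %d", case))
  }
})

test_that("Fitch agrees with an independent parsimony implementation", {
  set.seed(203)
  for (case in 1:10) {
    tree <- ape::rtree(8)
    states <- setNames(sample(c(0L, 1L), 8, replace = TRUE), tree$tip.label)
    dat <- phangorn::phyDat(matrix(as.character(states), ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("0", "1"))
    expect_equal(fitch_min_changes(tree, states)$count,
                 as.integer(phangorn::parsimony(tree, dat)))
  }
})

test_that("Dollo reconstructions place published gains and losses", {
  tree <- reference_tree()
  m <- content_matrix(extrinsic = TRUE)
  bin <- recode_binary(m, "pseudo_as_present")
  col <- function(s) setNames(bin[[s]], bin$taxon)

  d1 <- dollo_reconstruct(tree, col("rps12i346"), "root_present")
  expect_equal(d1$loss_count, 1)
  expect_setequal(strsplit(d1$losses$edge, "\\+")[[1]],
                  c(major_groups()$Psilotopsida, major_groups()$Equisetales))

  d2 <- dollo_reconstruct(tree, col("atp1i361"), "single_gain")
  expect_equal(d2$loss_count, 0)
  expect_setequal(strsplit(d2$gain_edge, "\\+")[[1]],
                  c(major_groups()$Marattiales, major_groups()$Polypodiopsida))

  d3 <- dollo_reconstruct(tree, col("clpPi363"), "root_present")
  expect_equal(d3$loss_count, 1)
  expect_setequal(strsplit(d3$losses$edge, "\\+")[[1]],
                  major_groups()$Equisetales)

  # trivial columns
  allp <- setNames(rep(1L, 10), tree$tip.label)
  expect_equal(dollo_reconstruct(tree, allp, "root_present")$loss_count, 0)
  none <- setNames(rep(0L, 10), tree$tip.label)
  d0 <- dollo_reconstruct(tree, none, "single_gain")
  expect_true(is.na(d0$gain_edge))
  expect_equal(d0$loss_count, 0)
})

test_that("replaying a Dollo reconstruction reproduces the tip states", {
  set.seed(204)
  tree <- ape::rtree(8)
  for (case in 1:25) {
    states <- setNames(sample(c(0L, 1L), 8, replace = TRUE), tree$tip.label)
    for (mode in c("root_present", "single_gain")) {
      d <- dollo_reconstruct(tree, states, mode)
      if (mode == "single_gain" && !any(states == 1)) next
      expect_identical(replay_dollo(d)[names(states)], states,
                       label = paste(mode, case))
    }
  }
})

test_that("Dollo loss counts are never below the Fitch bound", {
  set.seed(205)
  tree <- ape::rtree(7)
  for (case in 1:40) {
    states <- setNames(sample(c(0L, 1L), 7, replace = TRUE), tree$tip.label)
    f <- fitch_min_changes(tree, states)$count
    d <- dollo_reconstruct(tree, states, "root_present")
    expect_gte(d$loss_count, f)
  }
})

test_that("regrafting one tip of a five-tip tree yields four distinct topologies", {
  t5 <- read_newick("((A,(B,(C,D))),E);")
  alts <- regraft_placements(t5, "A")
  expect_equal(nrow(alts), 4)
  # all pairwise distinct and none equals the input
  for (i in seq_len(nrow(alts))) {
    expect_false(plastomes:::topo_identical(alts$tree[[i]], t5))
  }
  expect_error(regraft_placements(read_newick("((A,B),(C,D));"), c("A", "C")),
               "monophyletic")
})

test_that("the Equisetum scan keeps protected clades monophyletic", {
  tree <- reference_tree()
  alts <- regraft_placements(tree, major_groups()$Equisetales,
                             scope = fern_taxa(),
                             keep_monophyletic = major_groups())
  expect_gt(nrow(alts), 0)
  for (tr in alts$tree) {
    expect_true(ape::is.monophyletic(tr, major_groups()$Psilotopsida))
    expect_true(ape::is.monophyletic(tr, major_groups()$Polypodiopsida))
    expect_true(ape::is.binary(tr))
    expect_setequal(tr$tip.label, tree$tip.label)
  }
})

test_that("the placement scan reproduces the one-versus-two-losses argument", {
  tree <- reference_tree()
  m <- content_matrix(extrinsic = TRUE)
  sc <- placement_scan(tree, major_groups()$Equisetales, m,
                       c("rps12i346", "rps16"), fixture_defs(),
                       policy = "pseudo_as_present", scope = fern_taxa(),
                       keep_monophyletic = major_groups())
  orig <- sc[sc$original, ]
  alt <- sc[!sc$original, ]
  expect_equal(orig$rps12i346, 1L)
  expect_equal(orig$rps16, 1L)
  expect_equal(min(alt$rps12i346), 2L)
  expect_equal(min(alt$rps16), 2L)

  # a constant character costs nothing anywhere
  m2 <- m
  m2$constant <- "1"
  defs2 <- dplyr::bind_rows(
    fixture_defs(),
    tibble::tibble(symbol = "constant", kind = "gene", class = "protein",
                   host = NA, position = NA, direction = "loss", trans = FALSE))
  sc2 <- placement_scan(tree, major_groups()$Equisetales, m2, "constant",
                        defs2, scope = fern_taxa())
  expect_true(all(sc2$constant == 0L))
  expect_error(placement_scan(tree, major_groups()$Equisetales, m,
                              character(), fixture_defs()),
               "empty character subset")
})

test_that("scan totals are invariant to taxon order", {
  tree <- reference_tree()
  m <- content_matrix(extrinsic = TRUE)
  args <- list(clade = major_groups()$Equisetales,
               characters = c("rps12i346", "rps16"),
               defs = fixture_defs(), policy = "pseudo_as_present",
               scope = fern_taxa(), keep_monophyletic = major_groups())
  sc1 <- placement_scan(tree, args$clade, m, args$characters, args$defs,
                        args$policy, args$scope, args$keep_monophyletic)
  m_shuf <- m[sample(nrow(m)), ]
  sc2 <- placement_scan(tree, args$clade, m_shuf, args$characters, args$defs,
                        args$policy, args$scope, args$keep_monophyletic)
  expect_equal(sort(sc1$total), sort(sc2$total))
  expect_equal(sc1$total[sc1$original], sc2$total[sc2$original])
})

test_that("event mapping reproduces the published ledger with homoplasy flags", {
  tree <- reference_tree()
  m <- content_matrix(extrinsic = TRUE)
  ev <- map_events(tree, m, fixture_defs(), policy = "pseudo_as_present")

  irx <- ev[ev$character == "ir_expansion_lsc", ]
  expect_equal(unique(irx$n_events), 2)
  expect_true(all(irx$homoplasious))
  expect_setequal(irx$edge[irx$edge == "Psilotum_nudum"], "Psilotum_nudum")

  clp <- ev[ev$character == "clpPi363", ]
  expect_equal(nrow(clp), 1)
  expect_false(clp$homoplasious)
  expect_setequal(strsplit(clp$edge, "\\+")[[1]], major_groups()$Equisetales)

  # single-taxon loss maps to the pendant edge
  rpl <- ev[ev$character == "rpl16i9", ]
  expect_equal(rpl$edge, "Equisetum_hyemale")
  expect_false(rpl$homoplasious)

  atp <- ev[ev$character == "atp1i361", ]
  expect_equal(atp$event, "gain")
  expect_equal(atp$n_events, 1)
})

test_that("tidy and glance methods expose results as tibbles", {
  tree <- reference_tree()
  m <- content_matrix(extrinsic = TRUE)
  bin <- recode_binary(m)
  d <- dollo_reconstruct(tree, setNames(bin$rps12i346, bin$taxon),
                         "root_present")
  td <- generics::tidy(d)
  expect_named(td, c("event", "edge"))
  expect_equal(generics::glance(d)$losses, 1)

  sc <- placement_scan(tree, major_groups()$Equisetales, m, "rps12i346",
                       fixture_defs(), scope = fern_taxa(),
                       keep_monophyletic = major_groups())
  long <- generics::tidy(sc)
  expect_true(all(c("placement", "character", "losses") %in% names(long)))
  g <- generics::glance(sc)
  expect_equal(g$original_total, 1)
  expect_equal(g$alternative_min_total, 2)

  p <- detect_ir(make_ancestor(ancestor_spec(), seed = 1))
  expect_equal(nrow(generics::tidy(p)), 4)
  expect_s3_class(autoplot(p), "ggplot")
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(plot_matrix(content_matrix(),
                              c("rps16", "rps12i346", "clpPi363")), "ggplot")
})
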