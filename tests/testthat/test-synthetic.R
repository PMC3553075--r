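test_that("the ancestor is deterministic and its planted IR is recovered exactly", {
  a1 <- make_ancestor(ancestor_spec(), seed = 1)
  a2 <- make_ancestor(ancestor_spec(), seed = 1)
  expect_identical(a1$sequence, a2$sequence)
  expect_false(identical(a1$sequence,
                         make_ancestor(ancestor_spec(), seed = 2)$sequence))
  for (seed in 1:5) {
    a <- make_ancestor(ancestor_spec(), seed = seed)
    p <- detect_ir(a)
    expect_equal(p$ira, a$ir_interval$ira, label = paste("seed", seed))
    expect_equal(p$irb, a$ir_interval$irb, label = paste("seed", seed))
    expect_equal(p$mismatches, 0L)
  }
})

test_that("infeasible size targets error and feasible ones pad the genome", {
  expect_error(make_ancestor(ancestor_spec(size_target = 10000), seed = 1),
               "infeasible")
  base <- make_ancestor(ancestor_spec(), seed = 1)
  padded <- make_ancestor(ancestor_spec(size_target = base$length + 5000),
                          seed = 1)
  expect_equal(padded$length, base$length + 5000)
  expect_equal(detect_ir(padded)$ir_length, detect_ir(base)$ir_length)
})

test_that("zero rates give an empty log and tips identical to the ancestor", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 4)
  log <- simulate_history(tree, spec, rates = c(gene_loss = 0), seed = 4)
  expect_equal(nrow(log), 0)
  genomes <- emit_genomes(tree, anc, log)
  expect_identical(genomes[["Psilotum_nudum"]]$sequence, anc$sequence)
  expect_identical(genomes[["Isoetes_flaccida"]]$sequence, anc$sequence)
})

test_that("a forced intron loss is recovered on exactly the planted branch", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 4)
  node <- ape::getMRCA(tree, c(major_groups()$Psilotopsida,
                               major_groups()$Equisetales))
  log <- forced_log(tree, node, "intron_loss", "clpPi363")
  genomes <- emit_genomes(tree, anc, log)
  defs <- synthetic_definitions(spec)
  m <- build_matrix(genomes, defs, references = anc$references)
  bin <- recode_binary(m)
  d <- dollo_reconstruct(tree, setNames(bin$clpPi363, bin$taxon),
                         "root_present")
  expect_equal(d$loss_count, 1)
  expect_equal(d$losses$node, node)
})

test_that("simulated histories are deterministic and Dollo-coherent", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  l1 <- simulate_history(tree, spec, seed = 7, no_homoplasy = TRUE)
  l2 <- simulate_history(tree, spec, seed = 7, no_homoplasy = TRUE)
  expect_identical(as.data.frame(l1), as.data.frame(l2))
  # no character is hit twice in no-homoplasy mode
  hits <- l1[!l1$skipped & l1$type %in% c("gene_loss", "intron_loss",
                                          "pseudogenize"), ]
  expect_false(anyDuplicated(hits$target) > 0)
})

test_that("plant-and-recover: emitted genomes reproduce the planted truth end to end", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 7)
  log <- simulate_history(tree, spec, seed = 7, no_homoplasy = TRUE)
  genomes <- emit_genomes(tree, anc, log)
  defs <- synthetic_definitions(spec)

  # matrix built from annotations equals the truth matrix from the log
  m_obs <- build_matrix(genomes, defs, references = anc$references)
  m_tru <- truth_matrix(genomes)
  m_tru <- m_tru[match(m_obs$taxon, m_tru$taxon), names(m_obs)]
  expect_identical(as.data.frame(m_obs), as.data.frame(m_tru))

  # every emitted genome still yields its planted IR exactly
  for (g in genomes) {
    p <- detect_ir(g)
    expect_equal(p$ira, g$ir_interval$ira, label = g$taxon)
    expect_equal(p$irb, g$ir_interval$irb, label = g$taxon)
  }

  # every planted loss/pseudogenization event is recovered on its edge
  ev <- map_events(tree, m_obs, defs)
  expect_false(any(ev$homoplasious))
  planted <- log[!log$skipped &
                   log$type %in% c("gene_loss", "intron_loss", "pseudogenize"), ]
  for (i in seq_len(nrow(planted))) {
    expect_true(any(ev$character == planted$target[i] &
                      ev$edge == planted$branch[i]),
                label = paste(planted$type[i], planted$target[i]))
  }
  # and every inferred event is a planted one (or an intron implied by the
  # loss of its host gene on the same branch)
  for (i in seq_len(nrow(ev))) {
    direct <- any(planted$target == ev$character[i] &
                    planted$branch == ev$edge[i])
    host <- defs$host[match(ev$character[i], defs$symbol)]
    implied <- !is.na(host) &&
      any(planted$target == host & planted$type == "gene_loss" &
            planted$branch == ev$edge[i])
    expect_true(direct || implied, label = ev$character[i])
  }
})

test_that("an IR expansion duplicates the captured genes into both copies", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 9)
  log <- forced_log(tree, which(tree$tip.label == "Psilotum_nudum"),
                    "ir_expand", "SSC", detail = "ndhF,chlL")
  genomes <- emit_genomes(tree, anc, log)
  tip <- genomes[["Psilotum_nudum"]]
  p <- detect_ir(tip)
  regions <- tibble::tibble(
    symbol = c(spec$lsc$symbol, spec$ssc$symbol, spec$ir$symbol),
    region = rep(c("LSC", "SSC", "IR"),
                 c(nrow(spec$lsc), nrow(spec$ssc), nrow(spec$ir))))
  cb <- compare_boundaries(ir_gene_content(tip, p), regions = regions)
  expect_equal(cb$classification, "expanded")
  expect_setequal(cb$gained$symbol, c("ndhF", "chlL"))
  expect_true(all(cb$gained$origin == "SSC"))
  # other tips stay ancestral
  other <- genomes[["Ophioglossum_californicum"]]
  cb2 <- compare_boundaries(ir_gene_content(other, detect_ir(other)),
                            regions = regions)
  expect_equal(cb2$classification, "ancestral")
})

test_that("a planted inversion is a one-reversal scenario against the ancestor", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 9)
  log <- forced_log(tree, which(tree$tip.label == "Psilotum_nudum"),
                    "inversion", "psbC..ycf3", detail = "psbC,psbD,ycf3")
  genomes <- emit_genomes(tree, anc, log)
  tip <- genomes[["Psilotum_nudum"]]
  part_a <- detect_ir(anc); part_t <- detect_ir(tip)
  ord_a <- signed_gene_order(anc, part_a$lsc)
  ord_t <- signed_gene_order(tip, part_t$lsc)
  # exhaustive search is bounded, so compare an 8-gene window around the block
  window <- ord_a$symbol[match("rpoC1", ord_a$symbol) + 0:7]
  ord_a <- ord_a[ord_a$symbol %in% window, ]
  ord_t <- ord_t[ord_t$symbol %in% window, ]
  r <- reversal_scenario(ord_a, ord_t, max_depth = 2)
  expect_true(r$solved)
  expect_equal(r$distance, 1)
  # strands flipped inside the block only
  flip <- ord_t$orientation != ord_a$orientation[match(ord_t$symbol,
                                                       ord_a$symbol)]
  expect_setequal(ord_t$symbol[flip], c("psbC", "psbD", "ycf3"))
})

test_that("emitted flat files round-trip through the GenBank reader", {
  tree <- reference_tree()
  spec <- ancestor_spec()
  anc <- make_ancestor(spec, seed = 10)
  log <- simulate_history(tree, spec, seed = 10, no_homoplasy = TRUE)
  genomes <- emit_genomes(tree, anc, log)
  tip <- genomes[[tree$tip.label[3]]]
  path <- tempfile(fileext = ".gb")
  write_flatfile(tip, path)
  back <- read_genbank(path)
  expect_identical(back$sequence, tip$sequence)
  defs <- synthetic_definitions(spec)
  expect_identical(
    extract_states(back, defs, references = anc$references)[, -1],
    extract_states(tip, defs, references = anc$references)[, -1])
})
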