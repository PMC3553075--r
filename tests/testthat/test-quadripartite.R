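test_that("detect_ir recovers a planted repeat and matches the diagonal-scan oracle", {
  pc <- planted_circle()
  p <- detect_ir(pc$seq, min_length = 1000)
  expect_true(p$found)
  expect_equal(p$ir_length, pc$ir)
  expect_equal(p$lsc_length, pc$lsc)
  expect_equal(p$ssc_length, pc$ssc)
  expect_equal(p$mismatches, 0L)

  # independent O(n^2) oracle on a small instance
  small <- planted_circle(lsc = 700, ir = 300, ssc = 200, seed = 5)
  q <- detect_ir(small$seq, min_length = 100)
  expect_equal(q$ir_length, ir_arm_oracle(small$seq))
  expect_equal(q$ir_length, 300)
})

test_that("sequences without an inverted repeat yield a no-IR result, not an error", {
  set.seed(1)
  p <- detect_ir(random_dna_chr(10000), min_length = 1000)
  expect_false(p$found)
  expect_equal(p$ir_length, 0)
  # too-short sequences fall in the same bucket
  expect_false(detect_ir(random_dna_chr(100), min_length = 1000)$found)
})

test_that("detect_ir is rotation-invariant on the circle", {
  pc <- planted_circle(seed = 7)
  base <- detect_ir(pc$seq, min_length = 1000)
  n <- nchar(pc$seq)
  for (k in c(1, 2500, 5800, n - 3)) {
    p <- detect_ir(rotate_seq(pc$seq, k), min_length = 1000)
    expect_equal(p$ir_length, base$ir_length)
    expect_equal(p$lsc_length, base$lsc_length)
    expect_equal(p$ssc_length, base$ssc_length)
    # region starts shift by exactly the rotation
    expect_equal(plastomes:::pmod(p$ira[1] + k, n), base$ira[1])
  }
})

test_that("partitions tile the circle and IR copies are reverse complements", {
  for (seed in c(3, 9, 21)) {
    pc <- planted_circle(lsc = 3000, ir = 1100, ssc = 600, seed = seed)
    p <- detect_ir(pc$seq, min_length = 1000)
    expect_equal(p$lsc_length + p$ssc_length + 2 * p$ir_length,
                 nchar(pc$seq))
    ira <- plastomes:::circ_substr(pc$seq, p$ira[1], p$ira[2])
    irb <- plastomes:::circ_substr(pc$seq, p$irb[1], p$irb[2])
    expect_identical(rc_chr(ira), irb)
  }
})

test_that("bounded substitution tolerance merges across a planted mismatch", {
  pc <- planted_circle(seed = 13)
  s <- pc$seq
  pos <- pc$lsc + 600                    # inside the first IR copy
  old <- substr(s, pos, pos)
  repl <- setdiff(c("A", "C", "G", "T"), old)[1]
  substr(s, pos, pos) <- repl
  strict <- detect_ir(s, min_length = 1000, max_mismatch = 0)
  tol <- detect_ir(s, min_length = 1000, max_mismatch = 1)
  expect_false(strict$found && strict$ir_length == pc$ir)
  expect_true(tol$found)
  expect_equal(tol$ir_length, pc$ir)
  expect_equal(tol$mismatches, 1L)
})

test_that("plastome summaries count deduplicated features and report lengths", {
  anc <- make_ancestor(ancestor_spec(), seed = 1)
  p <- detect_ir(anc)
  sm <- summarize_plastome(anc, p)
  spec <- ancestor_spec()
  expect_equal(sm$trnas,
               sum(spec$lsc$kind == "tRNA") + sum(spec$ir$kind == "tRNA") +
                 sum(spec$ssc$kind == "tRNA"))
  expect_equal(sm$rrnas, sum(spec$ir$kind == "rRNA"))
  expect_equal(sm$proteins,
               sum(spec$lsc$kind == "protein") + sum(spec$ssc$kind == "protein"))
  expect_equal(sm$genes, sm$trnas + sm$rrnas + sm$proteins)
  expect_equal(sm$introns, nrow(spec$introns))
  expect_equal(sm$size_bp, sm$lsc_bp + sm$ssc_bp + 2 * sm$ir_bp)

  # duplicating a feature into the second IR copy does not change counts
  dup <- anc
  row <- dup$features[dup$features$name == "rrn16", ][1, ]
  dup$features <- dplyr::bind_rows(dup$features, row)
  expect_equal(summarize_plastome(dup, p)$rrnas, sm$rrnas)

  # featureless records still report lengths
  bare <- genome_record("X", "bare", anc$sequence)
  sm0 <- summarize_plastome(bare, p)
  expect_equal(sm0$genes, 0)
  expect_equal(sm0$size_bp, anc$length)

  # pseudogenes drop out of counts under the strict policy
  ps <- anc
  ps$features$pseudo[ps$features$name == "rbcL"] <- TRUE
  expect_equal(summarize_plastome(ps, p)$proteins, sm$proteins - 1)
  expect_equal(summarize_plastome(ps, p, "pseudo_as_present")$proteins,
               sm$proteins)
})

test_that("junction maps report flanks, signed distances and truncated copies", {
  anc <- make_ancestor(ancestor_spec(), seed = 1)
  p <- detect_ir(anc)
  jm <- junction_map(anc, p)
  expect_equal(jm$junction, c("LSC-IRa", "IRa-SSC", "SSC-IRb", "IRb-LSC"))
  # layout puts ndhB last in the LSC and rrn16 first in the IR
  expect_equal(jm$sc_gene[1], "ndhB")
  expect_equal(jm$ir_gene[1], "rrn16")
  expect_true(all(jm$sc_distance[c(1, 3)] <= 0))
  expect_true(all(is.na(jm$truncated)))

  # plant a gene straddling the LSC/IRa junction by 50 bp
  jpos <- p$ira[1]
  strad <- new_feature("ndhF", "protein", "+",
                       matrix(c(jpos - 50L, jpos + 50L), 1))
  rec2 <- genome_record(anc$identifier, anc$taxon, anc$sequence,
                        dplyr::bind_rows(anc$features, strad))
  jm2 <- junction_map(rec2, p)
  expect_match(jm2$truncated[1], "ndhF")
  expect_equal(jm2$sc_distance[1], 0L)
})

test_that("boundary classification splits gained genes by ancestral region", {
  anc <- make_ancestor(ancestor_spec(), seed = 1)
  p <- detect_ir(anc)
  genes <- ir_gene_content(anc, p)
  expect_setequal(genes, ancestral_ir_genes())
  cb <- compare_boundaries(genes)
  expect_equal(cb$classification, "ancestral")
  expect_equal(nrow(cb$gained), 0)
  expect_equal(nrow(cb$lost), 0)

  cb2 <- compare_boundaries(c(ancestral_ir_genes(), "ndhF", "rpl21", "psbA"))
  expect_equal(cb2$classification, "expanded")
  expect_setequal(cb2$gained$origin, c("SSC", "SSC", "LSC"))

  cb3 <- compare_boundaries(c(ancestral_ir_genes(), "notagene"))
  expect_equal(cb3$gained$origin, "unassigned")

  cb4 <- compare_boundaries(setdiff(ancestral_ir_genes(), "rrn5"))
  expect_equal(cb4$classification, "other")
  expect_equal(cb4$lost$symbol, "rrn5")
})
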