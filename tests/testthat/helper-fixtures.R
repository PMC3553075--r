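# shared helpers: tiny fixtures built in code + independent oracles

ord <- function(symbols, orientations) {
  tibble::tibble(symbol = symbols, orientation = orientations)
}

random_dna_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

rotate_seq <- function(s, k) {
  if (k == 0) return(s)
  paste0(substr(s, k + 1, nchar(s)), substr(s, 1, k))
}

# a synthetic circle with one planted inverted repeat: L + I + S + revcomp(I);
# flanking bases are nudged so a chance complementary base next to a junction
# cannot extend the repeat beyond the planted arm
planted_circle <- function(lsc = 5000, ir = 1200, ssc = 800, seed = 42) {
  set.seed(seed)
  L <- random_dna_chr(lsc); I <- random_dna_chr(ir); S <- random_dna_chr(ssc)
  comp <- function(x) chartr("ACGT", "TGCA", x)
  other <- function(bad) setdiff(c("A", "C", "G", "T"), bad)[1]
  if (substr(L, lsc, lsc) == comp(substr(L, 1, 1))) {
    substr(L, lsc, lsc) <- other(comp(substr(L, 1, 1)))
  }
  if (substr(S, 1, 1) == comp(substr(S, ssc, ssc))) {
    substr(S, 1, 1) <- other(comp(substr(S, ssc, ssc)))
  }
  list(seq = paste0(L, I, S, rc_chr(I)), lsc = lsc, ir = ir, ssc = ssc)
}

# O(n^2) diagonal-scan oracle: length of the longest circular common
# substring between the sequence and its reverse complement (= longest
# inverted-repeat arm, palindrome-free instances)
ir_arm_oracle <- function(s) {
  n <- nchar(s)
  cs <- strsplit(s, "")[[1]]
  cr <- strsplit(rc_chr(s), "")[[1]]
  best <- 0L
  for (d in 0:(n - 1)) {
    eq <- cs == cr[((seq_len(n) - 1 + d) %% n) + 1]
    r <- rle(eq)
    runs <- r$lengths[r$values]
    if (length(runs)) best <- max(best, max(runs))
    # circular wrap: first and last runs both TRUE join up
    if (r$values[1] && r$values[length(r$values)] && length(r$values) > 1) {
      best <- max(best, r$lengths[1] + r$lengths[length(r$lengths)])
    }
  }
  best
}

# exhaustive small-parsimony oracle: score all 2^Nnode internal labelings
fitch_oracle <- function(tree, states) {
  states <- states[tree$tip.label]
  nt <- ape::Ntip(tree); nn <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    lab <- c(states, as.integer(intToBits(mask))[seq_len(nn)])
    cost <- 0L
    for (r in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[r, 1]]; b <- lab[tree$edge[r, 2]]
      if (is.na(b)) next                     # unknown tip matches anything
      if (a != b) cost <- cost + 1L
    }
    best <- min(best, cost)
  }
  best
}

# iterative-deepening reversal search, independent of the BFS implementation
reversal_oracle <- function(a, b, max_depth = 4) {
  key <- function(p) paste(p, collapse = ",")
  target <- key(b)
  m <- length(a)
  dfs <- function(p, depth) {
    if (key(p) == target) return(TRUE)
    if (depth == 0) return(FALSE)
    for (i in 1:m) for (j in i:m) {
      q <- p; q[i:j] <- -rev(p[i:j])
      if (dfs(q, depth - 1)) return(TRUE)
    }
    FALSE
  }
  for (d in 0:max_depth) if (dfs(a, d)) return(d)
  NA_integer_
}

signed_vec <- function(o) {
  match(o$symbol, o$symbol[order(o$symbol)]) * ifelse(o$orientation == "+", 1L, -1L)
}

# minimal hand-written GenBank text for parser tests
mini_genbank <- function(path, n = 600) {
  set.seed(11)
  body <- tolower(random_dna_chr(n))
  lines <- c(
    sprintf("LOCUS       TEST0001 %d bp    DNA     circular PLN", n),
    "DEFINITION  hand-built test record.",
    "SOURCE      test",
    "  ORGANISM  Testus minimus",
    "FEATURES             Location/Qualifiers",
    "     gene            1..90",
    "                     /gene=\"psbA\"",
    "     CDS             1..90",
    "                     /gene=\"psbA\"",
    "     CDS             join(101..200,401..500)",
    "                     /gene=\"clpP\"",
    "     tRNA            complement(210..283)",
    "                     /gene=\"trnN-GUU\"",
    "     CDS             510..560",
    "                     /gene=\"rps16\"",
    "                     /pseudo",
    "     CDS             join(581..600,1..40)",
    "                     /gene=\"matK\"",
    "ORIGIN")
  for (s in seq(1, n, 60)) {
    chunk <- substr(body, s, min(s + 59, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  writeLines(c(lines, "//"), path)
  path
}

# a hand-assembled event log (bypasses the stochastic simulator)
forced_log <- function(tree, node, type, target, detail = NA_character_) {
  log <- tibble::tibble(branch = plastomes::edge_label(tree, node),
                        node = as.integer(node), order = 1L, type = type,
                        target = target, detail = detail, skipped = FALSE)
  class(log) <- c("event_log", class(log))
  log
}

fixture_defs <- function() {
  dplyr::bind_rows(character_definitions(), extrinsic_characters()$defs)
}
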