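#' Detect the inverted repeat and derive the quadripartite partition
#'
#' Finds the longest pair of disjoint, reverse-complementary segments on the
#' circular sequence: exact k-mer seeds shared between the sequence and its
#' reverse complement are grouped on anti-diagonals, extended into maximal
#' runs (circularly), and optionally merged across up to `max_mismatch`
#' substitutions. The two single-copy gaps between the chosen pair become
#' LSC (the longer) and SSC; IRa is the copy immediately following the LSC
#' in circle order. Equal-length candidates are tie-broken to the smallest
#' start coordinate, with a warning.
#'
#' @param sequence circular nucleotide string (or a [genome_record()]).
#' @param min_length minimum IR arm length in bp (default 1000; plastome IRs
#'   are an order of magnitude larger).
#' @param max_mismatch tolerated substitutions between the two copies
#'   (default 0: plastome IR copies are typically identical).
#' @param k seed k-mer length (default 31).
#' @return a `quadripartite_partition`: intervals (0-based half-open,
#'   possibly wrapping) for `ira`, `irb`, `lsc`, `ssc`, plus `ir_length` and
#'   `mismatches`. When no repeat of `min_length` exists the object has
#'   `found = FALSE` (a "no IR" result, not an error).
#' @export
detect_ir <- function(sequence, min_length = 1000, max_mismatch = 0, k = 31) {
  if (inherits(sequence, "genome_record")) sequence <- sequence$sequence
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 2 * min_length) return(no_ir(n))

  cand <- ir_candidates(sequence, k, max_mismatch)
  cand <- cand[cand$length >= min_length & cand$disjoint, , drop = FALSE]
  if (nrow(cand) == 0) return(no_ir(n))
  best_len <- max(cand$length)
  best <- cand[cand$length == best_len, , drop = FALSE]
  best <- best[order(best$a, best$b), , drop = FALSE]
  if (nrow(best) > 1) {
    warn("multiple equal-length IR candidates; taking the smallest start")
  }
  a <- best$a[1]; b <- best$b[1]; L <- best$length[1]

  ce <- function(start, len) if (start + len <= n) start + len else start + len - n
  gap1 <- interval_len(pmod(a + L, n), b, n)       # between copy A end and copy B
  gap2 <- interval_len(pmod(b + L, n), a, n)
  if (gap2 >= gap1) {
    lsc <- c(pmod(b + L, n), a); ira <- c(a, ce(a, L))
    ssc <- c(pmod(a + L, n), b); irb <- c(b, ce(b, L))
  } else {
    lsc <- c(pmod(a + L, n), b); ira <- c(b, ce(b, L))
    ssc <- c(pmod(b + L, n), a); irb <- c(a, ce(a, L))
  }
  ira_seq <- circ_substr(sequence, ira[1], ira[2])
  irb_seq <- circ_substr(sequence, irb[1], irb[2])
  mm <- sum(strsplit(ira_seq, "")[[1]] != strsplit(revcomp(irb_seq), "")[[1]])
  structure(
    list(found = TRUE, genome_length = n, ira = ira, irb = irb, lsc = lsc,
         ssc = ssc, ir_length = L, lsc_length = interval_len(lsc[1], lsc[2], n),
         ssc_length = interval_len(ssc[1], ssc[2], n), mismatches = mm),
    class = "quadripartite_partition")
}

no_ir <- function(n) {
  structure(list(found = FALSE, genome_length = n, ira = NULL, irb = NULL,
                 lsc = c(0, n), ssc = NULL, ir_length = 0,
                 lsc_length = n, ssc_length = 0, mismatches = 0L),
            class = "quadripartite_partition")
}

#' @export
print.quadripartite_partition <- function(x, ...) {
  if (!x$found) {
    cat(sprintf("<quadripartite_partition> no IR found (genome %d bp)\n",
                x$genome_length))
    return(invisible(x))
  }
  cat(sprintf("<quadripartite_partition> genome %s bp\n",
              format(x$genome_length, big.mark = ",")))
  cat(sprintf("  LSC [%d,%d) %d bp | IRa [%d,%d) | SSC [%d,%d) %d bp | IRb [%d,%d)\n",
              x$lsc[1], x$lsc[2], x$lsc_length, x$ira[1], x$ira[2],
              x$ssc[1], x$ssc[2], x$ssc_length, x$irb[1], x$irb[2]))
  cat(sprintf("  IR %d bp, %d mismatch(es) between copies\n",
              x$ir_length, x$mismatches))
  invisible(x)
}

# enumerate maximal inverted-repeat candidates via circular k-mer seeding
ir_candidates <- function(sequence, k, max_mismatch) {
  n <- nchar(sequence)
  rc <- revcomp(sequence)
  s2 <- paste0(sequence, substr(sequence, 1, k - 1))
  r2 <- paste0(rc, substr(rc, 1, k - 1))
  ks <- substring(s2, 1:n, k:(n + k - 1))
  kr <- substring(r2, 1:n, k:(n + k - 1))
  shared <- intersect(unique(ks), unique(kr))
  if (length(shared) == 0) {
    return(tibble(a = integer(), b = integer(), length = integer(),
                  disjoint = logical()))
  }
  si <- which(ks %in% shared)
  ri_by_kmer <- split(seq_len(n) - 1L, kr[seq_len(n)])[shared]
  pair_i <- integer(); pair_j <- integer()
  si_by_kmer <- split(si - 1L, ks[si])
  for (km in shared) {
    is <- si_by_kmer[[km]]; js <- ri_by_kmer[[km]]
    pair_i <- c(pair_i, rep(is, each = length(js)))
    pair_j <- c(pair_j, rep(js, times = length(is)))
  }
  d <- pmod(pair_j - pair_i, n)
  runs <- list()
  for (dg in unique(d)) {
    ii <- sort(pair_i[d == dg])
    brk <- which(diff(ii) != 1L)
    starts <- ii[c(1L, brk + 1L)]
    ends <- ii[c(brk, length(ii))]
    # wrap-around run on this diagonal
    if (length(starts) > 1 && starts[1] == 0L && ends[length(ends)] == n - 1L) {
      starts[1] <- starts[length(starts)]
      starts <- starts[-length(starts)]; ends <- ends[-length(ends)]
    }
    seg <- tibble(d = dg, i0 = starts, i1 = ends)
    runs[[length(runs) + 1]] <- merge_runs(seg, sequence, rc, n, k, max_mismatch)
  }
  runs <- bind_rows(runs)
  if (nrow(runs) == 0) {
    return(tibble(a = integer(), b = integer(), length = integer(),
                  disjoint = logical()))
  }
  L <- pmod(runs$i1 - runs$i0, n) + k
  a <- runs$i0
  cpos <- pmod(a + runs$d, n)
  b <- pmod(n - cpos - L, n)
  out <- tibble(a = as.integer(a), b = as.integer(b), length = as.integer(L))
  # canonical orientation and duplicate removal (each pair is found twice)
  flip <- out$b < out$a
  tmp <- out$a[flip]; out$a[flip] <- out$b[flip]; out$b[flip] <- tmp
  out <- distinct(out)
  out$disjoint <- pmap_lgl(out, function(a, b, length) {
    !interval_contains(a, pmod(a + length, nchar(sequence)), b, nchar(sequence)) &&
      !interval_contains(b, pmod(b + length, nchar(sequence)), a, nchar(sequence))
  })
  out
}

#' @importFrom purrr pmap_lgl
merge_runs <- function(seg, sequence, rc, n, k, max_mismatch) {
  if (max_mismatch == 0 || nrow(seg) < 2) return(seg)
  seg <- arrange(seg, .data$i0)
  out <- seg[1, ]
  budget <- max_mismatch
  for (r in 2:nrow(seg)) {
    gap_i0 <- out$i1[nrow(out)] + k     # first base after the matched block
    gap_i1 <- seg$i0[r] - 1L + k - 1L   # last base before next block's match
    if (gap_i1 < gap_i0) { out <- bind_rows(out, seg[r, ]); next }
    sa <- circ_substr(sequence, pmod(gap_i0, n), pmod(gap_i1 + 1L, n))
    ca <- circ_substr(rc, pmod(gap_i0 + out$d[1], n), pmod(gap_i1 + 1L + out$d[1], n))
    mm <- sum(strsplit(sa, "")[[1]] != strsplit(ca, "")[[1]])
    if (mm <= budget) {
      budget <- budget - mm
      out$i1[nrow(out)] <- seg$i1[r]
    } else {
      out <- bind_rows(out, seg[r, ])
      budget <- max_mismatch
    }
  }
  out
}
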