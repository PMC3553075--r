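#' Summary statistics for an annotated plastome
#'
#' Region lengths from the detected partition, GC over the full circle, and
#' deduplicated feature counts: genes appearing in both IR copies are
#' counted once (characters are symbols, not instances), pseudogenes are
#' excluded under the default policy, and trans-spliced genes/introns count
#' as present.
#'
#' @param record a [genome_record()].
#' @param partition matching [detect_ir()] result.
#' @param policy `"strict"` (pseudogenes excluded) or `"pseudo_as_present"`.
#' @return a one-row tibble of summary statistics.
#' @export
summarize_plastome <- function(record, partition = detect_ir(record),
                               policy = c("strict", "pseudo_as_present")) {
  policy <- match.arg(policy)
  if (partition$genome_length != record$length) {
    abort("partition and record disagree on genome length")
  }
  f <- record$features
  counted <- if (policy == "strict") filter(f, !.data$pseudo) else f
  n_kind <- function(kd) dplyr::n_distinct(counted$name[counted$kind == kd])
  introns <- filter(counted, .data$kind == "intron")
  n_introns <- dplyr::n_distinct(paste(introns$name, introns$note))
  tibble(
    taxon = record$taxon, accession = record$identifier,
    size_bp = record$length,
    lsc_bp = partition$lsc_length, ssc_bp = partition$ssc_length,
    ir_bp = partition$ir_length,
    gc_pct = gc_percent(record$sequence),
    trnas = n_kind("tRNA"), rrnas = n_kind("rRNA"), proteins = n_kind("protein"),
    genes = .data$trnas + .data$rrnas + .data$proteins,
    introns = n_introns)
}

#' Junction adjacencies of the four IR borders
#'
#' For each junction (LSC/IRa, IRa/SSC, SSC/IRb, IRb/LSC) reports the nearest
#' flanking feature on the single-copy side and on the IR side, the signed
#' distance from the junction to the feature's nearest edge (negative =
#' feature ends upstream of the junction, 0 = feature straddles it), and a
#' truncated-copy flag for features the border cuts (the fragmented second
#' copies the expansion literature describes).
#'
#' @inheritParams summarize_plastome
#' @return a tibble with one row per junction.
#' @export
junction_map <- function(record, partition = detect_ir(record)) {
  if (!partition$found) abort("no IR detected; junctions undefined")
  n <- record$length
  jn <- tibble(
    junction = c("LSC-IRa", "IRa-SSC", "SSC-IRb", "IRb-LSC"),
    position = c(partition$ira[1], partition$ira[2],
                 partition$irb[1], partition$irb[2]),
    sc_side = c("before", "after", "before", "after"))
  f <- record$features
  f <- filter(f, .data$kind != "intron")
  rows <- list()
  for (i in seq_len(nrow(jn))) {
    p <- jn$position[i]
    if (nrow(f) == 0) {
      rows[[i]] <- tibble(junction = jn$junction[i], position = p,
                          sc_gene = NA_character_, sc_distance = NA_integer_,
                          ir_gene = NA_character_, ir_distance = NA_integer_,
                          truncated = NA_character_)
      next
    }
    hull <- map(f$intervals, function(iv) c(iv[1, "start"], iv[nrow(iv), "end"]))
    strad <- map_lgl(hull, ~ interval_contains(.x[1], .x[2], p, n, strict = TRUE))
    d_before <- map_dbl(hull, ~ pmod(p - .x[2], n))
    d_after <- map_dbl(hull, ~ pmod(.x[1] - p, n))
    d_before[strad] <- 0; d_after[strad] <- 0
    before <- which.min(d_before); after <- which.min(d_after)
    before_val <- c(f$name[before], -d_before[before])
    after_val <- c(f$name[after], d_after[after])
    if (jn$sc_side[i] == "before") {
      sc <- before_val; ir <- after_val
    } else {
      sc <- after_val; ir <- before_val
    }
    rows[[i]] <- tibble(
      junction = jn$junction[i], position = p,
      sc_gene = sc[1], sc_distance = as.integer(sc[2]),
      ir_gene = ir[1], ir_distance = as.integer(ir[2]),
      truncated = if (any(strad)) paste(unique(f$name[strad]), collapse = ",")
                  else NA_character_)
  }
  bind_rows(rows)
}

#' Gene symbols fully contained in the inverted repeat
#'
#' A gene is "in the IR" only when every interval lies inside one IR copy;
#' genes straddling a border belong to the junction record instead.
#'
#' @inheritParams summarize_plastome
#' @return character vector of distinct gene symbols.
#' @export
ir_gene_content <- function(record, partition = detect_ir(record)) {
  if (!partition$found) return(character())
  n <- record$length
  inside <- function(iv, reg) {
    all(apply(iv, 1, function(r) {
      interval_contains(reg[1], reg[2], r["start"], n) &&
        interval_contains(reg[1], pmod(reg[2] + 1, n), r["end"], n)
    }))
  }
  f <- filter(record$features, .data$kind != "intron")
  keep <- map_lgl(f$intervals, function(iv) {
    inside(iv, record_region(partition, "ira")) ||
      inside(iv, record_region(partition, "irb"))
  })
  unique(f$name[keep])
}

record_region <- function(partition, which) partition[[which]]

#' Classify IR boundaries against the ancestral arrangement
#'
#' Compares the IR gene complement to the ancestral nine-gene set.
#' Classification is `"ancestral"` when the complements match, `"expanded"`
#' when extra genes were captured, `"other"` when genes were only lost. The
#' gained set is split by the single-copy region each gene ancestrally
#' occupied; symbols missing from the reference table are reported as
#' `"unassigned"`, not an error.
#'
#' @param ir_genes character vector from [ir_gene_content()].
#' @param ancestral_ir ancestral IR complement (default [ancestral_ir_genes()]).
#' @param regions reference gene-to-region table (default [region_membership()]).
#' @return list with `classification`, `gained` (tibble symbol/origin),
#'   `lost` (tibble symbol/origin).
#' @export
compare_boundaries <- function(ir_genes, ancestral_ir = ancestral_ir_genes(),
                               regions = region_membership()) {
  ir_genes <- normalize_symbol(ir_genes)
  gained <- setdiff(ir_genes, ancestral_ir)
  lost <- setdiff(ancestral_ir, ir_genes)
  origin <- function(sym) {
    r <- regions$region[match(sym, regions$symbol)]
    ifelse(is.na(r), "unassigned", r)
  }
  classification <- if (length(gained)) "expanded"
    else if (length(lost)) "other" else "ancestral"
  list(classification = classification,
       gained = tibble(symbol = gained, origin = origin(gained)),
       lost = tibble(symbol = lost, origin = origin(lost)))
}

#' Extract the signed gene order of a region
#'
#' @param record a [genome_record()].
#' @param region 0-based half-open interval `c(start, end)` on the circle, or
#'   `NULL` for the whole record.
#' @return a signed-gene-order tibble (`symbol`, `orientation`), ordered along
#'   the region; duplicate symbols are suffixed to stay unique.
#' @export
signed_gene_order <- function(record, region = NULL) {
  f <- filter(record$features, .data$kind != "intron")
  n <- record$length
  if (!is.null(region)) {
    keep <- map_lgl(f$intervals, function(iv) {
      interval_contains(region[1], region[2], iv[1, "start"], n)
    })
    f <- f[keep, ]
    f <- arrange(f, pmod(.data$start - region[1], n))
  } else {
    f <- arrange(f, .data$start)
  }
  sym <- f$name
  dup <- duplicated(sym) | duplicated(sym, fromLast = TRUE)
  sym[dup] <- paste0(sym[dup], "_", ave(seq_along(sym), sym, FUN = seq_along)[dup])
  tibble(symbol = sym, orientation = f$strand)
}
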