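#' Construct an annotated circular genome record
#'
#' The unit every pipeline stage consumes: a circular nucleotide sequence plus
#' an ordered feature table. Internal coordinates are 0-based half-open;
#' a feature interval that wraps the origin is stored as a single
#' `(start, end)` pair with `end < start`.
#'
#' @param identifier accession or name.
#' @param taxon display taxon name.
#' @param sequence nucleotide string over `A`, `C`, `G`, `T`, `N`.
#' @param features a feature tibble as built by [new_feature()] /
#'   [bind_features()]; may be empty.
#' @param circular logical; records lacking explicit topology are treated as
#'   circular with a warning upstream.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(identifier, taxon, sequence, features = empty_features(),
                          circular = TRUE) {
  sequence <- toupper(sequence)
  if (!grepl("^[ACGTN]*$", sequence)) {
    abort("sequence must be over the alphabet {A,C,G,T,N}")
  }
  n <- nchar(sequence)
  if (n == 0) abort("record has no sequence")
  features <- normalize_features(features, n, circular)
  structure(
    list(identifier = identifier, taxon = taxon, sequence = sequence,
         length = n, features = features, circular = circular),
    class = "genome_record")
}

#' Build one row of a feature table
#'
#' @param name normalized gene symbol (e.g. `"trnN-GUU"`, `"rps12"`).
#' @param kind one of `"protein"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"other"`.
#' @param strand `"+"` or `"-"`.
#' @param intervals integer matrix with columns `start`, `end` (0-based
#'   half-open); a wrapping interval has `end < start`.
#' @param pseudo logical pseudogene flag.
#' @param trans_spliced logical; exons transcribed from separate precursors.
#' @param note free text.
#' @return a one-row feature tibble.
#' @export
new_feature <- function(name, kind, strand, intervals, pseudo = FALSE,
                        trans_spliced = FALSE, note = NA_character_) {
  kind <- match.arg(kind, c("protein", "tRNA", "rRNA", "intron", "other"))
  if (!strand %in% c("+", "-")) abort("strand must be '+' or '-'")
  if (is.null(dim(intervals))) intervals <- matrix(intervals, ncol = 2, byrow = TRUE)
  if (nrow(intervals) == 0) abort("feature must have at least one interval")
  colnames(intervals) <- c("start", "end")
  storage.mode(intervals) <- "integer"
  tibble(name = normalize_symbol(name), kind = kind, strand = strand,
         start = intervals[1, 1], intervals = list(intervals),
         pseudo = pseudo, trans_spliced = trans_spliced, note = note)
}

#' @rdname new_feature
#' @param ... one-row feature tibbles to combine.
#' @export
bind_features <- function(...) bind_rows(...)

#' @rdname new_feature
#' @export
empty_features <- function() {
  tibble(name = character(), kind = character(), strand = character(),
         start = integer(), intervals = list(), pseudo = logical(),
         trans_spliced = logical(), note = character())
}

normalize_features <- function(features, n, circular) {
  if (nrow(features) == 0) return(features)
  features$intervals <- map(features$intervals, function(iv) {
    if (any(iv < 0) || any(iv > n)) {
      if (!circular) abort("feature extends beyond sequence on a non-circular record")
      iv <- pmod(iv, n)
    }
    if (any(iv[, "end"] == iv[, "start"])) abort("degenerate feature interval")
    iv
  })
  features$start <- map_int(features$intervals, ~ .x[1, "start"])
  arrange(features, start, name)
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s)\n", x$identifier, x$taxon))
  cat(sprintf("  %s bp, %s, %d features\n", format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear", nrow(x$features)))
  invisible(x)
}

# total feature length on the circle (sums all intervals, wrap-aware)
feature_span <- function(intervals, n) {
  sum(apply(intervals, 1, function(r) interval_len(r["start"], r["end"], n)))
}

#' Extract the spliced sequence of a feature
#'
#' Concatenates the feature's intervals in order (wrap-aware) and
#' reverse-complements on the minus strand.
#'
#' @param record a [genome_record()].
#' @param feature a one-row slice of `record$features`.
#' @return a nucleotide string.
#' @export
feature_sequence <- function(record, feature) {
  iv <- feature$intervals[[1]]
  parts <- apply(iv, 1, function(r) circ_substr(record$sequence, r["start"], r["end"]))
  s <- paste(parts, collapse = "")
  if (feature$strand == "-") s <- revcomp(s)
  s
}

# does interval (start,end) half-open, possibly wrapping, contain 0-based
# circular position p strictly inside (not at the start boundary)?
interval_contains <- function(start, end, p, n, strict = FALSE) {
  len <- interval_len(start, end, n)
  off <- pmod(p - start, n)
  if (strict) off > 0 && off < len else off < len
}
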