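#' Read an annotated genome from a GenBank flat file
#'
#' Parses the LOCUS/ORGANISM headers, the FEATURES table (including
#' `join`/`complement`/`order` compound locations) and the ORIGIN sequence of
#' a single-record GenBank flat file. Gene, CDS, tRNA and rRNA features are
#' captured; introns are materialized as features of kind `"intron"` from the
#' gaps between exon intervals of multi-interval CDS/tRNA features (skipped
#' for trans-spliced genes, whose "gaps" are not introns). Coordinates are
#' converted from GenBank 1-based inclusive to internal 0-based half-open; a
#' compound location spanning the origin of a circular record is folded into
#' a single wrapping interval.
#'
#' @param path path to a GenBank flat file.
#' @return a [genome_record()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort(sprintf("%s: no LOCUS line", path))
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  identifier <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  if (!circular) {
    warn(sprintf("%s: no explicit circular topology; treating as circular", identifier))
    circular <- TRUE
  }
  org <- grep("^  ORGANISM", lines, value = TRUE)
  taxon <- if (length(org)) trimws(sub("^  ORGANISM", "", org[1])) else identifier

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) abort(sprintf("%s: no ORIGIN sequence", identifier))
  end <- grep("^//", lines)
  end <- if (length(end)) end[end > ori[1]][1] else length(lines) + 1
  seq_lines <- lines[(ori[1] + 1):(end - 1)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(sequence)) abort(sprintf("%s: empty ORIGIN sequence", identifier))
  n <- nchar(sequence)

  feats <- parse_feature_table(lines, ori[1])
  features <- build_features(feats, n, circular, identifier)
  genome_record(identifier, taxon, sequence, features, circular = TRUE)
}

parse_feature_table <- function(lines, origin_at) {
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) return(list())
  block <- lines[(fstart[1] + 1):(origin_at - 1)]
  block <- block[!grepl("^(BASE COUNT|CONTIG)", block)]
  entries <- list()
  cur <- NULL
  for (ln in block) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) entries[[length(entries) + 1]] <- cur
      key <- trimws(substr(ln, 1, 21))
      rest <- trimws(substring(ln, 22))
      cur <- list(key = key, loc = rest, quals = character())
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
      } else if (length(cur$quals) == 0) {
        cur$loc <- paste0(cur$loc, txt)     # continued location
      } else {
        cur$quals[length(cur$quals)] <- paste(cur$quals[length(cur$quals)], txt)
      }
    }
  }
  if (!is.null(cur)) entries[[length(entries) + 1]] <- cur
  entries
}

# recursive-descent parse of a GenBank location string ->
# list(intervals = 1-based inclusive matrix in file order, strand)
parse_location <- function(loc) {
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- parse_location(sub("^complement\\((.*)\\)$", "\\1", loc))
    inner$strand <- if (inner$strand == "+") "-" else "+"
    return(inner)
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- split_toplevel(inner)
    parsed <- lapply(parts, parse_location)
    strands <- unique(map_chr(parsed, "strand"))
    iv <- do.call(rbind, lapply(parsed, `[[`, "intervals"))
    return(list(intervals = iv, strand = if (length(strands) == 1) strands else "+"))
  }
  m <- regmatches(loc, regexec("^<?(\\d+)(\\.\\.>?(\\d+))?$", loc))[[1]]
  if (length(m) == 0) abort(sprintf("cannot parse location '%s'", loc))
  a <- as.integer(m[2])
  b <- if (nzchar(m[4])) as.integer(m[4]) else a
  list(intervals = matrix(c(a, b), ncol = 2,
                          dimnames = list(NULL, c("start", "end"))), strand = "+")
}

split_toplevel <- function(x) {
  depth <- 0L; cuts <- integer()
  chars <- strsplit(x, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
  }
  starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, nchar(x))
  mapply(function(s, e) substr(x, s, e), starts, ends)
}

qual_value <- function(quals, name) {
  hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
}

build_features <- function(entries, n, circular, identifier) {
  keep <- c("gene", "CDS", "tRNA", "rRNA", "intron")
  rows <- list()
  typed_names <- character()
  for (e in entries) {
    if (!e$key %in% keep) next
    locp <- parse_location(e$loc)
    iv0 <- locp$intervals
    iv0[, "start"] <- iv0[, "start"] - 1L   # to 0-based half-open
    if (any(iv0[, "end"] > n)) {
      if (!circular) abort(sprintf("%s: feature beyond sequence end", identifier))
      iv0 <- pmod(iv0, n)
    }
    iv0 <- fold_origin(iv0, n)
    name <- qual_value(e$quals, "gene")
    if (is.na(name)) name <- qual_value(e$quals, "standard_name")
    if (is.na(name)) name <- qual_value(e$quals, "product")
    if (is.na(name)) name <- qual_value(e$quals, "locus_tag")
    if (is.na(name)) next
    pseudo <- any(grepl("^/pseudo(gene)?\\b|^/pseudo$", e$quals))
    trans <- any(grepl("^/trans_splicing", e$quals)) ||
      identical(qual_value(e$quals, "exception"), "trans-splicing")
    kind <- switch(e$key, CDS = "protein", tRNA = "tRNA", rRNA = "rRNA",
                   intron = "intron", gene = "other")
    rows[[length(rows) + 1]] <-
      new_feature(name, kind, locp$strand, iv0, pseudo = pseudo,
                  trans_spliced = trans, note = qual_value(e$quals, "note"))
    if (kind != "other") typed_names <- c(typed_names, normalize_symbol(name))
  }
  feats <- if (length(rows)) bind_rows(rows) else empty_features()
  # drop bare `gene` entries shadowed by a typed feature of the same symbol
  feats <- filter(feats, !(.data$kind == "other" & .data$name %in% typed_names))
  bind_rows(feats, derive_introns(feats, n))
}

# fold join(x..N, 1..y) on the circle into a single wrapping interval
fold_origin <- function(iv, n) {
  if (nrow(iv) < 2) return(iv)
  out <- iv[1, , drop = FALSE]
  for (i in 2:nrow(iv)) {
    last <- nrow(out)
    if (out[last, "end"] == n && iv[i, "start"] == 0) {
      out[last, "end"] <- iv[i, "end"]     # wrap: end < start
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

# introns from gaps between exon intervals of multi-part CDS/tRNA features
derive_introns <- function(feats, n) {
  hosts <- filter(feats, .data$kind %in% c("protein", "tRNA"),
                  !.data$trans_spliced,
                  map_int(.data$intervals, nrow) > 1)
  if (nrow(hosts) == 0) return(empty_features())
  rows <- list()
  for (i in seq_len(nrow(hosts))) {
    h <- hosts[i, ]
    iv <- h$intervals[[1]]
    m <- nrow(iv)
    exon_len <- apply(iv, 1, function(r) interval_len(r["start"], r["end"], n))
    for (k in seq_len(m - 1)) {
      gap <- matrix(c(iv[k, "end"], iv[k + 1, "start"]), ncol = 2,
                    dimnames = list(NULL, c("start", "end")))
      if (gap[1, 1] == gap[1, 2]) next
      # offset of the intron in coding coordinates (exon nt 5' of the gap)
      offset <- if (h$strand == "+") sum(exon_len[seq_len(k)]) else
        sum(exon_len[(k + 1):m])
      ordinal <- if (h$strand == "+") k else m - k
      rows[[length(rows) + 1]] <- new_feature(
        h$name, "intron", h$strand, gap,
        note = sprintf("host=%s;ordinal=%d;offset=%d", h$name, ordinal, offset))
    }
  }
  bind_rows(rows)
}

#' Read and write plain FASTA (sequences only)
#'
#' @param path file path.
#' @return `read_fasta()` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param sequences named character vector.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}
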