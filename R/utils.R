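#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join group_by
#'   summarise ungroup across row_number distinct pull rename if_else
#' @importFrom purrr map map_chr map_int map_dbl map_lgl map2 pmap imap keep
#' @importFrom stats setNames rpois
#' @importFrom utils head tail
NULL

# reverse complement for plain character vectors (one string per element)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# positive modulus (0-based circular coordinates)
pmod <- function(x, n) ((x %% n) + n) %% n

# circular substring of `seq` over the 0-based half-open window [start, end);
# end may exceed nchar(seq) or start may exceed end (wrap through the origin)
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  start <- pmod(start, n)
  end_raw <- end
  len <- if (end >= start) end - start else (n - start) + end
  if (start + len <= n) {
    substr(seq, start + 1, start + len)
  } else {
    paste0(substr(seq, start + 1, n), substr(seq, 1, start + len - n))
  }
}

# length of a possibly wrapping 0-based half-open interval on a circle of size n
interval_len <- function(start, end, n) {
  if (end > start) end - start else (n - start) + end
}

gc_percent <- function(seq) {
  freq <- Biostrings::letterFrequency(Biostrings::DNAString(seq), c("G", "C"))
  round(100 * sum(freq) / nchar(seq), 1)
}

#' Normalize a gene symbol into the shared cross-record symbol space
#'
#' Case conventions differ between annotation pipelines; comparisons across
#' records require a single symbol space. Transfer RNA symbols are folded to
#' the canonical `trn<AA>-<ANTICODON>` form, `ycf`/`rrn`/`rpl`/`rps` prefixes
#' are lower-cased, and the known matrix typo `cplPi363` is corrected to
#' `clpPi363`.
#'
#' @param x character vector of gene or intron symbols.
#' @return character vector of normalized symbols.
#' @export
#' @examples
#' normalize_symbol(c("TrnN-guu", "Ycf2", "cplPi363"))
normalize_symbol <- function(x) {
  out <- trimws(x)
  out[out == "cplPi363"] <- "clpPi363"
  # tRNA: trn + amino-acid letter(s) + anticodon, anticodon upper-cased
  is_trn <- grepl("^trn", out, ignore.case = TRUE)
  fix_trn <- function(s) {
    m <- regmatches(s, regexec("^trn(fM|[A-Za-z])[-_ ]?([ACGUTacgut]{3})?(.*)$", s,
                               ignore.case = TRUE))[[1]]
    if (length(m) == 0) return(s)
    aa <- m[2]
    if (tolower(aa) == "fm") aa <- "fM" else aa <- toupper(aa)
    anti <- toupper(chartr("Tt", "Uu", m[3]))
    rest <- m[4]
    if (!nzchar(anti)) return(paste0("trn", aa, rest))
    # positional intron labels stay concatenated (trnKUUUi37, not trnK-UUUi37)
    if (grepl("^i[0-9]+$", rest)) paste0("trn", aa, anti, rest)
    else paste0("trn", aa, "-", anti, rest)
  }
  out[is_trn] <- vapply(out[is_trn], fix_trn, character(1))
  pref <- grepl("^(ycf|rrn|rpl|rps|rpo|ndh|atp|psa|psb|pet|chl|clp|acc|ccs|cem|mat|inf|rbc)",
                out, ignore.case = TRUE)
  out[pref] <- paste0(tolower(substr(out[pref], 1, 3)), substring(out[pref], 4))
  out
}

path_package_file <- function(...) {
  system.file("extdata", ..., package = "plastomes", mustWork = TRUE)
}
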