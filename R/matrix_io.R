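#' Write a character matrix to CSV or NEXUS
#'
#' The CSV dialect stores taxa as rows and characters as columns with the
#' five-state alphabet `{1, 0, P, T, ?}` verbatim. The NEXUS dialect emits a
#' DATA block with `DATATYPE=STANDARD SYMBOLS="01"`: pseudogene, trans and
#' unknown states are recoded per the policy, and the policy used is recorded
#' in a comment inside the file so the encoding is self-describing.
#'
#' @param m a character-matrix tibble (see [content_matrix()]).
#' @param path output file path.
#' @param format `"csv"` or `"nexus"`.
#' @param policy recode policy for the NEXUS dialect (see [recode_binary()]).
#' @return the path, invisibly.
#' @export
write_matrix <- function(m, path, format = c("csv", "nexus"),
                         policy = "strict") {
  format <- match.arg(format)
  if (nrow(m) == 0 || ncol(m) < 2) abort("matrix is empty")
  validate_matrix(m)
  if (format == "csv") {
    readr::write_csv(m, path)
  } else {
    bin <- recode_binary(m, policy)
    chars <- setdiff(names(bin), "taxon")
    lines <- c(
      "#NEXUS",
      sprintf("[ recode policy: %s; P/T/? handled per plastomes::recode_binary ]",
              policy),
      "BEGIN DATA;",
      sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(bin), length(chars)),
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
      "  MATRIX")
    width <- max(nchar(bin$taxon)) + 2
    for (i in seq_len(nrow(bin))) {
      states <- unlist(bin[i, chars], use.names = FALSE)
      states <- ifelse(is.na(states), "?", as.character(states))
      lines <- c(lines, sprintf("    %-*s %s", width, bin$taxon[i],
                                paste(states, collapse = "")))
    }
    lines <- c(lines, "  ;", "END;")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a character matrix back from disk
#'
#' The CSV path restores the five-state matrix exactly; the NEXUS path (via
#' [ape::read.nexus.data()]) restores the binary recode with `?` as `NA`.
#'
#' @param path file path.
#' @param format `"csv"` or `"nexus"`.
#' @return a character-matrix tibble (CSV) or binary tibble (NEXUS).
#' @export
read_matrix <- function(path, format = c("csv", "nexus")) {
  format <- match.arg(format)
  if (format == "csv") {
    m <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
    validate_matrix(m)
    return(m)
  }
  nx <- ape::read.nexus.data(path)
  states <- do.call(rbind, nx)
  out <- tibble(taxon = rownames(states))
  for (j in seq_len(ncol(states))) {
    v <- states[, j]
    out[[paste0("char", j)]] <- suppressWarnings(as.integer(v))
  }
  out
}
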