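#' Positional intron nomenclature
#'
#' Names an intron by the nucleotide position of its insertion site within a
#' reference copy of the host gene: the host exon concatenation is globally
#' aligned to the reference coding sequence (match 1, mismatch -1, gap open
#' -4, gap extend -1) and the host coordinate immediately 5' of the intron is
#' mapped to its aligned reference coordinate. If the insertion column falls
#' in a reference gap, the position resolves to the nearest aligned
#' reference position 5' of the site. Hosts aligning at below 50% identity
#' are rejected so introns are never named against the wrong reference.
#'
#' @param host_exons concatenated exon sequence of the host gene.
#' @param intron_offset 1-based host coding coordinate of the last exon
#'   nucleotide before the intron.
#' @param reference_cds reference coding sequence.
#' @param host host gene symbol, used to form the label (hyphens are dropped,
#'   so the tRNA convention `trnGUCCi23` comes out right).
#' @return list with `host`, `position` (1-based reference coordinate) and
#'   `label` (`"<gene>i<position>"`).
#' @export
name_intron <- function(host_exons, intron_offset, reference_cds, host = "gene") {
  if (intron_offset < 1 || intron_offset > nchar(host_exons)) {
    abort("intron_offset outside the host coding sequence")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(host_exons),
    subject = Biostrings::DNAString(reference_cds),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  if (Biostrings::pid(aln) < 50) {
    abort(sprintf("host aligns to reference at %.1f%% identity (<50%%): unalignable",
                  Biostrings::pid(aln)))
  }
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  host_pos <- cumsum(pat != "-")
  ref_pos <- cumsum(sub != "-")
  col <- which(host_pos == intron_offset & pat != "-")[1]
  if (is.na(col)) abort("intron_offset not covered by the alignment")
  # nearest aligned reference position 5' of the insertion column
  cols5 <- seq_len(col)
  aligned5 <- cols5[sub[cols5] != "-"]
  position <- if (length(aligned5)) ref_pos[max(aligned5)] else 0L
  if (position < 1) abort("insertion site precedes the aligned reference")
  label <- paste0(gsub("-", "", host), "i", position)
  list(host = host, position = as.integer(position), label = label)
}
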