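# Pairwise sequence alignment and residue-number mapping between
# homologous structures.

.check_aa_alphabet <- function(seq, label) {
  letters1 <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters1, unname(.aa3_to_1))
  if (length(bad) > 0) {
    abort(sprintf(
      "non-standard amino-acid character(s) in %s: %s",
      label, paste(bad, collapse = ", ")
    ))
  }
  invisible(seq)
}

#' Global pairwise alignment of two amino-acid sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (BLOSUM62, gap open 10, gap extend 0.5 by default). Percent identity is
#' the number of identical aligned columns divided by the number of columns
#' that carry a residue on both sides (gap columns are excluded from the
#' denominator).
#'
#' @param seq_a,seq_b Amino-acid sequences (single strings, standard
#'   one-letter alphabet, upper case).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param substitution_matrix Name of the substitution matrix.
#' @return An `aa_alignment`: list with `aligned_a`, `aligned_b` (gapped
#'   strings of equal length), `percent_identity`, `n_identical`,
#'   `n_aligned_columns` and `score`.
#' @export
#' @examples
#' al <- pairwise_align("ACDE", "ACNE")
#' al$percent_identity # 75
pairwise_align <- function(seq_a, seq_b, gap_open = 10, gap_extend = 0.5,
                           substitution_matrix = "BLOSUM62") {
  if (!nzchar(seq_a) || !nzchar(seq_b)) abort("sequences must be non-empty")
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  .check_aa_alphabet(seq_a, "seq_a")
  .check_aa_alphabet(seq_b, "seq_b")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global"
  )
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  n_id <- sum(ca[both] == cb[both])
  out <- list(
    aligned_a = aligned_a, aligned_b = aligned_b,
    percent_identity = 100 * n_id / sum(both),
    n_identical = n_id, n_aligned_columns = sum(both),
    score = Biostrings::score(pa)
  )
  class(out) <- "aa_alignment"
  out
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf(
    "<aa_alignment> %d columns, %.1f%% identity (%d/%d aligned columns)\n",
    nchar(x$aligned_a), x$percent_identity, x$n_identical, x$n_aligned_columns
  ))
  invisible(x)
}

#' Map residue numbering through an alignment
#'
#' Only alignment columns carrying a residue on both sides produce a pair;
#' the resulting map is one-to-one and monotone in both numberings.
#'
#' @param alignment An `aa_alignment` from [pairwise_align()].
#' @param resno_a,resno_b Optional author residue numbers for the two
#'   sequences (e.g. from [calpha_trace()]); defaults to 1-based sequence
#'   positions.
#' @return A tibble with columns `pos_a`, `pos_b` (sequence positions),
#'   `resno_a`, `resno_b`, `aa_a`, `aa_b`, `match`.
#' @export
map_residue_numbering <- function(alignment, resno_a = NULL, resno_b = NULL) {
  stopifnot(inherits(alignment, "aa_alignment"))
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  pos_a <- cumsum(ca != "-")
  pos_b <- cumsum(cb != "-")
  both <- ca != "-" & cb != "-"
  pa <- pos_a[both]
  pb <- pos_b[both]
  resno_a <- resno_a %||% seq_len(max(pos_a))
  resno_b <- resno_b %||% seq_len(max(pos_b))
  if (length(resno_a) < max(pos_a) || length(resno_b) < max(pos_b)) {
    abort("residue-number vectors shorter than the aligned sequences")
  }
  tibble(
    pos_a = pa, pos_b = pb,
    resno_a = resno_a[pa], resno_b = resno_b[pb],
    aa_a = ca[both], aa_b = cb[both],
    match = ca[both] == cb[both]
  )
}
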