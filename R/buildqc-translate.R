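#' Selenocysteine-aware CDS translation
#'
#' Translates a coding sequence under the standard genetic code, with two
#' audit-specific behaviours: a TGA codon whose (1-based) index appears in
#' `sec_positions` is read as selenocysteine (U) instead of terminating —
#' the recoding that naive annotation pipelines miss when they assign
#' selenoproteins a premature stop — and codons containing ambiguous N bases
#' translate to X rather than failing.
#'
#' @param cds coding sequence (ACGTN), length at least 3; trailing bases that
#'   do not fill a codon are ignored.
#' @param sec_positions integer vector of 1-based codon indices recoded
#'   UGA -> Sec.
#' @return a list: `protein` (stop excluded), `premature_stop` (`TRUE` when an
#'   in-frame stop occurs before the final codon), `stop_codon_index` (1-based
#'   codon index of the first stop, `NA` if none).
#' @examples
#' translate_cds("ATGTGATAA", sec_positions = 2) # "MU", no premature stop
#' translate_cds("ATGTGATAA")                    # "M", premature stop
#' @export
translate_cds <- function(cds, sec_positions = integer(0)) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) stop_input("CDS must be at least one codon long")
  if (str_detect(cds, "[^ACGTN]")) stop_input("CDS alphabet is ACGTN")
  n_cod <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  codons <- str_sub(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  is_stop <- aa == "*"
  sec <- intersect(as.integer(sec_positions), seq_len(n_cod))
  recode <- sec[codons[sec] == "TGA"]
  aa[recode] <- "U"
  is_stop[recode] <- FALSE

  first_stop <- if (any(is_stop)) which(is_stop)[1] else NA_integer_
  premature <- !is.na(first_stop) && first_stop < n_cod
  keep <- if (is.na(first_stop)) n_cod else first_stop - 1L
  list(
    protein = paste(aa[seq_len(keep)], collapse = ""),
    premature_stop = premature,
    stop_codon_index = first_stop
  )
}

#' Protein-length checksum
#'
#' The audit's primary per-gene test: the predicted protein from a build must
#' have exactly the curated reference length (stop codons excluded).
#'
#' @param predicted predicted protein sequence or its length.
#' @param reference reference protein sequence or its length.
#' @return a one-row tibble: `predicted_length`, `reference_length`, `pass`
#'   (`TRUE` iff lengths are equal) and `ratio` (predicted/reference).
#' @examples
#' checksum_protein(strrep("A", 264), strrep("A", 865)) # ratio ~0.305
#' @export
checksum_protein <- function(predicted, reference) {
  len <- function(x) {
    if (is.character(x)) nchar(x) else as.integer(x)
  }
  p <- len(predicted); r <- len(reference)
  if (length(p) != 1 || length(r) != 1 || is.na(p) || is.na(r) ||
      p < 1 || r < 1) {
    stop_input("predicted and reference proteins must be non-empty")
  }
  tibble(predicted_length = p, reference_length = r, pass = p == r,
         ratio = p / r)
}
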