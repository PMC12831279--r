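the_matrix_cache <- new.env(parent = emptyenv())

#' Protein scoring matrix used throughout the package
#'
#' BLOSUM62 extended for the residues a genome audit encounters: selenocysteine
#' (U) scores as cysteine, and any-residue X scores 0 against everything.
#'
#' @return an integer substitution matrix over the extended amino-acid
#'   alphabet.
#' @export
audit_scoring_matrix <- function() {
  if (!is.null(the_matrix_cache$blosum)) return(the_matrix_cache$blosum)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  u <- m["C", , drop = TRUE]
  m <- rbind(m, U = u)
  m <- cbind(m, U = c(u, m["C", "C"]))
  m["X", ] <- 0L
  m[, "X"] <- 0L
  the_matrix_cache$blosum <- m
  m
}

#' Local (Smith-Waterman) protein alignment
#'
#' Optimal local alignment of two protein sequences under an explicit scoring
#' scheme; the computational stand-in for a protein BLAST search. Scores are
#' symmetric in the two sequences.
#'
#' @param seq_a,seq_b protein sequences (20 AA alphabet plus U for Sec and X).
#' @param matrix substitution matrix; defaults to [audit_scoring_matrix()].
#' @param gap_open,gap_extend affine gap penalties (positive numbers).
#' @return a one-row tibble: `score`, `identity` (matches over aligned
#'   columns; `NA` with `undefined = TRUE` for an empty input), and
#'   `aligned_length`.
#' @examples
#' pairwise_protein_align("HEAGAWGHEE", "PAWHEAE")
#' @export
pairwise_protein_align <- function(seq_a, seq_b, matrix = audit_scoring_matrix(),
                                   gap_open = 11, gap_extend = 1) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    return(tibble(score = 0, identity = NA_real_, aligned_length = 0L,
                  undefined = TRUE))
  }
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b), type = "local",
    substitutionMatrix = matrix, gapOpening = gap_open, gapExtension = gap_extend
  )
  w <- Biostrings::nchar(al)
  tibble(
    score = as.numeric(Biostrings::score(al)),
    identity = if (w > 0) Biostrings::nmatch(al) / w else NA_real_,
    aligned_length = as.integer(w),
    undefined = w == 0
  )
}

# all-vs-all local alignment scores: rows = set_a, cols = set_b
protein_score_matrix <- function(set_a, set_b, matrix = audit_scoring_matrix(),
                                 gap_open = 11, gap_extend = 1, type = "local") {
  a <- Biostrings::AAStringSet(set_a)
  out <- matrix(0, length(set_a), length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (j in seq_along(set_b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      a, Biostrings::AAString(set_b[[j]]), type = type,
      substitutionMatrix = matrix, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  out
}

# identity of the best local alignment, for thresholding ortholog candidates
protein_identity <- function(seq_a, seq_b, matrix = audit_scoring_matrix()) {
  pairwise_protein_align(seq_a, seq_b, matrix)$identity
}

# nucleotide score matrix for the RNA orthology tier
nuc_score_matrix <- function(set_a, set_b, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2) {
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  a <- Biostrings::DNAStringSet(set_a)
  out <- matrix(0, length(set_a), length(set_b),
                dimnames = list(names(set_a), names(set_b)))
  for (j in seq_along(set_b)) {
    out[, j] <- Biostrings::pairwiseAlignment(
      a, Biostrings::DNAString(set_b[[j]]), type = "local",
      substitutionMatrix = sub, gapOpening = gap_open,
      gapExtension = gap_extend, scoreOnly = TRUE
    )
  }
  out
}
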