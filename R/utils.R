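#' Round half away from zero
#'
#' Base `round()` rounds halves to even; reported percentages and ratios here
#' follow the print convention of rounding halves up (e.g. 58.85 -> 58.9).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(2.25, 1) # 2.3
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage with half-up rounding
#'
#' @param k numerator count.
#' @param n denominator count.
#' @param digits decimal places reported (default 1).
#' @return `100 * k / n`, rounded half-up.
#' @examples
#' pct(3614, 6135) # 58.9
#' @export
pct <- function(k, n, digits = 1) {
  stopifnot(all(n > 0))
  round_half_up(100 * k / n, digits)
}

# reverse complement for plain character vectors (ACGTN, case-insensitive)
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  unname(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)
  )))
}

# run body under a fixed seed when one is supplied; otherwise use current RNG
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# deterministic sub-seed per operator: one user seed drives every stage, each
# stage offset by a fixed constant so adding a stage does not reshuffle others
sub_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stop_input <- function(msg, ...) abort(sprintf(msg, ...), class = "buildaudit_input_error")

# exact amino-acid anchors (build + query in one shot; desk-scale subjects)
cpp_aa_anchors <- function(pattern, subject, k = 6L, max_occ = 512L) {
  cpp_index_query(cpp_index_build(subject, as.integer(k), TRUE),
                  pattern, as.integer(max_occ))
}
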