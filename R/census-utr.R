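#' Region-wise mRNA conservation: 5'UTR, CDS, 3'UTR
#'
#' Aligns the three regions of two orthologous mRNAs separately (global
#' alignment, identity = matches over aligned columns) and flags low UTR
#' conservation — the signature of builds that truncate or mis-assemble the
#' untranslated ends while the coding region is intact. A region that is
#' empty on either side has undefined identity and is never flagged low.
#'
#' @param ref list/one-row tibble with `mrna`, `cds_start`, `cds_end`
#'   (1-based transcript coordinates of the CDS).
#' @param ortholog same structure for the other species.
#' @param low5,low3 identity thresholds below which the UTR counts as lowly
#'   conserved.
#' @return one-row tibble: `utr5_identity`, `cds_identity`, `utr3_identity`,
#'   `low5`, `low3`.
#' @export
utr_conservation <- function(ref, ortholog, low5 = 0.60, low3 = 0.60) {
  for (x in list(ref, ortholog)) {
    if (x$cds_start < 1 || x$cds_end > nchar(x$mrna) || x$cds_start > x$cds_end) {
      stop_input("CDS boundaries must lie within the mRNA")
    }
  }
  region <- function(x, which) {
    switch(which,
      utr5 = str_sub(x$mrna, 1L, x$cds_start - 1L),
      cds = str_sub(x$mrna, x$cds_start, x$cds_end),
      utr3 = str_sub(x$mrna, x$cds_end + 1L, nchar(x$mrna))
    )
  }
  ident <- function(a, b) {
    if (nchar(a) == 0 || nchar(b) == 0) return(NA_real_)
    al <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                        Biostrings::DNAString(b),
                                        type = "global")
    Biostrings::nmatch(al) / Biostrings::nchar(al)
  }
  i5 <- ident(region(ref, "utr5"), region(ortholog, "utr5"))
  ic <- ident(region(ref, "cds"), region(ortholog, "cds"))
  i3 <- ident(region(ref, "utr3"), region(ortholog, "utr3"))
  tibble(
    utr5_identity = i5, cds_identity = ic, utr3_identity = i3,
    low5 = !is.na(i5) && i5 < low5,
    low3 = !is.na(i3) && i3 < low3
  )
}
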