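#' Detect insertion/deletion events from a spliced locus alignment
#'
#' Walks the inter-block gaps of one mapped locus and emits one event per gap
#' whose transcript-side and genome-side lengths differ, skipping junctions
#' that look like introns (genomic gap of at least `min_intron` with a
#' transcript-side gap of at most `max_qgap_intron`). Events are reported in
#' build coordinates: an `insertion` means the build carries extra bases
#' relative to the transcript, a `deletion` means bases are missing from the
#' build. `frameshifting` is `TRUE` exactly when the event lies inside the
#' CDS and its length is not a multiple of 3.
#'
#' @param locus one row of a [map_transcript()] result (or a list with
#'   `blocks`, `chrom`, `strand`).
#' @param cds_intervals optional tibble/data frame with `start`, `end`
#'   (transcript coordinates, alignment orientation) delimiting the CDS; with
#'   `NULL`, no event is called frameshifting.
#' @param params mapper parameters (shares the intron-calling thresholds).
#' @return a tibble of events sorted by genomic position: `chrom`,
#'   `position`, `kind`, `length`, `tpos`, `frameshifting`.
#' @export
detect_indels <- function(locus, cds_intervals = NULL, params = map_params()) {
  bl <- if (is.data.frame(locus)) locus$blocks[[1]] else locus$blocks
  if (is.null(bl)) stop_input("locus has no alignment blocks")
  chrom <- if (!is.null(locus$chrom)) locus$chrom[1] else NA_character_
  if (nrow(bl) < 2) return(empty_indels())
  if (any(diff(bl$tstart) < 0) || any(diff(bl$sstart) < 0)) {
    stop_input("alignment blocks are not co-linear")
  }
  i <- seq_len(nrow(bl))[-1]
  qgap <- bl$tstart[i] - bl$tend[i - 1L] - 1L
  sgap <- bl$sstart[i] - bl$send[i - 1L] - 1L
  is_intron <- sgap >= params$min_intron & qgap <= params$max_qgap_intron
  keep <- !is_intron & qgap != sgap
  if (!any(keep)) return(empty_indels())
  d <- (sgap - qgap)[keep]
  tpos <- bl$tend[i - 1L][keep] + 1L
  in_cds <- if (is.null(cds_intervals)) rep(FALSE, length(tpos)) else {
    map_lgl(tpos, function(tp) {
      any(tp >= cds_intervals$start & tp <= cds_intervals$end)
    })
  }
  ev <- tibble(
    chrom = chrom, position = bl$send[i - 1L][keep] + 1L,
    kind = ifelse(d > 0, "insertion", "deletion"), length = abs(d),
    tpos = tpos, frameshifting = in_cds & (abs(d) %% 3L != 0L)
  )
  arrange(ev, .data$position)
}

empty_indels <- function() {
  tibble(chrom = character(), position = integer(), kind = character(),
         length = integer(), tpos = integer(), frameshifting = logical())
}

# CDS transcript interval flipped into alignment orientation for minus loci
cds_in_alignment_orientation <- function(cds_start, cds_end, tx_len, strand) {
  if (strand == "+") tibble(start = cds_start, end = cds_end)
  else tibble(start = tx_len - cds_end + 1L, end = tx_len - cds_start + 1L)
}
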