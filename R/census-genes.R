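#' Classify genes as intronless, CDS-intronless or multi-exon
#'
#' Two flavours of intronless gene matter for annotation audits: genes made
#' of a single exon (`true_intronless`) and genes whose protein-coding region
#' sits entirely within one exon while introns interrupt only the UTRs
#' (`cds_intronless`). Everything else is `multi_exon`.
#'
#' @param annotation feature tibble (as from [emit_genome()]) with `exon` and
#'   `CDS` rows carrying a `gene_id` column; or a tibble of exon intervals
#'   plus `cds` ranges for a single gene.
#' @return a tibble: `gene_id`, `n_exons`, `intronless_class`.
#' @export
detect_intronless <- function(annotation) {
  genes <- unique(annotation$gene_id[annotation$type == "gene"])
  if (length(genes) == 0) genes <- unique(annotation$gene_id)
  out <- map(genes, function(g) {
    ex <- annotation[annotation$gene_id == g & annotation$type == "exon", ]
    cds <- annotation[annotation$gene_id == g & annotation$type == "CDS", ]
    if (nrow(cds) == 0) stop_input("gene '%s' has no CDS", g)
    if (nrow(ex) == 0) stop_input("gene '%s' has no exons", g)
    cls <- if (nrow(ex) == 1) {
      "true_intronless"
    } else {
      cds_lo <- min(cds$start); cds_hi <- max(cds$end)
      inside_one <- any(ex$start <= cds_lo & ex$end >= cds_hi)
      if (inside_one) "cds_intronless" else "multi_exon"
    }
    tibble(gene_id = g, n_exons = nrow(ex), intronless_class = cls)
  })
  bind_rows(out)
}

#' Confidence score for a candidate readthrough gene
#'
#' The 0-4 evidence scale for readthrough (conjoined) gene predictions:
#' 0 = no transcript could be predicted; 1 = predicted but no evidence of
#' existence in any other species; 2 = predicted with limited cross-species
#' evidence but no demonstrated pig transcription; 3 = predicted, limited
#' cross-species evidence (two species or fewer) and transcription
#' demonstrated in pig; 4 = predicted, evidence in two or more species and
#' transcription demonstrated in pig.
#'
#' @param transcript_predicted logical, can the readthrough transcript be
#'   predicted at all.
#' @param n_other_species_with_transcript number of other species with the
#'   transcript (integer, >= 0).
#' @param pig_transcription_evidence logical, transcription demonstrated in
#'   the pig.
#' @return integer score(s) 0-4 (vectorized).
#' @export
score_readthrough <- function(transcript_predicted,
                              n_other_species_with_transcript,
                              pig_transcription_evidence) {
  if (is.data.frame(transcript_predicted)) {
    ev <- transcript_predicted
    return(score_readthrough(ev$transcript_predicted,
                             ev$n_other_species_with_transcript,
                             ev$pig_transcription_evidence))
  }
  n <- as.integer(n_other_species_with_transcript)
  if (any(n < 0, na.rm = TRUE)) stop_input("species evidence count must be >= 0")
  out <- integer(length(transcript_predicted))
  pred <- as.logical(transcript_predicted)
  pig <- as.logical(pig_transcription_evidence)
  out[pred & pig & n >= 2L] <- 4L
  out[pred & pig & n < 2L] <- 3L
  out[pred & !pig & n >= 1L] <- 2L
  out[pred & !pig & n == 0L] <- 1L
  out
}

#' Exon-count and splice-variant conservation between two orthologs
#'
#' Reports the exon-count difference (reference minus ortholog; a positive
#' delta in a curated-vs-build comparison means the build under-annotates
#' exons) and, when a variant table is supplied, the fraction of reference
#' splice variants conserved.
#'
#' @param n_exons_a,n_exons_b exon counts (>= 1).
#' @param variants optional tibble with a logical `conserved` column, one row
#'   per reference splice variant.
#' @return one-row tibble: `exon_delta`, `variant_conserved_fraction`.
#' @export
splice_conservation <- function(n_exons_a, n_exons_b, variants = NULL) {
  stopifnot(n_exons_a >= 1, n_exons_b >= 1)
  frac <- if (!is.null(variants) && nrow(variants) > 0) {
    sum(variants$conserved) / nrow(variants)
  } else NA_real_
  tibble(exon_delta = as.integer(n_exons_a) - as.integer(n_exons_b),
         variant_conserved_fraction = frac)
}
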