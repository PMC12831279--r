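#' Classification thresholds for the per-gene error protocol
#'
#' @param c_present minimum single-locus coverage for the sequence to count
#'   as present in the build at all.
#' @param c_single coverage below which no single locus is considered to hold
#'   the whole gene (the split-locus boundary).
#' @param c_joint minimum summed coverage for two or more partial loci to
#'   jointly account for the transcript.
#' @return a list of thresholds.
#' @export
classify_params <- function(c_present = 0.30, c_single = 0.90, c_joint = 0.80) {
  list(c_present = c_present, c_single = c_single, c_joint = c_joint)
}

#' Classify one gene against a build
#'
#' Applies the audit's fixed decision order to the mapped loci of one gene:
#' (a) no locus covering at least `c_present` of the transcript ->
#' `sequence_not_present`; (b) two or more partial loci that jointly cover
#' the transcript, none individually reaching `c_single` ->
#' `split_multiple_loci`; (c) the locus lies under an annotated feature
#' carrying two or more distinct protein products ->
#' `multiple_genes_one_locus`; (d) no annotated gene feature over the locus
#' -> `not_annotated`; (e) the protein-length checksum fails, or the
#' predicted protein carries a premature stop, or a frameshifting indel or an
#' ambiguous-N fill overlaps the CDS -> `error_in_locus`; otherwise (f)
#' `correct`.
#'
#' @param gene one row of the truth model tibble (see
#'   [generate_gene_models()]).
#' @param alignments loci from [map_transcript()] for this gene's transcript
#'   against the build.
#' @param build a `ba_build` (or `ba_truth`) with `genome` and `annotation`.
#' @param params thresholds from [classify_params()].
#' @param map_pars mapper parameters used to produce `alignments`.
#' @return a one-row tibble: `gene_id`, `category`, the evidence fields
#'   (`n_loci`, `checksum_pass`, `has_premature_stop`, `has_frameshift`,
#'   `n_filled`) and `pseudogene_flag`.
#' @export
classify_gene <- function(gene, alignments, build, params = classify_params(),
                          map_pars = map_params()) {
  if (is.null(build$annotation)) stop_input("build has no annotation")
  loci <- alignments
  n_loci <- nrow(loci)
  ev <- list(n_loci = n_loci, checksum_pass = NA, has_premature_stop = NA,
             has_frameshift = NA, n_filled = NA)
  done <- function(category, pseudo = FALSE) {
    tibble(gene_id = gene$gene_id, category = category,
           n_loci = as.integer(ev$n_loci), checksum_pass = ev$checksum_pass,
           has_premature_stop = ev$has_premature_stop,
           has_frameshift = ev$has_frameshift, n_filled = ev$n_filled,
           pseudogene_flag = pseudo)
  }

  # (a) present at all?
  if (n_loci == 0 || max(loci$coverage) < params$c_present) {
    return(done("sequence_not_present"))
  }
  # (b) fragmented across loci?
  if (n_loci >= 2 && max(loci$coverage) < params$c_single &&
      sum(loci$coverage) >= params$c_joint) {
    return(done("split_multiple_loci"))
  }
  best <- loci[which.max(loci$coverage), ]
  ann <- build$annotation
  over <- ann[ann$type == "gene" & ann$seqid == best$chrom &
                ann$end >= best$start & ann$start <= best$end, ]
  # (c) one locus, several distinct annotated proteins?
  if (nrow(over) > 0) {
    for (gi in seq_len(nrow(over))) {
      prods <- locus_protein_products(over$ID[gi], ann, build$genome)
      if (length(unique(prods)) >= 2) return(done("multiple_genes_one_locus"))
    }
  }
  # (d) annotated at all?
  if (nrow(over) == 0) return(done("not_annotated"))

  # (e)/(f): checksum, stops, frameshifts, N fills on the annotated product
  ov_len <- pmin(over$end, best$end) - pmax(over$start, best$start)
  feat <- over[which.max(ov_len), ]
  cds_seq <- annotated_cds_seq(feat$ID, gene$gene_id, ann, build$genome)
  sec <- if (identical(gene$gene_class, "selenoprotein")) gene$sec_codons[[1]] else integer(0)
  ev$n_filled <- str_detect(cds_seq, "N")
  if (nchar(cds_seq) >= 3) {
    tr <- translate_cds(cds_seq, sec)
    ev$has_premature_stop <- tr$premature_stop
    cs <- checksum_protein(max(1L, nchar(tr$protein)),
                           gene$expected_protein_length)
    ev$checksum_pass <- cs$pass
  } else {
    ev$has_premature_stop <- TRUE
    ev$checksum_pass <- FALSE
  }
  cds_aln <- cds_in_alignment_orientation(gene$cds_start, gene$cds_end,
                                          gene$tx_len, best$strand)
  indels <- detect_indels(best, cds_aln, map_pars)
  # an annotated CDS whose nucleotide length shifted out of frame relative to
  # the curated CDS is frameshifted even when the alignment absorbed the edit
  truth_cds_len <- gene$cds_end - gene$cds_start + 1L
  len_shift <- nchar(cds_seq) - truth_cds_len
  ev$has_frameshift <- any(indels$frameshifting) ||
    (len_shift != 0L && len_shift %% 3L != 0L)

  if (!isTRUE(ev$checksum_pass) || isTRUE(ev$has_premature_stop) ||
      isTRUE(ev$has_frameshift) || isTRUE(ev$n_filled)) {
    pseudo <- isTRUE(ev$has_premature_stop) && !isTRUE(ev$n_filled)
    return(done("error_in_locus", pseudo = pseudo))
  }
  done("correct")
}

# distinct translated CDS products under one annotated gene container
locus_protein_products <- function(gene_feature_id, ann, genome) {
  mrnas <- ann[ann$type == "mRNA" & !is.na(ann$Parent) &
                 ann$Parent == gene_feature_id, ]
  map_chr(mrnas$ID, function(tid) {
    cds <- ann[ann$type == "CDS" & ann$Parent == tid, ]
    if (nrow(cds) == 0) return(NA_character_)
    splice_cds(cds, genome)
  })
}

annotated_cds_seq <- function(gene_feature_id, truth_gene_id, ann, genome) {
  mrnas <- ann[ann$type == "mRNA" & !is.na(ann$Parent) &
                 ann$Parent == gene_feature_id, ]
  own <- mrnas[mrnas$ID == paste0(truth_gene_id, ".t1"), ]
  tid <- if (nrow(own) > 0) own$ID[1] else mrnas$ID[1]
  cds <- ann[ann$type == "CDS" & ann$Parent == tid, ]
  if (is.na(tid) || nrow(cds) == 0) return("")
  splice_cds(cds, genome)
}

splice_cds <- function(cds, genome) {
  cds <- cds[order(cds$start), ]
  pieces <- str_sub(genome[[cds$seqid[1]]], cds$start, cds$end)
  spliced <- paste(pieces, collapse = "")
  if (cds$strand[1] == "-") revcomp(spliced) else spliced
}

#' Classify every gene of a truth library against a build
#'
#' Maps each truth transcript to the build (indexing the build genome once),
#' classifies it with [classify_gene()], and returns the per-gene calls.
#'
#' @param truth a `ba_truth` object.
#' @param build a `ba_build` (use `truth` itself to audit the uncorrupted
#'   build).
#' @param params,map_pars thresholds for [classify_gene()] and
#'   [map_transcript()].
#' @return a tibble of per-gene calls (one row per truth gene).
#' @export
classify_build <- function(truth, build, params = classify_params(),
                           map_pars = map_params()) {
  idx <- genome_index(build$genome, map_pars$k)
  calls <- map(seq_len(nrow(truth$models)), function(i) {
    gene <- truth$models[i, ]
    loci <- map_transcript(gene$transcript, idx, map_pars,
                           transcript_id = gene$gene_id)
    classify_gene(gene, loci, build, params, map_pars)
  })
  bind_rows(calls)
}
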