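#' Indel-rate injection-recovery experiment
#'
#' Generates one large synthetic coding truth set (single-exon genes so the
#' coding space is contiguous), then repeatedly corrupts it with coding
#' indels injected as a homogeneous Poisson process at the given mean
#' spacing, re-detects the indels by aligning each truth transcript back to
#' its corrupted locus, and estimates bp-per-indel with its exact Poisson
#' 95% interval. Events closer than the aligner's anchor resolution merge
#' into one, so the estimator applies the standard counting dead-time
#' correction (surveyed bp minus events times resolution window) before
#' forming the rate. One row is returned per injection seed.
#'
#' @param spacing_bp mean bp between injected coding indels.
#' @param n_genes,codons_per_gene coding-space geometry; the defaults give
#'   slightly over 50 Mb of CDS in 50 long single-exon loci.
#' @param seeds integer vector of injection seeds.
#' @param truth_seed seed for the (single) truth generation.
#' @param dialect indel representation dialect.
#' @param stride subject seed-sampling stride used for the locus re-mapping
#'   (event counts are stride-insensitive; only block ends blur).
#' @return tibble per seed: `seed`, `n_injected`, `n_detected`,
#'   `bp_per_indel`, `ci_lo`, `ci_hi`, `covers_truth`.
#' @export
indel_rate_experiment <- function(spacing_bp = 12465, n_genes = 50L,
                                  codons_per_gene = 334000L, seeds = 1:100,
                                  truth_seed = 1L, dialect = "truncate",
                                  stride = 8L) {
  cfg <- sim_config(
    n_multi_exon = 0, n_true_intronless = n_genes, n_cds_intronless = 0,
    n_selenoprotein = 0, cds_codons = c(codons_per_gene, codons_per_gene),
    utr5 = c(60L, 120L), utr3 = c(60L, 120L), p_minus = 0.25
  )
  models <- generate_gene_models(cfg, seed = truth_seed)
  truth <- emit_genome(models, intergenic = c(200L, 500L),
                       genes_per_chrom = n_genes, seed = truth_seed)
  covered_bp <- sum(models$cds_end - models$cds_start + 1L)
  prof <- error_profile(indel_spacing_bp = spacing_bp, dialect = dialect)
  # megabase-scale loci: longer seeds keep random k-mer collisions out of
  # the anchor chains
  mp <- map_params(k = 24L, stride = stride)

  rows <- map(seeds, function(sd) {
    inj <- inject_build_errors(truth, prof, seed = sd)
    n_inj <- nrow(attr(inj$ledger, "indel_positions") %||% tibble())
    ann <- inj$build$annotation
    genes <- ann[ann$type == "gene", ]
    n_det <- 0L
    for (i in seq_len(nrow(truth$models))) {
      g <- truth$models[i, ]
      row <- genes[genes$gene_id == g$gene_id, ]
      win <- str_sub(inj$build$genome[[row$seqid[1]]],
                     max(1L, row$start - 100L), row$end + 100L)
      loci <- map_transcript(g$transcript, setNames(win, "w"), mp,
                             transcript_id = g$gene_id)
      if (nrow(loci) == 0) next
      best <- loci[1, ]
      cds_aln <- cds_in_alignment_orientation(g$cds_start, g$cds_end,
                                              g$tx_len, best$strand)
      n_det <- n_det + nrow(detect_indels(best, cds_aln, mp))
    }
    # resolution (dead-time) correction: two events closer than the anchor
    # resolution w = k + stride - 1 cannot be separated, so each observed
    # event blinds a window of w bp — the standard non-paralyzable counter
    # correction subtracts that blinded space from the surveyed coverage
    w <- mp$k + mp$stride - 1L
    est <- estimate_indel_rate(n_det, covered_bp - as.numeric(n_det) * w)
    tibble(seed = sd, n_injected = n_inj, n_detected = n_det,
           bp_per_indel = est$bp_per_indel, ci_lo = est$ci_lo,
           ci_hi = est$ci_hi,
           covers_truth = est$ci_lo <= spacing_bp & spacing_bp <= est$ci_hi)
  })
  bind_rows(rows)
}

#' End-to-end classification injection-recovery experiment
#'
#' Generates a mixed synthetic gene library, corrupts the build so that each
#' gene independently receives an error with probability `p_error`
#' (partitioned over the documented error classes), runs the full
#' map-classify-summarize pipeline, and returns the build summary together
#' with the per-class recovery against the injection ledger.
#'
#' @param n_genes library size.
#' @param p_error per-gene corruption probability (`1 - expected error-free
#'   fraction`).
#' @param seed drives truth generation and corruption.
#' @param dialect indel representation dialect.
#' @return list: `summary` (`ba_build_summary`), `recovery` (per-class
#'   recall), `calls`, `ledger`, `percent_correct`, `injected_error_free`
#'   (the realized error-free fraction in the ledger, percent).
#' @export
classification_experiment <- function(n_genes = 2000L, p_error = 1 - 0.589,
                                      seed = 1L, dialect = "truncate") {
  n_seleno <- max(1L, round(n_genes * 0.10))
  n_true <- max(1L, round(n_genes * 0.10))
  n_cdsless <- max(1L, round(n_genes * 0.10))
  n_rt_pairs <- max(0L, round(n_genes * 0.01))
  n_multi <- n_genes - n_seleno - n_true - n_cdsless - 2L * n_rt_pairs
  cfg <- sim_config(
    n_multi_exon = n_multi, n_true_intronless = n_true,
    n_cds_intronless = n_cdsless, n_selenoprotein = n_seleno,
    n_readthrough_pairs = n_rt_pairs
  )
  models <- generate_gene_models(cfg, seed = seed)
  truth <- emit_genome(models, genes_per_chrom = 250L, seed = seed)

  # class mix of the corruption budget (fallbacks keep the total exact)
  mix <- c(indel = 0.48, missing_segment = 0.10, unannotated = 0.15,
           split_locus = 0.15, merged_locus = 0.05, premature_stop = 0.07)
  p <- p_error * mix
  prof <- error_profile(
    p_coding_indel = p[["indel"]], p_missing_segment = p[["missing_segment"]],
    p_unannotated = p[["unannotated"]], p_split_locus = p[["split_locus"]],
    p_merged_locus = p[["merged_locus"]],
    p_premature_stop_seleno = p[["premature_stop"]], dialect = dialect
  )
  inj <- inject_build_errors(truth, prof, seed = sub_seed(seed, 77L))
  calls <- classify_build(truth, inj$build)
  summary <- summarize_build(calls, build_id = "synthetic_corrupted")
  list(
    summary = summary,
    recovery = recovery_stats(calls, inj$ledger),
    calls = calls, ledger = inj$ledger,
    percent_correct = attr(summary, "percent_correct"),
    injected_error_free = pct(sum(inj$ledger$injected_error == "none"),
                              nrow(inj$ledger))
  )
}
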