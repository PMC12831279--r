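test_that("gene class invariants are enforced by construction", {
  m1 <- generate_gene_models(sim_config(
    n_multi_exon = 0, n_true_intronless = 1, n_cds_intronless = 0,
    n_selenoprotein = 0
  ), seed = 1)
  expect_equal(nrow(m1), 1)
  expect_equal(m1$n_exons, 1)
  expect_equal(m1$gene_class, "true_intronless")

  m2 <- generate_gene_models(sim_config(
    n_multi_exon = 0, n_true_intronless = 0, n_cds_intronless = 0,
    n_selenoprotein = 5
  ), seed = 7)
  expect_equal(nrow(m2), 5)
  for (i in 1:5) {
    sec <- m2$sec_codons[[i]]
    expect_gt(length(sec), 0)
    codons <- substring(m2$cds[i], 3 * (sec - 1) + 1, 3 * sec)
    expect_true(all(codons == "TGA"))
  }

  m3 <- generate_gene_models(sim_config(n_cds_intronless = 6), seed = 3)
  cdsless <- m3[m3$gene_class == "cds_intronless", ]
  for (i in seq_len(nrow(cdsless))) {
    ends <- cumsum(cdsless$exon_lens[[i]])
    starts <- ends - cdsless$exon_lens[[i]] + 1
    inside <- starts <= cdsless$cds_start[i] & ends >= cdsless$cds_end[i]
    expect_gte(cdsless$n_exons[i], 2)
    expect_true(any(inside)) # whole CDS within one exon
  }
})

test_that("generation is deterministic and proteins translate from the CDS", {
  cfg <- sim_config(n_multi_exon = 6, n_selenoprotein = 2)
  a <- generate_gene_models(cfg, seed = 42)
  b <- generate_gene_models(cfg, seed = 42)
  expect_identical(a, b)
  c <- generate_gene_models(cfg, seed = 43)
  expect_false(identical(a$transcript, c$transcript))

  for (i in seq_len(nrow(a))) {
    tr <- translate_cds(a$cds[i], a$sec_codons[[i]])
    expect_false(tr$premature_stop)
    expect_identical(tr$protein, a$protein[i])
    expect_equal(nchar(tr$protein), a$expected_protein_length[i])
    expect_equal((a$cds_end[i] - a$cds_start[i] + 1) %% 3, 0)
  }
})

test_that("emitted genomes splice back to the exact transcripts", {
  tr <- small_truth(seed = 19)
  for (g in tr$models$gene_id) {
    expect_identical(
      spliced_transcript(tr$genome, tr$annotation, g),
      tr$models$transcript[tr$models$gene_id == g]
    )
  }
  # readthrough parents adjacent, same strand, transcript order preserved
  rt <- tr$models[!is.na(tr$models$pair_id), ]
  expect_equal(nrow(rt), 2)
  expect_equal(rt$strand[1], rt$strand[2])
  expect_equal(rt$chrom[1], rt$chrom[2])
  expect_equal(rt$gene_start[2] - rt$gene_end[1], 1L)
})

test_that("annotation round-trips through GFF3", {
  tr <- small_truth(seed = 23, n_multi = 5, n_true = 1, n_cdsless = 1,
                    n_seleno = 1, n_rt_pairs = 0)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(tr$annotation, path)
  back <- read_gff3(path)
  key <- function(df) {
    df <- df[order(df$ID), c("seqid", "type", "start", "end", "strand", "ID",
                             "Parent", "gene_id")]
    rownames(df) <- NULL
    df
  }
  expect_equal(as.data.frame(key(back)), as.data.frame(key(tr$annotation)))
})

test_that("zero-rate injection is the identity and the ledger is exhaustive", {
  tr <- small_truth(seed = 29)
  out <- inject_build_errors(tr, error_profile(), seed = 5)
  expect_identical(out$build$genome, tr$genome)
  ord <- function(a) a[order(a$ID, a$start), ]
  expect_equal(as.data.frame(ord(out$build$annotation)),
               as.data.frame(ord(tr$annotation)), ignore_attr = TRUE)
  expect_true(all(out$ledger$injected_error == "none"))
  expect_setequal(out$ledger$gene_id, tr$models$gene_id)
  expect_equal(nrow(out$ledger), nrow(tr$models))
})

test_that("rate-1 unannotated removes every gene feature", {
  tr <- small_truth(seed = 31, n_multi = 8, n_true = 1, n_cdsless = 1,
                    n_seleno = 0, n_rt_pairs = 0)
  out <- inject_build_errors(tr, error_profile(p_unannotated = 1), seed = 2)
  expect_true(all(out$ledger$injected_error == "unannotated"))
  expect_equal(nrow(out$build$annotation), 0)
  expect_identical(out$build$genome, tr$genome)
})

test_that("ledger conservation holds across random profiles", {
  tr <- small_truth(seed = 37)
  for (sd in 1:5) {
    prof <- error_profile(p_coding_indel = 0.2, p_missing_segment = 0.1,
                          p_unannotated = 0.1, p_split_locus = 0.1,
                          p_merged_locus = 0.05,
                          p_premature_stop_seleno = 0.05)
    out <- inject_build_errors(tr, prof, seed = sd)
    led <- out$ledger
    expect_equal(nrow(led), nrow(tr$models))
    expect_setequal(led$gene_id, tr$models$gene_id)
    n_none <- sum(led$injected_error == "none")
    n_err <- sum(led$injected_error != "none")
    expect_equal(n_none + n_err, nrow(tr$models))
    # indel positions lie inside the corrupted build
    ip <- attr(led, "indel_positions")
    if (!is.null(ip) && nrow(ip) > 0) {
      expect_true(all(ip$pos >= 1 &
                        ip$pos <= nchar(out$build$genome[ip$chrom])))
    }
    # identical seed reproduces the corruption byte for byte
    again <- inject_build_errors(tr, prof, seed = sd)
    expect_identical(again$build$genome, out$build$genome)
    expect_identical(again$ledger$detail, out$ledger$detail)
  }
})

test_that("injected indel counts follow the Poisson law of the spacing", {
  # ~1.67 Mb of coding sequence, spacing 12,465 bp
  cfg <- sim_config(n_multi_exon = 0, n_true_intronless = 10,
                    n_cds_intronless = 0, n_selenoprotein = 0,
                    cds_codons = c(55600L, 55600L), utr5 = c(60L, 100L),
                    utr3 = c(60L, 100L))
  m <- generate_gene_models(cfg, seed = 2)
  tr <- emit_genome(m, genes_per_chrom = 10, seed = 2)
  span <- sum(m$cds_end - m$cds_start + 1)
  lambda <- span / 12465
  counts <- vapply(1:20, function(sd) {
    out <- inject_build_errors(tr, error_profile(indel_spacing_bp = 12465),
                               seed = sd)
    nrow(attr(out$ledger, "indel_positions"))
  }, numeric(1))
  # each draw within a 3-sigma band computed from the Poisson law directly
  expect_true(all(abs(counts - lambda) <= 3 * sqrt(lambda) + 1))
  # and the mean is unbiased within binomial-style tolerance
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / length(counts)))
})

test_that("injected counts fit a Poisson law across 50 seeds (chi-square)", {
  cfg <- sim_config(n_multi_exon = 0, n_true_intronless = 4,
                    n_cds_intronless = 0, n_selenoprotein = 0,
                    cds_codons = c(42000L, 42000L), utr5 = c(60L, 100L),
                    utr3 = c(60L, 100L))
  m <- generate_gene_models(cfg, seed = 5)
  tr <- emit_genome(m, genes_per_chrom = 4, seed = 5)
  span <- sum(m$cds_end - m$cds_start + 1)
  lambda <- span / 3000
  counts <- vapply(1:50, function(sd) {
    out <- inject_build_errors(tr, error_profile(indel_spacing_bp = 3000),
                               seed = sd)
    nrow(attr(out$ledger, "indel_positions"))
  }, numeric(1))
  # index-of-dispersion goodness of fit against the Poisson law at alpha 0.01
  disp <- sum((counts - lambda)^2 / lambda)
  p <- stats::pchisq(disp, df = length(counts), lower.tail = FALSE)
  expect_gt(p, 0.01)
  expect_lt(1 - p, 1 - 1e-6) # two-sided: under-dispersion also rejected
})

test_that("invalid configurations and profiles are rejected", {
  expect_error(sim_config(n_multi_exon = -1), class = "buildaudit_input_error")
  expect_error(sim_config(cds_codons = c(500, 100)),
               class = "buildaudit_input_error")
  expect_error(error_profile(p_unannotated = 1.2),
               class = "buildaudit_input_error")
  expect_error(error_profile(indel_spacing_bp = 0),
               class = "buildaudit_input_error")
  expect_error(error_profile(p_coding_indel = 0.7, p_unannotated = 0.7),
               class = "buildaudit_input_error")
  tr1 <- small_truth(seed = 3, n_multi = 1, n_true = 0, n_cdsless = 0,
                     n_seleno = 0, n_rt_pairs = 0)
  expect_error(
    inject_build_errors(tr1, error_profile(p_merged_locus = 0.5)),
    class = "buildaudit_input_error"
  )
})
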