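test_that("translation recodes Sec UGA and reports premature stops", {
  # UGA at a declared Sec codon reads through as U
  r1 <- translate_cds("ATGTGATAA", sec_positions = 2)
  expect_equal(r1$protein, "MU")
  expect_false(r1$premature_stop)
  # the same UGA without recoding is a premature stop
  r2 <- translate_cds("ATGTGATAA")
  expect_equal(r2$protein, "M")
  expect_true(r2$premature_stop)
  expect_equal(r2$stop_codon_index, 2)
  # plain standard-code translation
  r3 <- translate_cds("ATGAAATAA")
  expect_equal(r3$protein, "MK")
  expect_false(r3$premature_stop)
  # N codons become X and do not terminate
  r4 <- translate_cds("ATGANATAA")
  expect_equal(r4$protein, "MX")
  expect_false(r4$premature_stop)
  expect_error(translate_cds("AT"), class = "buildaudit_input_error")
  expect_error(translate_cds("ATGRZA"), class = "buildaudit_input_error")
})

test_that("the protein-length checksum follows its definition", {
  ok <- checksum_protein(strrep("A", 300), strrep("K", 300))
  expect_true(ok$pass)
  expect_equal(ok$ratio, 1.0)
  bad <- checksum_protein(264, 865)
  expect_false(bad$pass)
  expect_equal(bad$ratio, 264 / 865, tolerance = 1e-12)
  expect_equal(round(bad$ratio, 3), 0.305)
  expect_error(checksum_protein("", "AAA"), class = "buildaudit_input_error")
})

test_that("build summaries count, percent and partition correctly", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    category = c(rep("correct", 10))
  )
  s <- summarize_build(calls)
  expect_equal(attr(s, "percent_correct"), 100.0)
  # the in-print arithmetic: 3614 correct of 6135 genes
  calls2 <- tibble::tibble(
    gene_id = as.character(1:6135),
    category = c(rep("correct", 3614), rep("error_in_locus", 6135 - 3614))
  )
  expect_equal(attr(summarize_build(calls2), "percent_correct"), 58.9)
  # counts across categories always partition the genes
  set.seed(61)
  calls3 <- tibble::tibble(
    gene_id = as.character(1:500),
    category = sample(buildaudit:::audit_categories, 500, replace = TRUE)
  )
  s3 <- summarize_build(calls3)
  expect_equal(sum(s3$n), 500)
  expect_error(summarize_build(calls3[0, ]), class = "buildaudit_input_error")
})

test_that("indel-rate estimates match the Poisson interval definition", {
  e <- estimate_indel_rate(4, 49860)
  expect_equal(e$bp_per_indel, 12465.0)
  ci <- stats::poisson.test(4)$conf.int
  expect_equal(e$ci_lo, 49860 / ci[2])
  expect_equal(e$ci_hi, 49860 / ci[1])
  expect_true(e$ci_lo <= e$bp_per_indel && e$bp_per_indel <= e$ci_hi)
  z <- estimate_indel_rate(0, 1e6)
  expect_true(is.infinite(z$bp_per_indel))
  expect_true(z$undefined)
  expect_true(is.infinite(z$ci_hi))
  expect_error(estimate_indel_rate(3, 0), class = "buildaudit_input_error")
})

test_that("classification decision order resolves constructed cases", {
  tr <- small_truth(seed = 71, n_multi = 10, n_true = 2, n_cdsless = 2,
                    n_seleno = 2, n_rt_pairs = 1)
  # clause (f): the uncorrupted build is all correct
  calls <- classify_build(tr, tr)
  expect_true(all(calls$category == "correct"))
  expect_true(all(calls$n_loci == 1))
  expect_true(all(calls$checksum_pass))

  # clause (d): removing a gene's features makes it not_annotated
  inj <- inject_build_errors(tr, error_profile(p_unannotated = 1), seed = 1)
  calls_d <- classify_build(tr, inj$build)
  expect_true(all(calls_d$category == "not_annotated"))
})

test_that("a 60/40 split across distant loci is classified split_multiple_loci", {
  set.seed(72)
  # construct the case directly: 1.2 kb transcript split 60/40, 500 kb apart
  part1 <- cpp_random_dna(720)
  part2 <- cpp_random_dna(480)
  tx <- paste0(part1, part2)
  genome <- c(chr1 = paste0(
    cpp_random_dna(1000), part1, cpp_random_dna(499000), part2,
    cpp_random_dna(1000)
  ))
  loci <- map_transcript(tx, genome, transcript_id = "g1")
  # brute-force per-locus coverage from the construction itself
  expect_equal(sort(round(loci$coverage, 2)), c(0.40, 0.60))
  gene <- tibble::tibble(
    gene_id = "g1", gene_class = "multi_exon", strand = "+", tx_len = 1200L,
    cds_start = 101L, cds_end = 1000L, sec_codons = list(integer(0)),
    expected_protein_length = 299L
  )
  build <- list(genome = genome, annotation = tibble::tibble(
    seqid = character(), type = character(), start = integer(),
    end = integer(), strand = character(), ID = character(),
    Parent = character(), gene_id = character()
  ), dialect = "truncate")
  call <- classify_gene(gene, loci, build, classify_params(c_single = 0.9))
  expect_equal(call$category, "split_multiple_loci")
})

test_that("uncorrupted selenoproteins are never flagged premature", {
  tr <- small_truth(seed = 73, n_multi = 4, n_true = 0, n_cdsless = 0,
                    n_seleno = 6, n_rt_pairs = 0)
  calls <- classify_build(tr, tr)
  sel <- calls[tr$models$gene_class == "selenoprotein", ]
  expect_true(all(sel$category == "correct"))
  expect_true(all(!sel$has_premature_stop))
})

test_that("classifier recovers every injected class with high recall", {
  tr <- small_truth(seed = 74, n_multi = 80, n_true = 10, n_cdsless = 10,
                    n_seleno = 16, n_rt_pairs = 2, genes_per_chrom = 60)
  prof <- error_profile(
    p_coding_indel = 0.14, p_missing_segment = 0.07, p_unannotated = 0.08,
    p_split_locus = 0.08, p_merged_locus = 0.05,
    p_premature_stop_seleno = 0.06, dialect = "truncate"
  )
  inj <- inject_build_errors(tr, prof, seed = 8)
  calls <- classify_build(tr, inj$build)
  rec <- recovery_stats(calls, inj$ledger)
  expect_true(all(rec$recall >= 0.95),
              info = paste(capture.output(print(rec)), collapse = "\n"))
  # category exclusivity/exhaustiveness
  expect_equal(nrow(calls), nrow(tr$models))
  expect_true(all(calls$category %in% buildaudit:::audit_categories))
})

test_that("n_fill indel loci keep the annotated length but stay errors", {
  tr <- small_truth(seed = 75, n_multi = 12, n_true = 2, n_cdsless = 0,
                    n_seleno = 0, n_rt_pairs = 0)
  inj <- inject_build_errors(
    tr, error_profile(p_coding_indel = 0.5, dialect = "n_fill"), seed = 3
  )
  calls <- classify_build(tr, inj$build)
  hit <- inj$ledger$injected_error == "indel"
  expect_true(any(hit))
  flagged <- calls[match(inj$ledger$gene_id[hit], calls$gene_id), ]
  expect_true(all(flagged$category == "error_in_locus"))
  expect_true(all(flagged$n_filled))
  # the placeholder convention: annotated protein length still checks out
  expect_true(all(flagged$checksum_pass))
  # and a sequence-confirmed premature stop is what makes a pseudogene flag;
  # N fills must not raise it
  expect_true(all(!flagged$pseudogene_flag))
})
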