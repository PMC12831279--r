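test_that("identical architectures are fully shared; known diffs patterned", {
  arch <- tibble::tibble(protein_id = "p", domain = c("Ig", "FN3", "FN3"),
                         start = c(1, 120, 220), end = c(90, 210, 300))
  d <- compare_architectures(arch, arch, arch)
  expect_true(all(d$pattern == "shared_all"))
  expect_equal(nrow(d), 3) # one row per instance
  # the IL12B situation: an FN3 domain in pig and human, absent in mouse
  mouse <- arch[arch$start != 220, ]
  d2 <- compare_architectures(arch, mouse, arch)
  expect_equal(d2$pattern[d2$domain == "FN3" & d2$instance == 2], "pig_human")
  # the PTPRJ situation: FN3 in mouse and human, absent in pig
  d3 <- compare_architectures(mouse, arch, arch)
  expect_equal(d3$pattern[d3$domain == "FN3" & d3$instance == 2], "mouse_human")
  # every instance falls in exactly one pattern; counts sum to instances
  expect_equal(nrow(d2), sum(table(d2$pattern)))
  expect_error(compare_architectures(arch[0, ], arch[0, ], arch[0, ]),
               class = "buildaudit_input_error")
})

test_that("domain sharing ratio is the pig_human over mouse_human count", {
  diffs <- tibble::tibble(pattern = c(rep("pig_human", 40),
                                      rep("mouse_human", 20),
                                      rep("shared_all", 100)))
  r <- domain_sharing_ratio(diffs)
  expect_equal(r$ratio, 2.0)
  same <- domain_sharing_ratio(tibble::tibble(pattern = rep(c("pig_human",
                                                              "mouse_human"), 7)))
  expect_equal(same$ratio_1dp, 1.0)
  und <- domain_sharing_ratio(tibble::tibble(pattern = "pig_human"))
  expect_true(und$undefined)
  # planted frequencies recovered through the architecture comparison itself
  set.seed(301)
  n_ph <- 18; n_mh <- 6
  diffs2 <- list()
  for (i in seq_len(n_ph + n_mh)) {
    full <- tibble::tibble(protein_id = "x", domain = c("A", "B"),
                           start = c(1, 100), end = c(90, 190))
    lack <- full[1, ]
    if (i <= n_ph) d <- compare_architectures(full, lack, full)
    else d <- compare_architectures(lack, full, full)
    diffs2[[i]] <- d
  }
  r2 <- domain_sharing_ratio(dplyr::bind_rows(diffs2))
  expect_equal(r2$ratio, n_ph / n_mh)
})

test_that("intronless classification follows the two-category definition", {
  tr <- small_truth(seed = 81, n_multi = 6, n_true = 3, n_cdsless = 3,
                    n_seleno = 0, n_rt_pairs = 0)
  cls <- detect_intronless(tr$annotation)
  m <- tr$models[match(cls$gene_id, tr$models$gene_id), ]
  expect_equal(cls$intronless_class[m$gene_class == "true_intronless"],
               rep("true_intronless", 3))
  expect_equal(cls$intronless_class[m$gene_class == "cds_intronless"],
               rep("cds_intronless", 3))
  expect_equal(cls$intronless_class[m$gene_class == "multi_exon"],
               rep("multi_exon", 6))
  no_cds <- tr$annotation[tr$annotation$type != "CDS", ]
  expect_error(detect_intronless(no_cds), class = "buildaudit_input_error")
})

test_that("readthrough scoring matches its category definitions and is total", {
  expect_equal(score_readthrough(FALSE, 0, FALSE), 0L)
  expect_equal(score_readthrough(FALSE, 3, TRUE), 0L)
  expect_equal(score_readthrough(TRUE, 0, FALSE), 1L)
  expect_equal(score_readthrough(TRUE, 1, FALSE), 2L)
  expect_equal(score_readthrough(TRUE, 2, FALSE), 2L)
  expect_equal(score_readthrough(TRUE, 0, TRUE), 3L)
  expect_equal(score_readthrough(TRUE, 1, TRUE), 3L)
  expect_equal(score_readthrough(TRUE, 2, TRUE), 4L)
  expect_equal(score_readthrough(TRUE, 3, TRUE), 4L)
  # total function over the evidence grid
  grid <- expand.grid(pred = c(TRUE, FALSE), n = 0:6, pig = c(TRUE, FALSE))
  s <- score_readthrough(grid$pred, grid$n, grid$pig)
  expect_true(all(s %in% 0:4))
  expect_equal(length(s), nrow(grid))
  expect_true(all(s[!grid$pred] == 0))
  expect_error(score_readthrough(TRUE, -1, TRUE),
               class = "buildaudit_input_error")
})

test_that("region-wise mRNA conservation flags the corrupted UTR only", {
  set.seed(302)
  utr5 <- cpp_random_dna(120)
  cds <- paste0(cpp_random_cds(100, integer(0)), "TAA")
  utr3 <- cpp_random_dna(200)
  ref <- list(mrna = paste0(utr5, cds, utr3), cds_start = 121L,
              cds_end = 120L + nchar(cds))
  same <- utr_conservation(ref, ref)
  expect_equal(unlist(same[1, 1:3]), c(utr5_identity = 1, cds_identity = 1,
                                       utr3_identity = 1))
  expect_false(same$low5 || same$low3)
  # randomized 3'UTR, CDS untouched
  oth <- ref
  oth$mrna <- paste0(utr5, cds, cpp_random_dna(200))
  r <- utr_conservation(ref, oth)
  expect_equal(r$cds_identity, 1.0)
  expect_true(r$low3)
  expect_false(r$low5)
  # a missing 5'UTR is undefined, not low
  no5 <- list(mrna = paste0(cds, utr3), cds_start = 1L, cds_end = nchar(cds))
  r2 <- utr_conservation(ref, no5)
  expect_true(is.na(r2$utr5_identity))
  expect_false(r2$low5)
  expect_error(utr_conservation(list(mrna = "ACGT", cds_start = 0, cds_end = 3),
                                ref),
               class = "buildaudit_input_error")
})

test_that("splice conservation reports exon deltas and variant fractions", {
  expect_equal(splice_conservation(10, 10)$exon_delta, 0L)
  expect_equal(splice_conservation(26, 20)$exon_delta, 6L)
  v <- tibble::tibble(variant_id = 1:10, conserved = c(rep(TRUE, 9), FALSE))
  expect_equal(splice_conservation(5, 5, v)$variant_conserved_fraction, 0.9)
  expect_true(is.na(splice_conservation(5, 5)$variant_conserved_fraction))
})

test_that("six-frame search finds planted copies, stops and absences", {
  set.seed(303)
  q <- random_protein(80, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  orf <- paste(codons_for(q), collapse = "")
  genome1 <- c(chr1 = paste0(cpp_random_dna(500), orf, cpp_random_dna(400)))
  h1 <- orf_homology_search(q, genome1)
  expect_equal(nrow(h1), 1)
  expect_true(h1$intact)
  expect_equal(h1$start, 501)
  expect_equal(h1$strand, "+")
  # direct six-frame enumeration confirms the frame
  expect_equal(h1$frame, 1L + (h1$start - 1L) %% 3L)

  # one internal stop: reported, not intact, pseudogenized
  cods <- codons_for(q); cods[40] <- "TGA"
  genome2 <- c(chr1 = paste0(cpp_random_dna(500),
                             paste(cods, collapse = ""), cpp_random_dna(400)))
  h2 <- orf_homology_search(q, genome2)
  expect_equal(nrow(h2), 1)
  expect_false(h2$intact)
  expect_true(h2$pseudogenized)

  # absent query
  expect_equal(nrow(orf_homology_search(q, c(chr1 = cpp_random_dna(3000)))), 0)
  expect_error(orf_homology_search(substr(q, 1, 20), genome1),
               class = "buildaudit_input_error")
})

test_that("N non-overlapping planted copies give exactly N hits", {
  set.seed(304)
  q <- random_protein(60, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  orf <- paste(codons_for(q), collapse = "")
  for (n_copies in c(3, 17)) {
    pieces <- character(2 * n_copies + 1)
    pieces[seq(1, by = 2, length.out = n_copies + 1)] <-
      vapply(seq_len(n_copies + 1), function(i) cpp_random_dna(300), "")
    pieces[seq(2, by = 2, length.out = n_copies)] <- orf
    genome <- c(chr1 = paste(pieces, collapse = ""))
    h <- orf_homology_search(q, genome)
    expect_equal(nrow(h), n_copies)
    expect_true(all(h$intact))
  }
})
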