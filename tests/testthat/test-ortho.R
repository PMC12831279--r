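aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

test_that("a proteome against itself pairs every gene at tier protein", {
  set.seed(201)
  prots <- vapply(1:8, function(i) random_protein(80, aa20), character(1))
  sp <- tibble::tibble(gene_id = sprintf("g%d", 1:8), protein = prots)
  sp_b <- sp
  sp_b$gene_id <- sprintf("h%d", 1:8)
  pairs <- tiered_orthology(sp, sp_b)
  expect_equal(nrow(pairs), 8)
  expect_true(all(pairs$tier == "protein"))
  expect_true(all(pairs$reciprocal))
  expect_equal(sub("g", "", pairs$gene_a), sub("h", "", pairs$gene_b))
})

test_that("toy pairing equals the brute-force mutual-best oracle", {
  set.seed(202)
  a_prots <- vapply(1:5, function(i) random_protein(90, aa20), character(1))
  b_prots <- vapply(a_prots, mutate_protein, rate = 0.08, character(1))
  perm <- sample(5)
  sp_a <- tibble::tibble(gene_id = sprintf("a%d", 1:5), protein = a_prots)
  sp_b <- tibble::tibble(gene_id = sprintf("b%d", perm),
                         protein = b_prots[perm])
  pairs <- tiered_orthology(sp_a, sp_b)
  sc <- buildaudit:::protein_score_matrix(
    setNames(sp_a$protein, sp_a$gene_id), setNames(sp_b$protein, sp_b$gene_id)
  )
  oracle <- rbh_oracle(sc)
  expect_equal(nrow(pairs), nrow(oracle))
  expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                  paste(oracle[, 1], oracle[, 2]))
})

test_that("tied paralogs stay unpaired at sequence tiers; synteny resolves", {
  set.seed(203)
  anchor_prots <- vapply(1:8, function(i) random_protein(90, aa20), character(1))
  dup <- random_protein(90, aa20)
  # species A: 4 anchors, two identical paralogs, 4 anchors (ordered on chr1)
  sp_a <- tibble::tibble(
    gene_id = c(sprintf("a%d", 1:4), "dup1", "dup2", sprintf("a%d", 5:8)),
    protein = c(anchor_prots[1:4], dup, dup, anchor_prots[5:8]),
    chrom = "chr1", pos = 1:10
  )
  # species B: one counterpart of the duplicated gene, at the syntenic slot
  sp_b <- tibble::tibble(
    gene_id = c(sprintf("b%d", 1:4), "bdup", sprintf("b%d", 5:8)),
    protein = c(anchor_prots[1:4], dup, anchor_prots[5:8]),
    chrom = "chr1", pos = 1:9
  )
  pairs <- tiered_orthology(sp_a, sp_b)
  prot_pairs <- pairs[pairs$tier == "protein", ]
  expect_false(any(prot_pairs$gene_b == "bdup")) # tie blocks the sequence tier
  syn <- pairs[pairs$tier == "synteny", ]
  expect_equal(nrow(syn), 1)
  expect_equal(syn$gene_b, "bdup")
  expect_true(syn$gene_a %in% c("dup1", "dup2"))
})

test_that("duplicate gene ids are rejected", {
  sp <- tibble::tibble(gene_id = c("x", "x"), protein = c("AAAA", "CCCC"))
  expect_error(tiered_orthology(sp, sp), class = "buildaudit_input_error")
})

test_that("full conservation puts every gene in the central Venn region", {
  ids <- sprintf("g%d", 1:10)
  mk <- function(pre) paste0(pre, ids)
  ph <- tibble::tibble(gene_a = mk("p"), gene_b = mk("h"))
  pm <- tibble::tibble(gene_a = mk("p"), gene_b = mk("m"))
  mh <- tibble::tibble(gene_a = mk("m"), gene_b = mk("h"))
  v <- venn_partition(ph, pm, mh, list(pig = mk("p"), mouse = mk("m"),
                                       human = mk("h")))
  expect_equal(v$PMH, 10)
  expect_equal(unlist(v[1, c("PM", "PH", "MH", "P", "M", "H")]),
               c(PM = 0L, PH = 0L, MH = 0L, P = 0L, M = 0L, H = 0L))
  # a mouse-only gene increments exactly M
  v2 <- venn_partition(ph, pm, mh, list(pig = mk("p"),
                                        mouse = c(mk("m"), "m_extra"),
                                        human = mk("h")))
  expect_equal(v2$M, 1)
  expect_equal(v2$PMH, 10)
})

test_that("planted Venn regions are recovered and totals reconstruct", {
  set.seed(204)
  plant <- c(PMH = 12, PM = 4, PH = 7, MH = 5, P = 3, M = 6, H = 2)
  pig <- sprintf("p%03d", 1:(plant["PMH"] + plant["PM"] + plant["PH"] + plant["P"]))
  mouse <- sprintf("m%03d", 1:(plant["PMH"] + plant["PM"] + plant["MH"] + plant["M"]))
  human <- sprintf("h%03d", 1:(plant["PMH"] + plant["PH"] + plant["MH"] + plant["H"]))
  # layout: pig = [12 triples][7 PH][4 PM][3 P]; mouse = [12][4 PM][5 MH][6 M];
  # human = [12][7 PH][5 MH][2 H]
  ph <- tibble::tibble(gene_a = pig[1:19], gene_b = human[1:19])
  pm <- tibble::tibble(gene_a = pig[c(1:12, 20:23)], gene_b = mouse[1:16])
  mh <- tibble::tibble(gene_a = mouse[c(1:12, 17:21)],
                       gene_b = human[c(1:12, 20:24)])
  v <- venn_partition(ph, pm, mh,
                      list(pig = pig, mouse = mouse, human = human))
  expect_equal(unlist(v[1, names(plant)]), plant + 0L, ignore_attr = TRUE)
  # per-species totals reconstruct the universes
  g <- glance(v)
  expect_equal(g$pig_total, length(pig))
  expect_equal(g$mouse_total, length(mouse))
  expect_equal(g$human_total, length(human))
})

test_that("inconsistent pair sets are rejected", {
  ph <- tibble::tibble(gene_a = c("p1", "p1"), gene_b = c("h1", "h2"))
  ok <- tibble::tibble(gene_a = "p1", gene_b = "m1")
  mh <- tibble::tibble(gene_a = "m1", gene_b = "h1")
  expect_error(
    venn_partition(ph, ok, mh, list(pig = "p1", mouse = "m1",
                                    human = c("h1", "h2"))),
    class = "buildaudit_input_error"
  )
})

test_that("asymmetry ratios reproduce the reported arithmetic", {
  r <- asymmetry_ratios(list(PH = 598, MH = 120, M = 2246, H = 1024, P = 885))
  expect_equal(r$ph_over_mh_1dp, 5.0)
  expect_equal(r$m_over_h_1dp, 2.2)
  expect_equal(r$m_over_p_1dp, 2.5)
  # symmetry: equal regions give exactly 1.0 for any positive count
  for (k in c(1, 7, 120)) {
    rs <- asymmetry_ratios(list(PH = k, MH = k, M = k, H = k, P = k))
    expect_equal(rs$ph_over_mh_1dp, 1.0)
  }
  und <- asymmetry_ratios(list(PH = 5, MH = 0, M = 3, H = 1, P = 1))
  expect_true(und$undefined)
  expect_true(is.na(und$ph_over_mh))
})

test_that("paralog symbols follow the L-rank-asterisk convention", {
  fam <- tibble::tibble(gene_id = c("x1", "x2", "x3"), score = c(50, 90, 70))
  s <- assign_paralog_symbols(fam, "SLC7A3")
  expect_equal(s$symbol, c("SLC7A3L1*", "SLC7A3L2*", "SLC7A3L3*"))
  expect_equal(s$gene_id, c("x2", "x3", "x1")) # rank 1 = closest homology
  one <- assign_paralog_symbols(tibble::tibble(gene_id = "y", score = 1), "ABC")
  expect_equal(one$symbol, "ABCL1*")
  # ties break by gene id, independent of input order
  tie1 <- assign_paralog_symbols(
    tibble::tibble(gene_id = c("zb", "za"), score = c(5, 5)), "R")
  tie2 <- assign_paralog_symbols(
    tibble::tibble(gene_id = c("za", "zb"), score = c(5, 5)), "R")
  expect_identical(tie1, tie2)
  expect_equal(tie1$gene_id, c("za", "zb"))
  expect_error(assign_paralog_symbols(tibble::tibble(gene_id = character(),
                                                     score = numeric()), "R"),
               class = "buildaudit_input_error")
})

test_that("planted orthology is recovered under 5-15% divergence", {
  set.seed(205)
  n <- 40
  a_prots <- vapply(seq_len(n), function(i) random_protein(120, aa20),
                    character(1))
  recalls <- vapply(c(0.05, 0.15), function(rate) {
    b_prots <- vapply(a_prots, mutate_protein, rate = rate, character(1))
    perm <- sample(n)
    sp_a <- tibble::tibble(gene_id = sprintf("a%02d", seq_len(n)),
                           protein = a_prots)
    sp_b <- tibble::tibble(gene_id = sprintf("b%02d", perm),
                           protein = b_prots[perm])
    pairs <- tiered_orthology(sp_a, sp_b)
    truth <- setNames(sprintf("b%02d", perm), sprintf("a%02d", perm))
    mean(truth[pairs$gene_a] == pairs$gene_b &
           pairs$tier == "protein") * nrow(pairs) / n
  }, numeric(1))
  expect_true(all(recalls >= 0.98))
})
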