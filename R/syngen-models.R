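#' Simulation configuration for synthetic gene models
#'
#' Bundles the generation parameters of the synthetic truth library: how many
#' genes of each structural class to draw, transcript anatomy (UTR and CDS
#' length ranges, exon-count distribution, intron lengths) and the fraction of
#' minus-strand genes. The defaults emulate a compact mammalian protein-coding
#' library: CDS of 150-600 codons, multi-exon genes with on average five exons,
#' introns of 200-800 bp and selenoproteins carrying 1-3 Sec (UGA) codons.
#'
#' @param n_multi_exon,n_true_intronless,n_cds_intronless,n_selenoprotein
#'   counts of genes per structural class.
#' @param n_readthrough_pairs number of adjacent same-strand gene pairs flagged
#'   as readthrough parents (each pair contributes two genes).
#' @param n_retroelement single-exon retroelement ORF genes (the LINE-1-like
#'   reverse-transcriptase/transposase stand-ins).
#' @param cds_codons range (codons, stop excluded) the CDS length is drawn from.
#' @param utr5,utr3 UTR length ranges in bp.
#' @param exon_lambda Poisson rate for extra exons of multi-exon genes
#'   (exon count = 2 + Poisson(exon_lambda)).
#' @param intron intron length range in bp.
#' @param n_sec range for the number of Sec codons per selenoprotein.
#' @param p_minus probability a gene is placed on the minus strand.
#' @return a validated `ba_sim_config` list.
#' @export
sim_config <- function(n_multi_exon = 20, n_true_intronless = 5,
                       n_cds_intronless = 5, n_selenoprotein = 3,
                       n_readthrough_pairs = 0, n_retroelement = 0,
                       cds_codons = c(150L, 600L), utr5 = c(100L, 300L),
                       utr3 = c(150L, 400L), exon_lambda = 3,
                       intron = c(200L, 800L), n_sec = c(1L, 3L),
                       p_minus = 0.3) {
  cfg <- list(
    n_multi_exon = n_multi_exon, n_true_intronless = n_true_intronless,
    n_cds_intronless = n_cds_intronless, n_selenoprotein = n_selenoprotein,
    n_readthrough_pairs = n_readthrough_pairs, n_retroelement = n_retroelement,
    cds_codons = as.integer(cds_codons), utr5 = as.integer(utr5),
    utr3 = as.integer(utr3), exon_lambda = exon_lambda,
    intron = as.integer(intron), n_sec = as.integer(n_sec), p_minus = p_minus
  )
  counts <- unlist(cfg[1:6])
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_input("gene class counts must be non-negative integers")
  }
  for (f in c("cds_codons", "utr5", "utr3", "intron", "n_sec")) {
    if (length(cfg[[f]]) != 2 || any(cfg[[f]] < 1) || cfg[[f]][1] > cfg[[f]][2]) {
      stop_input("'%s' must be an increasing positive range", f)
    }
  }
  if (cfg$cds_codons[1] < 10) stop_input("cds_codons must allow >= 10 codons")
  if (exon_lambda < 0 || p_minus < 0 || p_minus > 1) {
    stop_input("exon_lambda must be >= 0 and p_minus in [0, 1]")
  }
  structure(cfg, class = "ba_sim_config")
}

runif_int <- function(n, range) {
  as.integer(floor(runif(n, range[1], range[2] + 1)))
}

#' Generate synthetic truth gene models
#'
#' Draws a library of gene models covering the structural classes a genome
#' audit must handle: multi-exon genes, true intronless genes (one exon),
#' CDS-intronless genes (CDS inside one exon, introns confined to the UTRs),
#' selenoproteins (in-frame UGA codons recoded to Sec), readthrough parent
#' pairs and retroelement ORFs. Each model carries its transcript, CDS and
#' Sec-aware translated protein; proteins translate exactly from the CDS.
#'
#' @param config a [sim_config()] object.
#' @param seed integer seed; the same seed reproduces the library byte for
#'   byte.
#' @return a tibble with one row per gene: `gene_id`, `gene_class`, `strand`,
#'   `n_exons`, `exon_lens`/`intron_lens` (list columns, transcript order),
#'   `tx_len`, `cds_start`/`cds_end` (transcript coordinates, 1-based, stop
#'   codon included), `sec_codons` (1-based CDS codon indices), `transcript`,
#'   `cds`, `protein` and `expected_protein_length` (AA, stop excluded).
#' @export
generate_gene_models <- function(config = sim_config(), seed = 1) {
  if (!inherits(config, "ba_sim_config")) config <- do.call(sim_config, config)
  classes <- c(
    rep("multi_exon", config$n_multi_exon),
    rep("true_intronless", config$n_true_intronless),
    rep("cds_intronless", config$n_cds_intronless),
    rep("selenoprotein", config$n_selenoprotein),
    rep("readthrough_parent", 2L * config$n_readthrough_pairs),
    rep("retroelement", config$n_retroelement)
  )
  n <- length(classes)
  if (n == 0) stop_input("configuration requests zero genes")

  with_seed_if(sub_seed(seed, 101L), {
    rows <- vector("list", n)
    # readthrough pairs must share a strand so they can abut head-to-tail
    strands <- ifelse(runif(n) < config$p_minus, "-", "+")
    rt_idx <- which(classes == "readthrough_parent")
    if (length(rt_idx)) {
      strands[rt_idx] <- rep(strands[rt_idx[c(TRUE, FALSE)]], each = 2)
    }
    for (i in seq_len(n)) {
      rows[[i]] <- sim_one_model(classes[i], strands[i], config, i)
    }
  })
  out <- bind_rows(rows)
  out$pair_id <- NA_character_
  if (length(rt_idx)) {
    out$pair_id[rt_idx] <- rep(sprintf("rt_pair_%03d", seq_len(length(rt_idx) / 2)),
                               each = 2)
  }
  out
}

sim_one_model <- function(gene_class, strand, config, i) {
  n_codons <- runif_int(1, config$cds_codons)
  sec <- integer(0)
  if (gene_class == "selenoprotein") {
    n_sec <- runif_int(1, config$n_sec)
    # Sec sites kept away from the termini so truncation at the UGA is visible
    sec <- sort(sample(seq(5L, n_codons - 5L), min(n_sec, n_codons - 10L)))
  }
  cds <- paste0(cpp_random_cds(n_codons, sec), "TAA")
  utr5 <- cpp_random_dna(runif_int(1, config$utr5))
  utr3 <- cpp_random_dna(runif_int(1, config$utr3))
  if (gene_class == "retroelement") { # bare ORF with token UTRs
    utr5 <- cpp_random_dna(30L)
    utr3 <- cpp_random_dna(30L)
  }
  tx <- paste0(utr5, cds, utr3)
  tx_len <- nchar(tx)
  cds_start <- nchar(utr5) + 1L
  cds_end <- cds_start + nchar(cds) - 1L

  n_exons <- switch(gene_class,
    true_intronless = 1L,
    retroelement = 1L,
    cds_intronless = max(2L, 1L + stats::rpois(1, config$exon_lambda / 2)),
    2L + stats::rpois(1, config$exon_lambda)
  )
  cuts <- sim_exon_cuts(gene_class, n_exons, tx_len, cds_start, cds_end)
  exon_lens <- diff(c(0L, cuts, tx_len))
  n_exons <- length(exon_lens)
  intron_lens <- if (n_exons > 1) runif_int(n_exons - 1, config$intron) else integer(0)

  tibble(
    gene_id = sprintf("g%04d", i), gene_class = gene_class, strand = strand,
    n_exons = n_exons, exon_lens = list(as.integer(exon_lens)),
    intron_lens = list(as.integer(intron_lens)), tx_len = tx_len,
    cds_start = cds_start, cds_end = cds_end, sec_codons = list(as.integer(sec)),
    transcript = tx, cds = cds, protein = translate_cds(cds, sec)$protein,
    expected_protein_length = n_codons
  )
}

# transcript-coordinate cut points (end of each non-terminal exon)
sim_exon_cuts <- function(gene_class, n_exons, tx_len, cds_start, cds_end) {
  if (n_exons == 1) return(integer(0))
  min_exon <- 40L
  # k cuts in [lo, hi], pairwise spacing >= min_exon, by direct construction
  # (k is reduced when the interval cannot hold that many exons)
  pick <- function(lo, hi, k) {
    if (hi < lo || k < 1) return(NULL)
    k <- min(k, (hi - lo) %/% min_exon + 1L)
    free <- (hi - lo) - (k - 1L) * min_exon
    if (k < 1 || free < 0) return(NULL)
    u <- sort(runif(k, 0, free))
    as.integer(round(lo + u + (seq_len(k) - 1L) * min_exon))
  }
  if (gene_class == "cds_intronless") {
    # introns only in the UTRs; put them 5' when room allows, else 3'
    k5 <- min(n_exons - 1, max(0, (cds_start - 1 - min_exon) %/% min_exon))
    k3 <- n_exons - 1 - k5
    cuts <- c(
      if (k5 > 0) pick(min_exon, cds_start - 1L - min_exon, k5),
      if (k3 > 0) pick(cds_end + min_exon, tx_len - min_exon, k3)
    )
    if (length(cuts) < n_exons - 1) { # not enough UTR room: fall back to 2 exons
      cuts <- pick(min_exon, cds_start - 1L - min_exon, 1L) %||%
        pick(cds_end + min_exon, tx_len - min_exon, 1L)
    }
    return(sort(as.integer(cuts)))
  }
  for (try in 1:200) {
    cuts <- pick(min_exon, tx_len - min_exon, n_exons - 1L)
    if (is.null(cuts)) return(integer(0))
    # multi-exon classes must have at least one intron inside the CDS
    if (any(cuts >= cds_start & cuts < cds_end)) return(as.integer(cuts))
  }
  # CDS-internal cut forced on the (rare) stubborn draw
  sort(unique(as.integer(c(cuts[-1], (cds_start + cds_end) %/% 2))))
}
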