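#' Orthology parameters
#'
#' @param t_protein minimum local-alignment identity for a protein-tier pair.
#' @param t_rna minimum identity for an RNA-tier pair.
#' @param margin best score must exceed the runner-up by this fraction for a
#'   best hit to count (guards against equally scoring paralogs).
#' @param synteny_flank how many already-paired flanking genes are examined
#'   on each side for the synteny tier.
#' @param synteny_support how many of them (per side combined) must agree in
#'   co-linear order.
#' @return a list of parameters.
#' @export
ortho_params <- function(t_protein = 0.35, t_rna = 0.60, margin = 0.05,
                         synteny_flank = 4L, synteny_support = 2L) {
  list(t_protein = t_protein, t_rna = t_rna, margin = margin,
       synteny_flank = as.integer(synteny_flank),
       synteny_support = as.integer(synteny_support))
}

#' Tiered 1:1 orthology between two species
#'
#' Pairs genes by reciprocal best hit on protein local-alignment score
#' (tier `protein`), retries unresolved genes on the RNA (tier `rna`), and
#' finally falls back to relative chromosomal location (tier `synteny`): an
#' unpaired gene is accepted against an unpaired candidate when enough of its
#' already-paired flanking genes map co-linearly around the candidate. A best
#' hit only counts when its score exceeds the runner-up by the configured
#' margin, so tied paralogs stay unpaired at the sequence tiers. Each gene
#' ends up in at most one pair. Gene families listed in `exclude` (the
#' olfactory receptor / TCR / BCR / MHC situation, where 1:1 orthology is not
#' determinable) are dropped before pairing.
#'
#' @param species_a,species_b tibbles with columns `gene_id`, `protein`,
#'   `rna` (optional), `chrom` and `pos` (gene order index on the
#'   chromosome; optional, needed for the synteny tier).
#' @param params [ortho_params()].
#' @param exclude character vector of gene_ids (either species) to omit.
#' @return a tibble of pairs: `gene_a`, `gene_b`, `tier`, `score`,
#'   `reciprocal`.
#' @export
tiered_orthology <- function(species_a, species_b, params = ortho_params(),
                             exclude = character(0)) {
  for (sp in list(species_a, species_b)) {
    if (anyDuplicated(sp$gene_id)) stop_input("duplicate gene_ids in a species")
  }
  a <- species_a[!species_a$gene_id %in% exclude, ]
  b <- species_b[!species_b$gene_id %in% exclude, ]

  pairs <- rbh_tier(setNames(a$protein, a$gene_id),
                    setNames(b$protein, b$gene_id),
                    threshold = params$t_protein, margin = params$margin,
                    tier = "protein", protein = TRUE)
  if ("rna" %in% names(a) && "rna" %in% names(b)) {
    rest_a <- a[!a$gene_id %in% pairs$gene_a, ]
    rest_b <- b[!b$gene_id %in% pairs$gene_b, ]
    if (nrow(rest_a) > 0 && nrow(rest_b) > 0) {
      pairs <- bind_rows(pairs, rbh_tier(
        setNames(rest_a$rna, rest_a$gene_id),
        setNames(rest_b$rna, rest_b$gene_id),
        threshold = params$t_rna, margin = params$margin,
        tier = "rna", protein = FALSE
      ))
    }
  }
  if (all(c("chrom", "pos") %in% names(a)) &&
      all(c("chrom", "pos") %in% names(b))) {
    pairs <- bind_rows(pairs, synteny_tier(a, b, pairs, params))
  }
  pairs
}

# reciprocal best hit with a score margin and identity threshold
rbh_tier <- function(seqs_a, seqs_b, threshold, margin, tier, protein) {
  if (length(seqs_a) == 0 || length(seqs_b) == 0) return(empty_pairs())
  sc <- if (protein) protein_score_matrix(seqs_a, seqs_b)
        else nuc_score_matrix(seqs_a, seqs_b)
  best_of <- function(v) { # index of an acceptable clear best, else 0
    o <- order(-v)
    if (length(v) > 1 && v[o[1]] < v[o[2]] * (1 + margin) + 1e-9 &&
        v[o[2]] > 0) return(0L)
    o[1]
  }
  ab <- apply(sc, 1, best_of)
  ba <- apply(sc, 2, best_of)
  out <- list()
  for (i in seq_along(seqs_a)) {
    j <- ab[i]
    if (j == 0L || ba[j] != i) next
    if (protein) {
      idt <- protein_identity(seqs_a[[i]], seqs_b[[j]])
    } else {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs_a[[i]]), Biostrings::DNAString(seqs_b[[j]]),
        type = "local")
      idt <- Biostrings::nmatch(al) / Biostrings::nchar(al)
    }
    if (is.na(idt) || idt < threshold) next
    out[[length(out) + 1L]] <- tibble(
      gene_a = names(seqs_a)[i], gene_b = names(seqs_b)[j], tier = tier,
      score = sc[i, j], reciprocal = TRUE
    )
  }
  if (length(out) == 0) empty_pairs() else bind_rows(out)
}

empty_pairs <- function() {
  tibble(gene_a = character(), gene_b = character(), tier = character(),
         score = numeric(), reciprocal = logical())
}

# relative chromosomal location: pair leftovers whose paired flanking genes
# agree in co-linear order
synteny_tier <- function(a, b, pairs, params) {
  rest_a <- a[!a$gene_id %in% pairs$gene_a, ]
  rest_b <- b[!b$gene_id %in% pairs$gene_b, ]
  if (nrow(rest_a) == 0 || nrow(rest_b) == 0) return(empty_pairs())
  partner <- setNames(pairs$gene_b, pairs$gene_a)
  b_pos <- setNames(b$pos, b$gene_id)
  b_chrom <- setNames(b$chrom, b$gene_id)
  out <- list()
  for (i in seq_len(nrow(rest_a))) {
    g <- rest_a[i, ]
    nbr <- a[a$chrom == g$chrom & a$gene_id != g$gene_id, ]
    nbr <- nbr[order(abs(nbr$pos - g$pos)), ]
    nbr <- nbr[nbr$gene_id %in% names(partner), ]
    left <- utils::head(nbr[nbr$pos < g$pos, ], params$synteny_flank)
    right <- utils::head(nbr[nbr$pos > g$pos, ], params$synteny_flank)
    support <- c(partner[left$gene_id], partner[right$gene_id])
    if (length(support) < params$synteny_support) next
    chroms <- b_chrom[support]
    target_chrom <- names(sort(table(chroms), decreasing = TRUE))[1]
    on_target <- support[chroms == target_chrom]
    if (length(on_target) < params$synteny_support) next
    lo <- if (nrow(left)) max(b_pos[partner[left$gene_id]], na.rm = TRUE) else -Inf
    hi <- if (nrow(right)) min(b_pos[partner[right$gene_id]], na.rm = TRUE) else Inf
    if (!is.finite(lo) && !is.finite(hi)) next
    cand <- rest_b[rest_b$chrom == target_chrom &
                     rest_b$pos > min(lo, hi) & rest_b$pos < max(lo, hi), ]
    if (nrow(cand) != 1) next # ambiguous slots stay unresolved
    out[[length(out) + 1L]] <- tibble(
      gene_a = g$gene_id, gene_b = cand$gene_id, tier = "synteny",
      score = NA_real_, reciprocal = FALSE
    )
    rest_b <- rest_b[rest_b$gene_id != cand$gene_id, ]
  }
  if (length(out) == 0) empty_pairs() else bind_rows(out)
}

#' Partition three species' genes into the seven Venn regions
#'
#' Takes the three pairwise 1:1 ortholog maps over pig (P), mouse (M) and
#' human (H) and assigns every gene to exactly one region. A gene is in the
#' central region `PMH` when it belongs to a consistent triple: its
#' pig-human and pig-mouse partners are themselves mouse-human partners
#' (closed triangle); `PMH` counts triples (one gene per species each).
#' Remaining pairs fill the two-species regions in the order PH, PM, MH, and
#' leftover genes are species-specific.
#'
#' @param pairs_ph,pairs_pm,pairs_mh pair tibbles (`gene_a` = first-named
#'   species) as from [tiered_orthology()].
#' @param universes named list of character vectors: `pig`, `mouse`, `human`.
#' @return a one-row `ba_venn` tibble with counts `PMH`, `PM`, `PH`, `MH`,
#'   `P`, `M`, `H`.
#' @export
venn_partition <- function(pairs_ph, pairs_pm, pairs_mh, universes) {
  stopifnot(all(c("pig", "mouse", "human") %in% names(universes)))
  check_one_to_one <- function(p, nm) {
    if (anyDuplicated(p$gene_a) || anyDuplicated(p$gene_b)) {
      stop_input("pair set %s is not 1:1", nm)
    }
  }
  check_one_to_one(pairs_ph, "pig-human")
  check_one_to_one(pairs_pm, "pig-mouse")
  check_one_to_one(pairs_mh, "mouse-human")

  ph <- setNames(pairs_ph$gene_b, pairs_ph$gene_a) # pig -> human
  pm <- setNames(pairs_pm$gene_b, pairs_pm$gene_a) # pig -> mouse
  mh <- setNames(pairs_mh$gene_b, pairs_mh$gene_a) # mouse -> human

  used <- list(pig = character(0), mouse = character(0), human = character(0))
  pmh <- 0L
  for (p in intersect(names(ph), names(pm))) {
    m <- pm[[p]]; h <- ph[[p]]
    if (m %in% names(mh) && identical(unname(mh[m]), h)) {
      pmh <- pmh + 1L
      used$pig <- c(used$pig, p); used$mouse <- c(used$mouse, m)
      used$human <- c(used$human, h)
    }
  }
  count_pairs <- function(pairs, sp_a, sp_b) {
    free <- !(pairs$gene_a %in% used[[sp_a]]) & !(pairs$gene_b %in% used[[sp_b]])
    used[[sp_a]] <<- c(used[[sp_a]], pairs$gene_a[free])
    used[[sp_b]] <<- c(used[[sp_b]], pairs$gene_b[free])
    sum(free)
  }
  n_ph <- count_pairs(pairs_ph, "pig", "human")
  n_pm <- count_pairs(pairs_pm, "pig", "mouse")
  n_mh <- count_pairs(pairs_mh, "mouse", "human")

  out <- tibble(
    PMH = pmh, PM = n_pm, PH = n_ph, MH = n_mh,
    P = length(setdiff(universes$pig, used$pig)),
    M = length(setdiff(universes$mouse, used$mouse)),
    H = length(setdiff(universes$human, used$human))
  )
  structure(out, class = c("ba_venn", class(out)),
            universe_sizes = lengths(universes)[c("pig", "mouse", "human")])
}

#' Venn asymmetry ratios
#'
#' The three ratios used to express how the species share genes when one of
#' the three genomes lacks a gene: `ph_over_mh` (pig-human only vs
#' mouse-human only pairs: how much likelier the pig is to have the human
#' gene than the mouse), and the unique-gene ratios `m_over_h` and
#' `m_over_p`. Raw ratios are kept alongside the 1-decimal half-up values
#' used for reporting.
#'
#' @param venn a `ba_venn` row from [venn_partition()] (or any list with the
#'   needed region counts).
#' @return a one-row tibble with raw and reported (`*_1dp`) ratios; a zero
#'   denominator yields `NA` and `undefined = TRUE`.
#' @examples
#' asymmetry_ratios(list(PH = 598, MH = 120, M = 2246, H = 1024, P = 885))
#' @export
asymmetry_ratios <- function(venn) {
  ratio <- function(num, den) if (isTRUE(den > 0)) num / den else NA_real_
  ph_mh <- ratio(venn$PH, venn$MH)
  m_h <- ratio(venn$M, venn$H)
  m_p <- ratio(venn$M, venn$P)
  tibble(
    ph_over_mh = ph_mh, m_over_h = m_h, m_over_p = m_p,
    ph_over_mh_1dp = round_half_up(ph_mh, 1),
    m_over_h_1dp = round_half_up(m_h, 1),
    m_over_p_1dp = round_half_up(m_p, 1),
    undefined = anyNA(c(ph_mh, m_h, m_p))
  )
}

#' Assign symbols to species-specific paralogs of a reference gene
#'
#' Paralogs with no 1:1 ortholog are named after the reference symbol they
#' resemble: `<symbol>L<rank>*`, rank 1 being the closest homolog, the
#' asterisk marking a provisional species-specific assignment. Ties in
#' similarity are broken by gene identifier so the naming is stable.
#'
#' @param candidates tibble with `gene_id` and `score` (similarity to the
#'   reference protein), or a character vector already ranked best-first.
#' @param reference_symbol the reference gene symbol (e.g. `"SLC7A3"`).
#' @return tibble with `gene_id`, `rank`, `symbol`.
#' @examples
#' assign_paralog_symbols(c("a", "b", "c"), "SLC7A3")
#' @export
assign_paralog_symbols <- function(candidates, reference_symbol) {
  if (is.character(candidates)) {
    candidates <- tibble(gene_id = candidates,
                         score = rev(seq_along(candidates)))
  }
  if (nrow(candidates) == 0) stop_input("paralog family is empty")
  o <- order(-candidates$score, candidates$gene_id)
  tibble(
    gene_id = candidates$gene_id[o],
    rank = seq_len(nrow(candidates)),
    symbol = sprintf("%sL%d*", reference_symbol, seq_len(nrow(candidates)))
  )
}
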