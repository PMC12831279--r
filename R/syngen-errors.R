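#' Error-injection profile for synthetic builds
#'
#' Parameterizes the documented error classes a corrupted build can carry.
#' Coding indels can be injected two ways: as a homogeneous Poisson process
#' along the coding sequence with mean spacing `indel_spacing_bp` (the
#' genome-wide statistic), and/or as a per-gene Bernoulli event with
#' probability `p_coding_indel` (one indel at a uniform CDS position). The
#' remaining probabilities are per-gene: a gene can lose its sequence
#' (`p_missing_segment`), its annotation (`p_unannotated`), be split across
#' two distant loci (`p_split_locus`), be merged with its neighbour into one
#' annotated locus (`p_merged_locus`), or — selenoproteins only — have its
#' annotated CDS truncated at the first Sec UGA as if it were a stop codon
#' (`p_premature_stop_seleno`). The per-gene probabilities partition a single
#' uniform draw, so each gene is corrupted with probability exactly equal to
#' their sum.
#'
#' `dialect` controls how indel loci are represented: `"n_fill"` overwrites a
#' window around the indel with ambiguous N bases and keeps the annotation's
#' protein length (the placeholder convention), `"truncate"` edits the bases
#' and leaves the annotation to track the shifted coordinates.
#'
#' @param indel_spacing_bp mean bp between Poisson-process coding indels
#'   (`Inf` disables the process).
#' @param p_coding_indel,p_missing_segment,p_unannotated,p_split_locus,p_merged_locus,p_premature_stop_seleno
#'   per-gene corruption probabilities; their sum must be at most 1.
#' @param dialect `"truncate"` or `"n_fill"`.
#' @param retroelement_copies extra unannotated copies of a retroelement gene
#'   region planted into intergenic space.
#' @param nfill_halfwin half-width (bp) of the N window in the n_fill dialect.
#' @param seed default seed used by [inject_build_errors()].
#' @return a validated `ba_error_profile` list.
#' @export
error_profile <- function(indel_spacing_bp = Inf, p_coding_indel = 0,
                          p_missing_segment = 0, p_unannotated = 0,
                          p_split_locus = 0, p_merged_locus = 0,
                          p_premature_stop_seleno = 0,
                          dialect = c("truncate", "n_fill"),
                          retroelement_copies = 0L, nfill_halfwin = 10L,
                          seed = NULL) {
  dialect <- match.arg(dialect)
  p <- c(indel = p_coding_indel, missing_segment = p_missing_segment,
         unannotated = p_unannotated, split_locus = p_split_locus,
         merged_locus = p_merged_locus, premature_stop = p_premature_stop_seleno)
  if (any(p < 0 | p > 1)) stop_input("profile probabilities must lie in [0, 1]")
  if (sum(p) > 1 + 1e-12) stop_input("profile probabilities must sum to at most 1")
  if (!(indel_spacing_bp > 0)) stop_input("indel_spacing_bp must be positive")
  if (retroelement_copies < 0) stop_input("retroelement_copies must be >= 0")
  structure(
    list(indel_spacing_bp = indel_spacing_bp, p = p, dialect = dialect,
         retroelement_copies = as.integer(retroelement_copies),
         nfill_halfwin = as.integer(nfill_halfwin), seed = seed),
    class = "ba_error_profile"
  )
}

#' Inject documented error classes into a truth build
#'
#' Produces a corrupted genome build from a truth build, together with an
#' exhaustive machine-readable ledger of every corruption (the acceptance
#' oracle for classifier benchmarking). With all rates zero the returned
#' build equals the truth byte for byte and every ledger entry is `none`.
#'
#' @param truth a `ba_truth` object from [emit_genome()].
#' @param profile an [error_profile()].
#' @param seed integer seed (defaults to the profile's seed, then 1).
#' @return a list with elements `build` (a `ba_build`: `genome`, `annotation`,
#'   `dialect`, `build_id`) and `ledger` (a `ba_ledger` tibble with one row
#'   per truth gene: `gene_id`, `injected_error`, `detail` JSON string; the
#'   genome-level indel table is in `attr(ledger, "indel_positions")`).
#' @export
inject_build_errors <- function(truth, profile = error_profile(), seed = NULL) {
  stopifnot(inherits(truth, "ba_truth"), inherits(profile, "ba_error_profile"))
  seed <- seed %||% profile$seed %||% 1L
  models <- truth$models
  n <- nrow(models)
  if (profile$p["merged_locus"] > 0 && n < 2) {
    stop_input("merged_locus injection requires at least 2 genes")
  }
  if (profile$retroelement_copies > 0 &&
      !any(models$gene_class == "retroelement")) {
    stop_input("retroelement_copies requested but no retroelement gene exists")
  }

  with_seed_if(sub_seed(seed, 303L), {
    plan <- draw_error_plan(models, profile)
    built <- assemble_corrupted(truth, plan, profile)
  })
  built
}

# per-gene error class assignment; one uniform draw per gene partitions the
# class probabilities so P(any error) is exactly sum(p)
draw_error_plan <- function(models, profile) {
  n <- nrow(models)
  p <- profile$p
  cuts <- cumsum(p)
  u <- runif(n)
  cls <- rep("none", n)
  for (j in seq_along(cuts)) {
    lo <- if (j == 1) 0 else cuts[j - 1]
    cls[u >= lo & u < cuts[j]] <- names(p)[j]
  }
  # feasibility fallbacks keep the gene errored (total probability intact);
  # a split is only injected when some exon boundary moves a substantive
  # share (15-85%) of the transcript — relocating a sliver is not the
  # "gene appears in two loci" situation
  cls[cls == "premature_stop" & models$gene_class != "selenoprotein"] <- "indel"
  for (i in which(cls == "split_locus")) {
    sh <- if (models$n_exons[i] < 2) 0 else best_split_share(models[i, ])
    if (sh < 0.15 || sh > 0.85) cls[i] <- "indel"
  }

  # merged pairs: only adjacent genes that BOTH drew an error can merge
  partner <- rep(NA_integer_, n)
  for (i in which(cls == "merged_locus")) {
    j <- i + 1L
    ok <- j <= n && models$chrom[j] == models$chrom[i] &&
      is.na(partner[i]) && is.na(partner[j]) &&
      cls[j] != "none" && !cls[j] %in% c("missing_segment", "merged_locus")
    if (ok) {
      cls[c(i, j)] <- "merged_locus"
      partner[i] <- j
      partner[j] <- i
    } else if (is.na(partner[i])) {
      cls[i] <- "indel"
    }
  }

  # indel positions: per-gene Bernoulli indels get one uniform CDS position
  # kept clear of exon boundaries (an edit hugging a splice junction is
  # invisible to spliced alignment and may not disrupt the spliced CDS at
  # all); the Poisson process spreads events over the coding space of clean
  # genes
  cds_len <- models$cds_end - models$cds_start + 1L
  pos_list <- vector("list", n)
  for (i in which(cls == "indel")) {
    pos_list[[i]] <- sample_exon_interior(models[i, ], margin = 20L)
  }
  if (is.finite(profile$indel_spacing_bp)) {
    open <- which(cls == "none")
    span <- sum(cds_len[open])
    n_ev <- rpois(1, span / profile$indel_spacing_bp)
    if (n_ev > 0) {
      off <- sort(ceiling(runif(n_ev) * span))
      off <- off[c(TRUE, diff(off) >= 4L)] # separate edits by >= 4 bp
      ends <- cumsum(cds_len[open])
      gi <- findInterval(off - 1L, c(0L, ends), rightmost.closed = TRUE)
      rel <- off - c(0L, ends)[gi]
      for (g in unique(gi)) {
        i <- open[g]
        cls[i] <- "indel"
        pos_list[[i]] <- pmin(pmax(rel[gi == g], 4L), cds_len[i] - 3L)
      }
    }
  }
  kind_list <- map(pos_list, function(p) {
    if (is.null(p)) NULL else sample(c(0L, 1L), length(p), replace = TRUE)
  })
  len_list <- map(pos_list, function(p) {
    if (is.null(p)) NULL else sample(c(1L, 1L, 2L), length(p), replace = TRUE)
  })
  list(class = cls, partner = partner, cds_pos = pos_list,
       kind = kind_list, len = len_list)
}

# a CDS offset at least `margin` bp from every exon boundary (CDS offsets,
# 1-based); falls back to the most interior position available
sample_exon_interior <- function(model, margin = 20L, n = 1L) {
  cds_len <- model$cds_end - model$cds_start + 1L
  cand <- seq(4L, cds_len - 3L)
  t <- model$cds_start + cand - 1L
  bnd <- cumsum(model$exon_lens[[1]])
  bnd <- bnd[-length(bnd)] # internal exon ends (transcript coords)
  if (length(bnd)) {
    dmin <- vapply(t, function(x) min(abs(x - bnd), abs(x - bnd - 1L)), numeric(1))
    ok <- cand[dmin > margin]
    if (length(ok) == 0) ok <- cand[order(-dmin)][1]
    cand <- ok
  }
  sample(cand, min(n, length(cand)))
}

# transcript coordinate -> region-relative genomic coordinate for one gene
tx_to_region <- function(model, tpos) {
  exon_lens <- model$exon_lens[[1]]
  tx_ends <- cumsum(exon_lens)
  tx_starts <- tx_ends - exon_lens + 1L
  ex <- model$exon_ranges[[1]] # absolute genomic, transcript order
  e <- findInterval(tpos, tx_starts)
  if (model$strand == "+") {
    g <- ex[e, "start"] + (tpos - tx_starts[e])
  } else {
    g <- ex[e, "end"] - (tpos - tx_starts[e])
  }
  as.integer(g - model$gene_start + 1L)
}

# shift a truth region-relative coordinate across truncate-dialect edits
remap_rel <- function(x, pos, kind, len) {
  if (length(pos) == 0) return(x)
  shift <- ifelse(kind == 1L, len, -len)
  vapply(x, function(xx) xx + sum(shift[pos <= xx]), numeric(1))
}

assemble_corrupted <- function(truth, plan, profile) {
  models <- truth$models
  ann <- truth$annotation
  n <- nrow(models)
  dialect <- profile$dialect
  cls <- plan$class
  models$new_offset <- NA_integer_
  models$new_offset2 <- NA_integer_

  region_seq <- str_sub(
    truth$genome[models$chrom], models$gene_start, models$gene_end
  )

  # per-gene corrupted region sequence + region-relative edit table
  edits <- vector("list", n)
  for (i in which(cls == "indel")) {
    rel <- tx_to_region(models[i, ], models$cds_start[i] + plan$cds_pos[[i]] - 1L)
    o <- order(rel)
    ed <- list(pos = rel[o], kind = plan$kind[[i]][o], len = plan$len[[i]][o])
    edits[[i]] <- ed
    region_seq[i] <- cpp_corrupt_seq(region_seq[i], ed$pos, ed$kind, ed$len,
                                     dialect, profile$nfill_halfwin)
  }

  # split plans: region-relative boundary of the relocated suffix block
  split_at <- vector("list", n)
  for (i in which(cls == "split_locus")) {
    split_at[[i]] <- plan_split(models[i, ])
  }

  new_genome <- character(0)
  new_ann <- vector("list", n + 4L)
  ledger_detail <- rep(NA_character_, n)
  indel_rows <- list()
  chrom_of <- models$chrom

  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    chrom_seq <- truth$genome[[ch]]
    elements <- list() # each: seq + optional (gene, block offset within region)
    prev_end <- 0L
    for (i in idx) {
      gap <- str_sub(chrom_seq, prev_end + 1L, models$gene_start[i] - 1L)
      drop_gap <- cls[i] == "merged_locus" && !is.na(plan$partner[i]) &&
        plan$partner[i] < i
      if (!drop_gap) elements[[length(elements) + 1L]] <- list(seq = gap)
      if (cls[i] == "missing_segment") {
        prev_end <- models$gene_end[i]
        next
      }
      reg <- region_seq[i]
      if (cls[i] == "split_locus") {
        s <- split_at[[i]]
        elements[[length(elements) + 1L]] <-
          list(seq = str_sub(reg, 1L, s$keep_end), gene = i, part = 1L)
        moved <- list(seq = str_sub(reg, s$move_start, nchar(reg)),
                      gene = i, part = 2L, block_off = s$move_start)
        # park the relocated block at the far chromosome end
        if (which(idx == i) <= length(idx) / 2) {
          attr(moved, "park") <- "tail"
        } else {
          attr(moved, "park") <- "head"
        }
        split_at[[i]]$moved_element <- moved
      } else {
        elements[[length(elements) + 1L]] <- list(seq = reg, gene = i, part = 1L)
      }
      prev_end <- models$gene_end[i]
    }
    elements[[length(elements) + 1L]] <-
      list(seq = str_sub(chrom_seq, prev_end + 1L, nchar(chrom_seq)))

    # relocated split blocks and planted retroelement copies
    for (i in idx) {
      if (cls[i] == "split_locus") {
        mv <- split_at[[i]]$moved_element
        spacer <- list(seq = cpp_random_dna(2000L))
        if (attr(mv, "park") == "tail") {
          elements <- c(elements, list(spacer, mv))
        } else {
          elements <- c(list(mv, spacer), elements)
        }
      }
    }
    if (profile$retroelement_copies > 0 && ch == chrom_of[1]) {
      src <- which(models$gene_class == "retroelement")[1]
      for (cc in seq_len(profile$retroelement_copies)) {
        elements <- c(elements, list(list(seq = cpp_random_dna(500L)),
                                     list(seq = region_seq[src])))
      }
    }

    # lay elements out, recording each gene part's new absolute offset
    offs <- cumsum(c(0L, map_int(elements, function(e) nchar(e$seq))))
    new_genome[ch] <- paste(map_chr(elements, "seq"), collapse = "")
    for (k in seq_along(elements)) {
      e <- elements[[k]]
      if (is.null(e$gene)) next
      i <- e$gene
      if (e$part == 1L) {
        models$new_offset[i] <- offs[k] + 1L
      } else {
        models$new_offset2[i] <- offs[k] + 1L
      }
    }
  }

  # rebuild annotation gene by gene
  k <- 1L
  for (i in seq_len(n)) {
    if (cls[i] %in% c("unannotated", "missing_segment")) next
    fa <- ann[ann$gene_id == models$gene_id[i], ]
    rel_s <- fa$start - models$gene_start[i] + 1L
    rel_e <- fa$end - models$gene_start[i] + 1L
    if (cls[i] == "indel" && dialect == "truncate") {
      ed <- edits[[i]]
      rel_s <- remap_rel(rel_s, ed$pos, ed$kind, ed$len)
      rel_e <- remap_rel(rel_e, ed$pos, ed$kind, ed$len)
    }
    if (cls[i] == "premature_stop") {
      fa2 <- truncate_seleno_annotation(models[i, ], fa)
      rel_s <- fa2$start - models$gene_start[i] + 1L
      rel_e <- fa2$end - models$gene_start[i] + 1L
      fa <- fa2
    }
    if (cls[i] == "split_locus") {
      s <- split_at[[i]]
      part2 <- rel_s >= s$move_start
      abs_s <- ifelse(part2, models$new_offset2[i] + (rel_s - s$move_start),
                      models$new_offset[i] + rel_s - 1L)
      abs_e <- ifelse(part2, models$new_offset2[i] + (rel_e - s$move_start),
                      models$new_offset[i] + rel_e - 1L)
      fa$start <- as.integer(abs_s)
      fa$end <- as.integer(abs_e)
      fa <- split_gene_annotation(fa, part2, models$gene_id[i])
    } else {
      fa$start <- as.integer(models$new_offset[i] + rel_s - 1L)
      fa$end <- as.integer(models$new_offset[i] + rel_e - 1L)
    }
    new_ann[[k]] <- fa
    k <- k + 1L
  }
  out_ann <- bind_rows(new_ann)
  if (nrow(out_ann) == 0) {
    out_ann <- ann[0, ]
  }
  out_ann <- merge_gene_annotations(out_ann, models, plan)
  out_ann <- out_ann[order(out_ann$seqid, out_ann$start,
                           match(out_ann$type, c("gene", "mRNA", "exon", "CDS"))), ]

  # ledger; indel positions are in corrupted-build coordinates (earlier edits
  # on the same region shift later positions in the truncate dialect)
  new_edit_pos <- function(i) {
    ed <- edits[[i]]
    shift <- if (dialect == "truncate") {
      s <- ifelse(ed$kind == 1L, ed$len, -ed$len)
      c(0L, cumsum(s))[seq_along(ed$pos)]
    } else 0L
    as.integer(models$new_offset[i] - 1L + ed$pos + shift)
  }
  detail <- map_chr(seq_len(n), function(i) {
    d <- switch(cls[i],
      indel = list(positions = new_edit_pos(i),
                   kind = ifelse(edits[[i]]$kind == 1L, "insertion", "deletion"),
                   len = edits[[i]]$len, dialect = dialect),
      split_locus = list(part2_offset = models$new_offset2[i]),
      merged_locus = list(partner = models$gene_id[plan$partner[i]]),
      NULL
    )
    if (is.null(d)) NA_character_
    else as.character(jsonlite::toJSON(d, auto_unbox = TRUE))
  })
  ledger <- tibble(gene_id = models$gene_id, injected_error = cls,
                   detail = detail)
  ip <- bind_rows(map(which(cls == "indel"), function(i) {
    ed <- edits[[i]]
    tibble(chrom = models$chrom[i], gene_id = models$gene_id[i],
           pos = new_edit_pos(i),
           kind = ifelse(ed$kind == 1L, "insertion", "deletion"), len = ed$len)
  }))
  attr(ledger, "indel_positions") <- ip
  class(ledger) <- c("ba_ledger", class(ledger))

  build <- structure(
    list(genome = new_genome, annotation = as_tibble(out_ann),
         dialect = dialect, build_id = "synthetic_corrupted"),
    class = "ba_build"
  )
  list(build = build, ledger = ledger)
}

# transcript share carried by the best genomic suffix block of exons
best_split_share <- function(model) {
  exon_lens <- model$exon_lens[[1]]
  n_ex <- length(exon_lens)
  ex <- model$exon_ranges[[1]]
  ord <- order(ex[, "start"])
  moved_tx <- vapply(2:n_ex, function(t) sum(exon_lens[ord[t:n_ex]]), numeric(1))
  moved_tx[which.min(abs(moved_tx - model$tx_len[1] / 2))] / model$tx_len[1]
}

# choose the genomic exon boundary whose downstream block carries a
# transcript share closest to 50%, and relocate that genomic suffix block
plan_split <- function(model) {
  exon_lens <- model$exon_lens[[1]] # transcript order
  n_ex <- length(exon_lens)
  ex <- model$exon_ranges[[1]] - model$gene_start[1] + 1L # region-relative
  ord <- order(ex[, "start"]) # genomic order of transcript exon indices
  moved_tx <- vapply(2:n_ex, function(t) sum(exon_lens[ord[t:n_ex]]), numeric(1))
  t <- which.min(abs(moved_tx - model$tx_len[1] / 2)) + 1L
  list(keep_end = ex[ord[t - 1L], "end"], move_start = ex[ord[t], "start"])
}

# annotated CDS truncated at the first Sec UGA, as if it terminated there
truncate_seleno_annotation <- function(model, fa) {
  sec1 <- model$sec_codons[[1]][1]
  new_cds_end <- model$cds_start[1] + 3L * sec1 - 1L # UGA kept as the "stop"
  exon_lens <- model$exon_lens[[1]]
  tx_ends <- cumsum(exon_lens)
  tx_starts <- tx_ends - exon_lens + 1L
  ex <- model$exon_ranges[[1]]
  cds <- cds_genomic_intervals(tx_starts, tx_ends, ex, model$strand[1],
                               model$cds_start[1], new_cds_end)
  keep <- fa$type != "CDS"
  tid <- fa$ID[fa$type == "mRNA"][1]
  bind_rows(
    fa[keep, ],
    tibble(seqid = fa$seqid[1], type = "CDS", start = cds[, "start"],
           end = cds[, "end"], strand = fa$strand[1],
           ID = sprintf("%s.c%d", tid, seq_len(nrow(cds))), Parent = tid,
           gene_id = fa$gene_id[1])
  )
}

# rebuild gene/mRNA container spans for the two halves of a split gene
split_gene_annotation <- function(fa, part2, gid) {
  leaf <- fa$type %in% c("exon", "CDS")
  halves <- map(list(which(leaf & !part2), which(leaf & part2)), function(ix) fa[ix, ])
  out <- list()
  for (h in 1:2) {
    lf <- halves[[h]]
    if (nrow(lf) == 0) next
    suffix <- if (h == 2) "_2" else ""
    gid_h <- paste0(gid, suffix)
    tid_h <- paste0(gid, suffix, ".t1")
    lf$Parent <- tid_h
    out[[length(out) + 1L]] <- bind_rows(
      tibble(seqid = lf$seqid[1], type = c("gene", "mRNA"),
             start = min(lf$start), end = max(lf$end), strand = lf$strand[1],
             ID = c(gid_h, tid_h), Parent = c(NA_character_, gid_h), gene_id = gid),
      lf
    )
  }
  bind_rows(out)
}

# replace the two gene containers of a merged pair with one spanning feature
merge_gene_annotations <- function(ann, models, plan) {
  firsts <- which(plan$class == "merged_locus" & !is.na(plan$partner) &
                    plan$partner > seq_along(plan$class))
  for (i in firsts) {
    j <- plan$partner[i]
    gids <- models$gene_id[c(i, j)]
    sel <- ann$gene_id %in% gids
    genes <- ann[sel & ann$type == "gene", ]
    mid <- paste(gids, collapse = "+")
    merged <- tibble(seqid = genes$seqid[1], type = "gene",
                     start = min(genes$start), end = max(genes$end),
                     strand = genes$strand[1], ID = mid, Parent = NA_character_,
                     gene_id = mid)
    ann <- ann[!(sel & ann$type == "gene"), ]
    ann$Parent[ann$gene_id %in% gids & ann$type == "mRNA"] <- mid
    ann <- bind_rows(ann, merged)
  }
  ann
}
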