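#' Emit a synthetic genome and truth annotation from gene models
#'
#' Lays the gene models out on chromosomes separated by random intergenic
#' sequence, with canonical GT..AG introns, and returns the genome together
#' with a GFF3-style truth annotation (gene/mRNA/exon/CDS features with
#' ID/Parent attributes). Readthrough parent pairs are always placed adjacent
#' on the same strand, transcript order preserved. Extracting each gene's
#' exons from the emitted genome and splicing them reproduces its transcript
#' exactly (see [spliced_transcript()]).
#'
#' @param models tibble from [generate_gene_models()].
#' @param intergenic intergenic gap range in bp.
#' @param genes_per_chrom genes placed per chromosome.
#' @param seed integer seed for the intergenic/intron sequence draw.
#' @return a `ba_truth` list: `genome` (named character vector of chromosome
#'   sequences), `annotation` (feature tibble with 1-based inclusive
#'   coordinates), `models` (input tibble plus `chrom`, `gene_start`,
#'   `gene_end` and genomic `exon_ranges`).
#' @export
emit_genome <- function(models, intergenic = c(300L, 1000L),
                        genes_per_chrom = 100L, seed = 1) {
  stopifnot(is.data.frame(models), nrow(models) > 0)
  n <- nrow(models)
  chrom_of <- sprintf("chr%d", ((seq_len(n) - 1L) %/% genes_per_chrom) + 1L)

  chroms <- unique(chrom_of)
  with_seed_if(sub_seed(seed, 202L), {
    regions <- pmap(models[c("transcript", "exon_lens", "intron_lens", "strand")],
                    build_gene_region)
    gaps <- map(seq_len(n), function(i) cpp_random_dna(runif_int(1, intergenic)))
    trailing <- setNames(
      map_chr(chroms, function(ch) cpp_random_dna(runif_int(1, intergenic))),
      chroms
    )
  })
  # readthrough pairs abut: drop the gap between the two parents
  if (!is.null(models$pair_id)) {
    second_of_pair <- which(!is.na(models$pair_id) &
                              duplicated(models$pair_id))
    for (i in second_of_pair) gaps[[i]] <- ""
  }

  genome <- character(0)
  ann <- vector("list", n)
  out_models <- models
  out_models$chrom <- chrom_of
  out_models$gene_start <- NA_integer_
  out_models$gene_end <- NA_integer_
  out_models$exon_ranges <- vector("list", n)

  for (ch in chroms) {
    idx <- which(chrom_of == ch)
    pieces <- character(0)
    at <- 1L
    for (j in seq_along(idx)) {
      i <- idx[j]
      gap <- gaps[[i]]
      pieces <- c(pieces, gap)
      at <- at + nchar(gap)
      reg <- regions[[i]]
      out_models$gene_start[i] <- at
      out_models$gene_end[i] <- at + nchar(reg$seq) - 1L
      out_models$exon_ranges[[i]] <- reg$exons + (at - 1L)
      ann[[i]] <- gene_features(models[i, ], ch, at, reg)
      pieces <- c(pieces, reg$seq)
      at <- at + nchar(reg$seq)
    }
    pieces <- c(pieces, trailing[[ch]])
    genome[ch] <- paste(pieces, collapse = "")
  }

  structure(
    list(genome = genome, annotation = bind_rows(ann), models = out_models),
    class = "ba_truth"
  )
}

# gene region on the genome: exons joined by GT..AG introns, reverse
# complemented for minus-strand genes. Returns the region sequence plus the
# genomic exon/CDS intervals (region-relative, transcript order).
build_gene_region <- function(transcript, exon_lens, intron_lens, strand) {
  n_ex <- length(exon_lens)
  ends <- cumsum(exon_lens)
  starts <- ends - exon_lens + 1L
  exon_seqs <- str_sub(transcript, starts, ends)
  introns <- map_chr(intron_lens, function(L) {
    paste0("GT", cpp_random_dna(max(0L, L - 4L)), "AG")
  })
  parts <- character(2L * n_ex - 1L)
  parts[seq(1L, by = 2L, length.out = n_ex)] <- exon_seqs
  if (n_ex > 1) parts[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
  sense <- paste(parts, collapse = "")
  reg_len <- nchar(sense)

  # region-relative exon intervals on the sense layout
  gstart <- integer(n_ex)
  at <- 1L
  for (e in seq_len(n_ex)) {
    gstart[e] <- at
    at <- at + exon_lens[e] + if (e < n_ex) nchar(introns[e]) else 0L
  }
  ex <- cbind(start = gstart, end = gstart + exon_lens - 1L)
  if (strand == "-") {
    seq_out <- revcomp(sense)
    ex <- cbind(start = reg_len - ex[, "end"] + 1L, end = reg_len - ex[, "start"] + 1L)
  } else {
    seq_out <- sense
  }
  list(seq = seq_out, exons = ex, tx_exon_starts = starts, tx_exon_ends = ends)
}

# feature rows (gene/mRNA/exon/CDS) for one placed gene; `at` is the genomic
# start of its region
gene_features <- function(model, chrom, at, reg) {
  ex <- reg$exons + (at - 1L)
  gid <- model$gene_id
  tid <- paste0(gid, ".t1")
  g_lo <- min(ex[, "start"]); g_hi <- max(ex[, "end"])
  rows <- list(
    tibble(seqid = chrom, type = c("gene", "mRNA"),
           start = g_lo, end = g_hi, strand = model$strand,
           ID = c(gid, tid), Parent = c(NA_character_, gid), gene_id = gid)
  )
  n_ex <- nrow(ex)
  rows[[2]] <- tibble(
    seqid = chrom, type = "exon", start = ex[, "start"], end = ex[, "end"],
    strand = model$strand, ID = sprintf("%s.e%d", tid, seq_len(n_ex)),
    Parent = tid, gene_id = gid
  )
  cds <- cds_genomic_intervals(
    reg$tx_exon_starts, reg$tx_exon_ends, ex, model$strand,
    model$cds_start, model$cds_end
  )
  rows[[3]] <- tibble(
    seqid = chrom, type = "CDS", start = cds[, "start"], end = cds[, "end"],
    strand = model$strand, ID = sprintf("%s.c%d", tid, seq_len(nrow(cds))),
    Parent = tid, gene_id = gid
  )
  bind_rows(rows)
}

# map the transcript-coordinate CDS span onto genomic intervals, exon by exon
cds_genomic_intervals <- function(tx_starts, tx_ends, exons_genomic, strand,
                                  cds_start, cds_end) {
  keep <- which(tx_ends >= cds_start & tx_starts <= cds_end)
  out <- matrix(0L, nrow = length(keep), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
  for (k in seq_along(keep)) {
    e <- keep[k]
    lo_t <- max(tx_starts[e], cds_start)
    hi_t <- min(tx_ends[e], cds_end)
    if (strand == "+") {
      out[k, ] <- c(exons_genomic[e, "start"] + (lo_t - tx_starts[e]),
                    exons_genomic[e, "start"] + (hi_t - tx_starts[e]))
    } else {
      out[k, ] <- c(exons_genomic[e, "end"] - (hi_t - tx_starts[e]),
                    exons_genomic[e, "end"] - (lo_t - tx_starts[e]))
    }
  }
  out[order(out[, "start"]), , drop = FALSE]
}

#' Splice a gene's transcript back out of a genome
#'
#' Extracts the annotated exons of one gene from a genome and splices them in
#' transcript order (reverse-complementing minus-strand genes). On an
#' uncorrupted truth build this reproduces the library transcript exactly.
#'
#' @param genome named character vector of chromosome sequences.
#' @param annotation feature tibble as produced by [emit_genome()].
#' @param gene_id gene identifier to extract.
#' @return the spliced transcript as a single string.
#' @export
spliced_transcript <- function(genome, annotation, gene_id) {
  ex <- annotation[annotation$gene_id == gene_id & annotation$type == "exon", ]
  if (nrow(ex) == 0) stop_input("gene '%s' has no exon features", gene_id)
  ex <- ex[order(ex$start), ]
  chrom <- genome[[ex$seqid[1]]]
  pieces <- str_sub(chrom, ex$start, ex$end)
  if (ex$strand[1] == "-") paste(rev(revcomp(pieces)), collapse = "")
  else paste(pieces, collapse = "")
}
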