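#' Six-frame homology search of a protein query against a genome
#'
#' The census tool for retroelement ORFs and unannotated microproteins:
#' translates the genome in all six frames, seeds candidate loci with exact
#' amino-acid word matches to the query, scores each candidate by local
#' protein alignment, and reports non-overlapping hits (greedy by score, then
#' leftmost). A hit is `intact` when it covers the query at full length with
#' no internal stop and at least the identity threshold; an internal stop (or
#' hits split across frames at one locus, the frameshift signature) within an
#' otherwise matching region marks it `pseudogenized`.
#'
#' @param query protein sequence, at least 30 AA.
#' @param genome named character vector of chromosomes (or
#'   `ba_truth`/`ba_build`).
#' @param min_identity minimum alignment identity for reporting a hit.
#' @param min_len_frac minimum fraction of the query an intact hit must
#'   cover.
#' @param seed_k exact amino-acid seed word length.
#' @return tibble of hits: `chrom`, `start`, `end` (genomic, forward
#'   coordinates), `strand`, `frame`, `score`, `identity`, `coverage`,
#'   `intact`, `pseudogenized`.
#' @export
orf_homology_search <- function(query, genome, min_identity = 0.60,
                                min_len_frac = 0.70, seed_k = 6L) {
  if (nchar(query) < 30) stop_input("query must be at least 30 AA")
  genome <- as_genome(genome)
  if (sum(nchar(genome)) == 0) stop_input("empty genome")
  qlen <- nchar(query)
  hits <- list()
  for (ch in names(genome)) {
    L <- nchar(genome[[ch]])
    for (strand in c("+", "-")) {
      seqs <- if (strand == "+") genome[[ch]] else revcomp(genome[[ch]])
      for (frame in 0:2) {
        n_cod <- (nchar(seqs) - frame) %/% 3L
        if (n_cod < seed_k) next
        aa <- six_frame_translate(str_sub(seqs, frame + 1L,
                                          frame + 3L * n_cod))
        anc <- cpp_aa_anchors(toupper(query), aa, as.integer(seed_k))
        if (nrow(anc) == 0) next
        for (cl in split_clusters(anc, max_gap = qlen)) {
          w_lo <- max(1L, min(cl[, "sstart"]) - qlen)
          w_hi <- min(nchar(aa), max(cl[, "sstart"] + cl[, "len"]) + qlen)
          win <- str_sub(aa, w_lo, w_hi)
          al <- Biostrings::pairwiseAlignment(
            Biostrings::AAString(toupper(query)), Biostrings::AAString(win),
            type = "local", substitutionMatrix = audit_scoring_matrix(),
            gapOpening = 11, gapExtension = 1
          )
          wq <- Biostrings::nchar(al)
          if (wq == 0) next
          idt <- Biostrings::nmatch(al) / wq
          if (idt < min_identity) next
          sub_aln <- as.character(Biostrings::alignedSubject(al))
          aa_lo <- w_lo + Biostrings::start(Biostrings::subject(al)) - 1L
          aa_hi <- w_lo + Biostrings::end(Biostrings::subject(al)) - 1L
          cov <- (Biostrings::end(Biostrings::pattern(al)) -
                    Biostrings::start(Biostrings::pattern(al)) + 1L) / qlen
          # frame AA interval -> forward genomic interval
          nt_lo <- frame + 3L * (aa_lo - 1L) + 1L
          nt_hi <- frame + 3L * aa_hi
          g <- if (strand == "+") c(nt_lo, nt_hi) else c(L - nt_hi + 1L, L - nt_lo + 1L)
          hits[[length(hits) + 1L]] <- tibble(
            chrom = ch, start = g[1], end = g[2], strand = strand,
            frame = frame + 1L, score = as.numeric(Biostrings::score(al)),
            identity = idt, coverage = cov,
            internal_stop = str_detect(sub_aln, "\\*")
          )
        }
      }
    }
  }
  if (length(hits) == 0) return(empty_orf_hits())
  hits <- bind_rows(hits)

  # greedy non-overlap resolution by score then leftmost; loci hit in more
  # than one frame before resolution carry the frameshift signature
  hits <- hits[order(-hits$score, hits$chrom, hits$start), ]
  kept <- list()
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    clash <- FALSE
    shifted <- FALSE
    for (k in kept) {
      if (k$chrom == h$chrom && k$start <= h$end && h$start <= k$end) {
        clash <- TRUE
        break
      }
    }
    if (clash) {
      j <- which(map_lgl(kept, function(k) {
        k$chrom == h$chrom && k$start <= h$end && h$start <= k$end &&
          (k$frame != h$frame || k$strand != h$strand)
      }))
      for (jj in j) kept[[jj]]$frame_split <- TRUE
      next
    }
    h$frame_split <- FALSE
    kept[[length(kept) + 1L]] <- h
  }
  out <- bind_rows(kept)
  out$intact <- !out$internal_stop & out$coverage >= min_len_frac &
    out$identity >= min_identity
  out$pseudogenized <- !out$intact & (out$internal_stop | out$frame_split)
  out <- out[order(out$chrom, out$start),
             c("chrom", "start", "end", "strand", "frame", "score", "identity",
               "coverage", "intact", "pseudogenized")]
  as_tibble(out)
}

empty_orf_hits <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         strand = character(), frame = integer(), score = numeric(),
         identity = numeric(), coverage = numeric(), intact = logical(),
         pseudogenized = logical())
}

six_frame_translate <- function(nt) {
  as.character(Biostrings::translate(
    Biostrings::DNAString(gsub("[^ACGTN]", "N", toupper(nt))),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}
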