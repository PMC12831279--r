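#' Mapping parameters for the spliced transcript mapper
#'
#' @param k seed k-mer length (nucleotides, exact match).
#' @param max_occ seeds occurring more often than this in the subject are
#'   skipped as repetitive.
#' @param min_identity minimum locus identity to report.
#' @param min_coverage minimum fraction of the transcript a locus must cover
#'   to be reported (kept low so both halves of a split gene surface).
#' @param max_locus_gap genomic gap (bp) beyond which anchors are considered
#'   separate loci rather than one spliced locus.
#' @param min_intron smallest genomic gap treated as an intron.
#' @param max_qgap_intron largest transcript-side gap still compatible with an
#'   intron junction.
#' @param splice_wobble how far (bp) a junction may be shifted in search of a
#'   canonical GT..AG intron.
#' @param stride subject k-mer sampling stride (1 = every position; larger
#'   values trade block-boundary resolution, at most `stride - 1` bp, for
#'   speed — gap lengths between blocks stay exact).
#' @return a list of mapper parameters.
#' @export
map_params <- function(k = 16L, max_occ = 64L, min_identity = 0.85,
                       min_coverage = 0.10, max_locus_gap = 50000L,
                       min_intron = 30L, max_qgap_intron = 4L,
                       splice_wobble = 5L, stride = 1L) {
  list(k = as.integer(k), max_occ = as.integer(max_occ),
       min_identity = min_identity, min_coverage = min_coverage,
       max_locus_gap = as.integer(max_locus_gap),
       min_intron = as.integer(min_intron),
       max_qgap_intron = as.integer(max_qgap_intron),
       splice_wobble = as.integer(splice_wobble),
       stride = as.integer(stride))
}

#' Prebuild a reusable k-mer index over a genome
#'
#' Indexing the genome once and mapping many transcripts against it is much
#' faster than re-indexing per transcript. The index holds external pointers
#' and is valid for the current session only.
#'
#' @param genome named character vector of chromosome sequences.
#' @param k seed length (must match the mapping parameters used later).
#' @param stride subject k-mer sampling stride (see [map_params()]).
#' @return a `ba_genome_index` object.
#' @export
genome_index <- function(genome, k = 16L, stride = 1L) {
  genome <- as_genome(genome)
  structure(
    list(genome = genome, k = as.integer(k),
         ptrs = map(genome, function(s) {
           cpp_index_build(s, as.integer(k), FALSE, as.integer(stride))
         })),
    class = "ba_genome_index"
  )
}

as_genome <- function(genome) {
  if (inherits(genome, c("ba_truth", "ba_build"))) genome <- genome$genome
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (!is.character(genome) || is.null(names(genome))) {
    stop_input("genome must be a named character vector of chromosomes")
  }
  lower <- vapply(genome, function(s) grepl("[a-z]", s, perl = TRUE), logical(1))
  genome[lower] <- toupper(genome[lower])
  genome
}

#' Map a transcript to a genome by seed-and-chain spliced alignment
#'
#' Finds all loci where the transcript aligns, chaining exact k-mer anchors
#' into co-linear blocks; genomic gaps of at least `min_intron` with little or
#' no transcript-side gap are treated as introns, with junctions nudged onto
#' canonical GT..AG boundaries (leftmost on ties). Both strands are searched;
#' coordinates are always reported on the forward genome. For minus-strand
#' loci the transcript-side block coordinates refer to the
#' reverse-complemented transcript (alignment orientation).
#'
#' @param transcript transcript sequence (a single string).
#' @param genome named character vector of chromosomes, a `ba_truth`/`ba_build`
#'   object, or a prebuilt [genome_index()].
#' @param params mapper parameters from [map_params()].
#' @param transcript_id identifier carried into the result.
#' @return a tibble of loci sorted by score (matched bases), with per-locus
#'   `chrom`, `strand`, `start`, `end`, `identity`, `coverage`, `score`,
#'   `n_blocks` and a `blocks` list column (`tstart`, `tend`, `sstart`,
#'   `send`, `mismatches`, `intron_before`). Zero rows when nothing maps.
#' @export
map_transcript <- function(transcript, genome, params = map_params(),
                           transcript_id = "tx") {
  if (nchar(transcript) < params$k) {
    stop_input("transcript shorter than the seed length")
  }
  if (inherits(genome, "ba_genome_index")) {
    idx <- genome
    if (idx$k != params$k) stop_input("genome index built with a different k")
  } else {
    idx <- genome_index(genome, params$k, params$stride)
  }
  if (sum(nchar(idx$genome)) == 0) stop_input("empty genome")

  tx_len <- nchar(transcript)
  if (grepl("[a-z]", transcript, perl = TRUE)) transcript <- toupper(transcript)
  pats <- c(`+` = transcript, `-` = revcomp(transcript))
  loci <- list()
  for (ch in names(idx$genome)) {
    for (std in c("+", "-")) {
      anc <- cpp_index_query(idx$ptrs[[ch]], pats[[std]], params$max_occ)
      if (nrow(anc) == 0) next
      for (cl in split_clusters(anc, params$max_locus_gap)) {
        loc <- chain_locus(cl, idx$genome[[ch]], tx_len, params, pats[[std]])
        if (is.null(loc)) next
        loc$chrom <- ch
        loc$strand <- std
        loci[[length(loci) + 1L]] <- loc
      }
    }
  }
  if (length(loci) == 0) return(empty_loci(transcript_id))
  out <- bind_rows(loci)
  out$transcript_id <- transcript_id
  out <- out[out$coverage >= params$min_coverage &
               out$identity >= params$min_identity, ]
  out <- out[order(-out$score, out$chrom, out$start),
             c("transcript_id", "chrom", "strand", "start", "end", "identity",
               "coverage", "score", "n_blocks", "blocks")]
  structure(as_tibble(out), class = c("ba_loci", class(as_tibble(out))))
}

empty_loci <- function(transcript_id) {
  structure(
    tibble(transcript_id = character(), chrom = character(),
           strand = character(), start = integer(), end = integer(),
           identity = numeric(), coverage = numeric(), score = numeric(),
           n_blocks = integer(), blocks = list()),
    class = c("ba_loci", class(tibble()))
  )
}

# split anchors into candidate loci by genomic gap
split_clusters <- function(anc, max_gap) {
  o <- order(anc[, "sstart"])
  anc <- anc[o, , drop = FALSE]
  send <- anc[, "sstart"] + anc[, "len"] - 1L
  brk <- c(0L, which(anc[-1L, "sstart"] - cummax(send)[-nrow(anc)] > max_gap),
           nrow(anc))
  map(seq_len(length(brk) - 1L), function(i) {
    anc[(brk[i] + 1L):brk[i + 1L], , drop = FALSE]
  })
}

# chain anchors of one candidate locus into co-linear blocks
chain_locus <- function(anc, chrom_seq, tx_len, params, pattern = NULL) {
  n <- nrow(anc)
  if (n > 3000L) { # keep the quadratic chain bounded on repeat blowups
    anc <- anc[order(-anc[, "len"])[1:3000], , drop = FALSE]
    n <- 3000L
  }
  o <- order(anc[, "qstart"], anc[, "sstart"])
  qs <- anc[o, "qstart"]; ss <- anc[o, "sstart"]; ln <- anc[o, "len"]
  qe <- qs + ln - 1L; se <- ss + ln - 1L

  score <- as.numeric(ln)
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (qe[j] >= qe[i] || se[j] >= se[i] || ss[j] > ss[i]) next
      qgap <- qs[i] - qe[j] - 1L
      sgap <- ss[i] - se[j] - 1L
      if (qgap < -ln[i] + 1L) next
      pen <- 0.01 * min(abs(qgap), abs(sgap)) + 0.5 * (qgap != sgap)
      cand <- score[j] + ln[i] - pen
      if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
    }
  }
  tail_i <- which.max(score)
  path <- integer(0)
  while (tail_i > 0L) { path <- c(tail_i, path); tail_i <- prev[tail_i] }

  # trim overlaps between successive chained anchors
  cq <- qs[path]; cs <- ss[path]; cl <- ln[path]
  for (i in seq_along(path)[-1]) {
    ov <- max((cq[i - 1] + cl[i - 1]) - cq[i], (cs[i - 1] + cl[i - 1]) - cs[i], 0L)
    cq[i] <- cq[i] + ov; cs[i] <- cs[i] + ov; cl[i] <- cl[i] - ov
  }
  keep <- cl > 0L
  cq <- cq[keep]; cs <- cs[keep]; cl <- cl[keep]
  if (length(cq) == 0) return(NULL)

  # merge same-diagonal neighbours (mismatch runs) into blocks
  b_tstart <- cq[1]; b_sstart <- cs[1]; b_mm <- 0L
  blocks <- list()
  intron_flag <- logical(0)
  flush <- function(tend, send) {
    blocks[[length(blocks) + 1L]] <<- c(b_tstart, tend, b_sstart, send, b_mm)
  }
  for (i in seq_along(cq)[-1]) {
    qgap <- cq[i] - (cq[i - 1] + cl[i - 1])
    sgap <- cs[i] - (cs[i - 1] + cl[i - 1])
    if (qgap == sgap && qgap <= 40L) {
      b_mm <- b_mm + qgap
      next
    }
    flush(cq[i] - qgap - 1L, cs[i] - sgap - 1L)
    intron_flag <- c(intron_flag,
                     sgap >= params$min_intron && qgap <= params$max_qgap_intron)
    b_tstart <- cq[i]; b_sstart <- cs[i]; b_mm <- 0L
  }
  flush(cq[length(cq)] + cl[length(cl)] - 1L, cs[length(cs)] + cl[length(cl)] - 1L)
  bm <- do.call(rbind, blocks)
  bl <- tibble(
    tstart = bm[, 1], tend = bm[, 2], sstart = bm[, 3], send = bm[, 4],
    mismatches = bm[, 5], intron_before = c(FALSE, intron_flag)
  )
  bl <- refine_splice_sites(bl, chrom_seq, params)
  if (!is.null(pattern)) bl <- centre_indel_gaps(bl, pattern, chrom_seq, params)

  aligned <- sum(bl$tend - bl$tstart + 1L)
  mism <- sum(bl$mismatches)
  tibble(
    start = min(bl$sstart), end = max(bl$send),
    identity = (aligned - mism) / aligned, coverage = aligned / tx_len,
    score = aligned - mism, n_blocks = nrow(bl), blocks = list(bl)
  )
}

# centre indel junctions within their placement-ambiguity run: when the base
# left of a gap also matches across it, the gap can slide; the midpoint of
# the slidable range is the canonical placement reported
centre_indel_gaps <- function(bl, pattern, chrom_seq, params) {
  for (i in seq_len(nrow(bl))[-1]) {
    qgap <- bl$tstart[i] - bl$tend[i - 1] - 1L
    sgap <- bl$sstart[i] - bl$send[i - 1] - 1L
    if (qgap == sgap) next
    if (sgap >= params$min_intron && qgap <= params$max_qgap_intron) next
    # a slide by one is valid when the trailing matched pair still matches
    # across the gap on both the transcript and the genome side
    L <- 0L
    while (L < 20L && bl$tend[i - 1] - L >= bl$tstart[i - 1] + 1L) {
      p_ok <- str_sub(pattern, bl$tend[i - 1] - L, bl$tend[i - 1] - L) ==
        str_sub(chrom_seq, bl$sstart[i] - 1L - L, bl$sstart[i] - 1L - L)
      s_ok <- str_sub(chrom_seq, bl$send[i - 1] - L, bl$send[i - 1] - L) ==
        str_sub(pattern, bl$tstart[i] - 1L - L, bl$tstart[i] - 1L - L)
      if (!p_ok || !s_ok) break
      L <- L + 1L
    }
    s <- L %/% 2L
    if (s > 0L) {
      bl$tend[i - 1] <- bl$tend[i - 1] - s
      bl$send[i - 1] <- bl$send[i - 1] - s
      bl$tstart[i] <- bl$tstart[i] - s
      bl$sstart[i] <- bl$sstart[i] - s
    }
  }
  bl
}

# nudge intron junctions onto GT..AG (smallest shift, leftmost on ties)
refine_splice_sites <- function(bl, chrom_seq, params) {
  for (i in which(bl$intron_before)) {
    donor <- bl$send[i - 1] + 1L
    acceptor <- bl$sstart[i] - 1L
    if (str_sub(chrom_seq, donor, donor + 1L) == "GT" &&
        str_sub(chrom_seq, acceptor - 1L, acceptor) == "AG") next
    for (d in order(abs(seq(-params$splice_wobble, params$splice_wobble)),
                    seq(-params$splice_wobble, params$splice_wobble))) {
      sh <- seq(-params$splice_wobble, params$splice_wobble)[d]
      if (sh == 0) next
      dn <- donor + sh; ac <- acceptor + sh
      if (str_sub(chrom_seq, dn, dn + 1L) == "GT" &&
          str_sub(chrom_seq, ac - 1L, ac) == "AG") {
        bl$send[i - 1] <- bl$send[i - 1] + sh
        bl$tend[i - 1] <- bl$tend[i - 1] + sh
        bl$sstart[i] <- bl$sstart[i] + sh
        bl$tstart[i] <- bl$tstart[i] + sh
        break
      }
    }
  }
  bl
}
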