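#' Write a genome (or any named sequences) as wrapped FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param protein write as amino-acid records instead of DNA.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path, protein = FALSE) {
  x <- if (protein) Biostrings::AAStringSet(seqs) else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path file path.
#' @param protein read as amino-acid records.
#' @return named character vector.
#' @export
read_fasta <- function(path, protein = FALSE) {
  x <- if (protein) Biostrings::readAAStringSet(path) else Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a feature table as GFF3
#'
#' Emits gene/mRNA/exon/CDS features with ID/Parent attributes, 1-based
#' inclusive coordinates (the internal feature tibbles already use GFF
#' conventions, so no shifting happens here).
#'
#' @param annotation feature tibble (`seqid`, `type`, `start`, `end`,
#'   `strand`, `ID`, `Parent`, `gene_id`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqid,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand
  )
  S4Vectors::mcols(gr)$type <- annotation$type
  S4Vectors::mcols(gr)$ID <- annotation$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(annotation$Parent), NA,
                                        annotation$Parent)
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  S4Vectors::mcols(gr)$phase <- cds_phase(annotation)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

# GFF3 phase per CDS piece: offset to the next codon start, accumulated in
# translation order (reverse genomic order on the minus strand)
cds_phase <- function(annotation) {
  phase <- rep(NA_integer_, nrow(annotation))
  is_cds <- annotation$type == "CDS"
  for (tid in unique(annotation$Parent[is_cds])) {
    i <- which(is_cds & annotation$Parent == tid)
    i <- i[order(annotation$start[i],
                 decreasing = annotation$strand[i[1]] == "-")]
    lens <- annotation$end[i] - annotation$start[i] + 1L
    phase[i] <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
  }
  phase
}

#' Read a GFF3 file into the package's feature tibble
#'
#' @param path file path.
#' @return feature tibble with `seqid`, `type`, `start`, `end`, `strand`,
#'   `ID`, `Parent`, `gene_id`.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- md$Parent
  if (!is.null(parent) && methods::is(parent, "List")) {
    parent <- map_chr(as.list(parent), function(p) {
      if (length(p) == 0) NA_character_ else p[[1]]
    })
  }
  tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(md$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ID = as.character(md$ID),
    Parent = parent %||% NA_character_,
    gene_id = if (!is.null(md$gene_id)) as.character(md$gene_id) else NA_character_
  )
}

#' Write / read an error ledger as TSV
#'
#' The ledger's `detail` column holds a JSON string per corrupted gene; the
#' genome-level indel table travels alongside as `<path>.indels.tsv`.
#'
#' @param ledger a `ba_ledger`.
#' @param path output path (TSV).
#' @return the path, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  utils::write.table(as.data.frame(ledger), path, sep = "\t", quote = TRUE,
                     qmethod = "double", row.names = FALSE, na = "")
  ip <- attr(ledger, "indel_positions")
  if (!is.null(ip) && nrow(ip) > 0) {
    utils::write.table(as.data.frame(ip), paste0(path, ".indels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_ledger
#' @export
read_ledger <- function(path) {
  led <- as_tibble(utils::read.delim(path, na.strings = ""))
  ipath <- paste0(path, ".indels.tsv")
  if (file.exists(ipath)) {
    attr(led, "indel_positions") <- as_tibble(utils::read.delim(ipath))
  }
  class(led) <- c("ba_ledger", class(led))
  led
}

#' Write a truth set or build to a directory
#'
#' Writes `genome.fa`, `annotation.gff3` and — for truth sets —
#' `transcripts.fa`, `proteins.fa` plus `run_metadata.json` echoing the
#' configuration and seed.
#'
#' @param x a `ba_truth` or `ba_build`.
#' @param dir output directory (created if needed).
#' @param metadata optional list (e.g. config echo and seed) written as JSON.
#' @return the directory, invisibly.
#' @export
write_build <- function(x, dir, metadata = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(x$genome, file.path(dir, "genome.fa"))
  write_gff3(x$annotation, file.path(dir, "annotation.gff3"))
  if (!is.null(x$models)) {
    write_fasta(setNames(x$models$transcript, x$models$gene_id),
                file.path(dir, "transcripts.fa"))
    write_fasta(setNames(x$models$protein, x$models$gene_id),
                file.path(dir, "proteins.fa"), protein = TRUE)
  }
  if (!is.null(metadata)) {
    jsonlite::write_json(metadata, file.path(dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(dir)
}
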