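#' Gene-set over-representation test
#'
#' The fold-enrichment plus multiple-testing machinery used to mine gene
#' lists against pathway collections: for every term, fold enrichment
#' `(k/n)/(K/N)` and a one-sided hypergeometric p-value for enrichment,
#' Benjamini-Hochberg adjusted across all terms of the collection.
#'
#' @param query character vector of query gene identifiers (must be a subset
#'   of the background).
#' @param background character vector: the gene universe.
#' @param collection named list of character vectors (e.g. from
#'   [read_gmt()]); terms are intersected with the background before testing.
#' @return a `ba_enrichment` tibble sorted by p: `term`, `k`, `n`, `K`, `N`,
#'   `fold`, `p`, `q`.
#' @examples
#' over_representation(c("a", "b"), letters[1:10], list(t1 = c("a", "b", "c")))
#' @export
over_representation <- function(query, background, collection) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background)) {
    stop_input("query genes must be a subset of the background")
  }
  if (length(collection) == 0 || any(lengths(collection) == 0)) {
    stop_input("collection terms must be non-empty")
  }
  N <- length(background)
  n <- length(query)
  rows <- imap(collection, function(genes, term) {
    term_bg <- intersect(unique(genes), background)
    K <- length(term_bg)
    k <- length(intersect(term_bg, query))
    tibble(
      term = term, k = k, n = n, K = K, N = N,
      fold = if (K > 0) (k / n) / (K / N) else NA_real_,
      p = if (K > 0) phyper(k - 1, K, N - K, n, lower.tail = FALSE) else NA_real_
    )
  })
  out <- bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  out <- arrange(out, .data$p, .data$term)
  structure(out, class = c("ba_enrichment", class(out)))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT layout: one term per line, tab-separated — name, description,
#' then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  setNames(
    map(parts, function(p) unique(p[-(1:2)])),
    map_chr(parts, 1)
  )
}
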