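#' Tidy a build summary
#'
#' @param x a `ba_build_summary`.
#' @param ... unused.
#' @return a plain tibble with one row per error category.
#' @export
tidy.ba_build_summary <- function(x, ...) {
  as_tibble(unclass_ba(x))
}

#' One-row summary of a build audit
#'
#' @param x a `ba_build_summary`.
#' @param ... unused.
#' @return tibble with `build_id`, `n_genes`, `percent_correct`.
#' @export
glance.ba_build_summary <- function(x, ...) {
  tibble(build_id = x$build_id[1], n_genes = attr(x, "n_genes"),
         percent_correct = attr(x, "percent_correct"))
}

#' Tidy a Venn partition into region/count rows
#'
#' @param x a `ba_venn`.
#' @param ... unused.
#' @return tibble with `region` and `n`.
#' @export
tidy.ba_venn <- function(x, ...) {
  tibble(region = names(x), n = as.integer(unlist(x[1, ])))
}

#' One-row summary of a Venn partition
#'
#' @param x a `ba_venn`.
#' @param ... unused.
#' @return tibble with per-species totals and the triple count.
#' @export
glance.ba_venn <- function(x, ...) {
  tibble(
    n_triples = x$PMH,
    pig_total = x$PMH + x$PM + x$PH + x$P,
    mouse_total = x$PMH + x$PM + x$MH + x$M,
    human_total = x$PMH + x$PH + x$MH + x$H
  )
}

#' Tidy an enrichment result
#'
#' @param x a `ba_enrichment`.
#' @param ... unused.
#' @return the underlying tibble.
#' @export
tidy.ba_enrichment <- function(x, ...) as_tibble(unclass_ba(x))

#' One-row summary of an enrichment run
#'
#' @param x a `ba_enrichment`.
#' @param alpha FDR threshold for counting significant terms.
#' @param ... unused.
#' @return tibble with `n_terms` and `n_significant`.
#' @export
glance.ba_enrichment <- function(x, alpha = 0.05, ...) {
  tibble(n_terms = nrow(x), n_significant = sum(x$q <= alpha, na.rm = TRUE))
}

#' Tidy an injection ledger into per-class counts
#'
#' @param x a `ba_ledger`.
#' @param ... unused.
#' @return tibble with `injected_error` and `n`.
#' @export
tidy.ba_ledger <- function(x, ...) {
  as_tibble(unclass_ba(x)) |>
    group_by(.data$injected_error) |>
    summarise(n = n(), .groups = "drop")
}

#' Tidy an indel-rate estimate
#'
#' @param x a `ba_indel_estimate`.
#' @param ... unused.
#' @return the underlying one-row tibble.
#' @export
tidy.ba_indel_estimate <- function(x, ...) as_tibble(unclass_ba(x))

unclass_ba <- function(x) {
  class(x) <- setdiff(class(x), c("ba_build_summary", "ba_venn",
                                  "ba_enrichment", "ba_ledger",
                                  "ba_indel_estimate", "ba_loci"))
  x
}
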