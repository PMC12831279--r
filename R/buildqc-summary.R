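audit_categories <- c("correct", "error_in_locus", "split_multiple_loci",
                      "multiple_genes_one_locus", "not_annotated",
                      "sequence_not_present")

#' Summarize per-gene error calls for a build
#'
#' Tallies the calls into the five error categories plus `correct` and
#' reports the percent of error-free genes, rounded half-up to one decimal
#' (the convention used when such audits are reported).
#'
#' @param calls tibble of calls from [classify_build()] / [classify_gene()].
#' @param build_id identifier carried into the summary.
#' @return a `ba_build_summary` tibble: one row per category with `n` and
#'   `percent`; `percent_correct` and `n_genes` are attributes (see
#'   [glance.ba_build_summary()]).
#' @export
summarize_build <- function(calls, build_id = "build") {
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    stop_input("at least one error call is required")
  }
  bad <- setdiff(unique(calls$category), audit_categories)
  if (length(bad)) stop_input("unknown category: %s", paste(bad, collapse = ", "))
  total <- nrow(calls)
  counts <- table(factor(calls$category, levels = audit_categories))
  out <- tibble(
    build_id = build_id, category = audit_categories,
    n = as.integer(counts), percent = pct(as.integer(counts), total)
  )
  structure(out, class = c("ba_build_summary", class(out)),
            n_genes = total,
            percent_correct = pct(sum(calls$category == "correct"), total))
}

#' Estimate the genome-wide indel rate
#'
#' Point estimate and exact Poisson 95% interval for the mean number of base
#' pairs per coding indel, the headline per-build statistic of the audit.
#'
#' @param events indel events (a [detect_indels()]-style tibble, or the event
#'   count itself).
#' @param covered_bp coding base pairs surveyed.
#' @param conf_level confidence level for the exact Poisson interval.
#' @return a one-row `ba_indel_estimate` tibble: `n_events`, `covered_bp`,
#'   `bp_per_indel`, `ci_lo`, `ci_hi` (bp per indel; `ci_hi = Inf` and
#'   `bp_per_indel = Inf` when no event was observed, flagged `undefined`).
#' @export
estimate_indel_rate <- function(events, covered_bp, conf_level = 0.95) {
  n <- if (is.data.frame(events)) nrow(events) else as.integer(events)
  if (!is.finite(covered_bp) || covered_bp <= 0) {
    stop_input("covered_bp must be positive")
  }
  ci_n <- stats::poisson.test(n, conf.level = conf_level)$conf.int
  out <- tibble(
    n_events = n, covered_bp = as.numeric(covered_bp),
    bp_per_indel = if (n > 0) covered_bp / n else Inf,
    ci_lo = covered_bp / ci_n[2],
    ci_hi = if (ci_n[1] > 0) covered_bp / ci_n[1] else Inf,
    undefined = n == 0
  )
  structure(out, class = c("ba_indel_estimate", class(out)))
}

#' Compare classifier calls with an injection ledger
#'
#' Joins per-gene calls to the truth ledger of an injected build and computes
#' the class-level recall of the expected mapping (`none -> correct`,
#' `indel`/`premature_stop -> error_in_locus`, `unannotated ->
#' not_annotated`, `missing_segment -> sequence_not_present`, `split_locus ->
#' split_multiple_loci`, `merged_locus -> multiple_genes_one_locus`).
#'
#' @param calls tibble from [classify_build()].
#' @param ledger `ba_ledger` from [inject_build_errors()].
#' @return a tibble per injected class: `injected_error`, `expected_category`,
#'   `n`, `n_recovered`, `recall`.
#' @export
recovery_stats <- function(calls, ledger) {
  expected <- c(none = "correct", indel = "error_in_locus",
                premature_stop = "error_in_locus",
                unannotated = "not_annotated",
                missing_segment = "sequence_not_present",
                split_locus = "split_multiple_loci",
                merged_locus = "multiple_genes_one_locus")
  joined <- left_join(as_tibble(ledger)[c("gene_id", "injected_error")],
                      calls[c("gene_id", "category")], by = "gene_id")
  joined$expected_category <- expected[joined$injected_error]
  joined |>
    group_by(.data$injected_error, .data$expected_category) |>
    summarise(n = n(),
              n_recovered = sum(.data$category == .data$expected_category),
              recall = .data$n_recovered / .data$n, .groups = "drop")
}
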