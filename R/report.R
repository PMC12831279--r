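#' Render a consolidated audit report
#'
#' Writes the audit's tables as TSV files plus a plain-text summation whose
#' sections mirror how such audits are reported: per-build error categories
#' and percent correct, Venn region counts with the asymmetry ratios, and any
#' census tables supplied. Output is deterministic: the same inputs produce
#' identical bytes, and every number in the text summary also appears in one
#' of the TSVs.
#'
#' @param build_summaries one `ba_build_summary` or a list of them.
#' @param venn optional `ba_venn` partition.
#' @param ratios optional [asymmetry_ratios()] row.
#' @param census optional named list of data frames, written as
#'   `census_<name>.tsv`.
#' @param enrichment optional `ba_enrichment` table.
#' @param dir output directory.
#' @return character vector of files written, invisibly.
#' @export
render_report <- function(build_summaries, venn = NULL, ratios = NULL,
                          census = NULL, enrichment = NULL, dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(build_summaries, "ba_build_summary")) {
    build_summaries <- list(build_summaries)
  }
  validate_report_inputs(build_summaries, venn, ratios, census)
  files <- character(0)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(df), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    files <<- c(files, p)
    p
  }
  tsv(bind_rows(map(build_summaries, as_tibble)), "build_summary.tsv")
  if (!is.null(venn)) tsv(as_tibble(venn), "venn_counts.tsv")
  if (!is.null(ratios)) tsv(ratios, "asymmetry_ratios.tsv")
  if (!is.null(enrichment)) {
    e <- as_tibble(enrichment)
    e$fold <- round_half_up(e$fold, 1)
    e$p <- formatC(e$p, format = "e", digits = 1)
    e$q <- formatC(e$q, format = "e", digits = 1)
    tsv(e, "enrichment.tsv")
  }
  if (!is.null(census)) {
    for (nm in names(census)) tsv(census[[nm]], sprintf("census_%s.tsv", nm))
  }

  lines <- c("Summation of results", strrep("=", 20), "")
  for (bs in build_summaries) {
    lines <- c(lines, sprintf(
      "Build %s: %d genes audited, %.1f%% error-free",
      bs$build_id[1], attr(bs, "n_genes"), attr(bs, "percent_correct")
    ))
    lines <- c(lines, sprintf("  %-26s %6d (%5.1f%%)", bs$category, bs$n,
                              bs$percent), "")
  }
  if (!is.null(venn)) {
    lines <- c(lines, "Three-species Venn partition:",
               sprintf("  %-4s %6d", names(venn), unlist(venn[1, ])), "")
  } else {
    lines <- c(lines, "Three-species Venn partition: (not provided)", "")
  }
  if (!is.null(ratios)) {
    lines <- c(lines, sprintf(
      "Asymmetry ratios: PH/MH = %.1f, M/H = %.1f, M/P = %.1f",
      ratios$ph_over_mh_1dp, ratios$m_over_h_1dp, ratios$m_over_p_1dp), "")
  } else {
    lines <- c(lines, "Asymmetry ratios: (not provided)", "")
  }
  if (!is.null(census)) {
    lines <- c(lines, sprintf("Census tables: %s",
                              paste(names(census), collapse = ", ")), "")
  } else {
    lines <- c(lines, "Census tables: (not provided)", "")
  }
  p <- file.path(dir, "summary.txt")
  writeLines(lines, p)
  files <- c(files, p)
  invisible(files)
}

validate_report_inputs <- function(build_summaries, venn, ratios, census) {
  for (bs in build_summaries) {
    missing <- setdiff(c("build_id", "category", "n", "percent"), names(bs))
    if (length(missing)) {
      stop_input("build summary lacks columns: %s", paste(missing, collapse = ", "))
    }
  }
  if (!is.null(venn)) {
    missing <- setdiff(c("PMH", "PM", "PH", "MH", "P", "M", "H"), names(venn))
    if (length(missing)) {
      stop_input("venn partition lacks regions: %s", paste(missing, collapse = ", "))
    }
  }
  if (!is.null(ratios) && !all(c("ph_over_mh_1dp", "m_over_h_1dp",
                                 "m_over_p_1dp") %in% names(ratios))) {
    stop_input("ratios input lacks the reported 1-decimal columns")
  }
  if (!is.null(census) && (is.null(names(census)) || any(!nzchar(names(census))))) {
    stop_input("census tables must be a named list")
  }
  invisible(TRUE)
}
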