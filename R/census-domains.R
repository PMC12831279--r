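#' Compare protein domain architectures across pig, mouse and human
#'
#' Matches domain instances across three orthologous proteins by domain name
#' and rank order (the formalization of comparing annotation graphic
#' summaries side by side), and assigns each instance a presence pattern:
#' `shared_all`, `pig_human`, `mouse_human`, `pig_mouse`, or a single-species
#' pattern. The coordinates are not compared — only which domains occur, and
#' how many times.
#'
#' @param arch_pig,arch_mouse,arch_human tibbles with columns `protein_id`,
#'   `domain`, `start`, `end` (AA coordinates; rows ordered or orderable by
#'   `start`).
#' @return a tibble per matched domain instance: `domain`, `instance`,
#'   `in_pig`, `in_mouse`, `in_human`, `pattern`.
#' @export
compare_architectures <- function(arch_pig, arch_mouse, arch_human) {
  archs <- list(pig = arch_pig, mouse = arch_mouse, human = arch_human)
  if (all(map_int(archs, nrow) == 0)) {
    stop_input("all three architectures are empty")
  }
  counts <- map(archs, function(a) {
    a <- a[order(a$start), ]
    table(a$domain)
  })
  domains <- sort(unique(unlist(map(counts, names))))
  out <- list()
  for (d in domains) {
    n <- map_int(counts, function(ct) {
      if (d %in% names(ct)) as.integer(ct[[d]]) else 0L
    })
    for (inst in seq_len(max(n))) {
      pres <- n >= inst
      pattern <- paste(names(pres)[pres], collapse = "_")
      pattern <- switch(pattern,
        pig_mouse_human = "shared_all", pig = "pig_only",
        mouse = "mouse_only", human = "human_only", pattern
      )
      out[[length(out) + 1L]] <- tibble(
        domain = d, instance = inst, in_pig = pres[["pig"]],
        in_mouse = pres[["mouse"]], in_human = pres[["human"]],
        pattern = pattern
      )
    }
  }
  bind_rows(out)
}

#' Pig-human over mouse-human domain-sharing ratio
#'
#' Over a set of per-gene architecture diffs, the ratio of domain instances
#' shared by pig and human but missing in mouse to those shared by mouse and
#' human but missing in pig — the statistic summarizing which species better
#' preserves the human domain complement.
#'
#' @param diffs tibble of domain diffs (rows from [compare_architectures()],
#'   possibly concatenated over many genes) with a `pattern` column.
#' @return one-row tibble: `n_pig_human`, `n_mouse_human`, `ratio`,
#'   `ratio_1dp`; `NA` ratio with `undefined = TRUE` when no mouse-human
#'   instance exists.
#' @export
domain_sharing_ratio <- function(diffs) {
  k_ph <- sum(diffs$pattern == "pig_human")
  k_mh <- sum(diffs$pattern == "mouse_human")
  r <- if (k_mh > 0) k_ph / k_mh else NA_real_
  tibble(n_pig_human = k_ph, n_mouse_human = k_mh, ratio = r,
         ratio_1dp = round_half_up(r, 1), undefined = k_mh == 0)
}
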