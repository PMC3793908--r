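#' Cross-study recurrence voting
#'
#' Counts, for each candidate gene, how many independent external studies
#' report it beyond a fold-change and p-value threshold (and, by default, in
#' the candidate's direction), then assigns recurrence tiers at >= 2, >= 3
#' and >= 4 votes. When a study carries several records for one gene (e.g.
#' multiple probesets) the record with the smallest p-value is used.
#'
#' @param dmb_genes tibble with `gene_symbol` and `direction` (+1/-1).
#' @param studies tibble of study summaries: `study_id`, `category`,
#'   `gene_symbol`, `fold_change` (signed linear scale), `p_value`.
#' @param p_max p-value threshold a study record must meet (default 0.01).
#' @param fold_min minimum absolute fold change (default 2).
#' @param require_direction only count records whose fold-change sign matches
#'   the candidate's direction (default `TRUE`).
#' @return tibble with `gene_symbol`, `direction`, `votes`, `tier`
#'   (`">=4"`, `">=3"`, `">=2"` or `NA`) and `categories` (list-column of
#'   per-category vote counts), one row per candidate gene.
#' @examples
#' genes <- tibble::tibble(gene_symbol = "CKS2", direction = 1L)
#' studies <- tibble::tibble(
#'   study_id = c("s1", "s2"), category = "tumor vs normal",
#'   gene_symbol = "CKS2", fold_change = c(2.5, 1.8),
#'   p_value = c(0.005, 0.001))
#' recurrence_vote(genes, studies)
#' @export
recurrence_vote <- function(dmb_genes, studies, p_max = 0.01, fold_min = 2.0,
                            require_direction = TRUE) {
  studies <- as_tibble(studies)
  if (nrow(studies) == 0) stop_data("`studies` must be non-empty.")
  dmb_genes <- as_tibble(dmb_genes)
  best <- studies |>
    mutate(key = symbol_key(.data$gene_symbol)) |>
    group_by(.data$study_id, .data$key) |>
    arrange(.data$p_value, .by_group = TRUE) |>
    slice(1) |>
    ungroup()
  cand <- dmb_genes |>
    mutate(key = symbol_key(.data$gene_symbol)) |>
    select("gene_symbol", "direction", "key")
  hits <- cand |>
    inner_join(best, by = "key", suffix = c("", "_study"),
               relationship = "many-to-many") |>
    filter(abs(.data$fold_change) >= fold_min, .data$p_value <= p_max) |>
    filter(!require_direction | sign(.data$fold_change) == .data$direction)
  counted <- hits |>
    group_by(.data$key) |>
    summarise(votes = dplyr::n_distinct(.data$study_id),
              categories = list(dplyr::count(dplyr::pick("category"),
                                             .data$category,
                                             name = "votes")),
              .groups = "drop")
  out <- cand |>
    left_join(counted, by = "key") |>
    mutate(
      votes = dplyr::coalesce(.data$votes, 0L),
      tier = dplyr::case_when(
        .data$votes >= 4 ~ ">=4",
        .data$votes >= 3 ~ ">=3",
        .data$votes >= 2 ~ ">=2",
        TRUE ~ NA_character_
      )
    ) |>
    select("gene_symbol", "direction", "votes", "tier", "categories")
  out
}

#' Gene-set enrichment by Fisher's exact test
#'
#' Tests whether the candidate set is enriched for target-set members within
#' a finite gene universe, optionally after restricting all three sets to a
#' conditioning set (e.g. a gene-ontology term), which guards against
#' enrichment driven purely by a shared broad category. Reports the 2x2
#' membership table, the one-sided (over-representation) hypergeometric
#' p-value, the two-sided Fisher p-value under the sum-of-smaller-
#' probabilities rule, and the odds ratio (with a Haldane 0.5 correction when
#' a cell is empty).
#'
#' @param candidates,targets,universe character vectors of gene symbols;
#'   candidates and targets must be subsets of the universe after
#'   restriction.
#' @param restrict_to optional character vector to intersect with all three
#'   sets before testing.
#' @return object of class `enrichment_result`; `tidy()` yields a one-row
#'   tibble with the table cells and both p-values.
#' @examples
#' fisher_enrichment(c("A", "B", "C", "D"), c("A", "E"),
#'   universe = LETTERS[1:8])
#' @export
fisher_enrichment <- function(candidates, targets, universe,
                              restrict_to = NULL) {
  u <- unique(symbol_key(universe))
  cset <- unique(symbol_key(candidates))
  tset <- unique(symbol_key(targets))
  desc <- "universe"
  if (!is.null(restrict_to)) {
    r <- unique(symbol_key(restrict_to))
    u <- intersect(u, r); cset <- intersect(cset, r)
    tset <- intersect(tset, r)
    desc <- "restricted universe"
  }
  if (length(u) == 0) stop_data("Restricted universe is empty.")
  if (!all(cset %in% u) || !all(tset %in% u)) {
    stop_data("Candidates and targets must be subsets of the universe.")
  }
  a <- length(intersect(cset, tset))
  b <- length(setdiff(cset, tset))
  cc <- length(setdiff(tset, cset))
  d <- length(u) - a - b - cc
  # hypergeometric: draws = |candidates|, white = |targets|
  p_one <- phyper(a - 1, length(tset), length(u) - length(tset),
                  length(cset), lower.tail = FALSE)
  support <- max(0, length(cset) + length(tset) - length(u)):
    min(length(cset), length(tset))
  dens <- dhyper(support, length(tset), length(u) - length(tset),
                 length(cset))
  p_two <- sum(dens[dens <= dhyper(a, length(tset),
                                   length(u) - length(tset),
                                   length(cset)) * (1 + 1e-7)])
  p_two <- min(1, p_two)
  haldane <- b * cc == 0
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  structure(
    list(table = c(a = a, b = b, c = cc, d = d),
         odds_ratio = or, haldane = haldane,
         p_one_sided = p_one, p_two_sided = p_two,
         universe_size = length(u), universe = desc),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> 2x2 = [%d %d; %d %d] over %d genes (%s)\n",
    x$table["a"], x$table["b"], x$table["c"], x$table["d"],
    x$universe_size, x$universe))
  cat(sprintf("  odds ratio %.4g%s; one-sided p %.4g; two-sided p %.4g\n",
              x$odds_ratio, if (x$haldane) " (Haldane-corrected)" else "",
              x$p_one_sided, x$p_two_sided))
  invisible(x)
}

#' @rdname fisher_enrichment
#' @param x an `enrichment_result`.
#' @param ... unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(
    in_both = x$table[["a"]], candidate_only = x$table[["b"]],
    target_only = x$table[["c"]], neither = x$table[["d"]],
    odds_ratio = x$odds_ratio, p_one_sided = x$p_one_sided,
    p_two_sided = x$p_two_sided, universe_size = x$universe_size
  )
}
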