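#' Reciprocal cross-species overlap of differential-expression results
#'
#' Matches each species' significant probesets to the other species through
#' an orthology map and reports the reciprocal overlap at two cross-species
#' FDR thresholds. A human significant probeset "overlaps" when *any*
#' orthologous mouse probeset has an adjusted value below the threshold, and
#' symmetrically for mouse-in-human (the permissive ANY rule for many-to-many
#' maps). The mouse-in-human denominator is the number of mouse significant
#' probesets whose gene has an annotated human counterpart in the map, since
#' only those can possibly overlap.
#'
#' @param human_de,mouse_de `de_result` objects from [run_de()].
#' @param orthology tibble with columns `human_probeset`, `gene_symbol`,
#'   `mouse_probeset` (many-to-many allowed; symbols matched
#'   case-insensitively).
#' @param cross_fdr numeric vector of cross-species thresholds (default
#'   `c(0.05, 0.01)`).
#' @return object of class `overlap_report`: list with `report` (tibble:
#'   `comparison`, `cross_fdr`, `count`, `denominator`, `percent`) and
#'   `pairs` (every orthologous probeset pair between the two full tables
#'   with both species' statistics, the substrate for [concordant_genes()]).
#' @examples
#' sim <- simulate_two_species(sim_config(n_genes_per_species = 200,
#'   n_concordant = 10, seed = 1))
#' hde <- run_de(sim$human); mde <- run_de(sim$mouse)
#' reciprocal_overlap(hde, mde, sim$orthology)
#' @export
reciprocal_overlap <- function(human_de, mouse_de, orthology,
                               cross_fdr = c(0.05, 0.01)) {
  stopifnot(inherits(human_de, "de_result"), inherits(mouse_de, "de_result"))
  orthology <- as_tibble(orthology)
  if (nrow(orthology) == 0) {
    warn("Empty orthology map: all overlap counts are zero.")
  }
  if (nrow(orthology) > 0 &&
      (anyDuplicated(orthology) ||
       any(!nzchar(trimws(orthology$gene_symbol))))) {
    stop_data("Orthology map has duplicate triples or empty gene symbols.")
  }

  h_full <- human_de$full
  m_full <- mouse_de$full
  pairs <- orthology |>
    inner_join(h_full, by = c(human_probeset = "probeset_id")) |>
    rename(p_human = "p_value", q_human = "q_value",
           fold_human = "fold_change", direction_human = "direction") |>
    select(-dplyr::any_of(c("gene_symbol.y", "f_stat"))) |>
    inner_join(m_full, by = c(mouse_probeset = "probeset_id")) |>
    rename(p_mouse = "p_value", q_mouse = "q_value",
           fold_mouse = "fold_change", direction_mouse = "direction") |>
    select("human_probeset", gene_symbol = "gene_symbol.x", "mouse_probeset",
           "p_human", "q_human", "fold_human", "direction_human",
           "p_mouse", "q_mouse", "fold_mouse", "direction_mouse")

  h_sig <- human_de$sig$probeset_id
  m_sig <- mouse_de$sig$probeset_id
  m_sig_mapped <- intersect(m_sig, orthology$mouse_probeset)

  report <- purrr::map(sort(cross_fdr, decreasing = TRUE), function(f) {
    him <- pairs |>
      filter(.data$human_probeset %in% h_sig, !is.na(.data$q_mouse),
             .data$q_mouse < f) |>
      pull("human_probeset") |> unique()
    mih <- pairs |>
      filter(.data$mouse_probeset %in% m_sig_mapped, !is.na(.data$q_human),
             .data$q_human < f) |>
      pull("mouse_probeset") |> unique()
    tibble(
      comparison = c("human_in_mouse", "mouse_in_human"),
      cross_fdr = f,
      count = c(length(him), length(mih)),
      denominator = c(length(h_sig), length(m_sig_mapped)),
      percent = c(
        if (length(h_sig)) percent_of(length(him), length(h_sig)) else 0,
        if (length(m_sig_mapped)) {
          percent_of(length(mih), length(m_sig_mapped))
        } else 0)
    )
  }) |> bind_rows()

  structure(
    list(report = report, pairs = pairs,
         n_human_sig = length(h_sig), n_mouse_sig = length(m_sig),
         n_mouse_sig_mapped = length(m_sig_mapped)),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> human sig %d; mouse sig %d (%d with mapped homolog)\n",
    x$n_human_sig, x$n_mouse_sig, x$n_mouse_sig_mapped))
  print(x$report)
  invisible(x)
}

#' @export
tidy.overlap_report <- function(x, ...) x$report

#' Collapse orthologous probeset pairs into concordant genes
#'
#' Groups the matched probeset pairs by gene symbol (case-insensitively) and
#' keeps genes with at least one pair in which both members pass the
#' cross-species FDR threshold *and* share a direction. The gene's direction
#' is taken from the pair maximising `min(|FC_human|, |FC_mouse|)` (ties
#' broken toward the smaller human p-value, then the lexicographically first
#' human probeset), and only records consistent with that direction are
#' retained in the per-species record lists. Genes whose every passing pair
#' is discordant are dropped by default and reported via the
#' `"discordant"` attribute; `keep_discordant = TRUE` retains them with the
#' dominant pair's human direction, reproducing the permissive behaviour of
#' published gene lists that keep an opposite-sign ortholog pair.
#'
#' @param pairs the `pairs` tibble of an [reciprocal_overlap()] result (or
#'   the result itself).
#' @param cross_fdr threshold both members of a pair must beat (default
#'   0.01).
#' @param keep_discordant keep genes whose pairs disagree in direction
#'   (default `FALSE`).
#' @return tibble of class `concordant_genes`: `gene_symbol`, `direction`,
#'   `max_abs_fold_human`, `max_abs_fold_mouse`, `n_human_probesets`,
#'   `n_mouse_probesets`, plus list-columns `human_records`/`mouse_records`
#'   of retained per-probeset statistics.
#' @export
concordant_genes <- function(pairs, cross_fdr = 0.01,
                             keep_discordant = FALSE) {
  if (inherits(pairs, "overlap_report")) pairs <- pairs$pairs
  passing <- pairs |>
    filter(!is.na(.data$q_human), !is.na(.data$q_mouse),
           .data$q_human < cross_fdr, .data$q_mouse < cross_fdr) |>
    mutate(key = symbol_key(.data$gene_symbol))

  empty_result <- function(dropped = character(0)) {
    out <- tibble(gene_symbol = character(), direction = integer(),
                  max_abs_fold_human = numeric(),
                  max_abs_fold_mouse = numeric(),
                  n_human_probesets = integer(), n_mouse_probesets = integer(),
                  human_records = list(), mouse_records = list())
    attr(out, "discordant") <- dropped
    class(out) <- c("concordant_genes", class(out))
    out
  }
  if (nrow(passing) == 0) return(empty_result())

  by_gene <- split(passing, passing$key)
  rows <- purrr::map(by_gene, function(g) {
    conc <- g[g$direction_human == g$direction_mouse, ]
    use <- if (nrow(conc) > 0) conc else if (keep_discordant) g else NULL
    if (is.null(use)) return(NULL)
    score <- pmin(abs(use$fold_human), abs(use$fold_mouse))
    best <- use[order(-score, use$p_human, use$human_probeset), ][1, ]
    dir <- best$direction_human
    keep_same <- nrow(conc) > 0
    h <- g |>
      filter(!keep_same | .data$direction_human == dir) |>
      distinct(.data$human_probeset, .keep_all = TRUE)
    m <- g |>
      filter(!keep_same | .data$direction_mouse == dir) |>
      distinct(.data$mouse_probeset, .keep_all = TRUE)
    tibble(
      gene_symbol = best$gene_symbol,
      direction = as.integer(dir),
      max_abs_fold_human = max(abs(h$fold_human)),
      max_abs_fold_mouse = max(abs(m$fold_mouse)),
      n_human_probesets = nrow(h),
      n_mouse_probesets = nrow(m),
      human_records = list(select(h, probeset_id = "human_probeset",
                                  p_value = "p_human", q_value = "q_human",
                                  fold_change = "fold_human")),
      mouse_records = list(select(m, probeset_id = "mouse_probeset",
                                  p_value = "p_mouse", q_value = "q_mouse",
                                  fold_change = "fold_mouse"))
    )
  })
  dropped <- names(by_gene)[purrr::map_lgl(rows, is.null)]
  if (length(dropped) > 0) {
    inform(sprintf("Dropped %d gene(s) with only direction-discordant pairs: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  if (all(purrr::map_lgl(rows, is.null))) return(empty_result(dropped))
  out <- bind_rows(rows) |> arrange(.data$gene_symbol)
  attr(out, "discordant") <- dropped
  class(out) <- c("concordant_genes", class(out))
  out
}

#' Remove genes belonging to exclusion gene sets
#'
#' Partitions a concordant gene list into genes absent from versus present in
#' the union of the supplied exclusion sets (e.g. signatures of normal B-cell
#' activation/proliferation, whose members are deregulated in any
#' resting-versus-proliferating contrast and are therefore uninformative
#' about the tumor state). Matching is case-insensitive.
#'
#' @param genes a `concordant_genes` tibble (or any tibble with
#'   `gene_symbol`).
#' @param exclusion_sets named list of character vectors, e.g. from
#'   [read_gmt()].
#' @return list with `kept`, `removed` (tibbles partitioning the input) and
#'   `set_counts` (per-set membership counts among the input genes).
#' @export
apply_exclusion <- function(genes, exclusion_sets) {
  genes <- as_tibble(genes)
  if (length(exclusion_sets) == 0) {
    return(list(kept = genes, removed = genes[0, ],
                set_counts = tibble(set = character(), n_members = integer())))
  }
  union_keys <- symbol_key(unique(unlist(exclusion_sets, use.names = FALSE)))
  hit <- symbol_key(genes$gene_symbol) %in% union_keys
  set_counts <- tibble(
    set = names(exclusion_sets) %||% paste0("set", seq_along(exclusion_sets)),
    n_members = unname(purrr::map_int(
      exclusion_sets,
      ~ sum(symbol_key(genes$gene_symbol) %in% symbol_key(.x))))
  )
  list(kept = genes[!hit, ], removed = genes[hit, ], set_counts = set_counts)
}

#' Minimum fold-change filter producing the final concordant gene list
#'
#' Keeps genes whose maximum absolute fold change reaches `threshold` in
#' *both* species; the removed genes are partitioned into up- and
#' down-regulated by their gene direction.
#'
#' @param genes a `concordant_genes` tibble (needs `max_abs_fold_human`,
#'   `max_abs_fold_mouse`, `direction`).
#' @param threshold linear-scale fold threshold, at least 1 (default 2).
#' @return list with `kept` (the final list), `removed`, `n_removed_up`,
#'   `n_removed_down`.
#' @export
fold_filter <- function(genes, threshold = 2.0) {
  if (!is.finite(threshold) || threshold < 1) {
    stop_config("`threshold` must be a fold change >= 1.")
  }
  genes <- as_tibble(genes)
  ok <- genes$max_abs_fold_human >= threshold &
    genes$max_abs_fold_mouse >= threshold
  removed <- genes[!ok, ]
  list(
    kept = genes[ok, ],
    removed = removed,
    n_removed_up = sum(removed$direction > 0),
    n_removed_down = sum(removed$direction < 0)
  )
}

#' Summarise the full concordance filtering cascade
#'
#' Collects the counts at every arrow of the analysis flow -- per-species
#' probesets tested, ANOVA-significant, FDR-surviving, reciprocal overlaps at
#' both thresholds, concordant annotated genes with their up/down split,
#' exclusion removals, fold-filter removals and the final list size -- with
#' percentages over the stated denominators.
#'
#' @param human_de,mouse_de `de_result` objects.
#' @param overlap an `overlap_report`.
#' @param concordant the `concordant_genes` tibble.
#' @param exclusion result of [apply_exclusion()].
#' @param fold result of [fold_filter()].
#' @return tibble with columns `stage`, `count`, `denominator`, `percent`.
#' @export
summarize_cascade <- function(human_de, mouse_de, overlap, concordant,
                              exclusion, fold) {
  row <- function(stage, count, denom = NA_real_) {
    tibble(stage = stage, count = count, denominator = denom,
           percent = if (is.na(denom) || denom == 0) NA_real_
                     else percent_of(count, denom))
  }
  rep_tab <- overlap$report
  ov_row <- function(cmp, f) {
    r <- rep_tab[rep_tab$comparison == cmp & rep_tab$cross_fdr == f, ]
    row(sprintf("%s_fdr%s", cmp, sub("^0[.]", "", format(f))),
        r$count, r$denominator)
  }
  n_conc <- nrow(concordant)
  bind_rows(
    row("human_probesets_tested", nrow(human_de$full)),
    row("human_p_significant", sum(human_de$full$p_value < human_de$p_cut),
        nrow(human_de$full)),
    row("human_fdr_significant", nrow(human_de$sig),
        sum(human_de$full$p_value < human_de$p_cut)),
    row("mouse_probesets_tested", nrow(mouse_de$full)),
    row("mouse_p_significant", sum(mouse_de$full$p_value < mouse_de$p_cut),
        nrow(mouse_de$full)),
    row("mouse_fdr_significant", nrow(mouse_de$sig),
        sum(mouse_de$full$p_value < mouse_de$p_cut)),
    row("mouse_sig_with_human_homolog", overlap$n_mouse_sig_mapped,
        overlap$n_mouse_sig),
    ov_row("human_in_mouse", 0.05),
    ov_row("human_in_mouse", 0.01),
    ov_row("mouse_in_human", 0.05),
    ov_row("mouse_in_human", 0.01),
    row("concordant_genes", n_conc),
    row("concordant_up", sum(concordant$direction > 0), n_conc),
    row("concordant_down", sum(concordant$direction < 0), n_conc),
    row("exclusion_removed", nrow(exclusion$removed), n_conc),
    row("fold_removed_up", fold$n_removed_up),
    row("fold_removed_down", fold$n_removed_down),
    row("final_genes", nrow(fold$kept), n_conc)
  )
}
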