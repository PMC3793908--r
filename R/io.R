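#' Read and write the pipeline's tab-separated formats
#'
#' All tabular inputs and outputs are TSV with a mandatory header row; lines
#' starting with `#` are comments. `read_expression_tsv()` expects probesets
#' in rows with the first column holding probeset ids and a sidecar TSV
#' mapping `sample_id` to `group` (`tumor`/`normal`).
#'
#' @param path file path.
#' @param groups_path sidecar TSV with columns `sample_id`, `group`.
#' @param species `"human"` or `"mouse"`.
#' @return `read_expression_tsv()` returns an [expr_matrix];
#'   `read_orthology_tsv()`, `read_edges_tsv()`, `read_study_tsv()` and
#'   `read_survival_tsv()` return tibbles in the column layouts the pipeline
#'   stages expect.
#' @name concord_io
NULL

read_tsv_c <- function(path, col_types = NULL) {
  readr::read_tsv(path, comment = "#", col_types = col_types %||%
                    readr::cols(), progress = FALSE)
}

#' @rdname concord_io
#' @export
read_expression_tsv <- function(path, groups_path, species) {
  tab <- read_tsv_c(path)
  ids <- as.character(tab[[1]])
  vals <- as.matrix(tab[-1])
  rownames(vals) <- ids
  gr <- read_tsv_c(groups_path)
  groups <- setNames(as.character(gr$group), gr$sample_id)
  expr_matrix(vals, species, groups)
}

#' @rdname concord_io
#' @param x object to write (see each writer's expected columns).
#' @export
write_expression_tsv <- function(x, path, groups_path) {
  stopifnot(inherits(x, "expr_matrix"))
  out <- dplyr::bind_cols(tibble(probeset_id = rownames(x$values)),
                          as_tibble(x$values))
  readr::write_tsv(out, path, progress = FALSE)
  readr::write_tsv(tibble(sample_id = names(x$groups),
                          group = unname(x$groups)),
                   groups_path, progress = FALSE)
  invisible(path)
}

#' @rdname concord_io
#' @export
read_orthology_tsv <- function(path) {
  tab <- read_tsv_c(path)
  need <- c("human_probeset", "gene_symbol", "mouse_probeset")
  if (!all(need %in% names(tab))) {
    stop_data("Orthology TSV needs columns human_probeset, gene_symbol, mouse_probeset.")
  }
  tab[need]
}

#' @rdname concord_io
#' @export
read_edges_tsv <- function(path) {
  tab <- read_tsv_c(path)
  names(tab)[1:3] <- c("node_a", "node_b", "confidence")
  as_edge_list(tab)
}

#' @rdname concord_io
#' @export
read_study_tsv <- function(path) {
  tab <- read_tsv_c(path)
  need <- c("study_id", "category", "gene_symbol", "fold_change", "p_value")
  if (!all(need %in% names(tab))) {
    stop_data("Study summary TSV needs columns study_id, category, gene_symbol, fold_change, p_value.")
  }
  tab[need]
}

#' @rdname concord_io
#' @export
read_survival_tsv <- function(path) {
  tab <- read_tsv_c(path)
  need <- c("subject_id", "time", "event", "arm")
  if (!all(need %in% names(tab))) {
    stop_data("Survival TSV needs columns subject_id, time, event, arm plus gene columns.")
  }
  tab
}

#' Read / write GMT gene-set files
#'
#' The GMT convention: one set per line, tab-separated as
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop_data("GMT lines need a name, description and >=1 member.")
  sets <- purrr::map(parts, ~ unique(.x[-(1:2)]))
  names(sets) <- purrr::map_chr(parts, 1)
  attr(sets, "descriptions") <- setNames(purrr::map_chr(parts, 2),
                                         names(sets))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_data("Every gene set needs a non-empty name.")
  }
  descriptions <- descriptions %||% attr(sets, "descriptions") %||%
    rep("", length(sets))
  lines <- purrr::map_chr(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Load a packaged published-table fixture
#'
#' `"table1"` is the 60-gene cross-species concordant list (per human
#' probeset, with the gene's single mouse probeset repeated); `"table2"` the
#' per-probeset survival screen results for the 8 survival-associated genes.
#' Both are invariant-checked on load: table 1 must contain exactly 60 genes,
#' every |fold| >= 2 and every p < 0.01, with >=1 human and exactly 1 mouse
#' probeset per gene; table 2 must have positive hazard ratios, ordered
#' interval bounds, and printed significance markers that agree with the
#' interval excluding 1.
#'
#' @param name `"table1"` or `"table2"`.
#' @return a tibble.
#' @examples
#' t1 <- load_fixture("table1")
#' dplyr::n_distinct(t1$gene_symbol)
#' @export
load_fixture <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  file <- c(table1 = "table1_dmb_genes.tsv",
            table2 = "table2_survival.tsv")[[name]]
  path <- system.file("extdata", file, package = "concord")
  if (!nzchar(path)) stop_data(sprintf("Fixture `%s` not found.", name))
  tab <- read_tsv_c(path)
  if (name == "table1") {
    genes <- unique(tab$gene_symbol)
    per_gene <- dplyr::count(tab, .data$gene_symbol)
    mouse_per_gene <- tab |>
      group_by(.data$gene_symbol) |>
      summarise(n_mouse = dplyr::n_distinct(.data$mouse_probeset),
                .groups = "drop")
    ok <- length(genes) == 60 &&
      all(per_gene$n >= 1) &&
      all(mouse_per_gene$n_mouse == 1) &&
      all(abs(tab$human_fold) >= 2) && all(abs(tab$mouse_fold) >= 2) &&
      all(tab$human_p < 0.01) && all(tab$mouse_p < 0.01) &&
      !anyDuplicated(tab$human_probeset)
    if (!ok) stop_data("table1 fixture failed its invariant checks.")
  } else {
    chop_sig <- tab$chop_ci_low > 1 | tab$chop_ci_high < 1
    rchop_sig <- tab$rchop_ci_low > 1 | tab$rchop_ci_high < 1
    ok <- nrow(tab) == 10 &&
      all(tab$chop_hr > 0) && all(tab$rchop_hr > 0) &&
      all(tab$chop_ci_low < tab$chop_ci_high) &&
      all(tab$rchop_ci_low < tab$rchop_ci_high) &&
      identical(chop_sig, tab$chop_significant) &&
      identical(rchop_sig, tab$rchop_significant)
    if (!ok) stop_data("table2 fixture failed its invariant checks.")
  }
  tab
}
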