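# Canonicalise an undirected weighted edge list: order node pairs, validate
# confidences, drop nothing silently.
as_edge_list <- function(edges) {
  edges <- as_tibble(edges)
  need <- c("node_a", "node_b", "confidence")
  if (!all(need %in% names(edges))) {
    stop_data("Edge list needs columns node_a, node_b, confidence.")
  }
  if (any(edges$node_a == edges$node_b)) {
    stop_data("Self-loops are not allowed in the interaction network.")
  }
  if (any(!is.finite(edges$confidence) | edges$confidence <= 0 |
          edges$confidence > 1)) {
    stop_data("Edge confidences must lie in (0, 1].")
  }
  out <- tibble(
    node_a = pmin(edges$node_a, edges$node_b),
    node_b = pmax(edges$node_a, edges$node_b),
    confidence = edges$confidence
  ) |> arrange(.data$node_a, .data$node_b)
  if (anyDuplicated(out[c("node_a", "node_b")])) {
    stop_data("Duplicate edges in the interaction network.")
  }
  out
}

#' Greedy confidence-weighted network expansion from seed genes
#'
#' Starting from the seed genes, repeatedly adds the non-member node with the
#' highest single-edge confidence to the current member set until the member
#' count reaches `target_n` or no connected candidate remains. Edges below
#' `min_confidence` are discarded before expansion ("highest confidence"
#' associations only). Ties are broken by the summed confidence of a
#' candidate's edges into the member set, then by lexicographic node id, so
#' the result is deterministic and invariant to edge-list input order;
#' expansion to n members is a prefix of expansion to n + 1.
#'
#' @param edges weighted undirected edge list: tibble with `node_a`,
#'   `node_b`, `confidence` in (0, 1].
#' @param seeds non-empty character vector of seed genes; every seed must be
#'   a node of the (unfiltered) network.
#' @param target_n total member count to expand to (default 50).
#' @param min_confidence confidence pre-filter applied before expansion
#'   (default 0.9).
#' @return object of class `expansion_result`: list with `members` (tibble:
#'   `node`, `is_seed`, `order_added`, `weighted_degree`, `degree`,
#'   `component`), `edges` (induced subgraph edges) and `seeds`.
#' @examples
#' edges <- tibble::tibble(
#'   node_a = c("a", "b", "a"), node_b = c("c", "c", "d"),
#'   confidence = c(0.95, 0.92, 0.91))
#' expand_network(edges, seeds = c("a", "b"), target_n = 3)
#' @export
expand_network <- function(edges, seeds, target_n = 50,
                           min_confidence = 0.9) {
  if (length(seeds) == 0) stop_data("`seeds` must be non-empty.")
  if (target_n < 1) stop_config("`target_n` must be at least 1.")
  edges <- as_edge_list(edges)
  all_nodes <- unique(c(edges$node_a, edges$node_b))
  missing <- setdiff(seeds, all_nodes)
  if (length(missing) > 0) {
    stop_data(sprintf("Seed gene(s) not present in the network: %s",
                      paste(missing, collapse = ", ")))
  }
  kept <- edges[edges$confidence >= min_confidence, ]
  members <- unique(seeds)
  n_seed <- length(members)
  order_added <- setNames(rep(0L, length(members)), members)
  while (length(members) < target_n) {
    inc <- kept[xor(kept$node_a %in% members, kept$node_b %in% members), ]
    if (nrow(inc) == 0) break
    cand_node <- ifelse(inc$node_a %in% members, inc$node_b, inc$node_a)
    stats_tab <- tibble(node = cand_node, confidence = inc$confidence) |>
      group_by(.data$node) |>
      summarise(best = max(.data$confidence),
                total = sum(.data$confidence), .groups = "drop") |>
      arrange(dplyr::desc(.data$best), dplyr::desc(.data$total), .data$node)
    nxt <- stats_tab$node[1]
    members <- c(members, nxt)
    order_added[nxt] <- length(members) - n_seed
  }
  induced <- kept[kept$node_a %in% members & kept$node_b %in% members, ]
  g <- igraph::graph_from_data_frame(
    induced[c("node_a", "node_b")], directed = FALSE,
    vertices = data.frame(name = members))
  comp <- igraph::components(g)$membership
  wdeg <- setNames(rep(0, length(members)), members)
  deg <- wdeg
  for (i in seq_len(nrow(induced))) {
    a <- induced$node_a[i]; b <- induced$node_b[i]
    wdeg[a] <- wdeg[a] + induced$confidence[i]
    wdeg[b] <- wdeg[b] + induced$confidence[i]
    deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
  }
  member_tab <- tibble(
    node = members,
    is_seed = members %in% seeds,
    order_added = unname(order_added[members]),
    weighted_degree = unname(wdeg[members]),
    degree = as.integer(unname(deg[members])),
    component = unname(comp[members])
  )
  structure(
    list(members = member_tab, edges = induced, seeds = unique(seeds),
         target_n = target_n, min_confidence = min_confidence),
    class = "expansion_result"
  )
}

#' @export
print.expansion_result <- function(x, ...) {
  cat(sprintf(
    "<expansion_result> %d members (%d seeds) over %d induced edges, %d component(s)\n",
    nrow(x$members), length(x$seeds), nrow(x$edges),
    length(unique(x$members$component))))
  invisible(x)
}

#' @export
tidy.expansion_result <- function(x, ...) x$members

#' Rank added nodes as hub candidates
#'
#' Orders the non-seed members of an expansion by their weighted degree in
#' the induced subgraph (sum of incident edge confidences), breaking ties by
#' unweighted degree and then node id, and reports how many seeds share a
#' connected component with each candidate -- a hub tied to most seeds by
#' high-confidence edges tops this ranking.
#'
#' @param result an `expansion_result`.
#' @return tibble: `node`, `weighted_degree`, `degree`, `seeds_in_component`,
#'   `rank`.
#' @export
hub_candidates <- function(result) {
  stopifnot(inherits(result, "expansion_result"))
  m <- result$members
  seeds_per_comp <- m |>
    group_by(.data$component) |>
    summarise(n_seeds = sum(.data$is_seed), .groups = "drop")
  cand <- m |>
    filter(!.data$is_seed) |>
    left_join(seeds_per_comp, by = "component") |>
    arrange(dplyr::desc(.data$weighted_degree), dplyr::desc(.data$degree),
            .data$node) |>
    mutate(rank = dplyr::row_number()) |>
    select("node", "weighted_degree", "degree",
           seeds_in_component = "n_seeds", "rank")
  cand
}

#' Seed membership per connected component
#'
#' Partitions the expansion members into connected components, counts seeds
#' per component, and names the seeds isolated from the largest seed-bearing
#' component (those sitting in satellite neighborhoods).
#'
#' @param result an `expansion_result`.
#' @return list with `components` (tibble: `component`, `size`, `n_seeds`,
#'   `members` list-column) and `isolated_seeds` (seeds outside the largest
#'   seed-bearing component).
#' @export
seed_component_report <- function(result) {
  stopifnot(inherits(result, "expansion_result"))
  m <- result$members
  comps <- m |>
    group_by(.data$component) |>
    summarise(size = n(), n_seeds = sum(.data$is_seed),
              members = list(.data$node), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_seeds), dplyr::desc(.data$size))
  main <- comps$component[which.max(comps$n_seeds)]
  isolated <- m$node[m$is_seed & m$component != main]
  list(components = comps, isolated_seeds = isolated)
}
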