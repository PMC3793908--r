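# Small constructors used across the suite.

# expr_matrix with one probeset per row of `tumor` / `normal` value lists
make_expr <- function(tumor, normal, species = "human",
                      ids = sprintf("ps%02d", seq_along(tumor))) {
  tumor <- if (is.list(tumor)) tumor else list(tumor)
  normal <- if (is.list(normal)) normal else list(normal)
  nt <- length(tumor[[1]]); nn <- length(normal[[1]])
  vals <- t(mapply(function(a, b) c(a, b), tumor, normal))
  samples <- c(paste0("T", seq_len(nt)), paste0("N", seq_len(nn)))
  dimnames(vals) <- list(ids, samples)
  groups <- stats::setNames(rep(c("tumor", "normal"), c(nt, nn)), samples)
  expr_matrix(vals, species, groups)
}

# hand-built de_result for concordance tests: supply the full table, the
# significant set is derived with the standard thresholds
fake_de <- function(full, species = "human", p_cut = 0.01, q_cut = 0.01) {
  full <- tibble::as_tibble(full)
  if (!"gene_symbol" %in% names(full)) full$gene_symbol <- full$probeset_id
  if (!"direction" %in% names(full)) {
    full$direction <- ifelse(full$fold_change >= 0, 1L, -1L)
  }
  sig <- dplyr::filter(full, p_value < p_cut, !is.na(q_value),
                       q_value < q_cut)
  structure(list(full = full, sig = sig, species = species, p_cut = p_cut,
                 q_cut = q_cut, fdr_scope = "subset"), class = "de_result")
}

# 1:1 orthology triples over shared symbols
map_1to1 <- function(symbols) {
  tibble::tibble(human_probeset = paste0(symbols, "_h"),
                 gene_symbol = symbols,
                 mouse_probeset = paste0(symbols, "_m"))
}

small_sim <- function(seed = 1, ...) {
  sim_config(n_genes_per_species = 300, n_concordant = 15, seed = seed, ...)
}
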