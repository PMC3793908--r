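abc_de <- function(sig_syms, all_syms, species, suffix) {
  fake_de(tibble::tibble(
    probeset_id = paste0(all_syms, suffix),
    gene_symbol = all_syms,
    p_value = ifelse(all_syms %in% sig_syms, 0.001, 0.5),
    q_value = ifelse(all_syms %in% sig_syms, 0.005, NA_real_),
    fold_change = ifelse(all_syms %in% sig_syms, 3, 1.1)
  ), species = species)
}

test_that("reciprocal overlap counts a hand-built set intersection", {
  syms <- c("A", "B", "C", "D", "E")
  hde <- abc_de(c("A", "B", "C"), syms, "human", "_h")
  mde <- abc_de(c("B", "C", "D"), syms, "mouse", "_m")
  ov <- reciprocal_overlap(hde, mde, map_1to1(syms))
  him <- dplyr::filter(ov$report, comparison == "human_in_mouse",
                       cross_fdr == 0.01)
  expect_equal(him$count, 2)      # B and C
  expect_equal(him$denominator, 3)
  mih <- dplyr::filter(ov$report, comparison == "mouse_in_human",
                       cross_fdr == 0.01)
  expect_equal(mih$count, 2)
  expect_equal(mih$denominator, 3)
})

test_that("an empty orthology map warns and reports zero overlap", {
  syms <- c("A", "B")
  hde <- abc_de("A", syms, "human", "_h")
  mde <- abc_de("B", syms, "mouse", "_m")
  expect_warning(ov <- reciprocal_overlap(hde, mde, map_1to1(syms)[0, ]),
                 "Empty orthology")
  expect_true(all(ov$report$count == 0))
})

test_that("species-swap symmetry: transposing the map swaps the two reports", {
  syms <- LETTERS[1:6]
  hde <- abc_de(c("A", "B", "C"), syms, "human", "_h")
  mde <- abc_de(c("B", "C", "E"), syms, "mouse", "_m")
  map <- map_1to1(syms)
  fwd <- reciprocal_overlap(hde, mde, map)$report
  tmap <- dplyr::rename(map, human_probeset = mouse_probeset,
                        mouse_probeset = human_probeset)
  rev <- reciprocal_overlap(mde, hde, tmap)$report
  for (f in c(0.05, 0.01)) {
    expect_equal(
      dplyr::filter(fwd, comparison == "human_in_mouse", cross_fdr == f)$count,
      dplyr::filter(rev, comparison == "mouse_in_human", cross_fdr == f)$count)
  }
})

test_that("overlap counts are monotone in the cross-species threshold", {
  sim <- simulate_two_species(small_sim(seed = 12, effect_log2 = 1))
  ov <- reciprocal_overlap(run_de(sim$human), run_de(sim$mouse),
                           sim$orthology)
  wide <- tidyr::pivot_wider(ov$report[c("comparison", "cross_fdr", "count")],
                             names_from = "cross_fdr", values_from = "count")
  expect_true(all(wide$`0.01` <= wide$`0.05`))
})

test_that("concordant gene assembly groups probesets and applies the direction rule", {
  pairs <- tibble::tibble(
    human_probeset = c("g1_h1", "g1_h2", "g2_h"),
    gene_symbol = c("G1", "G1", "G2"),
    mouse_probeset = c("g1_m", "g1_m", "g2_m"),
    p_human = c(0.001, 0.002, 0.001), q_human = c(0.004, 0.005, 0.004),
    fold_human = c(3, 2, 3), direction_human = c(1L, 1L, 1L),
    p_mouse = c(0.002, 0.002, 0.003), q_mouse = c(0.006, 0.006, 0.005),
    fold_mouse = c(4, 4, 2.5), direction_mouse = c(1L, 1L, 1L)
  )
  cg <- concordant_genes(pairs)
  expect_equal(nrow(cg), 2)
  g1 <- cg[cg$gene_symbol == "G1", ]
  expect_equal(g1$direction, 1L)
  expect_equal(g1$n_human_probesets, 2L)
  expect_equal(g1$max_abs_fold_human, 3)
  expect_equal(nrow(g1$human_records[[1]]), 2)
})

test_that("direction-discordant genes are dropped by default but kept on request", {
  pairs <- tibble::tibble(
    human_probeset = "d_h", gene_symbol = "DISC", mouse_probeset = "d_m",
    p_human = 1.8e-4, q_human = 0.001, fold_human = -2.39,
    direction_human = -1L,
    p_mouse = 6.5e-4, q_mouse = 0.002, fold_mouse = 2.34,
    direction_mouse = 1L
  )
  strict <- suppressMessages(concordant_genes(pairs))
  expect_equal(nrow(strict), 0)
  expect_equal(attr(strict, "discordant"), "DISC")
  permissive <- concordant_genes(pairs, keep_discordant = TRUE)
  expect_equal(nrow(permissive), 1)
  expect_equal(permissive$direction, -1L)   # human record dominates
})

test_that("planted concordant genes recovered by both screens are contained in the overlap", {
  sim <- simulate_two_species(small_sim(seed = 8))
  hde <- run_de(sim$human); mde <- run_de(sim$mouse)
  cg <- suppressMessages(
    concordant_genes(reciprocal_overlap(hde, mde, sim$orthology)))
  planted <- names(sim$truth$concordant_genes)
  both_sig <- planted[paste0(tolower(planted), "_h_at") %in%
                        hde$sig$probeset_id &
                      paste0(tolower(planted), "_m_at") %in%
                        mde$sig$probeset_id]
  expect_true(all(both_sig %in% toupper(cg$gene_symbol)))
})

test_that("exclusion partitions the input and counts per-set membership", {
  genes <- tibble::tibble(gene_symbol = c("A", "B", "C"),
                          direction = c(1L, -1L, 1L))
  none <- apply_exclusion(genes, list())
  expect_identical(none$kept, genes)
  expect_equal(nrow(none$removed), 0)

  res <- apply_exclusion(genes, list(prolif = c("B", "D")))
  expect_equal(res$removed$gene_symbol, "B")
  expect_setequal(c(res$kept$gene_symbol, res$removed$gene_symbol),
                  genes$gene_symbol)
  expect_equal(res$set_counts$n_members, 1L)

  # 130-gene scale: exactly the 17 planted members are removed
  big <- tibble::tibble(gene_symbol = sprintf("g%03d", 1:130),
                        direction = 1L)
  res2 <- apply_exclusion(big, list(prolif = sprintf("g%03d", 1:17)))
  expect_equal(nrow(res2$removed), 17)
  expect_equal(nrow(res2$kept), 113)
})

test_that("fold filter keeps genes clearing the threshold in both species", {
  genes <- tibble::tibble(
    gene_symbol = c("FAIL_H", "CLCF1", "UP"),
    direction = c(1L, -1L, 1L),
    max_abs_fold_human = c(1.9, 2.14, 5),
    max_abs_fold_mouse = c(3, 2.08, 1.2)
  )
  res <- fold_filter(genes)
  expect_equal(res$kept$gene_symbol, "CLCF1")
  expect_setequal(res$removed$gene_symbol, c("FAIL_H", "UP"))
  expect_equal(res$n_removed_up, 2)
  expect_equal(res$n_removed_down, 0)
  expect_error(fold_filter(genes, threshold = 0.5),
               class = "concord_config_error")
})

test_that("the published gene table passes the fold filter untouched", {
  t1 <- load_fixture("table1")
  per_gene <- t1 |>
    dplyr::group_by(gene_symbol) |>
    dplyr::summarise(direction = sign(human_fold[1]),
                     max_abs_fold_human = max(abs(human_fold)),
                     max_abs_fold_mouse = max(abs(mouse_fold)),
                     .groups = "drop")
  res <- fold_filter(per_gene)
  expect_equal(nrow(res$removed), 0)
  expect_equal(nrow(res$kept), 60)
})

test_that("report percentages round half-up to printed precision", {
  expect_equal(percent_of(599, 3268), 18.3)
  expect_equal(percent_of(1356, 2893), 46.9)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
})
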