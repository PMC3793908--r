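test_that("vote counting applies fold, p and direction thresholds", {
  genes <- tibble::tibble(gene_symbol = c("HIT", "MISS"),
                          direction = c(1L, 1L))
  studies <- dplyr::bind_rows(
    tibble::tibble(study_id = paste0("s", 1:4), category = "tumor vs normal",
                   gene_symbol = "HIT", fold_change = 2.5, p_value = 0.005),
    tibble::tibble(study_id = "s5", category = "tumor vs normal",
                   gene_symbol = "HIT", fold_change = 1.8, p_value = 0.001)
  )
  v <- recurrence_vote(genes, studies)
  expect_equal(v$votes[v$gene_symbol == "HIT"], 4L)   # s5 fails the fold cut
  expect_equal(v$tier[v$gene_symbol == "HIT"], ">=4")
  expect_equal(v$votes[v$gene_symbol == "MISS"], 0L)
  expect_true(is.na(v$tier[v$gene_symbol == "MISS"]))
})

test_that("direction matching is enforced by default and can be disabled", {
  genes <- tibble::tibble(gene_symbol = "G", direction = 1L)
  studies <- tibble::tibble(study_id = c("s1", "s2"), category = "c",
                            gene_symbol = "G", fold_change = c(3, -3),
                            p_value = 0.001)
  expect_equal(recurrence_vote(genes, studies)$votes, 1L)
  expect_equal(recurrence_vote(genes, studies,
                               require_direction = FALSE)$votes, 2L)
})

test_that("multiple records per study collapse to the smallest p", {
  genes <- tibble::tibble(gene_symbol = "G", direction = 1L)
  studies <- tibble::tibble(
    study_id = "s1", category = "c", gene_symbol = "G",
    fold_change = c(1.2, 4), p_value = c(0.5, 0.001))
  # the min-p record (fold 4, p 0.001) represents the study
  expect_equal(recurrence_vote(genes, studies)$votes, 1L)
})

test_that("votes are monotone under threshold relaxation", {
  set.seed(21)
  genes <- tibble::tibble(gene_symbol = sprintf("g%02d", 1:10),
                          direction = sample(c(-1L, 1L), 10, TRUE))
  studies <- tidyr::expand_grid(study_id = paste0("s", 1:5),
                                gene_symbol = genes$gene_symbol) |>
    dplyr::mutate(category = "c",
                  fold_change = sample(c(-1, 1), dplyr::n(), TRUE) *
                    runif(dplyr::n(), 1, 6),
                  p_value = runif(dplyr::n(), 0, 0.05))
  strict <- recurrence_vote(genes, studies, p_max = 0.01, fold_min = 3)
  loose <- recurrence_vote(genes, studies, p_max = 0.05, fold_min = 2)
  expect_true(all(loose$votes >= strict$votes))
})

test_that("enrichment reproduces the exact 2x2 hand case", {
  u <- paste0("g", 1:8)
  res <- fisher_enrichment(candidates = u[1:4], targets = u[c(1:3, 5)],
                           universe = u)
  expect_equal(unname(res$table), c(3, 1, 1, 3))
  expect_equal(res$p_one_sided, 17 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)
})

test_that("degenerate enrichment tables are handled at their boundaries", {
  u <- paste0("g", 1:10)
  none <- fisher_enrichment(u[1:3], u[4:6], u)
  expect_equal(none$p_one_sided, 1)

  perfect <- fisher_enrichment(u[1:5], u[1:5], u)
  expect_true(perfect$haldane)
  expect_gt(perfect$odds_ratio, 100)
  expect_equal(perfect$p_one_sided, 1 / choose(10, 5), tolerance = 1e-12)

  expect_error(fisher_enrichment("a", "a", universe = "a",
                                 restrict_to = "zzz"),
               class = "concord_data_error")
})

test_that("restriction conditions all three sets before testing", {
  u <- paste0("g", 1:20)
  go <- u[1:10]
  res <- fisher_enrichment(u[c(1:4, 15:16)], u[c(1:2, 5, 17)], u,
                           restrict_to = go)
  expect_equal(res$universe_size, 10)
  expect_equal(unname(res$table["a"]), 2)   # g1, g2 inside the GO slice
})

test_that("one-sided p equals exhaustive enumeration for small universes", {
  set.seed(33)
  for (i in 1:25) {
    n_u <- sample(8:50, 1)
    u <- paste0("g", seq_len(n_u))
    cand <- sample(u, sample(2:(n_u - 2), 1))
    targ <- sample(u, sample(2:(n_u - 2), 1))
    res <- fisher_enrichment(cand, targ, u)
    a <- length(intersect(cand, targ))
    # direct enumeration over all tables with these margins
    ks <- max(0, length(cand) + length(targ) - n_u):
      min(length(cand), length(targ))
    probs <- choose(length(targ), ks) *
      choose(n_u - length(targ), length(cand) - ks) /
      choose(n_u, length(cand))
    expect_equal(res$p_one_sided, sum(probs[ks >= a]), tolerance = 1e-10)
    # reference implementation agreement, both sidedness conventions
    mat <- matrix(c(a, length(setdiff(cand, targ)),
                    length(setdiff(targ, cand)),
                    n_u - length(union(cand, targ))), 2, byrow = TRUE)
    expect_equal(res$p_one_sided,
                 fisher.test(mat, alternative = "greater")$p.value,
                 tolerance = 1e-8)
    expect_equal(res$p_two_sided, fisher.test(mat)$p.value,
                 tolerance = 1e-8)
  }
})

test_that("enrichment p is invariant to swapping the candidate and target roles", {
  u <- paste0("g", 1:30)
  cand <- u[1:12]; targ <- u[8:18]
  a <- fisher_enrichment(cand, targ, u)
  b <- fisher_enrichment(targ, cand, u)
  expect_equal(a$p_one_sided, b$p_one_sided, tolerance = 1e-12)
  expect_equal(a$p_two_sided, b$p_two_sided, tolerance = 1e-12)
})
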