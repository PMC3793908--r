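test_that("generator is deterministic given seed and validates its config", {
  cfg <- small_sim(seed = 9)
  a <- simulate_two_species(cfg)
  b <- simulate_two_species(cfg)
  expect_identical(a$human$values, b$human$values)
  expect_identical(a$orthology, b$orthology)
  expect_identical(a$truth, b$truth)

  expect_error(sim_config(sigma = 0), class = "concord_config_error",
               regexp = "sigma")
  expect_error(sim_config(frac_de = 1.2), class = "concord_config_error",
               regexp = "frac_de")
  expect_error(sim_config(n_genes_per_species = 100, frac_de = 0.1,
                          n_concordant = 50),
               class = "concord_config_error", regexp = "n_concordant")
})

test_that("planted truth respects its own invariants", {
  sim <- simulate_two_species(small_sim(seed = 4))
  tr <- sim$truth
  expect_true(all(names(tr$concordant_genes) %in% tr$de_genes_human))
  expect_true(all(names(tr$concordant_genes) %in% tr$de_genes_mouse))
  expect_true(all(tr$concordant_genes %in% c(-1L, 1L)))
  expect_length(tr$concordant_genes, 15)
  # concordant genes shift in the same direction in both matrices
  g <- names(tr$concordant_genes)[1]
  for (m in list(sim$human, sim$mouse)) {
    ps <- grep(tolower(g), rownames(m$values), value = TRUE)
    d <- mean(m$values[ps[1], m$groups == "tumor"]) -
      mean(m$values[ps[1], m$groups == "normal"])
    expect_equal(sign(d), tr$concordant_genes[[g]])
  }
})

test_that("no planted signal means no DE truth and an empty significant set", {
  sim <- simulate_two_species(
    sim_config(n_genes_per_species = 200, frac_de = 0, n_concordant = 0,
               seed = 3))
  expect_length(sim$truth$de_genes_human, 0)
  expect_length(sim$truth$de_genes_mouse, 0)
  de <- run_de(sim$human)
  expect_lte(nrow(de$sig), 5)   # false discoveries only, FDR-bounded
})

test_that("null generator yields uniform-rate raw p-values", {
  # effect 0 but half the genes flagged DE: the flags must not leak signal
  frac <- sapply(1:50, function(s) {
    sim <- simulate_two_species(
      sim_config(n_genes_per_species = 100, frac_de = 0.5, n_concordant = 10,
                 effect_log2 = 0, n_tumor = 5, n_normal = 5, seed = s))
    mean(two_group_test(sim$human)$p_value < 0.05)
  })
  expect_lt(abs(mean(frac) - 0.05), 0.012)
})

test_that("survival generator recovers a planted log-hazard and flags no-event data", {
  truth <- structure(list(survival_genes = c(GENE0001 = 1)),
                     class = "sim_truth")
  cfg <- sim_config(seed = 11)
  co <- simulate_survival("GENE0001", truth, n_subjects = 200, config = cfg)
  fit <- fit_cox_univariate(co, "GENE0001")
  expect_lt(abs(fit$beta - 1), 2 * fit$se)

  expect_error(simulate_survival(character(0)), class = "concord_data_error")
  expect_error(simulate_survival("g", n_subjects = 10),
               class = "concord_config_error")
  all_censored <- simulate_survival(
    "GENE0001", truth, n_subjects = 50,
    config = sim_config(censor_time = 0, seed = 2))
  expect_true(all(all_censored$event == 0))
  expect_error(fit_cox_univariate(all_censored, "GENE0001"),
               regexp = "[Nn]o events")
})

test_that("network generator plants a recoverable high-confidence hub", {
  sim <- simulate_two_species(small_sim(seed = 5))
  seeds <- names(sim$truth$concordant_genes)[1:6]

  star_only <- simulate_network(
    sim$truth, seeds,
    config = small_sim(seed = 5, background_edge_prob = 0,
                       hub_seed_edges = 6))
  expect_setequal(star_only$node_a, sim$truth$hub_node)
  expect_setequal(star_only$node_b, seeds)
  expect_true(all(star_only$confidence >= 0.9))

  edges <- simulate_network(sim$truth, seeds, config = small_sim(seed = 5))
  expect_true(all(seeds %in% c(edges$node_a, edges$node_b)))
  res <- expand_network(edges, seeds, target_n = 10)
  expect_true(sim$truth$hub_node %in% res$members$node)
  expect_identical(hub_candidates(res)$node[1], sim$truth$hub_node)
})

test_that("study summaries hit the planted genes at the detection rate", {
  sim <- simulate_two_species(small_sim(seed = 6))
  conc <- tibble::tibble(gene_symbol = names(sim$truth$concordant_genes),
                         direction = unname(sim$truth$concordant_genes))

  all_in <- simulate_study_summaries(sim$truth, n_studies = 7,
                                     detect_prob = 1, config = small_sim(6))
  v <- recurrence_vote(conc, all_in)
  expect_true(all(v$votes == 7))

  none <- simulate_study_summaries(sim$truth, n_studies = 7,
                                   detect_prob = 0, config = small_sim(6))
  expect_true(all(recurrence_vote(conc, none)$votes == 0))

  means <- sapply(1:10, function(s) {
    st <- simulate_study_summaries(sim$truth, n_studies = 7,
                                   detect_prob = 0.5,
                                   config = small_sim(seed = s))
    mean(recurrence_vote(conc, st)$votes)
  })
  expect_lt(abs(mean(means) - 3.5), 0.35)
})
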