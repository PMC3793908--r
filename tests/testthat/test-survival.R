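random_cohort <- function(n = 30, beta = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t <- round(rexp(n, 0.2 * exp(beta * x)), 1) + 0.1   # rounding creates ties
  ev <- rbinom(n, 1, 0.7)
  tibble::tibble(subject_id = as.character(seq_len(n)), time = t,
                 event = ev, arm = "A", g = x)
}

test_that("degenerate survival inputs raise named errors", {
  co <- random_cohort(seed = 2)
  co$g <- 1
  expect_error(fit_cox_univariate(co, "g"), "[Dd]egenerate")
  co2 <- random_cohort(seed = 3)
  co2$event <- 0L
  expect_error(fit_cox_univariate(co2, "g"), "[Nn]o events")
  expect_error(fit_cox_univariate(random_cohort(), "nope"), "not found")
})

test_that("Wald interval and p-value significance agree exactly", {
  fits <- dplyr::bind_rows(lapply(1:10, function(s) {
    fit_cox_univariate(random_cohort(40, beta = 0.8, seed = s), "g")
  }))
  expect_equal(fits$ci_low > 1 | fits$ci_high < 1, fits$p_value < 0.05)
  expect_true(all(fits$ci_low < fits$hazard_ratio))
  expect_true(all(fits$hazard_ratio < fits$ci_high))
})

test_that("rescaling the covariate rescales beta and preserves the Wald test", {
  co <- random_cohort(50, beta = 0.6, seed = 9)
  f1 <- fit_cox_univariate(co, "g")
  co$g <- co$g * 4
  f4 <- fit_cox_univariate(co, "g")
  expect_equal(f4$beta, f1$beta / 4, tolerance = 1e-6)
  expect_equal(f4$p_value, f1$p_value, tolerance = 1e-8)
})

test_that("monotone likelihood is flagged, not fatal, and excluded from counts", {
  # covariate perfectly ordered with event times: beta diverges
  co <- tibble::tibble(
    subject_id = as.character(1:8),
    time = c(1, 2, 3, 4, 5, 6, 7, 8),
    event = 1L, arm = "A",
    g = c(8, 7, 6, 5, 4, 3, 2, 1))
  fit <- fit_cox_univariate(co, "g")
  expect_true(fit$monotone)
  expect_equal(fit$ci_high, Inf)
  scr <- suppressMessages(screen_genes(co, "g"))
  expect_length(scr$significant_genes, 0)
})

test_that("the screen finds a strongly planted gene in both arms", {
  truth <- structure(list(survival_genes = c(GENE0001 = 1)),
                     class = "sim_truth")
  co <- simulate_survival(c("GENE0001", "GENE0002"), truth,
                          n_subjects = 400, config = sim_config(seed = 5))
  scr <- screen_genes(co, c("GENE0001", "GENE0002"))
  fits <- tidy(scr)
  expect_true(all(fits$significant[fits$gene_symbol == "GENE0001"]))
  expect_true("GENE0001" %in% scr$significant_genes)
  expect_true(all(c("CHOP", "R-CHOP") %in% fits$arm))
  expect_true(all(!is.na(fits$arm_diff_p)))
  g <- glance(scr)
  expect_equal(g$n_significant >= 1, TRUE)
})

test_that("direction consistency follows the strict sign rule", {
  expect_true(direction_consistency(1.451, 1))    # up gene, HR > 1
  expect_true(direction_consistency(0.736, -1))   # down gene, HR < 1
  expect_false(direction_consistency(1.0, 1))     # boundary is inconsistent
  expect_false(direction_consistency(0.9, 1))
  expect_equal(direction_consistency(c(1.2, 0.8), c(1, 1)), c(TRUE, FALSE))
})

test_that("exact proportion interval matches closed forms and nests", {
  ci <- proportion_ci_exact(8, 60)
  expect_equal(round_half_up(ci$lower, 2), 0.06)
  expect_equal(round_half_up(ci$upper, 2), 0.25)
  expect_true(ci$excludes_chance)

  zero <- proportion_ci_exact(0, 10)
  expect_equal(zero$lower, 0)
  expect_equal(zero$upper, 1 - 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(proportion_ci_exact(10, 10)$upper, 1)

  wide <- proportion_ci_exact(8, 60, level = 0.99)
  expect_lt(wide$lower, ci$lower)
  expect_gt(wide$upper, ci$upper)

  # binom.test uses the same exact construction
  bt <- binom.test(8, 60)$conf.int
  expect_equal(c(ci$lower, ci$upper), as.numeric(bt), tolerance = 1e-10)

  expect_error(proportion_ci_exact(5, 4), class = "concord_data_error")
  expect_error(proportion_ci_exact(-1, 4), class = "concord_data_error")
})

test_that("the published survival table yields 8 significant genes, all direction-consistent", {
  t2 <- load_fixture("table2")
  sig <- t2[t2$chop_significant | t2$rchop_significant, ]
  expect_equal(dplyr::n_distinct(sig$gene_symbol), 8)
  # every significant fit agrees with the gene's expression direction
  chop_ok <- direction_consistency(sig$chop_hr, sig$direction)
  rchop_ok <- direction_consistency(sig$rchop_hr, sig$direction)
  expect_true(all(chop_ok[sig$chop_significant]))
  expect_true(all(rchop_ok[sig$rchop_significant]))
})
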