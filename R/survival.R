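# Newton-Raphson maximisation of the univariate Cox partial likelihood with
# Breslow handling of tied event times. Returns beta, its standard error from
# the observed information, the number of iterations, and a monotone-
# likelihood flag (covariate perfectly orders the events, beta diverging).
cox_partial_fit <- function(time, event, x, tol = 1e-8, max_iter = 25) {
  keep <- complete.cases(time, event, x)
  time <- time[keep]; event <- event[keep]; x <- x[keep]
  n_events <- sum(event == 1)
  if (n_events < 2) {
    stop_data("Cox fit needs at least 2 events (\"no events\" in this stratum).")
  }
  if (length(unique(x)) < 2 || stats::sd(x) == 0) {
    stop_data("Degenerate covariate: expression is constant across subjects.")
  }
  # centre for numerical stability; beta is unaffected
  xc <- x - mean(x)
  ord <- order(-time, event)          # descending time
  tt <- time[ord]; ev <- event[ord]; xv <- xc[ord]
  # risk set of an event at time t = all with time >= t; with the descending
  # sort that is the prefix through the last index whose time equals t
  event_idx <- which(ev == 1)
  risk_end <- vapply(event_idx, function(i) {
    max(which(tt >= tt[i]))
  }, integer(1))

  beta <- 0
  monotone <- FALSE
  for (iter in seq_len(max_iter)) {
    w <- exp(beta * xv)
    s0 <- cumsum(w)
    s1 <- cumsum(xv * w)
    s2 <- cumsum(xv^2 * w)
    mu <- s1[risk_end] / s0[risk_end]
    score <- sum(xv[event_idx] - mu)
    info <- sum(s2[risk_end] / s0[risk_end] - mu^2)
    if (!is.finite(score) || !is.finite(info) || info < 1e-12 ||
        abs(beta) > 20) {
      monotone <- TRUE
      break
    }
    step <- score / info
    beta <- beta + step
    if (abs(score) < tol) break
  }
  w <- exp(beta * xv)
  s0 <- cumsum(w); s1 <- cumsum(xv * w); s2 <- cumsum(xv^2 * w)
  mu <- s1[risk_end] / s0[risk_end]
  info <- sum(s2[risk_end] / s0[risk_end] - mu^2)
  se <- if (monotone || info <= 0) Inf else 1 / sqrt(info)
  list(beta = beta, se = se, n = length(xv), n_events = n_events,
       iterations = iter, monotone = monotone,
       converged = !monotone && abs(sum(xv[event_idx] - mu)) < 1e-6)
}

#' Univariate Cox proportional-hazards fit for one gene in one arm
#'
#' Estimates the log hazard ratio per one-unit increase in a gene's
#' expression by Newton-Raphson maximisation of the Cox partial likelihood
#' (Breslow convention for tied event times, started from beta = 0, iterated
#' until the score drops below 1e-8 or 25 iterations). The standard error
#' comes from the observed information at the optimum; the 95% interval and
#' p-value are Wald-based, so significance by "CI excludes 1" and by
#' "p < 0.05" coincide exactly. Monotone-likelihood fits (the covariate
#' perfectly separates the risk ordering) are returned flagged with infinite
#' confidence bounds rather than raising an error.
#'
#' @param cohort survival tibble: `time`, `event` (1 death / 0 censored),
#'   `arm`, plus one numeric column per gene (as from
#'   [simulate_survival()]).
#' @param gene gene column to model.
#' @param arm treatment arm to subset to, or `NULL` for the whole cohort.
#' @param level confidence level (default 0.95).
#' @return one-row tibble of class `cox_fit`: `gene_symbol`, `arm`, `beta`,
#'   `se`, `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `n`, `n_events`,
#'   `converged`, `monotone`.
#' @export
fit_cox_univariate <- function(cohort, gene, arm = NULL, level = 0.95) {
  cohort <- as_tibble(cohort)
  if (!gene %in% names(cohort)) {
    stop_data(sprintf("Gene column `%s` not found in the cohort.", gene))
  }
  if (!is.null(arm)) {
    cohort <- cohort[cohort$arm == arm, ]
    if (nrow(cohort) == 0) stop_data(sprintf("No subjects in arm `%s`.", arm))
  }
  if (sum(cohort$event == 1) == 0) {
    stop_data("No events in this stratum; survival screen cannot proceed.")
  }
  fit <- cox_partial_fit(cohort$time, cohort$event, cohort[[gene]])
  z <- qnorm(1 - (1 - level) / 2)
  wald <- if (is.finite(fit$se)) fit$beta / fit$se else NA_real_
  out <- tibble(
    gene_symbol = gene,
    arm = arm %||% "all",
    beta = fit$beta,
    se = fit$se,
    hazard_ratio = exp(fit$beta),
    ci_low = exp(fit$beta - z * fit$se),
    ci_high = exp(fit$beta + z * fit$se),
    p_value = if (is.na(wald)) NA_real_ else 2 * pnorm(-abs(wald)),
    n = fit$n, n_events = fit$n_events,
    converged = fit$converged, monotone = fit$monotone
  )
  class(out) <- c("cox_fit", class(out))
  out
}

#' Per-gene, per-arm survival screen
#'
#' Fits a univariate Cox model for every gene separately within each
#' treatment arm (arms are modelled separately because baseline risk differs
#' between regimens), flags fits whose Wald interval excludes a hazard ratio
#' of 1, and calls a gene significant when any of its fits in any arm is.
#' For genes fit in both arms a normal z-test on the difference of log hazard
#' ratios, `z = (b1 - b2) / sqrt(se1^2 + se2^2)`, quantifies the
#' between-treatment difference. Failed fits (no events, constant covariate)
#' and monotone-likelihood fits are logged and excluded from significance
#' counting.
#'
#' @param cohort survival tibble (see [fit_cox_univariate()]).
#' @param genes character vector of gene columns to screen.
#' @param alpha significance level (default 0.05).
#' @return object of class `cox_screen`: list with `fits` (per gene x arm
#'   rows plus `significant` flags and per-gene `arm_diff_p`),
#'   `significant_genes`, `failed` (tibble of skipped fits with reasons) and
#'   `alpha`. `tidy()` returns the fit table; `glance()` the significant
#'   count with its exact binomial proportion interval against chance.
#' @export
screen_genes <- function(cohort, genes, alpha = 0.05) {
  cohort <- as_tibble(cohort)
  if (length(genes) == 0) stop_data("`genes` must be non-empty.")
  arms <- sort(unique(cohort$arm))
  grid <- tidyr::expand_grid(gene = genes, arm = arms)
  res <- purrr::pmap(grid, function(gene, arm) {
    tryCatch(fit_cox_univariate(cohort, gene, arm, level = 1 - alpha),
             error = function(e) {
               tibble(gene_symbol = gene, arm = arm,
                      reason = conditionMessage(e))
             })
  })
  ok <- purrr::map_lgl(res, inherits, "cox_fit")
  fits <- bind_rows(res[ok])
  failed <- bind_rows(res[!ok])
  if (nrow(failed) > 0) {
    inform(sprintf("%d fit(s) skipped: %s", nrow(failed),
                   paste(unique(failed$reason), collapse = "; ")))
  }
  if (nrow(fits) > 0) {
    fits <- fits |>
      mutate(significant = !.data$monotone & is.finite(.data$se) &
               (.data$ci_low > 1 | .data$ci_high < 1)) |>
      group_by(.data$gene_symbol) |>
      mutate(arm_diff_p = {
        usable <- is.finite(.data$se)
        if (sum(usable) == 2) {
          zd <- diff(.data$beta[usable]) / sqrt(sum(.data$se[usable]^2))
          2 * pnorm(-abs(zd))
        } else NA_real_
      }) |>
      ungroup()
    sig_genes <- unique(fits$gene_symbol[fits$significant])
  } else {
    sig_genes <- character(0)
  }
  structure(
    list(fits = fits, significant_genes = sort(sig_genes), failed = failed,
         alpha = alpha, n_genes = length(genes)),
    class = "cox_screen"
  )
}

#' @export
print.cox_screen <- function(x, ...) {
  cat(sprintf(
    "<cox_screen> %d genes screened; %d significant in >=1 arm at alpha = %g\n",
    x$n_genes, length(x$significant_genes), x$alpha))
  invisible(x)
}

#' @rdname screen_genes
#' @param x a `cox_screen`.
#' @param ... unused.
#' @export
tidy.cox_screen <- function(x, ...) x$fits

#' @rdname screen_genes
#' @param chance_level chance proportion the interval is compared against
#'   (default 0.05).
#' @export
glance.cox_screen <- function(x, chance_level = 0.05, ...) {
  k <- length(x$significant_genes)
  ci <- proportion_ci_exact(k, x$n_genes, chance = chance_level)
  tibble(
    n_genes = x$n_genes, n_significant = k,
    proportion = k / x$n_genes,
    ci_lower = ci$lower, ci_upper = ci$upper,
    excludes_chance = ci$excludes_chance
  )
}

#' Consistency between a survival fit and the expression direction
#'
#' A hazard-expression association is direction-consistent when higher
#' expression of an up-regulated gene increases the death rate (HR > 1), or
#' higher expression of a down-regulated gene decreases it (HR < 1). The
#' comparison is strict: HR exactly 1 is inconsistent by convention.
#'
#' @param hazard_ratio numeric vector of hazard ratios.
#' @param de_direction integer vector of +1/-1 expression directions.
#' @return logical vector, `TRUE` when consistent.
#' @examples
#' direction_consistency(c(1.451, 0.736, 1.0), c(1, -1, 1))
#' @export
direction_consistency <- function(hazard_ratio, de_direction) {
  stopifnot(all(de_direction %in% c(-1, 1)))
  (de_direction > 0 & hazard_ratio > 1) |
    (de_direction < 0 & hazard_ratio < 1)
}

#' Exact (Clopper-Pearson) binomial confidence interval for a proportion
#'
#' Beta-quantile form of the exact interval: with `k` successes in `n`
#' trials, the lower bound is the `alpha/2` quantile of Beta(k, n - k + 1)
#' (0 when k = 0) and the upper bound the `1 - alpha/2` quantile of
#' Beta(k + 1, n - k) (1 when k = n). Also reports whether the interval
#' excludes a stated chance level.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param level confidence level (default 0.95).
#' @param chance chance proportion to compare against (default 0.05).
#' @return one-row tibble: `lower`, `upper`, `excludes_chance`.
#' @examples
#' proportion_ci_exact(8, 60)   # (0.06, 0.25) at 2 decimals
#' @export
proportion_ci_exact <- function(k, n, level = 0.95, chance = 0.05) {
  if (length(k) != 1 || length(n) != 1 || !is.finite(k) || !is.finite(n) ||
      n < 1 || k < 0 || k > n || k != floor(k) || n != floor(n)) {
    stop_data("`k` and `n` must be integers with 0 <= k <= n and n >= 1.")
  }
  alpha <- 1 - level
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  tibble(lower = lower, upper = upper,
         excludes_chance = chance < lower || chance > upper)
}
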