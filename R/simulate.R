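#' Configuration for the synthetic two-species study generator
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' the design of a small cross-species tumor/normal array study: 9 human
#' tumors against 3 normal B-cell controls, 7 mouse tumors against 3 controls,
#' 2,000 genes per species of which 10% are differentially expressed, and 60
#' planted genes that are deregulated concordantly (same direction) in both
#' species with a 1.5 log2-unit mean shift against a within-group SD of 0.5.
#'
#' @param n_genes_per_species number of genes (and, with a 1:1 map, probesets)
#'   simulated per species.
#' @param n_tumor,n_normal group sizes; either a single count used for both
#'   species or a length-2 vector `c(human, mouse)`.
#' @param frac_de fraction of genes differentially expressed within each
#'   species.
#' @param n_concordant number of planted genes DE in *both* species with a
#'   shared direction; must not exceed `frac_de * n_genes_per_species`.
#' @param effect_log2 mean tumor-vs-normal shift, log2 units, applied with the
#'   gene's planted direction.
#' @param sigma within-group SD on the log2 scale.
#' @param frac_proliferation_overlap fraction of the concordant genes also
#'   planted into the proliferation exclusion gene set (genes a
#'   resting-vs-activated B-cell contrast would also flag).
#' @param survival_beta true log-hazard per one-unit expression increase for
#'   the survival-linked subset of concordant genes (0 disables any link).
#' @param baseline_hazard events per unit time for a subject at expression 0.
#' @param censor_time administrative censoring horizon.
#' @param hub_seed_edges number of high-confidence edges from the planted
#'   network hub to the seed genes.
#' @param background_edge_prob probability of a low-confidence background edge
#'   between any two network nodes.
#' @param extra_probeset_genes number of genes given a second human probeset,
#'   to exercise many-to-many orthology handling (default 0: a 1:1 map).
#' @param seed RNG seed; every generator derives its stream from this plus a
#'   fixed per-operation offset so stages are independently reproducible.
#' @return a validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_genes_per_species = 200, n_concordant = 10, seed = 7)
#' @export
sim_config <- function(n_genes_per_species = 2000,
                       n_tumor = c(9, 7),
                       n_normal = c(3, 3),
                       frac_de = 0.1,
                       n_concordant = 60,
                       effect_log2 = 1.5,
                       sigma = 0.5,
                       frac_proliferation_overlap = 0.13,
                       survival_beta = 0.5,
                       baseline_hazard = 0.1,
                       censor_time = 10,
                       hub_seed_edges = 5,
                       background_edge_prob = 0.02,
                       extra_probeset_genes = 0,
                       seed = 1) {
  cfg <- list(
    n_genes_per_species = n_genes_per_species,
    n_tumor = rep_len(n_tumor, 2), n_normal = rep_len(n_normal, 2),
    frac_de = frac_de, n_concordant = n_concordant,
    effect_log2 = effect_log2, sigma = sigma,
    frac_proliferation_overlap = frac_proliferation_overlap,
    survival_beta = survival_beta, baseline_hazard = baseline_hazard,
    censor_time = censor_time, hub_seed_edges = hub_seed_edges,
    background_edge_prob = background_edge_prob,
    extra_probeset_genes = extra_probeset_genes, seed = seed
  )
  counts <- c("n_genes_per_species", "n_tumor", "n_normal", "hub_seed_edges")
  for (f in counts) {
    v <- cfg[[f]]
    if (any(!is.finite(v)) || any(v != floor(v)) ||
        any(v <= 0 & f != "hub_seed_edges") || any(v < 0)) {
      stop_config(sprintf("sim_config field `%s` must hold positive integers.", f))
    }
  }
  for (f in c("frac_de", "frac_proliferation_overlap", "background_edge_prob")) {
    v <- cfg[[f]]
    if (!is.finite(v) || v < 0 || v > 1) {
      stop_config(sprintf("sim_config field `%s` must lie in [0, 1].", f))
    }
  }
  if (!is.finite(cfg$sigma) || cfg$sigma <= 0) {
    stop_config("sim_config field `sigma` must be > 0.")
  }
  for (f in c("n_concordant", "extra_probeset_genes", "censor_time",
              "baseline_hazard")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop_config(sprintf("sim_config field `%s` must be non-negative.", f))
    }
  }
  if (cfg$n_concordant > cfg$frac_de * cfg$n_genes_per_species) {
    stop_config(paste0(
      "sim_config field `n_concordant` exceeds frac_de * n_genes_per_species; ",
      "cannot plant more concordant genes than DE genes."))
  }
  structure(cfg, class = "sim_config")
}

# Per-operation RNG offsets (kept small so seed + offset stays far below 2^31).
.sim_offsets <- c(expression = 101, survival = 202, network = 303, studies = 404)

sim_gene_symbols <- function(n) sprintf("GENE%04d", seq_len(n))

#' Simulate a matched human/mouse expression study with planted truth
#'
#' Draws log2 expression for both species on a shared gene universe, plants
#' per-species differentially expressed genes (tumor mean shifted by
#' `effect_log2` times a random direction) and a core of concordant genes that
#' are DE with the same direction in both species. Human symbols are
#' upper-case and mouse symbols title-case, as in real annotation, and the
#' orthology map links them probeset-to-probeset.
#'
#' @param config a [sim_config()].
#' @return a list with elements `human` and `mouse` ([expr_matrix] objects),
#'   `orthology` (tibble: `human_probeset`, `gene_symbol`, `mouse_probeset`)
#'   and `truth` (class `sim_truth`: the planted DE/concordant/proliferation/
#'   survival/hub assignments).
#' @examples
#' sim <- simulate_two_species(sim_config(n_genes_per_species = 100,
#'   n_concordant = 5, seed = 1))
#' sim$human
#' @export
simulate_two_species <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  with_seed(config$seed + .sim_offsets[["expression"]], {
    n <- config$n_genes_per_species
    genes <- sim_gene_symbols(n)
    n_de <- round(config$frac_de * n)
    nc <- config$n_concordant
    n_extra <- n_de - nc
    if (nc + 2 * n_extra > n) {
      stop_config("Gene universe too small for disjoint species-specific DE sets.")
    }
    shuffled <- sample(genes)
    concordant <- sort(shuffled[seq_len(nc)])
    extra_h <- sort(shuffled[nc + seq_len(n_extra)])
    extra_m <- sort(shuffled[nc + n_extra + seq_len(n_extra)])
    dir_conc <- setNames(sample(c(-1L, 1L), nc, replace = TRUE), concordant)
    dir_h <- c(dir_conc, setNames(sample(c(-1L, 1L), n_extra, TRUE), extra_h))
    dir_m <- c(dir_conc, setNames(sample(c(-1L, 1L), n_extra, TRUE), extra_m))

    n_prolif_conc <- round(config$frac_proliferation_overlap * nc)
    prolif <- character(0)
    if (n_prolif_conc > 0) prolif <- sort(sample(concordant, n_prolif_conc))
    # pad the exclusion set with non-DE genes, as a real activation signature
    # would contain mostly genes outside the tumor-concordant core
    non_de <- setdiff(genes, c(concordant, extra_h, extra_m))
    prolif <- sort(c(prolif, sample(non_de, min(40, length(non_de)))))

    surv_beta <- setNames(rep(0, nc), concordant)
    if (nc > 0) {
      n_surv <- max(1, round(0.13 * nc))
      surv_beta[sample(concordant, n_surv)] <- config$survival_beta
    }

    make_species <- function(species, dirs, n_tumor, n_normal) {
      sym <- if (species == "human") genes else to_title(genes)
      ps <- paste0(tolower(sym), if (species == "human") "_h_at" else "_m_at")
      extra_idx <- seq_len(config$extra_probeset_genes)
      if (species == "human" && config$extra_probeset_genes > 0) {
        ps <- c(ps, paste0(tolower(sym[extra_idx]), "_h2_at"))
        sym <- c(sym, sym[extra_idx])
      }
      samples <- c(paste0(toupper(substr(species, 1, 1)), "_T", seq_len(n_tumor)),
                   paste0(toupper(substr(species, 1, 1)), "_N", seq_len(n_normal)))
      groups <- setNames(rep(c("tumor", "normal"), c(n_tumor, n_normal)), samples)
      baseline <- runif(length(ps), 4, 12)
      shift <- dirs[symbol_key(sym)]
      shift[is.na(shift)] <- 0
      mu <- outer(baseline, rep(0, length(samples)), "+")
      mu[, groups == "tumor"] <- mu[, groups == "tumor"] +
        shift * config$effect_log2
      vals <- mu + matrix(rnorm(length(mu), 0, config$sigma),
                          nrow = nrow(mu))
      dimnames(vals) <- list(ps, samples)
      list(mat = expr_matrix(vals, species, groups),
           ann = tibble(probeset_id = ps, gene_symbol = sym))
    }

    hum <- make_species("human", dir_h, config$n_tumor[1], config$n_normal[1])
    mou <- make_species("mouse", dir_m, config$n_tumor[2], config$n_normal[2])

    orthology <- inner_join(
      mutate(hum$ann, key = symbol_key(.data$gene_symbol)),
      mutate(mou$ann, key = symbol_key(.data$gene_symbol)),
      by = "key", suffix = c("_h", "_m"), relationship = "many-to-many"
    )
    orthology <- tibble(
      human_probeset = orthology$probeset_id_h,
      gene_symbol = orthology$gene_symbol_h,
      mouse_probeset = orthology$probeset_id_m
    )

    truth <- structure(list(
      genes = genes,
      de_genes_human = sort(c(concordant, extra_h)),
      de_genes_mouse = sort(c(concordant, extra_m)),
      concordant_genes = dir_conc,
      proliferation_genes = prolif,
      survival_genes = surv_beta,
      hub_node = "HUB001"
    ), class = "sim_truth")

    list(human = hum$mat, mouse = mou$mat, orthology = orthology, truth = truth)
  })
}

to_title <- function(x) {
  paste0(toupper(substr(x, 1, 1)), tolower(substr(x, 2, nchar(x))))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf(
    "<sim_truth> %d genes; DE human %d, mouse %d; concordant %d; hub %s\n",
    length(x$genes), length(x$de_genes_human), length(x$de_genes_mouse),
    length(x$concordant_genes), x$hub_node))
  invisible(x)
}

#' Simulate a two-arm survival cohort linked to gene expression
#'
#' Event times are exponential with subject hazard
#' `baseline_hazard * exp(sum(beta_g * x_g))`, where the per-gene log-hazard
#' coefficients come from the planted truth (genes absent from the truth's
#' survival map contribute 0). Subjects still alive at `censor_time` are
#' administratively censored. Two treatment arms, labelled CHOP and R-CHOP,
#' are assigned at random; the expression-hazard link is identical in both.
#'
#' @param genes character vector of gene symbols to carry as expression
#'   columns (must be non-empty).
#' @param truth a `sim_truth` from [simulate_two_species()], or `NULL` for an
#'   all-null cohort.
#' @param n_subjects cohort size, at least 20 (default 400).
#' @param config a [sim_config()] supplying `baseline_hazard`, `censor_time`
#'   and the seed.
#' @return tibble with `subject_id`, `time`, `event` (1 death, 0 censored),
#'   `arm`, and one numeric column per gene.
#' @export
simulate_survival <- function(genes, truth = NULL, n_subjects = 400,
                              config = sim_config()) {
  if (length(genes) == 0) stop_data("`genes` must name at least one gene.")
  if (n_subjects < 20) stop_config("`n_subjects` must be at least 20.")
  betas <- setNames(rep(0, length(genes)), genes)
  if (!is.null(truth)) {
    hit <- intersect(names(truth$survival_genes), genes)
    betas[hit] <- truth$survival_genes[hit]
  }
  with_seed(config$seed + .sim_offsets[["survival"]], {
    x <- matrix(rnorm(n_subjects * length(genes)), n_subjects,
                dimnames = list(NULL, genes))
    hazard <- config$baseline_hazard * exp(as.vector(x %*% betas))
    t_event <- rexp(n_subjects, rate = hazard)
    time <- pmin(t_event, config$censor_time)
    event <- as.integer(t_event <= config$censor_time)
    arm <- sample(rep_len(c("CHOP", "R-CHOP"), n_subjects))
    out <- tibble(
      subject_id = sprintf("S%04d", seq_len(n_subjects)),
      time = time, event = event, arm = arm
    )
    dplyr::bind_cols(out, as_tibble(x))
  })
}

#' Simulate a weighted interaction network with a planted hub
#'
#' Builds an undirected confidence-weighted gene graph in which a planted hub
#' node is tied to `hub_seed_edges` of the seed genes by high-confidence edges
#' (confidence at least 0.9) on top of sparse low-confidence background edges
#' (confidence at most 0.4), mimicking the topology where most seeds share one
#' high-confidence neighborhood around an undiscovered regulator.
#'
#' @param truth a `sim_truth` (supplies the hub symbol and gene universe).
#' @param seed_genes non-empty character vector of seed gene symbols.
#' @param config a [sim_config()].
#' @return tibble edge list with columns `node_a`, `node_b`, `confidence`.
#' @export
simulate_network <- function(truth, seed_genes, config = sim_config()) {
  if (length(seed_genes) == 0) stop_data("`seed_genes` must be non-empty.")
  with_seed(config$seed + .sim_offsets[["network"]], {
    pool <- setdiff(truth$genes, seed_genes)
    background_nodes <- sample(pool, min(45, length(pool)))
    nodes <- unique(c(seed_genes, truth$hub_node, background_nodes))
    k <- min(config$hub_seed_edges, length(seed_genes))
    hub_edges <- tibble(
      node_a = truth$hub_node,
      node_b = seed_genes[seq_len(k)],
      confidence = runif(k, 0.9, 0.99)
    )
    pairs <- utils::combn(sort(nodes), 2)
    take <- runif(ncol(pairs)) < config$background_edge_prob
    bg <- tibble(
      node_a = pairs[1, take], node_b = pairs[2, take],
      confidence = runif(sum(take), 0.05, 0.4)
    )
    edges <- bind_rows(hub_edges, bg)
    # every seed must be a node of the graph: give stranded seeds one
    # low-confidence background tie
    stranded <- setdiff(seed_genes, c(edges$node_a, edges$node_b))
    if (length(stranded) > 0) {
      partners <- sample(setdiff(nodes, stranded), length(stranded),
                         replace = length(nodes) - length(stranded) == 1)
      edges <- bind_rows(edges, tibble(
        node_a = stranded, node_b = partners,
        confidence = runif(length(stranded), 0.05, 0.4)))
    }
    # drop background duplicates of hub edges (keep the high-confidence one)
    key <- paste(pmin(edges$node_a, edges$node_b),
                 pmax(edges$node_a, edges$node_b))
    edges[!duplicated(key), ]
  })
}

#' Simulate external differential-expression study summaries
#'
#' Each of `n_studies` independent studies reports each planted concordant
#' gene with probability `detect_prob`, at an over-threshold signed fold
#' change (|FC| >= 2) and p <= 0.01 in the planted direction; a sample of
#' non-concordant genes is reported with sub-threshold statistics so the vote
#' counter has something to reject.
#'
#' @param truth a `sim_truth`.
#' @param n_studies number of studies (>= 1).
#' @param detect_prob per-study detection probability for a concordant gene.
#' @param config a [sim_config()].
#' @return tibble with columns `study_id`, `category`, `gene_symbol`,
#'   `fold_change`, `p_value`.
#' @export
simulate_study_summaries <- function(truth, n_studies = 7, detect_prob = 0.5,
                                     config = sim_config()) {
  if (n_studies < 1) stop_config("`n_studies` must be at least 1.")
  if (detect_prob < 0 || detect_prob > 1) {
    stop_config("`detect_prob` must lie in [0, 1].")
  }
  categories <- rep_len(c("tumor vs normal", "high vs low grade",
                          "subtype contrast", "transformation"), n_studies)
  conc <- names(truth$concordant_genes)
  with_seed(config$seed + .sim_offsets[["studies"]], {
    purrr::map(seq_len(n_studies), function(s) {
      hit <- conc[runif(length(conc)) < detect_prob]
      det <- tibble(
        study_id = sprintf("study%02d", s),
        category = categories[s],
        gene_symbol = hit,
        fold_change = unname(truth$concordant_genes[hit]) * runif(length(hit), 2.1, 8),
        p_value = runif(length(hit), 1e-6, 0.0099)
      )
      others <- sample(setdiff(truth$genes, conc), 50)
      bg <- tibble(
        study_id = sprintf("study%02d", s),
        category = categories[s],
        gene_symbol = others,
        fold_change = sample(c(-1, 1), 50, TRUE) * runif(50, 1, 1.9),
        p_value = runif(50, 0.02, 1)
      )
      bind_rows(det, bg)
    }) |> bind_rows()
  })
}
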