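#' Construct an expression matrix with group labels
#'
#' Container for log2-scale probeset-by-sample intensities for one species,
#' with a tumor/normal group label per sample. Values are expected on the
#' log2 scale (the convention of RMA-normalised array data), so a one-unit
#' difference in group means is a two-fold linear change.
#'
#' @param values numeric matrix, probesets in rows (rownames = probeset ids),
#'   samples in columns (colnames = sample ids). No missing or non-finite
#'   entries are allowed.
#' @param species `"human"` or `"mouse"`.
#' @param groups named character vector mapping every sample id to `"tumor"`
#'   or `"normal"`; each group needs at least 2 samples.
#' @return an object of class `expr_matrix`.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("ps", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, "human",
#'   c(s1 = "tumor", s2 = "tumor", s3 = "normal", s4 = "normal"))
#' em
#' @export
expr_matrix <- function(values, species = c("human", "mouse"), groups) {
  species <- match.arg(species)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("`values` must be a numeric matrix (probesets x samples).")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop_data("`values` needs unique probeset ids as rownames.")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    stop_data("`values` needs unique sample ids as colnames.")
  }
  if (any(!is.finite(values))) {
    stop_data("Expression values must be finite with no missing entries.")
  }
  groups <- groups[colnames(values)]
  if (anyNA(groups) || !all(groups %in% c("tumor", "normal"))) {
    stop_data("`groups` must label every sample as 'tumor' or 'normal'.")
  }
  tab <- table(factor(groups, levels = c("tumor", "normal")))
  if (any(tab < 2)) {
    stop_data("Each of the tumor and normal groups needs at least 2 samples.")
  }
  structure(
    list(values = values, species = species,
         groups = setNames(as.character(groups), colnames(values))),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  tab <- table(x$groups)
  cat(sprintf(
    "<expr_matrix> %s: %d probesets x %d samples (%s tumor, %s normal)\n",
    x$species, nrow(x$values), ncol(x$values),
    tab[["tumor"]], tab[["normal"]]
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Long-format view of an expression matrix
#'
#' @param x an `expr_matrix`.
#' @param ... unused.
#' @return a tibble with columns `probeset_id`, `sample_id`, `group`,
#'   `log2_value`.
#' @export
as_tibble.expr_matrix <- function(x, ...) {
  tibble(
    probeset_id = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(unname(x$groups), each = nrow(x$values)),
    log2_value = as.vector(x$values)
  )
}
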