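#' Preprocessing configuration
#'
#' Bundles the tunable preprocessing constants: the pseudo-count added
#' before log transformation, the logarithm base, the per-gene missing
#' fraction tolerated, and the clamping bounds applied after the second
#' scaling of the denoised data.
#'
#' @param pseudo_count Positive constant added before taking logs
#'   (default 1, so zero maps to zero).
#' @param log_base Logarithm base, greater than 1 (default 2).
#' @param max_missing_fraction Per-gene fraction of missing cells tolerated
#'   by [filter_missing_fraction()] (default 0.10).
#' @param clamp_bounds Length-2 numeric, lower < upper (default `c(-2, 2)`).
#' @param require_complete If `TRUE` downstream stages use only genes
#'   without any missing cell.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(pseudo_count = 1, log_base = 2,
                              max_missing_fraction = 0.10,
                              clamp_bounds = c(-2, 2),
                              require_complete = FALSE) {
  stopifnot(pseudo_count > 0, log_base > 1,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            length(clamp_bounds) == 2L, clamp_bounds[1] < clamp_bounds[2])
  structure(list(pseudo_count = pseudo_count, log_base = log_base,
                 max_missing_fraction = max_missing_fraction,
                 clamp_bounds = clamp_bounds,
                 require_complete = require_complete),
            class = "preprocess_config")
}

#' Keep genes observed in both omics layers
#'
#' Retains exactly the genes with at least one non-missing expression value
#' and at least one non-missing methylation value; everything measured in a
#' single layer cannot inform the methylation/expression interplay and is
#' dropped. Gene order is preserved.
#'
#' @param m An `omics_matrix` containing at least one expression and one
#'   methylation variable.
#' @return The filtered `omics_matrix` (possibly with zero genes).
#' @export
filter_min_per_class <- function(m) {
  is_expr <- m$variables$omic_type == "expression"
  if (!any(is_expr) || all(is_expr))
    stop("matrix must contain both expression and methylation variables")
  obs <- !is.na(m$values)
  keep <- rowSums(obs[, is_expr, drop = FALSE]) >= 1L &
          rowSums(obs[, !is_expr, drop = FALSE]) >= 1L
  m[keep, ]
}

#' Drop genes exceeding a missing-cell fraction
#'
#' The fraction is computed per gene over all variables; `max_frac = 0`
#' yields the complete-case gene set.
#'
#' @param m An `omics_matrix`.
#' @param max_frac Maximum tolerated fraction of missing cells in `[0, 1]`.
#' @return The filtered `omics_matrix`, gene order preserved.
#' @export
filter_missing_fraction <- function(m, max_frac = 0.10) {
  stopifnot(max_frac >= 0, max_frac <= 1)
  frac <- rowMeans(is.na(m$values))
  m[frac <= max_frac, ]
}

#' Log-transform with a pseudo-count
#'
#' Applies `x -> log(pseudo_count + x) / log(log_base)` to every
#' non-missing cell, leaving missing cells missing. With the defaults this
#' is `log2(1 + x)`, which maps zero to zero and compresses extreme values
#' while preserving within-column ranks.
#'
#' @param m An `omics_matrix` with non-negative values.
#' @param cfg A [preprocess_config()].
#' @return The transformed `omics_matrix`.
#' @export
log_transform <- function(m, cfg = preprocess_config()) {
  neg <- which(m$values < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop(sprintf("negative value %g at gene '%s', variable '%s'; log transform requires non-negative input",
                 m$values[neg[1, , drop = FALSE]],
                 rownames(m$values)[neg[1, 1]],
                 colnames(m$values)[neg[1, 2]]))
  }
  m$values <- log(cfg$pseudo_count + m$values, base = cfg$log_base)
  m
}

#' Center and scale each variable
#'
#' Column means and sample standard deviations (denominator n - 1) are
#' computed on non-missing cells only; missing cells stay missing.
#'
#' @param m An `omics_matrix`; every column needs at least two non-missing
#'   values and non-zero variance.
#' @return A list with `matrix` (the standardised `omics_matrix`) and
#'   `scaling` (data frame of per-variable `mean` and `sd`, usable to undo
#'   or report the transformation).
#' @export
center_scale <- function(m) {
  mu <- colMeans(m$values, na.rm = TRUE)
  s  <- apply(m$values, 2L, sd, na.rm = TRUE)
  n_obs <- colSums(!is.na(m$values))
  if (any(n_obs < 2L))
    stop("column(s) with fewer than 2 non-missing values: ",
         paste(colnames(m$values)[n_obs < 2L], collapse = ", "))
  degenerate <- !is.finite(s) | s <= 0
  if (any(degenerate))
    stop("zero-variance column(s): ",
         paste(colnames(m$values)[degenerate], collapse = ", "))
  m$values <- sweep(sweep(m$values, 2L, mu, "-"), 2L, s, "/")
  list(matrix = m,
       scaling = data.frame(name = colnames(m$values), mean = mu, sd = s,
                            row.names = NULL))
}

#' Clamp values into a fixed interval
#'
#' Values above the upper bound are set to it, values below the lower
#' bound likewise; interior values (and missing cells) are untouched. The
#' operation is idempotent.
#'
#' @param m An `omics_matrix` or a numeric matrix.
#' @param bounds Length-2 numeric `c(lower, upper)`.
#' @return Same type as `m`.
#' @export
clamp <- function(m, bounds = c(-2, 2)) {
  stopifnot(length(bounds) == 2L, bounds[1] < bounds[2])
  if (inherits(m, "omics_matrix")) {
    m$values <- pmin(pmax(m$values, bounds[1]), bounds[2])
    m
  } else {
    pmin(pmax(m, bounds[1]), bounds[2])
  }
}

#' Run the full preprocessing stage
#'
#' Applies, in order: the both-layers presence filter, the per-gene
#' missing-fraction filter, optionally the complete-case filter, and the
#' log transform. Gene counts after every stage are recorded, mirroring
#' how gene-centric studies report their successive filters.
#'
#' @param m An `omics_matrix` of raw (non-negative) values.
#' @param cfg A [preprocess_config()].
#' @param log If `FALSE` the data are assumed already on a log-like scale
#'   and the transform is skipped.
#' @return A list with `matrix` (filtered, transformed), `counts` (named
#'   integer vector of gene counts after each stage) and `config`.
#' @export
preprocess <- function(m, cfg = preprocess_config(), log = TRUE) {
  counts <- c(input = nrow(m$values))
  m <- filter_min_per_class(m)
  counts["min_per_class"] <- nrow(m$values)
  m <- filter_missing_fraction(m, cfg$max_missing_fraction)
  counts["missing_fraction"] <- nrow(m$values)
  if (isTRUE(cfg$require_complete)) {
    m <- filter_missing_fraction(m, 0)
    counts["complete_cases"] <- nrow(m$values)
  }
  if (log) m <- log_transform(m, cfg)
  list(matrix = m, counts = counts, config = cfg)
}
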