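#' Select master-driver candidates by extreme omics profiles
#'
#' Returns the genes whose standardised profile is extreme in *every*
#' variable of both layers: all methylation values strictly above
#' `meth_min` and all expression values strictly below `expr_max`. On
#' centered/scaled (optionally denoised and re-scaled) data with the
#' defaults this selects genes highly methylated and lowly expressed
#' across all populations — the footprint of a shared
#' methylation-expression interplay.
#'
#' Thresholds are applied before any clamping; with the default clamp
#' bounds (+/-2) and thresholds (+/-1) the two orders are observationally
#' equivalent.
#'
#' @param m An `omics_matrix` (or `cim_result`) of transformed values,
#'   complete (the rule quantifies over all values, so missing cells are
#'   an error).
#' @param meth_min Lower threshold every methylation value must exceed
#'   (default 1).
#' @param expr_max Upper threshold every expression value must stay below
#'   (default -1).
#' @param provenance Label recorded with the set, conventionally
#'   `"non_denoised"` or `"denoised"`.
#' @return A list of class `gene_set` with `ids` (character vector in gene
#'   order), `provenance` and `thresholds`.
#' @export
select_extreme <- function(m, meth_min = 1, expr_max = -1,
                           provenance = c("non_denoised", "denoised")) {
  provenance <- match.arg(provenance)
  if (inherits(m, "cim_result")) {
    values <- m$matrix
    variables <- m$variables
  } else {
    values <- m$values
    variables <- m$variables
  }
  if (anyNA(values))
    stop("extreme-profile selection requires complete data (the rule quantifies over all values)")
  is_expr <- variables$omic_type == "expression"
  if (!any(is_expr) || all(is_expr))
    stop("matrix must contain both expression and methylation variables")
  meth_ok <- rowSums(values[, !is_expr, drop = FALSE] > meth_min) == sum(!is_expr)
  expr_ok <- rowSums(values[, is_expr, drop = FALSE] < expr_max) == sum(is_expr)
  structure(list(ids = rownames(values)[meth_ok & expr_ok],
                 provenance = provenance,
                 thresholds = c(meth_min = meth_min, expr_max = expr_max)),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set (%s): %d genes (methylation > %g, expression < %g)\n",
              x$provenance, length(x$ids),
              x$thresholds["meth_min"], x$thresholds["expr_max"]))
  invisible(x)
}

#' Compare two candidate gene sets
#'
#' Partition of the union of two gene sets into the genes exclusive to
#' each and the shared ones, as summarised by a two-set Venn diagram.
#'
#' @param a,b `gene_set` objects (or bare character vectors).
#' @return A list with `only_a`, `shared`, `only_b` (character vectors)
#'   and `counts` (named integer vector of their sizes).
#' @export
compare_gene_sets <- function(a, b) {
  ids_a <- if (inherits(a, "gene_set")) a$ids else as.character(a)
  ids_b <- if (inherits(b, "gene_set")) b$ids else as.character(b)
  only_a <- setdiff(ids_a, ids_b)
  shared <- intersect(ids_a, ids_b)
  only_b <- setdiff(ids_b, ids_a)
  list(only_a = only_a, shared = shared, only_b = only_b,
       counts = c(only_a = length(only_a), shared = length(shared),
                  only_b = length(only_b)))
}

#' MA comparison of denoised versus non-denoised data
#'
#' For every cell, computes the Bland-Altman coordinates on the log2
#' scale: `M = denoised - raw` (the log fold change introduced by
#' denoising) and `A = (denoised + raw) / 2` (the mean level), flagging
#' cells with `|M|` above the cutoff. A per-variable summary of flag
#' counts quantifies where denoising changed the data most.
#'
#' @param raw Numeric matrix (or `omics_matrix`) of non-denoised values on
#'   a log2-like scale.
#' @param den Matrix of the same shape, same row and column names, after
#'   denoising.
#' @param cutoff Absolute log2 fold-change threshold (default 1).
#' @return A list with `records` (data frame: `gene`, `variable`, `A`,
#'   `M`, `flagged`) and `by_variable` (data frame: `variable`,
#'   `n_flagged`, `fraction_flagged`).
#' @export
ma_compare <- function(raw, den, cutoff = 1) {
  x <- if (inherits(raw, "omics_matrix")) raw$values else raw
  y <- if (inherits(den, "omics_matrix")) den$values else den
  if (!identical(dim(x), dim(y)) || !identical(dimnames(x), dimnames(y)))
    stop("raw and denoised matrices must have identical shapes and names")
  M <- y - x
  A <- (y + x) / 2
  flagged <- abs(M) > cutoff
  records <- data.frame(
    gene = rep(rownames(x), times = ncol(x)),
    variable = rep(colnames(x), each = nrow(x)),
    A = as.vector(A), M = as.vector(M),
    flagged = as.vector(flagged),
    row.names = NULL)
  by_variable <- data.frame(
    variable = colnames(x),
    n_flagged = colSums(flagged),
    fraction_flagged = colMeans(flagged),
    row.names = NULL)
  list(records = records, by_variable = by_variable, cutoff = cutoff)
}
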