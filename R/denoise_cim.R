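#' Clustered-image-map options
#'
#' @param denoise Replace each block by its projection onto its variate
#'   span (components x loadings), discarding the residuals.
#' @param scale2 Center and scale each column a second time, after
#'   denoising.
#' @param cutoff Clamp values into `clamp_bounds` after the optional
#'   second scaling.
#' @param k_groups Number of gene groups obtained by cutting the row
#'   dendrogram (default 4).
#' @param clamp_bounds Bounds used when `cutoff` is `TRUE`
#'   (default `c(-2, 2)`).
#' @return A list of class `cim_options`. Distance is fixed to Euclidean
#'   and linkage to Ward.
#' @export
cim_options <- function(denoise = TRUE, scale2 = TRUE, cutoff = TRUE,
                        k_groups = 4L, clamp_bounds = c(-2, 2)) {
  stopifnot(k_groups >= 1L, length(clamp_bounds) == 2L,
            clamp_bounds[1] < clamp_bounds[2])
  structure(list(denoise = denoise, scale2 = scale2, cutoff = cutoff,
                 k_groups = as.integer(k_groups),
                 clamp_bounds = clamp_bounds,
                 distance = "euclidean", linkage = "ward"),
            class = "cim_options")
}

#' Low-rank denoising of fitted blocks
#'
#' Splits each block exactly into a denoised part plus residuals:
#' `X_j = Xhat_j + R_j`, where `Xhat_j = T_j (T_j' T_j)^{-1} T_j' X_j` is
#' the orthogonal projection of the block onto the span of its variates.
#' Under own-variate deflation the variates are orthogonal, so this equals
#' the sum over components of `t_j p_j'` with regression loadings
#' `p_j = X_j' t_j / (t_j' t_j)`. The denoised part keeps the variability
#' shared across blocks that the components capture; the residuals hold
#' variability specific to single genes or variables (noise).
#'
#' @param bs The complete, centered and scaled `block_set` the model was
#'   fitted on.
#' @param model A `block_pls_model` from [fit_block_pls()].
#' @return A list with `denoised` and `residuals`, both `block_set`s with
#'   the same shapes as `bs`; their values sum exactly to `bs`.
#' @export
denoise_blocks <- function(bs, model) {
  stopifnot(identical(names(bs), model$block_names))
  denoised <- bs
  residuals <- bs
  for (j in seq_along(bs)) {
    X <- bs[[j]]$values
    T_j <- model$variates[[j]]
    gram <- crossprod(T_j)
    if (rcond(gram) < 1e-12)
      stop("rank-deficient variate matrix for block '", names(bs)[j], "'")
    Xhat <- T_j %*% solve(gram, crossprod(T_j, X))
    dimnames(Xhat) <- dimnames(X)
    denoised[[j]]$values <- Xhat
    residuals[[j]]$values <- X - Xhat
  }
  list(denoised = denoised, residuals = residuals)
}

scale_matrix_columns <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2L, sd)
  if (any(s <= 0 | !is.finite(s)))
    stop("zero-variance column(s) during second scaling: ",
         paste(colnames(x)[s <= 0 | !is.finite(s)], collapse = ", "))
  sweep(sweep(x, 2L, mu, "-"), 2L, s, "/")
}

relabel_first_appearance <- function(labels) {
  first <- unique(labels)
  out <- match(labels, first)
  names(out) <- names(labels)
  out
}

#' Build a denoised clustered image map
#'
#' The heart of the denoising/heatmap method: applies, in fixed order, the
#' optional transforms denoise, second center/scale, and clamp; then
#' concatenates the blocks column-wise, computes Euclidean distances
#' between genes and between variables, builds both dendrograms by Ward
#' agglomeration (`ward.D2` on Euclidean distances), and cuts the gene
#' dendrogram into `k_groups` clusters, labelled by order of first gene
#' appearance.
#'
#' @param bs A complete, centered and scaled `block_set`.
#' @param model A `block_pls_model` fitted on `bs` (used when
#'   `opt$denoise` is `TRUE`).
#' @param opt A [cim_options()].
#' @return A list of class `cim_result` with `matrix` (the transformed
#'   genes x variables matrix), `variables` (metadata of the concatenated
#'   columns), `row_tree`/`col_tree` (`hclust` objects), `row_order`/
#'   `col_order` (dendrogram permutations) and `clusters` (named integer
#'   vector, gene -> group in `1:k_groups`).
#' @export
build_cim <- function(bs, model = NULL, opt = cim_options()) {
  stopifnot(inherits(bs, "block_set"))
  parent <- concat_blocks(bs)
  if (anyNA(parent$values))
    stop("clustered image maps require complete data; filter to complete cases first")
  if (opt$k_groups > nrow(parent$values))
    stop("k_groups exceeds the number of genes")

  work <- bs
  if (isTRUE(opt$denoise)) {
    if (is.null(model))
      stop("denoise = TRUE requires a fitted block_pls_model")
    work <- denoise_blocks(work, model)$denoised
  }
  x <- concat_blocks(work)$values
  if (isTRUE(opt$scale2)) x <- scale_matrix_columns(x)
  if (isTRUE(opt$cutoff)) x <- clamp(x, opt$clamp_bounds)

  row_tree <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  col_tree <- hclust(dist(t(x), method = "euclidean"), method = "ward.D2")
  clusters <- relabel_first_appearance(cutree(row_tree, k = opt$k_groups))

  structure(list(matrix = x, variables = parent$variables,
                 row_tree = row_tree, col_tree = col_tree,
                 row_order = row_tree$order, col_order = col_tree$order,
                 clusters = clusters, options = opt),
            class = "cim_result")
}

#' @export
print.cim_result <- function(x, ...) {
  cat(sprintf("cim_result: %d genes x %d variables, %d gene groups (denoise=%s, scale2=%s, cutoff=%s)\n",
              nrow(x$matrix), ncol(x$matrix), max(x$clusters),
              x$options$denoise, x$options$scale2, x$options$cutoff))
  print(table(group = x$clusters))
  invisible(x)
}

#' Average omics profile of each gene group
#'
#' For each gene group of a clustered image map and each variable, the
#' mean of the transformed values over the group's genes; the per-group
#' gene counts are attached.
#'
#' @param res A `cim_result`.
#' @return A data frame with one row per group x variable combination:
#'   `group`, `size`, `variable`, `mean`.
#' @export
cluster_profiles <- function(res) {
  groups <- sort(unique(res$clusters))
  out <- do.call(rbind, lapply(groups, function(g) {
    rows <- res$clusters == g
    data.frame(group = g, size = sum(rows),
               variable = colnames(res$matrix),
               mean = colMeans(res$matrix[rows, , drop = FALSE]),
               row.names = NULL)
  }))
  out
}

#' Plot a clustered image map as a heatmap with dendrograms
#'
#' Renders the transformed matrix with the precomputed Ward/Euclidean
#' dendrograms on both axes, on a blue-to-red scale fixed to the clamp
#' bounds. Requires the `pheatmap` package.
#'
#' @param res A `cim_result`.
#' @param filename Optional output file (PNG/PDF by extension).
#' @param ... Passed on to [pheatmap::pheatmap()].
#' @return The `pheatmap` object, invisibly.
#' @export
plot_cim <- function(res, filename = NA, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE))
    stop("plot_cim requires the 'pheatmap' package")
  b <- res$options$clamp_bounds
  breaks <- seq(b[1], b[2], length.out = 101)
  colors <- grDevices::colorRampPalette(c("blue", "white", "red"))(100)
  ann <- data.frame(group = factor(res$clusters),
                    row.names = names(res$clusters))
  p <- pheatmap::pheatmap(res$matrix,
                          cluster_rows = res$row_tree,
                          cluster_cols = res$col_tree,
                          color = colors, breaks = breaks,
                          annotation_row = ann,
                          show_rownames = nrow(res$matrix) <= 60,
                          filename = filename, silent = !is.na(filename),
                          ...)
  invisible(p)
}
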