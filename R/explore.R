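#' Pairwise Spearman correlation matrix
#'
#' Computes rank (Spearman) correlations between every pair of variables
#' using pairwise-complete observations and average ranks for ties — the
#' only option compatible with matrices that retain genes carrying some
#' missing cells. The returned ordering arranges correlated variables
#' contiguously via the angular order of the eigenvectors (AOE).
#'
#' @param m An `omics_matrix`.
#' @param min_pairs Minimum number of pairwise-complete genes required for
#'   every variable pair (default 3).
#' @return A list of class `correlation_result` with elements `corr`
#'   (p x p symmetric matrix, unit diagonal), `n_pairs` (integer matrix of
#'   pairwise non-missing counts) and `order` (AOE permutation of
#'   `1:p`).
#' @export
spearman_matrix <- function(m, min_pairs = 3L) {
  x <- m$values
  obs <- !is.na(x)
  n_pairs <- crossprod(obs)
  storage.mode(n_pairs) <- "integer"
  too_few <- which(n_pairs < min_pairs & upper.tri(n_pairs), arr.ind = TRUE)
  if (nrow(too_few)) {
    stop(sprintf("variable pair ('%s', '%s') has only %d pairwise-complete genes (< %d)",
                 colnames(x)[too_few[1, 1]], colnames(x)[too_few[1, 2]],
                 n_pairs[too_few[1, , drop = FALSE]], min_pairs))
  }
  corr <- cor(x, method = "spearman", use = "pairwise.complete.obs")
  diag(corr) <- 1
  res <- structure(list(corr = corr, n_pairs = n_pairs,
                        order = seq_len(ncol(x))),
                   class = "correlation_result")
  res$order <- aoe_order(res)
  res
}

#' Angular order of the eigenvectors (AOE)
#'
#' Orders variables by their angle in the plane spanned by the two leading
#' eigenvectors of the correlation matrix, so that mutually correlated
#' groups of variables occupy contiguous positions. Each variable i gets
#' the angle `atan2(e2[i], e1[i])` mapped into `[0, 2*pi)`; variables are
#' sorted by ascending angle, ties broken by original index, and the order
#' is anchored at the smallest angle.
#'
#' @param c A `correlation_result` (or a bare correlation matrix).
#' @return An integer permutation of the variable indices.
#' @export
aoe_order <- function(c) {
  corr <- if (inherits(c, "correlation_result")) c$corr else c
  p <- ncol(corr)
  if (p < 2L) return(seq_len(max(p, 0L)))
  ## fully uncorrelated variables: the eigenbasis is arbitrary, keep the
  ## input order
  if (all(abs(corr[upper.tri(corr)]) < 1e-12)) return(seq_len(p))
  e <- eigen(corr, symmetric = TRUE)
  e1 <- e$vectors[, 1L]
  e2 <- e$vectors[, 2L]
  alpha <- atan2(e2, e1) %% (2 * pi)
  order(alpha, seq_len(p))
}

#' NIPALS principal component analysis tolerant of missing values
#'
#' Estimates principal components by the iterative NIPALS algorithm, where
#' every inner regression sums only over non-missing cells. On complete
#' data the result coincides with SVD-based PCA up to component signs.
#' Signs are fixed so the largest-magnitude loading of each component is
#' positive (ties broken by the lowest index).
#'
#' @param m An `omics_matrix`, already centered and scaled.
#' @param H Number of components, at most `min(n, p)`.
#' @param tol Convergence tolerance on the relative change of the score
#'   vector between successive iterations (default 1e-6).
#' @param max_iter Maximum NIPALS iterations per component (default 500).
#' @return A list of class `pca_model` with `loadings` (p x H, unit-norm
#'   columns), `scores` (n x H), `explained_variance_fraction` (length H)
#'   and `iterations` (length H).
#' @export
pca_nipals <- function(m, H = 2L, tol = 1e-6, max_iter = 500L) {
  X <- if (inherits(m, "omics_matrix")) m$values else m
  n <- nrow(X); p <- ncol(X)
  stopifnot(H >= 1L, H <= min(n, p))
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0          # zero stands in for "skip" in the masked sums below
  total_ss <- sum(X0^2)

  loadings <- matrix(0, p, H, dimnames = list(colnames(X), NULL))
  scores <- matrix(0, n, H, dimnames = list(rownames(X), NULL))
  evf <- numeric(H)
  iters <- integer(H)
  Xh <- X0

  for (h in seq_len(H)) {
    ss_before <- sum(Xh^2)
    j0 <- which.max(colSums(Xh^2))
    t_vec <- Xh[, j0]
    if (all(t_vec == 0)) stop("degenerate component ", h, ": residual matrix is zero")
    for (it in seq_len(max_iter)) {
      # p_j = sum_i t_i x_ij / sum_i t_i^2, sums over observed cells
      denom_p <- crossprod(obs, t_vec^2)
      p_vec <- crossprod(Xh, t_vec) / pmax(denom_p, .Machine$double.eps)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      denom_t <- obs %*% p_vec^2
      t_new <- (Xh %*% p_vec) / pmax(denom_t, .Machine$double.eps)
      delta <- sqrt(sum((t_new - t_vec)^2)) / sqrt(sum(t_new^2))
      t_vec <- as.numeric(t_new)
      if (delta < tol) break
    }
    if (delta >= tol)
      stop(sprintf("NIPALS did not converge for component %d after %d iterations (achieved %.3g, tol %.3g)",
                   h, max_iter, delta, tol))
    iters[h] <- it
    p_vec <- as.numeric(p_vec)
    k <- which.max(abs(p_vec))
    if (p_vec[k] < 0) { p_vec <- -p_vec; t_vec <- -t_vec }
    loadings[, h] <- p_vec
    scores[, h] <- t_vec
    Xh <- Xh - obs * tcrossprod(t_vec, p_vec)
    evf[h] <- (ss_before - sum(Xh^2)) / total_ss
  }
  structure(list(loadings = loadings, scores = scores,
                 explained_variance_fraction = evf, iterations = iters),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d components over %d variables\n",
              ncol(x$loadings), nrow(x$loadings)))
  cat("explained variance fraction:",
      paste(sprintf("%.3f", x$explained_variance_fraction), collapse = ", "),
      "\n")
  invisible(x)
}
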