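#' Multi-block PLS configuration
#'
#' @param n_components Number of latent components per block (default 2).
#' @param scheme Inner-weighting scheme applied to covariances between
#'   block variates: `"horst"` (identity, the default), `"centroid"`
#'   (sign) or `"factorial"` (covariance).
#' @param tol Convergence tolerance on the largest sup-norm change of any
#'   block loading between inner iterations (default 1e-6).
#' @param max_iter Maximum inner iterations per component (default 100).
#' @param mode `"regression"` (default) or `"canonical"`. Both deflate
#'   every block on its own variate; the distinction is kept for interface
#'   compatibility and reporting.
#' @return A list of class `block_pls_config`.
#' @export
block_pls_config <- function(n_components = 2L,
                             scheme = c("horst", "centroid", "factorial"),
                             tol = 1e-6, max_iter = 100L,
                             mode = c("regression", "canonical")) {
  scheme <- match.arg(scheme)
  mode <- match.arg(mode)
  stopifnot(n_components >= 1L, tol > 0, max_iter >= 1L)
  structure(list(n_components = as.integer(n_components), scheme = scheme,
                 tol = tol, max_iter = as.integer(max_iter), mode = mode),
            class = "block_pls_config")
}

scheme_weight <- function(scheme, covariance) {
  switch(scheme,
         horst = 1,
         centroid = sign(covariance),
         factorial = covariance)
}

scheme_g <- function(scheme, covariance) {
  switch(scheme,
         horst = covariance,
         centroid = abs(covariance),
         factorial = covariance^2)
}

first_right_singular <- function(X) {
  v <- svd(X, nu = 0L, nv = 1L)$v[, 1L]
  v / sqrt(sum(v^2))
}

fix_sign <- function(a, t) {
  k <- which.max(abs(a))            # which.max takes the lowest index on ties
  if (a[k] < 0) list(a = -a, t = -t) else list(a = a, t = t)
}

#' Fit a design-matrix-weighted multi-block PLS
#'
#' Extracts, for each of `H` components, one unit-norm loading vector
#' `a_j` and one variate `t_j = X_j a_j` per block, chosen to maximise the
#' design-weighted sum of covariances `sum_{j<k} c_jk g(cov(t_j, t_k))`
#' (with `g` set by the scheme). The inner loop is a Gauss-Seidel
#' block-relaxation: each block's loading is updated in turn from the
#' weighted sum of the other blocks' current variates,
#' `a_j <- X_j' w_j / ||X_j' w_j||` with
#' `w_j = sum_k c_jk s_jk t_k`, which makes the objective monotonically
#' non-decreasing over iterations. After each component every block is
#' deflated on its own variate:
#' `X_j <- X_j - t_j (t_j' X_j) / (t_j' t_j)`, which renders the variates
#' of one block mutually orthogonal across components.
#'
#' Initialisation uses each block's leading right singular vector, so the
#' fit is deterministic. The sign of each `(a_j, t_j)` pair is fixed so
#' the largest-magnitude loading entry is positive.
#'
#' @param bs A `block_set` with complete (no missing), centered and scaled
#'   blocks.
#' @param design J x J symmetric design matrix of non-negative weights
#'   named by the blocks; see [integration_design()].
#' @param cfg A [block_pls_config()].
#' @return A list of class `block_pls_model` with per-block `loadings`
#'   (p_j x H), `variates` (n x H), `deflated` final blocks, `iterations`
#'   and `converged` per component, and `objective_trace` (list over
#'   components of the objective value at each inner iteration).
#' @export
fit_block_pls <- function(bs, design, cfg = block_pls_config()) {
  stopifnot(inherits(bs, "block_set"))
  validate_design(design, names(bs))
  design <- design[names(bs), names(bs)]
  J <- length(bs)
  n <- nrow(bs[[1L]]$values)
  H <- cfg$n_components

  X <- lapply(bs, function(b) b$values)
  has_na <- vapply(X, anyNA, logical(1))
  if (any(has_na))
    stop("missing values in block(s): ",
         paste(names(bs)[has_na], collapse = ", "),
         "; filter to complete cases first")
  isolated <- rowSums(design) == 0
  if (any(isolated))
    stop("block(s) with all-zero design weights: ",
         paste(names(bs)[isolated], collapse = ", "))

  loadings <- lapply(X, function(x)
    matrix(0, ncol(x), H, dimnames = list(colnames(x), NULL)))
  variates <- lapply(X, function(x)
    matrix(0, n, H, dimnames = list(rownames(x), NULL)))
  iterations <- integer(H)
  converged <- logical(H)
  objective_trace <- vector("list", H)

  objective <- function(tlist) {
    val <- 0
    for (j in seq_len(J - 1L)) for (k in (j + 1L):J) {
      if (design[j, k] == 0) next
      cv <- crossprod(tlist[[j]], tlist[[k]])[1L] / (n - 1L)
      val <- val + design[j, k] * scheme_g(cfg$scheme, cv)
    }
    val
  }

  for (h in seq_len(H)) {
    a <- lapply(X, first_right_singular)
    t_list <- Map(function(x, aj) as.numeric(x %*% aj), X, a)
    trace_h <- objective(t_list)

    for (it in seq_len(cfg$max_iter)) {
      delta <- 0
      for (j in seq_len(J)) {
        w <- numeric(n)
        for (k in seq_len(J)) {
          if (k == j || design[j, k] == 0) next
          cv <- crossprod(t_list[[j]], t_list[[k]])[1L] / (n - 1L)
          w <- w + design[j, k] * scheme_weight(cfg$scheme, cv) * t_list[[k]]
        }
        if (all(w == 0))
          stop("all-zero inner target for block '", names(bs)[j], "'")
        a_new <- crossprod(X[[j]], w)
        a_new <- as.numeric(a_new) / sqrt(sum(a_new^2))
        delta <- max(delta, max(abs(a_new - a[[j]])))
        a[[j]] <- a_new
        t_list[[j]] <- as.numeric(X[[j]] %*% a_new)
      }
      trace_h <- c(trace_h, objective(t_list))
      if (delta < cfg$tol) break
    }
    iterations[h] <- it
    converged[h] <- delta < cfg$tol
    if (!converged[h])
      warning(sprintf("component %d did not converge after %d iterations (last change %.3g)",
                      h, cfg$max_iter, delta))
    objective_trace[[h]] <- trace_h

    for (j in seq_len(J)) {
      fixed <- fix_sign(a[[j]], t_list[[j]])
      loadings[[j]][, h] <- fixed$a
      variates[[j]][, h] <- fixed$t
      tj <- fixed$t
      X[[j]] <- X[[j]] - tj %*% (crossprod(tj, X[[j]]) / sum(tj^2))
    }
  }

  structure(list(loadings = loadings, variates = variates, deflated = X,
                 design = design, config = cfg, block_names = names(bs),
                 iterations = iterations, converged = converged,
                 objective_trace = objective_trace),
            class = "block_pls_model")
}

#' @export
print.block_pls_model <- function(x, ...) {
  cat(sprintf("block_pls_model: %d blocks, %d components (%s scheme, %s mode)\n",
              length(x$loadings), x$config$n_components,
              x$config$scheme, x$config$mode))
  cat("iterations per component:", paste(x$iterations, collapse = ", "), "\n")
  if (!all(x$converged))
    cat("warning: component(s)", paste(which(!x$converged), collapse = ", "),
        "did not converge\n")
  invisible(x)
}

#' Per-block explained variance of a multi-block PLS fit
#'
#' Fraction of each block's total (centered and scaled) sum of squares
#' captured by the orthogonal projection of the block onto each of its
#' variates. Because own-variate deflation makes a block's variates
#' mutually orthogonal, the fractions of one block sum to at most 1.
#'
#' @param model A `block_pls_model`.
#' @param bs The `block_set` the model was fitted on.
#' @return Numeric matrix, blocks x components.
#' @export
explained_variance <- function(model, bs) {
  stopifnot(identical(names(bs), model$block_names))
  H <- ncol(model$variates[[1L]])
  out <- matrix(0, length(bs), H,
                dimnames = list(names(bs), paste0("comp", seq_len(H))))
  for (j in seq_along(bs)) {
    X <- bs[[j]]$values
    total <- sum(X^2)
    for (h in seq_len(H)) {
      t_h <- model$variates[[j]][, h]
      out[j, h] <- sum(crossprod(X, t_h)^2) / sum(t_h^2) / total
    }
  }
  out
}
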