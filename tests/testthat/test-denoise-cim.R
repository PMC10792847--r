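fit_toy_model <- function(bs, H = 2L) {
  d <- matrix(1, length(bs), length(bs), dimnames = list(names(bs), names(bs)))
  diag(d) <- 0
  suppressWarnings(fit_block_pls(bs, d, block_pls_config(n_components = H)))
}

test_that("denoising splits every block exactly into fit plus residuals", {
  bs <- random_block_set(n = 20, p = c(5L, 4L, 3L), seed = 13)
  fit <- fit_toy_model(bs)
  parts <- denoise_blocks(bs, fit)
  for (j in seq_along(bs)) {
    recomposed <- parts$denoised[[j]]$values + parts$residuals[[j]]$values
    expect_lt(max(abs(recomposed - bs[[j]]$values)), 1e-12)
    expect_lte(qr(parts$denoised[[j]]$values)$rank, 2L)
    ## residuals orthogonal to the variate span
    expect_lt(max(abs(crossprod(fit$variates[[j]], parts$residuals[[j]]$values))),
              1e-9)
  }
})

test_that("denoising is an idempotent projection", {
  bs <- random_block_set(n = 15, p = c(4L, 3L), seed = 14)
  fit <- fit_toy_model(bs)
  once <- denoise_blocks(bs, fit)$denoised
  twice <- denoise_blocks(once, fit)$denoised
  for (j in seq_along(bs))
    expect_lt(max(abs(twice[[j]]$values - once[[j]]$values)), 1e-10)
})

test_that("variates spanning a block's column space leave zero residual", {
  ## rank-2 blocks fitted with 2 components: projection is exact
  set.seed(15)
  ids <- sprintf("g%03d", 1:25)
  mk <- function(p, tag) {
    basis <- matrix(rnorm(50), 25, 2)
    vals <- basis %*% matrix(rnorm(2 * p), 2, p)
    vals <- scale(vals)
    attr(vals, "scaled:center") <- attr(vals, "scaled:scale") <- NULL
    dimnames(vals) <- list(ids, paste0(tag, "_v", seq_len(p)))
    omics_matrix(vals, data.frame(name = colnames(vals), omic_type = "expression",
                                  feature = "none", context = "none",
                                  population = paste0("P", seq_len(p))))
  }
  bs <- block_set(list(a = mk(3, "a"), b = mk(4, "b")))
  fit <- fit_toy_model(bs, H = 2L)
  parts <- denoise_blocks(bs, fit)
  for (j in 1:2)
    expect_lt(max(abs(parts$residuals[[j]]$values)), 1e-9)
})

test_that("two identical blocks reduce to PCA: denoised block equals SVD truncation", {
  set.seed(16)
  ids <- sprintf("g%03d", 1:30)
  vals <- scale(matrix(rnorm(30 * 5), 30, 5))
  attr(vals, "scaled:center") <- attr(vals, "scaled:scale") <- NULL
  dimnames(vals) <- list(ids, paste0("x_v", 1:5))
  b1 <- omics_matrix(vals, data.frame(name = colnames(vals), omic_type = "expression",
                                      feature = "none", context = "none",
                                      population = paste0("P", 1:5)))
  vals2 <- vals
  colnames(vals2) <- paste0("y_v", 1:5)
  b2 <- omics_matrix(vals2, data.frame(name = colnames(vals2), omic_type = "methylation",
                                       feature = "gene_body", context = "CG",
                                       population = paste0("P", 1:5)))
  bs <- block_set(list(x = b1, y = b2))
  fit <- fit_block_pls(bs, pair_design(names(bs)),
                       block_pls_config(n_components = 1L, tol = 1e-10,
                                        max_iter = 1000L))
  den <- denoise_blocks(bs, fit)$denoised
  sv <- svd(vals)
  rank1 <- sv$d[1] * tcrossprod(sv$u[, 1], sv$v[, 1])
  expect_lt(max(abs(den$x$values - rank1)), 1e-6)
})

test_that("Ward merge sequence matches the brute-force Lance-Williams oracle", {
  set.seed(17)
  x <- matrix(rnorm(24, sd = 2), 6, 4)
  tree <- hclust(dist(x), method = "ward.D2")
  or <- oracle_ward(x)
  expect_equal(tree$height, or$heights, tolerance = 1e-10)
  expect_identical(hclust_merge_sets(tree), or$merges)
})

test_that("build_cim with all transforms off only reorders the input", {
  bs <- random_block_set(n = 12, p = c(3L, 2L), seed = 18)
  fit <- fit_toy_model(bs)
  res <- build_cim(bs, fit, cim_options(denoise = FALSE, scale2 = FALSE,
                                        cutoff = FALSE, k_groups = 3L))
  parent <- concat_blocks(bs)$values
  expect_identical(res$matrix, parent)
  expect_setequal(res$row_order, seq_len(nrow(parent)))
  expect_setequal(res$col_order, seq_len(ncol(parent)))
  ## tree heights non-decreasing along merges
  expect_true(all(diff(res$row_tree$height) >= -1e-12))
  expect_true(all(diff(res$col_tree$height) >= -1e-12))
})

test_that("cutting the gene tree yields consistent, order-invariant clusters", {
  bs <- random_block_set(n = 14, p = c(4L, 3L), seed = 19)
  fit <- fit_toy_model(bs)
  res <- build_cim(bs, fit, cim_options(k_groups = 4L))
  expect_setequal(unique(res$clusters), 1:4)
  ## labels are consistent with cutree on the row tree
  raw_cut <- cutree(res$row_tree, k = 4)
  expect_equal(length(unique(paste(res$clusters, raw_cut))), 4L)

  ## degenerate cuts
  res1 <- build_cim(bs, fit, cim_options(k_groups = 1L))
  expect_true(all(res1$clusters == 1L))
  resn <- build_cim(bs, fit, cim_options(k_groups = 14L))
  expect_setequal(resn$clusters, 1:14)
  expect_error(build_cim(bs, fit, cim_options(k_groups = 15L)), "exceeds")

  ## permuting gene order relabels but does not regroup
  perm <- c(7, 1, 12, 3, 14, 5, 2, 9, 4, 11, 6, 13, 8, 10)
  bs_p <- block_set(lapply(bs, function(b) b[perm, ]))
  fit_p <- fit_toy_model(bs_p)
  res_p <- build_cim(bs_p, fit_p, cim_options(k_groups = 4L))
  tab <- table(res$clusters[names(res_p$clusters)], res_p$clusters)
  expect_equal(sum(tab > 0), 4L)   # one-to-one label correspondence
})

test_that("cluster profiles average the transformed matrix per group", {
  bs <- random_block_set(n = 10, p = c(2L, 2L), seed = 20)
  fit <- fit_toy_model(bs)
  res <- build_cim(bs, fit, cim_options(denoise = FALSE, scale2 = FALSE,
                                        cutoff = FALSE, k_groups = 3L))
  prof <- cluster_profiles(res)
  for (g in unique(res$clusters)) {
    rows <- names(res$clusters)[res$clusters == g]
    sub <- prof[prof$group == g, ]
    expect_equal(sub$size, rep(length(rows), ncol(res$matrix)))
    expect_equal(sub$mean,
                 unname(colMeans(res$matrix[rows, , drop = FALSE])))
  }
  ## a single-gene group's profile is that gene's row
  res1 <- build_cim(bs, fit, cim_options(denoise = FALSE, scale2 = FALSE,
                                         cutoff = FALSE, k_groups = 10L))
  prof1 <- cluster_profiles(res1)
  g1 <- names(res1$clusters)[res1$clusters == 1][1]
  expect_equal(prof1$mean[prof1$group == 1], unname(res1$matrix[g1, ]))
})
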