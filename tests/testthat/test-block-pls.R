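test_that("two single-column blocks give unit loadings and the scaled column as variate", {
  bs <- random_block_set(n = 15, p = c(1L, 1L), seed = 2)
  fit <- fit_block_pls(bs, pair_design(names(bs)),
                       block_pls_config(n_components = 1L))
  for (j in 1:2) {
    expect_equal(abs(unname(fit$loadings[[j]][, 1])), 1)
    expect_equal(fit$variates[[j]][, 1],
                 bs[[j]]$values[, 1] * fit$loadings[[j]][1, 1])
  }
})

test_that("two-block fits recover the leading singular pair of X1'X2 (20 random instances)", {
  worst <- 0
  for (s in 1:20) {
    bs <- random_block_set(n = 30, p = c(5L, 4L), seed = s)
    fit <- fit_block_pls(bs, pair_design(names(bs)),
                         block_pls_config(n_components = 1L, tol = 1e-10,
                                          max_iter = 1000L))
    or <- oracle_two_block(bs[[1]]$values, bs[[2]]$values)
    worst <- max(worst,
                 max_dev_up_to_sign(fit$loadings[[1]][, 1], or$a1),
                 max_dev_up_to_sign(fit$loadings[[2]][, 1], or$a2))
  }
  expect_lt(worst, 1e-6)
})

test_that("variates of one block are mutually orthogonal across components", {
  bs <- random_block_set(n = 25, p = c(6L, 5L, 4L), seed = 9)
  d <- matrix(c(0, 1, 0.5, 1, 0, 0.2, 0.5, 0.2, 0), 3, 3,
              dimnames = list(names(bs), names(bs)))
  fit <- suppressWarnings(
    fit_block_pls(bs, d, block_pls_config(n_components = 3L)))
  for (j in seq_along(bs)) {
    T_j <- fit$variates[[j]]
    for (h in 1:2) for (k in (h + 1):3) {
      expect_lt(abs(crossprod(T_j[, h], T_j[, k])),
                1e-8 * sqrt(sum(T_j[, h]^2) * sum(T_j[, k]^2)))
    }
  }
  ## loading columns unit norm
  for (j in seq_along(bs))
    expect_equal(unname(colSums(fit$loadings[[j]]^2)), rep(1, 3))
})

test_that("the design-weighted covariance objective is non-decreasing over inner iterations", {
  for (scheme in c("horst", "centroid", "factorial")) {
    bs <- random_block_set(n = 20, p = c(4L, 3L, 5L), seed = 4)
    d <- matrix(0.5, 3, 3, dimnames = list(names(bs), names(bs)))
    diag(d) <- 0
    fit <- suppressWarnings(
      fit_block_pls(bs, d, block_pls_config(n_components = 2L, scheme = scheme)))
    for (trace in fit$objective_trace)
      expect_true(all(diff(trace) >= -1e-10))
  }
})

test_that("permuting gene rows permutes variates identically and leaves loadings unchanged", {
  bs <- random_block_set(n = 18, p = c(4L, 3L), seed = 6)
  fit <- fit_block_pls(bs, pair_design(names(bs)))
  perm <- sample(18)
  bs_perm <- block_set(lapply(bs, function(b) b[perm, ]))
  fit_perm <- fit_block_pls(bs_perm, pair_design(names(bs)))
  for (j in 1:2) {
    expect_equal(fit_perm$loadings[[j]], fit$loadings[[j]], tolerance = 1e-9)
    expect_equal(fit_perm$variates[[j]], fit$variates[[j]][perm, ],
                 tolerance = 1e-9)
  }
})

test_that("missing values and isolated blocks are rejected", {
  bs <- random_block_set(n = 10, p = c(3L, 2L), seed = 1)
  bs_na <- bs
  bs_na[[1]]$values[1, 1] <- NA_real_
  bs_na <- structure(bs_na, class = "block_set")
  expect_error(fit_block_pls(bs_na, pair_design(names(bs))), "missing values")

  expect_error(fit_block_pls(bs, pair_design(names(bs), weight = 0)),
               "all-zero design weights")
})

test_that("explained variance matches the direct projection formula and spans [0, 1]", {
  bs <- random_block_set(n = 20, p = c(3L, 4L), seed = 8)
  fit <- fit_block_pls(bs, pair_design(names(bs)))
  ev <- explained_variance(fit, bs)
  for (j in 1:2) for (h in 1:2) {
    X <- bs[[j]]$values
    t_h <- fit$variates[[j]][, h]
    p_h <- crossprod(X, t_h) / sum(t_h^2)
    direct <- sum(tcrossprod(t_h, p_h)^2) / sum(X^2)
    expect_equal(ev[j, h], direct, tolerance = 1e-10)
  }
  expect_true(all(ev >= 0 & ev <= 1))
  expect_true(all(rowSums(ev) <= 1 + 1e-10))

  ## a rank-1 block is fully explained by one component
  set.seed(12)
  ids <- sprintf("g%03d", 1:20)
  v1 <- scale(tcrossprod(rnorm(20), c(1, 2, 3)))
  attr(v1, "scaled:center") <- attr(v1, "scaled:scale") <- NULL
  dimnames(v1) <- list(ids, paste0("a_v", 1:3))
  b1 <- omics_matrix(v1, data.frame(name = colnames(v1), omic_type = "expression",
                                    feature = "none", context = "none",
                                    population = paste0("P", 1:3)))
  b2 <- random_block_set(n = 20, p = c(2L, 2L), seed = 12)[[2]]
  bs1 <- block_set(list(rank1 = b1, other = b2))
  fit1 <- fit_block_pls(bs1, pair_design(names(bs1)),
                        block_pls_config(n_components = 1L))
  expect_equal(explained_variance(fit1, bs1)["rank1", 1], 1, tolerance = 1e-8)
})

test_that("the multi-block fit agrees with an independent reference implementation", {
  skip_if_not_installed("mixOmics")
  bs <- random_block_set(n = 40, p = c(5L, 4L, 6L), seed = 21)
  d <- matrix(c(0, 1, 0.1, 1, 0, 0.1, 0.1, 0.1, 0), 3, 3,
              dimnames = list(names(bs), names(bs)))
  fit <- fit_block_pls(bs, d, block_pls_config(n_components = 1L, tol = 1e-9,
                                               max_iter = 500L))
  X <- lapply(bs, function(b) b$values)
  ref <- mixOmics::block.pls(X, indY = 1, ncomp = 1, design = d,
                             scheme = "horst", mode = "regression",
                             scale = FALSE, tol = 1e-9, max.iter = 500)
  for (j in names(bs)) {
    expect_lt(max_dev_up_to_sign(as.numeric(fit$loadings[[j]][, 1]),
                                 as.numeric(ref$loadings[[j]][, 1])),
              1e-4)
  }
})
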