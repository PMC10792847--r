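small_cfg <- function(...) {
  sim_config(n_genes = 300L, n_drivers = 10L, ...)
}

test_that("the generator is deterministic under a fixed seed and leaves the RNG alone", {
  a <- simulate_omics(small_cfg(), seed = 5)
  b <- simulate_omics(small_cfg(), seed = 5)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth$genes, b$truth$genes)
  c <- simulate_omics(small_cfg(), seed = 6)
  expect_false(identical(a$matrix$values, c$matrix$values))

  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulate_omics(small_cfg(), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("the emitted layout is the 7-kind x population grid", {
  sim <- simulate_omics(sim_config(n_genes = 50, n_populations = 10,
                                   n_drivers = 5), seed = 2)
  m <- sim$matrix
  expect_identical(dim(m$values), c(50L, 70L))
  bs <- split_blocks(m)
  expect_length(bs, 7L)
  expect_true(all(vapply(bs, function(b) ncol(b$values), integer(1)) == 10L))
  expect_setequal(unique(m$variables$population), sprintf("P%02d", 1:10))
  ## truth covers every gene with a typology and the requested driver count
  expect_identical(sim$truth$genes$gene_id, gene_ids(m))
  expect_true(all(sim$truth$genes$typology %in% 1:4))
  expect_equal(sum(sim$truth$genes$is_driver), 5L)
})

test_that("driver genes are planted complete with the extreme latent pattern", {
  sim <- simulate_omics(small_cfg(missing_rate = 0.1), seed = 3)
  drv <- sim$truth$genes$is_driver
  expect_equal(sum(drv), 10L)
  ## drivers carry no missing cells
  expect_false(anyNA(sim$matrix$values[drv, ]))
  ## latent pattern: methylation above every non-driver latent mean,
  ## expression below
  lat <- sim$truth$latent_means
  expect_true(all(lat[drv, "expression"] < min(lat[!drv, "expression"])))
  for (k in colnames(lat)[-1])
    expect_true(all(lat[drv, k] > max(lat[!drv, k])))
})

test_that("same-kind columns are strongly correlated across populations", {
  ## Monte-Carlo check of the planted inter-population structure
  rhos <- sapply(1:5, function(s) {
    sim <- simulate_omics(sim_config(n_genes = 2000, missing_rate = 0), seed = s)
    x <- sim$matrix$values[, grep("gene_body_CG", colnames(sim$matrix$values))]
    cc <- cor(x, method = "spearman")
    mean(cc[upper.tri(cc)])
  })
  expect_true(all(rhos >= 0.8))
})

test_that("expression is zero-inflated and promoter methylation heavy-tailed", {
  sim <- simulate_omics(sim_config(n_genes = 3000, missing_rate = 0), seed = 4)
  x <- sim$matrix$values
  expr <- x[, grep("^expression", colnames(x))]
  expect_gt(mean(expr == 0), 0.05)
  ## excess kurtosis of promoter noise far above the Gaussian value
  kurt <- function(v) mean((v - mean(v))^4) / mean((v - mean(v))^2)^2 - 3
  prom <- x[, grep("^promoter_CG", colnames(x))]
  body <- x[, grep("^gene_body_CG", colnames(x))]
  expect_gt(kurt(as.vector(prom)), kurt(as.vector(body)) + 1)
})

test_that("missing cells hit the configured overall rate and spare drivers", {
  sim <- simulate_omics(sim_config(n_genes = 4000), seed = 7)
  rate <- mean(is.na(sim$matrix$values))
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
  drv <- sim$truth$genes$is_driver
  expect_false(anyNA(sim$matrix$values[drv, ]))
  ## missingness is gene-clustered: most genes are fully observed
  expect_gt(mean(rowSums(is.na(sim$matrix$values)) == 0), 0.5)
})

test_that("raw-scale output exercises the log transform back to the log scale", {
  sim_log <- simulate_omics(small_cfg(missing_rate = 0), seed = 8)
  sim_raw <- simulate_omics(small_cfg(missing_rate = 0), seed = 8,
                            raw_scale = TRUE)
  relogged <- log_transform(sim_raw$matrix)
  expect_equal(relogged$values, sim_log$matrix$values, tolerance = 1e-10)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(n_genes = 10, n_drivers = 20), "exceeds")
  expect_error(sim_config(typology_proportions = c(0.5, 0.5, 0, 0.1)), "1e-09|sum")
  expect_error(sim_config(missing_rate = 0.5, missing_gene_fraction = 0.3),
               "may not exceed")
})

test_that("scoreboard reproduces exact and hypergeometric expectations", {
  sim <- simulate_omics(small_cfg(), seed = 9)
  truth <- sim$truth
  drivers <- truth$genes$gene_id[truth$genes$is_driver]

  exact <- scoreboard(truth, selected = drivers)
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$false_discovery_proportion, 0)

  none <- scoreboard(truth, selected = character(0))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$false_discovery_proportion, 0)

  ## random selections of |drivers| genes: mean sensitivity matches the
  ## hypergeometric expectation K/N
  set.seed(10)
  sens <- replicate(200, {
    pick <- sample(truth$genes$gene_id, length(drivers))
    scoreboard(truth, selected = pick)$sensitivity
  })
  expect_lt(abs(mean(sens) - length(drivers) / nrow(truth$genes)), 0.015)

  ## ARI of a clustering identical to the typologies is 1 (drivers excluded)
  lab <- truth$genes$typology
  names(lab) <- truth$genes$gene_id
  expect_equal(scoreboard(truth, clusters = lab)$adjusted_rand_index, 1)
})
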