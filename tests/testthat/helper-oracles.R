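## independent oracles, deliberately brute-force ------------------------------

## Ward agglomeration by the Lance-Williams update on Euclidean input
## distances (ward.D2 convention: distances, not squared distances, are
## reported as heights). Returns the merge heights and the member sets of
## each merge, enough to compare merge sequences with hclust.
oracle_ward <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(dist(x))^2            # work on squared distances
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1L, n)
  heights <- numeric(0)
  merges <- list()
  while (length(active) > 1L) {
    best <- c(NA, NA); best_val <- Inf
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1L)) {
      a <- active[ii]; b <- active[jj]
      if (d2[a, b] < best_val) { best_val <- d2[a, b]; best <- c(b, a) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, sqrt(best_val))
    merges <- c(merges, list(sort(c(members[[i]], members[[j]]))))
    ## Lance-Williams (Ward): d2(ij,k) =
    ##   ((n_i+n_k) d2_ik + (n_j+n_k) d2_jk - n_k d2_ij) / (n_i+n_j+n_k)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      d2_new <- ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] -
                   nk * d2[i, j]) / (ni + nj + nk)
      d2[i, k] <- d2[k, i] <- d2_new
    }
    members[[i]] <- sort(c(members[[i]], members[[j]]))
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  list(heights = heights, merges = merges)
}

## member sets of each hclust merge, in merge order
hclust_merge_sets <- function(tree) {
  n <- nrow(tree$merge) + 1L
  sets <- vector("list", nrow(tree$merge))
  for (m in seq_len(nrow(tree$merge))) {
    grab <- function(v) if (v < 0) -v else sets[[v]]
    sets[[m]] <- sort(c(grab(tree$merge[m, 1]), grab(tree$merge[m, 2])))
  }
  sets
}

## EM-style rank-1 fit under missing values: impute with the current
## reconstruction, take the exact leading SVD component, iterate.
oracle_em_rank1 <- function(x, tol = 1e-12, max_iter = 5000) {
  obs <- !is.na(x)
  filled <- x
  filled[!obs] <- mean(x, na.rm = TRUE) * 0   # start from zero imputation
  rec_old <- filled
  for (i in seq_len(max_iter)) {
    s <- svd(filled, nu = 1, nv = 1)
    rec <- s$d[1] * tcrossprod(s$u[, 1], s$v[, 1])
    filled[!obs] <- rec[!obs]
    if (max(abs(rec - rec_old)) < tol) break
    rec_old <- rec
  }
  p <- s$v[, 1]
  t_vec <- s$d[1] * s$u[, 1]
  k <- which.max(abs(p))
  if (p[k] < 0) { p <- -p; t_vec <- -t_vec }
  list(loading = p, scores = t_vec)
}

## Spearman correlation of two vectors by hand: average ranks, then the
## Pearson product-moment formula
oracle_spearman <- function(a, b) {
  keep <- !is.na(a) & !is.na(b)
  ra <- rank(a[keep]); rb <- rank(b[keep])
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

## leading singular-vector pair of X1'X2: the closed-form solution of
## two-block PLS with one component
oracle_two_block <- function(x1, x2) {
  s <- svd(crossprod(x1, x2), nu = 1, nv = 1)
  list(a1 = s$u[, 1], a2 = s$v[, 1])
}

max_dev_up_to_sign <- function(a, b) {
  min(max(abs(a - b)), max(abs(a + b)))
}
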