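VARIABLE_KINDS <- c("expression",
                    "promoter_CG", "promoter_CHG", "promoter_CHH",
                    "gene_body_CG", "gene_body_CHG", "gene_body_CHH")

## typology templates in noise-sd units, one row per gene typology,
## columns in VARIABLE_KINDS order:
##  1 highly expressed, lowly methylated everywhere
##  2 lowly expressed, low CG gene-body methylation, moderate elsewhere
##  3 highly methylated, moderately-low expression
##  4 highly expressed with high CG gene-body methylation, moderate elsewhere
TYPOLOGY_TEMPLATES <- matrix(c(
   2.0, -2.0, -2.0, -2.0, -2.0, -2.0, -2.0,
  -2.0,  0.75, 0.75, 0.75, -2.0,  0.75, 0.75,
  -1.0,  2.0,  2.0,  2.0,  2.0,  2.0,  2.0,
   2.0,  0.75, 0.75, 0.75,  2.0,  0.75, 0.75),
  nrow = 4, byrow = TRUE,
  dimnames = list(paste0("typology", 1:4), VARIABLE_KINDS))

#' Simulation configuration
#'
#' Describes the synthetic gene-centric methylome/transcriptome matrix the
#' generator emits: a genes x (populations x 7 variable kinds) layout with
#' one expression and six methylation variables (promoter and gene body,
#' each in the CG, CHG and CHH contexts) per population, four planted gene
#' typologies, a set of planted master-driver genes (high methylation and
#' low expression in every variable), strong inter-population correlation,
#' zero-inflated expression, heavy-tailed promoter methylation, and
#' gene-clustered missing values.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_populations Number of populations (default 10; with 7 variable
#'   kinds this gives 70 columns).
#' @param typology_proportions Four fractions summing to 1 giving the
#'   share of each gene typology (default equal).
#' @param n_drivers Number of planted master-driver genes (default 30).
#' @param driver_effect Driver shift in column-standardised (z) units
#'   (default 2.5): drivers are planted `driver_effect` marginal standard
#'   deviations above the column mean for every methylation kind and
#'   below it for expression.
#' @param population_correlation Correlation of a gene's values for one
#'   variable kind across populations, in `[0, 1)` (default 0.9).
#' @param missing_rate Overall fraction of missing cells (default 0.05).
#' @param missing_gene_fraction Fraction of (non-driver) genes that carry
#'   the missing cells (default 0.35); missingness in aggregated omics
#'   tables is gene-clustered, because low-coverage genes lose several
#'   variables at once. Drivers are always complete.
#' @param expression_zero_fraction Ceiling of the per-cell probability
#'   that an expression value collapses to the zero-expression mass
#'   (default 0.3); the probability decreases with the gene's latent
#'   expression level.
#' @param promoter_tail_df Degrees of freedom of the standardised Student
#'   noise used for promoter methylation (default 3); smaller values give
#'   heavier tails.
#' @param noise_sd Standard deviation of the per-cell noise on the log2
#'   scale (default 1).
#' @param shared_gene_sd Standard deviation of the gene-level effect added
#'   to all of a gene's variables (default 0.3).
#' @param seed Default seed used by [simulate_omics()] (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_populations = 10L,
                       typology_proportions = rep(0.25, 4),
                       n_drivers = 30L, driver_effect = 2.5,
                       population_correlation = 0.9,
                       missing_rate = 0.05, missing_gene_fraction = 0.35,
                       expression_zero_fraction = 0.3,
                       promoter_tail_df = 3, noise_sd = 1,
                       shared_gene_sd = 0.3, seed = 1L) {
  stopifnot(n_genes >= 1L, n_populations >= 2L,
            length(typology_proportions) == 4L,
            abs(sum(typology_proportions) - 1) <= 1e-9,
            all(typology_proportions >= 0),
            population_correlation >= 0, population_correlation < 1,
            missing_rate >= 0, missing_rate <= 1,
            missing_gene_fraction >= 0, missing_gene_fraction <= 1,
            expression_zero_fraction >= 0, expression_zero_fraction <= 1,
            promoter_tail_df > 2, noise_sd > 0, shared_gene_sd >= 0)
  if (n_drivers > n_genes)
    stop("n_drivers exceeds n_genes")
  if (missing_rate > 0 && missing_gene_fraction == 0)
    stop("missing_rate > 0 requires missing_gene_fraction > 0")
  if (missing_rate > missing_gene_fraction)
    stop("missing_rate may not exceed missing_gene_fraction (per-affected-gene rate would exceed 1)")
  structure(list(n_genes = as.integer(n_genes),
                 n_populations = as.integer(n_populations),
                 typology_proportions = typology_proportions,
                 n_drivers = as.integer(n_drivers),
                 driver_effect = driver_effect,
                 population_correlation = population_correlation,
                 missing_rate = missing_rate,
                 missing_gene_fraction = missing_gene_fraction,
                 expression_zero_fraction = expression_zero_fraction,
                 promoter_tail_df = promoter_tail_df,
                 noise_sd = noise_sd, shared_gene_sd = shared_gene_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## standardised noise: unit variance; Student tails for promoter kinds
draw_noise <- function(n, kind, df) {
  if (startsWith(kind, "promoter")) {
    rt(n, df = df) / sqrt(df / (df - 2))
  } else {
    rnorm(n)
  }
}

#' Simulate a gene-centric methylome/transcriptome matrix
#'
#' Generates values on the log2-like scale. For gene g of typology c,
#' variable kind k and population q:
#' `x = baseline_k + noise_sd * template[c, k] + s_g +
#'  noise_sd * (sqrt(rho) u_gk + sqrt(1 - rho) e_gkq)` where `s_g` is a
#' gene-level effect shared across all variables, `u_gk` is a gene-by-kind
#' effect shared across populations (this is what gives same-kind columns
#' their inter-population correlation `rho`, and what low-rank denoising
#' cannot use cross-block information to keep), and `e_gkq` is
#' population-specific noise. Promoter-methylation noise is heavy-tailed
#' (standardised Student). Planted drivers override the typology
#' template, landing `driver_effect` marginal standard deviations above
#' the column mean in every methylation kind and below it in expression.
#' Expression cells collapse to the zero mass with a
#' probability that grows as the latent expression level falls. Values are
#' floored at zero (the log2(1+x) scale has no negative values). Missing
#' cells are confined to a random subset of non-driver genes.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. The same seed always
#'   reproduces the identical matrix.
#' @param raw_scale If `TRUE`, emit `2^x - 1` (TPM-like raw values) so
#'   that [log_transform()] can be exercised; default `FALSE`.
#' @return A list with `matrix` (an `omics_matrix`, genes x
#'   `7 * n_populations` variables) and `truth` (a `sim_truth` list with
#'   `genes` data frame — `gene_id`, `typology`, `is_driver` — and
#'   `latent_means`, the genes x kinds latent mean matrix).
#' @export
simulate_omics <- function(cfg = sim_config(), seed = cfg$seed,
                           raw_scale = FALSE) {
  with_local_seed(seed, {
    n <- cfg$n_genes
    P <- cfg$n_populations
    kinds <- VARIABLE_KINDS
    baselines <- c(expression = 4, setNames(rep(3, 6), kinds[-1]))
    gene_id <- sprintf("gene%05d", seq_len(n))
    pops <- sprintf("P%02d", seq_len(P))

    typology <- sample(1:4, n, replace = TRUE,
                       prob = cfg$typology_proportions)
    is_driver <- rep(FALSE, n)
    if (cfg$n_drivers > 0L)
      is_driver[sample.int(n, cfg$n_drivers)] <- TRUE

    ## latent means per gene x kind on the log2 scale
    latent <- matrix(0, n, length(kinds), dimnames = list(gene_id, kinds))
    for (k in seq_along(kinds))
      latent[, k] <- baselines[k] + cfg$noise_sd * TYPOLOGY_TEMPLATES[typology, k]
    ## driver_effect is in column-z units: plant drivers driver_effect
    ## marginal standard deviations from the analytic column mean (the
    ## marginal variance combines the typology spread, the shared gene
    ## effect and the noise; zero-inflation and flooring are ignored here)
    templ_mean <- as.numeric(cfg$typology_proportions %*% TYPOLOGY_TEMPLATES)
    templ_var <- as.numeric(cfg$typology_proportions %*% TYPOLOGY_TEMPLATES^2) -
      templ_mean^2
    col_mean <- baselines + cfg$noise_sd * templ_mean
    col_sd <- sqrt(cfg$noise_sd^2 * templ_var + cfg$shared_gene_sd^2 +
                     cfg$noise_sd^2)
    if (any(is_driver)) {
      latent[is_driver, "expression"] <-
        col_mean["expression"] - cfg$driver_effect * col_sd[1L]
      for (k in 2:length(kinds))
        latent[is_driver, kinds[k]] <- col_mean[kinds[k]] +
          cfg$driver_effect * col_sd[k]
    }
    shared_gene <- rnorm(n, sd = cfg$shared_gene_sd)

    rho <- cfg$population_correlation
    values <- matrix(NA_real_, n, length(kinds) * P)
    col_names <- character(length(kinds) * P)
    meta <- vector("list", length(kinds))
    for (k in seq_along(kinds)) {
      kind <- kinds[k]
      u <- draw_noise(n, kind, cfg$promoter_tail_df)
      e <- matrix(draw_noise(n * P, kind, cfg$promoter_tail_df), n, P)
      x <- latent[, k] + shared_gene +
        cfg$noise_sd * (sqrt(rho) * u + sqrt(1 - rho) * e)
      if (kind == "expression" && cfg$expression_zero_fraction > 0) {
        z_latent <- (latent[, k] - baselines[k]) / cfg$noise_sd
        p_zero <- cfg$expression_zero_fraction * plogis(-1.5 * z_latent)
        zero_mask <- matrix(runif(n * P) < p_zero, n, P)
        x[zero_mask] <- 0
      }
      x <- pmax(x, 0)
      cols <- (k - 1L) * P + seq_len(P)
      values[, cols] <- x
      col_names[cols] <- paste(kind, pops, sep = "_")
      meta[[k]] <- data.frame(
        name = col_names[cols],
        omic_type = if (kind == "expression") "expression" else "methylation",
        feature = if (kind == "expression") "none" else
          sub("_(CG|CHG|CHH)$", "", kind),
        context = if (kind == "expression") "none" else
          sub("^.*_", "", kind),
        population = pops, stringsAsFactors = FALSE)
    }
    dimnames(values) <- list(gene_id, col_names)

    if (cfg$missing_rate > 0) {
      eligible <- which(!is_driver)
      n_affected <- min(length(eligible),
                        round(cfg$missing_gene_fraction * n))
      affected <- sample(eligible, n_affected)
      cell_rate <- cfg$missing_rate * n / max(n_affected, 1L)
      mask <- matrix(runif(n_affected * ncol(values)) < cell_rate,
                     n_affected, ncol(values))
      values[affected, ][mask] <- NA_real_
    }
    if (raw_scale) values <- 2^values - 1

    truth <- structure(list(
      genes = data.frame(gene_id = gene_id, typology = typology,
                         is_driver = is_driver, stringsAsFactors = FALSE),
      latent_means = latent), class = "sim_truth")
    list(matrix = omics_matrix(values, do.call(rbind, meta)), truth = truth)
  })
}

#' Score predictions against the simulation ground truth
#'
#' @param truth A `sim_truth` from [simulate_omics()].
#' @param selected A `gene_set` (or character vector) of predicted driver
#'   genes, or `NULL` to skip the driver scores.
#' @param clusters Named integer vector of cluster labels (gene ->
#'   group), or `NULL` to skip the ARI. Genes absent from `clusters`
#'   (e.g. dropped by filters) are ignored for the ARI, as are driver
#'   genes: their planted profile overrides the typology template, so
#'   their typology label no longer describes their data.
#' @return A list with `sensitivity` (fraction of true drivers selected),
#'   `false_discovery_proportion` (fraction of selected genes that are not
#'   drivers; 0 when nothing is selected) and `adjusted_rand_index`
#'   (between planted typologies and cluster labels over non-driver
#'   genes).
#' @export
scoreboard <- function(truth, selected = NULL, clusters = NULL) {
  genes <- truth$genes
  out <- list(sensitivity = NA_real_,
              false_discovery_proportion = NA_real_,
              adjusted_rand_index = NA_real_)
  if (!is.null(selected)) {
    ids <- if (inherits(selected, "gene_set")) selected$ids else as.character(selected)
    drivers <- genes$gene_id[genes$is_driver]
    out$sensitivity <- if (length(drivers)) {
      length(intersect(ids, drivers)) / length(drivers)
    } else NA_real_
    out$false_discovery_proportion <- if (length(ids)) {
      length(setdiff(ids, drivers)) / length(ids)
    } else 0
  }
  if (!is.null(clusters)) {
    common <- intersect(names(clusters),
                        genes$gene_id[!genes$is_driver])
    truth_lab <- genes$typology[match(common, genes$gene_id)]
    out$adjusted_rand_index <-
      mclust::adjustedRandIndex(truth_lab, clusters[common])
  }
  out
}
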