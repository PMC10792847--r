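#' Pipeline configuration
#'
#' One object holding everything the end-to-end workflow needs: input
#' paths (or an in-memory matrix), output directory, and the per-stage
#' configurations.
#'
#' @param matrix_path Path to the genes x variables value table, or `NULL`
#'   when `matrix` is given.
#' @param metadata_path Path to the variable metadata sidecar.
#' @param out_dir Output directory (created if absent).
#' @param matrix Optional in-memory `omics_matrix` (overrides the paths).
#' @param preprocess A [preprocess_config()].
#' @param log_input Whether the input is on the raw scale and needs the
#'   log transform (default `TRUE`).
#' @param design_expr_meth,design_meth_meth Design weights passed to
#'   [integration_design()].
#' @param block_pls A [block_pls_config()].
#' @param cim A [cim_options()] (its `denoise` flag is ignored: the
#'   pipeline always builds both the non-denoised and the denoised map).
#' @param meth_min,expr_max Selection thresholds for [select_extreme()].
#' @param ma_cutoff Log2 fold-change cutoff for [ma_compare()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, metadata_path = NULL,
                            out_dir = tempfile("omicblocks_run_"),
                            matrix = NULL,
                            preprocess = preprocess_config(),
                            log_input = TRUE,
                            design_expr_meth = 1, design_meth_meth = 0.1,
                            block_pls = block_pls_config(),
                            cim = cim_options(),
                            meth_min = 1, expr_max = -1, ma_cutoff = 1) {
  if (is.null(matrix)) {
    if (is.null(matrix_path) || is.null(metadata_path))
      stop("either `matrix` or both `matrix_path` and `metadata_path` are required")
    if (!file.exists(matrix_path)) stop("matrix file not found: ", matrix_path)
    if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  }
  structure(list(matrix_path = matrix_path, metadata_path = metadata_path,
                 out_dir = out_dir, matrix = matrix,
                 preprocess = preprocess, log_input = log_input,
                 design_expr_meth = design_expr_meth,
                 design_meth_meth = design_meth_meth,
                 block_pls = block_pls, cim = cim,
                 meth_min = meth_min, expr_max = expr_max,
                 ma_cutoff = ma_cutoff),
            class = "pipeline_config")
}

log_line <- function(log_path, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE, sep = "")
}

#' Run the full integration workflow
#'
#' Executes the stages in fixed order: preprocessing (presence and
#' missing-fraction filters, log transform), exploratory statistics
#' (Spearman/AOE correlation, NIPALS PCA), complete-case reduction,
#' centering/scaling, block splitting, multi-block PLS, the non-denoised
#' and denoised clustered image maps, extreme-profile selection on both,
#' their comparison, and the MA quantification of the denoising effect.
#' Every artifact is written under `cfg$out_dir` and listed, with an MD5
#' checksum, in the returned manifest; gene counts after each filter are
#' logged.
#'
#' @param cfg A [pipeline_config()].
#' @return A list with `manifest` (data frame: `file`, `md5`), `counts`
#'   (gene counts after each stage), `selected` (the two `gene_set`s and
#'   their comparison) and `results` (in-memory stage outputs).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run.log")
  cat("", file = log_path)
  artifacts <- character(0)
  emit <- function(path) { artifacts <<- c(artifacts, path); path }

  m <- if (!is.null(cfg$matrix)) cfg$matrix else
    read_omics_matrix(cfg$matrix_path, cfg$metadata_path)
  log_line(log_path, "input: %d genes x %d variables",
           nrow(m$values), ncol(m$values))

  ## stage 1: preprocess
  pp <- preprocess(m, cfg$preprocess, log = cfg$log_input)
  counts <- pp$counts
  log_line(log_path, "after min-per-class filter: %d genes", counts["min_per_class"])
  log_line(log_path, "after missing-fraction filter (<= %g): %d genes",
           cfg$preprocess$max_missing_fraction, counts["missing_fraction"])
  write_omics_matrix(pp$matrix,
                     emit(file.path(cfg$out_dir, "preprocessed_matrix.tsv")),
                     emit(file.path(cfg$out_dir, "variable_metadata.tsv")))

  ## stage 2: explore
  corr <- spearman_matrix(pp$matrix)
  write_numeric_table(corr$corr,
                      emit(file.path(cfg$out_dir, "spearman_correlation.tsv")),
                      id_col = "variable")
  write_delim_df(data.frame(position = seq_along(corr$order),
                            variable = colnames(corr$corr)[corr$order]),
                 emit(file.path(cfg$out_dir, "aoe_order.tsv")))
  cs_all <- center_scale(pp$matrix)
  pca <- pca_nipals(cs_all$matrix, H = 2L)
  write_numeric_table(pca$loadings,
                      emit(file.path(cfg$out_dir, "pca_loadings.tsv")),
                      id_col = "variable")
  write_delim_df(data.frame(component = seq_along(pca$explained_variance_fraction),
                            explained_variance_fraction = pca$explained_variance_fraction),
                 emit(file.path(cfg$out_dir, "pca_explained_variance.tsv")))
  log_line(log_path, "PCA explained variance: %s",
           paste(sprintf("%.1f%%", 100 * pca$explained_variance_fraction),
                 collapse = ", "))

  ## stage 3: integrate (complete cases, centered/scaled, block PLS)
  complete <- filter_missing_fraction(pp$matrix, 0)
  counts["complete_cases"] <- nrow(complete$values)
  log_line(log_path, "complete-case set for integration: %d genes",
           counts["complete_cases"])
  cs <- center_scale(complete)
  bs <- split_blocks(cs$matrix)
  design <- integration_design(bs, cfg$design_expr_meth, cfg$design_meth_meth)
  write_numeric_table(design, emit(file.path(cfg$out_dir, "design.tsv")),
                      id_col = "block")
  model <- fit_block_pls(bs, design, cfg$block_pls)
  for (j in seq_along(bs)) {
    write_numeric_table(model$loadings[[j]],
                        emit(file.path(cfg$out_dir,
                                       paste0("loadings_", names(bs)[j], ".tsv"))),
                        id_col = "variable")
  }
  ev <- explained_variance(model, bs)
  write_numeric_table(ev, emit(file.path(cfg$out_dir, "block_explained_variance.tsv")),
                      id_col = "block")
  log_line(log_path, "block PLS converged: %s (iterations %s)",
           paste(model$converged, collapse = ", "),
           paste(model$iterations, collapse = ", "))

  ## stages 4-5: clustered image maps without and with denoising
  opt_raw <- cim_options(denoise = FALSE, scale2 = cfg$cim$scale2,
                         cutoff = cfg$cim$cutoff, k_groups = cfg$cim$k_groups,
                         clamp_bounds = cfg$cim$clamp_bounds)
  opt_den <- cim_options(denoise = TRUE, scale2 = cfg$cim$scale2,
                         cutoff = cfg$cim$cutoff, k_groups = cfg$cim$k_groups,
                         clamp_bounds = cfg$cim$clamp_bounds)
  cim_raw <- build_cim(bs, model, opt_raw)
  cim_den <- build_cim(bs, model, opt_den)
  for (tag in c("non_denoised", "denoised")) {
    res <- if (tag == "denoised") cim_den else cim_raw
    write_numeric_table(res$matrix,
                        emit(file.path(cfg$out_dir, paste0("cim_matrix_", tag, ".tsv"))),
                        id_col = "gene_id")
    write_delim_df(data.frame(gene_id = names(res$clusters),
                              group = unname(res$clusters)),
                   emit(file.path(cfg$out_dir, paste0("clusters_", tag, ".tsv"))))
    write_delim_df(cluster_profiles(res),
                   emit(file.path(cfg$out_dir, paste0("cluster_profiles_", tag, ".tsv"))))
  }

  ## stage 6: selection, comparison, MA
  ## thresholds act on the unclamped scale2 output (equivalent under the
  ## default bounds, exact in general)
  opt_sel_raw <- cim_options(denoise = FALSE, scale2 = cfg$cim$scale2,
                             cutoff = FALSE, k_groups = cfg$cim$k_groups)
  opt_sel_den <- cim_options(denoise = TRUE, scale2 = cfg$cim$scale2,
                             cutoff = FALSE, k_groups = cfg$cim$k_groups)
  sel_input_raw <- build_cim(bs, model, opt_sel_raw)
  sel_input_den <- build_cim(bs, model, opt_sel_den)
  set_raw <- select_extreme(sel_input_raw, cfg$meth_min, cfg$expr_max,
                            provenance = "non_denoised")
  set_den <- select_extreme(sel_input_den, cfg$meth_min, cfg$expr_max,
                            provenance = "denoised")
  comparison <- compare_gene_sets(set_raw, set_den)
  log_line(log_path,
           "candidates: %d non-denoised, %d denoised (%d shared, %d denoised-only)",
           length(set_raw$ids), length(set_den$ids),
           comparison$counts["shared"], comparison$counts["only_b"])
  write_gene_set(set_raw$ids,
                 emit(file.path(cfg$out_dir, "candidates_non_denoised.txt")))
  write_gene_set(set_den$ids,
                 emit(file.path(cfg$out_dir, "candidates_denoised.txt")))
  write_delim_df(data.frame(partition = names(comparison$counts),
                            count = unname(comparison$counts)),
                 emit(file.path(cfg$out_dir, "venn_counts.tsv")))
  ma <- ma_compare(sel_input_raw$matrix, sel_input_den$matrix, cfg$ma_cutoff)
  write_delim_df(ma$by_variable,
                 emit(file.path(cfg$out_dir, "ma_by_variable.tsv")))

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         row.names = NULL)
  write_delim_df(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  log_line(log_path, "wrote %d artifacts to %s", nrow(manifest), cfg$out_dir)

  list(manifest = manifest, counts = counts,
       selected = list(non_denoised = set_raw, denoised = set_den,
                       comparison = comparison),
       results = list(preprocess = pp, correlation = corr, pca = pca,
                      blocks = bs, design = design, model = model,
                      explained_variance = ev,
                      cim_non_denoised = cim_raw, cim_denoised = cim_den,
                      ma = ma))
}
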