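## small builders used across the suite -------------------------------------

toy_variables <- function(n_populations = 2L,
                          kinds = c("expression",
                                    "promoter_CG", "promoter_CHG", "promoter_CHH",
                                    "gene_body_CG", "gene_body_CHG", "gene_body_CHH")) {
  pops <- sprintf("P%02d", seq_len(n_populations))
  do.call(rbind, lapply(kinds, function(kind) {
    data.frame(
      name = paste(kind, pops, sep = "_"),
      omic_type = if (kind == "expression") "expression" else "methylation",
      feature = if (kind == "expression") "none" else sub("_(CG|CHG|CHH)$", "", kind),
      context = if (kind == "expression") "none" else sub("^.*_", "", kind),
      population = pops, stringsAsFactors = FALSE)
  }))
}

## deterministic toy matrix: n genes x (7 * n_populations) variables
toy_omics <- function(n_genes = 6L, n_populations = 2L, seed = 42L,
                      missing = NULL) {
  vars <- toy_variables(n_populations)
  set.seed(seed)
  vals <- matrix(rnorm(n_genes * nrow(vars), mean = 3),
                 n_genes, nrow(vars),
                 dimnames = list(sprintf("g%02d", seq_len(n_genes)), vars$name))
  if (!is.null(missing)) vals[missing] <- NA_real_
  omics_matrix(vals, vars)
}

## two-variable matrix (1 expression + 1 methylation), values given directly
two_var_omics <- function(expr, meth, ids = sprintf("g%d", seq_along(expr))) {
  vals <- cbind(expression_P01 = expr, gene_body_CG_P01 = meth)
  rownames(vals) <- ids
  vars <- data.frame(name = colnames(vals),
                     omic_type = c("expression", "methylation"),
                     feature = c("none", "gene_body"),
                     context = c("none", "CG"),
                     population = "P01", stringsAsFactors = FALSE)
  omics_matrix(vals, vars)
}

## centered+scaled random block set over shared genes
random_block_set <- function(n = 30L, p = c(5L, 4L), seed = 1L,
                             names_ = paste0("block", seq_along(p))) {
  set.seed(seed)
  ids <- sprintf("g%03d", seq_len(n))
  blocks <- lapply(seq_along(p), function(j) {
    vals <- matrix(rnorm(n * p[j]), n, p[j],
                   dimnames = list(ids, sprintf("%s_v%d", names_[j], seq_len(p[j]))))
    vals <- scale(vals)
    attr(vals, "scaled:center") <- NULL
    attr(vals, "scaled:scale") <- NULL
    type <- if (j == 1L) "expression" else "methylation"
    vars <- data.frame(name = colnames(vals),
                       omic_type = type,
                       feature = if (type == "expression") "none" else "gene_body",
                       context = if (type == "expression") "none" else "CG",
                       population = sprintf("P%02d", seq_len(p[j])),
                       stringsAsFactors = FALSE)
    omics_matrix(vals, vars)
  })
  names(blocks) <- names_
  block_set(blocks)
}

pair_design <- function(names_, weight = 1) {
  d <- matrix(weight, 2, 2, dimnames = list(names_, names_))
  diag(d) <- 0
  d
}
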