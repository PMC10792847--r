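#' @importFrom stats cor sd cov dist hclust cutree rnorm rt runif rbinom
#'   plogis setNames
#' @importFrom utils write.table
#' @importFrom grDevices colorRampPalette
NULL

OMIC_TYPES <- c("expression", "methylation")
FEATURES   <- c("promoter", "gene_body", "none")
CONTEXTS   <- c("CG", "CHG", "CHH", "none")

#' Construct a gene-centric omics matrix
#'
#' The central container of the package: a numeric genes x variables matrix
#' (rows = genes, columns = omics variables such as per-population expression
#' or methylation levels) together with a per-variable metadata table.
#' Missing cells are stored as `NA`.
#'
#' @param values Numeric matrix, genes in rows, variables in columns. Row
#'   names are gene identifiers, column names are variable names.
#' @param variables Data frame with one row per column of `values` and
#'   columns `name`, `omic_type` (`"expression"` or `"methylation"`),
#'   `feature` (`"promoter"`, `"gene_body"` or `"none"`), `context`
#'   (`"CG"`, `"CHG"`, `"CHH"` or `"none"`) and `population`.
#'
#' @details Expression variables must have `feature == "none"` and
#'   `context == "none"`; methylation variables must have both set. Gene
#'   identifiers and variable names must be unique and no column may be
#'   entirely missing.
#'
#' @return An object of class `omics_matrix` with elements `values` and
#'   `variables`.
#' @export
omics_matrix <- function(values, variables) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene identifiers as row names and variable names as column names")
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  required <- c("name", "omic_type", "feature", "context", "population")
  missing_cols <- setdiff(required, names(variables))
  if (length(missing_cols))
    stop("variable metadata lacks column(s): ", paste(missing_cols, collapse = ", "))
  variables <- variables[, required]
  for (col in required) variables[[col]] <- as.character(variables[[col]])

  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(variables$name))
    stop("duplicate variable names in metadata")
  if (nrow(variables) != ncol(values) || !identical(variables$name, colnames(values)))
    stop("variable metadata must match the matrix columns (same names, same order)")

  bad_type <- !variables$omic_type %in% OMIC_TYPES
  if (any(bad_type))
    stop("unknown omic_type: ", paste(unique(variables$omic_type[bad_type]), collapse = ", "))
  if (any(!variables$feature %in% FEATURES))
    stop("feature must be one of ", paste(FEATURES, collapse = ", "))
  if (any(!variables$context %in% CONTEXTS))
    stop("context must be one of ", paste(CONTEXTS, collapse = ", "))
  expr <- variables$omic_type == "expression"
  if (any(expr & (variables$feature != "none" | variables$context != "none")))
    stop("expression variables must have feature = 'none' and context = 'none'")
  if (any(!expr & (variables$feature == "none" | variables$context == "none")))
    stop("methylation variables must have a gene feature and a methylation context")

  if (any(!is.finite(values) & !is.na(values)))
    stop("non-finite values present; missing cells must be NA")
  all_missing <- colSums(!is.na(values)) == 0L
  if (any(all_missing))
    stop("column(s) entirely missing: ",
         paste(colnames(values)[all_missing], collapse = ", "))

  structure(list(values = values, variables = variables),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  n_miss <- sum(is.na(x$values))
  cat(sprintf("omics_matrix: %d genes x %d variables (%d expression, %d methylation), %.2f%% missing\n",
              nrow(x$values), ncol(x$values),
              sum(x$variables$omic_type == "expression"),
              sum(x$variables$omic_type == "methylation"),
              100 * n_miss / length(x$values)))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Gene identifiers of an omics matrix
#' @param m An `omics_matrix`.
#' @return Character vector of gene identifiers, in row order.
#' @export
gene_ids <- function(m) rownames(m$values)

#' Subset an omics matrix
#'
#' Row (gene) and column (variable) subsetting that keeps the variable
#' metadata aligned with the value matrix.
#'
#' @param x An `omics_matrix`.
#' @param i Gene index (integer, logical or character).
#' @param j Variable index (integer, logical or character).
#' @param ... Ignored.
#' @return An `omics_matrix`.
#' @export
`[.omics_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  omics_matrix(x$values[i, j, drop = FALSE], x$variables[j, , drop = FALSE])
}

## ---- reading / writing -----------------------------------------------------

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an omics matrix and its variable metadata from disk
#'
#' @param path Delimited text file (`.tsv` tab, `.csv` comma; anything else
#'   is read as tab) with a header row of variable names and gene
#'   identifiers in the first column.
#' @param metadata_path Delimited text file with columns `name`,
#'   `omic_type`, `feature`, `context`, `population`, one row per variable.
#' @param missing_tokens Character vector of cell contents treated as
#'   missing (case-sensitive). Defaults to `"NA"` and the empty string.
#'
#' @return An `omics_matrix`. Cells equal to a missing token become `NA`;
#'   any other non-numeric cell is an error reporting its gene and variable.
#' @export
read_omics_matrix <- function(path, metadata_path,
                              missing_tokens = c("NA", "")) {
  sep <- delim_for(path)
  raw <- data.table::fread(path, sep = sep, header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           data.table = FALSE)
  if (ncol(raw) < 2L) stop("matrix file must have a gene-ID column plus at least one variable")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  meta <- data.table::fread(metadata_path, sep = delim_for(metadata_path),
                            header = TRUE, colClasses = "character",
                            data.table = FALSE)
  var_names <- colnames(raw)[-1L]
  absent <- setdiff(var_names, meta$name)
  if (length(absent))
    stop("variable(s) in matrix header absent from metadata: ",
         paste(absent, collapse = ", "))
  meta <- meta[match(var_names, meta$name), , drop = FALSE]

  vals <- matrix(NA_real_, nrow = nrow(raw), ncol = length(var_names),
                 dimnames = list(ids, var_names))
  for (j in seq_along(var_names)) {
    cell <- raw[[j + 1L]]
    is_missing <- cell %in% missing_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_missing & is.na(num)
    if (any(bad)) {
      k <- which(bad)[1L]
      stop(sprintf("non-numeric cell '%s' at gene '%s', variable '%s'",
                   cell[k], ids[k], var_names[j]))
    }
    num[is_missing] <- NA_real_
    vals[, j] <- num
  }
  omics_matrix(vals, meta)
}

#' Write an omics matrix (values + metadata) to disk
#'
#' Values are written with enough significant digits that reading the file
#' back reproduces them bit-exactly.
#'
#' @param m An `omics_matrix`.
#' @param path Output path for the value matrix (TSV/CSV by extension).
#' @param metadata_path Output path for the variable metadata table.
#' @param missing_token Token written for missing cells (default `"NA"`).
#' @return Invisibly, `path`.
#' @export
write_omics_matrix <- function(m, path, metadata_path,
                               missing_token = "NA") {
  write_numeric_table(m$values, path, missing_token = missing_token,
                      id_col = "gene_id")
  write_delim_df(m$variables, metadata_path)
  invisible(path)
}

## full-precision numeric formatting: %.17g round-trips doubles exactly
format_full <- function(x, missing_token = "NA") {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- missing_token
  out
}

#' Write a numeric matrix as a delimited table with row names
#'
#' Round-trip safe: values are formatted with 17 significant digits, so a
#' write/read cycle reproduces every double bit-exactly.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file; `.csv` extension selects a comma separator,
#'   anything else tab.
#' @param missing_token Written for `NA` cells.
#' @param id_col Header for the row-name column.
#' @return Invisibly, `path`.
#' @export
write_numeric_table <- function(x, path, missing_token = "NA",
                                id_col = "id") {
  sep <- delim_for(path)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(x)), collapse = sep), con)
  body <- apply(x, 1L, function(row)
    paste(format_full(row, missing_token), collapse = sep))
  writeLines(paste(rownames(x), body, sep = sep), con)
  invisible(path)
}

#' Read back a numeric table written by [write_numeric_table()]
#' @param path File to read.
#' @param missing_tokens Tokens treated as missing.
#' @return Numeric matrix with row and column names.
#' @export
read_numeric_table <- function(path, missing_tokens = c("NA", "")) {
  raw <- data.table::fread(path, sep = delim_for(path), header = TRUE,
                           colClasses = "character", na.strings = NULL,
                           data.table = FALSE)
  ids <- raw[[1L]]
  vals <- vapply(raw[-1L], function(cell) {
    num <- suppressWarnings(as.numeric(cell))
    num[cell %in% missing_tokens] <- NA_real_
    num
  }, numeric(nrow(raw)))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(ids, colnames(raw)[-1L]))
  vals
}

write_delim_df <- function(df, path) {
  sep <- delim_for(path)
  write.table(df, path, sep = sep, quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Write a gene set as one identifier per line
#'
#' @param ids Character vector of gene identifiers (may be empty).
#' @param path Output file. The first line is a `gene_id` header.
#' @return Invisibly, `path`.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(c("gene_id", as.character(ids)), path)
  invisible(path)
}

#' Read a gene set written by [write_gene_set()]
#' @param path File with a `gene_id` header line.
#' @return Character vector of identifiers.
#' @export
read_gene_set <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1L] != "gene_id")
    stop("not a gene-set file (missing 'gene_id' header): ", path)
  lines[-1L]
}

## ---- blocks ----------------------------------------------------------------

#' Split an omics matrix into named blocks
#'
#' Partitions the variables into blocks sharing the gene rows. The default
#' grouping assigns expression variables to the `"expression"` block and
#' methylation variables to `feature_context` blocks
#' (`promoter_CG`, ..., `gene_body_CHH`): the seven-block layout used for
#' joint methylome/transcriptome analysis.
#'
#' @param m An `omics_matrix`.
#' @param grouping Either `NULL` (default grouping above) or a function
#'   taking the variable metadata data frame and returning one block name
#'   per variable.
#' @return A `block_set`: a named list of `omics_matrix` blocks, in order
#'   of first appearance of each block name, all sharing `gene_ids(m)`.
#' @export
split_blocks <- function(m, grouping = NULL) {
  if (is.null(grouping)) {
    names_out <- ifelse(m$variables$omic_type == "expression",
                        "expression",
                        paste(m$variables$feature, m$variables$context, sep = "_"))
  } else {
    names_out <- as.character(grouping(m$variables))
    if (length(names_out) != ncol(m$values))
      stop("grouping must return one block name per variable")
  }
  if (anyNA(names_out) || any(!nzchar(names_out)))
    stop("every variable must map to a non-empty block name")
  block_names <- unique(names_out)
  blocks <- lapply(block_names, function(b) m[, names_out == b])
  names(blocks) <- block_names
  block_set(blocks)
}

#' Assemble a block set from omics matrices
#'
#' @param blocks Named list of `omics_matrix` objects with identical gene
#'   identifiers in identical order and disjoint variable names.
#' @return A `block_set`.
#' @export
block_set <- function(blocks) {
  if (is.null(names(blocks)) || anyDuplicated(names(blocks)) ||
      any(!nzchar(names(blocks))))
    stop("blocks must have unique non-empty names")
  if (!length(blocks)) stop("at least one block required")
  if (!all(vapply(blocks, inherits, logical(1), "omics_matrix")))
    stop("every block must be an omics_matrix")
  ids <- gene_ids(blocks[[1L]])
  same <- vapply(blocks, function(b) identical(gene_ids(b), ids), logical(1))
  if (!all(same))
    stop("all blocks must share identical gene identifiers in identical order")
  all_vars <- unlist(lapply(blocks, function(b) colnames(b$values)))
  if (anyDuplicated(all_vars))
    stop("variable names must be disjoint across blocks")
  structure(blocks, class = "block_set")
}

#' @export
print.block_set <- function(x, ...) {
  cat(sprintf("block_set: %d blocks over %d genes\n",
              length(x), nrow(x[[1L]]$values)))
  for (nm in names(x))
    cat(sprintf("  %-16s %d variables\n", nm, ncol(x[[nm]]$values)))
  invisible(x)
}

#' Concatenate a block set back into a single omics matrix
#'
#' Columns appear block by block, in block order. Together with
#' [split_blocks()] this realises the partition property: splitting then
#' concatenating recovers the parent matrix up to column order.
#'
#' @param bs A `block_set`.
#' @return An `omics_matrix`.
#' @export
concat_blocks <- function(bs) {
  vals <- do.call(cbind, lapply(bs, function(b) b$values))
  meta <- do.call(rbind, lapply(bs, function(b) b$variables))
  rownames(meta) <- NULL
  omics_matrix(vals, meta)
}

## ---- design matrix ---------------------------------------------------------

#' Validate an inter-block design matrix
#'
#' @param design Square numeric matrix of inter-block weights with row and
#'   column names, symmetric, zero diagonal, entries in `[0, 1]`.
#' @param block_names Optional block names the design must cover.
#' @return The design matrix, invisibly, after validation.
#' @export
validate_design <- function(design, block_names = NULL) {
  if (!is.matrix(design) || nrow(design) != ncol(design))
    stop("design must be a square matrix")
  if (is.null(rownames(design)) || !identical(rownames(design), colnames(design)))
    stop("design must have identical row and column names")
  if (!isTRUE(all.equal(design, t(design))))
    stop("design must be symmetric")
  if (any(diag(design) != 0))
    stop("design diagonal must be zero (no block is weighted with itself)")
  if (any(design < 0 | design > 1))
    stop("design weights must lie in [0, 1]")
  if (!is.null(block_names) && !setequal(rownames(design), block_names))
    stop("design block names must match the block set")
  invisible(design)
}

#' Default methylome-on-transcriptome design matrix
#'
#' Builds the symmetric weight matrix used to focus a multi-block PLS on
#' methylation/expression interplay: weight `expr_meth` (default 1) between
#' every methylation block and the expression block, `meth_meth` (default
#' 0.1) between pairs of methylation blocks, and 0 on the diagonal.
#'
#' @param bs A `block_set`; each block must be purely expression or purely
#'   methylation.
#' @param expr_meth Weight between expression and each methylation block.
#' @param meth_meth Weight between pairs of methylation blocks.
#' @return A named J x J design matrix.
#' @export
integration_design <- function(bs, expr_meth = 1, meth_meth = 0.1) {
  types <- vapply(bs, function(b) {
    u <- unique(b$variables$omic_type)
    if (length(u) != 1L)
      stop("block '", b$variables$name[1L], "' mixes omic types")
    u
  }, character(1))
  J <- length(bs)
  d <- matrix(0, J, J, dimnames = list(names(bs), names(bs)))
  for (j in seq_len(J)) for (k in seq_len(J)) {
    if (j == k) next
    d[j, k] <- if (types[j] != types[k]) expr_meth else
      if (types[j] == "methylation") meth_meth else 0
  }
  validate_design(d, names(bs))
  d
}
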