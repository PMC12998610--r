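#' Construct a per-cell expression dataset
#'
#' A `cell_dataset` bundles a genes x cells log-normalized expression matrix
#' with the per-cell annotations (cell type, subject, optionally condition)
#' that drive per-subject signaling inference.
#'
#' @param expr Numeric genes x cells matrix (base or `Matrix` sparse) of
#'   log-normalized expression; no negative entries.
#' @param cell_type,subject Character vectors, one entry per cell, no missing
#'   values.
#' @param condition Optional character vector, one entry per cell.
#' @param genes,cells Optional dimension names; default to `dimnames(expr)`.
#' @return An object of class `cell_dataset`.
#' @export
cell_dataset <- function(expr, cell_type, subject, condition = NULL,
                         genes = rownames(expr), cells = colnames(expr)) {
  if (is.null(genes) || is.null(cells)) {
    .stop_input("expression matrix must have gene and cell names")
  }
  n <- ncol(expr)
  if (length(cell_type) != n || length(subject) != n) {
    .stop_input("cell_type and subject must have one entry per cell")
  }
  if (anyNA(cell_type) || anyNA(subject)) {
    .stop_input("every cell must have a non-missing cell_type and subject")
  }
  if (!is.null(condition) && length(condition) != n) {
    .stop_input("condition must have one entry per cell")
  }
  if (min(expr) < 0) {
    .stop_input("expression must be non-negative (log-normalized counts)")
  }
  rownames(expr) <- genes
  colnames(expr) <- cells
  structure(
    list(
      expr = expr,
      genes = genes,
      cells = cells,
      cell_type = as.character(cell_type),
      subject = as.character(subject),
      condition = if (is.null(condition)) NULL else as.character(condition)
    ),
    class = "cell_dataset"
  )
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf(
    "cell_dataset: %d genes x %d cells; %d cell type(s), %d subject(s)%s\n",
    length(x$genes), length(x$cells),
    length(unique(x$cell_type)), length(unique(x$subject)),
    if (is.null(x$condition)) "" else
      sprintf(", %d condition(s)", length(unique(x$condition)))
  ))
  invisible(x)
}

#' Subset a dataset to a set of cells
#'
#' @param ds A `cell_dataset`.
#' @param idx Integer or logical index, or character cell ids.
#' @return A `cell_dataset` restricted to those cells (order preserved).
#' @export
subset_cells <- function(ds, idx) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (is.character(idx)) idx <- match(idx, ds$cells)
  cell_dataset(
    ds$expr[, idx, drop = FALSE],
    cell_type = ds$cell_type[idx],
    subject = ds$subject[idx],
    condition = if (is.null(ds$condition)) NULL else ds$condition[idx]
  )
}

#' Load an expression dataset with cell metadata
#'
#' Supports MatrixMarket triplets (matrix + features + barcodes sidecars) and
#' dense delimited matrices. Cells are reordered to match the metadata table;
#' duplicated gene symbols are dropped (first occurrence wins) with a message.
#'
#' @param expr_path Path to the `.mtx` file or the dense CSV/TSV matrix
#'   (genes in rows, cells in columns, first column = gene symbol).
#' @param meta_path Delimited metadata with columns `cell_id`, `cell_type`,
#'   `subject` and optionally `condition`.
#' @param fmt `"mtx"` or `"csv"`.
#' @param features_path,barcodes_path Sidecar paths for `fmt = "mtx"`;
#'   default to `features.tsv` / `barcodes.tsv` next to the matrix.
#' @return A [cell_dataset()].
#' @export
load_dataset <- function(expr_path, meta_path, fmt = c("mtx", "csv"),
                         features_path = NULL, barcodes_path = NULL) {
  fmt <- match.arg(fmt)
  meta <- .read_table(meta_path)
  required <- c("cell_id", "cell_type", "subject")
  absent <- setdiff(required, names(meta))
  if (length(absent)) {
    .stop_input(sprintf(
      "metadata %s is missing required column(s): %s",
      meta_path, paste(absent, collapse = ", ")
    ))
  }
  if (fmt == "mtx") {
    dir <- dirname(expr_path)
    features_path <- features_path %||% file.path(dir, "features.tsv")
    barcodes_path <- barcodes_path %||% file.path(dir, "barcodes.tsv")
    for (p in c(expr_path, features_path, barcodes_path)) {
      if (!file.exists(p)) .stop_input(sprintf("file not found: %s", p))
    }
    m <- if (grepl("\\.gz$", expr_path)) {
      Matrix::readMM(gzfile(expr_path))
    } else {
      Matrix::readMM(expr_path)
    }
    feats <- utils::read.table(features_path,
      sep = "\t", header = FALSE,
      stringsAsFactors = FALSE
    )
    bars <- utils::read.table(barcodes_path,
      sep = "\t", header = FALSE,
      stringsAsFactors = FALSE
    )
    # 10x convention: gene symbol in column 2 when present, else column 1
    sym_col <- if (ncol(feats) >= 2) 2 else 1
    genes <- feats[[sym_col]]
    cells <- bars[[1]]
    if (nrow(m) != length(genes) || ncol(m) != length(cells)) {
      .stop_parse("matrix dimensions disagree with features/barcodes sidecars")
    }
    rownames(m) <- genes
    colnames(m) <- cells
    expr <- m
  } else {
    tab <- .read_table(expr_path)
    genes <- as.character(tab[[1]])
    expr <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(expr) <- "double"
    rownames(expr) <- genes
  }
  dup <- duplicated(rownames(expr))
  if (any(dup)) {
    message(sprintf(
      "load_dataset: dropped %d duplicated gene symbol(s), keeping first occurrence",
      sum(dup)
    ))
    expr <- expr[!dup, , drop = FALSE]
  }
  missing_cells <- setdiff(meta$cell_id, colnames(expr))
  if (length(missing_cells)) {
    shown <- utils::head(missing_cells, 10)
    .stop_input(sprintf(
      "%d metadata cell id(s) absent from the expression matrix: %s%s",
      length(missing_cells), paste(shown, collapse = ", "),
      if (length(missing_cells) > 10) ", ..." else ""
    ))
  }
  expr <- expr[, meta$cell_id, drop = FALSE]
  cell_dataset(
    expr,
    cell_type = meta$cell_type,
    subject = meta$subject,
    condition = if ("condition" %in% names(meta)) meta$condition else NULL
  )
}

#' Z-score expression per gene
#'
#' Centers and scales each gene using the population standard deviation
#' (divide by n). Genes with zero variance within a scope map to all-zero
#' rows, so they can never pass the strictly-positive ligand sender gate.
#'
#' @param ds A [cell_dataset()].
#' @param scope `"per_subject"` (default; scaling is done independently
#'   within each subject's cells, so sender calls cannot leak cross-subject
#'   composition) or `"global"`.
#' @return A dense genes x cells matrix of scaled expression, cells in the
#'   dataset's order.
#' @export
scale_expression <- function(ds, scope = c("per_subject", "global")) {
  scope <- match.arg(scope)
  stopifnot(inherits(ds, "cell_dataset"))
  if (scope == "global") {
    if (ncol(ds$expr) < 2) .stop_input("need at least 2 cells to scale")
    return(.zscore_rows(ds$expr))
  }
  out <- matrix(0, nrow = length(ds$genes), ncol = length(ds$cells),
                dimnames = list(ds$genes, ds$cells))
  for (s in unique(ds$subject)) {
    idx <- which(ds$subject == s)
    if (length(idx) < 2) {
      .stop_input(sprintf(
        "subject %s has a single cell; merge or drop it before scaling", s
      ))
    }
    out[, idx] <- .zscore_rows(ds$expr[, idx, drop = FALSE])
  }
  out
}

#' Per-cell-type expression profiles for one subject
#'
#' For every cell type present in the subject's cells, computes the number of
#' cells, the per-gene mean of scaled expression (scaled within that
#' subject), and the per-gene fraction of cells with expression strictly
#' greater than zero.
#'
#' @param ds A [cell_dataset()].
#' @param subject Subject id present in `ds`.
#' @return A named list (one element per cell type) of lists with fields
#'   `cell_type`, `n_cells`, `mean_scaled` (named numeric) and
#'   `pct_expressing` (named numeric in `[0, 1]`).
#' @export
profile_cell_types <- function(ds, subject) {
  stopifnot(inherits(ds, "cell_dataset"))
  idx <- which(ds$subject == subject)
  if (length(idx) == 0) {
    .stop_input(sprintf("unknown subject: %s", subject))
  }
  expr <- as.matrix(ds$expr[, idx, drop = FALSE])
  ct <- ds$cell_type[idx]
  scaled <- .zscore_rows(expr)
  types <- sort(unique(ct))
  ind <- vapply(types, function(k) as.numeric(ct == k), numeric(length(ct)))
  n_k <- colSums(ind)
  mean_scaled <- sweep(scaled %*% ind, 2, n_k, "/")
  pct <- sweep((expr > 0) %*% ind, 2, n_k, "/")
  colnames(mean_scaled) <- colnames(pct) <- types
  profiles <- lapply(types, function(k) {
    list(
      cell_type = k,
      n_cells = as.integer(n_k[[k]]),
      mean_scaled = stats::setNames(mean_scaled[, k], rownames(expr)),
      pct_expressing = stats::setNames(pct[, k], rownames(expr))
    )
  })
  names(profiles) <- types
  profiles
}
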