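#' Transcription factor activity matrices
#'
#' A `tf_activity` object is a TFs x cells matrix of activity scores in
#' `[0, 1]` with a `method` attribute recording how the scores were obtained
#' (`"external"`, `"aucell"` or `"targeted_regulons"`).
#'
#' @param scores Numeric TFs x cells matrix with dimnames.
#' @param method Provenance label.
#' @return A `tf_activity` object.
#' @export
tf_activity <- function(scores,
                        method = c("external", "aucell", "targeted_regulons")) {
  method <- match.arg(method)
  scores <- as.matrix(scores)
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    .stop_input("TF score matrix must have TF and cell names")
  }
  if (any(scores < 0) || any(scores > 1)) {
    .stop_input("TF activity scores must lie in [0, 1]")
  }
  structure(scores, class = c("tf_activity", "matrix"), method = method)
}

#' @export
print.tf_activity <- function(x, ...) {
  cat(sprintf(
    "tf_activity (%s): %d TFs x %d cells\n",
    attr(x, "method"), nrow(x), ncol(x)
  ))
  invisible(x)
}

#' Load an externally computed TF activity score matrix
#'
#' Reads a delimited matrix (e.g. exported from SCENIC/AUCell). Values
#' outside `[0, 1]` are clipped with a reported count.
#'
#' @param path CSV/TSV file, first column = TF (or cell) names.
#' @param orientation `"tfs_in_rows"` (default) or `"tfs_in_cols"`.
#' @return A [tf_activity()] with `method = "external"`.
#' @export
load_tf_scores <- function(path,
                           orientation = c("tfs_in_rows", "tfs_in_cols")) {
  orientation <- match.arg(orientation)
  tab <- .read_table(path)
  rn <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(m))))[1]
    coord <- arrayInd(bad, dim(m))
    .stop_parse(sprintf(
      "non-numeric TF score at row %d, column %d of %s",
      coord[1], coord[2], path
    ))
  }
  rownames(m) <- rn
  if (orientation == "tfs_in_cols") m <- t(m)
  n_clip <- sum(m < 0 | m > 1)
  if (n_clip > 0) {
    message(sprintf("load_tf_scores: clipped %d value(s) into [0, 1]", n_clip))
    m <- pmin(pmax(m, 0), 1)
  }
  out <- tf_activity(m, method = "external")
  attr(out, "n_clipped") <- n_clip
  out
}

#' Read regulon gene sets
#'
#' Accepts GMT (`tf<TAB>description<TAB>gene...`) or a two-column TSV with a
#' header (`tf`, `target`).
#'
#' @param path Regulon file.
#' @param format `"auto"` (by extension), `"gmt"` or `"tsv"`.
#' @return Named list mapping each TF to its character vector of target
#'   genes.
#' @export
read_regulons <- function(path, format = c("auto", "gmt", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    out <- lapply(lines, function(l) {
      f <- strsplit(l, "\t", fixed = TRUE)[[1]]
      if (length(f) < 3) .stop_parse("GMT lines need tf, description, >=1 gene")
      unique(f[-(1:2)])
    })
    names(out) <- vapply(lines, function(l) {
      strsplit(l, "\t", fixed = TRUE)[[1]][1]
    }, character(1))
    return(out)
  }
  tab <- .read_table(path)
  absent <- setdiff(c("tf", "target"), names(tab))
  if (length(absent)) {
    .stop_input(sprintf(
      "regulon table missing column(s): %s", paste(absent, collapse = ", ")
    ))
  }
  lapply(split(as.character(tab$target), tab$tf), unique)
}

# Core AUCell-style recovery-curve score for one cell.
# ranks: integer rank (1 = highest expression) of each target gene;
# t: number of top ranks considered; n_targets: regulon size after pruning
# to genes present. Normalized by the maximal achievable area so every
# regulon spans [0, 1] regardless of size.
.auc_one <- function(target_ranks, t, n_targets) {
  r <- target_ranks[target_ranks <= t]
  num <- sum(t - r + 1)
  i <- seq_len(t)
  den <- sum(pmin(i, n_targets))
  num / den
}

#' AUCell-style regulon activity scoring
#'
#' For each cell, genes are ranked by decreasing expression (ties broken by a
#' fixed random permutation drawn once from `seed`, recorded in the output)
#' and each regulon is scored by the normalized area under its recovery
#' curve within the top `ceil(top_frac * n_genes)` ranks.
#'
#' @param ds A [cell_dataset()].
#' @param regulons Named list TF -> character vector of target genes.
#'   Targets absent from `ds` are pruned; regulons left empty are dropped
#'   with a warning.
#' @param top_frac Fraction of the ranking considered (default 0.05).
#' @param seed Integer seed for the tie-breaking permutation.
#' @return A [tf_activity()] with `method = "aucell"`.
#' @export
aucell_score <- function(ds, regulons, top_frac = 0.05, seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (length(regulons) == 0) .stop_input("empty regulon list")
  if (!(top_frac > 0 && top_frac <= 1)) {
    .stop_input("top_frac must lie in (0, 1]")
  }
  present <- lapply(regulons, function(g) intersect(g, ds$genes))
  empty <- vapply(present, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf(
      "dropping %d regulon(s) with no targets in the dataset: %s",
      sum(empty), paste(names(regulons)[empty], collapse = ", ")
    ))
    present <- present[!empty]
  }
  if (length(present) == 0) .stop_input("no regulon has targets in the dataset")
  n_genes <- length(ds$genes)
  t_top <- as.integer(ceiling(top_frac * n_genes))
  expr <- as.matrix(ds$expr)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  set.seed(as.integer(seed))
  tiebreak <- sample.int(n_genes)
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  target_idx <- lapply(present, function(g) match(g, ds$genes))
  scores <- matrix(0, nrow = length(present), ncol = ncol(expr),
                   dimnames = list(names(present), colnames(expr)))
  rk <- integer(n_genes)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], tiebreak)
    rk[ord] <- seq_len(n_genes)
    for (i in seq_along(present)) {
      scores[i, j] <- .auc_one(rk[target_idx[[i]]], t_top,
                               length(target_idx[[i]]))
    }
  }
  out <- tf_activity(scores, method = "aucell")
  attr(out, "tie_seed") <- as.integer(seed)
  attr(out, "top_frac") <- top_frac
  out
}

#' Chromatin accessibility mask from a gene-activity matrix
#'
#' A gene is annotated accessible in a cell type when at least `min_frac` of
#' that type's cells have non-zero gene activity (the comparison is `>=`, so
#' exactly 10 percent qualifies at the default).
#'
#' @param gene_activity Genes x cells numeric matrix (e.g. scATAC gene
#'   activity) with gene names.
#' @param cell_type Per-cell labels, length = number of columns.
#' @param min_frac Accessibility threshold (default 0.10).
#' @return An `accessibility_mask`: named list cell type -> character vector
#'   of accessible genes.
#' @export
compute_accessibility <- function(gene_activity, cell_type, min_frac = 0.10) {
  if (length(cell_type) != ncol(gene_activity)) {
    .stop_input("cell_type labels must match gene_activity columns")
  }
  if (!(min_frac >= 0 && min_frac <= 1)) {
    .stop_input("min_frac must lie in [0, 1]")
  }
  ga <- as.matrix(gene_activity)
  types <- sort(unique(as.character(cell_type)))
  mask <- lapply(types, function(k) {
    idx <- which(cell_type == k)
    frac <- rowMeans(ga[, idx, drop = FALSE] > 0)
    rownames(ga)[frac >= min_frac]
  })
  names(mask) <- types
  structure(mask, class = "accessibility_mask")
}

#' Prune regulons to accessible targets per cell type
#'
#' For each cell type in the mask, intersects every regulon's targets with
#' that type's accessible gene set; regulons left with no targets are dropped
#' for that type.
#'
#' @param regulons Named list TF -> targets.
#' @param mask An [compute_accessibility()] mask (or equivalently named list).
#' @return Named list cell type -> pruned regulon list.
#' @export
prune_regulons <- function(regulons, mask) {
  if (length(mask) == 0) .stop_input("accessibility mask is empty")
  out <- lapply(mask, function(acc) {
    pruned <- lapply(regulons, function(g) intersect(g, acc))
    pruned[vapply(pruned, length, integer(1)) > 0]
  })
  names(out) <- names(mask)
  out
}

#' TF activity from accessibility-pruned (targeted) regulons
#'
#' Scores each cell with the regulon pruned for that cell's type, so a target
#' gene contributes to a TF's activity only where it is accessible. TFs whose
#' pruned regulon is empty in a cell type score 0 for that type's cells.
#'
#' @inheritParams aucell_score
#' @param mask Accessibility mask from [compute_accessibility()].
#' @return A [tf_activity()] with `method = "targeted_regulons"`.
#' @export
targeted_regulon_scores <- function(ds, regulons, mask, top_frac = 0.05,
                                    seed = 1L) {
  stopifnot(inherits(ds, "cell_dataset"))
  pruned <- prune_regulons(regulons, mask)
  tfs <- names(regulons)
  scores <- matrix(0, nrow = length(tfs), ncol = length(ds$cells),
                   dimnames = list(tfs, ds$cells))
  for (k in unique(ds$cell_type)) {
    idx <- which(ds$cell_type == k)
    regs_k <- pruned[[k]]
    if (is.null(regs_k) || length(regs_k) == 0) next
    sub <- subset_cells(ds, idx)
    sc <- aucell_score(sub, regs_k, top_frac = top_frac, seed = seed)
    scores[rownames(sc), idx] <- unclass(sc)
  }
  out <- tf_activity(scores, method = "targeted_regulons")
  attr(out, "tie_seed") <- as.integer(seed)
  attr(out, "top_frac") <- top_frac
  out
}
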