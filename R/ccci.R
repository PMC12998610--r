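#' Configuration for per-subject signaling inference
#'
#' Default thresholds follow the inference parameters used throughout the
#' package: a transcription factor is called enriched in a cell type at
#' one-sided rank-sum p < 0.001, a receptor-TF correlation must reach
#' Spearman rho >= 0.15, at least 5 percent of a cell type's cells must
#' express every receptor component, and a cell type sends a ligand when the
#' mean scaled expression of every ligand component is strictly greater
#' than 0.
#'
#' @param min_tf_pval One-sided Wilcoxon rank-sum p-value threshold (strict
#'   `<`) for TF enrichment per cell type.
#' @param rec_tf_cor_threshold Spearman rho threshold (inclusive `>=`) on the
#'   receptor-TF correlation; for complexes the minimum over components must
#'   pass.
#' @param min_rec_percentage Minimum expressing-cell fraction (inclusive
#'   `>=`) for every receptor component in the recipient cell type.
#' @param sender_mean_scaled_threshold Ligand sender gate: mean scaled
#'   expression of every ligand component must be strictly greater than this.
#' @param max_tfs_per_celltype Optional cap on enriched TFs per cell type
#'   (lowest p kept; ties broken by larger median difference then TF name).
#' @param max_recs_per_tf Optional cap on receptors linked to one TF
#'   (highest complex rho kept).
#' @param exclude_regulon_targets Drop receptor-TF pairs where the receptor
#'   gene is a target of the TF's regulon (applied when regulons are given).
#' @return A `ccci_config` list.
#' @export
ccci_config <- function(min_tf_pval = 0.001,
                        rec_tf_cor_threshold = 0.15,
                        min_rec_percentage = 0.05,
                        sender_mean_scaled_threshold = 0,
                        max_tfs_per_celltype = NULL,
                        max_recs_per_tf = NULL,
                        exclude_regulon_targets = TRUE) {
  stopifnot(
    min_tf_pval > 0, min_tf_pval <= 1,
    rec_tf_cor_threshold >= -1, rec_tf_cor_threshold <= 1,
    min_rec_percentage >= 0, min_rec_percentage <= 1
  )
  if (!is.null(max_tfs_per_celltype)) stopifnot(max_tfs_per_celltype >= 1)
  if (!is.null(max_recs_per_tf)) stopifnot(max_recs_per_tf >= 1)
  structure(
    list(
      min_tf_pval = min_tf_pval,
      rec_tf_cor_threshold = rec_tf_cor_threshold,
      min_rec_percentage = min_rec_percentage,
      sender_mean_scaled_threshold = sender_mean_scaled_threshold,
      max_tfs_per_celltype = max_tfs_per_celltype,
      max_recs_per_tf = max_recs_per_tf,
      exclude_regulon_targets = isTRUE(exclude_regulon_targets)
    ),
    class = "ccci_config"
  )
}

# One-sided (greater) Wilcoxon rank-sum p-value: exact enumeration for
# small tie-free samples, otherwise the normal approximation with tie and
# continuity correction (the same conventions as stats::wilcox.test).
.ranksum_p_greater <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  v <- c(x, y)
  if (n1 + n2 <= 50 && !anyDuplicated(v)) {
    return(stats::wilcox.test(x, y, alternative = "greater",
                              exact = TRUE)$p.value)
  }
  r <- rank(v)
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n <- n1 + n2
  ties <- rle(sort(v))$lengths
  sigma2 <- (n1 * n2 / 12) *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - n1 * n2 / 2 - 0.5 # continuity correction
  stats::pnorm(z / sqrt(sigma2), lower.tail = FALSE)
}

#' Cell-type-enriched transcription factors
#'
#' A TF is enriched in a cell type when its activity scores in that type are
#' higher than in all other cells by a one-sided Wilcoxon rank-sum test at
#' `cfg$min_tf_pval` (strict `<`). Cell types with fewer than 3 cells are
#' skipped with a message.
#'
#' @param tf_scores A [tf_activity()] matrix (cells matching `cell_type`).
#' @param cell_type Per-cell labels.
#' @param cfg A [ccci_config()].
#' @return Data frame with columns `cell_type`, `tf`, `p_value`, one row per
#'   enriched (cell type, TF) pair.
#' @export
enriched_tfs <- function(tf_scores, cell_type, cfg = ccci_config()) {
  scores <- as.matrix(tf_scores)
  if (length(cell_type) != ncol(scores)) {
    .stop_input("cell_type labels must match TF score columns")
  }
  types <- sort(unique(as.character(cell_type)))
  if (length(types) < 2) {
    .stop_input("TF enrichment needs at least 2 cell types (no comparison group)")
  }
  small <- types[vapply(types, function(k) sum(cell_type == k) < 3, logical(1))]
  if (length(small)) {
    message(sprintf(
      "enriched_tfs: skipping cell type(s) with < 3 cells: %s",
      paste(small, collapse = ", ")
    ))
    types <- setdiff(types, small)
  }
  rows <- list()
  for (k in types) {
    in_k <- cell_type == k
    for (tf in rownames(scores)) {
      x <- scores[tf, in_k]
      y <- scores[tf, !in_k]
      p <- .ranksum_p_greater(x, y)
      if (is.finite(p) && p < cfg$min_tf_pval) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell_type = k, tf = tf, p_value = p,
          median_diff = stats::median(x) - stats::median(y),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    cell_type = character(), tf = character(), p_value = numeric(),
    median_diff = numeric(), stringsAsFactors = FALSE
  )
  if (!is.null(cfg$max_tfs_per_celltype) && nrow(out) > 0) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$cell_type), function(i) {
      o <- i[order(out$p_value[i], -out$median_diff[i], out$tf[i])]
      utils::head(o, cfg$max_tfs_per_celltype)
    }))
    out <- out[sort(keep), , drop = FALSE]
  }
  rownames(out) <- NULL
  out[, c("cell_type", "tf", "p_value")]
}

#' Receptor gene to TF activity Spearman correlation
#'
#' Computes Spearman rho between the expression of every receptor component
#' gene in the database and every TF's activity, across all cells supplied
#' (one subject's cells in per-subject mode). Constant vectors give an
#' undefined rho, recorded as `NA`. When `regulons` are provided and
#' `cfg$exclude_regulon_targets` is `TRUE`, pairs where the receptor gene is
#' a target of the TF's regulon are set to `NA` (excluded).
#'
#' @param ds A [cell_dataset()] (already restricted to the cells of
#'   interest).
#' @param tf_scores A [tf_activity()] with the same cells.
#' @param db An [lr_database()].
#' @param regulons Optional named list TF -> targets.
#' @param cfg A [ccci_config()].
#' @return Numeric matrix (receptor genes x TFs) of rho values, `NA` where
#'   undefined or excluded. Receptor genes absent from `ds` are omitted.
#' @export
receptor_tf_correlation <- function(ds, tf_scores, db, regulons = NULL,
                                    cfg = ccci_config()) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(db, "lr_database"))
  scores <- as.matrix(tf_scores)
  if (ncol(scores) != length(ds$cells)) {
    .stop_input("TF scores and dataset must cover the same cells")
  }
  rec_genes <- unique(unlist(db$interactions$receptor_components))
  present <- intersect(rec_genes, ds$genes)
  absent <- setdiff(rec_genes, ds$genes)
  if (length(absent)) {
    message(sprintf(
      "receptor_tf_correlation: %d receptor gene(s) absent from the dataset",
      length(absent)
    ))
  }
  if (length(present) == 0) {
    return(matrix(numeric(), 0, nrow(scores),
                  dimnames = list(character(), rownames(scores))))
  }
  rec_expr <- t(as.matrix(ds$expr[present, , drop = FALSE]))
  rho <- suppressWarnings(
    stats::cor(rec_expr, t(scores), method = "spearman")
  )
  # constant vectors -> NA (cor already yields NA, make it explicit)
  const_rec <- apply(rec_expr, 2, function(v) min(v) == max(v))
  rho[const_rec, ] <- NA_real_
  if (!is.null(regulons) && cfg$exclude_regulon_targets) {
    for (tf in intersect(colnames(rho), names(regulons))) {
      excl <- intersect(rownames(rho), regulons[[tf]])
      rho[excl, tf] <- NA_real_
    }
  }
  rho
}

#' Intracellular receptor-TF linkages
#'
#' A linkage (cell type, TF, receptor) is established when the TF is enriched
#' in the cell type, every component gene of the receptor complex correlates
#' with the TF at `rho >= cfg$rec_tf_cor_threshold`, and every component is
#' expressed by at least `cfg$min_rec_percentage` of the type's cells. The
#' complex-level rho is the minimum over components (conservative AND
#' semantics).
#'
#' @param profiles Output of [profile_cell_types()] for one subject.
#' @param enriched Output of [enriched_tfs()].
#' @param correlations Output of [receptor_tf_correlation()].
#' @param db An [lr_database()].
#' @param cfg A [ccci_config()].
#' @return List with `tfs_rec` (character vector of
#'   `"cell_type|tf|receptor"` keys) and `rec` (`"cell_type|receptor"`
#'   projection).
#' @export
intracellular_linkages <- function(profiles, enriched, correlations, db,
                                   cfg = ccci_config()) {
  receptors <- unique(db$interactions$receptor_name)
  comp_of <- db$interactions$receptor_components[
    match(receptors, db$interactions$receptor_name)
  ]
  names(comp_of) <- receptors
  tfs_rec <- character()
  for (i in seq_len(nrow(enriched))) {
    ct <- enriched$cell_type[i]
    tf <- enriched$tf[i]
    prof <- profiles[[ct]]
    if (is.null(prof) || !(tf %in% colnames(correlations))) next
    cand <- character()
    cand_rho <- numeric()
    for (rec in receptors) {
      comps <- comp_of[[rec]]
      if (!all(comps %in% rownames(correlations))) next
      rhos <- correlations[comps, tf]
      if (anyNA(rhos) || any(rhos < cfg$rec_tf_cor_threshold)) next
      pcts <- prof$pct_expressing[comps]
      if (anyNA(pcts) || any(pcts < cfg$min_rec_percentage)) next
      cand <- c(cand, rec)
      cand_rho <- c(cand_rho, min(rhos))
    }
    if (!is.null(cfg$max_recs_per_tf) && length(cand) > cfg$max_recs_per_tf) {
      o <- order(-cand_rho, cand)
      cand <- cand[o[seq_len(cfg$max_recs_per_tf)]]
    }
    if (length(cand)) {
      tfs_rec <- c(tfs_rec, .join_key(ct, tf, cand))
    }
  }
  tfs_rec <- sort(unique(tfs_rec))
  rec <- sort(unique(vapply(.split_key(tfs_rec), function(f) {
    .join_key(f[1], f[3])
  }, character(1))))
  list(tfs_rec = tfs_rec, rec = rec)
}

#' Ligand sender cell types
#'
#' A cell type sends a ligand when the mean scaled expression of every
#' component gene of the ligand complex is strictly greater than
#' `cfg$sender_mean_scaled_threshold` in that type.
#'
#' @inheritParams intracellular_linkages
#' @return Character vector of `"cell_type|ligand"` keys.
#' @export
ligand_senders <- function(profiles, db, cfg = ccci_config()) {
  ligands <- unique(db$interactions$ligand_name)
  comp_of <- db$interactions$ligand_components[
    match(ligands, db$interactions$ligand_name)
  ]
  names(comp_of) <- ligands
  out <- character()
  for (ct in names(profiles)) {
    ms <- profiles[[ct]]$mean_scaled
    for (lig in ligands) {
      comps <- comp_of[[lig]]
      if (!all(comps %in% names(ms))) next
      if (all(ms[comps] > cfg$sender_mean_scaled_threshold)) {
        out <- c(out, .join_key(ct, lig))
      }
    }
  }
  sort(unique(out))
}

#' Per-subject signaling inference
#'
#' Composes TF enrichment, receptor-TF correlation, intracellular linkage
#' calling and ligand sender identification into the full set of linkages
#' for one subject: an intercellular linkage
#' `(recipient, receptor, ligand, sender)` is assembled for every database
#' interaction whose receptor is active in the recipient cell type and whose
#' ligand is sent by the sender cell type (autocrine pairs allowed).
#'
#' @param ds A [cell_dataset()].
#' @param tf_scores A [tf_activity()] covering the dataset's cells.
#' @param db An [lr_database()].
#' @param cfg A [ccci_config()].
#' @param subject Subject id; may be omitted when `ds` holds one subject.
#' @param regulons Optional regulon list for receptor-target exclusion.
#' @return A `subject_linkages` object: list with `subject`, `cell_types`,
#'   and sorted character-key sets `tfs`, `rec`, `incoming_lig`, `tfs_rec`,
#'   `cl_rec_lig`.
#' @export
infer_subject <- function(ds, tf_scores, db, cfg = ccci_config(),
                          subject = NULL, regulons = NULL) {
  stopifnot(inherits(ds, "cell_dataset"))
  subs <- unique(ds$subject)
  if (is.null(subject)) {
    if (length(subs) != 1) {
      .stop_input("subject must be given when the dataset holds several subjects")
    }
    subject <- subs
  }
  if (!(subject %in% subs)) .stop_input(sprintf("unknown subject: %s", subject))
  idx <- which(ds$subject == subject)
  sub <- if (length(idx) == length(ds$cells)) ds else subset_cells(ds, idx)
  scores <- as.matrix(tf_scores)
  sc_idx <- match(sub$cells, colnames(scores))
  if (anyNA(sc_idx)) {
    .stop_input("TF scores do not cover all of the subject's cells")
  }
  scores <- scores[, sc_idx, drop = FALSE]

  profiles <- profile_cell_types(sub, subject)
  enriched <- enriched_tfs(scores, sub$cell_type, cfg)
  correlations <- receptor_tf_correlation(sub, scores, db,
                                          regulons = regulons, cfg = cfg)
  intra <- intracellular_linkages(profiles, enriched, correlations, db, cfg)
  senders <- ligand_senders(profiles, db, cfg)

  sender_set <- senders
  rec_set <- intra$rec
  cl_rec_lig <- character()
  for (i in seq_len(nrow(db$interactions))) {
    rec <- db$interactions$receptor_name[i]
    lig <- db$interactions$ligand_name[i]
    for (ct_r in names(profiles)) {
      if (!(.join_key(ct_r, rec) %in% rec_set)) next
      for (ct_s in names(profiles)) {
        if (.join_key(ct_s, lig) %in% sender_set) {
          cl_rec_lig <- c(cl_rec_lig, .join_key(ct_r, rec, lig, ct_s))
        }
      }
    }
  }
  cl_rec_lig <- sort(unique(cl_rec_lig))
  incoming_lig <- sort(unique(vapply(.split_key(cl_rec_lig), function(f) {
    .join_key(f[1], f[3])
  }, character(1))))
  structure(
    list(
      subject = subject,
      cell_types = names(profiles),
      tfs = sort(unique(.join_key(enriched$cell_type, enriched$tf))),
      rec = rec_set,
      incoming_lig = incoming_lig,
      tfs_rec = intra$tfs_rec,
      cl_rec_lig = cl_rec_lig
    ),
    class = "subject_linkages"
  )
}

#' @export
print.subject_linkages <- function(x, ...) {
  cat(sprintf(
    "subject_linkages [%s]: %d tfs, %d rec, %d tfs_rec, %d cl_rec_lig\n",
    x$subject, length(x$tfs), length(x$rec), length(x$tfs_rec),
    length(x$cl_rec_lig)
  ))
  invisible(x)
}
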