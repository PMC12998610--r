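#' Bootstrap plan for pseudo-replicates
#'
#' Describes how to resample cells of one condition into bootstrap
#' pseudo-subjects so that the differential cell signaling test can be
#' applied to pooled designs lacking biological replicates.
#'
#' @param condition Condition label to resample from.
#' @param n_boot Number of pseudo-subjects (default 20).
#' @param stratify_by_cell_type Resample within cell-type strata, preserving
#'   per-type cell counts (default `TRUE`).
#' @param sample_fraction Fraction of each stratum drawn (with replacement)
#'   per pseudo-subject (default 1).
#' @param seed Integer seed; per-pseudo-subject streams are derived
#'   deterministically from `(seed, i)`.
#' @return A `bootstrap_plan` list.
#' @export
bootstrap_plan <- function(condition, n_boot = 20,
                           stratify_by_cell_type = TRUE,
                           sample_fraction = 1, seed = 1L) {
  stopifnot(.is_count(n_boot), n_boot >= 2,
            sample_fraction > 0, sample_fraction <= 1)
  structure(
    list(
      condition = condition, n_boot = as.integer(n_boot),
      stratify_by_cell_type = isTRUE(stratify_by_cell_type),
      sample_fraction = sample_fraction, seed = as.integer(seed)
    ),
    class = "bootstrap_plan"
  )
}

#' Generate bootstrap pseudo-subjects from one condition
#'
#' Draws cells with replacement (within each cell-type stratum when
#' stratified) from the condition's cells; each pseudo-subject gets subject
#' id `"{condition}_boot{i}"` and position-suffixed cell ids so duplicated
#' source cells remain distinguishable. The mapping back to source cells is
#' kept in the `"source_cells"` attribute of each pseudo-subject so per-cell
#' TF scores can be carried over.
#'
#' @param ds A [cell_dataset()] whose `condition` labels include the plan's
#'   condition.
#' @param plan A [bootstrap_plan()].
#' @return List of `n_boot` [cell_dataset()] pseudo-subjects.
#' @export
make_bootstraps <- function(ds, plan) {
  stopifnot(inherits(ds, "cell_dataset"), inherits(plan, "bootstrap_plan"))
  if (is.null(ds$condition)) {
    .stop_input("dataset has no condition labels")
  }
  pool <- which(ds$condition == plan$condition)
  if (length(pool) == 0) {
    .stop_input(sprintf("condition not present: %s", plan$condition))
  }
  ct <- ds$cell_type[pool]
  strata <- if (plan$stratify_by_cell_type) {
    split(pool, ct)
  } else {
    list(all = pool)
  }
  small <- names(strata)[vapply(strata, length, integer(1)) < 2]
  if (length(small)) {
    .stop_input(sprintf(
      "cell type(s) with fewer than 2 cells in condition %s: %s",
      plan$condition, paste(small, collapse = ", ")
    ))
  }
  lapply(seq_len(plan$n_boot), function(i) {
    old <- if (exists(".Random.seed", .GlobalEnv)) {
      get(".Random.seed", .GlobalEnv)
    } else NULL
    set.seed(.mix_seed(plan$seed, i))
    draw <- unlist(lapply(strata, function(idx) {
      size <- max(1L, as.integer(round(plan$sample_fraction * length(idx))))
      sample(idx, size, replace = TRUE)
    }), use.names = FALSE)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    subj <- sprintf("%s_boot%d", plan$condition, i)
    src <- ds$cells[draw]
    expr <- ds$expr[, draw, drop = FALSE]
    colnames(expr) <- sprintf("%s.%d", src, seq_along(draw))
    out <- cell_dataset(
      expr,
      cell_type = ds$cell_type[draw],
      subject = rep(subj, length(draw)),
      condition = rep(plan$condition, length(draw))
    )
    attr(out, "source_cells") <- src
    out
  })
}

#' Bootstrap linkage summary for pooled conditions
#'
#' Builds `n_boot` pseudo-subjects per condition, runs [infer_subject()] on
#' each (per-cell TF scores are carried over from the source cells), and
#' collates everything into a linkage summary with a `condition` metadata
#' variable, ready for [test_differential_linkages()].
#'
#' @param ds A [cell_dataset()] with condition labels.
#' @param conditions Character vector of two or more condition labels.
#' @param tf_scores A [tf_activity()] covering `ds`'s cells.
#' @param db An [lr_database()].
#' @param cfg A [ccci_config()].
#' @param n_boot Bootstraps per condition (default 20).
#' @param seed Integer seed.
#' @param sample_fraction,stratify_by_cell_type Passed to
#'   [bootstrap_plan()].
#' @return A `linkage_summary` with `sum(n_boot)` pseudo-subjects.
#' @export
bootstrap_summary <- function(ds, conditions, tf_scores, db,
                              cfg = ccci_config(), n_boot = 20, seed = 1L,
                              sample_fraction = 1,
                              stratify_by_cell_type = TRUE) {
  stopifnot(inherits(ds, "cell_dataset"))
  if (length(conditions) < 2) {
    .stop_input("need at least 2 conditions for a differential comparison")
  }
  absent <- setdiff(conditions, unique(ds$condition))
  if (length(absent)) {
    .stop_input(sprintf(
      "condition(s) not present: %s", paste(absent, collapse = ", ")
    ))
  }
  scores <- as.matrix(tf_scores)
  entries <- list()
  meta_rows <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[ci]
    plan <- bootstrap_plan(cond,
      n_boot = n_boot, seed = .mix_seed(seed, ci),
      sample_fraction = sample_fraction,
      stratify_by_cell_type = stratify_by_cell_type
    )
    boots <- make_bootstraps(ds, plan)
    for (b in boots) {
      src <- attr(b, "source_cells")
      sc <- scores[, match(src, colnames(scores)), drop = FALSE]
      colnames(sc) <- b$cells
      subj <- b$subject[1]
      entries[[subj]] <- infer_subject(b, tf_activity(sc, "external"), db,
                                       cfg = cfg, subject = subj)
      meta_rows[[subj]] <- data.frame(
        subject = subj, condition = cond, stringsAsFactors = FALSE
      )
    }
  }
  build_summary(entries, do.call(rbind, meta_rows))
}
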