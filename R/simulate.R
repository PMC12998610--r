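# Two-condition synthetic cohorts with ground-truth differential linkages,
# and the sensitivity/specificity benchmark of the differential cell
# signaling test over sample-size and cell-count grids.

.SIM_CONDS <- c("C1", "C2")
.SIM_GENES <- c("L1", "L2", "R1", "R2")

.default_expr_prob <- function(background = 0.02) {
  list(
    C1 = list(
      A = c(L1 = 0.6, L2 = 0.5, R1 = background, R2 = background),
      B = c(L1 = 0.1, L2 = background, R1 = 0.5, R2 = 0.5)
    ),
    C2 = list(
      A = c(L1 = 0.1, L2 = 0.5, R1 = background, R2 = background),
      B = c(L1 = 0.6, L2 = background, R1 = 0.5, R2 = 0.5)
    )
  )
}

#' Configuration of the two-cell-type signaling simulation
#'
#' Emulates a cohort with two cell types (A, B), two ligand-receptor
#' cascades (L1-R1, L2-R2) and two experimental conditions (C1, C2) whose
#' per-cell expression probabilities differ: L1 is sent predominantly by A
#' in C1 and by B in C2 (creating the two condition-dependent interactions),
#' while the L2-R2 interaction from A is equally likely in both conditions.
#' TF activity is simulated directly as a noisy clipped-linear function of
#' the matched receptor's expression, so the benchmark isolates the
#' linkage-calling and testing stack from regulon scoring.
#'
#' @param n_samples_per_condition Samples (subjects) per condition.
#' @param n_cells Named counts `c(A = ..., B = ...)` per sample (>= 10).
#' @param expr_prob Nested list condition -> cell type -> named Bernoulli
#'   probabilities for `L1, L2, R1, R2`.
#' @param expr_level `c(meanlog, sdlog)` of the lognormal magnitude given
#'   expression.
#' @param tf_coupling Slope linking receptor expression to the matched TF's
#'   activity.
#' @param tf_noise_sd Gaussian noise SD on TF activity (> 0).
#' @param background_prob Expression probability of background genes.
#' @param n_background_genes Number of background genes (default 50).
#' @param seed Integer seed; every sample is deterministic under
#'   `(seed, condition, sample index)`.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_samples_per_condition = 15,
                              n_cells = c(A = 500, B = 100),
                              expr_prob = .default_expr_prob(),
                              expr_level = c(meanlog = 0, sdlog = 0.5),
                              tf_coupling = 0.5,
                              tf_noise_sd = 0.5,
                              background_prob = 0.3,
                              n_background_genes = 50,
                              seed = 1L) {
  stopifnot(
    .is_count(n_samples_per_condition), n_samples_per_condition >= 1,
    all(c("A", "B") %in% names(n_cells)), all(n_cells >= 10),
    tf_noise_sd > 0, .is_count(n_background_genes)
  )
  for (cond in .SIM_CONDS) {
    for (k in c("A", "B")) {
      p <- expr_prob[[cond]][[k]]
      if (!all(.SIM_GENES %in% names(p)) || any(p < 0) || any(p > 1)) {
        .stop_input("expr_prob must give [0,1] probabilities for L1, L2, R1, R2")
      }
    }
  }
  structure(
    list(
      n_samples_per_condition = as.integer(n_samples_per_condition),
      n_cells = n_cells,
      expr_prob = expr_prob,
      expr_level = expr_level,
      tf_coupling = tf_coupling,
      tf_noise_sd = tf_noise_sd,
      background_prob = background_prob,
      n_background_genes = as.integer(n_background_genes),
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Ligand-receptor database of the simulated system
#'
#' @return An [lr_database()] with the two single-gene pairs L1-R1 and
#'   L2-R2.
#' @export
simulation_lr_database <- function() {
  lr_database(
    id = c("L1_R1", "L2_R2"),
    ligand_name = c("L1", "L2"),
    receptor_name = c("R1", "R2"),
    ligand_components = list("L1", "L2"),
    receptor_components = list("R1", "R2"),
    source = "simulation"
  )
}

# One simulated sample: expression + matched TF activity.
.simulate_sample <- function(cfg, condition, sample_index) {
  set.seed(.mix_seed(cfg$seed, match(condition, .SIM_CONDS), sample_index))
  n_a <- as.integer(cfg$n_cells[["A"]])
  n_b <- as.integer(cfg$n_cells[["B"]])
  n <- n_a + n_b
  ct <- c(rep("A", n_a), rep("B", n_b))
  n_bg <- cfg$n_background_genes
  genes <- c(.SIM_GENES, if (n_bg > 0) sprintf("BG%03d", seq_len(n_bg)))
  prob <- matrix(cfg$background_prob, nrow = length(genes), ncol = 2,
                 dimnames = list(genes, c("A", "B")))
  prob[.SIM_GENES, "A"] <- cfg$expr_prob[[condition]]$A[.SIM_GENES]
  prob[.SIM_GENES, "B"] <- cfg$expr_prob[[condition]]$B[.SIM_GENES]
  p_cells <- prob[, ifelse(ct == "A", 1, 2)]
  on <- matrix(stats::rbinom(length(p_cells), 1, p_cells),
               nrow = length(genes))
  magn <- matrix(stats::rlnorm(length(p_cells), cfg$expr_level[["meanlog"]],
                               cfg$expr_level[["sdlog"]]),
                 nrow = length(genes))
  expr <- on * magn
  subj <- sprintf("%s_s%02d", condition, sample_index)
  dimnames(expr) <- list(genes, sprintf("%s_c%04d", subj, seq_len(n)))
  ds <- cell_dataset(expr,
    cell_type = ct,
    subject = rep(subj, n),
    condition = rep(condition, n)
  )
  # TF activity is a clipped noisy linear function of the matched receptor's
  # expression, so the receptor-TF association per expressing cell does not
  # depend on how many cells express the receptor
  raw <- cfg$tf_coupling * expr[c("R1", "R2"), , drop = FALSE] +
    matrix(stats::rnorm(2 * n, 0, cfg$tf_noise_sd), nrow = 2)
  tf <- matrix(pmin(1, pmax(0, raw)), nrow = 2,
               dimnames = list(c("TF1", "TF2"), colnames(expr)))
  list(ds = ds, tf = tf_activity(tf, method = "external"))
}

#' Simulate one condition's cohort
#'
#' @param cfg A [simulation_config()].
#' @param condition `"C1"` or `"C2"`.
#' @return List of `n_samples_per_condition` elements, each a list with
#'   `ds` (a [cell_dataset()], one subject) and `tf` (a [tf_activity()]).
#' @export
simulate_cohort <- function(cfg, condition = c("C1", "C2")) {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "simulation_config"))
  lapply(seq_len(cfg$n_samples_per_condition), function(i) {
    .simulate_sample(cfg, condition, i)
  })
}

#' Ground truth of the default simulated network
#'
#' @return List with `differential` (the C1-specific paracrine interaction
#'   `B|R1|L1|A` and the C2-specific autocrine interaction `B|R1|L1|B`) and
#'   `null_linkages` (the condition-independent `B|R2|L2|A`).
#' @export
default_truth <- function() {
  list(
    differential = c(
      .join_key("B", "R1", "L1", "A"),
      .join_key("B", "R1", "L1", "B")
    ),
    null_linkages = .join_key("B", "R2", "L2", "A")
  )
}

#' Sensitivity and specificity of one differential-test run
#'
#' A truth linkage counts as detected when it appears in the result table
#' with `p_adj < alpha`; linkages never inferred in any subject count as not
#' detected.
#'
#' @param results A [test_differential_linkages()] table.
#' @param truth A [default_truth()]-style list.
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Named numeric `c(sensitivity, specificity)`.
#' @export
evaluate_run <- function(results, truth, alpha = 0.05) {
  sig <- results$linkage[results$p_adj < alpha]
  sens <- if (length(truth$differential)) {
    mean(truth$differential %in% sig)
  } else {
    NA_real_
  }
  spec <- if (length(truth$null_linkages)) {
    1 - mean(truth$null_linkages %in% sig)
  } else {
    NA_real_
  }
  c(sensitivity = sens, specificity = spec)
}

# Run per-sample inference + DCST for one simulated cohort pair and return
# the detection indicator for each truth linkage.
.run_cohort_pair <- function(cfg, db, ccci_cfg, truth, alpha,
                             recipient = "B") {
  entries <- list()
  meta_rows <- list()
  for (cond in .SIM_CONDS) {
    for (samp in simulate_cohort(cfg, cond)) {
      subj <- samp$ds$subject[1]
      entries[[subj]] <- infer_subject(samp$ds, samp$tf, db, cfg = ccci_cfg,
                                       subject = subj)
      meta_rows[[subj]] <- data.frame(
        subject = subj, condition = cond, stringsAsFactors = FALSE
      )
    }
  }
  s <- build_summary(entries, do.call(rbind, meta_rows))
  res <- test_differential_linkages(s, "condition", "cl_rec_lig", recipient,
                                    reference_group = "C1")
  sig <- res$linkage[res$p_adj < alpha]
  all_truth <- c(truth$differential, truth$null_linkages)
  stats::setNames(all_truth %in% sig, all_truth)
}

# Redraw each simulated-signal probability uniformly within +/- width of its
# default, clipped to [0.01, 0.95]. Entries equal across conditions share
# one draw so condition-independent interactions remain truly null;
# background-level entries are left untouched.
.jitter_expr_prob <- function(expr_prob, width = 0.1, floor_prob = 0.05) {
  out <- expr_prob
  for (k in c("A", "B")) {
    for (g in .SIM_GENES) {
      p1 <- expr_prob$C1[[k]][[g]]
      p2 <- expr_prob$C2[[k]][[g]]
      draw <- function(p) {
        if (p <= floor_prob) return(p)
        min(0.95, max(0.01, stats::runif(1, p - width, p + width)))
      }
      if (p1 == p2) {
        v <- draw(p1)
        out$C1[[k]][[g]] <- v
        out$C2[[k]][[g]] <- v
      } else {
        out$C1[[k]][[g]] <- draw(p1)
        out$C2[[k]][[g]] <- draw(p2)
      }
    }
  }
  out
}

#' Benchmark DCST sensitivity and specificity on simulated cohorts
#'
#' For each of `n_init` initializations, the condition-dependent expression
#' probabilities are jittered around the base configuration; for each grid
#' point, `n_rep_per_init` cohort pairs are simulated, run through
#' per-sample inference and the differential test (recipient cell type B,
#' intercellular class, reference C1), and the detection rate of every
#' ground-truth linkage is recorded. Sensitivity and specificity are
#' averaged within each initialization, then summarized as mean and SD over
#' initializations.
#'
#' @param base_cfg A [simulation_config()].
#' @param vary `"n_samples"` (samples per condition) or `"n_cells"` (cells
#'   in cluster B).
#' @param grid Counts to sweep.
#' @param n_init Initializations of the simulation parameters (default 10).
#' @param n_rep_per_init Cohort pairs per initialization and grid point
#'   (default 25).
#' @param alpha Detection criterion: BH-adjusted p < `alpha`.
#' @param ccci_cfg Inference configuration.
#' @param seed Integer master seed.
#' @return A `benchmark_result` data frame, one row per grid point, with
#'   mean/SD sensitivity and specificity plus per-linkage detection rates
#'   (columns `det.<linkage>` / `det_sd.<linkage>`); the full per-init
#'   detection array is kept in the `"detection"` attribute.
#' @export
run_benchmark <- function(base_cfg, vary = c("n_samples", "n_cells"),
                          grid, n_init = 10, n_rep_per_init = 25,
                          alpha = 0.05, ccci_cfg = ccci_config(),
                          seed = 1L) {
  vary <- match.arg(vary)
  stopifnot(inherits(base_cfg, "simulation_config"), length(grid) >= 1)
  db <- simulation_lr_database()
  truth <- default_truth()
  all_truth <- c(truth$differential, truth$null_linkages)
  n_diff <- length(truth$differential)
  detection <- array(
    NA_real_,
    dim = c(n_init, length(all_truth), length(grid)),
    dimnames = list(NULL, all_truth, as.character(grid))
  )
  for (init in seq_len(n_init)) {
    set.seed(.mix_seed(seed, 7001, init))
    probs <- .jitter_expr_prob(base_cfg$expr_prob)
    for (gi in seq_along(grid)) {
      cfg <- base_cfg
      cfg$expr_prob <- probs
      if (vary == "n_samples") {
        cfg$n_samples_per_condition <- as.integer(grid[gi])
      } else {
        cfg$n_cells[["B"]] <- as.integer(grid[gi])
      }
      hits <- matrix(0, nrow = n_rep_per_init, ncol = length(all_truth))
      for (rep_i in seq_len(n_rep_per_init)) {
        cfg$seed <- .mix_seed(seed, init, gi, rep_i)
        hits[rep_i, ] <- .run_cohort_pair(cfg, db, ccci_cfg, truth, alpha)
      }
      detection[init, , gi] <- colMeans(hits)
    }
  }
  sens_init <- apply(detection[, seq_len(n_diff), , drop = FALSE],
                     c(1, 3), mean)
  spec_init <- 1 - apply(
    detection[, -seq_len(n_diff), , drop = FALSE], c(1, 3), mean
  )
  out <- data.frame(
    grid = grid,
    mean_sensitivity = colMeans(sens_init),
    sd_sensitivity = apply(sens_init, 2, stats::sd),
    mean_specificity = colMeans(spec_init),
    sd_specificity = apply(spec_init, 2, stats::sd)
  )
  for (li in seq_along(all_truth)) {
    out[[paste0("det.", all_truth[li])]] <-
      apply(detection[, li, , drop = FALSE], 3, mean)
    out[[paste0("det_sd.", all_truth[li])]] <-
      apply(detection[, li, , drop = FALSE], 3, stats::sd)
  }
  rownames(out) <- NULL
  attr(out, "detection") <- detection
  attr(out, "vary") <- vary
  class(out) <- c("benchmark_result", "data.frame")
  out
}
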