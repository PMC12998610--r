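# Differential cell signaling test: exact tests on linkage occurrence
# contingency tables, odds ratios, and BH adjustment within the family of
# unique linkages incoming to one recipient cell type.

# Relative tolerance when comparing table probabilities to the observed
# probability in the two-sided "probability mass <= observed" rule.
.P_TOL <- 1e-7

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of hypergeometric
#' probabilities (margins fixed) of all tables whose probability does not
#' exceed that of the observed table (within relative tolerance 1e-7). The
#' odds ratio is the conditional maximum-likelihood estimate under the
#' noncentral hypergeometric model; boundary tables give 0 or `Inf`, and a
#' zero margin gives an undefined (`NA`) odds ratio with p = 1.
#'
#' @param counts 2x2 matrix of non-negative integers; rows = groups, columns
#'   = (with linkage, without linkage).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`,
#'   referring to the odds of the first row.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(counts,
                             alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) .stop_input("counts must be a 2x2 matrix")
  if (any(counts < 0) || any(counts != round(counts))) {
    .stop_input("counts must be non-negative integers")
  }
  a <- counts[1, 1]
  m1 <- sum(counts[1, ]) # size of group 1
  m2 <- sum(counts[2, ])
  c1 <- sum(counts[, 1]) # subjects with the linkage
  n <- m1 + m2
  if (m1 == 0 || m2 == 0 || c1 == 0 || c1 == n) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  kmin <- max(0, c1 - m2)
  kmax <- min(c1, m1)
  support <- kmin:kmax
  probs <- stats::dhyper(support, m1, m2, c1)
  p_obs <- probs[support == a]
  p_value <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + .P_TOL)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a])
  )
  p_value <- min(1, p_value)
  # conditional MLE of the odds ratio: solve E_psi[A] = a
  odds_ratio <- if (a == kmax) {
    Inf
  } else if (a == kmin) {
    0
  } else {
    lw0 <- stats::dhyper(support, m1, m2, c1, log = TRUE)
    mean_at <- function(log_psi) {
      lw <- lw0 + support * log_psi
      w <- exp(lw - max(lw))
      sum(support * w) / sum(w) - a
    }
    exp(stats::uniroot(mean_at, c(-40, 40), tol = 1e-10)$root)
  }
  list(odds_ratio = odds_ratio, p_value = p_value)
}

# Enumerate all r x 2 tables with the given row sums and first-column total.
# Returns the log-probability of each under the multivariate hypergeometric
# distribution; used by fisher_exact_rx2.
.rx2_log_probs <- function(row_sums, c1) {
  r <- length(row_sums)
  n <- sum(row_sums)
  denom <- lchoose(n, c1)
  # recursively build first-column vectors k with sum(k) = c1, 0 <= k_i <= s_i
  out <- new.env()
  out$lp <- numeric(0)
  out$keys <- list()
  recurse <- function(i, remaining, acc, lp_acc) {
    if (i == r) {
      if (remaining <= row_sums[r]) {
        k <- c(acc, remaining)
        out$lp <- c(out$lp, lp_acc + lchoose(row_sums[r], remaining) - denom)
        out$keys[[length(out$keys) + 1L]] <- k
      }
      return(invisible())
    }
    tail_max <- sum(row_sums[(i + 1):r])
    lo <- max(0, remaining - tail_max)
    hi <- min(row_sums[i], remaining)
    if (lo > hi) return(invisible())
    for (k_i in lo:hi) {
      recurse(i + 1, remaining - k_i, c(acc, k_i),
              lp_acc + lchoose(row_sums[i], k_i))
    }
  }
  recurse(1, c1, integer(0), 0)
  list(log_probs = out$lp, tables = out$keys)
}

#' Freeman-Halton exact test for an r x 2 table
#'
#' Generalizes the two-sided Fisher test to three or more groups: the
#' p-value sums the multivariate hypergeometric probabilities (margins
#' fixed) of all tables at most as probable as the observed one (relative
#' tolerance 1e-7). Groups with zero subjects are dropped before testing; no
#' odds ratio is defined for r > 2.
#'
#' @param counts r x 2 matrix of non-negative integers (r >= 2).
#' @param max_tables Enumeration budget; exceeding it raises an error
#'   suggesting collapsing groups.
#' @return List with `p_value` (and `odds_ratio = NA`).
#' @export
fisher_exact_rx2 <- function(counts, max_tables = 1e7) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 2 || nrow(counts) < 2) {
    .stop_input("counts must be an r x 2 matrix with r >= 2")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    .stop_input("counts must be non-negative integers")
  }
  counts <- counts[rowSums(counts) > 0, , drop = FALSE]
  r <- nrow(counts)
  if (r < 2) return(list(odds_ratio = NA_real_, p_value = 1))
  row_sums <- rowSums(counts)
  c1 <- sum(counts[, 1])
  if (c1 == 0 || c1 == sum(row_sums)) {
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  budget <- prod(pmin(row_sums, c1) + 1)
  if (budget > max_tables) {
    .stop_input(sprintf(
      "enumeration budget exceeded (%.3g candidate tables); collapse groups",
      budget
    ))
  }
  enum <- .rx2_log_probs(row_sums, c1)
  lp_obs <- sum(lchoose(row_sums, counts[, 1])) - lchoose(sum(row_sums), c1)
  p <- sum(exp(enum$log_probs[
    enum$log_probs <= lp_obs + log1p(.P_TOL)
  ]))
  list(odds_ratio = NA_real_, p_value = min(1, p))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`:
#' `q_(i) = min_{j >= i} min(1, m * p_(j) / j)` mapped back to input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    .stop_input("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential cell signaling test over a linkage summary
#'
#' Tests, for every unique linkage of one class incoming to one recipient
#' cell type, whether the linkage's presence across subjects depends on a
#' grouping variable. Two group levels use [fisher_exact_2x2()] with rows
#' ordered (reference, alternative); three or more use [fisher_exact_rx2()].
#' Adjusted p-values are Benjamini-Hochberg within exactly this family (all
#' unique linkages of the class incoming to the cell type); linkages absent
#' from every subject are not tested.
#'
#' @param s A [build_summary()] result.
#' @param group_var Metadata variable to compare across.
#' @param linkage_class One of `"tfs"`, `"rec"`, `"incoming_lig"`,
#'   `"tfs_rec"`, `"cl_rec_lig"`.
#' @param cell_type Recipient cell type whose incoming linkages are tested.
#' @param reference_group Optional reference level (first row of each
#'   table); defaults to the first level in metadata order.
#' @param subjects Optional subject subset.
#' @param alpha Unused in the computation; kept for callers that record it.
#' @return A `dcst_result` data frame with one row per tested linkage:
#'   linkage key, class, cell type, per-group with/without counts,
#'   conditional-MLE odds ratio, naive cross-product odds ratio, `p_value`
#'   and `p_adj`, sorted by p-value then linkage key.
#' @export
test_differential_linkages <- function(s, group_var, linkage_class,
                                       cell_type, reference_group = NULL,
                                       subjects = NULL, alpha = 0.05) {
  stopifnot(inherits(s, "linkage_summary"))
  if (!(group_var %in% names(s$meta))) {
    .stop_input(sprintf("unknown grouping variable: %s", group_var))
  }
  if (!(linkage_class %in% .LINKAGE_CLASSES)) {
    .stop_input(sprintf("unknown linkage class: %s", linkage_class))
  }
  subjects <- subjects %||% s$subjects
  groups <- as.character(s$meta[[group_var]][match(subjects, s$subjects)])
  levels <- unique(groups)
  if (length(levels) < 2) {
    .stop_input("grouping variable must have at least 2 levels among included subjects")
  }
  if (!is.null(reference_group)) {
    if (!(reference_group %in% levels)) {
      .stop_input(sprintf("reference group %s not among levels", reference_group))
    }
    levels <- c(reference_group, setdiff(levels, reference_group))
  }
  # family: unique linkages of this class incoming to this cell type,
  # restricted to the included subjects
  keys <- unique(unlist(lapply(s$linkages[subjects], `[[`, linkage_class)))
  if (length(keys)) {
    first <- vapply(.split_key(keys), `[[`, character(1), 1)
    keys <- sort(keys[first == cell_type])
  } else {
    keys <- character()
  }
  member <- lapply(s$linkages[subjects], `[[`, linkage_class)
  rows <- lapply(keys, function(key) {
    has <- vapply(member, function(set) key %in% set, logical(1))
    tab <- t(vapply(levels, function(g) {
      c(sum(has[groups == g]), sum(!has[groups == g]))
    }, numeric(2)))
    if (length(levels) == 2) {
      ft <- fisher_exact_2x2(tab)
      or <- ft$odds_ratio
      a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
      or_cross <- (a * d) / (b * c2)
    } else {
      ft <- fisher_exact_rx2(tab)
      or <- NA_real_
      or_cross <- NA_real_
    }
    cnt <- as.vector(t(tab))
    names(cnt) <- as.vector(t(outer(levels, c("n_with", "n_without"),
                                    function(g, w) paste(w, g, sep = "."))))
    c(
      list(linkage = key, linkage_class = linkage_class,
           cell_type = cell_type),
      as.list(cnt),
      list(odds_ratio = or, odds_ratio_cross = or_cross,
           p_value = ft$p_value)
    )
  })
  if (length(rows) == 0) {
    out <- data.frame(
      linkage = character(), linkage_class = character(),
      cell_type = character(), odds_ratio = numeric(),
      odds_ratio_cross = numeric(), p_value = numeric(), p_adj = numeric(),
      stringsAsFactors = FALSE
    )
    class(out) <- c("dcst_result", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)
  }))
  out$p_adj <- bh_adjust(out$p_value)
  out <- out[order(out$p_value, out$linkage), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dcst_result", "data.frame")
  attr(out, "group_var") <- group_var
  attr(out, "groups") <- levels
  out
}

#' Write a DCST result table as TSV
#'
#' Infinite odds ratios are rendered as `Inf` and undefined values as `NA`;
#' [read_results()] restores them, so a round trip is lossless.
#'
#' @param res A [test_differential_linkages()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
render_results <- function(res, path) {
  ok <- tryCatch(
    {
      utils::write.table(as.data.frame(res), path,
        sep = "\t", quote = FALSE,
        row.names = FALSE, na = "NA"
      )
      TRUE
    },
    error = function(e) FALSE
  )
  if (!ok) .stop_input(sprintf("cannot write results to %s", path))
  invisible(path)
}

#' @rdname render_results
#' @export
read_results <- function(path) {
  out <- utils::read.table(path,
    sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  class(out) <- c("dcst_result", "data.frame")
  out
}
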