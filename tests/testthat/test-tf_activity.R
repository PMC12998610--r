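mk_rank_dataset <- function(values, genes = paste0("g", seq_along(values))) {
  expr <- matrix(values, ncol = 1, dimnames = list(genes, "cell1"))
  cell_dataset(expr, cell_type = "A", subject = "s1")
}

test_that("recovery-curve scores match hand evaluation", {
  # 10 genes ranked g1 (highest) .. g10; t = 5
  ds <- mk_rank_dataset(10:1)
  # two targets at ranks 4 and 5: R = (0,0,0,1,2), score = 3/9
  s <- aucell_score(ds, list(TFa = c("g4", "g5")), top_frac = 0.5)
  expect_equal(unname(s["TFa", "cell1"]), 1 / 3)
  # targets occupying the top ranks score exactly 1
  s2 <- aucell_score(ds, list(TFb = c("g1", "g2")), top_frac = 0.5)
  expect_equal(unname(s2["TFb", "cell1"]), 1)
  # no target in the top t ranks scores 0
  s3 <- aucell_score(ds, list(TFc = c("g9", "g10")), top_frac = 0.5)
  expect_equal(unname(s3["TFc", "cell1"]), 0)
})

test_that("scores are rank-based: invariant under monotone transforms", {
  set.seed(5)
  vals <- sort(runif(30), decreasing = TRUE) # distinct, no tie ambiguity
  ds1 <- mk_rank_dataset(vals)
  ds2 <- mk_rank_dataset(vals^3)
  regs <- list(T1 = c("g2", "g9", "g17"), T2 = c("g1", "g25"))
  expect_equal(
    unclass(aucell_score(ds1, regs, top_frac = 0.3)),
    unclass(aucell_score(ds2, regs, top_frac = 0.3))
  )
})

test_that("regulons without targets in the dataset are dropped, scores bounded", {
  ds <- mk_rank_dataset(5:1)
  expect_warning(
    s <- aucell_score(ds, list(T1 = "g1", T2 = "zzz"), top_frac = 0.6),
    "no targets"
  )
  expect_equal(rownames(s), "T1")
  expect_true(all(s >= 0 & s <= 1))
  expect_error(aucell_score(ds, list()), "empty regulon",
               class = "linksig_input_error")
})

test_that("external TF matrices load with clipping and orientation handling", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "tf.csv")
  tab <- data.frame(tf = c("T1", "T2"), c1 = c(0.2, 1.0000001),
                    c2 = c(0.5, 0), c3 = c(1, 0.3))
  write.csv(tab, p, row.names = FALSE)
  expect_message(m <- load_tf_scores(p), "clipped 1")
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(unname(m["T2", "c1"]), 1)

  pt <- file.path(dir, "tf_t.csv")
  tabt <- data.frame(cell = c("c1", "c2", "c3"), T1 = c(0.2, 0.5, 1),
                     T2 = c(1, 0, 0.3))
  write.csv(tabt, pt, row.names = FALSE)
  mt <- load_tf_scores(pt, orientation = "tfs_in_cols")
  expect_equal(unclass(mt)[, ], unclass(m)[, ])
})

test_that("accessibility is per cell type with an inclusive threshold", {
  ga <- matrix(0, nrow = 2, ncol = 20,
               dimnames = list(c("gX", "gY"), paste0("c", 1:20)))
  ct <- rep(c("k", "other"), each = 10)
  ga["gX", 1] <- 1 # 1 of 10 type-k cells: exactly 10%
  ga["gY", 11:14] <- 1 # only in the other type
  mask <- compute_accessibility(ga, ct, min_frac = 0.10)
  expect_true("gX" %in% mask$k)
  expect_false("gY" %in% mask$k)
  expect_true("gY" %in% mask$other)
  expect_false("gX" %in% mask$other)
})

test_that("regulon pruning intersects targets and drops emptied regulons", {
  regs <- list(T1 = c("g1", "g2", "g3"), T2 = c("g9"))
  mask <- list(A = c("g1", "g3"), B = c("g1", "g2", "g3", "g9"))
  pruned <- prune_regulons(regs, mask)
  expect_setequal(pruned$A$T1, c("g1", "g3"))
  expect_null(pruned$A$T2) # all targets inaccessible in A
  expect_equal(pruned$B, regs) # unchanged when everything is accessible
})

test_that("targeted scoring reduces to plain scoring under a permissive mask", {
  set.seed(7)
  expr <- matrix(rexp(20 * 8), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("c", 1:8)))
  ds <- cell_dataset(expr, cell_type = rep(c("A", "B"), each = 4),
                     subject = rep("s1", 8))
  regs <- list(T1 = c("g1", "g5", "g7"), T2 = c("g2", "g11"))
  mask_all <- list(A = rownames(expr), B = rownames(expr))
  plain <- aucell_score(ds, regs, top_frac = 0.25)
  targeted <- targeted_regulon_scores(ds, regs, mask_all, top_frac = 0.25)
  expect_equal(unclass(targeted)[, ], unclass(plain)[, ])
  expect_identical(attr(targeted, "method"), "targeted_regulons")

  # a TF fully pruned in B scores 0 for B cells and never uses masked genes
  mask_b <- list(A = rownames(expr), B = setdiff(rownames(expr), regs$T2))
  t2 <- targeted_regulon_scores(ds, regs, mask_b, top_frac = 0.25)
  expect_true(all(unclass(t2)["T2", ds$cell_type == "B"] == 0))
  expect_equal(unclass(t2)["T1", ], unclass(plain)["T1", ])
})
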