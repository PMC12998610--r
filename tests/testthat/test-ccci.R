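test_that("full-path inference matches an exhaustive rule-evaluation oracle", {
  for (seed in c(21, 22, 23)) {
    fx <- mk_infer_fixture(seed)
    got <- infer_subject(fx$ds, fx$tf, fx$db)
    want <- oracle_infer(fx)
    expect_equal(got$tfs, want$tfs, info = paste("seed", seed))
    expect_equal(got$rec, want$rec, info = paste("seed", seed))
    expect_equal(got$tfs_rec, want$tfs_rec, info = paste("seed", seed))
    expect_equal(got$cl_rec_lig, want$cl_rec_lig, info = paste("seed", seed))
    # internal consistency invariants
    for (l in got$tfs_rec) {
      f <- strsplit(l, "|", fixed = TRUE)[[1]]
      expect_true(paste(f[1], f[2], sep = "|") %in% got$tfs)
      expect_true(paste(f[1], f[3], sep = "|") %in% got$rec)
    }
    proj <- unique(vapply(strsplit(got$cl_rec_lig, "|", fixed = TRUE),
                          function(f) paste(f[1], f[3], sep = "|"),
                          character(1)))
    expect_setequal(got$incoming_lig, proj)
  }
})

test_that("TF enrichment uses a strict one-sided p threshold", {
  # exact rank-sum null: type k = {0.9, 0.8, 0.7}, others = {0.1, 0.2}
  # one-sided p = 1 / choose(5, 3) = 0.1 -> not enriched at 0.001
  scores <- matrix(c(0.9, 0.8, 0.7, 0.1, 0.2), nrow = 1,
                   dimnames = list("T1", paste0("c", 1:5)))
  ct <- c("k", "k", "k", "o", "o")
  expect_equal(nrow(enriched_tfs(tf_activity(scores, "external"), ct,
                                 ccci_config())), 0)
  expect_equal(linksig:::.ranksum_p_greater(scores[1, 1:3], scores[1, 4:5]),
               0.1)
  # complete separation at adequate n clears 0.001
  set.seed(1)
  big <- matrix(c(runif(30, 0.6, 1), runif(30, 0, 0.4)), nrow = 1,
                dimnames = list("T1", paste0("c", 1:60)))
  ctb <- rep(c("k", "o"), each = 30)
  out <- enriched_tfs(tf_activity(big, "external"), ctb, ccci_config())
  expect_equal(out$cell_type, "k")
  expect_equal(out$tf, "T1")
  # identical distributions are never enriched
  same <- matrix(rep(c(0.3, 0.6), 30), nrow = 1,
                 dimnames = list("T1", paste0("c", 1:60)))
  expect_equal(nrow(enriched_tfs(tf_activity(same, "external"), ctb,
                                 ccci_config())), 0)
  expect_error(enriched_tfs(tf_activity(big, "external"), rep("k", 60),
                            ccci_config()),
               "2 cell types", class = "linksig_input_error")
})

test_that("receptor-TF correlation handles monotone, constant and regulon cases", {
  n <- 12
  expr <- matrix(0, nrow = 3, ncol = n,
                 dimnames = list(c("Rm", "Rc", "Lx"), paste0("c", 1:n)))
  expr["Rm", ] <- seq_len(n) # strictly increasing with TF score
  expr["Rc", ] <- 1 # constant
  ds <- cell_dataset(expr, cell_type = rep(c("A", "B"), 6),
                     subject = rep("s1", n))
  tf <- matrix(seq(0.01, 0.9, length.out = n), nrow = 1,
               dimnames = list("T1", colnames(expr)))
  db <- lr_database("i", "Lx", "Rm", list("Lx"), list("Rm"))
  db2 <- lr_database(c("i", "j"), c("Lx", "Lx"), c("Rm", "Rc"),
                     list("Lx", "Lx"), list("Rm", "Rc"))
  rho <- receptor_tf_correlation(ds, tf_activity(tf, "external"), db2)
  expect_equal(unname(rho["Rm", "T1"]), 1)
  expect_true(is.na(rho["Rc", "T1"])) # undefined correlation convention
  # regulon-target exclusion removes the pair
  rho2 <- receptor_tf_correlation(ds, tf_activity(tf, "external"), db,
                                  regulons = list(T1 = "Rm"))
  expect_true(is.na(rho2["Rm", "T1"]))
  rho3 <- receptor_tf_correlation(
    ds, tf_activity(tf, "external"), db, regulons = list(T1 = "Rm"),
    cfg = ccci_config(exclude_regulon_targets = FALSE)
  )
  expect_equal(unname(rho3["Rm", "T1"]), 1)
})

test_that("intracellular gate boundaries: rho >= 0.15 and pct >= 0.05", {
  profiles <- list(B = list(
    cell_type = "B", n_cells = 100,
    mean_scaled = c(R1 = 0.2, RCa = 0.1, RCb = 0.1),
    pct_expressing = c(R1 = 0.05, RCa = 0.06, RCb = 0.04)
  ))
  enriched <- data.frame(cell_type = "B", tf = "T1", p_value = 1e-5,
                         stringsAsFactors = FALSE)
  db <- lr_database(
    c("i1", "i2"), c("L1", "L2"), c("R1", "RC"),
    list("L1", "L2"), list("R1", c("RCa", "RCb"))
  )
  cors <- matrix(c(0.15, 0.3, 0.3), ncol = 1,
                 dimnames = list(c("R1", "RCa", "RCb"), "T1"))
  out <- intracellular_linkages(profiles, enriched, cors, db)
  # rho exactly at threshold passes; pct exactly at threshold passes
  expect_equal(out$tfs_rec, "B|T1|R1")
  # complex fails because one component sits below min_rec_percentage
  expect_false("B|T1|RC" %in% out$tfs_rec)

  cors2 <- cors
  cors2["R1", "T1"] <- 0.1499
  out2 <- intracellular_linkages(profiles, enriched, cors2, db)
  expect_equal(length(out2$tfs_rec), 0)

  # lifting the failing component's pct to the boundary admits the complex
  profiles$B$pct_expressing["RCb"] <- 0.05
  out3 <- intracellular_linkages(profiles, enriched, cors, db)
  expect_true("B|T1|RC" %in% out3$tfs_rec)
})

test_that("ligand sender gate is strictly greater than the threshold", {
  profiles <- list(
    A = list(cell_type = "A", n_cells = 10,
             mean_scaled = c(L1 = 0.5, L2 = 0, La = 0.3, Lb = -0.1),
             pct_expressing = c(L1 = 1, L2 = 1, La = 1, Lb = 1)),
    B = list(cell_type = "B", n_cells = 10,
             mean_scaled = c(L1 = 1e-9, L2 = -0.2, La = 0, Lb = 0),
             pct_expressing = c(L1 = 1, L2 = 1, La = 1, Lb = 1))
  )
  db <- lr_database(
    c("i1", "i2", "i3"), c("L1", "L2", "Lab"), c("R1", "R2", "R3"),
    list("L1", "L2", c("La", "Lb")), list("R1", "R2", "R3")
  )
  senders <- ligand_senders(profiles, db)
  expect_true("A|L1" %in% senders)
  expect_false("A|L2" %in% senders) # exactly 0 is not a sender
  expect_true("B|L1" %in% senders) # any positive margin qualifies
  expect_false("A|Lab" %in% senders) # every complex component must pass
})

test_that("raising thresholds never adds linkages (monotonicity)", {
  fx <- mk_infer_fixture(31)
  base <- infer_subject(fx$ds, fx$tf, fx$db, ccci_config())
  for (rho_thr in c(0.2, 0.35, 0.6)) {
    for (pct_thr in c(0.1, 0.3)) {
      stricter <- infer_subject(
        fx$ds, fx$tf, fx$db,
        ccci_config(rec_tf_cor_threshold = rho_thr,
                    min_rec_percentage = pct_thr)
      )
      expect_true(all(stricter$tfs_rec %in% base$tfs_rec))
      expect_true(all(stricter$cl_rec_lig %in% base$cl_rec_lig))
    }
  }
  # determinism: identical inputs give identical linkages
  again <- infer_subject(fx$ds, fx$tf, fx$db, ccci_config())
  expect_identical(base[names(base) != "subject"],
                   again[names(again) != "subject"])
})
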