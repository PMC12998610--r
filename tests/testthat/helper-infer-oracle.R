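# Fixture for full-path inference: 2 cell types, single-gene pair L1-R1 and
# a two-component receptor complex RC = {RCa, RCb} for ligand L2.
mk_infer_fixture <- function(seed = 21, n_per_type = 30) {
  set.seed(seed)
  genes <- c("L1", "L2", "R1", "RCa", "RCb", "F1", "F2")
  ct <- rep(c("A", "B"), each = n_per_type)
  n <- length(ct)
  expr <- matrix(0, nrow = length(genes), ncol = n,
                 dimnames = list(genes, sprintf("c%03d", 1:n)))
  # A expresses ligands, B expresses receptors
  expr["L1", ct == "A"] <- rexp(n_per_type, 1)
  expr["L2", ct == "A"] <- rexp(n_per_type, 1)
  expr["R1", ct == "B"] <- rbinom(n_per_type, 1, 0.6) * rexp(n_per_type, 1)
  expr["RCa", ct == "B"] <- rbinom(n_per_type, 1, 0.5) * rexp(n_per_type, 1)
  expr["RCb", ct == "B"] <- rbinom(n_per_type, 1, 0.5) * rexp(n_per_type, 1)
  expr["F1", ] <- rexp(n, 1)
  ds <- cell_dataset(expr, cell_type = ct, subject = rep("s1", n))
  tf <- rbind(
    TF1 = pmin(1, pmax(0, 0.6 * expr["R1", ] + rnorm(n, 0, 0.15))),
    TF2 = pmin(1, pmax(0, 0.5 * expr["RCa", ] + 0.5 * expr["RCb", ] +
                         rnorm(n, 0, 0.15)))
  )
  colnames(tf) <- colnames(expr)
  db <- lr_database(
    id = c("i1", "i2"),
    ligand_name = c("L1", "L2"),
    receptor_name = c("R1", "RC"),
    ligand_components = list("L1", "L2"),
    receptor_components = list("R1", c("RCa", "RCb")),
    source = "test"
  )
  list(ds = ds, tf = tf_activity(tf, "external"), db = db)
}

# Independent rule-by-rule oracle for infer_subject on the fixture above:
# plain loops, stats:: primitives, no shared code paths.
oracle_infer <- function(fx, cfg = ccci_config()) {
  ds <- fx$ds
  expr <- as.matrix(ds$expr)
  ct <- ds$cell_type
  scores <- as.matrix(fx$tf)
  types <- sort(unique(ct))
  # scaled expression: population SD z-score
  sc <- t(apply(expr, 1, function(v) {
    s <- sqrt(mean((v - mean(v))^2))
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
  receptors <- list(R1 = "R1", RC = c("RCa", "RCb"))
  ligand_of <- c(R1 = "L1", RC = "L2")
  enr <- list()
  for (k in types) {
    for (tf in rownames(scores)) {
      p <- suppressWarnings(stats::wilcox.test(
        scores[tf, ct == k], scores[tf, ct != k],
        alternative = "greater", exact = FALSE, correct = TRUE
      )$p.value)
      if (p < cfg$min_tf_pval) enr[[length(enr) + 1]] <- c(k, tf)
    }
  }
  tfs_rec <- character()
  for (e in enr) {
    k <- e[1]; tf <- e[2]
    for (rec in names(receptors)) {
      comps <- receptors[[rec]]
      ok <- TRUE
      for (g in comps) {
        rho <- suppressWarnings(
          stats::cor(expr[g, ], scores[tf, ], method = "spearman")
        )
        pct <- mean(expr[g, ct == k] > 0)
        if (is.na(rho) || rho < cfg$rec_tf_cor_threshold ||
              pct < cfg$min_rec_percentage) {
          ok <- FALSE
        }
      }
      if (ok) tfs_rec <- c(tfs_rec, paste(k, tf, rec, sep = "|"))
    }
  }
  senders <- character()
  for (k in types) {
    for (lig in c("L1", "L2")) {
      if (mean(sc[lig, ct == k]) > cfg$sender_mean_scaled_threshold) {
        senders <- c(senders, paste(k, lig, sep = "|"))
      }
    }
  }
  rec_set <- unique(vapply(strsplit(tfs_rec, "|", fixed = TRUE),
                           function(f) paste(f[1], f[3], sep = "|"),
                           character(1)))
  cl <- character()
  for (rec in names(receptors)) {
    for (kr in types) {
      if (!(paste(kr, rec, sep = "|") %in% rec_set)) next
      for (ks in types) {
        if (paste(ks, ligand_of[[rec]], sep = "|") %in% senders) {
          cl <- c(cl, paste(kr, rec, ligand_of[[rec]], ks, sep = "|"))
        }
      }
    }
  }
  list(
    tfs = sort(vapply(enr, function(e) paste(e[1], e[2], sep = "|"),
                      character(1))),
    rec = sort(rec_set),
    tfs_rec = sort(tfs_rec),
    cl_rec_lig = sort(cl)
  )
}

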