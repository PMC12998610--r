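# Fixture builders shared across the test files. Everything is generated in
# code at test time; no binary fixtures.

# Minimal CellPhoneDB v4-style directory. Includes a simple pair L -> R, a
# complex receptor RC = {R1a, R1b}, and one interaction with an unresolvable
# partner.
write_cpdb_fixture <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("cpdb")
    dir.create(dir)
  }
  write.csv(
    data.frame(
      id_cp_interaction = c("CPI-1", "CPI-2", "CPI-3"),
      partner_a = c("P_L", "P_L2", "P_MISSING"),
      partner_b = c("P_R", "cplx_RC", "P_R"),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "interaction_input.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(
      complex_name = "cplx_RC",
      uniprot_1 = "P_R1A", uniprot_2 = "P_R1B",
      uniprot_3 = NA, uniprot_4 = NA,
      stringsAsFactors = FALSE
    ),
    file.path(dir, "complex_input.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(
      uniprot = c("P_L", "P_R", "P_L2", "P_R1A", "P_R1B"),
      protein_name = c("L_h", "R_h", "L2_h", "R1A_h", "R1B_h"),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "protein_input.csv"), row.names = FALSE
  )
  write.csv(
    data.frame(
      gene_name = c("L", "R", "L2", "R1a", "R1b"),
      uniprot = c("P_L", "P_R", "P_L2", "P_R1A", "P_R1B"),
      stringsAsFactors = FALSE
    ),
    file.path(dir, "gene_input.csv"), row.names = FALSE
  )
  dir
}

# Small deterministic dataset: 2 cell types x 2 subjects.
toy_dataset <- function(n_per_type = 6, seed = 11) {
  set.seed(seed)
  genes <- c("L1", "R1", "TFT1", "G1")
  subjects <- rep(c("s1", "s2"), each = 2 * n_per_type)
  ct <- rep(rep(c("A", "B"), each = n_per_type), 2)
  n <- length(ct)
  expr <- matrix(round(stats::rexp(length(genes) * n), 3),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("c%03d", seq_len(n))))
  cell_dataset(expr, cell_type = ct, subject = subjects,
               condition = rep("X", n))
}

# A hand-assembled linkage summary: 6 subjects in 2 groups; linkage
# "B|R1|L1|A" present in all of group g1 and one subject of g2, plus a
# ubiquitous null linkage "B|R2|L2|A".
toy_summary <- function() {
  mk <- function(subject, cl) {
    structure(
      list(
        subject = subject,
        cell_types = c("A", "B"),
        tfs = character(),
        rec = sort(unique(vapply(strsplit(cl, "|", fixed = TRUE),
                                 function(f) paste(f[1], f[2], sep = "|"),
                                 character(1)))),
        incoming_lig = sort(unique(vapply(strsplit(cl, "|", fixed = TRUE),
                                          function(f) paste(f[1], f[3], sep = "|"),
                                          character(1)))),
        tfs_rec = character(),
        cl_rec_lig = sort(cl)
      ),
      class = "subject_linkages"
    )
  }
  subjects <- sprintf("s%d", 1:6)
  groups <- rep(c("g1", "g2"), each = 3)
  entries <- list()
  for (i in seq_along(subjects)) {
    cl <- "B|R2|L2|A"
    if (groups[i] == "g1" || subjects[i] == "s4") {
      cl <- c(cl, "B|R1|L1|A")
    }
    entries[[subjects[i]]] <- mk(subjects[i], cl)
  }
  build_summary(entries, data.frame(subject = subjects, group = groups,
                                    stringsAsFactors = FALSE))
}

# Brute-force two-sided Fisher p for a 2x2 table by explicit enumeration of
# all tables with the observed margins (factorial formula, no dhyper).
enum_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  m1 <- a + b; m2 <- c2 + d; c1 <- a + c2; n <- m1 + m2
  if (m1 == 0 || m2 == 0 || c1 == 0 || c1 == n) return(1)
  lp <- function(k) {
    lfactorial(m1) + lfactorial(m2) + lfactorial(c1) + lfactorial(n - c1) -
      lfactorial(n) - lfactorial(k) - lfactorial(m1 - k) -
      lfactorial(c1 - k) - lfactorial(m2 - c1 + k)
  }
  ks <- max(0, c1 - m2):min(c1, m1)
  probs <- exp(vapply(ks, lp, numeric(1)))
  p_obs <- probs[ks == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Brute-force Freeman-Halton p for an r x 2 table by exhaustive recursion.
enum_fisher_rx2 <- function(tab) {
  s <- rowSums(tab)
  keep <- s > 0
  tab <- tab[keep, , drop = FALSE]
  s <- s[keep]
  r <- nrow(tab)
  if (r < 2) return(1)
  c1 <- sum(tab[, 1])
  n <- sum(s)
  if (c1 == 0 || c1 == n) return(1)
  lp <- function(k) sum(lchoose(s, k)) - lchoose(n, c1)
  all_k <- list()
  gen <- function(i, remaining, acc) {
    if (i == r) {
      if (remaining <= s[r]) all_k[[length(all_k) + 1L]] <<- c(acc, remaining)
      return(invisible())
    }
    for (k in 0:min(s[i], remaining)) gen(i + 1, remaining - k, c(acc, k))
  }
  gen(1, c1, integer(0))
  probs <- vapply(all_k, function(k) exp(lp(k)), numeric(1))
  p_obs <- exp(lp(tab[, 1]))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# Step-up BH from first principles (independent of stats::p.adjust).
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, m * p[o[i]] / i)
    q[o[i]] <- min(1, running)
  }
  q
}
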