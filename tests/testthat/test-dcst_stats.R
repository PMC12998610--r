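test_that("2x2 exact test reproduces enumeration oracles", {
  # symmetric table
  r <- fisher_exact_2x2(matrix(c(3, 3, 3, 3), 2, byrow = TRUE))
  expect_equal(r$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(r$p_value, 1)
  # complete separation: p = 2 / choose(10, 5)
  r2 <- fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2, byrow = TRUE))
  expect_equal(r2$p_value, 2 / choose(10, 5))
  expect_identical(r2$odds_ratio, Inf)
  # hypergeometric enumeration oracle: [[8,2],[1,9]] -> 920 / 167960
  t3 <- matrix(c(8, 2, 1, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact_2x2(t3)$p_value, 920 / 167960)
  expect_equal(fisher_exact_2x2(t3)$p_value, enum_fisher_2x2(t3))
  # degenerate margin: everyone has the linkage
  r4 <- fisher_exact_2x2(matrix(c(4, 0, 4, 0), 2, byrow = TRUE))
  expect_equal(r4$p_value, 1)
  expect_true(is.na(r4$odds_ratio))
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)),
               class = "linksig_input_error")
})

test_that("2x2 p-values and CMLE odds ratios agree with stats::fisher.test", {
  set.seed(42)
  for (i in 1:60) {
    tab <- matrix(rpois(4, 4), 2)
    ours <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    if (is.finite(ours$odds_ratio) && ours$odds_ratio > 0) {
      expect_equal(ours$odds_ratio, unname(ref$estimate), tolerance = 1e-4)
    }
  }
})

test_that("group-label swap maps OR to its reciprocal and keeps p", {
  set.seed(7)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 3) + c(1, 0, 0, 1), 2)
    a <- fisher_exact_2x2(tab)
    b <- fisher_exact_2x2(tab[2:1, ])
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    if (is.finite(a$odds_ratio) && a$odds_ratio > 0) {
      expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-5)
    }
  }
})

test_that("r x 2 exact test matches enumeration and reduces to the 2x2 case", {
  expect_equal(
    fisher_exact_rx2(matrix(c(2, 2, 2, 2, 2, 2), 3, byrow = TRUE))$p_value, 1
  )
  t2 <- matrix(c(2, 0, 0, 2, 1, 1), 3, byrow = TRUE)
  expect_equal(fisher_exact_rx2(t2)$p_value, 12 / 20)
  expect_equal(fisher_exact_rx2(t2)$p_value, enum_fisher_rx2(t2))
  # zero-subject group dropped
  t3 <- rbind(t2, c(0, 0))
  expect_equal(fisher_exact_rx2(t3)$p_value, fisher_exact_rx2(t2)$p_value)
  # r = 2 consistency with the dedicated 2x2 test
  set.seed(3)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 3), 2)
    expect_equal(fisher_exact_rx2(tab)$p_value,
                 fisher_exact_2x2(tab)$p_value, tolerance = 1e-12)
  }
  expect_error(fisher_exact_rx2(matrix(50000, 40, 2), max_tables = 100),
               "budget", class = "linksig_input_error")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(11)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_bh(p))
    expect_true(all(q >= p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.2, 1.4)), class = "linksig_input_error")
})

test_that("exact tests are conservative under a Bernoulli null", {
  set.seed(19)
  n_fam <- 1e4
  n_per_group <- 10
  p_rate <- 0.3
  raw <- numeric(n_fam)
  for (i in seq_len(n_fam)) {
    x <- rbinom(1, n_per_group, p_rate)
    y <- rbinom(1, n_per_group, p_rate)
    raw[i] <- fisher_exact_2x2(matrix(
      c(x, n_per_group - x, y, n_per_group - y), 2, byrow = TRUE
    ))$p_value
  }
  frac <- mean(raw < 0.05)
  se <- sqrt(0.05 * 0.95 / n_fam)
  expect_lte(frac, 0.05 + 3 * se)
})

test_that("differential testing builds the per-recipient family and ordering", {
  s <- toy_summary()
  res <- test_differential_linkages(s, "group", "cl_rec_lig", "B",
                                    reference_group = "g1")
  expect_s3_class(res, "dcst_result")
  expect_equal(nrow(res), 2) # only linkages observed somewhere are tested
  r1 <- res[res$linkage == "B|R1|L1|A", ]
  # 3/3 vs 1/3: enumeration gives p = 0.4
  expect_equal(r1$p_value, enum_fisher_2x2(matrix(c(3, 0, 1, 2), 2,
                                                  byrow = TRUE)))
  expect_identical(r1$odds_ratio, Inf)
  # ubiquitous linkage is uninformative
  r2 <- res[res$linkage == "B|R2|L2|A", ]
  expect_equal(r2$p_value, 1)
  expect_true(is.na(r2$odds_ratio))
  # BH within exactly this family
  expect_equal(res$p_adj, bh_adjust(res$p_value))
  expect_equal(res$p_value, sort(res$p_value))
  # 3/3 vs 0/3 complete separation: p = 2 / choose(6, 3) = 0.1
  s2 <- toy_summary()
  s2$linkages$s4$cl_rec_lig <- "B|R2|L2|A"
  s2$linkages$s4$rec <- "B|R2"
  s2$linkages$s4$incoming_lig <- "B|L2"
  res2 <- test_differential_linkages(s2, "group", "cl_rec_lig", "B",
                                     reference_group = "g1")
  expect_equal(res2[res2$linkage == "B|R1|L1|A", "p_value"], 0.1)
  expect_error(test_differential_linkages(s, "nope", "cl_rec_lig", "B"),
               "grouping", class = "linksig_input_error")
  expect_error(
    test_differential_linkages(s, "group", "cl_rec_lig", "B",
                               subjects = c("s1", "s2")),
    "2 levels", class = "linksig_input_error"
  )
})

test_that("result tables render to TSV and read back losslessly", {
  s <- toy_summary()
  res <- test_differential_linkages(s, "group", "cl_rec_lig", "B")
  path <- withr::local_tempfile(fileext = ".tsv")
  render_results(res, path)
  lines <- readLines(path)
  expect_equal(length(lines), nrow(res) + 1)
  expect_true(any(grepl("\tInf\t", lines)) || any(grepl("Inf", lines)))
  back <- read_results(path)
  expect_equal(back$linkage, res$linkage)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-12)
  expect_equal(back$odds_ratio, res$odds_ratio)
  # empty table: header only
  empty <- test_differential_linkages(s, "group", "cl_rec_lig", "Z")
  render_results(empty, path)
  expect_equal(length(readLines(path)), 1)
})
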