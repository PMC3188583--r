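test_that("allele spectra count two chromosomes per typed individual", {
  sp <- allele_spectrum(table1_fixture(6.40), "MUC5AC")
  expect_equal(sp$pooled[abs(sp$allele - 6.40) < 1e-9], 2L * 43L + 135L)  # 221
  expect_equal(sum(sp$pooled), 936L)
  expect_equal(sp$pooled, sp$severe + sp$mild)

  one <- make_cohort("severe", a = 6.3, b = 6.4)
  sp1 <- allele_spectrum(one, "MUC5AC")
  expect_equal(sp1$severe, c(1L, 1L))

  empty <- make_cohort(character(), a = numeric(), b = numeric())
  expect_equal(nrow(allele_spectrum(empty, "MUC5AC")), 0L)
})

test_that("rank-sum severity comparison is symmetric and centered at the null", {
  # identical spectra in both groups: statistic at the null center, p = 1
  coh <- make_cohort(rep(c("severe", "mild"), each = 4),
                     a = rep(c(6.3, 6.4, 6.3, 6.5), 2),
                     b = rep(c(6.4, 6.4, 6.3, 6.5), 2))
  rs <- ranksum_severity(allele_spectrum(coh, "MUC5AC"))
  expect_equal(rs$p_value, 1)

  # complete separation: extreme rank-sum statistic, small two-sided p,
  # and agreement with the tie-corrected normal approximation on the
  # chromosome-expanded data
  sep <- make_cohort(rep(c("severe", "mild"), each = 5),
                     a = rep(c(6.4, 6.3), each = 5),
                     b = rep(c(6.4, 6.3), each = 5))
  sp <- allele_spectrum(sep, "MUC5AC")
  rs2 <- ranksum_severity(sp)
  expect_equal(rs2$statistic, 100)  # all severe chromosomes rank above all mild
  ref <- wilcox.test(rep(6.4, 10), rep(6.3, 10), exact = FALSE, correct = FALSE)
  expect_equal(rs2$p_value, ref$p.value)
  expect_lt(rs2$p_value, 1e-3)

  # swapping group labels leaves the two-sided p unchanged
  swapped <- sep
  swapped$phenotype <- factor(ifelse(sep$phenotype == "severe", "mild", "severe"),
                              levels = c("severe", "mild"))
  rs3 <- ranksum_severity(allele_spectrum(swapped, "MUC5AC"))
  expect_equal(rs3$p_value, rs2$p_value)

  expect_error(ranksum_severity(allele_spectrum(
    make_cohort("severe", a = 6.3, b = 6.4), "MUC5AC")), "both severity groups")
})

test_that("designated tables classify genotypes by designated-allele count", {
  coh <- make_cohort(c("severe", "severe", "mild"),
                     a = c(6.4, 6.3, 6.3), b = c(6.4, 6.4, 6.3))
  tab <- designated_table(coh, "MUC5AC", 6.4)
  expect_equal(unname(tab["severe", ]), c(1L, 1L, 0L))
  expect_equal(unname(tab["mild", ]), c(0L, 0L, 1L))
  # no carriers: first two classes empty
  none <- designated_table(coh, "MUC5AC", 6.9)
  expect_equal(unname(colSums(none)), c(0L, 0L, 3L))
  expect_error(designated_table(coh, "MUC5AC", 6.42), "off the")
})

test_that("the exact test matches brute-force enumeration on 2x3 tables", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(6:30, 1)
    cells <- as.vector(rmultinom(1, n, prob = runif(6, 0.2, 1)))
    m <- matrix(cells, 2, 3)
    if (any(rowSums(m) == 0) || sum(colSums(m) > 0) < 2) next
    expect_equal(fisher_exact_rxc(m)$p_value, oracle_fh_2xc(m),
                 tolerance = 1e-10)
  }
  # margin-structured sweep: every first-row total against fixed columns
  for (r1 in c(2, 5, 9, 14)) {
    m <- matrix(c(r1, 0, 2, 4, 3, 6), 2, 3)
    expect_equal(fisher_exact_rxc(m)$p_value, oracle_fh_2xc(m),
                 tolerance = 1e-10)
  }
})

test_that("the exact test reduces to the hypergeometric 2x2 form", {
  set.seed(202)
  for (rep in 1:50) {
    m <- matrix(rpois(4, 6) + 1L, 2, 2)
    expect_equal(fisher_exact_rxc(m)$p_value,
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }
  expect_equal(fisher_exact_rxc(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
})

test_that("exact p values are invariant to column permutation and transposition", {
  m <- matrix(c(4, 9, 2, 7, 11, 3), 2, 3)
  p <- fisher_exact_rxc(m)$p_value
  expect_equal(fisher_exact_rxc(m[, c(3, 1, 2)])$p_value, p)
  expect_equal(fisher_exact_rxc(t(m))$p_value, p)
})

test_that("degenerate and oversized tables are handled explicitly", {
  expect_equal(fisher_exact_rxc(matrix(c(5, 0, 7, 0), 2))$p_value, 1)
  expect_error(fisher_exact_rxc(matrix(c(3, -1, 2, 2), 2)), "non-negative")
  big <- matrix(rep(500L, 12), 3, 4)
  expect_error(fisher_exact_rxc(big, max_tables = 1e4), "montecarlo")
})

test_that("Monte Carlo mode is seeded, reproducible and close to enumeration", {
  m <- rbind(c(22, 76, 96), c(21, 59, 194))
  exact <- fisher_exact_rxc(m)$p_value
  mc1 <- fisher_exact_rxc(m, method = "montecarlo", n_mc = 20000, seed = 9)
  mc2 <- fisher_exact_rxc(m, method = "montecarlo", n_mc = 20000, seed = 9)
  expect_identical(mc1$p_value, mc2$p_value)
  # add-one MC estimate of a p ~ 1.4e-5 at 2e4 draws: expect at most a few hits
  expect_lt(mc1$p_value, 20 / 20001)
  expect_gt(mc1$p_value, 0)
  expect_lt(abs(fisher_exact_rxc(rbind(c(8, 12), c(14, 6)),
                                 method = "montecarlo", n_mc = 50000,
                                 seed = 4)$p_value -
                fisher_exact_rxc(rbind(c(8, 12), c(14, 6)))$p_value), 0.01)
  expect_true(is.finite(exact))
})

test_that("carrier odds ratios collapse the genotype table correctly", {
  tab <- designated_table(table1_fixture(6.40), "MUC5AC", 6.40)
  or <- carrier_odds_ratio(tab)
  expect_equal(or$or, (98 * 194) / (80 * 96), tolerance = 1e-12)
  expect_false(or$corrected)
  expect_true(or$ci_lo < or$or && or$or < or$ci_hi)

  # equal carrier proportions give OR 1
  eq <- structure(matrix(c(10L, 20L, 10L, 20L, 80L, 160L), 2, 3),
                  class = "genotype_contingency")
  expect_equal(carrier_odds_ratio(eq)$or, 1)

  # allele enriched in the mild group has OR < 1
  or30 <- carrier_odds_ratio(designated_table(table1_fixture(6.30), "MUC5AC", 6.30))
  expect_lt(or30$or, 1)

  # zero cell triggers the continuity correction and flags it
  zc <- structure(matrix(c(0L, 2L, 0L, 10L, 50L, 60L), 2, 3),
                  class = "genotype_contingency")
  expect_true(carrier_odds_ratio(zc)$corrected)
})

test_that("designated scans filter by allele frequency and register tests", {
  coh <- table1_fixture(6.50)
  # the 6.50 allele reaches 4% of carriers but only 3.95% of chromosomes:
  # the two bases genuinely differ on this row
  by_car <- designated_scan(coh, "MUC5AC", freq_basis = "carriers")
  by_chr <- designated_scan(coh, "MUC5AC", freq_basis = "chromosomes")
  expect_true(any(abs(by_car$allele - 6.50) < 1e-9))
  expect_false(any(abs(by_chr$allele - 6.50) < 1e-9))

  scan40 <- designated_scan(table1_fixture(6.40), "MUC5AC")
  row <- scan40[abs(scan40$allele - 6.40) < 1e-9, ]
  expect_equal(signif(row$p_nominal, 2), 1.4e-5)
  led <- scan_ledger(scan40)
  expect_equal(nrow(led), nrow(scan40))
  expect_true("MUC5AC_D_6.40" %in% led$test_id)

  expect_equal(nrow(designated_scan(coh, "MUC5AC", min_allele_freq = 1.0)), 0L)
})

test_that("a null simulated scan has nominal type-I error for the common allele", {
  hits <- 0L
  n_rep <- 120L
  for (i in seq_len(n_rep)) {
    coh <- simulate_cohort(sim_config(seed = 4000 + i, n_severe = 97,
                                      n_mild = 137, carrier_odds_ratio = 1))
    tab <- designated_table(coh, "MUC5AC", 6.40)
    hits <- hits + (fisher_exact_rxc(tab)$p_value < 0.05)
  }
  rate <- hits / n_rep
  se <- sqrt(0.05 * 0.95 / n_rep)
  # exact tests are conservative, so only the upper 3 SE bound binds
  expect_lt(rate, 0.05 + 3 * se)
})

test_that("the Bonferroni ledger corrects within declared families", {
  led <- test_ledger()
  led <- ledger_add(led, "t1", "designated allele test", 1.4e-5,
                    c("table", "table_plus_dist", "all"))
  led <- ledger_add(led, "t2", "another test", 0.5, "table")
  led <- ledger_declare_family(led, "table", 8L)
  led <- ledger_declare_family(led, "table_plus_dist", 12L)
  led <- ledger_declare_family(led, "all", 44L)

  expect_equal(bonferroni(led, "table")$p_corrected[1], 1.4e-5 * 8)
  expect_equal(bonferroni(led, "table_plus_dist")$p_corrected[1], 1.4e-5 * 12)
  expect_equal(bonferroni(led, "all")$p_corrected[1], 1.4e-5 * 44)
  # capped at 1
  expect_equal(bonferroni(led, "table")$p_corrected[2], 1)
  # corrected p monotone in family size and never below nominal
  b8 <- bonferroni(led, "table")$p_corrected[1]
  b44 <- bonferroni(led, "all")$p_corrected[1]
  expect_true(b8 <= b44 && b8 >= 1.4e-5)

  # undeclared family size falls back to member count
  expect_equal(bonferroni(led, "table_plus_dist")$family_size[1], 12L)
  led2 <- ledger_add(test_ledger(), "a", "x", 0.01, "fam")
  expect_equal(bonferroni(led2, "fam")$family_size, 1L)
  expect_error(bonferroni(led2, "ghost"), "not registered")
  expect_error(ledger_add(led2, "a", "dup", 0.2), "already registered")
})
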