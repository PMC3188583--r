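sl_655 <- function() partition_sl(6.55, "long_inclusive")

test_that("EM equals closed-form counting when phase is unambiguous", {
  # homozygote-only cohort: haplotype counts are directly observable
  coh <- make_cohort(rep("severe", 6),
                     a = c(6.3, 6.3, 6.4, 6.4, 6.9, 6.9),
                     b = c(6.3, 6.3, 6.4, 6.4, 6.9, 6.9),
                     snps = list(rs1 = c(0L, 2L, 0L, 0L, 2L, 2L)))
  em <- em_haplotypes(coh, "MUC5AC", fine_63_64(), "rs1")
  h <- em$h
  expect_equal(h["6.3", "major"], 2 / 12)
  expect_equal(h["6.3", "minor"], 2 / 12)
  expect_equal(h["6.4", "major"], 4 / 12)
  expect_equal(h["other", "minor"], 4 / 12)
  expect_true(em$converged)

  # single heterozygote at one locus only is still unambiguous
  coh2 <- make_cohort(c("severe", "mild"),
                      a = c(6.3, 6.3), b = c(6.4, 6.3),
                      snps = list(rs1 = c(0L, 1L)))
  h2 <- em_haplotypes(coh2, "MUC5AC", fine_63_64(), "rs1")$h
  expect_equal(h2["6.4", "major"], 0.25)
  expect_equal(h2["6.3", "minor"], 0.25)
})

test_that("a lone double heterozygote stays at the symmetric fixed point", {
  coh <- make_cohort("severe", a = 6.3, b = 6.4, snps = list(rs1 = 1L))
  em <- em_haplotypes(coh, "MUC5AC", fine_63_64(), "rs1", restarts = 0)
  expect_equal(as.vector(em$h), rep(0.25, 4), tolerance = 1e-9)
})

test_that("EM attains the simplex maximum found by direct search", {
  for (seed in c(3, 17, 42)) {
    cfg <- sim_config(seed = seed, n_severe = 15, n_mild = 15,
                      snp_panel = list(rs1 = c(".default" = 0.3,
                                               "6.40" = 0.7)))
    coh <- simulate_cohort(cfg)
    em <- em_haplotypes(coh, "MUC5AC", fine_63_64(), "rs1")
    gc_a <- coh$MUC5AC_a; gc_b <- coh$MUC5AC_b
    labels <- em$labels
    la <- match(partition_assign(fine_63_64(), gc_a, 0.05), labels)
    lb <- match(partition_assign(fine_63_64(), gc_b, 0.05), labels)
    oracle <- oracle_max_loglik(la, lb, coh$rs1, length(labels))
    expect_lt(abs(em$loglik - oracle), 1e-6)
    expect_true(all(diff(em$trace) >= -1e-9))
    expect_equal(sum(em$h), 1, tolerance = 1e-9)
  }
})

test_that("the EM log-likelihood equals the explicit phase-sum likelihood", {
  cfg <- sim_config(seed = 8, n_severe = 20, n_mild = 20,
                    snp_panel = list(rs1 = c(".default" = 0.4)))
  coh <- simulate_cohort(cfg)
  em <- em_haplotypes(coh, "MUC5AC", fine_63_64(), "rs1")
  la <- match(partition_assign(fine_63_64(), coh$MUC5AC_a, 0.05), em$labels)
  lb <- match(partition_assign(fine_63_64(), coh$MUC5AC_b, 0.05), em$labels)
  expect_equal(em$loglik,
               oracle_two_locus_loglik(em$h, la, lb, coh$rs1),
               tolerance = 1e-8)
})

test_that("r-squared hits its closed-form anchors", {
  # perfect coupling: only (6.3, minor) and (other, major) haplotypes
  coh <- make_cohort(rep("severe", 8),
                     a = c(rep(6.3, 4), rep(6.9, 4)),
                     b = c(rep(6.3, 4), rep(6.9, 4)),
                     snps = list(rs1 = c(rep(2L, 4), rep(0L, 4))))
  expect_equal(r_squared(coh, "rs1", gene = "MUC5AC", partition = sl_655()), 1)

  # independent loci with balanced frequencies: r^2 near 0
  coh2 <- make_cohort(rep(c("severe", "mild"), 8),
                      a = rep(c(6.3, 6.9), 8), b = rep(c(6.3, 6.9), 8),
                      snps = list(rs1 = rep(c(0L, 2L, 2L, 0L), 4)))
  expect_lt(r_squared(coh2, "rs1", gene = "MUC5AC", partition = sl_655()), 1e-6)

  # monomorphic VNTR violates the biallelic precondition
  mono <- make_cohort(rep("severe", 4), a = rep(6.3, 4), b = rep(6.3, 4),
                      snps = list(rs1 = c(0L, 1L, 2L, 1L)))
  expect_error(r_squared(mono, "rs1", gene = "MUC5AC", partition = sl_655()),
               "exactly 2 observed classes")
  # monomorphic SNP makes r^2 undefined
  mono_snp <- make_cohort(rep("severe", 4), a = c(6.3, 6.3, 6.9, 6.9),
                          b = c(6.3, 6.3, 6.9, 6.9),
                          snps = list(rs1 = rep(0L, 4)))
  expect_true(is.na(r_squared(mono_snp, "rs1", gene = "MUC5AC",
                              partition = sl_655())))
})

test_that("r-squared is invariant to allele-label swaps at either locus", {
  cfg <- sim_config(seed = 23, n_severe = 100, n_mild = 100,
                    snp_panel = list(rs1 = c(".default" = 0.2, "6.40" = 0.7),
                                     rs2 = c(".default" = 0.4)))
  coh <- simulate_cohort(cfg)
  r_ab <- r_squared(coh, "rs1", "rs2")
  swapped <- tibble::as_tibble(coh)
  swapped$rs1 <- 2L - swapped$rs1
  swapped <- new_cohort(swapped, genes = attr(coh, "genes"),
                        snps = attr(coh, "snps"))
  expect_equal(r_squared(swapped, "rs1", "rs2"), r_ab, tolerance = 1e-6)
})

test_that("independent simulated loci give near-zero r-squared", {
  ok <- 0L
  for (i in 1:100) {
    cfg <- sim_config(seed = 1200 + i, n_severe = 250, n_mild = 250,
                      carrier_odds_ratio = 1,
                      snp_panel = list(rs1 = c(".default" = 0.3)))
    coh <- simulate_cohort(cfg)
    r2 <- r_squared(coh, "rs1", gene = "MUC5AC", partition = sl_655())
    if (r2 < 0.02) ok <- ok + 1L
  }
  expect_gte(ok, 95L)
})

test_that("chi-square of SNP genotype against VNTR genotype behaves", {
  # a SNP that perfectly tags short/long is overwhelmingly significant
  cfg <- sim_config(seed = 31, snp_panel = list(
    rs1 = c(".default" = 0, "6.90" = 1, "7.00" = 1, "7.20" = 1)))
  coh <- simulate_cohort(cfg)
  res <- chi2_vntr_snp(coh, "MUC5AC", sl_655(), "rs1")
  expect_lt(res$p_value, 1e-10)

  # dropping a zero-margin row equals removing those individuals' class
  coh2 <- make_cohort(rep(c("severe", "mild"), 6),
                      a = rep(c(6.3, 6.9), 6), b = rep(c(6.3, 6.9), 6),
                      snps = list(rs1 = rep(c(0L, 1L, 2L), 4)))
  res2 <- chi2_vntr_snp(coh2, "MUC5AC", sl_655(), "rs1")
  expect_equal(res2$dropped_rows[[1]], "L/S")   # no S/L genotypes exist
  tab <- table(ifelse(abs(coh2$MUC5AC_a - 6.3) < 1e-9, "SS", "LL"), coh2$rs1)
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(res2$chi2, unname(ref$statistic))
  expect_equal(res2$p_value, ref$p.value)
})

test_that("null chi-square p values are roughly uniform", {
  ps <- vapply(1:150, function(i) {
    coh <- simulate_cohort(sim_config(
      seed = 2500 + i, n_severe = 100, n_mild = 100, carrier_odds_ratio = 1,
      snp_panel = list(rs1 = c(".default" = 0.4))
    ))
    chi2_vntr_snp(coh, "MUC5AC", sl_655(), "rs1")$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("LD maps are symmetric and binned per the published thresholds", {
  cfg <- sim_config(seed = 77, n_severe = 80, n_mild = 80,
                    snp_panel = list(rs1 = c(".default" = 0.2, "6.40" = 0.8),
                                     rs2 = c(".default" = 0.5),
                                     rs3 = c(".default" = 0.3, "6.90" = 0.6)))
  coh <- simulate_cohort(cfg)
  map <- ld_map(coh, "MUC5AC", sl_655(), c("rs1", "rs2", "rs3"))
  expect_equal(map$r2, t(map$r2))
  expect_true(all(diag(map$r2) == 1))
  expect_equal(nrow(map$vntr), 3L)

  expect_equal(as.character(ld_bin(c(1, 0.05, 1e-5, 1e-7, 1e-12, 1e-55))),
               c("white", "light_blue", "medium_blue", "medium_blue",
                 "dark_blue", "red"))
  expect_error(ld_map(coh, "MUC5AC", sl_655(), "rs1"), "at least 2")
})
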