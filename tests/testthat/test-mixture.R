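# spectrum-shaped input for generative mixture draws
draw_spectrum <- function(n, mu, sigma, pi1, seed, unit = 0.05) {
  set.seed(seed)
  comp <- rbinom(n, 1, 1 - pi1) + 1
  x <- rnorm(n, mu[comp], sigma[comp])
  x <- round(x / unit) * unit
  agg <- as.data.frame(table(x))
  tibble::tibble(allele = as.numeric(as.character(agg$x)),
                 pooled = as.integer(agg$Freq))
}

test_that("well-separated point masses recover means and weights", {
  spec <- tibble::tibble(allele = c(3.6, 5.6), pooled = c(50L, 50L))
  fit <- fit_mixture(spec)
  expect_equal(fit$mu, c(3.6, 5.6), tolerance = 1e-6)
  expect_equal(fit$pi, c(0.5, 0.5), tolerance = 1e-6)
  # zero within-component spread collapses sigma: flagged, no cut-point
  expect_true(fit$degenerate)
  expect_error(cut_point(fit), "degenerate")
})

test_that("mixture parameters are recovered from a bimodal sample", {
  spec <- draw_spectrum(1000, c(3.6, 5.6), c(0.3, 0.5), pi1 = 0.6, seed = 31)
  fit <- fit_mixture(spec)
  expect_true(fit$converged && !fit$degenerate && fit$bimodal)
  expect_equal(fit$mu, c(3.6, 5.6), tolerance = 0.06)
  expect_equal(fit$sigma, c(0.3, 0.5), tolerance = 0.07)
  expect_equal(fit$pi[1], 0.6, tolerance = 0.05)
  # EM log-likelihood is non-decreasing at every iteration
  expect_true(all(diff(fit$trace) >= -1e-9))
})

test_that("the fitted likelihood is not beaten by a reference mixture fitter", {
  suppressPackageStartupMessages(library(mclust))
  spec <- draw_spectrum(800, c(3.6, 5.6), c(0.3, 0.5), pi1 = 0.55, seed = 77)
  fit <- fit_mixture(spec)
  x <- rep(spec$allele, spec$pooled)
  ref <- Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_gt(fit$loglik, ref$loglik - 0.1)
})

test_that("unimodal spectra fail the bimodality screen and refuse a cut-point", {
  spec <- draw_spectrum(800, c(4.5, 4.5), c(0.4, 0.4), pi1 = 0.5, seed = 13)
  fit <- fit_mixture(spec)
  expect_false(fit$bimodal)
  # refused either via the BIC screen or, if the overlapping components
  # are still drifting, via the convergence flag
  expect_error(cut_point(fit), "not bimodal|did not converge")
  expect_error(fit_mixture(tibble::tibble(allele = 4.5, pooled = 10L)),
               "at least 2 distinct")
})

test_that("cut-point rules follow their closed forms", {
  fake <- structure(list(mu = c(3.6, 5.6), sigma = c(0.2, 0.3),
                         pi = c(0.5, 0.5), converged = TRUE,
                         degenerate = FALSE, bimodal = TRUE),
                    class = "mixture_fit")
  # midpoint of (mu1 + 2 s1, mu2 - 2 s2) = midpoint of (4.0, 5.0)
  expect_equal(cut_point(fake), 4.5)
  expect_equal(cut_point(NULL, 4.9), 4.9)
  # symmetric components put the cut at the center of symmetry
  sym <- fake
  sym$mu <- c(-2, 2); sym$sigma <- c(0.3, 0.3)
  expect_equal(cut_point(sym), 0)
  # density-crossing rule: equal weights and sds cross midway
  expect_equal(cut_point(fake, "density_crossing"), 4.54, tolerance = 0.05)
})

test_that("generative cut-points are recovered across replicates", {
  target <- mean(c(3.6 + 2 * 0.3, 5.6 - 2 * 0.5))  # 4.4 under the 2-sd rule
  hits <- 0L
  for (i in 1:100) {
    spec <- draw_spectrum(1000, c(3.6, 5.6), c(0.3, 0.5), pi1 = 0.6,
                          seed = 500 + i)
    fit <- fit_mixture(spec)
    if (!fit$converged || fit$degenerate || !fit$bimodal) next
    if (abs(cut_point(fit) - target) <= 0.2) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("short/long genotypes respect both boundary conventions", {
  coh <- make_cohort(c("severe", "mild"), a = c(4.3, 6.7), b = c(5.0, 6.7),
                     unit = 0.05)
  g_short <- sl_genotypes(coh, "MUC5AC", 4.3, "short_inclusive")
  expect_equal(as.character(g_short$sl_genotype[1]), "SL")   # 4.3 counts as S
  g_long <- sl_genotypes(coh, "MUC5AC", 6.7, "long_inclusive")
  expect_equal(as.character(g_long$sl_genotype[2]), "LL")    # 6.7 counts as L

  low <- make_cohort(c("severe", "mild"), a = c(4.0, 4.1), b = c(4.2, 4.3))
  expect_true(all(sl_genotypes(low, "MUC5AC", 4.3)$sl_genotype == "SS"))
  expect_error(sl_genotypes(low, "MUC5AC", 9.9), "outside the observed")
})

test_that("short/long association degenerates to p = 1 when one class is absent", {
  low <- make_cohort(c("severe", "mild"), a = c(4.0, 4.1), b = c(4.2, 4.3))
  res <- sl_association(low, "MUC5AC", 4.3)
  expect_equal(res$p_value, 1)
})

test_that("short-allele enrichment in severe patients is detected at study scale", {
  # a two-allele spectrum where the short allele itself carries the risk:
  # S excess among severe at carrier OR 2 must show in the S/L table
  detected <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(seed = 900 + i, carrier_odds_ratio = 2,
                      spectrum = c("6.30" = 0.45, "6.90" = 0.55),
                      designated_allele = 6.3)
    coh <- simulate_cohort(cfg)
    res <- sl_association(coh, "MUC5AC", 6.55, "long_inclusive")
    detected <- detected + (res$p_value < 0.05)
  }
  expect_gt(detected / n_rep, 0.5)
})
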