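# Haplotype score test for a VNTR-class x SNP pair with a binary
# severity phenotype. Each individual's posterior expected haplotype
# dosages are computed once under the phenotype-independent EM model
# (double heterozygotes split between their two phase resolutions); the
# score vector is the dosage-weighted sum of phenotype residuals, the
# global statistic its quadratic form in the estimated null covariance
# (generalized inverse), and the permutation null is built by permuting
# phenotype labels with the dosages held fixed. Not re-estimating the
# posteriors within permutations is the standard score-test construction
# and is what makes 100,000 permutations tractable; it is the key
# approximation of this module.

# Posterior expected haplotype dosages (n x 2k matrix) under a fitted
# haplotype model; columns ordered (class1:major, class2:major, ...,
# class1:minor, ...).
hap_dosages <- function(h, ia, ib, g) {
  k <- nrow(h)
  n <- length(ia)
  D <- matrix(0, n, 2L * k)
  col_of <- function(cls, allele) (allele - 1L) * k + cls
  for (i in seq_len(n)) {
    if (g[i] == 0L) {
      D[i, col_of(ia[i], 1L)] <- D[i, col_of(ia[i], 1L)] + 1
      D[i, col_of(ib[i], 1L)] <- D[i, col_of(ib[i], 1L)] + 1
    } else if (g[i] == 2L) {
      D[i, col_of(ia[i], 2L)] <- D[i, col_of(ia[i], 2L)] + 1
      D[i, col_of(ib[i], 2L)] <- D[i, col_of(ib[i], 2L)] + 1
    } else if (ia[i] == ib[i]) {
      D[i, col_of(ia[i], 1L)] <- D[i, col_of(ia[i], 1L)] + 1
      D[i, col_of(ia[i], 2L)] <- D[i, col_of(ia[i], 2L)] + 1
    } else {
      w1 <- h[ia[i], 2] * h[ib[i], 1]   # (ia, minor) + (ib, major)
      w2 <- h[ia[i], 1] * h[ib[i], 2]
      s <- w1 + w2
      if (s <= 0) { w1 <- 0.5; w2 <- 0.5 } else { w1 <- w1 / s; w2 <- w2 / s }
      D[i, col_of(ia[i], 2L)] <- D[i, col_of(ia[i], 2L)] + w1
      D[i, col_of(ib[i], 1L)] <- D[i, col_of(ib[i], 1L)] + w1
      D[i, col_of(ia[i], 1L)] <- D[i, col_of(ia[i], 1L)] + w2
      D[i, col_of(ib[i], 2L)] <- D[i, col_of(ib[i], 2L)] + w2
    }
  }
  D
}

#' Haplotype score test with permutation p values
#'
#' @param cohort A `vntr_cohort`.
#' @param gene VNTR gene name.
#' @param partition An [allele_partition()] coding the VNTR alleles.
#' @param snp SNP column name.
#' @param n_perm Number of phenotype-label permutations (default 1e5;
#'   fewer than 100 draws triggers a warning). Permutation p values use
#'   the add-one estimator `(b + 1) / (B + 1)`.
#' @param seed Seed for the permutation stream.
#' @param rare_freq Haplotypes with EM frequency below this are pooled
#'   into a single `rare` class before scoring (stabilizes the
#'   covariance).
#' @param ... Passed to [em_haplotypes()].
#' @return A `haplo_score`: list with `haplotypes` (tibble: haplotype,
#'   frequency, score, z, p_asym, p_perm), `global` (tibble: statistic,
#'   df = covariance rank, p_asym, p_perm), `n`, `n_perm`, `seed`, and
#'   the fitted `model`.
#' @export
haplo_score_test <- function(cohort, gene, partition, snp, n_perm = 1e5,
                             seed = 1L, rare_freq = 0.005, ...) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) warn("fewer than 100 permutations: permutation p values will be very coarse")
  check_snp(cohort, snp)
  gc <- gene_complete(cohort, gene)
  g <- gc$data[[snp]]
  keep <- !is.na(g)
  if (!any(keep)) abort("no individuals with both loci observed")
  a <- gc$a[keep]; b <- gc$b[keep]; g <- as.integer(g[keep])
  phen <- gc$data$phenotype[keep]

  la <- partition_assign(partition, a, gc$unit)
  lb <- partition_assign(partition, b, gc$unit)
  labels <- sort(unique(c(la, lb)))
  k <- length(labels)
  fit <- em_two_locus(two_locus_classes(match(la, labels), match(lb, labels), g),
                      k, ...)
  if (!fit$converged) warn("haplotype EM did not converge; scores use the last iterate")
  h <- fit$h

  D <- hap_dosages(h, match(la, labels), match(lb, labels), g)
  hap_names <- c(paste0(labels, ":major"), paste0(labels, ":minor"))
  freqs <- c(h[, 1], h[, 2])

  common <- freqs >= rare_freq
  if (all(!common)) abort("all haplotypes fall below the rare-frequency threshold")
  if (any(!common)) {
    D <- cbind(D[, common, drop = FALSE],
               rare = rowSums(D[, !common, drop = FALSE]))
    hap_names <- c(hap_names[common], "rare")
    freqs <- c(freqs[common], sum(freqs[!common]))
  }

  y <- as.numeric(phen == "severe")
  n <- length(y)
  ybar <- mean(y)
  if (ybar %in% c(0, 1)) abort("both phenotype groups must be present")
  Dc <- scale(D, center = TRUE, scale = FALSE)
  V <- ybar * (1 - ybar) * crossprod(Dc)
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(ev) * 1e-10)
  if (rank == 0L) abort("degenerate data: score covariance has rank 0 (all individuals identical)")
  G <- MASS::ginv(V)
  U <- drop(crossprod(Dc, y))
  stat <- drop(U %*% G %*% U)
  vd <- diag(V)
  z <- ifelse(vd > 0, U / sqrt(vd), NA_real_)

  perm <- with_seed(seed, {
    hits_g <- 0L
    hits_h <- integer(length(U))
    batch <- 5000L
    done <- 0L
    while (done < n_perm) {
      m <- min(batch, n_perm - done)
      Y <- vapply(seq_len(m), function(j) sample(y), numeric(n))
      S <- crossprod(Dc, Y)                  # k x m score vectors
      stats_b <- colSums(S * (G %*% S))
      hits_g <- hits_g + sum(stats_b >= stat - 1e-12)
      zb <- abs(S / sqrt(pmax(vd, 1e-300)))
      hits_h <- hits_h + rowSums(zb >= abs(z) - 1e-12, na.rm = TRUE)
      done <- done + m
    }
    list(g = hits_g, h = hits_h)
  })

  structure(
    list(
      haplotypes = tibble::tibble(
        haplotype = hap_names, frequency = freqs, score = U, z = z,
        p_asym = 2 * pnorm(-abs(z)),
        p_perm = (perm$h + 1) / (n_perm + 1)
      ),
      global = tibble::tibble(
        statistic = stat, df = rank,
        p_asym = pchisq(stat, rank, lower.tail = FALSE),
        p_perm = (perm$g + 1) / (n_perm + 1)
      ),
      n = n, n_perm = n_perm, seed = seed,
      model = structure(
        list(h = matrix(h, k, 2, dimnames = list(labels, c("major", "minor"))),
             loglik = fit$loglik, converged = fit$converged, n = n, k = k,
             df = 2L * k - 1L, labels = labels, snp = snp,
             partition = partition$name, trace = fit$trace),
        class = "haplotype_model"
      )
    ),
    class = "haplo_score"
  )
}

#' Score test restricted to phase-unambiguous cohorts (oracle mode)
#'
#' Identical to [haplo_score_test()] but requires that the cohort contain
#' no double heterozygotes, so every posterior dosage is integral and the
#' score reduces to a standard contingency score test. Used as an oracle
#' for validating the phase-ambiguous path.
#'
#' @inheritParams haplo_score_test
#' @return A `haplo_score` (see [haplo_score_test()]).
#' @export
score_with_unambiguous_phase <- function(cohort, gene, partition, snp,
                                         n_perm = 1e5, seed = 1L,
                                         rare_freq = 0, ...) {
  check_snp(cohort, snp)
  gc <- gene_complete(cohort, gene)
  g <- gc$data[[snp]]
  keep <- !is.na(g)
  la <- partition_assign(partition, gc$a[keep], gc$unit)
  lb <- partition_assign(partition, gc$b[keep], gc$unit)
  if (any(la != lb & g[keep] == 1L)) {
    abort("cohort contains double heterozygotes; phase is not unambiguous")
  }
  haplo_score_test(cohort, gene, partition, snp, n_perm = n_perm,
                   seed = seed, rare_freq = rare_freq, ...)
}

#' @export
print.haplo_score <- function(x, ...) {
  cat(sprintf(
    "Haplotype score test (%s x %s, n = %d, %d permutations)\n  global: stat %.3f, df %d, asymptotic p %s, permutation p %s\n",
    x$model$partition, x$model$snp, x$n, x$n_perm,
    x$global$statistic, x$global$df,
    format_p2(x$global$p_asym), format_p2(x$global$p_perm)
  ))
  print(x$haplotypes)
  invisible(x)
}

#' @export
tidy.haplo_score <- function(x, ...) x$haplotypes

#' @export
glance.haplo_score <- function(x, ...) {
  tibble::tibble(
    statistic = x$global$statistic, df = x$global$df,
    p_asym = x$global$p_asym, p_perm = x$global$p_perm,
    n = x$n, n_perm = x$n_perm, seed = x$seed
  )
}
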