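# Differential-LD test: does splitting one VNTR size class into two
# (e.g. treating 6.3 kb and 6.4 kb as separate alleles) improve the fit
# of the two-locus haplotype model at a SNP, relative to keeping them
# collapsed? Both models are fit by EM on the same individuals and
# compared by a nested likelihood ratio.
#
# Nesting is made exact by lifting the coarse model onto the fine sample
# space: under the null, a merged class's haplotypes carry the SNP allele
# with a single shared conditional frequency, and the identity of the
# fine allele within its coarse class is an independent multinomial draw.
# The fine-data log-likelihood of that null model factorizes as
#   logL_null = logL_coarse + logL_split,
# where logL_split is the fully observed multinomial log-likelihood of
# the fine-within-coarse allele split (including the pairing constant for
# heterozygous-within-class genotypes). The statistic
#   Lambda = 2 (logL_fine - logL_null) >= 0
# is referred to a chi-square with df = (k_fine - k_coarse) x
# (SNP alleles - 1): the extra fine classes add one free SNP-conditional
# frequency each, while their marginal frequencies are absorbed by the
# split term. The true null can sit on the simplex boundary (a haplotype
# frequency of zero), so the chi-square reference is an approximation
# whose actual type-I error the calibration suite quantifies.

#' Nested likelihood-ratio comparison of two allele partitions at a SNP
#'
#' @param cohort A `vntr_cohort`.
#' @param gene VNTR gene name.
#' @param fine,coarse [allele_partition()] objects; `fine` must refine
#'   `coarse` (every fine class maps into exactly one coarse class) and
#'   have strictly more observed classes.
#' @param snp SNP column name.
#' @param ... Passed to the EM (`tol`, `max_iter`, `restarts`).
#' @return A `partition_lrt` one-row tibble: `snp`, `k_fine`, `k_coarse`,
#'   `logl_fine`, `logl_coarse`, `logl_split`, `lambda`, `df`, `p_value`,
#'   `converged`. When either EM fails to converge the comparison is
#'   flagged and `p_value` is `NA`.
#' @export
compare_partitions <- function(cohort, gene, fine, coarse, snp, ...) {
  check_snp(cohort, snp)
  gc <- gene_complete(cohort, gene)
  g <- gc$data[[snp]]
  keep <- !is.na(g)
  if (!any(keep)) abort("no individuals with both loci observed")
  a <- gc$a[keep]; b <- gc$b[keep]; g <- as.integer(g[keep])

  fa <- partition_assign(fine, a, gc$unit)
  fb <- partition_assign(fine, b, gc$unit)
  ca <- partition_assign(coarse, a, gc$unit)
  cb <- partition_assign(coarse, b, gc$unit)

  # refinement check on the observed alleles
  map_fc <- unique(tibble::tibble(f = c(fa, fb), c = c(ca, cb)))
  if (anyDuplicated(map_fc$f)) {
    abort("partitions are not nested: a fine class maps to more than one coarse class")
  }
  k_f <- length(unique(map_fc$f))
  k_c <- length(unique(map_fc$c))
  if (k_f == k_c) {
    abort("fine partition does not refine coarse on the observed alleles (df = 0)")
  }

  fl <- sort(unique(c(fa, fb)))
  cl <- sort(unique(c(ca, cb)))
  fit_f <- em_two_locus(two_locus_classes(match(fa, fl), match(fb, fl), g),
                        k_f, ...)
  fit_c <- em_two_locus(two_locus_classes(match(ca, cl), match(cb, cl), g),
                        k_c, ...)

  # fully observed split likelihood of fine alleles within coarse classes
  n_fine <- table(factor(c(fa, fb), levels = fl))
  coarse_of <- map_fc$c[match(fl, map_fc$f)]
  n_coarse_for_fine <- vapply(coarse_of,
                              function(cc) sum(n_fine[coarse_of == cc]),
                              numeric(1))
  q_hat <- as.numeric(n_fine) / n_coarse_for_fine
  terms <- as.numeric(n_fine) * log(q_hat)
  terms[as.numeric(n_fine) == 0] <- 0
  n_het_within <- sum(fa != fb & ca == cb)
  logl_split <- sum(terms) + n_het_within * log(2)

  converged <- fit_f$converged && fit_c$converged
  lambda <- 2 * (fit_f$loglik - fit_c$loglik - logl_split)
  if (is.finite(lambda) && lambda < -1e-6) {
    warn(sprintf("likelihood ratio fell below the numerical floor (%.3g); clipped to 0", lambda))
  }
  lambda <- max(lambda, 0)
  df <- (k_f - k_c) * 1L
  out <- tibble::tibble(
    snp = snp, k_fine = k_f, k_coarse = k_c,
    logl_fine = fit_f$loglik, logl_coarse = fit_c$loglik,
    logl_split = logl_split, lambda = lambda, df = df,
    p_value = if (converged) pchisq(lambda, df, lower.tail = FALSE) else NA_real_,
    converged = converged
  )
  class(out) <- c("partition_lrt", class(out))
  out
}

#' Scan a SNP panel with the partition likelihood-ratio test
#'
#' Runs [compare_partitions()] at each SNP and applies a Bonferroni
#' correction over the number of SNPs scanned, registering every test in
#' the ledger.
#'
#' @inheritParams compare_partitions
#' @param snps Ordered character vector of SNP names (may be empty).
#' @param ledger A [test_ledger()] to extend.
#' @param family Ledger family label for the scan.
#' @return Tibble with one row per SNP (columns of [compare_partitions()]
#'   plus `p_corrected`); the updated ledger is attached as attribute
#'   `"ledger"`.
#' @export
scan_partitions <- function(cohort, gene, fine, coarse, snps,
                            ledger = test_ledger(),
                            family = paste0(gene, "_partition_lrt"), ...) {
  rows <- purrr::map_dfr(snps, function(s) {
    compare_partitions(cohort, gene, fine, coarse, s, ...)
  })
  if (nrow(rows)) {
    rows$p_corrected <- pmin(1, rows$p_value * length(snps))
    for (i in seq_len(nrow(rows))) {
      ledger <- ledger_add(
        ledger,
        test_id = sprintf("%s_lrt_%s", gene, rows$snp[i]),
        description = sprintf(
          "partition LRT (%s vs %s) at %s", fine$name, coarse$name, rows$snp[i]
        ),
        p = rows$p_value[i], families = family
      )
    }
  } else {
    rows <- tibble::tibble(
      snp = character(), k_fine = integer(), k_coarse = integer(),
      logl_fine = numeric(), logl_coarse = numeric(),
      logl_split = numeric(), lambda = numeric(), df = integer(),
      p_value = numeric(), converged = logical(), p_corrected = numeric()
    )
  }
  attr(rows, "ledger") <- ledger
  rows
}
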