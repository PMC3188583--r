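# Two-locus haplotype-frequency EM from unphased genotypes. Locus A is a
# VNTR coded into k partition classes (or a SNP coded as 2 classes),
# locus B a biallelic SNP. The only phase-ambiguous configuration is the
# double heterozygote, which the E-step splits between its two phase
# resolutions in proportion to the current haplotype-frequency products;
# the M-step re-estimates frequencies from expected haplotype counts. The
# reported log-likelihood is the observed-data (phase-marginalized)
# multinomial likelihood over unordered two-locus genotypes.

# Collapse per-individual data into genotype classes: (ia <= ib) label
# indices at locus A, SNP minor-allele count g, and a count n per class.
two_locus_classes <- function(la, lb, g) {
  ia <- pmin(la, lb)
  ib <- pmax(la, lb)
  df <- dplyr::count(tibble::tibble(ia = ia, ib = ib, g = g),
                     .data$ia, .data$ib, .data$g, name = "n")
  df
}

# P(genotype class | h) for an n x 2 haplotype frequency matrix h
# (columns: major, minor allele at the SNP).
class_prob <- function(h, cls) {
  p <- numeric(nrow(cls))
  for (r in seq_len(nrow(cls))) {
    ia <- cls$ia[r]; ib <- cls$ib[r]; g <- cls$g[r]
    p[r] <- if (g == 0L) {
      if (ia == ib) h[ia, 1]^2 else 2 * h[ia, 1] * h[ib, 1]
    } else if (g == 2L) {
      if (ia == ib) h[ia, 2]^2 else 2 * h[ia, 2] * h[ib, 2]
    } else if (ia == ib) {
      2 * h[ia, 1] * h[ia, 2]
    } else {
      2 * h[ia, 2] * h[ib, 1] + 2 * h[ia, 1] * h[ib, 2]
    }
  }
  p
}

em_two_locus <- function(cls, k, tol = 1e-10, max_iter = 1000L,
                         restarts = 5L) {
  n_ind <- sum(cls$n)

  # marginal-product start
  a_counts <- numeric(k)
  for (r in seq_len(nrow(cls))) {
    a_counts[cls$ia[r]] <- a_counts[cls$ia[r]] + cls$n[r]
    a_counts[cls$ib[r]] <- a_counts[cls$ib[r]] + cls$n[r]
  }
  minor_frac <- sum(cls$n * cls$g) / (2 * n_ind)
  h0 <- outer(a_counts / sum(a_counts), c(1 - minor_frac, minor_frac))
  h0 <- pmax(h0, 1e-12)
  h0 <- h0 / sum(h0)

  run <- function(h) {
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p <- class_prob(h, cls)
      if (any(p <= 0 & cls$n > 0)) {
        trace <- c(trace, -Inf)
        break
      }
      ll <- sum(cls$n * log(p))
      trace <- c(trace, ll)
      # E-step: expected haplotype counts
      cnt <- matrix(0, k, 2)
      for (r in seq_len(nrow(cls))) {
        ia <- cls$ia[r]; ib <- cls$ib[r]; g <- cls$g[r]; n <- cls$n[r]
        if (g == 0L) {
          cnt[ia, 1] <- cnt[ia, 1] + n
          cnt[ib, 1] <- cnt[ib, 1] + n
        } else if (g == 2L) {
          cnt[ia, 2] <- cnt[ia, 2] + n
          cnt[ib, 2] <- cnt[ib, 2] + n
        } else if (ia == ib) {
          cnt[ia, 1] <- cnt[ia, 1] + n
          cnt[ia, 2] <- cnt[ia, 2] + n
        } else {
          w1 <- h[ia, 2] * h[ib, 1]   # (ia, minor) + (ib, major)
          w2 <- h[ia, 1] * h[ib, 2]
          s <- w1 + w2
          w1 <- w1 / s; w2 <- w2 / s
          cnt[ia, 2] <- cnt[ia, 2] + n * w1
          cnt[ib, 1] <- cnt[ib, 1] + n * w1
          cnt[ia, 1] <- cnt[ia, 1] + n * w2
          cnt[ib, 2] <- cnt[ib, 2] + n * w2
        }
      }
      h_new <- cnt / (2 * n_ind)
      if (it > 1L && trace[it] - trace[it - 1L] < tol) {
        converged <- TRUE
        h <- h_new
        break
      }
      h <- h_new
    }
    list(h = h, loglik = trace[length(trace)], trace = trace,
         converged = converged)
  }

  best <- run(h0)
  # jittered restarts guard against multimodal likelihoods at small n;
  # fixed internal seeds keep the function deterministic
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      hj <- with_seed(1000L + r, {
        j <- h0 * exp(matrix(runif(2 * k, -0.7, 0.7), k, 2))
        j / sum(j)
      })
      cand <- run(hj)
      if (is.finite(cand$loglik) && cand$loglik > best$loglik + 1e-6) best <- cand
    }
  }
  best
}

# Build the two-locus data for a VNTR (partitioned) x SNP pair with
# pairwise deletion of individuals missing either locus.
vntr_snp_data <- function(cohort, gene, partition, snp) {
  check_snp(cohort, snp)
  gc <- gene_complete(cohort, gene)
  g <- gc$data[[snp]]
  keep <- !is.na(g)
  if (!any(keep)) abort("no individuals with both loci observed")
  lab_a <- partition_assign(partition, gc$a[keep], gc$unit)
  lab_b <- partition_assign(partition, gc$b[keep], gc$unit)
  labels <- sort(unique(c(lab_a, lab_b)))
  list(
    labels = labels,
    cls = two_locus_classes(match(lab_a, labels), match(lab_b, labels),
                            as.integer(g[keep])),
    n = sum(keep),
    ids = gc$data$id[keep]
  )
}

#' Two-locus haplotype-frequency EM for a VNTR x SNP pair
#'
#' @param cohort A `vntr_cohort`.
#' @param gene VNTR gene name.
#' @param partition An [allele_partition()] coding the VNTR alleles into
#'   k classes.
#' @param snp SNP column name.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations.
#' @param restarts Number of jittered restarts retained if any improves
#'   the log-likelihood by more than 1e-6.
#' @return A `haplotype_model`: list with `h` (k x 2 frequency matrix,
#'   rows the partition classes, columns major/minor SNP allele),
#'   `loglik`, `trace`, `converged`, `n` (individuals used), `k`,
#'   `df` (free parameters, 2k - 1), `labels`, `snp`, `partition`.
#' @export
em_haplotypes <- function(cohort, gene, partition, snp, tol = 1e-10,
                          max_iter = 1000L, restarts = 5L) {
  dat <- vntr_snp_data(cohort, gene, partition, snp)
  fit <- em_two_locus(dat$cls, length(dat$labels), tol, max_iter, restarts)
  h <- fit$h
  dimnames(h) <- list(dat$labels, c("major", "minor"))
  structure(
    list(h = h, loglik = fit$loglik, trace = fit$trace,
         converged = fit$converged, n = dat$n, k = length(dat$labels),
         df = 2L * length(dat$labels) - 1L, labels = dat$labels,
         snp = snp, partition = partition$name),
    class = "haplotype_model"
  )
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf(
    "Two-locus haplotype model: %s x %s (n = %d, logLik %.4f%s)\n",
    x$partition, x$snp, x$n, x$loglik,
    if (x$converged) "" else ", NOT converged"
  ))
  print(round(x$h, 4))
  invisible(x)
}

#' @export
tidy.haplotype_model <- function(x, ...) {
  tibble::tibble(
    vntr_class = rep(rownames(x$h), 2),
    snp_allele = rep(colnames(x$h), each = nrow(x$h)),
    frequency = as.vector(x$h)
  )
}

#' @export
glance.haplotype_model <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, converged = x$converged, n = x$n,
                 k = x$k, df = x$df, n_iter = length(x$trace))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' `r^2 = D^2 / (p (1-p) q (1-q))` with `D` taken from EM-estimated
#' two-locus haplotype frequencies. Either two SNPs, or (when `snp_b` is
#' `NULL`) the VNTR under a two-class partition against `snp_a`.
#'
#' @param cohort A `vntr_cohort`.
#' @param snp_a First SNP.
#' @param snp_b Second SNP, or `NULL` to pair the VNTR with `snp_a`.
#' @param gene,partition VNTR gene and a two-class [allele_partition()],
#'   required when `snp_b` is `NULL`.
#' @return r-squared in `[0, 1]`, or `NA` if either locus is monomorphic
#'   in the data used.
#' @export
r_squared <- function(cohort, snp_a, snp_b = NULL, gene = NULL,
                      partition = NULL) {
  if (is.null(snp_b)) {
    if (is.null(gene) || is.null(partition)) {
      abort("gene and a two-class partition are required for a VNTR pair")
    }
    dat <- vntr_snp_data(cohort, gene, partition, snp_a)
    if (length(dat$labels) != 2L) {
      abort("VNTR partition must yield exactly 2 observed classes for r-squared")
    }
    fit <- em_two_locus(dat$cls, 2L)
  } else {
    check_snp(cohort, snp_a)
    check_snp(cohort, snp_b)
    ga <- cohort[[snp_a]]
    gb <- cohort[[snp_b]]
    keep <- !is.na(ga) & !is.na(gb)
    if (!any(keep)) abort("no individuals with both SNPs observed")
    # code snp_a's alleles as locus-A classes: 1 = major, 2 = minor
    ga <- as.integer(ga[keep]); gb <- as.integer(gb[keep])
    la <- ifelse(ga >= 1L, 2L, 1L)
    lb <- ifelse(ga == 2L, 2L, 1L)
    fit <- em_two_locus(two_locus_classes(la, lb, gb), 2L)
  }
  h <- fit$h
  pa <- sum(h[1, ]); qa <- 1 - pa
  pb <- sum(h[, 1]); qb <- 1 - pb
  denom <- pa * qa * pb * qb
  if (denom <= 0) return(NA_real_)
  D <- h[1, 1] - pa * pb
  min(1, D^2 / denom)
}

#' Chi-square test of SNP genotype against VNTR partition genotype
#'
#' Pearson chi-square (no continuity correction) on the genotype-by-
#' genotype table: VNTR partition genotype classes (unordered pairs of
#' class labels) against SNP minor-allele count (0/1/2). Rows or columns
#' with zero margin are dropped and recorded in the result.
#'
#' @inheritParams em_haplotypes
#' @return One-row tibble: `chi2`, `df`, `p_value`, `n`, and list-columns
#'   `dropped_rows`/`dropped_cols` with the dropped margin labels.
#' @export
chi2_vntr_snp <- function(cohort, gene, partition, snp) {
  check_snp(cohort, snp)
  gc <- gene_complete(cohort, gene)
  g <- gc$data[[snp]]
  keep <- !is.na(g)
  if (!any(keep)) abort("no individuals with both loci observed")
  la <- partition_assign(partition, gc$a[keep], gc$unit)
  lb <- partition_assign(partition, gc$b[keep], gc$unit)
  labels <- sort(unique(c(la, lb)))
  pairs <- outer(labels, labels, paste, sep = "/")
  geno_levels <- pairs[upper.tri(pairs, diag = TRUE)]
  geno <- factor(paste(pmin(la, lb), pmax(la, lb), sep = "/"),
                 levels = geno_levels)
  tab <- table(vntr = geno, snp = factor(g[keep], levels = 0:2))
  dropped_rows <- rownames(tab)[rowSums(tab) == 0]
  dropped_cols <- colnames(tab)[colSums(tab) == 0]
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    return(tibble::tibble(
      chi2 = NA_real_, df = 0L, p_value = 1, n = sum(keep),
      dropped_rows = list(dropped_rows), dropped_cols = list(dropped_cols)
    ))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble::tibble(
    chi2 = unname(ct$statistic), df = unname(ct$parameter),
    p_value = ct$p.value, n = sum(keep),
    dropped_rows = list(dropped_rows), dropped_cols = list(dropped_cols)
  )
}

#' Significance bins for LD-map p values
#'
#' Bins follow the conventional LD-map color coding: `white` (p > 0.1),
#' `light_blue` (1e-5 < p <= 0.1), `medium_blue` (1e-10 < p <= 1e-5),
#' `dark_blue` (1e-50 < p <= 1e-10), `red` (p <= 1e-50).
#'
#' @param p Numeric vector of p values.
#' @return Factor of bin labels.
#' @export
ld_bin <- function(p) {
  lv <- c("white", "light_blue", "medium_blue", "dark_blue", "red")
  out <- ifelse(p > 0.1, "white",
         ifelse(p > 1e-5, "light_blue",
         ifelse(p > 1e-10, "medium_blue",
         ifelse(p > 1e-50, "dark_blue", "red"))))
  factor(out, levels = lv)
}

#' Pairwise LD map for a SNP panel around a partitioned VNTR
#'
#' Computes the symmetric matrix of pairwise SNP r-squared values (via
#' the two-locus EM) together with the chi-square test of each SNP's
#' genotype against the VNTR partition genotype, binned with [ld_bin()].
#'
#' @inheritParams em_haplotypes
#' @param snps Ordered character vector of >= 2 SNP names.
#' @return An `ld_map`: list with `r2` (named symmetric matrix) and
#'   `vntr` (tibble: snp, chi2, df, p_value, bin).
#' @export
ld_map <- function(cohort, gene, partition, snps) {
  if (length(snps) < 2L) abort("need at least 2 SNPs for an LD map")
  m <- length(snps)
  r2 <- matrix(NA_real_, m, m, dimnames = list(snps, snps))
  diag(r2) <- 1
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      v <- r_squared(cohort, snps[i], snps[j])
      r2[i, j] <- v
      r2[j, i] <- v
    }
  }
  vntr <- purrr::map_dfr(snps, function(s) {
    res <- chi2_vntr_snp(cohort, gene, partition, s)
    tibble::tibble(snp = s, chi2 = res$chi2, df = res$df,
                   p_value = res$p_value)
  })
  vntr$bin <- ld_bin(vntr$p_value)
  structure(list(r2 = r2, vntr = vntr, snps = snps, gene = gene,
                 partition = partition$name),
            class = "ld_map")
}

#' @export
print.ld_map <- function(x, ...) {
  cat(sprintf("LD map: %d SNPs around %s (%s)\n", length(x$snps), x$gene,
              x$partition))
  print(round(x$r2, 3))
  print(x$vntr)
  invisible(x)
}

#' @export
tidy.ld_map <- function(x, ...) {
  idx <- which(upper.tri(x$r2), arr.ind = TRUE)
  tibble::tibble(
    marker1 = rownames(x$r2)[idx[, 1]],
    marker2 = colnames(x$r2)[idx[, 2]],
    r2 = x$r2[idx]
  )
}

#' Plot an LD map
#'
#' @param object An [ld_map()].
#' @param ... Unused.
#' @return A ggplot: r-squared heat map with the VNTR-association bin of
#'   each SNP along the top.
#' @export
autoplot.ld_map <- function(object, ...) {
  long <- tidy(object)
  long$marker1 <- factor(long$marker1, levels = object$snps)
  long$marker2 <- factor(long$marker2, levels = object$snps)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker1, y = .data$marker2,
                                     fill = .data$r2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(r^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
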