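# Independent oracles and small builders used across the suite. These are
# deliberately written from first principles (different algorithms and
# parameterizations than the package) so they can certify the package's
# results rather than mirror them.

# Brute-force Freeman-Halton p value for a 2-row table: enumerate every
# feasible first row directly from a cartesian grid and sum multivariate
# hypergeometric probabilities computed via lfactorial.
oracle_fh_2xc <- function(m) {
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  logp <- function(t) {
    sum(lfactorial(rs)) + sum(lfactorial(cs)) - lfactorial(n) -
      sum(lfactorial(t))
  }
  obs <- logp(m)
  nc <- ncol(m)
  grid <- expand.grid(lapply(seq_len(nc), function(j) 0:min(rs[1], cs[j])))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    a <- as.integer(grid[r, ])
    if (sum(a) != rs[1]) next
    t <- rbind(a, cs - a)
    if (any(t < 0)) next
    lp <- logp(t)
    if (lp <= obs + log1p(1e-7)) tot <- tot + exp(lp)
  }
  min(1, tot)
}

# Observed-data two-locus log-likelihood of unphased genotypes computed by
# explicit summation over ordered haplotype-pair assignments (alleles
# coded 1 = major, 2 = minor at the SNP).
oracle_two_locus_loglik <- function(h, la, lb, g) {
  k <- nrow(h)
  key <- paste(pmin(la, lb), pmax(la, lb), g)
  classes <- unique(key)
  ll <- 0
  for (cl in classes) {
    i <- which(key == cl)[1]
    p <- 0
    for (c1 in 1:k) for (a1 in 1:2) for (c2 in 1:k) for (a2 in 1:2) {
      if (all(sort(c(c1, c2)) == sort(c(la[i], lb[i]))) &&
          (a1 == 2L) + (a2 == 2L) == g[i]) {
        p <- p + h[c1, a1] * h[c2, a2]
      }
    }
    ll <- ll + sum(key == cl) * log(p)
  }
  ll
}

# Direct maximization of the two-locus likelihood over the haplotype
# frequency simplex via multi-start quasi-Newton search on a softmax
# parameterization -- independent of the EM under test.
oracle_max_loglik <- function(la, lb, g, k, n_starts = 8) {
  neg <- function(theta) {
    h <- matrix(exp(theta - max(theta)), k, 2)
    h <- h / sum(h)
    -oracle_two_locus_loglik(h, la, lb, g)
  }
  # independent marginal-product start from raw allele counts
  a_counts <- tabulate(c(la, lb), k)
  mf <- sum(g) / (2 * length(g))
  h0 <- outer(pmax(a_counts, 0.5) / sum(pmax(a_counts, 0.5)),
              c(1 - mf, max(mf, 1e-3)))
  starts <- list(log(h0))
  for (s in seq_len(n_starts)) {
    set.seed(7000 + s)
    starts[[s + 1]] <- matrix(rnorm(2 * k, 0, 1.5), k, 2)
  }
  best <- Inf
  for (th in starts) {
    o1 <- optim(as.vector(th), neg, method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    o2 <- optim(o1$par, neg, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))
    best <- min(best, o1$value, o2$value)
  }
  -best
}

# Minimal cohort builder for hand-made genotype configurations.
make_cohort <- function(phenotype, a, b, snps = list(), gene = "MUC5AC",
                        unit = 0.05) {
  df <- tibble::tibble(
    id = sprintf("i%03d", seq_along(phenotype)), phenotype = phenotype
  )
  df[[paste0(gene, "_a")]] <- a
  df[[paste0(gene, "_b")]] <- b
  for (s in names(snps)) df[[s]] <- snps[[s]]
  new_cohort(df, genes = setNames(unit, gene), snps = names(snps))
}

# Shared partitions for the 6.3 / 6.4 differential-LD analyses.
fine_63_64 <- function() {
  allele_partition(list(`6.3` = 6.3, `6.4` = 6.4), other = "other")
}
coarse_63_64 <- function() {
  allele_partition(list(`6.3/6.4` = c(6.3, 6.4)), other = "other")
}
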