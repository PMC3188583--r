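# Two-component normal mixture on a (chromosome-weighted) allele-size
# spectrum, used to dichotomize a bimodal spectrum into short (S) and
# long (L) alleles at a data-driven cut-point.

#' Fit a two-component normal mixture to a pooled allele spectrum
#'
#' EM on allele sizes with chromosome counts as weights (each chromosome
#' is one observation). Initialization is deterministic: the sample is
#' split at the weighted median and each half provides the starting mean,
#' standard deviation and weight of one component. Components are
#' canonicalized by increasing mean. Convergence when the log-likelihood
#' gain falls below `tol` or after `max_iter` iterations. A component
#' standard deviation collapsing below 0.01 (the size-grid floor) marks
#' the fit degenerate; a BIC comparison against a single normal records
#' whether the mixture is actually supported (`bimodal`), and
#' [cut_point()] refuses fits that fail either screen.
#'
#' @param spec An [allele_spectrum()] (pooled counts are used), or a
#'   two-column data frame `allele`/`pooled`.
#' @param tol Log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return A `mixture_fit`: list with `mu`, `sigma`, `pi` (each length 2,
#'   ordered by mean), `loglik`, `trace` (per-iteration log-likelihood),
#'   `converged`, `degenerate`, `bimodal`, `bic_mixture`, `bic_single`,
#'   `n_chrom`.
#' @export
fit_mixture <- function(spec, tol = 1e-8, max_iter = 500L) {
  x <- spec$allele
  w <- as.numeric(spec$pooled)
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (length(x) < 2L) abort("need at least 2 distinct allele sizes to fit a mixture")
  n <- sum(w)

  # deterministic split at the weighted median
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cum <- cumsum(w) / n
  split <- which(cum >= 0.5)[1]
  lo <- seq_len(split)
  hi <- if (split < length(x)) (split + 1L):length(x) else split
  wmean <- function(v, wt) sum(v * wt) / sum(wt)
  wsd <- function(v, wt) {
    m <- wmean(v, wt)
    sqrt(max(sum(wt * (v - m)^2) / sum(wt), 1e-4))
  }
  mu <- c(wmean(x[lo], w[lo]), wmean(x[hi], w[hi]))
  sg <- c(wsd(x[lo], w[lo]), wsd(x[hi], w[hi]))
  pi1 <- sum(w[lo]) / n
  pp <- c(pi1, 1 - pi1)
  if (mu[1] == mu[2]) mu <- mu + c(-0.5, 0.5) * max(diff(range(x)) / 4, 0.05)

  loglik_of <- function(mu, sg, pp) {
    dens <- pp[1] * dnorm(x, mu[1], sg[1]) + pp[2] * dnorm(x, mu[2], sg[2])
    sum(w * log(pmax(dens, 1e-300)))
  }
  trace <- loglik_of(mu, sg, pp)
  converged <- FALSE
  degenerate <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pp[1] * dnorm(x, mu[1], sg[1])
    d2 <- pp[2] * dnorm(x, mu[2], sg[2])
    tot <- pmax(d1 + d2, 1e-300)
    g1 <- w * d1 / tot
    g2 <- w * d2 / tot
    pp <- c(sum(g1), sum(g2)) / n
    mu <- c(sum(g1 * x) / sum(g1), sum(g2 * x) / sum(g2))
    sg <- c(
      sqrt(sum(g1 * (x - mu[1])^2) / sum(g1)),
      sqrt(sum(g2 * (x - mu[2])^2) / sum(g2))
    )
    if (any(!is.finite(sg)) || any(sg < 0.01)) {
      degenerate <- TRUE
      sg <- pmax(sg, 0.01, na.rm = TRUE)
      trace <- c(trace, loglik_of(mu, sg, pp))
      break
    }
    ll <- loglik_of(mu, sg, pp)
    trace <- c(trace, ll)
    if (ll - trace[length(trace) - 1L] < tol) {
      converged <- TRUE
      break
    }
  }

  # canonical order by mean
  o <- order(mu)
  mu <- mu[o]; sg <- sg[o]; pp <- pp[o]
  ll <- trace[length(trace)]

  # single-normal reference for the bimodality screen
  m0 <- wmean(x, w)
  s0 <- wsd(x, w)
  ll0 <- sum(w * log(pmax(dnorm(x, m0, s0), 1e-300)))
  bic_mix <- -2 * ll + 5 * log(n)
  bic_one <- -2 * ll0 + 2 * log(n)

  structure(
    list(
      mu = mu, sigma = sg, pi = pp, loglik = ll, trace = trace,
      converged = converged, degenerate = degenerate,
      bimodal = bic_mix < bic_one,
      bic_mixture = bic_mix, bic_single = bic_one, n_chrom = n
    ),
    class = "mixture_fit"
  )
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf(
    "2-component normal mixture (n = %g chromosomes)\n  mu = (%.3f, %.3f)  sigma = (%.3f, %.3f)  pi = (%.3f, %.3f)\n  logLik %.4f  converged: %s  bimodal (BIC): %s%s\n",
    x$n_chrom, x$mu[1], x$mu[2], x$sigma[1], x$sigma[2], x$pi[1], x$pi[2],
    x$loglik, x$converged, x$bimodal,
    if (x$degenerate) "  [degenerate]" else ""
  ))
  invisible(x)
}

#' @export
tidy.mixture_fit <- function(x, ...) {
  tibble::tibble(
    component = 1:2, mu = x$mu, sigma = x$sigma, pi = x$pi
  )
}

#' @export
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, converged = x$converged, degenerate = x$degenerate,
    bimodal = x$bimodal, bic_mixture = x$bic_mixture,
    bic_single = x$bic_single, n_chrom = x$n_chrom
  )
}

#' Short/long cut-point from a mixture fit
#'
#' The `"mixture_2sd"` rule places the cut halfway between "two standard
#' deviations above the lower component's mean" and "two standard
#' deviations below the upper component's mean", i.e. the midpoint of
#' `mu1 + 2*sigma1` and `mu2 - 2*sigma2`. The `"density_crossing"` rule
#' returns the point between the two means where the weighted component
#' densities are equal. A numeric `rule` is a fixed cut-point returned
#' as-is (the externally motivated "biological" cut-point pathway), in
#' which case `fit` may be `NULL`.
#'
#' @param fit A [fit_mixture()] result (or `NULL` for a fixed rule).
#' @param rule `"mixture_2sd"`, `"density_crossing"`, or a number.
#' @return The cut-point in kb.
#' @export
cut_point <- function(fit, rule = "mixture_2sd") {
  if (is.numeric(rule)) {
    assert_scalar_number(rule, "rule", positive = TRUE)
    return(rule)
  }
  rule <- match.arg(rule, c("mixture_2sd", "density_crossing"))
  if (is.null(fit) || !inherits(fit, "mixture_fit")) {
    abort("a mixture_fit is required unless a fixed numeric cut-point is given")
  }
  if (fit$degenerate) abort("degenerate mixture fit (collapsed component); no cut-point")
  if (!fit$converged) abort("mixture fit did not converge; no cut-point")
  if (!fit$bimodal) {
    abort("spectrum is not bimodal by the BIC screen; refusing to dichotomize")
  }
  if (rule == "mixture_2sd") {
    cut <- mean(c(fit$mu[1] + 2 * fit$sigma[1], fit$mu[2] - 2 * fit$sigma[2]))
  } else {
    f <- function(z) {
      log(fit$pi[1]) + dnorm(z, fit$mu[1], fit$sigma[1], log = TRUE) -
        log(fit$pi[2]) - dnorm(z, fit$mu[2], fit$sigma[2], log = TRUE)
    }
    if (f(fit$mu[1]) * f(fit$mu[2]) > 0) {
      abort("no density crossing between the component means")
    }
    cut <- uniroot(f, c(fit$mu[1], fit$mu[2]))$root
  }
  if (cut <= fit$mu[1] || cut >= fit$mu[2]) {
    abort("cut-point fell outside the open interval between component means")
  }
  cut
}

#' Assign short/long genotypes at a cut-point
#'
#' Each allele is classified short (S) or long (L) relative to the
#' cut-point; a genotype is the unordered pair. Both boundary conventions
#' are explicit because published analyses use both: `"short_inclusive"`
#' puts an allele equal to the cut-point in S (S <= cut < L),
#' `"long_inclusive"` puts it in L (S < cut <= L).
#'
#' @param cohort A `vntr_cohort`.
#' @param gene Gene name.
#' @param cut The cut-point (kb).
#' @param boundary `"short_inclusive"` or `"long_inclusive"`.
#' @return Tibble: `id`, `phenotype`, `sl_genotype` (factor SS/SL/LL) for
#'   individuals typed at the gene.
#' @export
sl_genotypes <- function(cohort, gene, cut,
                         boundary = c("short_inclusive", "long_inclusive")) {
  boundary <- match.arg(boundary)
  gc <- gene_complete(cohort, gene)
  rng <- range(c(gc$a, gc$b))
  if (cut < rng[1] || cut > rng[2]) {
    abort(sprintf("cut-point %.3f outside the observed allele range [%.2f, %.2f]",
                  cut, rng[1], rng[2]))
  }
  eps <- gc$unit * 1e-6
  is_short <- function(v) if (boundary == "short_inclusive") v <= cut + eps else v < cut - eps
  n_short <- is_short(gc$a) + is_short(gc$b)
  tibble::tibble(
    id = gc$data$id, phenotype = gc$data$phenotype,
    sl_genotype = factor(c("LL", "SL", "SS")[n_short + 1L],
                         levels = c("SS", "SL", "LL"))
  )
}

#' Severity association of short/long genotypes
#'
#' Fisher-Freeman-Halton exact test on the 2 x 3 severity-by-genotype
#' (SS/SL/LL) table at a given cut-point.
#'
#' @inheritParams sl_genotypes
#' @return List of class `sl_assoc`: `table` (2 x 3 counts), `p_value`,
#'   `cut`, `boundary`, `test` (the underlying `fh_test`).
#' @export
sl_association <- function(cohort, gene, cut,
                           boundary = c("short_inclusive", "long_inclusive")) {
  boundary <- match.arg(boundary)
  g <- sl_genotypes(cohort, gene, cut, boundary)
  tab <- table(phenotype = g$phenotype, genotype = g$sl_genotype)
  m <- matrix(as.integer(tab), nrow = 2,
              dimnames = list(phenotype = rownames(tab), genotype = colnames(tab)))
  ft <- fisher_exact_rxc(m)
  structure(
    list(table = m, p_value = ft$p_value, cut = cut, boundary = boundary,
         test = ft),
    class = "sl_assoc"
  )
}

#' @export
print.sl_assoc <- function(x, ...) {
  cat(sprintf("S/L genotype association (cut %.3f, %s): p = %s\n",
              x$cut, x$boundary, format_p2(x$p_value)))
  print(x$table)
  invisible(x)
}

#' @export
tidy.sl_assoc <- function(x, ...) {
  tibble::tibble(cut = x$cut, boundary = x$boundary, p_value = x$p_value)
}

#' Plot a mixture fit over the allele spectrum
#'
#' @param object A [fit_mixture()] result.
#' @param spec The [allele_spectrum()] the fit was computed from (for the
#'   histogram layer); optional.
#' @param cut Optional cut-point to mark.
#' @param ... Unused.
#' @return A ggplot of the weighted component densities (and spectrum).
#' @export
autoplot.mixture_fit <- function(object, spec = NULL, cut = NULL, ...) {
  lim <- if (!is.null(spec)) range(spec$allele) else
    range(object$mu + c(-3, 3) * object$sigma)
  grid <- seq(lim[1] - 0.2, lim[2] + 0.2, length.out = 400)
  dens <- tibble::tibble(
    allele = rep(grid, 2),
    component = factor(rep(1:2, each = length(grid))),
    density = c(object$pi[1] * dnorm(grid, object$mu[1], object$sigma[1]),
                object$pi[2] * dnorm(grid, object$mu[2], object$sigma[2]))
  )
  p <- ggplot2::ggplot()
  if (!is.null(spec)) {
    bw <- attr(spec, "unit") %||% 0.05
    p <- p + ggplot2::geom_col(
      data = tibble::tibble(allele = spec$allele,
                            density = spec$pooled / (sum(spec$pooled) * bw)),
      ggplot2::aes(x = .data$allele, y = .data$density),
      width = bw, fill = "grey80"
    )
  }
  p <- p + ggplot2::geom_line(
    data = dens,
    ggplot2::aes(x = .data$allele, y = .data$density, colour = .data$component)
  )
  if (!is.null(cut)) p <- p + ggplot2::geom_vline(xintercept = cut, linetype = 2)
  p + ggplot2::labs(x = "allele size (kb)", y = "density") +
    ggplot2::theme_minimal()
}
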