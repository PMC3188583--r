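# Freeman-Halton exact test for r x c contingency tables: the probability
# of a table with fixed margins is multivariate hypergeometric,
#   P(T) = prod(r_i!) prod(c_j!) / (n! prod(T_ij!)),
# and the two-sided p value sums P over every margin-consistent table whose
# probability does not exceed the observed table's (probability ordering,
# with a relative tolerance on the inclusion comparison so that ties are
# included despite floating-point noise).

# log P(T) = K - sum(lgamma(T+1)); K depends only on the margins, so table
# ordering needs only s(T) = sum(lgamma(T+1)) (larger s <=> less probable).
fh_log_const <- function(rs, cs) {
  sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(sum(rs) + 1)
}

# Enumerate margin-consistent tables row by row; for each completed table
# accumulate P(T) if s(T) >= s_obs - log(1 + rel_tol). Row compositions are
# generated recursively cell by cell under the remaining column margins.
fh_enumerate <- function(rs, cs, s_obs, rel_tol) {
  nr <- length(rs)
  nc <- length(cs)
  thresh <- s_obs - log1p(rel_tol)
  total <- 0
  n_tables <- 0L

  rec_row <- function(i, cols_left, s_acc) {
    if (i == nr) {
      # last row forced by the remaining column margins
      s <- s_acc + sum(lgamma(cols_left + 1))
      n_tables <<- n_tables + 1L
      if (s >= thresh) total <<- total + exp(fh_log_const(rs, cs) - s)
      return(invisible())
    }
    rec_cell <- function(j, left_in_row, cols_left, s_acc) {
      if (j == nc) {
        if (left_in_row <= cols_left[nc]) {
          cl <- cols_left
          cl[nc] <- cl[nc] - left_in_row
          rec_row(i + 1L, cl, s_acc + lgamma(left_in_row + 1))
        }
        return(invisible())
      }
      # cell value bounded by the row remainder and the column margin;
      # lower bound keeps later columns feasible
      hi <- min(left_in_row, cols_left[j])
      lo <- max(0L, left_in_row - sum(cols_left[(j + 1L):nc]))
      for (v in lo:hi) {
        cl <- cols_left
        cl[j] <- cl[j] - v
        rec_cell(j + 1L, left_in_row - v, cl, s_acc + lgamma(v + 1))
      }
    }
    rec_cell(1L, rs[i], cols_left, s_acc)
  }
  rec_row(1L, cs, 0)
  list(p = min(1, total), n_tables = n_tables)
}

# Loose upper bound on the number of margin-consistent tables, used to
# refuse enumeration of hopeless inputs before starting.
fh_count_bound <- function(rs, cs) {
  nr <- length(rs)
  nc <- length(cs)
  b <- 1
  for (i in seq_len(nr - 1L)) {
    for (j in seq_len(nc - 1L)) b <- b * (min(rs[i], cs[j]) + 1)
    if (b > 1e15) return(Inf)
  }
  b
}

#' Freeman-Halton exact test on an r x c contingency table
#'
#' Generalization of Fisher's exact test to r x c tables: the two-sided p
#' value is the total probability, under the multivariate hypergeometric
#' distribution with the observed margins, of all tables whose probability
#' is at most that of the observed table (probability ordering, relative
#' tolerance `rel_tol` on the comparison). Zero-margin rows and columns are
#' dropped first; a table with fewer than two informative rows or columns
#' is degenerate and has p = 1.
#'
#' By default the full margin-constrained lattice is enumerated; when the
#' lattice is larger than `max_tables`, enumeration refuses with an error
#' suggesting the Monte Carlo mode, which samples margin-fixed tables with
#' [stats::r2dtable()] and reports the add-one estimate
#' `(1 + #\{P(T) <= P(obs)\}) / (1 + n_mc)`.
#'
#' @param x Matrix (or data frame) of non-negative integer counts.
#' @param method `"enumerate"` (exact, default) or `"montecarlo"`.
#' @param n_mc Number of Monte Carlo tables in `"montecarlo"` mode.
#' @param seed Seed for the Monte Carlo mode (ignored when enumerating).
#' @param max_tables Refusal bound for enumeration.
#' @param rel_tol Relative tolerance when comparing table probabilities.
#' @return An `fh_test` object: list with `p_value`, `method`, `table`,
#'   and `n_tables` (enumeration) or `n_mc`/`seed` (Monte Carlo).
#' @export
#' @examples
#' fisher_exact_rxc(rbind(c(22, 76, 96), c(21, 59, 194)))
fisher_exact_rxc <- function(x, method = c("enumerate", "montecarlo"),
                             n_mc = 1e5, seed = NULL, max_tables = 5e6,
                             rel_tol = 1e-7) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (any(is.na(x)) || any(x < 0) || any(abs(x - round(x)) > 1e-8)) {
    abort("table must contain non-negative integer counts")
  }
  storage.mode(x) <- "integer"
  x <- x[rowSums(x) > 0L, colSums(x) > 0L, drop = FALSE]
  if (nrow(x) < 2L || ncol(x) < 2L) {
    return(structure(
      list(p_value = 1, method = "degenerate", table = x, n_tables = 1L),
      class = "fh_test"
    ))
  }
  rs <- rowSums(x)
  cs <- colSums(x)
  s_obs <- sum(lgamma(x + 1))

  if (method == "enumerate") {
    bound <- fh_count_bound(rs, cs)
    if (bound > max_tables) {
      abort(sprintf(
        "margin lattice too large for enumeration (bound %.3g > %.3g); use method = 'montecarlo'",
        bound, max_tables
      ))
    }
    res <- fh_enumerate(rs, cs, s_obs, rel_tol)
    structure(
      list(p_value = res$p, method = "enumerate", table = x,
           n_tables = res$n_tables),
      class = "fh_test"
    )
  } else {
    draws <- with_seed(seed, r2dtable(n_mc, rs, cs))
    s <- vapply(draws, function(t) sum(lgamma(t + 1)), numeric(1))
    hits <- sum(s >= s_obs - log1p(rel_tol))
    structure(
      list(p_value = (1 + hits) / (1 + n_mc), method = "montecarlo",
           table = x, n_mc = n_mc, seed = seed),
      class = "fh_test"
    )
  }
}

#' @export
print.fh_test <- function(x, ...) {
  cat(sprintf("Freeman-Halton exact test (%s): p = %s\n",
              x$method, format_p2(x$p_value)))
  invisible(x)
}

#' @export
tidy.fh_test <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, method = x$method,
    n_tables = x$n_tables %||% NA_integer_
  )
}
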