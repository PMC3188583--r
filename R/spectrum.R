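#' Allele-size spectrum by severity group
#'
#' Counts chromosomes per allele size within the severe and mild groups
#' (each non-missing individual contributes two chromosomes) and pooled.
#'
#' @param cohort A `vntr_cohort`.
#' @param gene Gene name.
#' @return An `allele_spectrum` tibble with columns `allele`, `severe`,
#'   `mild`, `pooled`, sorted by allele size; attributes `gene` and `unit`.
#' @export
allele_spectrum <- function(cohort, gene) {
  gc <- gene_complete(cohort, gene)
  alle <- c(gc$a, gc$b)
  phen <- rep(gc$data$phenotype, 2L)
  keys <- allele_key(alle, gc$unit)
  uk <- sort(unique(keys))
  out <- tibble::tibble(
    allele = uk * gc$unit,
    severe = as.integer(tabulate(match(keys[phen == "severe"], uk), length(uk))),
    mild = as.integer(tabulate(match(keys[phen == "mild"], uk), length(uk)))
  )
  out$pooled <- out$severe + out$mild
  structure(out, gene = gene, unit = gc$unit,
            class = c("allele_spectrum", class(tibble::tibble())))
}

#' Wilcoxon rank-sum comparison of allele sizes between severity groups
#'
#' Two-sided rank-sum test on allele sizes, treating each chromosome as
#' one observation, using the normal approximation with tie correction
#' (allele sizes are heavily tied on the size grid) and no continuity
#' correction. The within-patient dependence of the two chromosomes is
#' acknowledged, not modeled.
#'
#' @param spec An [allele_spectrum()].
#' @return One-row tibble: `statistic` (rank-sum W), `p_value`,
#'   `n_severe`, `n_mild` (chromosome counts).
#' @export
ranksum_severity <- function(spec) {
  if (sum(spec$severe) == 0L || sum(spec$mild) == 0L) {
    abort("both severity groups must contribute at least one chromosome")
  }
  x <- rep(spec$allele, spec$severe)
  y <- rep(spec$allele, spec$mild)
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE, correct = FALSE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_severe = length(x), n_mild = length(y)
  )
}

#' Plot an allele-size spectrum by severity group
#'
#' @param object An [allele_spectrum()].
#' @param ... Unused.
#' @return A ggplot: chromosome counts per allele size, dodged by group.
#' @export
autoplot.allele_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("allele", "severe", "mild")],
    c("severe", "mild"), names_to = "group", values_to = "chromosomes"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$allele, y = .data$chromosomes,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = sprintf("%s allele size", attr(object, "gene") %||% "VNTR"),
      y = "chromosomes", fill = NULL
    ) +
    ggplot2::theme_minimal()
}
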