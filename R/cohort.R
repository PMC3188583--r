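#' Construct a validated cohort table
#'
#' The cohort is the single input object for every analysis stage: a tibble
#' with one row per individual, a binary severity phenotype, two allele-size
#' columns per VNTR locus (`<gene>_a`, `<gene>_b`, in kb on a 0.05 kb grid,
#' or integer repeat counts for PCR-typed loci), and one minor-allele-count
#' column per SNP (0/1/2, `NA` for missing).
#'
#' Validation enforces: unique ids; phenotype in `{"severe", "mild"}` and
#' never missing; allele sizes strictly positive, on the locus grid, and
#' canonicalized so `<gene>_a <= <gene>_b`; no half-calls (both alleles of a
#' genotype present or both missing); SNP counts in `{0, 1, 2, NA}`.
#'
#' @param data Data frame with columns `id`, `phenotype`, per-gene
#'   `<gene>_a`/`<gene>_b` pairs and per-SNP count columns.
#' @param genes Named numeric vector mapping gene name to its allele-size
#'   grid unit (kb per grid step, or 1 for repeat-count loci). If `NULL`,
#'   genes are detected from `_a`/`_b` column pairs with a default unit
#'   of `0.05`.
#' @param snps Character vector of SNP column names. If `NULL`, every
#'   column that is not `id`, `phenotype` or a VNTR pair is taken as a SNP.
#' @param strict If `TRUE`, allele sizes off the grid raise an error
#'   instead of being snapped.
#' @return A `vntr_cohort` tibble with `genes` (named units) and `snps`
#'   attributes.
#' @export
new_cohort <- function(data, genes = NULL, snps = NULL, strict = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("id", "phenotype") %in% names(data))) {
    abort("cohort table must have `id` and `phenotype` columns")
  }
  if (is.null(genes)) {
    a_cols <- grep("_a$", names(data), value = TRUE)
    cand <- sub("_a$", "", a_cols)
    cand <- cand[paste0(cand, "_b") %in% names(data)]
    genes <- setNames(rep(0.05, length(cand)), cand)
  }
  gene_cols <- as.vector(rbind(paste0(names(genes), "_a"), paste0(names(genes), "_b")))
  missing_cols <- setdiff(gene_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("missing VNTR columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (is.null(snps)) {
    snps <- setdiff(names(data), c("id", "phenotype", gene_cols))
  }

  data$id <- as.character(data$id)
  if (anyDuplicated(data$id)) {
    abort(paste0(
      "duplicated individual ids: ",
      paste(unique(data$id[duplicated(data$id)]), collapse = ", ")
    ))
  }
  bad_phen <- !data$phenotype %in% c("severe", "mild")
  if (any(bad_phen)) {
    abort(sprintf(
      "unknown phenotype label(s) at row(s) %s: %s",
      paste(which(bad_phen), collapse = ", "),
      paste(unique(data$phenotype[bad_phen]), collapse = ", ")
    ))
  }
  data$phenotype <- factor(data$phenotype, levels = c("severe", "mild"))

  for (g in names(genes)) {
    unit <- genes[[g]]
    a <- as.numeric(data[[paste0(g, "_a")]])
    b <- as.numeric(data[[paste0(g, "_b")]])
    half <- xor(is.na(a), is.na(b))
    if (any(half)) {
      abort(sprintf(
        "half-called %s genotype (one allele missing) at row(s): %s",
        g, paste(which(half), collapse = ", ")
      ))
    }
    if (any(a <= 0 | b <= 0, na.rm = TRUE)) {
      abort(sprintf("non-positive %s allele size", g))
    }
    a <- snap_allele(a, unit, strict, paste0(g, " allele"))
    b <- snap_allele(b, unit, strict, paste0(g, " allele"))
    swap <- !is.na(a) & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    data[[paste0(g, "_a")]] <- a
    data[[paste0(g, "_b")]] <- b
  }

  for (s in snps) {
    v <- data[[s]]
    if (!all(is.na(v) | v %in% c(0, 1, 2))) {
      abort(sprintf("SNP `%s` has genotype counts outside {0, 1, 2, NA}", s))
    }
    data[[s]] <- as.integer(v)
  }

  structure(
    data[, c("id", "phenotype", gene_cols, snps)],
    genes = genes, snps = snps,
    class = c("vntr_cohort", class(tibble::tibble()))
  )
}

#' Read a cohort table from a tab-separated file
#'
#' File layout: one row per individual with columns `id`, `phenotype`
#' (`severe`/`mild`), per-gene `<gene>_a`/`<gene>_b` allele sizes, then SNP
#' minor-allele counts. The configurable missing code (default `"NA"`) is
#' normalized to `NA` before validation.
#'
#' @inheritParams new_cohort
#' @param path Path to the TSV file.
#' @param missing Missing-value code in the file.
#' @return A validated [new_cohort()] tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "id\tphenotype\tMUC5AC_a\tMUC5AC_b\trs1",
#'   "s1\tsevere\t6.45\t6.30\t1"
#' ), f)
#' read_cohort(f)
read_cohort <- function(path, genes = NULL, snps = NULL, missing = "NA",
                        strict = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, na = missing, show_col_types = FALSE,
                         progress = FALSE)
  prob <- readr::problems(raw)
  if (nrow(prob)) {
    abort(sprintf(
      "malformed cohort file %s: first problem at line %d (%s)",
      path, prob$row[1] + 1L, prob$expected[1]
    ))
  }
  new_cohort(raw, genes = genes, snps = snps, strict = strict)
}

#' Write a cohort table to TSV
#'
#' Inverse of [read_cohort()]: the round trip reproduces the file up to
#' column order and missing-code normalization. Allele sizes are rendered
#' in kb with two decimals (or as integers for unit-1 loci).
#'
#' @param cohort A `vntr_cohort`.
#' @param path Output path.
#' @export
write_cohort <- function(cohort, path) {
  genes <- attr(cohort, "genes")
  out <- tibble::as_tibble(cohort)
  for (g in names(genes)) {
    dec <- if (genes[[g]] >= 1) 0L else 2L
    for (col in paste0(g, c("_a", "_b"))) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           formatC(out[[col]], format = "f", digits = dec))
    }
  }
  out$phenotype <- as.character(out$phenotype)
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read SNP genotypes from PLINK text ped/map files
#'
#' Parses the text dialect of PLINK pedigree files: six leading columns
#' (family, individual, father, mother, sex, phenotype) followed by two
#' allele-code columns per SNP, with `0` the missing code. The minor allele
#' is determined from the data at each SNP and genotypes are converted to
#' minor-allele counts keyed by individual id, ready to merge onto a cohort.
#'
#' @param ped Path to the `.ped` file.
#' @param map Path to the `.map` file (columns chromosome, snp id, genetic
#'   distance, position).
#' @return Tibble with `id` plus one 0/1/2 count column per SNP.
#' @export
read_plink_ped <- function(ped, map) {
  map_df <- utils::read.table(map, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(map_df) < 4) abort("map file must have >= 4 columns")
  snp_ids <- as.character(map_df[[2]])
  ped_df <- utils::read.table(ped, header = FALSE, stringsAsFactors = FALSE,
                              colClasses = "character")
  n_snp <- length(snp_ids)
  if (ncol(ped_df) != 6 + 2 * n_snp) {
    abort(sprintf(
      "ped/map mismatch: ped has %d genotype columns but map declares %d SNPs",
      ncol(ped_df) - 6L, n_snp
    ))
  }
  ids <- ped_df[[2]]
  counts <- matrix(NA_integer_, nrow(ped_df), n_snp,
                   dimnames = list(NULL, snp_ids))
  for (j in seq_len(n_snp)) {
    a1 <- toupper(ped_df[[6 + 2 * j - 1]])
    a2 <- toupper(ped_df[[6 + 2 * j]])
    ok <- c(a1, a2) %in% c("A", "C", "G", "T", "0")
    if (!all(ok)) {
      abort(sprintf(
        "SNP %s has allele codes outside {A,C,G,T,0}: %s",
        snp_ids[j], paste(unique(c(a1, a2)[!ok]), collapse = ", ")
      ))
    }
    called <- a1 != "0" & a2 != "0"
    tab <- table(factor(c(a1[called], a2[called]), levels = c("A", "C", "G", "T")))
    present <- names(tab)[tab > 0]
    if (length(present) > 2) {
      abort(sprintf("SNP %s is not biallelic (%s)", snp_ids[j],
                    paste(present, collapse = "/")))
    }
    minor <- if (length(present)) present[which.min(tab[present])] else NA_character_
    counts[called, j] <- (a1[called] == minor) + (a2[called] == minor)
  }
  tibble::as_tibble(cbind(tibble::tibble(id = ids), as.data.frame(counts)))
}

#' Merge a SNP genotype fragment onto a cohort
#'
#' @param cohort A `vntr_cohort`.
#' @param fragment Tibble from [read_plink_ped()] (column `id` plus SNP
#'   count columns); individuals absent from the fragment get missing
#'   genotypes.
#' @return The cohort with the fragment's SNP columns appended.
#' @export
cohort_add_snps <- function(cohort, fragment) {
  new_snps <- setdiff(names(fragment), "id")
  clash <- intersect(new_snps, names(cohort))
  if (length(clash)) {
    abort(paste0("SNP column(s) already present: ", paste(clash, collapse = ", ")))
  }
  merged <- dplyr::left_join(tibble::as_tibble(cohort), fragment, by = "id")
  new_cohort(merged, genes = attr(cohort, "genes"),
             snps = c(attr(cohort, "snps"), new_snps))
}

#' Summarize a cohort
#'
#' Per-gene chromosome counts and call rates, per-SNP minor allele
#' frequencies (computed over non-missing chromosomes; an all-missing SNP
#' is flagged with `NA` frequency), and group sizes.
#'
#' @param cohort A `vntr_cohort`.
#' @return A `cohort_summary` list with elements `n`, `n_severe`, `n_mild`,
#'   `genes` (tibble: gene, n_typed, n_chromosomes, n_alleles, call_rate)
#'   and `snps` (tibble: snp_id, n_typed, call_rate, maf, all_missing).
#' @export
summarize_cohort <- function(cohort) {
  genes <- attr(cohort, "genes")
  snps <- attr(cohort, "snps")
  n <- nrow(cohort)
  gene_tbl <- purrr::map_dfr(names(genes), function(g) {
    a <- cohort[[paste0(g, "_a")]]
    b <- cohort[[paste0(g, "_b")]]
    typed <- sum(!is.na(a))
    tibble::tibble(
      gene = g, n_typed = typed, n_chromosomes = 2L * typed,
      n_alleles = length(unique(c(a[!is.na(a)], b[!is.na(b)]))),
      call_rate = if (n) typed / n else NA_real_
    )
  })
  snp_tbl <- purrr::map_dfr(snps, function(s) {
    v <- cohort[[s]]
    typed <- sum(!is.na(v))
    tibble::tibble(
      snp_id = s, n_typed = typed,
      call_rate = if (n) typed / n else NA_real_,
      maf = if (typed) sum(v, na.rm = TRUE) / (2 * typed) else NA_real_,
      all_missing = typed == 0L && n > 0L
    )
  })
  structure(
    list(
      n = n,
      n_severe = sum(cohort$phenotype == "severe"),
      n_mild = sum(cohort$phenotype == "mild"),
      genes = gene_tbl, snps = snp_tbl
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals (%d severe, %d mild)\n",
              x$n, x$n_severe, x$n_mild))
  if (nrow(x$genes)) { cat("VNTR loci:\n"); print(x$genes) }
  if (nrow(x$snps)) { cat("SNPs:\n"); print(x$snps) }
  invisible(x)
}

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(n = x$n, n_severe = x$n_severe, n_mild = x$n_mild,
                 n_genes = nrow(x$genes), n_snps = nrow(x$snps))
}

# Keep cohort attributes through dplyr-style subsetting of rows.
#' @export
`[.vntr_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("id", "phenotype") %in% names(out))) {
    attr(out, "genes") <- attr(x, "genes")
    attr(out, "snps") <- intersect(attr(x, "snps"), names(out))
    class(out) <- class(x)
  }
  out
}

# Internal: pairwise-complete genotype frame for one gene (individuals
# missing that gene's VNTR genotype are dropped for the analysis at hand,
# not globally).
gene_complete <- function(cohort, gene) {
  genes <- attr(cohort, "genes")
  if (!gene %in% names(genes)) {
    abort(sprintf("gene `%s` not present in cohort (have: %s)", gene,
                  paste(names(genes), collapse = ", ")))
  }
  a <- cohort[[paste0(gene, "_a")]]
  keep <- !is.na(a)
  list(
    data = cohort[keep, , drop = FALSE],
    a = cohort[[paste0(gene, "_a")]][keep],
    b = cohort[[paste0(gene, "_b")]][keep],
    unit = genes[[gene]]
  )
}

check_snp <- function(cohort, snp) {
  if (!snp %in% attr(cohort, "snps")) {
    abort(sprintf("SNP `%s` not present in cohort", snp))
  }
  invisible(snp)
}
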