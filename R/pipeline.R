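# Pipeline driver: a single structured config (YAML/JSON file or list)
# runs the analysis stages in dependency order, writes every stage output
# under a run directory, and emits a manifest with config hash, seeds,
# per-file checksums and the final test ledger, so an identical config
# reproduces identical checksums.

pipeline_stage_names <- c("spectrum", "ranksum", "mixture", "assoc", "ld",
                          "partition_lrt", "haplo_score")

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) abort(paste0("no such config file: ", config))
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) abort("config must be a list or a YAML/JSON file path")
  allowed <- c("seed", "out_dir", "gene", "cohort", "stages",
               "assoc", "mixture", "ld", "partition_lrt", "haplo_score")
  bad <- setdiff(names(config), allowed)
  if (length(bad)) {
    abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
  }
  if (is.null(config$cohort)) abort("config must declare a `cohort` source")
  src <- intersect(names(config$cohort), c("file", "table1_fixture", "simulate"))
  if (length(src) != 1L) {
    abort("cohort must declare exactly one of: file, table1_fixture, simulate")
  }
  config$stages <- as.character(config$stages %||% character())
  bad_stage <- setdiff(config$stages, pipeline_stage_names)
  if (length(bad_stage)) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$gene <- config$gene %||% "MUC5AC"
  config
}

config_partition <- function(x, default = NULL) {
  if (is.null(x)) {
    if (is.null(default)) abort("a partition specification is required")
    return(default)
  }
  if (!is.null(x$sl_cut)) {
    return(partition_sl(x$sl_cut, x$boundary %||% "short_inclusive"))
  }
  classes <- lapply(x$classes, as.numeric)
  allele_partition(classes, other = x$other %||% "other", name = x$name)
}

#' Run the full analysis pipeline from a config
#'
#' Stages (`spectrum`, `ranksum`, `mixture`, `assoc`, `ld`,
#' `partition_lrt`, `haplo_score`) run in dependency order; any stage
#' failure halts the run with an error naming the stage. All outputs are
#' written as TSV/JSON under the run directory and summarized in a
#' `manifest.json` carrying the config hash, seed, per-file md5 checksums,
#' the final test ledger, and the package version. Every p value emitted
#' by a stage appears exactly once in the manifest's ledger.
#'
#' @param config Path to a YAML/JSON config file, or an equivalent list.
#'   Required: `cohort` with exactly one of `file` (cohort TSV),
#'   `table1_fixture` (designated allele size), or `simulate`
#'   ([sim_config()] fields). Optional: `seed`, `gene`, `out_dir`,
#'   `stages`, and per-stage parameter blocks (`assoc`, `mixture`, `ld`,
#'   `partition_lrt`, `haplo_score`).
#' @param out_dir Run directory (overrides the config; default a fresh
#'   directory under `tempdir()`).
#' @return The manifest, invisibly (`run_manifest` list).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||%
    file.path(tempdir(), paste0("vntrassoc-run-", cfg$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gene <- cfg$gene
  ledger <- test_ledger()
  outputs <- character()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage `%s` failed: %s", name, conditionMessage(e)))
    })
  }
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    readr::write_tsv(tibble::as_tibble(df), path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  cohort <- run_stage("cohort", {
    if (!is.null(cfg$cohort$file)) {
      read_cohort(cfg$cohort$file)
    } else if (!is.null(cfg$cohort$table1_fixture)) {
      table1_fixture(as.numeric(cfg$cohort$table1_fixture))
    } else {
      sim <- do.call(sim_config, modifyList(list(seed = cfg$seed),
                                            cfg$cohort$simulate))
      simulate_cohort(sim)
    }
  })
  cohort_path <- file.path(out_dir, "cohort.tsv")
  write_cohort(cohort, cohort_path)
  outputs <- c(outputs, cohort_path)

  spec <- NULL
  if (any(c("spectrum", "ranksum", "mixture") %in% cfg$stages)) {
    spec <- run_stage("spectrum", allele_spectrum(cohort, gene))
    if ("spectrum" %in% cfg$stages) emit(spec, "spectrum.tsv")
  }
  if ("ranksum" %in% cfg$stages) {
    rs <- run_stage("ranksum", ranksum_severity(spec))
    emit(rs, "ranksum.tsv")
    ledger <- ledger_add(ledger, paste0(gene, "_ranksum"),
                         sprintf("rank-sum severity comparison of %s allele sizes", gene),
                         rs$p_value, paste0(gene, "_distribution"))
  }
  if ("mixture" %in% cfg$stages) {
    mx <- cfg$mixture %||% list()
    res <- run_stage("mixture", {
      fit <- fit_mixture(spec)
      rule <- if (!is.null(mx$fixed)) as.numeric(mx$fixed) else
        (mx$rule %||% "mixture_2sd")
      cut <- cut_point(fit, rule)
      sl <- sl_association(cohort, gene, cut,
                           mx$boundary %||% "short_inclusive")
      list(fit = fit, cut = cut, sl = sl)
    })
    emit(cbind(glance(res$fit), cut = res$cut), "mixture.tsv")
    emit(tidy(res$sl), "sl_assoc.tsv")
    ledger <- ledger_add(ledger, paste0(gene, "_sl_assoc"),
                         sprintf("S/L genotype association at cut %.3f", res$cut),
                         res$sl$p_value, paste0(gene, "_cutpoint"))
  }
  if ("assoc" %in% cfg$stages) {
    as_cfg <- cfg$assoc %||% list()
    scan <- run_stage("assoc", designated_scan(
      cohort, gene,
      min_allele_freq = as_cfg$min_allele_freq %||% 0.04,
      freq_basis = as_cfg$freq_basis %||% "carriers",
      ledger = ledger
    ))
    ledger <- scan_ledger(scan)
    emit(scan, "assoc.tsv")
  }
  if ("ld" %in% cfg$stages) {
    ld_cfg <- cfg$ld %||% list()
    map <- run_stage("ld", ld_map(
      cohort, gene, config_partition(ld_cfg$partition), as.character(ld_cfg$snps)
    ))
    emit(tidy(map), "ld_r2.tsv")
    emit(map$vntr, "ld_vntr.tsv")
  }
  if ("partition_lrt" %in% cfg$stages) {
    pl <- cfg$partition_lrt %||% list()
    scan <- run_stage("partition_lrt", scan_partitions(
      cohort, gene,
      fine = config_partition(pl$fine), coarse = config_partition(pl$coarse),
      snps = as.character(pl$snps), ledger = ledger
    ))
    ledger <- scan_ledger(scan)
    emit(scan, "partition_lrt.tsv")
  }
  if ("haplo_score" %in% cfg$stages) {
    hs_cfg <- cfg$haplo_score %||% list()
    hs <- run_stage("haplo_score", haplo_score_test(
      cohort, gene, config_partition(hs_cfg$partition),
      snp = hs_cfg$snp, n_perm = hs_cfg$n_perm %||% 1e5,
      seed = cfg$seed
    ))
    emit(tidy(hs), "haplo_score.tsv")
    emit(glance(hs), "haplo_score_global.tsv")
    ledger <- ledger_add(ledger,
                         sprintf("%s_haplo_score_%s", gene, hs_cfg$snp),
                         sprintf("global haplotype score permutation test at %s", hs_cfg$snp),
                         hs$global$p_perm, paste0(gene, "_haplo_score"))
  }

  ledger_path <- file.path(out_dir, "ledger.json")
  jsonlite::write_json(
    list(tests = tibble::as_tibble(ledger),
         family_sizes = as.list(attr(ledger, "family_sizes"))),
    ledger_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  outputs <- c(outputs, ledger_path)

  cfg_file <- file.path(out_dir, "config.json")
  cfg_canon <- cfg[setdiff(names(cfg), "out_dir")]
  jsonlite::write_json(cfg_canon, cfg_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_file)),
    seed = cfg$seed,
    version = as.character(utils::packageVersion("vntrassoc")),
    stages = cfg$stages,
    outputs = lapply(setNames(outputs, basename(outputs)),
                     function(p) unname(tools::md5sum(p))),
    ledger = list(
      tests = lapply(seq_len(nrow(ledger)), function(i) list(
        test_id = ledger$test_id[i], description = ledger$description[i],
        p_nominal = ledger$p_nominal[i],
        families = as.list(ledger$families[[i]])
      )),
      family_sizes = as.list(attr(ledger, "family_sizes"))
    )
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  structure(manifest, class = "run_manifest", path = manifest_path,
            out_dir = out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d, %d stage(s), %d output file(s))\n",
              x$seed, length(x$stages), length(x$outputs)))
  cat("  out_dir:", attr(x, "out_dir"), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}
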