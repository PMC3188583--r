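# Allele partitions: mappings from VNTR allele size to a small set of
# class labels. They express both the short/long dichotomy and the
# "treat 6.3 and 6.4 as separate alleles, collapse the rest" systems used
# to probe whether same-mode alleles are genetically distinct.

#' Define an allele partition from explicit size classes
#'
#' @param classes Named list: class label -> numeric vector of allele
#'   sizes belonging to it. Labels must be distinct and no size may occur
#'   in two classes.
#' @param other Label for alleles not listed in any class (set to `NULL`
#'   to forbid unlisted alleles).
#' @param name Optional partition name.
#' @return An `allele_partition`.
#' @export
#' @examples
#' three <- allele_partition(list(`6.3` = 6.3, `6.4` = 6.4), other = "other")
#' two <- allele_partition(list(`6.3/6.4` = c(6.3, 6.4)), other = "other")
allele_partition <- function(classes, other = "other", name = NULL) {
  if (is.null(names(classes)) || anyDuplicated(names(classes))) {
    abort("classes must be a uniquely named list")
  }
  if (!is.null(other) && other %in% names(classes)) {
    abort("`other` label collides with a class label")
  }
  sizes <- unlist(classes, use.names = FALSE)
  if (anyDuplicated(round(sizes * 1e6))) {
    abort("an allele size occurs in more than one class")
  }
  structure(
    list(type = "classes", classes = classes, other = other,
         name = name %||% paste(names(classes), collapse = "|")),
    class = "allele_partition"
  )
}

#' Define the short/long partition at a cut-point
#'
#' @param cut Cut-point (kb).
#' @param boundary `"short_inclusive"` (S <= cut < L) or
#'   `"long_inclusive"` (S < cut <= L).
#' @param name Optional partition name.
#' @return An `allele_partition` with classes `S` and `L`.
#' @export
partition_sl <- function(cut, boundary = c("short_inclusive", "long_inclusive"),
                         name = NULL) {
  boundary <- match.arg(boundary)
  assert_scalar_number(cut, "cut", positive = TRUE)
  structure(
    list(type = "sl", cut = cut, boundary = boundary,
         name = name %||% sprintf("S/L@%.2f", cut)),
    class = "allele_partition"
  )
}

#' @export
print.allele_partition <- function(x, ...) {
  if (x$type == "sl") {
    cat(sprintf("Allele partition %s: short/long at %.3f kb (%s)\n",
                x$name, x$cut, x$boundary))
  } else {
    cat(sprintf("Allele partition %s:\n", x$name))
    for (lab in names(x$classes)) {
      cat(sprintf("  %s: %s\n", lab,
                  paste(format(x$classes[[lab]], nsmall = 2), collapse = ", ")))
    }
    if (!is.null(x$other)) cat(sprintf("  %s: all remaining alleles\n", x$other))
  }
  invisible(x)
}

# Assign class labels to allele sizes (grid-keyed equality).
partition_assign <- function(partition, sizes, unit) {
  if (partition$type == "sl") {
    eps <- unit * 1e-6
    short <- if (partition$boundary == "short_inclusive") {
      sizes <= partition$cut + eps
    } else {
      sizes < partition$cut - eps
    }
    return(ifelse(short, "S", "L"))
  }
  keys <- allele_key(sizes, unit)
  out <- rep(NA_character_, length(sizes))
  for (lab in names(partition$classes)) {
    out[keys %in% allele_key(partition$classes[[lab]], unit)] <- lab
  }
  if (any(is.na(out) & !is.na(sizes))) {
    if (is.null(partition$other)) {
      abort(sprintf(
        "allele size(s) not covered by partition `%s` and no `other` class: %s",
        partition$name,
        paste(unique(format(sizes[is.na(out) & !is.na(sizes)])), collapse = ", ")
      ))
    }
    out[is.na(out) & !is.na(sizes)] <- partition$other
  }
  out
}

# Does `fine` refine `coarse` on the observed alleles? Every fine class
# must map into exactly one coarse class.
partition_refines <- function(fine, coarse, sizes, unit) {
  f <- partition_assign(fine, sizes, unit)
  c_ <- partition_assign(coarse, sizes, unit)
  all(vapply(split(c_, f), function(v) length(unique(v)) == 1L, logical(1)))
}
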