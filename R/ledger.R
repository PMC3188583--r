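# Every hypothesis test the pipeline runs is registered in a ledger so the
# Bonferroni arithmetic over (possibly nested) test families is explicit
# and auditable, rather than scattered across call sites.

#' Create an empty test ledger
#'
#' The ledger records each test with its nominal p value and the family
#' labels it belongs to. Families may be nested (a test can belong to
#' several), and a family's size may be declared explicitly when the full
#' membership is known only as a printed count; otherwise the size is the
#' number of registered member tests.
#'
#' @param family_sizes Optional named integer vector of declared family
#'   sizes.
#' @return A `test_ledger` tibble (`test_id`, `description`, `p_nominal`,
#'   `families` list-column) with a `family_sizes` attribute.
#' @export
test_ledger <- function(family_sizes = integer()) {
  structure(
    tibble::tibble(
      test_id = character(), description = character(),
      p_nominal = numeric(), families = list()
    ),
    family_sizes = family_sizes,
    class = c("test_ledger", class(tibble::tibble()))
  )
}

#' Register a test in a ledger
#'
#' @param ledger A [test_ledger()].
#' @param test_id Unique identifier for the test.
#' @param description Human-readable description.
#' @param p Nominal p value.
#' @param families Character vector of family labels.
#' @return The updated ledger.
#' @export
ledger_add <- function(ledger, test_id, description, p, families = character()) {
  if (test_id %in% ledger$test_id) {
    abort(sprintf("test id `%s` already registered", test_id))
  }
  if (!is.na(p) && (p < 0 || p > 1)) abort("p must lie in [0, 1]")
  out <- dplyr::bind_rows(
    tibble::as_tibble(ledger),
    tibble::tibble(test_id = test_id, description = description,
                   p_nominal = p, families = list(as.character(families)))
  )
  structure(out, family_sizes = attr(ledger, "family_sizes"),
            class = class(ledger))
}

#' Declare the size of a test family
#'
#' Used when a family's full membership is known only as a count (for
#' example a published footnote stating how many tests the correction
#' covers); the declared size overrides the registered member count.
#'
#' @param ledger A [test_ledger()].
#' @param family Family label.
#' @param size Declared number of tests in the family.
#' @return The updated ledger.
#' @export
ledger_declare_family <- function(ledger, family, size) {
  fs <- attr(ledger, "family_sizes")
  fs[[family]] <- as.integer(size)
  attr(ledger, "family_sizes") <- fs
  ledger
}

ledger_family_size <- function(ledger, family) {
  fs <- attr(ledger, "family_sizes")
  if (!is.null(fs) && family %in% names(fs)) return(fs[[family]])
  members <- vapply(ledger$families, function(f) family %in% f, logical(1))
  n <- sum(members)
  if (n == 0L) abort(sprintf("family `%s` is not registered in the ledger", family))
  n
}

#' Bonferroni-corrected p values for a test family
#'
#' `p_corrected = min(1, p_nominal * family_size)`, with the family size
#' taken from a declared override when present, else from the count of
#' registered member tests.
#'
#' @param ledger A [test_ledger()].
#' @param family Family label (declared or with registered members).
#' @return Tibble of the family's registered member tests with columns
#'   `test_id`, `p_nominal`, `family`, `family_size`, `p_corrected`.
#' @export
bonferroni <- function(ledger, family) {
  size <- ledger_family_size(ledger, family)
  members <- vapply(ledger$families, function(f) family %in% f, logical(1))
  sub <- tibble::as_tibble(ledger)[members, c("test_id", "p_nominal")]
  sub$family <- family
  sub$family_size <- size
  sub$p_corrected <- pmin(1, sub$p_nominal * size)
  sub
}

#' @export
glance.test_ledger <- function(x, ...) {
  fams <- unique(c(unlist(x$families), names(attr(x, "family_sizes"))))
  tibble::tibble(n_tests = nrow(x), n_families = length(fams))
}
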