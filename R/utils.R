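# Internal helpers shared across modules.

# Integer grid key for an allele size: sizes live on a fixed grid
# (0.05 kb for Southern-blot loci, 1 repeat for PCR loci); all equality
# comparisons go through keys so floating point never bites.
allele_key <- function(size, unit) {
  as.integer(round(size / unit))
}

# Snap sizes onto the grid; in strict mode an off-grid value is an error
# rather than silently rounded.
snap_allele <- function(size, unit, strict = FALSE, what = "allele") {
  key <- round(size / unit)
  snapped <- key * unit
  off <- !is.na(size) & abs(size - snapped) > unit * 1e-6
  if (strict && any(off)) {
    abort(sprintf(
      "%s value(s) off the %.3g grid under strict parsing: %s",
      what, unit, paste(format(size[off]), collapse = ", ")
    ))
  }
  snapped
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's state afterwards. Keeps library functions from
# clobbering user-level set.seed() streams.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Two-significant-figure formatting used when echoing p values in print
# methods (reporting convention; tests always compare unrounded values).
format_p2 <- function(p) {
  ifelse(is.na(p), "NA", formatC(signif(p, 2), format = "g", digits = 2))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive", name))
  }
  invisible(x)
}
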