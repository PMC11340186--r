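#' @import methods
#' @importFrom stats median rbinom rpois rnbinom rlnorm runif rnorm setNames
#'   quantile approx wilcox.test p.adjust binom.test predict coef sd
#'   complete.cases aggregate
#' @importFrom utils head modifyList
#' @importFrom data.table data.table as.data.table rbindlist fread fwrite
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stable 31-bit string hash
#'
#' Polynomial rolling hash of the UTF-8 bytes of `x`, reduced modulo
#' `2^31 - 1`. Used to derive per-sample random seeds from sample
#' identifiers so that adding samples to a cohort never perturbs the draws
#' of existing samples.
#'
#' @param x Character vector.
#' @return Integer vector of hashes in `[0, 2^31 - 2]`.
#' @keywords internal
stableHash <- function(x) {
  vapply(x, function(s) {
    bytes <- as.integer(charToRaw(enc2utf8(s)))
    h <- 0
    for (b in bytes) h <- (h * 131 + b) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

# Derive a valid set.seed() argument from a base seed and a string key.
childSeed <- function(seed, key) {
  as.integer((as.numeric(seed) * 7919 + stableHash(key)) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded by (seed, key).
withChildSeed <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(childSeed(seed, key))
  expr
}

#' Round half away from zero
#'
#' Base R `round()` rounds half to even; screening reports conventionally
#' print rates rounded half-up to one decimal (so 26.65% renders 26.7%).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a one-decimal percentage string
#'
#' @param k Successes.
#' @param n Total.
#' @return Character like `"41.9% (39/93)"`.
#' @export
formatPercent <- function(k, n) {
  sprintf("%s%% (%d/%d)", formatC(roundHalfUp(100 * k / n, 1),
                                  format = "f", digits = 1), k, n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assertThat <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

# Coerce labels to the canonical factor, controls first (case = positive).
canonicalLabels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("case", "control"))
  assertThat(length(bad) == 0,
             "labels must be 'case'/'control'; found: %s",
             paste(bad, collapse = ", "))
  factor(labels, levels = c("control", "case"))
}

readTsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = TRUE)
}

writeTsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE)
  invisible(path)
}

# Deterministic md5 of an R object via its canonical JSON rendering.
configHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
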