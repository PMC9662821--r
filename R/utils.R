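#' @keywords internal
"_PACKAGE"

## Imports used across the package
#' @importFrom stats lm lm.fit glm glm.fit binomial coef vcov pnorm qnorm
#'   rnorm rbinom rexp runif quantile sd var cor complete.cases setNames
#'   model.matrix pchisq as.formula weighted.mean ave
#' @importFrom utils head modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

## Numeric-in-range check with a readable error
check_range <- function(x, lo, hi, name, open_lo = FALSE, open_hi = FALSE,
                        allow_na = FALSE) {
  if (allow_na) x <- x[!is.na(x)]
  assert_that(all(is.finite(x)), "%s must be finite", name)
  lo_ok <- if (open_lo) all(x > lo) else all(x >= lo)
  hi_ok <- if (open_hi) all(x < hi) else all(x <= hi)
  assert_that(lo_ok && hi_ok, "%s must lie in %s%g, %g%s", name,
              if (open_lo) "(" else "[", lo, hi, if (open_hi) ")" else "]")
  invisible(TRUE)
}

## Exact 32-bit FNV-1a hash of a character vector; used only to stamp run
## outputs with a config fingerprint.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low 16 bits (b < 2^16); keep h a double
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, as.integer(b %% 65536))
    ## h * 16777619 mod 2^32, split to stay in exact double precision
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

## Derive a child seed from a base seed and an index, kept below 2^31.
derive_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483587
}
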