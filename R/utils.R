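#' @keywords internal
#' @import stats
#' @import utils
"_PACKAGE"

stopf <- function(fmt, ..., class = "plqsar_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "plqsar_error")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# deterministic 31-bit integer-sequence hash; double arithmetic keeps every
# intermediate below 2^53 so it is exact
hash_ints <- function(ints) {
  h <- 5381
  m <- 2147483647          # 2^31 - 1
  for (v in ints) {
    h <- (h * 1159 + abs(v) %% m) %% m
  }
  h
}
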