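# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` uses round-half-to-even; reporting rules here
#' (threshold rounding, figure bar scaling) use the conventional
#' round-half-up instead.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Geometric mean
#'
#' @param x positive numeric vector
#' @param na.rm drop missing values first
#' @return geometric mean, NA if no values remain
#' @keywords internal
geo_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  exp(mean(log(x)))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single non-missing number", name)
  if (integer && x != floor(x))
    stopf("'%s' must be an integer", name)
  if (x < min || x > max)
    stopf("'%s' = %s out of range [%s, %s]", name, format(x),
          format(min), format(max))
  invisible(x)
}

assert_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L)
    stopf("'%s' is missing required column(s): %s", name,
          paste(missing, collapse = ", "))
  invisible(df)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific seed from a master seed. Keeps results below
# 2^31 - 1 so set.seed() accepts them.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used for config fingerprints in run manifests (no external digest
# dependency). Multiplication is split into 16-bit halves to stay within
# double precision.
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low8 <- h %% 256
    h <- (h - low8) + bitwXor(as.integer(low8), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
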