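#' IBM System/370 double-precision codec
#'
#' SAS XPORT transport files store numeric values in the IBM System/370
#' hexadecimal floating-point format: a sign bit, a 7-bit base-16 exponent
#' biased by 64, and a 56-bit fraction, so that a word decodes as
#' `sign * 16^(exponent - 64) * fraction / 2^56`. Missing values are
#' sentinel words whose first byte is `0x2E` (`.`), `0x5F` (`._`) or
#' `0x41`--`0x5A` (`.A` through `.Z`) with all remaining bytes zero.
#'
#' `ibm_to_ieee()` decodes a raw vector of 8-byte words into doubles;
#' missing sentinels decode to `NA` and the sentinel spelling (`"."`,
#' `".A"`, ..., `"._"`) is returned in the `"na_code"` attribute.
#' `ieee_to_ibm()` encodes finite doubles (and missing codes) back to the
#' normalized IBM representation; because the IBM fraction carries 56 bits
#' against IEEE's 53, every finite double within the representable
#' magnitude range round-trips exactly.
#'
#' @param bytes A raw vector whose length is a multiple of 8.
#' @param x A double vector; `NA` encodes a missing value.
#' @param na_code Optional character vector recycled along `x`, giving the
#'   missing sentinel to use where `x` is `NA` (`"."` by default, or one of
#'   `".A"`--`".Z"`, `"._"`). Ignored for non-missing elements.
#' @return `ibm_to_ieee()`: a double vector with one element per 8-byte
#'   word, carrying a `"na_code"` character attribute when any special
#'   (non-`"."`) sentinel was seen. `ieee_to_ibm()`: a raw vector of
#'   `8 * length(x)` bytes.
#' @examples
#' ieee_to_ibm(c(1, -1, 32))
#' ibm_to_ieee(as.raw(c(0x41, 0x10, 0, 0, 0, 0, 0, 0)))
#' @export
ibm_to_ieee <- function(bytes) {
  stopifnot(is.raw(bytes))
  if (length(bytes) %% 8L != 0L) {
    stop("raw input length must be a multiple of 8 bytes", call. = FALSE)
  }
  n <- length(bytes) %/% 8L
  if (n == 0L) {
    return(double(0))
  }
  m <- matrix(as.integer(bytes), nrow = n, ncol = 8L, byrow = TRUE)
  b1 <- m[, 1L]

  rest_zero <- rowSums(m[, -1L, drop = FALSE]) == 0L
  sentinel <- rest_zero & (b1 == 0x2EL | b1 == 0x5FL | (b1 >= 0x41L & b1 <= 0x5AL))

  sign <- ifelse(b1 >= 128L, -1, 1)
  expo <- b1 %% 128L
  # split the 56-bit fraction so each partial sum stays exact in a double
  hi <- (m[, 2L] * 256 + m[, 3L]) * 256 + m[, 4L]
  lo <- ((m[, 5L] * 256 + m[, 6L]) * 256 + m[, 7L]) * 256 + m[, 8L]
  frac <- hi * 4294967296 + lo
  out <- sign * frac * 2^(4 * (expo - 64) - 56)
  out[frac == 0 & !sentinel] <- 0

  if (any(sentinel)) {
    code <- character(n)
    code[sentinel] <- vapply(b1[sentinel], function(b) {
      if (b == 0x2EL) "." else if (b == 0x5FL) "._" else paste0(".", rawToChar(as.raw(b)))
    }, character(1))
    out[sentinel] <- NA_real_
    if (any(code != "." & code != "")) {
      attr(out, "na_code") <- code
    }
  }
  out
}

#' @rdname ibm_to_ieee
#' @export
ieee_to_ibm <- function(x, na_code = NULL) {
  x <- as.double(x)
  if (any(is.nan(x) | is.infinite(x))) {
    stop("NaN and Inf have no XPORT representation", call. = FALSE)
  }
  n <- length(x)
  code <- rep_len(if (is.null(na_code)) "." else as.character(na_code), n)
  code[is.na(code) | code == ""] <- "."
  out <- matrix(0L, nrow = n, ncol = 8L)

  miss <- is.na(x)
  if (any(miss)) {
    sentinel_byte <- vapply(code[miss], function(cd) {
      if (cd == ".") return(0x2EL)
      if (cd == "._") return(0x5FL)
      if (grepl("^\\.[A-Za-z]$", cd)) return(as.integer(charToRaw(toupper(substr(cd, 2, 2)))))
      stop("unknown missing code: '", cd, "'", call. = FALSE)
    }, integer(1))
    out[miss, 1L] <- sentinel_byte
  }

  idx <- which(!miss & x != 0)
  for (i in idx) {
    a <- abs(x[i])
    E <- floor(log2(a) / 4) + 1
    while (a * 2^(-4 * E) >= 1) E <- E + 1
    while (a * 2^(-4 * E) < 1 / 16) E <- E - 1
    f <- round(a * 2^(56 - 4 * E))
    if (f >= 2^56) {
      f <- f / 16
      E <- E + 1
    }
    eb <- E + 64
    if (eb < 0 || eb > 127) {
      stop("magnitude ", format(a), " not representable in IBM/370 double", call. = FALSE)
    }
    hi <- floor(f / 4294967296)
    lo <- f - hi * 4294967296
    out[i, 1L] <- eb + if (x[i] < 0) 128L else 0L
    out[i, 2L] <- as.integer(hi %/% 65536)
    out[i, 3L] <- as.integer((hi %/% 256) %% 256)
    out[i, 4L] <- as.integer(hi %% 256)
    out[i, 5L] <- as.integer(lo %/% 16777216)
    out[i, 6L] <- as.integer((lo %/% 65536) %% 256)
    out[i, 7L] <- as.integer((lo %/% 256) %% 256)
    out[i, 8L] <- as.integer(lo %% 256)
  }
  as.raw(t(out))
}
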