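# Internal helpers: exact big-integer arithmetic (base 1e7 digit vectors,
# little-endian) for library diversity counts, plus small validation utilities.
# Digit products stay below 2^53 so plain doubles carry the arithmetic exactly.

.BIG_BASE <- 1e7

big_from_int <- function(x) {
  stopifnot(x >= 0, x == floor(x))
  if (x == 0) return(0)
  d <- numeric(0)
  while (x > 0) {
    d <- c(d, x %% .BIG_BASE)
    x <- x %/% .BIG_BASE
  }
  d
}

big_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= .BIG_BASE) {
      carry <- d[i] %/% .BIG_BASE
      d[i] <- d[i] %% .BIG_BASE
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  big_carry(c(a, numeric(n - length(a))) + c(b, numeric(n - length(b))))
}

big_mul <- function(a, b) {
  out <- numeric(length(a) + length(b))
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
    # carry eagerly so accumulated entries stay well below 2^53
    out <- big_carry(out)
    out <- c(out, numeric(max(0L, length(a) + length(b) - length(out))))
  }
  big_carry(out)
}

big_pow <- function(base, exponent) {
  stopifnot(exponent >= 0, exponent == floor(exponent))
  out <- big_from_int(1)
  b <- big_from_int(base)
  e <- exponent
  while (e > 0) {
    if (e %% 2 == 1) out <- big_mul(out, b)
    b <- big_mul(b, b)
    e <- e %/% 2
  }
  out
}

big_to_string <- function(d) {
  if (length(d) == 1L) return(format(d, scientific = FALSE))
  hi <- format(d[length(d)], scientific = FALSE)
  lo <- vapply(rev(d[-length(d)]), function(x)
    formatC(x, width = 7, flag = "0", format = "d"), character(1))
  paste0(hi, paste(lo, collapse = ""))
}

big_log10 <- function(d) {
  s <- big_to_string(d)
  if (s == "0") return(-Inf)
  nd <- nchar(s)
  lead <- as.numeric(substr(s, 1L, min(15L, nd)))
  (nd - 1L) - (min(15L, nd) - 1L) + log10(lead)
}

# --- misc validation ------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (strict_lower && x <= lower)
    stop(sprintf("'%s' must be > %g", name, lower), call. = FALSE)
  if (!strict_lower && x < lower)
    stop(sprintf("'%s' must be >= %g", name, lower), call. = FALSE)
  if (x > upper)
    stop(sprintf("'%s' must be <= %g", name, upper), call. = FALSE)
  invisible(x)
}

# Run an expression under a fixed seed without disturbing the caller's RNG.
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
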