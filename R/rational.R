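#' Exact rational numbers
#'
#' Replication ratios are reported as exact rationals rather than floating
#' point numbers: the Calvin-cycle ratio of 3-phosphoglycerate is exactly
#' 4/3, and equality tests on ratios should not depend on rounding.
#' `rational()` builds a reduced fraction; the usual arithmetic and
#' comparison operators are available via an [Ops] group method.
#'
#' @param num integer numerator.
#' @param den integer denominator (non-zero).
#' @return An object of class `replikit_rational` with fields `num` and
#'   `den` (coprime, `den > 0`).
#' @examples
#' rational(4, 3)
#' rational(8, 6) == rational(4, 3)
#' as.numeric(rational(4, 3))
#' @export
rational <- function(num, den = 1L) {
  num <- as.integer(num)
  den <- as.integer(den)
  if (is.na(num) || is.na(den)) stop("rational parts must be finite integers")
  if (den == 0L) stop("denominator must be non-zero")
  if (den < 0L) {
    num <- -num
    den <- -den
  }
  g <- gcd_int(abs(num), den)
  if (g > 1L) {
    num <- num %/% g
    den <- den %/% g
  }
  structure(list(num = num, den = den), class = "replikit_rational")
}

gcd_int <- function(a, b) {
  while (b != 0L) {
    t <- b
    b <- a %% b
    a <- t
  }
  if (a == 0L) 1L else a
}

#' @export
format.replikit_rational <- function(x, ...) {
  if (x$den == 1L) as.character(x$num) else paste0(x$num, "/", x$den)
}

#' @export
print.replikit_rational <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.double.replikit_rational <- function(x, ...) x$num / x$den

as_rational <- function(x) {
  if (inherits(x, "replikit_rational")) return(x)
  if (is.numeric(x) && length(x) == 1L && x == round(x)) return(rational(x))
  stop("cannot coerce to rational: ", deparse(substitute(x)))
}

#' @export
Ops.replikit_rational <- function(e1, e2) {
  if (nargs() == 1L) {
    if (.Generic == "-") return(rational(-e1$num, e1$den))
    stop("unary ", .Generic, " not supported for rationals")
  }
  a <- as_rational(e1)
  b <- as_rational(e2)
  switch(.Generic,
    "+" = rational(a$num * b$den + b$num * a$den, a$den * b$den),
    "-" = rational(a$num * b$den - b$num * a$den, a$den * b$den),
    "*" = rational(a$num * b$num, a$den * b$den),
    "/" = rational(a$num * b$den, a$den * b$num),
    "==" = a$num == b$num && a$den == b$den,
    "!=" = !(a$num == b$num && a$den == b$den),
    "<" = a$num * b$den < b$num * a$den,
    ">" = a$num * b$den > b$num * a$den,
    "<=" = a$num * b$den <= b$num * a$den,
    ">=" = a$num * b$den >= b$num * a$den,
    stop(.Generic, " not supported for rationals")
  )
}

# ---- exact non-negative integer counts of arbitrary size ----------------
#
# State counts S = A^L overflow doubles already for modest sequence
# lengths (4^30 > 2^53), while the limited/unlimited boundary N <= S must
# be decided exactly. Counts are kept as little-endian base-1e4 digit
# vectors; only multiplication by a small integer and comparison are
# needed.

big_from_int <- function(n) {
  n <- as.numeric(n)
  stopifnot(n >= 0, n == floor(n), n < 2^53)
  d <- integer(0)
  repeat {
    d <- c(d, n %% 10000)
    n <- n %/% 10000
    if (n == 0) break
  }
  as.integer(d)
}

big_mul_small <- function(d, k) {
  k <- as.numeric(k)
  out <- as.numeric(d) * k
  carry <- 0
  for (i in seq_along(out)) {
    v <- out[i] + carry
    out[i] <- v %% 10000
    carry <- v %/% 10000
  }
  while (carry > 0) {
    out <- c(out, carry %% 10000)
    carry <- carry %/% 10000
  }
  as.integer(out)
}

big_cmp <- function(a, b) {
  # strip leading (high-order) zeros
  trim <- function(x) {
    while (length(x) > 1L && x[length(x)] == 0L) x <- x[-length(x)]
    x
  }
  a <- trim(a)
  b <- trim(b)
  if (length(a) != length(b)) return(sign(length(a) - length(b)))
  for (i in rev(seq_along(a))) {
    if (a[i] != b[i]) return(sign(a[i] - b[i]))
  }
  0L
}

big_format <- function(d) {
  n <- length(d)
  parts <- sprintf("%04d", rev(d))
  parts[1] <- sub("^0+(?=\\d)", "", parts[1], perl = TRUE)
  paste(parts, collapse = "")
}

#' Number of possible sequence states
#'
#' The number of distinct sequences of length `L` over an alphabet of `A`
#' symbols, computed exactly. For long sequences the result exceeds what a
#' double can represent exactly; such values are returned as an object of
#' class `replikit_bigcount` (an exact decimal integer) which
#' [classify_sn()] compares exactly against the population size.
#'
#' @param L sequence length (non-negative integer).
#' @param A alphabet size (positive integer).
#' @return A plain number when `A^L` is exactly representable as a double,
#'   otherwise a `replikit_bigcount`.
#' @examples
#' sequence_state_count(3, 4)   # 64
#' sequence_state_count(0, 4)   # 1
#' sequence_state_count(40, 4)  # exact 25-digit integer
#' @export
sequence_state_count <- function(L, A) {
  stopifnot(length(L) == 1L, length(A) == 1L)
  if (is.na(L) || L < 0 || L != floor(L)) stop("L must be a non-negative integer")
  if (is.na(A) || A < 1 || A != floor(A)) stop("A must be a positive integer")
  if (L == 0) return(1)
  if (A == 1) return(1)
  if (L * log2(A) <= 53) return(A^L)
  d <- big_from_int(1)
  for (i in seq_len(L)) d <- big_mul_small(d, A)
  structure(list(digits = d), class = "replikit_bigcount")
}

#' @export
format.replikit_bigcount <- function(x, ...) big_format(x$digits)

#' @export
print.replikit_bigcount <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.replikit_bigcount <- function(x, ...) big_format(x$digits)

#' @export
as.double.replikit_bigcount <- function(x, ...) {
  sum(as.vector(x$digits, mode = "numeric") * 10000^(seq_along(x$digits) - 1))
}

# three-way comparison of a state count (number, Inf, or bigcount) with a
# finite number; returns sign(S - N)
state_count_cmp <- function(S, N) {
  if (inherits(S, "replikit_bigcount")) {
    if (is.infinite(N)) return(-1L)
    return(big_cmp(S$digits, big_from_int(N)))
  }
  if (is.infinite(S)) return(if (is.infinite(N)) 0L else 1L)
  sign(as.numeric(S) - as.numeric(N))
}
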