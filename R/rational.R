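# Exact integer / rational helpers.
#
# All stoichiometric coefficients are held as pairs of integer-valued doubles
# (numerator, denominator) and every elementary-mode computation runs on
# gcd-reduced integer vectors.  Doubles represent integers exactly up to
# 2^53; any operation that would exceed that bound aborts rather than
# silently losing exactness.

.INT_EXACT_MAX <- 2^53

.check_exact <- function(x, what = "integer arithmetic") {
  if (any(abs(x) >= .INT_EXACT_MAX)) {
    stop(sprintf("%s exceeded the exact-integer range (2^53); ",
                 what),
         "the network's coefficients are too large for exact enumeration",
         call. = FALSE)
  }
  invisible(x)
}

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0.5) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

# gcd of a vector; 0 for the all-zero vector
.gcd_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(0)
  Reduce(.gcd2, x)
}

.lcm2 <- function(a, b) {
  if (a == 0 || b == 0) return(0)
  r <- abs(a / .gcd2(a, b) * b)
  .check_exact(r, "lcm")
  r
}

.lcm_vec <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(1)
  Reduce(.lcm2, x)
}

# Reduce an integer vector by its gcd (no-op on the zero vector).
.reduce_int <- function(x) {
  g <- .gcd_vec(x)
  if (g > 1) x / g else x
}

# Parse a coefficient string: plain integer ("2"), fraction ("3/2") or
# decimal ("0.25", expanded by powers of ten).  Returns c(num, den), reduced.
.parse_coef <- function(s) {
  s <- trimws(s)
  if (grepl("^[0-9]+/[0-9]+$", s)) {
    parts <- as.numeric(strsplit(s, "/", fixed = TRUE)[[1]])
    if (parts[2] == 0) stop("zero denominator in coefficient '", s, "'", call. = FALSE)
    num <- parts[1]; den <- parts[2]
  } else if (grepl("^[0-9]+$", s)) {
    num <- as.numeric(s); den <- 1
  } else if (grepl("^[0-9]*\\.[0-9]+$", s)) {
    frac <- sub("^[0-9]*\\.", "", s)
    den <- 10^nchar(frac)
    num <- round(as.numeric(s) * den)
  } else {
    stop("cannot parse coefficient '", s, "'", call. = FALSE)
  }
  .check_exact(c(num, den), "coefficient parsing")
  g <- .gcd2(num, den)
  if (g > 1) { num <- num / g; den <- den / g }
  c(num, den)
}

# Format a rational num/den as "3" or "3/2" (den assumed positive, reduced).
.format_rat <- function(num, den) {
  ifelse(den == 1, format(num, scientific = FALSE, trim = TRUE),
         paste0(format(num, scientific = FALSE, trim = TRUE), "/",
                format(den, scientific = FALSE, trim = TRUE)))
}

# Parse a vector of rational strings to a list(num, den).
.parse_rat_vec <- function(s) {
  out <- vapply(s, .parse_coef, numeric(2), USE.NAMES = FALSE)
  list(num = out[1, ], den = out[2, ])
}

# Exact rank of an integer matrix by fraction-free (Bareiss) elimination.
.bareiss_rank <- function(M) {
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  m <- nrow(M); n <- ncol(M)
  if (m == 0L || n == 0L) return(0L)
  A <- M
  prev <- 1
  r <- 0L
  row <- 1L
  for (col in seq_len(n)) {
    piv <- which(A[row:m, col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    if (row < m) {
      idx <- (row + 1L):m
      new <- (A[idx, , drop = FALSE] * A[row, col] -
                outer(A[idx, col], A[row, ])) / prev
      .check_exact(new, "rank computation")
      A[idx, ] <- new
    }
    prev <- A[row, col]
    r <- r + 1L
    if (row == m) break
    row <- row + 1L
  }
  r
}

# Exact 1-dimensional nullspace of an integer matrix restricted to given
# columns.  Returns a reduced integer vector of length length(cols) spanning
# the kernel, or NULL if the kernel dimension is not exactly 1.
.nullspace_1d <- function(M, cols) {
  A <- M[, cols, drop = FALSE]
  k <- length(cols)
  r <- .bareiss_rank(A)
  if (r != k - 1L) return(NULL)
  # Solve by rational Gauss-Jordan: reduce to row echelon with exact
  # integer rows, then back-substitute for the single free variable.
  A <- A[rowSums(A != 0) > 0, , drop = FALSE]
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(k)) {
    if (row > nrow(A)) break
    piv <- which(A[row:nrow(A), col] != 0)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    for (i in seq_len(nrow(A))) {
      if (i != row && A[i, col] != 0) {
        new <- A[i, ] * A[row, col] - A[row, ] * A[i, col]
        .check_exact(new, "nullspace computation")
        A[i, ] <- .reduce_int(new)
      }
    }
    A[row, ] <- .reduce_int(A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(k), pivots)
  if (length(free) != 1L) return(NULL)
  # kernel vector: x[free] = L (lcm of pivot coefficients), pivot entries
  # solved exactly.
  v <- numeric(k)
  pivcoef <- vapply(seq_along(pivots), function(i) A[i, pivots[i]], numeric(1))
  L <- .lcm_vec(pivcoef)
  v[free] <- L
  for (i in seq_along(pivots)) {
    v[pivots[i]] <- -A[i, free] * (L / pivcoef[i])
  }
  .check_exact(v, "nullspace computation")
  .reduce_int(v)
}
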