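# Sobol low-discrepancy sequence, Saltelli design, and variance-based
# sensitivity index estimators.

# Joe-Kuo direction-number parameters for dimensions 2..16 (dimension 1 is
# the van der Corput sequence in base 2).  Columns: s = polynomial degree,
# a = encoded primitive-polynomial coefficients, m = initial direction
# integers.
.sobol_dirnum <- list(
  list(s = 1L, a = 0L,  m = c(1L)),
  list(s = 2L, a = 1L,  m = c(1L, 3L)),
  list(s = 3L, a = 1L,  m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L,  m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L,  m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L,  m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L,  m = c(1L, 1L, 5L, 5L, 17L)),
  list(s = 5L, a = 4L,  m = c(1L, 1L, 5L, 5L, 5L)),
  list(s = 5L, a = 7L,  m = c(1L, 1L, 7L, 11L, 19L)),
  list(s = 5L, a = 11L, m = c(1L, 1L, 5L, 1L, 1L)),
  list(s = 5L, a = 13L, m = c(1L, 1L, 1L, 3L, 11L)),
  list(s = 5L, a = 14L, m = c(1L, 3L, 5L, 5L, 31L)),
  list(s = 6L, a = 1L,  m = c(1L, 3L, 3L, 9L, 7L, 49L)),
  list(s = 6L, a = 13L, m = c(1L, 1L, 1L, 15L, 21L, 21L)),
  list(s = 6L, a = 16L, m = c(1L, 3L, 1L, 13L, 27L, 49L))
)

.SOBOL_BITS <- 30L

# Direction numbers v_1..v_bits for one dimension, scaled to integers below
# 2^30.
.sobol_directions <- function(dim) {
  bits <- .SOBOL_BITS
  if (dim == 1L) return(as.integer(2^(bits - seq_len(bits))))
  par <- .sobol_dirnum[[dim - 1L]]
  s <- par$s; a <- par$a; m <- as.integer(par$m)
  if (bits > s) {
    m <- c(m, integer(bits - s))
    for (k in (s + 1L):bits) {
      mk <- bitwXor(m[k - s], as.integer(m[k - s] * 2^s))
      for (i in seq_len(s - 1L)) {
        ai <- bitwAnd(bitwShiftR(a, s - 1L - i), 1L)
        if (ai == 1L) mk <- bitwXor(mk, as.integer(m[k - i] * 2^i))
      }
      m[k] <- mk
    }
  }
  as.integer(m * 2^(bits - seq_len(bits)))
}

#' Sobol low-discrepancy sequence
#'
#' Generates the first `n` points (after the all-zero origin, which is
#' skipped) of the d-dimensional Sobol sequence, using Joe-Kuo
#' direction numbers.  Supports up to 16 dimensions.
#'
#' @param n number of points.
#' @param d dimension (1..16).
#' @param skip number of initial points to skip (default 1, the origin).
#' @return an `n x d` matrix of points in (0, 1)^d (first row includes 0s
#'   only if `skip = 0`).
#' @export
sobol_sequence <- function(n, d, skip = 1L) {
  stopifnot(n >= 1, d >= 1)
  if (d > 16L)
    stop("sobol_sequence supports at most 16 dimensions", call. = FALSE)
  n <- as.integer(n); skip <- as.integer(skip)
  out <- matrix(0, n, d)
  denom <- 2^.SOBOL_BITS
  for (j in seq_len(d)) {
    v <- .sobol_directions(j)
    x <- 0L
    # Gray-code order: point i flips the direction indexed by the lowest
    # zero bit of i-1.
    col <- numeric(n)
    total <- skip + n
    for (i in seq_len(total - 1L)) {
      c0 <- 1L
      ii <- i - 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c0 <- c0 + 1L }
      x <- bitwXor(x, v[c0])
      if (i >= skip) col[i - skip + 1L] <- x / denom
    }
    if (skip == 0L) col <- c(0, col[seq_len(n - 1L)])
    out[, j] <- col
  }
  out
}

#' Saltelli design for Sobol index estimation
#'
#' Builds the A, B and AB_i sample matrices over the parameter hypercube
#' defined by `ranges`.  A and B are two independent Latin hypercube samples
#' (seeded, reproducible); AB_i equals A with column i replaced by B's.
#' Model evaluations over the design total `n_base * (d + 2)`.
#'
#' @param ranges data.frame with `parameter`, `lower`, `upper` columns.
#' @param n_base base sample size (powers of 2 recommended).
#' @param seed integer seed.
#' @return a list with matrices `A`, `B` (n_base x d) and list `AB` of d
#'   matrices, plus `parameters`.
#' @export
saltelli_design <- function(ranges, n_base, seed = 1L) {
  stopifnot(n_base >= 2)
  d <- nrow(ranges)
  set.seed(seed)
  u <- lhs::randomLHS(as.integer(n_base) * 2L, d)
  scale_u <- function(m) {
    m <- sweep(m, 2L, ranges$upper - ranges$lower, `*`)
    m <- sweep(m, 2L, ranges$lower, `+`)
    colnames(m) <- ranges$parameter
    m
  }
  A <- scale_u(u[seq_len(n_base), , drop = FALSE])
  B <- scale_u(u[n_base + seq_len(n_base), , drop = FALSE])
  AB <- lapply(seq_len(d), function(i) { m <- A; m[, i] <- B[, i]; m })
  list(A = A, B = B, AB = AB, parameters = ranges$parameter)
}

#' Sobol sensitivity indices from Saltelli-design evaluations
#'
#' Jansen estimators of the first-order and total-order Sobol indices given
#' model outputs on the A, B and AB_i matrices of a [saltelli_design()]:
#' `S1_i = (V - mean((yB - yAB_i)^2)/2) / V` and
#' `ST_i = mean((yA - yAB_i)^2) / (2 V)` with `V = var(c(yA, yB))`.
#'
#' @param yA,yB numeric vectors of model outputs on A and B.
#' @param yAB list of d numeric vectors of outputs on the AB_i matrices.
#' @param parameters optional parameter names.
#' @return data.frame with columns `parameter`, `S1`, `ST`.  If the outputs
#'   have (numerically) zero variance the indices are undefined and returned
#'   as `NA` with a warning.
#' @export
sobol_indices <- function(yA, yB, yAB, parameters = NULL) {
  stopifnot(length(yA) == length(yB), is.list(yAB))
  d <- length(yAB)
  if (is.null(parameters)) parameters <- paste0("x", seq_len(d))
  v <- stats::var(c(yA, yB))
  if (!is.finite(v) || v <= .Machine$double.eps * mean(abs(c(yA, yB, 1)))) {
    warning("zero-variance outcome: Sobol indices undefined")
    return(data.frame(parameter = parameters, S1 = NA_real_, ST = NA_real_))
  }
  s1 <- vapply(yAB, function(y) (v - mean((yB - y)^2) / 2) / v, numeric(1))
  st <- vapply(yAB, function(y) mean((yA - y)^2) / (2 * v), numeric(1))
  data.frame(parameter = parameters, S1 = s1, ST = st, row.names = NULL)
}
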