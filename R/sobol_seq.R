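# Digitally-shifted Sobol' low-discrepancy sequence (31-bit, Gray code),
# direction numbers from the standard Joe-Kuo table for the first 21
# dimensions. The random digital shift (seeded) preserves uniform marginals
# exactly and makes the point set a randomized QMC estimator.

# per-dimension primitive polynomial degree s, coefficient bits a, and
# initial direction values m (dimension 1 is the van der Corput sequence)
sobol_dirdata <- list(
  list(s = 1, a = 0, m = 1),            # dim 2
  list(s = 2, a = 1, m = c(1, 3)),      # dim 3
  list(s = 3, a = 1, m = c(1, 3, 1)),
  list(s = 3, a = 2, m = c(1, 1, 1)),
  list(s = 4, a = 1, m = c(1, 1, 3, 3)),
  list(s = 4, a = 4, m = c(1, 3, 5, 13)),
  list(s = 5, a = 2, m = c(1, 1, 5, 5, 17)),
  list(s = 5, a = 4, m = c(1, 1, 5, 5, 5)),
  list(s = 5, a = 7, m = c(1, 1, 7, 11, 19)),
  list(s = 5, a = 11, m = c(1, 1, 5, 1, 1)),
  list(s = 5, a = 13, m = c(1, 1, 1, 3, 11)),
  list(s = 5, a = 14, m = c(1, 3, 5, 5, 31)),
  list(s = 6, a = 1, m = c(1, 3, 3, 9, 7, 49)),
  list(s = 6, a = 13, m = c(1, 1, 1, 15, 21, 21)),
  list(s = 6, a = 16, m = c(1, 3, 1, 13, 27, 49)),
  list(s = 6, a = 19, m = c(1, 1, 1, 15, 7, 5)),
  list(s = 6, a = 22, m = c(1, 3, 1, 15, 13, 25)),
  list(s = 6, a = 25, m = c(1, 1, 5, 5, 19, 61)),
  list(s = 7, a = 1, m = c(1, 3, 7, 11, 23, 15, 103)),
  list(s = 7, a = 4, m = c(1, 3, 7, 13, 13, 15, 69)))

NBITS <- 31L

# direction integers v_j = m_j * 2^(NBITS - j) for one dimension
sobol_directions <- function(dim) {
  if (dim == 1) return(bitwShiftL(1L, NBITS - seq_len(NBITS)))
  dd <- sobol_dirdata[[dim - 1]]
  s <- dd$s
  m <- as.integer(dd$m)
  if (NBITS > s) {
    m <- c(m, integer(NBITS - s))
    for (k in (s + 1):NBITS) {
      mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
      if (s > 1) for (j in 1:(s - 1))
        if (bitwAnd(dd$a, bitwShiftL(1L, s - 1L - j)) != 0L)
          mk <- bitwXor(mk, bitwShiftL(m[k - j], j))
      m[k] <- mk
    }
  }
  vapply(seq_len(NBITS), function(j) bitwShiftL(m[j], NBITS - j), integer(1))
}

# N x dims matrix of scrambled Sobol points in (0, 1)
sobol_points <- function(N, dims, shift = NULL) {
  if (dims > length(sobol_dirdata) + 1)
    stop("Sobol sequence implemented up to ", length(sobol_dirdata) + 1,
         " dimensions")
  X <- matrix(0L, nrow = N, ncol = dims)
  for (d in seq_len(dims)) {
    v <- sobol_directions(d)
    x <- 0L
    col <- integer(N)
    for (i in seq_len(N)) {
      # Gray-code order: flip the direction of the lowest zero bit of i-1
      c0 <- 1L
      ii <- i - 1L
      while (bitwAnd(ii, 1L) == 1L) { ii <- bitwShiftR(ii, 1L); c0 <- c0 + 1L }
      x <- bitwXor(x, v[c0])
      col[i] <- x
    }
    X[, d] <- col
  }
  if (!is.null(shift))
    X <- vapply(seq_len(dims), function(d) bitwXor(X[, d], shift[d]),
                integer(N))
  (X + 0.5) / 2^NBITS
}

# seeded random digital shift
sobol_shift <- function(dims) {
  as.integer(floor(stats::runif(dims) * 2^NBITS))
}
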