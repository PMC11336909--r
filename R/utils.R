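`%||%` <- function(a, b) if (is.null(a)) b else a

#' Zero-phase IIR filtering along columns
#'
#' Forward-backward application of an IIR filter to each column of a matrix,
#' with odd-reflection edge padding and steady-state initial conditions so
#' that transients do not leak into the output (the scheme used by standard
#' scientific filtfilt implementations). Real and imaginary parts of complex
#' input are filtered independently; the operation is linear.
#'
#' @param b,a numerator / denominator filter coefficients.
#' @param x numeric or complex matrix, series along rows (one column per
#'   channel), or a vector.
#' @return Filtered matrix (or vector) of the same shape.
#' @keywords internal
zeroPhaseFilter <- function(b, a, x) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  if (is.complex(x))
    return(zeroPhaseFilter(b, a, Re(x)) + 1i * zeroPhaseFilter(b, a, Im(x)))
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  pad <- 3L * (n - 1L)
  nt <- nrow(x)
  if (nt <= pad)
    stop("series too short for zero-phase filtering (need > ", pad, " samples)")
  zi <- .filterZi(b, a)
  run <- function(y) {
    # y: (nt + 2 pad) x npix, forward pass with scaled initial state
    .iirFilter(b, a, y, zi)
  }
  top <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
  bot <- 2 * x[rep(nt, pad), , drop = FALSE] -
    x[(nt - 1L):(nt - pad), , drop = FALSE]
  y <- rbind(top, x, bot)
  y <- run(y)
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- run(y)
  y <- y[nrow(y):1L, , drop = FALSE]
  out <- y[(pad + 1L):(pad + nt), , drop = FALSE]
  if (vec) out[, 1L] else out
}

# Steady-state initial filter state (direct form II transposed), the
# classic lfilter_zi construction.
.filterZi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  IminusA <- diag(n - 1L) -
    cbind(-a[-1L], rbind(diag(1, n - 2L), matrix(0, 1L, max(n - 2L, 0L))))
  B <- b[-1L] - a[-1L] * b[1L]
  as.numeric(solve(IminusA, B))
}

# Direct form II transposed IIR filter, vectorized across columns, with
# per-column initial state zi * y[1, ].
.iirFilter <- function(b, a, y, zi) {
  nt <- nrow(y); npix <- ncol(y); ns <- length(zi)
  out <- matrix(0, nt, npix)
  z <- outer(zi, y[1L, ])               # ns x npix state
  for (t in seq_len(nt)) {
    xt <- y[t, ]
    yt <- b[1L] * xt + z[1L, ]
    if (ns > 1L)
      for (k in seq_len(ns - 1L))
        z[k, ] <- b[k + 1L] * xt + z[k + 1L, ] - a[k + 1L] * yt
    z[ns, ] <- b[ns + 1L] * xt - a[ns + 1L] * yt
    out[t, ] <- yt
  }
  out
}

#' Optimal assignment by the Hungarian algorithm
#'
#' Minimum-total-cost bipartite assignment of rows to columns of a cost
#' matrix (potentials + shortest augmenting path, O(n^3)). Requires
#' \code{nrow(cost) <= ncol(cost)}; every row is assigned a distinct column.
#'
#' @param cost numeric matrix of pairwise costs (finite).
#' @return integer vector, \code{assignment[i]} = column assigned to row i.
#' @examples
#' cost <- matrix(c(4, 2, 8, 4, 3, 7, 3, 1, 6), 3, 3)
#' hungarianAssign(cost)
#' @export
hungarianAssign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L) return(integer(0))
  stopifnot(n <= m, all(is.finite(cost)))
  V <- m + 1L  # virtual start column
  u <- numeric(n); v <- numeric(m + 1L)
  p <- integer(m + 1L)                  # row matched to each column (0 = none)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, m)
    way <- integer(m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      free <- which(!used[seq_len(m)])
      if (length(free)) {
        cur <- cost[i0, free] - u[i0] - v[free]
        upd <- cur < minv[free]
        if (any(upd)) {
          minv[free[upd]] <- cur[upd]
          way[free[upd]] <- j0
        }
        jrel <- which.min(minv[free])
        delta <- minv[free[jrel]]
        j1 <- free[jrel]
      }
      usedCols <- which(used)
      rows <- p[usedCols]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      vc <- usedCols[usedCols <= m]
      v[vc] <- v[vc] - delta
      if (length(free)) minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- if (j1 == V) i else p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

# Seeded evaluation that leaves the caller's RNG state untouched.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

# Complex circular Gaussian noise, sd per real/imaginary component.
.cnoise <- function(n, sigma) {
  complex(real = stats::rnorm(n, sd = sigma),
          imaginary = stats::rnorm(n, sd = sigma))
}

# Reshape an IQ movie to its (space x time) Casorati matrix and back.
.casorati <- function(arr) {
  d <- dim(arr)
  matrix(arr, nrow = d[1] * d[2], ncol = d[3])
}

.uncasorati <- function(mat, d) array(mat, dim = d)
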