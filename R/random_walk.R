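#' @include AllClasses.R accessors.R utils.R
NULL

#' Seeded random-walker segmentation of one slice
#'
#' Solves the combinatorial Dirichlet problem on the 4-connected pixel
#' lattice: edge weights are Gaussian in the intensity difference,
#' \eqn{w_{ij} = \exp(-\beta (g_i - g_j)^2)} (plus a small floor of 1e-10
#' keeping the system nonsingular on flat regions), and the returned value
#' at each pixel is the probability that a random walk started there,
#' with transition probabilities proportional to edge weights, reaches the
#' foreground seed before the background seed. This is the harmonic
#' function with Dirichlet values 1 at the foreground seed and 0 at the
#' background seed, obtained by solving the unseeded block of the graph
#' Laplacian.
#'
#' Two labels only (foreground/background); the background probability is
#' `1 - p` everywhere.
#'
#' @param slice numeric matrix with intensities in \[0, 1\]
#'   (apply [autoWindow()] first).
#' @param seeds a [SeedSpec-class]; both seeds must be in bounds and
#'   distinct.
#' @param beta edge-weight sharpness (> 0); default 130, a conventional
#'   value for \[0, 1\] intensities.
#' @param tol solver residual tolerance (default 1e-8). Systems with more
#'   than 1e5 unseeded pixels are solved by conjugate gradients at this
#'   tolerance; smaller systems use a direct sparse solve.
#' @return a [ProbabilityMap-class].
#' @examples
#' s <- matrix(0, 1, 4)
#' p <- solveRW(s, SeedSpec(fg = c(0, 0), bg = c(0, 3)))
#' probValues(p)   # (1, 2/3, 1/3, 0) on a unit-weight path graph
#' @export
solveRW <- function(slice, seeds, beta = 130, tol = 1e-8) {
  if (!is.matrix(slice)) stop("'slice' must be a matrix", call. = FALSE)
  stopIfNot01(slice, "slice intensities")
  if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
  dm <- dim(slice)
  fg <- seedToIndex(seeds@fg, dm, "foreground seed")
  bg <- seedToIndex(seeds@bg, dm, "background seed")
  if (all(fg == bg)) stop("seeds must not coincide", call. = FALSE)

  nr <- dm[1L]; nc <- dm[2L]; P <- nr * nc
  idx <- matrix(seq_len(P), nr, nc)
  iV <- as.vector(idx[-nr, , drop = FALSE]); jV <- as.vector(idx[-1L, , drop = FALSE])
  iH <- as.vector(idx[, -nc, drop = FALSE]); jH <- as.vector(idx[, -1L, drop = FALSE])
  ii <- c(iV, iH); jj <- c(jV, jH)
  g <- as.vector(slice)
  w <- exp(-beta * (g[ii] - g[jj])^2) + 1e-10

  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(w, w),
                            dims = c(P, P))
  L <- Matrix::Diagonal(P, Matrix::rowSums(W)) - W
  sFg <- idx[fg[1L], fg[2L]]; sBg <- idx[bg[1L], bg[2L]]
  U <- seq_len(P)[-c(sFg, sBg)]

  # Dirichlet data: p = 1 at fg, 0 at bg, so rhs = -L[U, fg].
  b <- -as.numeric(L[U, sFg, drop = FALSE])
  A <- L[U, U, drop = FALSE]
  x <- if (length(U) > 1e5) cgSolve(A, b, tol) else as.numeric(Matrix::solve(A, b))

  res <- sqrt(sum((as.numeric(A %*% x) - b)^2))
  if (res > max(tol, tol * sqrt(sum(b * b))))
    stop(sprintf("random-walker solver did not reach tolerance (residual %.3g)",
                 res), call. = FALSE)

  p <- numeric(P)
  p[U] <- pmin(1, pmax(0, x))
  p[sFg] <- 1; p[sBg] <- 0
  new("ProbabilityMap", values = matrix(p, nr, nc), seeds = seeds)
}

# Plain conjugate gradients for the SPD unseeded Laplacian block.
cgSolve <- function(A, b, tol, maxIter = 10000L) {
  x <- numeric(length(b))
  r <- b; p <- r
  rs <- sum(r * r)
  for (it in seq_len(maxIter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- sum(r * r)
    if (sqrt(rsNew) <= tol * max(1, sqrt(sum(b * b)))) break
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  x
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' `thValue` (the boundary value is foreground).
#'
#' @param prob a [ProbabilityMap-class] or a numeric matrix in \[0, 1\].
#' @param thValue threshold in the open interval (0, 1); default 0.5
#'   (majority label).
#' @return an integer 0/1 matrix.
#' @examples
#' thresholdMask(matrix(c(0.49, 0.5), 1, 2), 0.5)
#' @export
thresholdMask <- function(prob, thValue = 0.5) {
  if (!(thValue > 0 && thValue < 1))
    stop("'thValue' must lie strictly between 0 and 1", call. = FALSE)
  v <- if (is(prob, "ProbabilityMap")) prob@values else prob
  matrix(as.integer(v >= thValue), nrow(v), ncol(v))
}
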