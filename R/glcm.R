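#' @include AllClasses.R utils.R
NULL

#' Quantize an ROI into N grey levels
#'
#' Equal-width binning over the in-mask intensity range: level
#' `min(N, floor((v - min) / (max - min) * N) + 1)`. A constant ROI maps
#' entirely to level 1. The raster layout is preserved (out-of-mask pixels
#' are NA) so that spatial texture matrices can be built downstream.
#'
#' @param slice numeric matrix of intensities.
#' @param mask 0/1 matrix of the same shape; must be nonempty.
#' @param N grey-level count, 2..256 (default 64).
#' @return a [QuantizedROI-class].
#' @examples
#' q <- quantizeROI(matrix(c(10, 20, 30, 40), 2), matrix(1, 2, 2), 4)
#' q@values
#' @export
quantizeROI <- function(slice, mask, N = 64L) {
  if (!identical(dim(slice), dim(mask))) stop("shape mismatch", call. = FALSE)
  if (N < 2L || N > 256L) stop("'N' must lie in 2..256", call. = FALSE)
  inMask <- mask != 0
  if (!any(inMask)) stop("empty mask", call. = FALSE)
  v <- slice[inMask]
  lo <- min(v); hi <- max(v)
  q <- matrix(NA_integer_, nrow(slice), ncol(slice))
  if (hi == lo) {
    q[inMask] <- 1L
  } else {
    q[inMask] <- pmin(as.integer(N), as.integer(floor((v - lo) / (hi - lo) * N)) + 1L)
  }
  new("QuantizedROI", levels = as.integer(N), values = q,
      nPixels = as.integer(sum(inMask)))
}

# Direction unit steps (drow, dcol) for the standard 2-D offsets.
directionStep <- function(angle) {
  switch(as.character(angle),
    "0" = c(0L, 1L), "45" = c(-1L, 1L), "90" = c(-1L, 0L), "135" = c(-1L, -1L),
    stop("offsets must be among 0, 45, 90, 135 degrees", call. = FALSE))
}

#' Build a grey-level co-occurrence matrix
#'
#' Counts pairs of in-mask pixels separated by `distance` along each
#' offset direction, both pixels inside the ROI. Counts are symmetrized
#' (each pair counted in both orders), accumulated over all offsets into
#' one matrix, and normalized to sum to 1. The marginal mean \eqn{\mu} and
#' variance \eqn{\sigma^2} and the sum/difference distributions
#' `fSum` (k = 2..2N) and `fDiff` (k = 0..N-1) are precomputed.
#'
#' @param qroi a [QuantizedROI-class].
#' @param offsets offset angles in degrees, subset of `c(0, 45, 90, 135)`
#'   (default all four, giving direction-balanced counts).
#' @param distance pair distance in pixels (default 1).
#' @return a [CoocMatrix-class].
#' @examples
#' q <- quantizeROI(matrix(1, 4, 4), matrix(1, 4, 4), 8)
#' buildGLCM(q)@f[1, 1]   # degenerate constant ROI: all mass at (1, 1)
#' @export
buildGLCM <- function(qroi, offsets = c(0, 45, 90, 135), distance = 1L) {
  if (length(offsets) < 1L) stop("empty offset set", call. = FALSE)
  N <- qroi@levels
  v <- qroi@values
  nr <- nrow(v); nc <- ncol(v)
  counts <- matrix(0, N, N)
  for (ang in offsets) {
    d <- directionStep(ang) * as.integer(distance)
    r1 <- max(1L, 1L - d[1L]):min(nr, nr - d[1L])
    c1 <- max(1L, 1L - d[2L]):min(nc, nc - d[2L])
    if (length(r1) < 1L || length(c1) < 1L) next
    a <- v[r1, c1, drop = FALSE]
    b <- v[r1 + d[1L], c1 + d[2L], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    tab <- tabulate((a[ok] - 1L) * N + b[ok], nbins = N * N)
    counts <- counts + matrix(tab, N, N, byrow = TRUE)
  }
  counts <- counts + t(counts)          # symmetrize: count each pair both ways
  total <- sum(counts)
  if (total == 0) stop("ROI has no valid pixel pairs (single pixel?)", call. = FALSE)
  f <- counts / total

  marg <- rowSums(f)
  x <- seq_len(N)
  mu <- sum(x * marg)
  sigma2 <- sum((x - mu)^2 * marg)

  X <- matrix(x, N, N); Y <- t(X)
  fSum <- vapply(2L:(2L * N), function(k) sum(f[X + Y == k]), numeric(1L))
  names(fSum) <- as.character(2L:(2L * N))
  fDiff <- vapply(0L:(N - 1L), function(k) sum(f[abs(X - Y) == k]), numeric(1L))
  names(fDiff) <- as.character(0L:(N - 1L))

  new("CoocMatrix", f = f, mu = mu, sigma2 = sigma2,
      fSum = fSum, fDiff = fDiff, levels = N)
}

#' GLCM texture features
#'
#' Computes the 18 co-occurrence texture features (all GLCM-family
#' features except convexity, which is mask-based; see [convexity()]).
#'
#' In the default `corrected` dialect the standard forms are used:
#' autocorrelation \eqn{\sum xy f}, correlation
#' \eqn{\sum (x-\mu)(y-\mu) f / \sigma^2}, contrast \eqn{\sum (x-y)^2 f},
#' dissimilarity \eqn{\sum |x-y| f}, homogeneity \eqn{\sum f/(1+|x-y|)},
#' entropies \eqn{-\sum q \log_2 q} (with 0 log 0 = 0), sum variance
#' centred on the sum average with a square, and difference variance
#' centred on the (internal) difference average with a square. The
#' `printed` dialect reproduces the verbatim published variants of
#' autocorrelation, dissimilarity, the three entropies, homogeneity
#' (terms with zero denominator are dropped), sum variance and difference
#' variance, restricting sum/difference sums to k = 1..2N-1.
#'
#' When \eqn{\sigma^2 = 0} (degenerate single-level GLCM), correlation and
#' both information measures are defined as 0 with a warning.
#'
#' @param m a [CoocMatrix-class].
#' @param dialect `"corrected"` (default) or `"printed"`.
#' @return named numeric(18).
#' @export
glcmFeatures <- function(m, dialect = c("corrected", "printed")) {
  dialect <- match.arg(dialect)
  f <- m@f; N <- m@levels; mu <- m@mu; s2 <- m@sigma2
  x <- seq_len(N)
  X <- matrix(x, N, N); Y <- t(X)
  kSum <- as.integer(names(m@fSum)); kDiff <- as.integer(names(m@fDiff))
  fSum <- m@fSum; fDiff <- m@fDiff
  printed <- dialect == "printed"
  if (printed) {
    # published index range k = 1..2N-1 for sum/difference distributions
    keepS <- kSum <= 2L * N - 1L
    fSumP <- fSum[keepS]; kSumP <- kSum[keepS]
    keepD <- kDiff >= 1L
    fDiffP <- fDiff[keepD]; kDiffP <- kDiff[keepD]
  }

  degenerate <- s2 == 0
  if (degenerate)
    warning("GLCM has zero marginal variance; correlation-type features set to 0")
  covTerm <- sum(f * (X - mu) * (Y - mu))

  savg <- if (printed) sum(kSumP * fSumP) else sum(kSum * fSum)
  davg <- if (printed) sum(kDiffP * fDiffP) else sum(kDiff * fDiff)
  svar <- if (printed) sum(fSumP * (kSumP - savg))
          else sum((kSum - savg)^2 * fSum)
  dvar <- if (printed) sum(fDiffP * (kDiffP - svar))
          else sum((kDiff - davg)^2 * fDiff)

  homo <- if (printed) {
    den <- 1 + X - Y
    sum((f / den)[den != 0])
  } else sum(f / (1 + abs(X - Y)))

  c(
    gcm_rxx = if (printed) sum(f * (X - mu)^2) else sum(f * X * Y),
    gcm_cpro = sum(f * (X + Y - 2 * mu)^4),
    gcm_cshd = sum(f * (X + Y - 2 * mu)^3),
    gcm_corr = if (degenerate) 0 else covTerm / s2,
    gcm_contr = sum(f * (X - Y)^2),
    gcm_disim = if (printed) sum(f * (X - Y)) else sum(f * abs(X - Y)),
    gcm_dvar = dvar,
    gcm_dentro = if (printed) sum(xlog2x(fDiffP)) else -sum(xlog2x(fDiff)),
    gcm_ener = sum(f^2),
    gcm_entro = if (printed) sum(xlog2x(f)) else -sum(xlog2x(f)),
    gcm_homo = homo,
    gcm_imc1 = if (degenerate) 0 else covTerm / s2,
    gcm_imc2 = if (degenerate) 0 else covTerm / (s2 + 1 / s2),
    gcm_imn = sum(f / (1 + (X - Y)^2)),
    gcm_max_prob = max(f),
    gcm_savg = savg,
    gcm_svar = svar,
    gcm_sentro = if (printed) sum(xlog2x(fSumP)) else -sum(xlog2x(fSum))
  )
}

#' Convexity (solidity) of a mask stack
#'
#' Per slice, the ratio of the mask pixel count to the pixel count of the
#' filled convex hull of the mask (pixels whose centers lie inside or on
#' the hull polygon); the feature is the mean over slices. Convex regions
#' score 1; concavities lower the score. Range (0, 1].
#'
#' @param masks a [MaskStack-class] (or a single 0/1 matrix). Empty slices
#'   are skipped with a warning; all-empty input is an error.
#' @return numeric(1), the mean per-slice convexity.
#' @examples
#' m <- matrix(0L, 7, 7); m[2:6, 2:6] <- 1L
#' convexity(MaskStack(m))   # filled square: 1
#' @export
convexity <- function(masks) {
  if (is.matrix(masks)) masks <- MaskStack(masks)
  vals <- numeric(0L)
  for (i in seq_along(masks@slices)) {
    m <- masks@slices[[i]]
    if (sum(m) == 0L) {
      warning(sprintf("slice %d mask is empty; skipped from convexity", i - 1L))
      next
    }
    vals <- c(vals, sliceConvexity(m))
  }
  if (length(vals) == 0L) stop("all mask slices empty", call. = FALSE)
  mean(vals)
}

sliceConvexity <- function(m) {
  idx <- which(m != 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 1L) return(1)
  pr <- idx[, 1L]; pc <- idx[, 2L]
  # collinear point sets: the hull degenerates to a segment whose filled
  # "hull" is its lattice pixels (gcd + 1 of the endpoint offsets)
  o <- order(pr, pc)
  a <- c(pr[o[1L]], pc[o[1L]]); b <- c(pr[o[n]], pc[o[n]])
  collinear <- all((pr - a[1L]) * (b[2L] - a[2L]) -
                   (pc - a[2L]) * (b[1L] - a[1L]) == 0)
  if (collinear) {
    hullPixels <- gcdInt(abs(b[1L] - a[1L]), abs(b[2L] - a[2L])) + 1L
    return(n / hullPixels)
  }
  hull <- grDevices::chull(pc, pr)           # hull vertex order
  hr <- pr[hull]; hc <- pc[hull]
  rows <- min(pr):max(pr); cols <- min(pc):max(pc)
  cand <- expand.grid(r = rows, c = cols)
  inside <- pracma::inpolygon(cand$c, cand$r, hc, hr, boundary = TRUE)
  n / sum(inside)
}

gcdInt <- function(a, b) {
  while (b != 0L) { t <- a %% b; a <- b; b <- t }
  a
}
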