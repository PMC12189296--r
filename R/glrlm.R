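#' @include AllClasses.R utils.R glcm.R
NULL

# Extract the ordered value sequences of a raster along one direction;
# NA (out-of-mask) entries break runs downstream.
directionLines <- function(v, angle) {
  nr <- nrow(v); nc <- ncol(v)
  switch(as.character(angle),
    "0" = lapply(seq_len(nr), function(r) v[r, ]),
    "90" = lapply(seq_len(nc), function(c) v[, c]),
    "45" = {
      # anti-diagonals: constant row + col
      s <- row(v) + col(v)
      lapply(split(seq_along(v), s), function(ix) v[ix])
    },
    "135" = {
      # main diagonals: constant col - row
      s <- col(v) - row(v)
      lapply(split(seq_along(v), s), function(ix) v[ix])
    },
    stop("directions must be among 0, 45, 90, 135 degrees", call. = FALSE))
}

#' Build a grey-level run length matrix
#'
#' Counts maximal runs of equal grey level along each direction of
#' `directions`, restricted to in-mask pixels (runs break at mask
#' boundaries), and accumulates all directions into a single
#' levels x run-length matrix `R`, normalized to `p = R / RTotal`.
#'
#' @param qroi a [QuantizedROI-class].
#' @param directions angles in degrees, nonempty subset of
#'   `c(0, 45, 90, 135)` (default all four).
#' @return a [RunLengthMatrix-class].
#' @examples
#' q <- quantizeROI(matrix(1, 4, 4), matrix(1, 4, 4), 8)
#' buildGLRLM(q, directions = 0)@R[1, 4]   # four horizontal runs of length 4
#' @export
buildGLRLM <- function(qroi, directions = c(0, 45, 90, 135)) {
  if (length(directions) < 1L) stop("empty direction set", call. = FALSE)
  v <- qroi@values
  N <- qroi@levels
  lv <- integer(0L); ln <- integer(0L)
  for (ang in directions) {
    for (line in directionLines(v, ang)) {
      r <- rle(as.vector(line))
      keep <- !is.na(r$values)
      lv <- c(lv, as.integer(r$values[keep]))
      ln <- c(ln, r$lengths[keep])
    }
  }
  if (length(lv) == 0L) stop("ROI produced no runs", call. = FALSE)
  Nr <- max(ln)
  R <- matrix(0, N, Nr)
  for (k in seq_along(lv)) R[lv[k], ln[k]] <- R[lv[k], ln[k]] + 1
  RTotal <- sum(R)
  new("RunLengthMatrix", R = R, p = R / RTotal, RTotal = RTotal,
      Nr = as.integer(Nr), nPixels = qroi@nPixels)
}

#' GLRLM texture features
#'
#' The seven run-length features. In the default `corrected` dialect the
#' standard forms are used: short-run emphasis \eqn{\sum p/y^2}, long-run
#' emphasis \eqn{\sum p y^2}, grey-level non-uniformity
#' \eqn{\sum_x (\sum_y R)^2 / R_{total}}, run-length non-uniformity
#' \eqn{\sum_y (\sum_x R)^2 / R_{total}}, run percentage
#' \eqn{R_{total} / n_{pixels}}, low/high grey-level run emphasis
#' \eqn{\sum p/x^2} and \eqn{\sum p x^2}. The `printed` dialect evaluates
#' the published variants verbatim where they define a scalar
#' (non-uniformities \eqn{\sum p^2 / N_r} and \eqn{\sum p^2 / N}, low
#' emphasis \eqn{\sum p x^2}, high emphasis \eqn{\sum p x^2/y^2});
#' short-run emphasis and run percentage, whose published forms do not
#' reduce to scalars, keep the corrected forms.
#'
#' @param m a [RunLengthMatrix-class].
#' @param dialect `"corrected"` (default) or `"printed"`.
#' @return named numeric(7).
#' @export
glrlmFeatures <- function(m, dialect = c("corrected", "printed")) {
  dialect <- match.arg(dialect)
  p <- m@p; R <- m@R
  N <- nrow(R); Nr <- m@Nr
  X <- matrix(seq_len(N), N, Nr)          # grey level
  Y <- matrix(seq_len(Nr), N, Nr, byrow = TRUE)  # run length
  printed <- dialect == "printed"
  c(
    grlm_sr = sum(p / Y^2),
    grlm_lr = sum(p * Y^2),
    grlm_gn = if (printed) sum(p^2) / Nr
              else sum(rowSums(R)^2) / m@RTotal,
    grlm_rln = if (printed) sum(p^2) / N
               else sum(colSums(R)^2) / m@RTotal,
    grlm_rper = m@RTotal / m@nPixels,
    grlm_hgr = if (printed) sum(p * X^2 / Y^2) else sum(p * X^2),
    grlm_lgr = if (printed) sum(p * X^2) else sum(p / X^2)
  )
}
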