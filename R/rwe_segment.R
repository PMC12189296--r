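#' @include AllClasses.R accessors.R random_walk.R
NULL

#' Pixelwise OR integration of binary masks
#'
#' The ensemble accumulator: a pixel is set in the result iff it is set in
#' the accumulator or in the new mask. Commutative, with the empty mask as
#' identity; the accumulator is non-decreasing under repeated integration.
#'
#' @param accumulator,newMask 0/1 matrices of identical shape.
#' @return an integer 0/1 matrix.
#' @examples
#' integrateMasks(matrix(c(0, 0, 1, 1), 2), matrix(c(0, 1, 0, 1), 2))
#' @export
integrateMasks <- function(accumulator, newMask) {
  if (!identical(dim(accumulator), dim(newMask)))
    stop("mask shapes differ", call. = FALSE)
  matrix(as.integer(accumulator != 0 | newMask != 0),
         nrow(accumulator), ncol(accumulator))
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`; defined as 1 when both masks are
#' empty.
#'
#' @param a,b 0/1 matrices of identical shape.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' dice(matrix(1, 2, 2), matrix(1, 2, 2))   # 1
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ", call. = FALSE)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Derive seed points from an ensemble mask
#'
#' The foreground seed is, by default, the mask's most interior pixel:
#' the in-mask pixel maximizing Euclidean distance to the mask complement
#' (ties broken by smallest (row, col)). This keeps the seed in the core
#' of the nodule even when the ensemble has absorbed an attached
#' structure (pleural wall, vessel) that skews the centroid toward the
#' mask boundary; `fgMethod = "centroid"` instead takes the mask
#' centroid, snapped to the nearest in-mask pixel when it falls outside.
#' For convex, unattached masks the two rules agree.
#'
#' The background seed is the pixel maximizing Euclidean distance to the
#' mask dilated by `dilationRadius` pixels (ties broken by smallest
#' (row, col)), keeping it safely off the nodule.
#'
#' @param mask nonempty 0/1 matrix (the accumulated ensemble).
#' @param sliceIndex 0-based slice index recorded in the result.
#' @param dilationRadius dilation radius in pixels (default 5).
#' @param fgMethod `"interior"` (default) or `"centroid"`.
#' @return a [SeedSpec-class] with 0-based coordinates.
#' @examples
#' m <- matrix(0L, 9, 9); m[3:7, 3:7] <- 1L
#' fgSeed(deriveSeeds(m))   # center of the square: (4, 4)
#' @export
deriveSeeds <- function(mask, sliceIndex = 0L, dilationRadius = 5L,
                        fgMethod = c("interior", "centroid")) {
  fgMethod <- match.arg(fgMethod)
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("ensemble collapsed: empty mask", call. = FALSE)
  if (fgMethod == "interior") {
    # pad with a zero border so that outside-the-image counts as
    # complement; otherwise structures hugging the image edge (e.g. a
    # pleural band) acquire spuriously deep interiors
    nr <- nrow(mask); nc <- ncol(mask)
    padded <- matrix(0L, nr + 2L, nc + 2L)
    padded[2L:(nr + 1L), 2L:(nc + 1L)] <- as.integer(mask != 0)
    depth <- EBImage::distmap(padded)[2L:(nr + 1L), 2L:(nc + 1L)]
    deep <- which(depth == max(depth), arr.ind = TRUE)
    fg <- deep[order(deep[, 1L], deep[, 2L])[1L], ] - 1L
  } else {
    cent <- colMeans(idx) - 1
    d2 <- (idx[, 1L] - 1 - cent[1L])^2 + (idx[, 2L] - 1 - cent[2L])^2
    fg <- idx[lexicographicMin(which(d2 == min(d2)), idx), ] - 1L
  }

  m01 <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  dil <- if (dilationRadius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilationRadius) + 1L, "disc")
    m <- EBImage::dilate(m01, brush)
    matrix(as.integer(m != 0), nrow(mask), ncol(mask))
  } else m01
  if (all(dil != 0)) {
    # dilation swallowed the slice; fall back to distance from the raw mask
    dil <- m01
  }
  dist <- EBImage::distmap(1L - dil)
  far <- which(dist == max(dist), arr.ind = TRUE)
  bg <- far[order(far[, 1L], far[, 2L])[1L], ] - 1L
  SeedSpec(fg = as.numeric(fg), bg = as.numeric(bg),
           sliceIndex = as.integer(sliceIndex))
}

# Keep the connected component of `mask` containing the (0-based) fg seed;
# empty result if the seed pixel itself is background.
keepSeedComponent <- function(mask, fg) {
  at <- seedToIndex(fg, dim(mask), "foreground seed")
  if (mask[at[1L], at[2L]] == 0L)
    return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  keep <- lab[at[1L], at[2L]]
  matrix(as.integer(lab == keep), nrow(mask), ncol(mask))
}

#' Random-walker ensemble segmentation of a patient stack
#'
#' One pass applies, to every slice, the seeded random walker
#' ([solveRW()]), thresholding ([thresholdMask()]) and a connected-
#' component filter keeping the component containing the foreground seed,
#' and accumulates the per-slice masks into a cross-slice ensemble mask
#' (pixelwise OR by default). After each pass, new seed points are derived
#' from the ensemble ([deriveSeeds()]) and the pass repeats, until the
#' Dice overlap between consecutive ensembles reaches `stabilityDice` or
#' `maxPasses` passes have run. The same (fg, bg) seed pair is applied to
#' all J slices within a pass.
#'
#' @param stack an [ImageStack-class] windowed to \[0, 1\]
#'   (see [autoWindow()]).
#' @param initialSeeds a [SeedSpec-class] applied to every slice in pass 1.
#' @param beta,tol passed to [solveRW()].
#' @param threshold probability threshold in (0, 1); default 0.5.
#' @param maxPasses maximum number of passes (default 5; 2 reproduces a
#'   single seed-reselection round).
#' @param stabilityDice stop when consecutive ensembles overlap at this
#'   Dice or better (default 0.99).
#' @param integrate `"or"` (default) for pixelwise union, or `"vote"` for
#'   a cross-slice majority ensemble.
#' @param dilationRadius dilation used for background-seed derivation.
#' @param fgMethod foreground seed derivation rule, see [deriveSeeds()].
#' @return an [EnsembleResult-class]: final-pass per-slice masks, the
#'   ensemble mask, the pass count, the inter-pass Dice trace and the
#'   seeds used on each pass. Slices whose thresholded mask is empty
#'   contribute nothing (with a warning); if all slices come up empty the
#'   segmentation fails with an error.
#' @export
segmentPatient <- function(stack, initialSeeds, beta = 130, threshold = 0.5,
                           tol = 1e-8, maxPasses = 5L, stabilityDice = 0.99,
                           integrate = c("or", "vote"), dilationRadius = 5L,
                           fgMethod = c("interior", "centroid")) {
  integrate <- match.arg(integrate)
  fgMethod <- match.arg(fgMethod)
  if (maxPasses < 1L) stop("'maxPasses' must be >= 1", call. = FALSE)
  J <- nSlices(stack)
  dm <- dim(getSlice(stack, 1L))
  for (s in stack@slices) stopIfNot01(s, "stack intensities")

  seeds <- initialSeeds
  ensPrev <- NULL
  diceTrace <- numeric(0L)
  seedTrace <- list()
  masks <- NULL; ens <- NULL

  for (pass in seq_len(maxPasses)) {
    seedTrace[[pass]] <- seeds
    masks <- vector("list", J)
    acc <- matrix(0L, dm[1L], dm[2L])
    votes <- matrix(0L, dm[1L], dm[2L])
    for (j in seq_len(J)) {
      pm <- solveRW(getSlice(stack, j), seeds, beta = beta, tol = tol)
      m <- thresholdMask(pm, threshold)
      m <- keepSeedComponent(m, seeds@fg)
      if (sum(m) == 0L)
        warning(sprintf("slice %d produced an empty mask on pass %d; skipped",
                        j - 1L, pass))
      masks[[j]] <- m
      acc <- integrateMasks(acc, m)
      votes <- votes + m
    }
    if (sum(acc) == 0L)
      stop("all slices yielded empty masks; segmentation failed", call. = FALSE)
    ens <- if (integrate == "or") acc
           else matrix(as.integer(votes > J / 2), dm[1L], dm[2L])

    if (pass > 1L) {
      d <- dice(ens, ensPrev)
      diceTrace <- c(diceTrace, d)
      if (d >= stabilityDice) { ensPrev <- ens; break }
    }
    ensPrev <- ens
    if (pass < maxPasses)
      seeds <- deriveSeeds(ens, seeds@sliceIndex, dilationRadius, fgMethod)
  }

  new("EnsembleResult",
      perSliceMasks = MaskStack(masks), ensembleMask = ens,
      nPasses = length(seedTrace), diceTrace = diceTrace,
      seedTrace = seedTrace)
}
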