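#' @include AllGenerics.R
NULL

#' Construct an ImageStack
#'
#' @param slices list of numeric matrices (or a single matrix), all of the
#'   same dimension, finite values.
#' @param patientId character(1) patient identifier.
#' @param pixelSpacing numeric(2) (row, col) spacing in mm.
#' @param sliceIds optional character vector of slice identifiers;
#'   defaults to `"s0001"`, `"s0002"`, ...
#' @return an [ImageStack-class].
#' @examples
#' stk <- ImageStack(list(matrix(0, 4, 4)), patientId = "p1")
#' nSlices(stk)
#' @export
ImageStack <- function(slices, patientId = "patient",
                       pixelSpacing = c(1, 1), sliceIds = NULL) {
  if (is.matrix(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) {
    storage.mode(s) <- "double"
    s
  })
  if (is.null(sliceIds)) sliceIds <- sprintf("s%04d", seq_along(slices))
  new("ImageStack", patientId = as.character(patientId), slices = slices,
      pixelSpacing = as.numeric(pixelSpacing), sliceIds = as.character(sliceIds))
}

#' Construct a MaskStack
#'
#' @param slices list of 0/1 matrices (or a single matrix). Any nonzero
#'   value is coerced to 1.
#' @return a [MaskStack-class].
#' @examples
#' MaskStack(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
MaskStack <- function(slices) {
  if (is.matrix(slices)) slices <- list(slices)
  slices <- lapply(slices, function(s) {
    m <- matrix(as.integer(s != 0), nrow(s), ncol(s))
    m
  })
  new("MaskStack", slices = slices)
}

#' Construct a SeedSpec
#'
#' @param fg,bg numeric(2) 0-based (row, col) seed coordinates.
#' @param sliceIndex integer(1) 0-based slice index (default 0).
#' @return a [SeedSpec-class].
#' @examples
#' SeedSpec(fg = c(3, 3), bg = c(0, 0))
#' @export
SeedSpec <- function(fg, bg, sliceIndex = 0L) {
  new("SeedSpec", fg = as.numeric(fg), bg = as.numeric(bg),
      sliceIndex = as.integer(sliceIndex))
}

#' @describeIn ImageStack-class patient identifier
#' @param x an object
#' @export
setMethod("patientId", "ImageStack", function(x) x@patientId)

#' @describeIn ImageStack-class number of slices J
#' @export
setMethod("nSlices", "ImageStack", function(x) length(x@slices))

#' @describeIn MaskStack-class number of slices
#' @export
setMethod("nSlices", "MaskStack", function(x) length(x@slices))

#' @describeIn ImageStack-class extract slice `i` (1-based list index)
#' @param i slice number, 1-based
#' @export
setMethod("getSlice", "ImageStack", function(x, i) x@slices[[i]])

#' @describeIn MaskStack-class extract mask slice `i` (1-based list index)
#' @export
setMethod("getSlice", "MaskStack", function(x, i) x@slices[[i]])

#' @describeIn ImageStack-class list of all slices
#' @export
setMethod("stackSlices", "ImageStack", function(x) x@slices)

#' @describeIn MaskStack-class list of all mask slices
#' @export
setMethod("stackSlices", "MaskStack", function(x) x@slices)

#' @describeIn ImageStack-class (row, col) pixel spacing in mm
#' @export
setMethod("pixelSpacing", "ImageStack", function(x) x@pixelSpacing)

#' @describeIn ImageStack-class per-slice identifiers
#' @export
setMethod("sliceIds", "ImageStack", function(x) x@sliceIds)

#' @describeIn SeedSpec-class 0-based (row, col) foreground seed
#' @export
setMethod("fgSeed", "SeedSpec", function(x) x@fg)

#' @describeIn SeedSpec-class 0-based (row, col) background seed
#' @export
setMethod("bgSeed", "SeedSpec", function(x) x@bg)

#' @describeIn ProbabilityMap-class matrix of foreground probabilities
#' @export
setMethod("probValues", "ProbabilityMap", function(x) x@values)

#' @describeIn FeatureTable-class patients x 38 feature matrix
#' @export
setMethod("featureValues", "FeatureTable", function(x) x@values)

#' @describeIn FeatureTable-class `"rwe"` or `"ground_truth"`
#' @export
setMethod("provenance", "FeatureTable", function(x) x@provenance)

#' @describeIn EnsembleResult-class number of segmentation passes run
#' @export
setMethod("nPasses", "EnsembleResult", function(x) x@nPasses)

#' @describeIn EnsembleResult-class Dice between consecutive pass ensembles
#' @export
setMethod("diceTrace", "EnsembleResult", function(x) x@diceTrace)

#' @describeIn EnsembleResult-class accumulated cross-slice ensemble mask
#' @export
setMethod("ensembleMask", "EnsembleResult", function(x) x@ensembleMask)

#' @describeIn EnsembleResult-class final-pass per-slice MaskStack
#' @export
setMethod("perSliceMasks", "EnsembleResult", function(x) x@perSliceMasks)

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf("ImageStack '%s': %d slice(s) of %d x %d, spacing (%g, %g) mm\n",
              object@patientId, length(object@slices), d[1L], d[2L],
              object@pixelSpacing[1L], object@pixelSpacing[2L]))
  rng <- range(unlist(lapply(object@slices, range)))
  cat(sprintf("  intensity range: [%g, %g]\n", rng[1L], rng[2L]))
})

setMethod("show", "MaskStack", function(object) {
  d <- dim(object@slices[[1L]])
  cat(sprintf("MaskStack: %d slice(s) of %d x %d, foreground pixels per slice: %s\n",
              length(object@slices), d[1L], d[2L],
              paste(vapply(object@slices, sum, numeric(1L)), collapse = ", ")))
})

setMethod("show", "SeedSpec", function(object) {
  cat(sprintf("SeedSpec: fg=(%g, %g), bg=(%g, %g) on slice %d [0-based]\n",
              object@fg[1L], object@fg[2L], object@bg[1L], object@bg[2L],
              object@sliceIndex))
})

setMethod("show", "ProbabilityMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("ProbabilityMap: %d x %d, mean p = %.4f\n",
              d[1L], d[2L], mean(object@values)))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec '%s': %s nodule, r=%g px, %d slice(s) of %d x %d, noise sd %g HU, seed %d\n",
              object@patientId, object@noduleClass, object@noduleRadius,
              object@nSlices, object@grid[1L], object@grid[2L],
              object@noiseSd, object@rngSeed))
})

setMethod("show", "PhantomCase", function(object) {
  cat("PhantomCase:\n  ")
  show(object@spec)
  cat("  ")
  show(object@seeds)
})

setMethod("show", "CoocMatrix", function(object) {
  cat(sprintf("CoocMatrix: %d grey levels, mu=%.4f, sigma2=%.4f\n",
              object@levels, object@mu, object@sigma2))
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix: %d grey levels, max run length %d, %g runs over %d pixels\n",
              nrow(object@R), object@Nr, object@RTotal, object@nPixels))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable [%s]: %d patient(s) x %d features\n",
              object@provenance, nrow(object@values), ncol(object@values)))
})

setMethod("show", "EnsembleResult", function(object) {
  cat(sprintf("EnsembleResult: %d pass(es), ensemble mask %d px; dice trace: %s\n",
              object@nPasses, sum(object@ensembleMask),
              if (length(object@diceTrace)) paste(sprintf("%.4f", object@diceTrace), collapse = ", ") else "(single pass)"))
})
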