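#' @import methods
NULL

#' ImageStack: an ordered stack of CT slices for one patient
#'
#' Container for the J two-dimensional intensity rasters of one patient,
#' together with in-plane pixel spacing and per-slice identifiers.
#' Intensities are Hounsfield units (HU) for raw CT data, or dimensionless
#' values in \[0, 1\] after [autoWindow()].
#'
#' All pixel coordinates exposed by this package are 0-based `(row, col)`
#' pairs in row-major raster order; slices are indexed `0..J-1`.
#'
#' @slot patientId character(1), patient identifier.
#' @slot slices list of numeric matrices, all of identical dimension.
#' @slot pixelSpacing numeric(2), (row, col) spacing in millimetres.
#' @slot sliceIds character vector of per-slice identifiers.
#'
#' @seealso [ImageStack()] for the constructor, [MaskStack-class].
#' @name ImageStack-class
#' @aliases ImageStack-class
#' @exportClass ImageStack
setClass("ImageStack",
  slots = c(
    patientId = "character",
    slices = "list",
    pixelSpacing = "numeric",
    sliceIds = "character"
  )
)

setValidity("ImageStack", function(object) {
  if (length(object@slices) < 1L) return("'slices' must contain at least one slice")
  if (!all(vapply(object@slices, is.matrix, logical(1L))))
    return("every slice must be a numeric matrix")
  dims <- vapply(object@slices, dim, integer(2L))
  if (length(object@slices) > 1L && any(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L]))
    return("all slices must have identical dimensions")
  if (!all(vapply(object@slices, function(s) all(is.finite(s)), logical(1L))))
    return("all slice intensities must be finite")
  if (length(object@pixelSpacing) != 2L || any(!is.finite(object@pixelSpacing)) ||
      any(object@pixelSpacing <= 0))
    return("'pixelSpacing' must be two positive values (row, col)")
  if (length(object@sliceIds) != length(object@slices))
    return("'sliceIds' must have one entry per slice")
  TRUE
})

#' MaskStack: binary segmentations aligned to an ImageStack
#'
#' Ordered list of binary (0/1 integer) rasters, one per slice of a
#' companion [ImageStack-class].
#'
#' @slot slices list of 0/1 integer matrices of identical dimension.
#'
#' @seealso [MaskStack()], [dice()], [convexity()].
#' @name MaskStack-class
#' @aliases MaskStack-class
#' @exportClass MaskStack
setClass("MaskStack", slots = c(slices = "list"))

setValidity("MaskStack", function(object) {
  if (length(object@slices) < 1L) return("'slices' must contain at least one slice")
  if (!all(vapply(object@slices, is.matrix, logical(1L))))
    return("every mask slice must be a matrix")
  dims <- vapply(object@slices, dim, integer(2L))
  if (length(object@slices) > 1L && any(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L]))
    return("all mask slices must have identical dimensions")
  ok <- vapply(object@slices, function(s) all(s %in% c(0L, 1L)), logical(1L))
  if (!all(ok)) return("mask values must be 0 or 1")
  TRUE
})

#' SeedSpec: foreground/background seed points for the random walker
#'
#' Seed coordinates are 0-based `(row, col)` pairs; `sliceIndex` is the
#' 0-based slice on which the pair was derived (the same pair is applied
#' to every slice of a stack during a segmentation pass).
#'
#' @slot fg numeric(2), foreground seed `(row, col)`.
#' @slot bg numeric(2), background seed `(row, col)`.
#' @slot sliceIndex integer(1), 0-based slice index.
#'
#' @seealso [SeedSpec()], [solveRW()], [deriveSeeds()].
#' @name SeedSpec-class
#' @aliases SeedSpec-class
#' @exportClass SeedSpec
setClass("SeedSpec",
  slots = c(fg = "numeric", bg = "numeric", sliceIndex = "integer"))

setValidity("SeedSpec", function(object) {
  if (length(object@fg) != 2L || length(object@bg) != 2L)
    return("'fg' and 'bg' must be (row, col) pairs")
  if (any(!is.finite(c(object@fg, object@bg)))) return("seed coordinates must be finite")
  if (any(c(object@fg, object@bg) < 0)) return("seed coordinates must be >= 0 (0-based)")
  if (all(object@fg == object@bg)) return("foreground and background seeds must differ")
  if (length(object@sliceIndex) != 1L || object@sliceIndex < 0L)
    return("'sliceIndex' must be a single non-negative integer")
  TRUE
})

#' ProbabilityMap: per-pixel foreground probabilities from the random walker
#'
#' The harmonic solution of the seeded Dirichlet problem on the pixel
#' lattice: 1 at the foreground seed, 0 at the background seed, values in
#' \[0, 1\] elsewhere.
#'
#' @slot values numeric matrix of foreground probabilities.
#' @slot seeds the [SeedSpec-class] that anchored the solution.
#'
#' @seealso [solveRW()], [thresholdMask()].
#' @name ProbabilityMap-class
#' @aliases ProbabilityMap-class
#' @exportClass ProbabilityMap
setClass("ProbabilityMap", slots = c(values = "matrix", seeds = "SeedSpec"))

setValidity("ProbabilityMap", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("probabilities must be finite")
  if (any(v < -1e-9 | v > 1 + 1e-9)) return("probabilities must lie in [0, 1]")
  fg <- object@seeds@fg + 1; bg <- object@seeds@bg + 1
  if (abs(v[fg[1L], fg[2L]] - 1) > 1e-9) return("foreground seed must have probability 1")
  if (abs(v[bg[1L], bg[2L]]) > 1e-9) return("background seed must have probability 0")
  TRUE
})

#' PhantomSpec: parameters of one synthetic CT nodule phantom
#'
#' Describes a synthetic patient: a hyperintense spherical nodule in a
#' low-intensity lung field, optionally attached to a vessel-like cylinder
#' (`juxta_vascular`) or abutting a bright pleural band at the image edge
#' (`juxta_pleural`), plus i.i.d. Gaussian noise. Intensities are in HU.
#'
#' @slot patientId character(1).
#' @slot noduleClass one of `"solid"`, `"juxta_vascular"`, `"juxta_pleural"`.
#' @slot grid integer(2), (rows, cols) of each slice.
#' @slot nSlices integer(1), number of slices J.
#' @slot noduleRadius numeric(1), sphere radius in pixels.
#' @slot noduleIntensity,lungIntensity,wallIntensity,vesselIntensity numeric(1), HU.
#' @slot vesselRadius numeric(1), vessel cylinder radius in pixels.
#' @slot noiseSd numeric(1), Gaussian noise standard deviation in HU.
#' @slot lobulation integer(1), number of surface bumps (radius r/3) giving
#'   the nodule a lobulated outline; 0 = pure sphere.
#' @slot rngSeed integer(1), seed controlling all randomness of the case.
#'
#' @seealso [PhantomSpec()], [generatePhantom()], [generateCohort()].
#' @name PhantomSpec-class
#' @aliases PhantomSpec-class
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  slots = c(
    patientId = "character",
    noduleClass = "character",
    grid = "integer",
    nSlices = "integer",
    noduleRadius = "numeric",
    noduleIntensity = "numeric",
    lungIntensity = "numeric",
    wallIntensity = "numeric",
    vesselIntensity = "numeric",
    vesselRadius = "numeric",
    noiseSd = "numeric",
    lobulation = "integer",
    rngSeed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  if (!object@noduleClass %in% c("solid", "juxta_vascular", "juxta_pleural"))
    return("'noduleClass' must be one of solid, juxta_vascular, juxta_pleural")
  if (length(object@grid) != 2L || any(object@grid < 32L))
    return("'grid' must be (rows, cols) with both >= 32")
  if (object@nSlices < 1L) return("'nSlices' must be >= 1")
  if (object@noduleRadius < 2) return("'noduleRadius' must be >= 2")
  if (2 * object@noduleRadius + 4 > min(object@grid))
    return("'noduleRadius' too large: nodule must fit inside grid")
  if (object@noiseSd < 0) return("'noiseSd' must be >= 0")
  if (object@lobulation < 0L) return("'lobulation' must be >= 0")
  if (object@vesselRadius < 1) return("'vesselRadius' must be >= 1")
  TRUE
})

#' PhantomCase: a generated phantom with its analytic ground truth
#'
#' @slot stack the synthetic [ImageStack-class].
#' @slot truth the analytic nodule-only [MaskStack-class] (vessel and
#'   pleural wall excluded).
#' @slot seeds initial [SeedSpec-class]: foreground at the truth centroid
#'   of the middle slice, background at the lung-field pixel farthest from
#'   the nodule.
#' @slot spec the generating [PhantomSpec-class].
#'
#' @seealso [generatePhantom()].
#' @name PhantomCase-class
#' @aliases PhantomCase-class
#' @exportClass PhantomCase
setClass("PhantomCase",
  slots = c(stack = "ImageStack", truth = "MaskStack",
            seeds = "SeedSpec", spec = "PhantomSpec"))

setValidity("PhantomCase", function(object) {
  if (length(object@stack@slices) != length(object@truth@slices))
    return("truth mask must be aligned slice-for-slice with the stack")
  if (any(vapply(object@truth@slices, sum, numeric(1L)) < 1))
    return("every truth slice must contain at least one foreground pixel")
  TRUE
})

#' CoocMatrix: a normalized, symmetric grey-level co-occurrence matrix
#'
#' Holds the normalized GLCM `f` (summing to 1) accumulated over the
#' configured offsets, plus its derived marginals: the marginal mean
#' \eqn{\mu} and variance \eqn{\sigma^2}, and the sum/difference
#' distributions `fSum(k)` (k = 2..2N) and `fDiff(k)` (k = 0..N-1).
#'
#' @slot f N x N numeric matrix, symmetric, nonnegative, sums to 1.
#' @slot mu,sigma2 numeric(1), marginal mean and variance of `f`.
#' @slot fSum named numeric, sum distribution over k = 2..2N.
#' @slot fDiff named numeric, absolute-difference distribution over k = 0..N-1.
#' @slot levels integer(1), the number of grey levels N.
#'
#' @seealso [buildGLCM()], [glcmFeatures()].
#' @name CoocMatrix-class
#' @aliases CoocMatrix-class
#' @exportClass CoocMatrix
setClass("CoocMatrix",
  slots = c(f = "matrix", mu = "numeric", sigma2 = "numeric",
            fSum = "numeric", fDiff = "numeric", levels = "integer"))

setValidity("CoocMatrix", function(object) {
  if (abs(sum(object@f) - 1) > 1e-8) return("'f' must sum to 1")
  if (any(object@f < 0)) return("'f' must be nonnegative")
  if (max(abs(object@f - t(object@f))) > 1e-12) return("'f' must be symmetric")
  if (abs(sum(object@fSum) - 1) > 1e-8) return("'fSum' must sum to 1")
  if (abs(sum(object@fDiff) - 1) > 1e-8) return("'fDiff' must sum to 1")
  if (nrow(object@f) != object@levels) return("'f' must be N x N")
  TRUE
})

#' RunLengthMatrix: grey-level run length counts and probabilities
#'
#' Run counts `R(x, y)` for grey level x (1..N) and run length y (1..Nr),
#' accumulated over the configured direction set, with the normalized
#' matrix `p = R / RTotal`.
#'
#' @slot R N x Nr numeric matrix of run counts.
#' @slot p N x Nr numeric matrix, `R` normalized by the total run count.
#' @slot RTotal numeric(1), total number of runs.
#' @slot Nr integer(1), maximum run length observed.
#' @slot nPixels integer(1), number of ROI pixels.
#'
#' @seealso [buildGLRLM()], [glrlmFeatures()].
#' @name RunLengthMatrix-class
#' @aliases RunLengthMatrix-class
#' @exportClass RunLengthMatrix
setClass("RunLengthMatrix",
  slots = c(R = "matrix", p = "matrix", RTotal = "numeric",
            Nr = "integer", nPixels = "integer"))

setValidity("RunLengthMatrix", function(object) {
  if (object@RTotal <= 0) return("'RTotal' must be positive")
  if (abs(sum(object@p) - 1) > 1e-8) return("'p' must sum to 1")
  if (any(object@R < 0)) return("'R' must be nonnegative")
  TRUE
})

#' QuantizedROI: grey-level-quantized region of interest
#'
#' In-mask pixel intensities mapped to integer grey levels 1..N with the
#' raster layout preserved (out-of-mask pixels are NA), as input to GLCM
#' and GLRLM construction.
#'
#' @slot levels integer(1), grey-level count N.
#' @slot values integer matrix with levels 1..N in-mask and NA elsewhere.
#' @slot nPixels integer(1), in-mask pixel count.
#'
#' @seealso [quantizeROI()].
#' @name QuantizedROI-class
#' @aliases QuantizedROI-class
#' @exportClass QuantizedROI
setClass("QuantizedROI",
  slots = c(levels = "integer", values = "matrix", nPixels = "integer"))

setValidity("QuantizedROI", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) < 1L) return("ROI must contain at least one pixel")
  if (any(v < 1L | v > object@levels)) return("quantized values must lie in 1..levels")
  if (object@nPixels != length(v)) return("'nPixels' must equal the in-mask count")
  TRUE
})

#' FeatureTable: patients x 38 canonical radiomic features
#'
#' A numeric matrix with one row per patient (rownames are patient ids)
#' and the 38 canonical feature columns in fixed order (19 GLCM-family,
#' 7 GLRLM-family, 12 histogram-family; see [canonicalFeatureNames()]).
#'
#' @slot values numeric matrix, patients x 38, finite.
#' @slot provenance character(1), `"rwe"` or `"ground_truth"`.
#'
#' @seealso [extractPatientFeatures()], [concordanceTable()].
#' @name FeatureTable-class
#' @aliases FeatureTable-class
#' @exportClass FeatureTable
setClass("FeatureTable",
  slots = c(values = "matrix", provenance = "character"))

setValidity("FeatureTable", function(object) {
  v <- object@values
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    return("patient ids (rownames) must be present and unique")
  if (!identical(colnames(v), canonicalFeatureNames()))
    return("columns must be the 38 canonical feature names in canonical order")
  if (any(!is.finite(v))) return("all feature values must be finite")
  if (!object@provenance %in% c("rwe", "ground_truth"))
    return("'provenance' must be \"rwe\" or \"ground_truth\"")
  TRUE
})

#' EnsembleResult: output of the random-walker ensemble segmentation
#'
#' @slot perSliceMasks final-pass per-slice [MaskStack-class].
#' @slot ensembleMask 2-D binary matrix, the accumulated cross-slice
#'   ensemble of the final pass.
#' @slot nPasses integer(1), number of passes executed.
#' @slot diceTrace numeric, Dice between consecutive pass ensembles
#'   (length `nPasses - 1`).
#' @slot seedTrace list of the [SeedSpec-class] used on each pass.
#'
#' @seealso [segmentPatient()].
#' @name EnsembleResult-class
#' @aliases EnsembleResult-class
#' @exportClass EnsembleResult
setClass("EnsembleResult",
  slots = c(perSliceMasks = "MaskStack", ensembleMask = "matrix",
            nPasses = "integer", diceTrace = "numeric", seedTrace = "list"))

setValidity("EnsembleResult", function(object) {
  if (object@nPasses < 1L) return("'nPasses' must be >= 1")
  if (length(object@diceTrace) != object@nPasses - 1L)
    return("'diceTrace' must have one entry per pass transition")
  TRUE
})
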