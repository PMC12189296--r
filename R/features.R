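#' @include glcm.R glrlm.R intensity.R image_io.R
NULL

#' Extract the 38 canonical radiomic features for one patient
#'
#' GLCM and GLRLM texture features are computed per slice on the
#' grey-level-quantized in-mask region and averaged over the slices that
#' contain the nodule; convexity is the mean per-slice solidity of the
#' masks; the 12 histogram features are computed on the in-mask
#' intensities pooled over all slices. By default features are computed on
#' the raw stack intensities (`useRawHu = TRUE`); set it to FALSE to
#' compute on percentile-windowed values (see [autoWindow()]) instead.
#' Windowed values saturate at the clipping percentile, which degenerates
#' the pooled intensity maximum, so raw intensities are the default.
#'
#' Slices with an empty mask, or whose ROI is a single pixel (no
#' co-occurring pairs), are skipped with a warning; if no usable slice
#' remains the extraction fails.
#'
#' @param stack an [ImageStack-class].
#' @param masks a [MaskStack-class] aligned to `stack` (segmentation
#'   output or ground truth).
#' @param levels grey-level count for quantization (default 64).
#' @param dialect `"corrected"` or `"printed"` feature formulas.
#' @param histBins histogram bin count for the intensity entropy.
#' @param useRawHu if TRUE, skip windowing and use raw intensities.
#' @param pLow,pHigh windowing percentiles when `useRawHu = FALSE`.
#' @param offsets,distance GLCM/GLRLM direction set and pair distance.
#' @return named numeric(38) in canonical order.
#' @seealso [canonicalFeatureNames()], [extractCohortFeatures()]
#' @export
extractPatientFeatures <- function(stack, masks, levels = 64L,
                                   dialect = c("corrected", "printed"),
                                   histBins = 64L, useRawHu = TRUE,
                                   pLow = 1, pHigh = 99,
                                   offsets = c(0, 45, 90, 135), distance = 1L) {
  dialect <- match.arg(dialect)
  if (nSlices(stack) != nSlices(masks))
    stop("stack and masks have different slice counts", call. = FALSE)
  work <- if (useRawHu) stack else autoWindow(stack, pLow, pHigh)

  glcmRows <- list(); glrlmRows <- list()
  pooled <- numeric(0L)
  for (j in seq_len(nSlices(stack))) {
    m <- getSlice(masks, j)
    if (sum(m) == 0L) {
      warning(sprintf("slice %d mask is empty; skipped", j - 1L))
      next
    }
    s <- getSlice(work, j)
    pooled <- c(pooled, s[m != 0])
    if (sum(m) < 2L) {
      warning(sprintf("slice %d ROI is a single pixel; no texture pairs", j - 1L))
      next
    }
    q <- quantizeROI(s, m, levels)
    glcmRows[[length(glcmRows) + 1L]] <-
      glcmFeatures(buildGLCM(q, offsets = offsets, distance = distance), dialect)
    glrlmRows[[length(glrlmRows) + 1L]] <-
      glrlmFeatures(buildGLRLM(q, directions = offsets), dialect)
  }
  if (length(glcmRows) == 0L)
    stop("no usable slices: all masks empty or single-pixel", call. = FALSE)

  glcmMean <- colMeans(do.call(rbind, glcmRows))
  glrlmMean <- colMeans(do.call(rbind, glrlmRows))
  conv <- convexity(masks)
  histFeat <- histogramFeatures(pooled, bins = histBins)

  out <- c(glcmMean, gcm_conv = conv, glrlmMean, histFeat)
  out[canonicalFeatureNames()]
}

#' Extract a cohort FeatureTable
#'
#' Applies [extractPatientFeatures()] to each patient and assembles a
#' [FeatureTable-class].
#'
#' @param stacks list of [ImageStack-class] objects.
#' @param maskList list of [MaskStack-class] objects aligned to `stacks`.
#' @param provenance `"rwe"` or `"ground_truth"`.
#' @param ... passed to [extractPatientFeatures()].
#' @return a [FeatureTable-class] with one row per patient.
#' @export
extractCohortFeatures <- function(stacks, maskList,
                                  provenance = c("rwe", "ground_truth"), ...) {
  provenance <- match.arg(provenance)
  if (length(stacks) != length(maskList))
    stop("'stacks' and 'maskList' must have equal length", call. = FALSE)
  rows <- lapply(seq_along(stacks), function(i)
    extractPatientFeatures(stacks[[i]], maskList[[i]], ...))
  m <- do.call(rbind, rows)
  rownames(m) <- vapply(stacks, patientId, character(1L))
  FeatureTable(m, provenance = provenance)
}
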