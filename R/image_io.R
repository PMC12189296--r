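#' @include AllClasses.R accessors.R utils.R
NULL

# Stacks are serialized as 16-bit unsigned multi-page TIFF with a fixed
# +32768 offset, lossless for integer HU in [-32768, 32767].
.TIFF_OFFSET <- 32768

#' Write an ImageStack to a multi-page TIFF
#'
#' Intensities are stored as 16-bit unsigned samples with a fixed +32768
#' offset; the round trip through [readStack()] is the identity for
#' integer-valued stacks (CT HU are integers).
#'
#' @param stack an [ImageStack-class] with integer-valued intensities in
#'   \[-32768, 32767\].
#' @param path output file path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @seealso [readStack()]
#' @export
writeStack <- function(stack, path) {
  vals <- unlist(lapply(stack@slices, as.numeric))
  if (any(vals != round(vals)))
    stop("writeStack() stores integer intensities; round the stack first",
         call. = FALSE)
  if (any(vals < -.TIFF_OFFSET | vals > .TIFF_OFFSET - 1))
    stop("intensities outside the representable range [-32768, 32767]",
         call. = FALSE)
  pages <- lapply(stack@slices, function(s) (s + .TIFF_OFFSET) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

#' Read an ImageStack from a multi-page TIFF
#'
#' @param path a multi-page TIFF written by [writeStack()].
#' @param patientId patient identifier to attach (default: file stem).
#' @return an [ImageStack-class]; a single-page TIFF yields J = 1.
#' @seealso [writeStack()]
#' @export
readStack <- function(path, patientId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(patientId)) patientId <- sub("\\.[^.]*$", "", basename(path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2L))
  if (length(pages) > 1L && any(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L]))
    stop("inconsistent slice shapes in ", path, call. = FALSE)
  slices <- lapply(pages, function(p) {
    m <- matrix(as.numeric(p), nrow(p), ncol(p))
    m - .TIFF_OFFSET
  })
  ImageStack(slices, patientId = patientId)
}

#' Write a MaskStack as per-slice 8-bit PNG files
#'
#' Foreground is written as 255, background as 0. Files are named
#' `mask_0001.png`, `mask_0002.png`, ... in slice order.
#'
#' @param masks a [MaskStack-class].
#' @param dir output directory (created if absent).
#' @return character vector of file paths, invisibly.
#' @seealso [readMaskStack()]
#' @export
writeMaskStack <- function(masks, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, sprintf("mask_%04d.png", seq_along(masks@slices)))
  for (i in seq_along(masks@slices))
    png::writePNG(masks@slices[[i]] + 0, paths[i])   # 0/1 -> 8-bit 0/255
  invisible(paths)
}

#' Read a MaskStack from a directory of PNG files
#'
#' PNGs are read in lexicographic filename order; any nonzero pixel value
#' (e.g. 255 in a 0/255 mask) reads as foreground 1.
#'
#' @param dir directory containing one PNG per slice.
#' @return a [MaskStack-class].
#' @seealso [writeMaskStack()]
#' @export
readMaskStack <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) < 1L) stop("no PNG mask files in ", dir, call. = FALSE)
  slices <- lapply(files, function(f) {
    p <- png::readPNG(f)
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    matrix(as.integer(p != 0), nrow(p), ncol(p))
  })
  MaskStack(slices)
}

#' Percentile auto-windowing of a CT stack
#'
#' Clips intensities to the `[pLow, pHigh]` percentiles computed over the
#' whole stack, then rescales linearly to \[0, 1\]. This is a robust,
#' reproducible analog of an interactive auto-contrast adjustment, and is
#' the normalization expected by [solveRW()]. The mapping is monotone
#' non-decreasing.
#'
#' @param stack an [ImageStack-class].
#' @param pLow,pHigh percentiles, `0 <= pLow < pHigh <= 100`
#'   (defaults 1 and 99).
#' @return an [ImageStack-class] with values in \[0, 1\]. A constant stack
#'   maps to all zeros with a warning.
#' @examples
#' stk <- ImageStack(matrix(0:99, 10, 10))
#' range(getSlice(autoWindow(stk, 0, 100), 1))
#' @export
autoWindow <- function(stack, pLow = 1, pHigh = 99) {
  if (!(pLow >= 0 && pHigh <= 100 && pLow < pHigh))
    stop("need 0 <= pLow < pHigh <= 100", call. = FALSE)
  vals <- unlist(stack@slices)
  qs <- stats::quantile(vals, c(pLow, pHigh) / 100, names = FALSE)
  if (qs[2L] <= qs[1L]) {
    warning("constant stack: auto-window maps all intensities to 0")
    slices <- lapply(stack@slices, function(s) s * 0)
  } else {
    slices <- lapply(stack@slices, function(s)
      pmin(pmax((s - qs[1L]) / (qs[2L] - qs[1L]), 0), 1))
  }
  new("ImageStack", patientId = stack@patientId, slices = slices,
      pixelSpacing = stack@pixelSpacing, sliceIds = stack@sliceIds)
}

#' Write a FeatureTable to CSV
#'
#' Columns are `patient_id` followed by the 38 canonical feature names in
#' canonical order; UTF-8, header row, `.` decimal separator.
#'
#' @param table a [FeatureTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @seealso [readFeatureTable()]
#' @export
writeFeatureTable <- function(table, path) {
  df <- data.frame(patient_id = rownames(table@values),
                   table@values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a FeatureTable from CSV
#'
#' The CSV must contain a `patient_id` column plus exactly the 38
#' canonical feature columns; a missing canonical column or an unknown
#' column is an error naming the column. Row order is preserved.
#'
#' @param path CSV path.
#' @param provenance `"rwe"` or `"ground_truth"` tag to attach.
#' @return a [FeatureTable-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, provenance = c("rwe", "ground_truth")) {
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  canonical <- canonicalFeatureNames()
  missing <- setdiff(c("patient_id", canonical), names(df))
  if (length(missing))
    stop("missing canonical column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(names(df), c("patient_id", canonical))
  if (length(unknown))
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, canonical, drop = FALSE])
  rownames(m) <- as.character(df$patient_id)
  new("FeatureTable", values = m, provenance = provenance)
}

#' Construct a FeatureTable from a patients x features matrix
#'
#' @param values numeric matrix with patient-id rownames and the 38
#'   canonical feature columns (any order; reordered canonically).
#' @param provenance `"rwe"` or `"ground_truth"`.
#' @return a [FeatureTable-class].
#' @export
FeatureTable <- function(values, provenance = c("rwe", "ground_truth")) {
  provenance <- match.arg(provenance)
  canonical <- canonicalFeatureNames()
  missing <- setdiff(canonical, colnames(values))
  if (length(missing))
    stop("missing canonical feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  new("FeatureTable", values = values[, canonical, drop = FALSE],
      provenance = provenance)
}
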