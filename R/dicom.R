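#' @include AllClasses.R accessors.R
NULL

# Minimal DICOM reader: uncompressed little-endian files (explicit or
# implicit VR), single-frame CT slices. Only the tags the pipeline needs
# are decoded; sequences with undefined length are not supported.

.dcmU16 <- function(raw, at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
.dcmU32 <- function(raw, at) {
  as.numeric(raw[at]) + 256 * as.numeric(raw[at + 1L]) +
    65536 * as.numeric(raw[at + 2L]) + 16777216 * as.numeric(raw[at + 3L])
}
.dcmStr <- function(raw) {
  # strip trailing padding (null or space) before decoding
  while (length(raw) && raw[length(raw)] %in% as.raw(c(0L, 32L)))
    raw <- raw[-length(raw)]
  rawToChar(raw)
}

.LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# Parse one DICOM file into a tag list. Stops at unsupported encodings.
parseDicomFile <- function(path) {
  n <- file.size(path)
  raw <- readBin(path, "raw", n = n)
  if (n < 140 || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path, call. = FALSE)

  pos <- 133L
  explicit <- TRUE          # file meta group is always explicit VR LE
  transfer <- "1.2.840.10008.1.2.1"
  out <- list()
  bitsAllocated <- 16L; pixelRep <- 0L; rows <- NA_integer_; cols <- NA_integer_

  while (pos + 7L <= n) {
    group <- .dcmU16(raw, pos); elem <- .dcmU16(raw, pos + 2L)
    if (group != 2L && explicit && transfer == "1.2.840.10008.1.2")
      explicit <- FALSE     # leave meta group: switch to implicit VR
    if (explicit) {
      vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
      if (vr %in% .LONG_VRS) {
        len <- .dcmU32(raw, pos + 8L); hdr <- 12L
      } else {
        len <- .dcmU16(raw, pos + 6L); hdr <- 8L
      }
    } else {
      len <- .dcmU32(raw, pos + 4L); hdr <- 8L; vr <- NA_character_
    }
    if (len == 4294967295) stop("undefined-length elements unsupported: ", path,
                                call. = FALSE)
    valAt <- pos + hdr
    val <- if (len > 0) raw[valAt:(valAt + len - 1L)] else raw[0L]
    tag <- sprintf("%04x,%04x", group, elem)

    if (tag == "0002,0010") transfer <- .dcmStr(val)
    else if (tag == "0020,000e") out$seriesUID <- .dcmStr(val)
    else if (tag == "0020,0013") out$instanceNumber <- as.integer(.dcmStr(val))
    else if (tag == "0020,0032")
      out$position <- as.numeric(strsplit(.dcmStr(val), "\\\\")[[1L]])
    else if (tag == "0028,0030")
      out$pixelSpacing <- as.numeric(strsplit(.dcmStr(val), "\\\\")[[1L]])
    else if (tag == "0028,0010") rows <- .dcmU16(val, 1L)
    else if (tag == "0028,0011") cols <- .dcmU16(val, 1L)
    else if (tag == "0028,0100") bitsAllocated <- .dcmU16(val, 1L)
    else if (tag == "0028,0103") pixelRep <- .dcmU16(val, 1L)
    else if (tag == "0028,1052") out$rescaleIntercept <- as.numeric(.dcmStr(val))
    else if (tag == "0028,1053") out$rescaleSlope <- as.numeric(.dcmStr(val))
    else if (tag == "7fe0,0010") {
      if (!transfer %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1"))
        stop("unsupported transfer syntax '", transfer, "' in ", path,
             call. = FALSE)
      if (is.na(rows) || is.na(cols))
        stop("pixel data precedes Rows/Columns in ", path, call. = FALSE)
      if (!bitsAllocated %in% c(8L, 16L))
        stop("unsupported BitsAllocated ", bitsAllocated, " in ", path,
             call. = FALSE)
      sz <- bitsAllocated %/% 8L
      px <- readBin(val, "integer", n = rows * cols, size = sz,
                    signed = pixelRep == 1L, endian = "little")
      out$pixels <- matrix(px, nrow = rows, ncol = cols, byrow = TRUE)
    }
    pos <- valAt + len
  }
  if (is.null(out$pixels)) stop("no pixel data found in ", path, call. = FALSE)
  out$file <- path
  out
}

#' Read a DICOM series as an ImageStack
#'
#' Reads every `.dcm` file (or, failing that, every file) in `directory`,
#' checks that all belong to one series, orders slices by the z component
#' of the image position tag (falling back to instance number), and maps
#' stored values to Hounsfield units via the affine rescale
#' `HU = slope * stored + intercept`. If the rescale tags are absent,
#' slope 1 / intercept 0 are assumed with a warning.
#'
#' Only uncompressed little-endian files (explicit or implicit VR) are
#' supported.
#'
#' @param directory directory holding the files of one DICOM series.
#' @return an [ImageStack-class] in HU, with pixel spacing read from the
#'   pixel-spacing tag (1 mm assumed, with a warning, if absent).
#' @export
readDicomSeries <- function(directory) {
  files <- list.files(directory, pattern = "\\.dcm$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0L) files <- list.files(directory, full.names = TRUE)
  if (length(files) == 0L)
    stop("no DICOM files found in ", directory, call. = FALSE)
  parsed <- lapply(files, parseDicomFile)

  uids <- unique(vapply(parsed, function(p)
    if (is.null(p$seriesUID)) NA_character_ else p$seriesUID, character(1L)))
  uids <- uids[!is.na(uids)]
  if (length(uids) > 1L)
    stop("directory contains multiple series UIDs: ",
         paste(uids, collapse = " and "), call. = FALSE)

  zs <- vapply(parsed, function(p)
    if (!is.null(p$position) && length(p$position) >= 3L) p$position[3L]
    else NA_real_, numeric(1L))
  ord <- if (all(!is.na(zs))) order(zs)
         else order(vapply(parsed, function(p)
           if (is.null(p$instanceNumber)) NA_integer_ else p$instanceNumber,
           integer(1L)))
  parsed <- parsed[ord]

  slices <- lapply(parsed, function(p) {
    slope <- p$rescaleSlope; icpt <- p$rescaleIntercept
    if (is.null(slope) || is.null(icpt)) {
      warning("missing rescale tags in ", basename(p$file),
              "; assuming slope 1, intercept 0")
      slope <- 1; icpt <- 0
    }
    p$pixels * slope + icpt
  })
  spacing <- parsed[[1L]]$pixelSpacing
  if (is.null(spacing) || length(spacing) != 2L) {
    warning("missing pixel-spacing tag; assuming 1 mm x 1 mm")
    spacing <- c(1, 1)
  }
  sliceIds <- vapply(parsed, function(p) basename(p$file), character(1L))
  ImageStack(slices, patientId = basename(normalizePath(directory)),
             pixelSpacing = spacing, sliceIds = sliceIds)
}
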