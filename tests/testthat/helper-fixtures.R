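# Shared fixtures. Heavyweight objects (the 20-case study cohort and its
# segmentations) are computed once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# The study cohort: the pipeline defaults (20 mixed-class patients,
# noise sd 20 HU, master seed 1).
studyPipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    .fixtures$pipeline <- suppressWarnings(runAll(quiet = TRUE))
  }
  .fixtures$pipeline
}

# Per-slice Dice of every segmented slice against the analytic truth.
studyDice <- function() {
  res <- studyPipeline()
  unlist(lapply(seq_along(res$cohort$cases), function(i)
    mapply(dice, perSliceMasks(res$segmentations[[i]])@slices,
           res$cohort$cases[[i]]@truth@slices)))
}

# A small, fast phantom for unit tests (64 x 64, 3 slices).
smallPhantom <- function(class = "solid", noiseSd = 0, seed = 7L, ...) {
  generatePhantom(PhantomSpec("small", class, grid = c(64L, 64L),
                              nSlices = 3L, noduleRadius = 8,
                              noiseSd = noiseSd, rngSeed = seed, ...))
}

# ---- minimal DICOM writer (explicit or implicit VR little endian) ---------

u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                            x %/% 65536 %% 256, x %/% 16777216 %% 256))

dcmElement <- function(group, elem, vr, value, explicit = TRUE) {
  if (vr %in% c("UI", "IS", "DS", "LO")) {
    val <- charToRaw(value)
    if (length(val) %% 2 == 1) val <- c(val, as.raw(0L))
  } else if (vr == "US") {
    val <- u16(value)
  } else {
    val <- value   # raw vector (pixel data)
  }
  hdr <- c(u16(group), u16(elem))
  if (explicit) {
    if (vr %in% c("OB", "OW")) {
      c(hdr, charToRaw(vr), as.raw(c(0, 0)), u32(length(val)), val)
    } else {
      c(hdr, charToRaw(vr), u16(length(val)), val)
    }
  } else {
    c(hdr, u32(length(val)), val)
  }
}

# Write a single-slice CT DICOM file. `pixels` is a stored-value integer
# matrix (row-major on disk).
writeTestDicom <- function(path, pixels, seriesUID = "1.2.3.4",
                           instance = 1L, zPos = 0,
                           spacing = c(0.7, 0.7),
                           slope = 1, intercept = -1024,
                           rescale = TRUE, implicit = FALSE) {
  stored <- as.integer(t(pixels))   # row-major
  px <- writeBin(stored, raw(), size = 2L, endian = "little")
  transfer <- if (implicit) "1.2.840.10008.1.2" else "1.2.840.10008.1.2.1"

  meta <- c(
    dcmElement(0x0002, 0x0010, "UI", transfer)
  )
  # meta group length element (UL), written by hand
  metaLen <- c(u16(0x0002), u16(0x0000), charToRaw("UL"), u16(4L),
               u32(length(meta)))

  body <- c(
    dcmElement(0x0020, 0x000E, "UI", seriesUID, !implicit),
    dcmElement(0x0020, 0x0013, "IS", as.character(instance), !implicit),
    dcmElement(0x0020, 0x0032, "DS",
               sprintf("0\\0\\%g", zPos), !implicit),
    dcmElement(0x0028, 0x0010, "US", nrow(pixels), !implicit),
    dcmElement(0x0028, 0x0011, "US", ncol(pixels), !implicit),
    dcmElement(0x0028, 0x0030, "DS",
               sprintf("%g\\%g", spacing[1L], spacing[2L]), !implicit),
    dcmElement(0x0028, 0x0100, "US", 16L, !implicit),
    dcmElement(0x0028, 0x0103, "US", 1L, !implicit)
  )
  if (rescale) {
    body <- c(body,
      dcmElement(0x0028, 0x1052, "DS", as.character(intercept), !implicit),
      dcmElement(0x0028, 0x1053, "DS", as.character(slope), !implicit))
  }
  body <- c(body, dcmElement(0x7FE0, 0x0010, "OW", px, !implicit))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128L), charToRaw("DICM"), metaLen, meta, body), con)
  invisible(path)
}
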