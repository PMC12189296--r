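#' @include AllClasses.R utils.R accessors.R
NULL

#' Construct a PhantomSpec
#'
#' Parameters of a synthetic CT nodule phantom. Defaults give CT-like
#' contrast: a +20 HU nodule in a -800 HU lung field with 20 HU Gaussian
#' noise, a +40 HU pleural wall and a +10 HU vessel.
#'
#' @param patientId character(1).
#' @param noduleClass `"solid"`, `"juxta_vascular"` or `"juxta_pleural"`.
#' @param grid integer(2) (rows, cols), both >= 32.
#' @param nSlices integer(1) number of slices J.
#' @param noduleRadius sphere radius in pixels (>= 2, must fit the grid).
#' @param noduleIntensity,lungIntensity,wallIntensity,vesselIntensity HU.
#' @param vesselRadius vessel cylinder radius in pixels.
#' @param noiseSd Gaussian noise standard deviation in HU (>= 0).
#' @param lobulation number of surface bumps (radius r/3) rendered on the
#'   sphere, giving a lobulated outline; 0 (default) = pure sphere.
#' @param rngSeed integer seed; all phantom randomness derives from it.
#' @return a validated [PhantomSpec-class].
#' @examples
#' PhantomSpec("P001", "solid", noiseSd = 0)
#' @export
PhantomSpec <- function(patientId = "phantom",
                        noduleClass = c("solid", "juxta_vascular", "juxta_pleural"),
                        grid = c(128L, 128L), nSlices = 5L,
                        noduleRadius = 10, noduleIntensity = 20,
                        lungIntensity = -800, wallIntensity = 40,
                        vesselIntensity = 10, vesselRadius = 3,
                        noiseSd = 20, lobulation = 0L, rngSeed = 1L) {
  noduleClass <- match.arg(noduleClass)
  obj <- try(new("PhantomSpec",
    patientId = as.character(patientId), noduleClass = noduleClass,
    grid = as.integer(grid), nSlices = as.integer(nSlices),
    noduleRadius = as.numeric(noduleRadius),
    noduleIntensity = as.numeric(noduleIntensity),
    lungIntensity = as.numeric(lungIntensity),
    wallIntensity = as.numeric(wallIntensity),
    vesselIntensity = as.numeric(vesselIntensity),
    vesselRadius = as.numeric(vesselRadius),
    noiseSd = as.numeric(noiseSd), lobulation = as.integer(lobulation),
    rngSeed = as.integer(rngSeed)),
    silent = TRUE)
  if (inherits(obj, "try-error"))
    stop("invalid PhantomSpec: ", attr(obj, "condition")$message, call. = FALSE)
  obj
}

# Width of the pleural band in pixels and how far the sphere penetrates it.
.PLEURAL_BAND_WIDTH <- 6L
.PLEURAL_OVERLAP <- 2L

# Slice z-offsets (pixel units). Spacing is chosen so that for J > 1 the
# outermost slices cut the sphere at in-plane radius r/2: dz = r*sqrt(3)/(J-1).
# Every slice therefore intersects the sphere with a comfortable margin.
phantomSliceOffsets <- function(r, J) {
  if (J == 1L) return(0)
  dz <- r * sqrt(3) / (J - 1L)
  (seq_len(J) - (J + 1) / 2) * dz
}

# Geometry shared by generation and by tests: 0-based centers.
phantomGeometry <- function(spec) {
  rows <- spec@grid[1L]; cols <- spec@grid[2L]
  r <- spec@noduleRadius
  cr <- (rows - 1) / 2
  cc <- switch(spec@noduleClass,
    solid = (cols - 1) / 2,
    juxta_vascular = (cols - 1) / 2 - spec@vesselRadius,
    juxta_pleural = (cols - .PLEURAL_BAND_WIDTH) - r + .PLEURAL_OVERLAP)
  vesselCol <- cc + r + spec@vesselRadius   # analytically tangent cylinder axis
  bandStart <- cols - .PLEURAL_BAND_WIDTH   # first 0-based column of the band
  list(center = c(cr, cc), vesselCol = vesselCol, bandStart = bandStart)
}

#' Generate a synthetic CT nodule phantom
#'
#' Renders a spherical nodule in a uniform lung field, slice by slice. A
#' pixel is foreground iff its center lies strictly inside the analytic
#' sphere; slice spacing places the outermost slices at in-plane radius
#' `noduleRadius / 2`. For `juxta_vascular` the sphere is analytically
#' tangent to a vertical vessel cylinder of similar intensity; for
#' `juxta_pleural` the sphere overlaps a bright pleural band at the right
#' image edge. The ground-truth mask is the nodule region only (vessel and
#' band excluded). Intensities are rounded to integer HU (as on CT
#' scanners) after adding i.i.d. Gaussian noise from the seeded RNG.
#'
#' The initial seeds are the truth centroid of the middle slice
#' (foreground, snapped into the mask if needed) and the lung-field pixel
#' farthest from the nodule (background).
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PhantomCase-class] with `stack`, `truth`, `seeds`, `spec`.
#' @examples
#' case <- generatePhantom(PhantomSpec("P1", "solid", noiseSd = 0))
#' sum(getSlice(case@truth, 3))   # middle-slice nodule area, ~ pi * r^2
#' @export
generatePhantom <- function(spec) {
  validObject(spec)
  rows <- spec@grid[1L]; cols <- spec@grid[2L]; J <- spec@nSlices
  r <- spec@noduleRadius
  geo <- phantomGeometry(spec)
  cr <- geo$center[1L]; cc <- geo$center[2L]
  zs <- phantomSliceOffsets(r, J)

  rowd2 <- (seq_len(rows) - 1 - cr)^2
  cold <- seq_len(cols) - 1 - cc
  inPlane2 <- outer(rowd2, cold^2, "+")      # squared in-plane distance to center

  vessel <- matrix(FALSE, rows, cols)
  band <- matrix(FALSE, rows, cols)
  if (spec@noduleClass == "juxta_vascular") {
    # finite vessel segment (half-length 3r), so the lung field stays
    # connected around it
    vcols <- abs(seq_len(cols) - 1 - geo$vesselCol) < spec@vesselRadius
    vrows <- abs(seq_len(rows) - 1 - cr) <= 3 * r
    vessel[vrows, vcols] <- TRUE
  }
  if (spec@noduleClass == "juxta_pleural") {
    band[, (geo$bandStart + 1L):cols] <- TRUE
  }

  draws <- withSeed(spec@rngSeed, {
    bumps <- if (spec@lobulation > 0L) {
      # bump centers uniformly distributed on the sphere surface
      u <- matrix(stats::rnorm(3L * spec@lobulation), ncol = 3L)
      u / sqrt(rowSums(u^2)) * r
    } else matrix(numeric(0L), 0L, 3L)
    noise <- if (spec@noiseSd > 0) {
      lapply(seq_len(J), function(k)
        matrix(stats::rnorm(rows * cols, 0, spec@noiseSd), rows, cols))
    } else rep(list(matrix(0, rows, cols)), J)
    list(bumps = bumps, noise = noise)
  })
  noise <- draws$noise
  bumps <- draws$bumps
  rb <- r / 3

  slices <- vector("list", J)
  truths <- vector("list", J)
  for (k in seq_len(J)) {
    sphere <- inPlane2 < (r^2 - zs[k]^2)
    for (b in seq_len(nrow(bumps))) {
      rb2 <- rb^2 - (zs[k] - bumps[b, 3L])^2
      if (rb2 <= 0) next
      bd2 <- outer((seq_len(rows) - 1 - cr - bumps[b, 1L])^2,
                   (seq_len(cols) - 1 - cc - bumps[b, 2L])^2, "+")
      sphere <- sphere | bd2 < rb2
    }
    img <- matrix(spec@lungIntensity, rows, cols)
    img[vessel] <- spec@vesselIntensity
    img[band] <- spec@wallIntensity
    nodule <- sphere & !band
    img[nodule] <- spec@noduleIntensity
    slices[[k]] <- round(img + noise[[k]])
    truths[[k]] <- matrix(as.integer(nodule), rows, cols)
  }

  stack <- ImageStack(slices, patientId = spec@patientId)
  truth <- MaskStack(truths)

  mid <- (J + 1L) %/% 2L                       # 1-based middle slice
  seeds <- phantomSeeds(truths[[mid]], vessel | band, mid - 1L)
  new("PhantomCase", stack = stack, truth = truth, seeds = seeds, spec = spec)
}

# fg = truth centroid snapped to the nearest in-mask pixel; bg = lung-field
# pixel farthest from the truth mask; ties broken by smallest (row, col).
phantomSeeds <- function(truthSlice, structures, sliceIndex0) {
  idx <- which(truthSlice == 1L, arr.ind = TRUE)
  cent <- colMeans(idx) - 1                    # 0-based
  d2 <- (idx[, 1L] - 1 - cent[1L])^2 + (idx[, 2L] - 1 - cent[2L])^2
  fg <- idx[lexicographicMin(which(d2 == min(d2)), idx), ] - 1L

  dist <- EBImage::distmap(1L - truthSlice)
  lungField <- truthSlice == 0L & !structures
  dist[!lungField] <- -Inf
  far <- which(dist == max(dist), arr.ind = TRUE)
  bg <- far[order(far[, 1L], far[, 2L])[1L], ] - 1L

  SeedSpec(fg = as.numeric(fg), bg = as.numeric(bg), sliceIndex = sliceIndex0)
}

lexicographicMin <- function(which, idx) {
  sub <- idx[which, , drop = FALSE]
  which[order(sub[, 1L], sub[, 2L])[1L]]
}

#' Default jitter ranges for cohort generation
#'
#' Per-patient parameter ranges emulating a heterogeneous cohort: nodule
#' radii 8-12 px, nodule intensities 5-35 HU; noise level fixed at the
#' template's value.
#'
#' @return named list of length-2 numeric ranges.
#' @export
defaultJitter <- function() {
  list(noduleRadius = c(8, 12), noduleIntensity = c(5, 35))
}

#' Generate a reproducible cohort of phantom cases
#'
#' Draws per-patient specs from the template, with the fields named in
#' `jitter` drawn uniformly from their ranges and nodule classes cycled
#' `solid`, `juxta_vascular`, `juxta_pleural`, ... so that all three
#' classes appear whenever `nPatients >= 3`. All randomness (jitter draws
#' and per-case noise seeds) derives from `masterSeed`.
#'
#' @param nPatients integer >= 1.
#' @param template a [PhantomSpec-class] providing non-jittered fields.
#' @param jitter named list of length-2 numeric ranges over numeric
#'   `PhantomSpec` fields; see [defaultJitter()].
#' @param masterSeed integer(1).
#' @return list with `cases` (list of [PhantomCase-class]) and `manifest`
#'   (data.frame: patient_id, nodule_class, nodule_radius,
#'   nodule_intensity, noise_sd, rng_seed).
#' @examples
#' coh <- generateCohort(3, masterSeed = 7)
#' coh$manifest
#' @export
generateCohort <- function(nPatients, template = PhantomSpec(),
                           jitter = defaultJitter(), masterSeed = 1L) {
  if (nPatients < 1L) stop("'nPatients' must be >= 1", call. = FALSE)
  jitterable <- c("noduleRadius", "noduleIntensity", "lungIntensity",
                  "wallIntensity", "vesselIntensity", "vesselRadius", "noiseSd")
  if (length(jitter)) {
    bad <- setdiff(names(jitter), jitterable)
    if (length(bad)) stop("unknown jitter field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    for (nm in names(jitter)) {
      rg <- jitter[[nm]]
      if (length(rg) != 2L || any(!is.finite(rg)) || rg[1L] > rg[2L])
        stop(sprintf("jitter range for '%s' must be a finite (lo, hi) pair", nm),
             call. = FALSE)
    }
  }
  classes <- c("solid", "juxta_vascular", "juxta_pleural")

  draws <- withSeed(masterSeed, {
    d <- lapply(names(jitter), function(nm)
      stats::runif(nPatients, jitter[[nm]][1L], jitter[[nm]][2L]))
    names(d) <- names(jitter)
    d$caseSeed <- sample.int(.Machine$integer.max - 1L, nPatients)
    d
  })

  cases <- vector("list", nPatients)
  rows <- vector("list", nPatients)
  for (i in seq_len(nPatients)) {
    spec <- template
    spec@patientId <- sprintf("P%03d", i)
    spec@noduleClass <- classes[(i - 1L) %% 3L + 1L]
    for (nm in names(jitter)) slot(spec, nm) <- draws[[nm]][i]
    spec@rngSeed <- draws$caseSeed[i]
    validObject(spec)
    cases[[i]] <- generatePhantom(spec)
    rows[[i]] <- data.frame(
      patient_id = spec@patientId, nodule_class = spec@noduleClass,
      nodule_radius = spec@noduleRadius, nodule_intensity = spec@noduleIntensity,
      noise_sd = spec@noiseSd, lobulation = spec@lobulation,
      rng_seed = spec@rngSeed, stringsAsFactors = FALSE)
  }
  list(cases = cases, manifest = do.call(rbind, rows))
}
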