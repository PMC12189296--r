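test_that("phantom generation is a pure function of its PhantomSpec", {
  spec <- PhantomSpec("P1", "juxta_vascular", noiseSd = 15, rngSeed = 11L,
                      lobulation = 2L)
  a <- generatePhantom(spec)
  b <- generatePhantom(spec)
  expect_identical(stackSlices(a@stack), stackSlices(b@stack))
  expect_identical(stackSlices(a@truth), stackSlices(b@truth))
  expect_identical(fgSeed(a@seeds), fgSeed(b@seeds))
  expect_identical(bgSeed(a@seeds), bgSeed(b@seeds))
})

test_that("noiseless solid truth areas match the analytic sphere cross-sections", {
  case <- generatePhantom(PhantomSpec("P1", "solid", noiseSd = 0,
                                      noduleRadius = 10, nSlices = 5L))
  zs <- rwensemble:::phantomSliceOffsets(10, 5L)
  for (k in 1:5) {
    analytic <- pi * (10^2 - zs[k]^2)
    expect_lt(abs(sum(getSlice(case@truth, k)) - analytic) / analytic, 0.10)
  }
})

test_that("phantom invariants hold: truth nonempty, intensity contrast, seed placement", {
  for (cl in c("solid", "juxta_vascular", "juxta_pleural")) {
    case <- generatePhantom(PhantomSpec("P", cl, noiseSd = 0))
    spec <- case@spec
    geo <- rwensemble:::phantomGeometry(spec)
    for (k in seq_len(nSlices(case@truth))) {
      truth <- getSlice(case@truth, k)
      expect_gte(sum(truth), 1)
      img <- getSlice(case@stack, k)
      # noiseless contrast: truth pixels at nodule HU exactly
      expect_true(all(img[truth == 1] == spec@noduleIntensity))
    }
    # mean contrast over lung field
    img <- getSlice(case@stack, 3)
    truth <- getSlice(case@truth, 3)
    lung <- img == spec@lungIntensity
    expect_equal(mean(img[truth == 1]) - mean(img[lung]),
                 spec@noduleIntensity - spec@lungIntensity)
    # fg seed inside truth, bg seed in the lung field
    mid <- getSlice(case@truth, 3)
    fg <- fgSeed(case@seeds) + 1
    bg <- bgSeed(case@seeds) + 1
    expect_equal(mid[fg[1], fg[2]], 1L)
    expect_equal(mid[bg[1], bg[2]], 0L)
    expect_equal(getSlice(case@stack, 3)[bg[1], bg[2]], spec@lungIntensity)
  }
})

test_that("juxta-pleural truth abuts but never enters the pleural band", {
  case <- generatePhantom(PhantomSpec("P", "juxta_pleural", noiseSd = 0))
  geo <- rwensemble:::phantomGeometry(case@spec)
  bandCols <- (geo$bandStart + 1):ncol(getSlice(case@truth, 1))
  adjacent <- FALSE
  for (k in seq_len(nSlices(case@truth))) {
    truth <- getSlice(case@truth, k)
    expect_equal(sum(truth[, bandCols]), 0)          # truth excludes the band
    # 8-adjacency: any truth pixel in the column just left of the band
    if (any(truth[, geo$bandStart] == 1)) adjacent <- TRUE
  }
  expect_true(adjacent)
})

test_that("invalid phantom specs fail with errors naming the field", {
  expect_error(PhantomSpec(grid = c(16L, 16L)), "grid")
  expect_error(PhantomSpec(noduleRadius = 1), "noduleRadius")
  expect_error(PhantomSpec(noduleRadius = 100), "noduleRadius")
  expect_error(PhantomSpec(noiseSd = -1), "noiseSd")
  expect_error(PhantomSpec(nSlices = 0L), "nSlices")
})

test_that("cohort generation cycles classes, is seed-reproducible, and respects jitter", {
  coh3 <- generateCohort(3, masterSeed = 5)
  expect_setequal(coh3$manifest$nodule_class,
                  c("solid", "juxta_vascular", "juxta_pleural"))

  a <- generateCohort(6, masterSeed = 9)
  b <- generateCohort(6, masterSeed = 9)
  expect_identical(a$manifest, b$manifest)

  jit <- list(noduleRadius = c(8, 12), noduleIntensity = c(5, 35))
  coh <- generateCohort(12, jitter = jit, masterSeed = 3)
  expect_equal(nrow(coh$manifest), 12)
  expect_true(all(coh$manifest$nodule_radius >= 8 &
                  coh$manifest$nodule_radius <= 12))
  expect_true(all(coh$manifest$nodule_intensity >= 5 &
                  coh$manifest$nodule_intensity <= 35))
  for (case in coh$cases) {
    expect_true(validObject(case))
    # seeds lie inside / outside the truth of their slice
    mid <- getSlice(case@truth, case@seeds@sliceIndex + 1L)
    fg <- fgSeed(case@seeds) + 1; bg <- bgSeed(case@seeds) + 1
    expect_equal(mid[fg[1], fg[2]], 1L)
    expect_equal(mid[bg[1], bg[2]], 0L)
  }
})

test_that("cohort generation validates its inputs", {
  expect_error(generateCohort(0), "nPatients")
  expect_error(generateCohort(2, jitter = list(noduleRadius = numeric(0))),
               "noduleRadius")
  expect_error(generateCohort(2, jitter = list(bogus = c(1, 2))), "bogus")
})
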