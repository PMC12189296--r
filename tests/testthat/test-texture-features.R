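test_that("quantization respects equal-width bin edges and degenerate ranges", {
  q <- quantizeROI(matrix(c(10, 20, 30, 40), 2, 2), matrix(1, 2, 2), 4)
  expect_equal(sort(as.vector(q@values)), 1:4)

  qc <- quantizeROI(matrix(7, 3, 3), matrix(1, 3, 3), 16)
  expect_true(all(qc@values == 1L))

  set.seed(2)
  v <- matrix(runif(1e4), 100, 100)
  q8 <- quantizeROI(v, matrix(1, 100, 100), 8)
  cnt <- tabulate(q8@values, 8)
  expect_true(all(abs(cnt - 1250) / 1250 < 0.05))

  expect_error(quantizeROI(v, matrix(0, 100, 100), 8), "empty")
  expect_error(quantizeROI(v, matrix(1, 100, 100), 1), "N")
})

test_that("GLCM of the classic 4x4 image matches exhaustive pair enumeration", {
  img <- matrix(c(1, 1, 2, 2,
                  1, 1, 2, 2,
                  1, 3, 3, 3,
                  3, 3, 4, 4), 4, 4, byrow = TRUE)
  mask <- matrix(1, 4, 4)
  q <- quantizeROI(img, mask, 4)
  expect_equal(q@values, img)   # integer image already at bin edges

  for (offs in list(0, 90, c(0, 45, 90, 135))) {
    m <- buildGLCM(q, offsets = offs)
    expect_equal(m@f, naiveGLCM(img, 4, offsets = offs), tolerance = 1e-12)
  }
  m0 <- buildGLCM(q, offsets = 0)
  # hand enumeration of the 12 horizontal neighbor pairs, symmetrized (/24)
  hand <- matrix(0, 4, 4)
  hand[1, 1] <- 4; hand[2, 2] <- 4; hand[3, 3] <- 6; hand[4, 4] <- 2
  hand[1, 2] <- 2; hand[2, 1] <- 2
  hand[1, 3] <- 1; hand[3, 1] <- 1
  hand[3, 4] <- 1; hand[4, 3] <- 1
  expect_equal(m0@f, hand / sum(hand))
})

test_that("GLCM marginals are distributions with consistent moments", {
  set.seed(5)
  for (i in 1:10) {
    img <- matrix(sample(1:6, 49, replace = TRUE), 7, 7)
    mask <- matrix(rbinom(49, 1, 0.8), 7, 7)
    if (sum(mask) < 4) next
    q <- quantizeROI(img, mask, 6)
    m <- tryCatch(buildGLCM(q), error = function(e) NULL)
    if (is.null(m)) next
    expect_equal(sum(m@f), 1, tolerance = 1e-12)
    expect_equal(m@f, t(m@f))
    expect_equal(sum(m@fSum), 1, tolerance = 1e-12)
    expect_equal(sum(m@fDiff), 1, tolerance = 1e-12)
    expect_equal(m@mu, sum(seq_len(6) * rowSums(m@f)), tolerance = 1e-12)
  }
})

test_that("all GLCM features match a term-by-term oracle on random ROIs", {
  set.seed(11)
  for (i in 1:50) {
    img <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
    q <- quantizeROI(img, matrix(1, 6, 6), 5)
    m <- buildGLCM(q)
    got <- glcmFeatures(m)
    want <- naiveGLCMFeatures(m@f)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("degenerate single-level GLCM yields its forced feature identities", {
  q <- quantizeROI(matrix(3, 4, 4), matrix(1, 4, 4), 8)
  m <- buildGLCM(q)
  f <- suppressWarnings(glcmFeatures(m))
  expect_equal(f[["gcm_ener"]], 1)
  expect_equal(f[["gcm_entro"]], 0)
  expect_equal(f[["gcm_contr"]], 0)
  expect_equal(f[["gcm_homo"]], 1)
  expect_equal(f[["gcm_max_prob"]], 1)
  expect_equal(f[["gcm_savg"]], 2)
  expect_equal(f[["gcm_svar"]], 0)
  expect_warning(glcmFeatures(m), "variance")
})

test_that("symmetric two-cell GLCM has the hand-computed marginals and no shade", {
  f <- matrix(0, 2, 2); f[1, 2] <- 0.5; f[2, 1] <- 0.5
  m <- new("CoocMatrix", f = f, mu = 1.5, sigma2 = 0.25,
           fSum = c("2" = 0, "3" = 1, "4" = 0),
           fDiff = c("0" = 0, "1" = 1), levels = 2L)
  feats <- glcmFeatures(m)
  expect_equal(feats[["gcm_cshd"]], 0)        # x + y - 2mu = 0 everywhere
  expect_equal(feats[["gcm_savg"]], 3)
  expect_equal(feats[["gcm_disim"]], 1)
  expect_equal(m@mu, 1.5)
})

test_that("printed-dialect feature variants follow the published formulas", {
  set.seed(3)
  img <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
  m <- buildGLCM(quantizeROI(img, matrix(1, 6, 6), 4))
  pr <- glcmFeatures(m, dialect = "printed")
  co <- glcmFeatures(m, dialect = "corrected")
  # printed entropies are the sign-flipped corrected ones (k-range aside)
  expect_lte(pr[["gcm_entro"]], 0)
  expect_equal(pr[["gcm_entro"]], -co[["gcm_entro"]])
  # printed autocorrelation collapses to the marginal variance
  expect_equal(pr[["gcm_rxx"]], sum(m@f * (matrix(1:4, 4, 4) - m@mu)^2))
  # printed dissimilarity sums f * (x - y), which vanishes on a symmetric GLCM
  expect_equal(pr[["gcm_disim"]], 0, tolerance = 1e-12)
  expect_gt(co[["gcm_disim"]], 0)

  rl <- buildGLRLM(quantizeROI(img, matrix(1, 6, 6), 4))
  prl <- glrlmFeatures(rl, dialect = "printed")
  crl <- glrlmFeatures(rl, dialect = "corrected")
  expect_equal(prl[["grlm_lgr"]], crl[["grlm_hgr"]])   # printed lgr uses x^2
  expect_equal(prl[["grlm_sr"]], crl[["grlm_sr"]])     # fallback forms
  expect_equal(prl[["grlm_rper"]], crl[["grlm_rper"]])
})

test_that("convexity is exact for convex shapes, concave shapes, and slice means", {
  sq <- matrix(0L, 7, 7); sq[2:6, 2:6] <- 1L
  expect_equal(convexity(MaskStack(list(sq, sq))), 1)

  plus <- matrix(0L, 7, 7); plus[4, 2:6] <- 1L; plus[2:6, 4] <- 1L
  idx <- which(plus != 0, arr.ind = TRUE)
  hullCount <- naiveHullPixelCount(idx)
  expect_equal(convexity(MaskStack(plus)), 9 / hullCount)
  expect_lt(convexity(MaskStack(plus)), 1)

  # mean over slices with different convexities
  c1 <- convexity(MaskStack(sq)); c2 <- convexity(MaskStack(plus))
  expect_equal(convexity(MaskStack(list(sq, plus))), (c1 + c2) / 2)

  # degenerate slices: single pixel and a collinear segment
  dot <- matrix(0L, 5, 5); dot[3, 3] <- 1L
  expect_equal(convexity(MaskStack(dot)), 1)
  seg <- matrix(0L, 5, 5); seg[2, c(2, 5)] <- 1L
  expect_equal(convexity(MaskStack(seg)), 2 / 4)

  empty <- matrix(0L, 7, 7)
  expect_warning(v <- convexity(MaskStack(list(sq, empty))), "empty")
  expect_equal(v, 1)
  expect_error(suppressWarnings(convexity(MaskStack(empty))), "empty")
})

test_that("GLRLM runs match hand enumeration and the run-count identity", {
  qc <- quantizeROI(matrix(1, 4, 4), matrix(1, 4, 4), 8)
  r0 <- buildGLRLM(qc, directions = 0)
  expect_equal(r0@R[1, 4], 4)
  expect_equal(r0@RTotal, 4)

  striped <- matrix(rep(c(1, 1, 2, 2), each = 4), 4, 4)
  qs <- quantizeROI(striped, matrix(1, 4, 4), 2)
  rs <- buildGLRLM(qs, directions = 0)
  expect_equal(rs@R[1, 2], 4)
  expect_equal(rs@R[2, 2], 4)

  dot <- matrix(0, 3, 3); dot[2, 2] <- 1
  qd <- quantizeROI(matrix(5, 3, 3), dot, 8)
  rd <- buildGLRLM(qd)
  expect_equal(rd@RTotal, 4)          # one unit run per direction
  expect_equal(rd@R[1, 1], 4)

  # total in-run pixels per direction equal the ROI pixel count
  set.seed(9)
  img <- matrix(sample(1:3, 64, replace = TRUE), 8, 8)
  mask <- matrix(rbinom(64, 1, 0.7), 8, 8)
  if (sum(mask) > 0) {
    q <- quantizeROI(img, mask, 3)
    for (ang in c(0, 45, 90, 135)) {
      r1 <- buildGLRLM(q, directions = ang)
      expect_equal(sum(r1@R %*% seq_len(r1@Nr)), q@nPixels)
    }
  }
})

test_that("GLRLM features match the naive oracle on random masked ROIs", {
  set.seed(13)
  for (i in 1:50) {
    img <- matrix(sample(1:5, 36, replace = TRUE), 6, 6)
    mask <- matrix(rbinom(36, 1, 0.85), 6, 6)
    if (sum(mask) < 2) next
    q <- quantizeROI(img, mask, 5)
    m <- buildGLRLM(q)
    R <- naiveGLRLM(q@values, 5)
    expect_equal(unname(m@R), unname(R))
    got <- glrlmFeatures(m)
    want <- naiveGLRLMFeatures(R, q@nPixels)
    expect_equal(got[names(want)], want, tolerance = 1e-10)
  }
})

test_that("single-pixel and single-level ROIs give the degenerate run features", {
  dot <- matrix(0, 3, 3); dot[1, 1] <- 1
  q <- quantizeROI(matrix(2, 3, 3), dot, 4)
  f <- glrlmFeatures(buildGLRLM(q))
  expect_equal(f[["grlm_sr"]], 1)
  expect_equal(f[["grlm_lr"]], 1)
  expect_equal(f[["grlm_rper"]], 4)   # 4 unit runs (one per direction) / 1 px
  expect_equal(f[["grlm_lgr"]], 1)    # all runs at level 1
  expect_equal(f[["grlm_hgr"]], 1)
})

test_that("four-direction texture features are invariant to 90-degree rotation", {
  set.seed(21)
  img <- matrix(sample(1:6, 100, replace = TRUE), 10, 10)
  mask <- matrix(rbinom(100, 1, 0.8), 10, 10)
  rot <- function(m) t(m)[, nrow(m):1]
  q1 <- quantizeROI(img, mask, 6)
  q2 <- quantizeROI(rot(img), rot(mask), 6)
  expect_equal(glcmFeatures(buildGLCM(q1)), glcmFeatures(buildGLCM(q2)),
               tolerance = 1e-12)
  expect_equal(glrlmFeatures(buildGLRLM(q1)), glrlmFeatures(buildGLRLM(q2)),
               tolerance = 1e-12)
})

test_that("feature bounds hold across random ROIs", {
  set.seed(31)
  for (i in 1:20) {
    img <- matrix(runif(64), 8, 8)
    q <- quantizeROI(img, matrix(1, 8, 8), 8)
    f <- glcmFeatures(buildGLCM(q))
    for (nm in c("gcm_ener", "gcm_homo", "gcm_imn", "gcm_max_prob")) {
      expect_gt(f[[nm]], 0); expect_lte(f[[nm]], 1)
    }
    expect_gte(f[["gcm_entro"]], 0)
    expect_gte(f[["gcm_sentro"]], 0)
    expect_gte(f[["gcm_dentro"]], 0)
    expect_gte(f[["gcm_contr"]], 0)
  }
})

test_that("patient-level extraction averages per slice and orders canonically", {
  case <- smallPhantom(noiseSd = 10)
  f <- extractPatientFeatures(case@stack, case@truth)
  expect_length(f, 38)
  expect_identical(names(f), canonicalFeatureNames())
  expect_true(all(is.finite(f)))

  # identical slices: averaging is the identity
  oneSlice <- getSlice(case@stack, 2); oneMask <- getSlice(case@truth, 2)
  stk3 <- ImageStack(list(oneSlice, oneSlice, oneSlice), patientId = "rep")
  msk3 <- MaskStack(list(oneMask, oneMask, oneMask))
  f3 <- extractPatientFeatures(stk3, msk3)
  f1 <- extractPatientFeatures(ImageStack(oneSlice, patientId = "one"),
                               MaskStack(oneMask))
  tex <- setdiff(canonicalFeatureNames(), canonicalFeatureNames("hist"))
  expect_equal(f3[tex], f1[tex], tolerance = 1e-12)

  # determinism: truth masks vs an identical copy
  f2 <- extractPatientFeatures(case@stack, MaskStack(stackSlices(case@truth)))
  expect_identical(f, f2)
})
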