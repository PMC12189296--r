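test_that("tie-aware ranking averages positional ranks", {
  expect_equal(rankWithTies(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(rankWithTies(sort(runif(9))), 1:9)
  expect_equal(rankWithTies(rep(7, 5)), rep(3, 5))
  expect_error(rankWithTies(1), "at least 2")
  set.seed(14)
  for (i in 1:20) {
    v <- sample(1:6, 15, replace = TRUE)
    r <- rankWithTies(v)
    expect_equal(sum(r), 15 * 16 / 2)   # ranks always sum to n(n+1)/2
  }
})

test_that("Spearman reproduces the rank-difference shortcut and its limits", {
  x <- c(3, 1, 4, 1.5, 9)
  expect_equal(spearmanRho(x, x), 1)
  expect_equal(spearmanRho(x, -x), -1)
  expect_equal(spearmanRho(1:5, c(2, 1, 4, 3, 5)), 0.8)   # sum d^2 = 4
  expect_equal(spearmanRho(x, exp(x)), 1)                  # monotone invariance
  expect_equal(spearmanRho(c(1, 2, 3), c(1, 2, 3)),
               spearmanRho(c(1, 2, 3), c(10, 20, 30)))
  expect_error(spearmanRho(1:4, 1:5), "length")
  expect_error(spearmanRho(1:2, 2:1), "at least 3")
  rho <- spearmanRho(rep(1, 5), 1:5)
  expect_true(is.nan(rho))
  expect_true(attr(rho, "undefined"))
})

test_that("Spearman matches naive rank-then-Pearson and cor() on 100 random pairs", {
  set.seed(20)
  for (i in 1:100) {
    x <- rnorm(50); y <- 0.5 * x + rnorm(50)
    if (i %% 2 == 0) {         # inject ties into both vectors
      x <- round(x, 1); y <- round(y, 1)
    }
    got <- spearmanRho(x, y)
    expect_equal(got, naiveSpearman(x, y), tolerance = 1e-12)
    expect_equal(got, suppressWarnings(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    expect_equal(got, spearmanRho(y, x), tolerance = 1e-12)
  }
})

test_that("strength banding reproduces the published value/label pairs", {
  # (value, strength, direction) pairs from the per-family concordance tables
  published <- list(
    list(0.57, "moderate"), list(0.44, "weak"), list(0.73, "strong"),
    list(0.14, "weak"), list(0.38, "weak"), list(0.50, "moderate"),
    list(0.57, "moderate"), list(0.35, "weak"), list(0.65, "moderate"),
    list(0.55, "moderate"), list(0.43, "weak"), list(0.50, "moderate"),
    list(0.44, "weak"), list(0.86, "strong"), list(0.83, "strong"),
    list(0.36, "weak"), list(0.67, "moderate"), list(0.82, "strong"),
    list(0.78, "strong"), list(0.65, "moderate"), list(0.83, "strong"),
    list(0.37, "weak"), list(0.77, "strong"))
  for (p in published) {
    cls <- classifyStrength(p[[1]])
    expect_equal(cls$strength, p[[2]])
    expect_equal(cls$direction, "positive")
  }
  # band boundaries and the negative mirror
  expect_equal(classifyStrength(0)$strength, "none")
  expect_equal(classifyStrength(0.005)$strength, "none")    # rounds to 0.00
  expect_equal(classifyStrength(0.01)$strength, "weak")
  expect_equal(classifyStrength(0.49)$strength, "weak")
  expect_equal(classifyStrength(0.494)$strength, "weak")
  expect_equal(classifyStrength(0.50)$strength, "moderate")
  expect_equal(classifyStrength(0.69)$strength, "moderate")
  expect_equal(classifyStrength(0.70)$strength, "strong")
  expect_equal(classifyStrength(1)$strength, "strong")
  expect_equal(classifyStrength(-0.17),
               list(strength = "weak", direction = "negative"))
  expect_equal(classifyStrength(-1),
               list(strength = "strong", direction = "negative"))
})

test_that("every coefficient maps to exactly one strength/direction cell", {
  for (v in seq(-1, 1, by = 0.01)) {
    cls <- classifyStrength(v)
    expect_true(cls$strength %in% c("none", "weak", "moderate", "strong"))
    expect_true(cls$direction %in% c("none", "positive", "negative"))
    expect_equal(cls$direction == "none", cls$strength == "none")
  }
})

test_that("the correlation t test matches its closed form", {
  expect_equal(sccTTest(0, 10), list(t = 0, p = 1))
  expect_equal(sccTTest(1, 8)$p, 0)
  expect_equal(sccTTest(0.8, 5)$t, 0.8 * sqrt(3 / 0.36), tolerance = 1e-10)
  tt <- sccTTest(0.6, 25)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 23), tolerance = 1e-12)
  expect_error(sccTTest(0.5, 2), "n >= 3")
})

test_that("concordance of a table with itself is perfect and join is order-free", {
  set.seed(33)
  m <- matrix(rnorm(8 * 38), 8, 38,
              dimnames = list(paste0("p", 1:8), canonicalFeatureNames()))
  truth <- FeatureTable(m, provenance = "ground_truth")
  self <- concordanceTable(FeatureTable(m, provenance = "rwe"), truth)
  expect_equal(nrow(self), 38)
  expect_true(all(self$scc == 1))
  expect_true(all(self$strength == "strong"))
  expect_true(all(self$p < 1e-6))

  shuf <- FeatureTable(m[sample(8), ], provenance = "rwe")
  again <- concordanceTable(shuf, truth)
  expect_equal(again, self)

  bad <- FeatureTable(m[1:7, ], provenance = "rwe")
  expect_error(concordanceTable(bad, truth), "p8")
})

test_that("rank pairs exported for scatter plots carry both rank vectors", {
  set.seed(34)
  m <- matrix(rnorm(5 * 38), 5, 38,
              dimnames = list(paste0("p", 1:5), canonicalFeatureNames()))
  m2 <- m + rnorm(length(m), sd = 0.2)
  conc <- concordanceTable(FeatureTable(m2, "rwe"), FeatureTable(m, "ground_truth"))
  rp <- attr(conc, "rankPairs")
  expect_length(rp, 38)
  expect_equal(colnames(rp[["hist_mean"]]), c("truth_rank", "extracted_rank"))
  expect_equal(sort(rp[["gcm_conv"]][, 1]), 1:5)
})

test_that("per-family selection takes the strongest features with stable ties", {
  set.seed(35)
  m <- matrix(rnorm(6 * 38), 6, 38,
              dimnames = list(paste0("p", 1:6), canonicalFeatureNames()))
  m2 <- m + rnorm(length(m), sd = 1.5)
  conc <- concordanceTable(FeatureTable(m2, "rwe"), FeatureTable(m, "ground_truth"))

  sel <- selectFeatures(conc)
  expect_length(sel, 24)
  expect_equal(as.integer(table(featureFamily(sel))[c("gcm", "grlm", "hist")]),
               c(12L, 6L, 6L))
  # each family's selection is its top-|scc| subset
  for (fam in c("gcm", "grlm", "hist")) {
    sub <- conc[conc$family == fam, ]
    k <- c(gcm = 12, grlm = 6, hist = 6)[[fam]]
    expect_equal(sort(abs(sub$scc[sub$feature %in% sel]), decreasing = TRUE),
                 sort(abs(sub$scc), decreasing = TRUE)[1:k])
  }

  expect_length(selectFeatures(conc, c(0, 0, 0)), 0)
  expect_warning(sel2 <- selectFeatures(conc, c(25, 6, 6)), "returning all")
  expect_length(sel2, 19 + 6 + 6)

  # tie at the cutoff: lexicographically-first canonical name wins
  tied <- conc
  tied$scc <- rep(0.5, 38)
  selTied <- selectFeatures(tied, c(1, 1, 1))
  expect_equal(selTied, c("gcm_rxx", "grlm_sr", "hist_ener"))
})
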