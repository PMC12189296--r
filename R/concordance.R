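#' @include utils.R image_io.R
NULL

#' Tie-aware ascending ranks
#'
#' Ranks values in ascending order; tied values receive the average of
#' their positional ranks, so the ranks always sum to n(n+1)/2.
#'
#' @param values finite numeric vector, length >= 2.
#' @return numeric vector of average ranks.
#' @examples
#' rankWithTies(c(10, 20, 20, 30))   # 1, 2.5, 2.5, 4
#' @export
rankWithTies <- function(values) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 observations to rank", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  ord <- order(values)
  pos <- numeric(n)
  pos[ord] <- seq_len(n)
  # average positional ranks within tie groups
  avg <- stats::ave(pos, match(values, values), FUN = mean)
  avg
}

#' Spearman's rank correlation coefficient
#'
#' Ranks both vectors with average ranks for ties. Without ties the
#' classical shortcut \eqn{1 - 6 \sum d_i^2 / (n (n^2 - 1))} over the rank
#' differences \eqn{d_i} is used; with ties the coefficient is the Pearson
#' correlation of the two rank vectors (the two coincide in the tie-free
#' case). The result is clamped to \[-1, 1\] against rounding.
#'
#' If either vector is entirely tied its ranks have zero variance and the
#' coefficient is undefined: `NaN` is returned with attribute
#' `undefined = TRUE`.
#'
#' @param x,y finite numeric vectors of equal length n >= 3.
#' @return numeric(1) in \[-1, 1\], or flagged NaN.
#' @examples
#' spearmanRho(1:5, c(2, 1, 4, 3, 5))   # 1 - 6*4/120 = 0.8
#' @export
spearmanRho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  rx <- rankWithTies(x); ry <- rankWithTies(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    out <- NaN
    attr(out, "undefined") <- TRUE
    return(out)
  }
  hasTies <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  rho <- if (hasTies) {
    dx <- rx - mean(rx); dy <- ry - mean(ry)
    sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
  } else {
    1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  }
  min(1, max(-1, rho))
}

#' Classify the strength and direction of a Spearman coefficient
#'
#' Bands on `|rho|` rounded to 2 decimals: 0 = none, 0.01-0.49 = weak,
#' 0.50-0.69 = moderate, >= 0.70 = strong; the direction is the sign. A
#' negative coefficient carries the mirrored strength of its magnitude.
#' A flagged-undefined coefficient (see [spearmanRho()]) maps to
#' (`"none"`, `"none"`).
#'
#' @param scc numeric(1) in \[-1, 1\], or flagged NaN.
#' @return named list with `strength` (none/weak/moderate/strong) and
#'   `direction` (positive/negative/none).
#' @examples
#' classifyStrength(0.73)    # strong positive
#' classifyStrength(-0.17)   # weak negative
#' @export
classifyStrength <- function(scc) {
  if (is.nan(scc) || isTRUE(attr(scc, "undefined")))
    return(list(strength = "none", direction = "none"))
  if (abs(scc) > 1 + 1e-9) stop("'scc' must lie in [-1, 1]", call. = FALSE)
  r2 <- round(abs(scc), 2)
  strength <- if (r2 == 0) "none"
              else if (r2 <= 0.49) "weak"
              else if (r2 <= 0.69) "moderate"
              else "strong"
  direction <- if (r2 == 0) "none" else if (scc > 0) "positive" else "negative"
  list(strength = strength, direction = direction)
}

#' t test for a Spearman coefficient against zero
#'
#' `t = scc * sqrt((n - 2) / (1 - scc^2))` with a two-sided p value from
#' Student's t on n - 2 degrees of freedom; `|scc| = 1` gives p = 0.
#'
#' @param scc coefficient in \[-1, 1\].
#' @param n number of paired observations, >= 3.
#' @return named list with `t` and `p`.
#' @examples
#' sccTTest(0.8, 5)$t   # 0.8 * sqrt(3 / 0.36) = 2.3094
#' @export
sccTTest <- function(scc, n) {
  if (n < 3L) stop("need n >= 3", call. = FALSE)
  if (is.nan(scc)) return(list(t = NaN, p = NaN))
  if (abs(scc) > 1 + 1e-9) stop("'scc' must lie in [-1, 1]", call. = FALSE)
  if (abs(scc) >= 1) return(list(t = Inf * sign(scc), p = 0))
  t <- scc * sqrt((n - 2) / (1 - scc^2))
  p <- 2 * stats::pt(-abs(t), df = n - 2)
  list(t = t, p = p)
}

#' Feature-wise Spearman concordance between two feature tables
#'
#' Joins the extracted and ground-truth tables on patient id (order-
#' independent) and computes, per canonical feature, the Spearman
#' coefficient, its direction and strength band, the t statistic and p
#' value, and the paired rank vectors (ground-truth ranks first) for
#' scatter export.
#'
#' @param extracted,truth [FeatureTable-class] objects over the same
#'   patient id set, n >= 3.
#' @return data.frame with columns `feature`, `family`, `scc`,
#'   `direction`, `strength`, `t`, `p`, `n`, plus an attribute
#'   `rankPairs`: a named list of n x 2 matrices
#'   (`truth_rank`, `extracted_rank`).
#' @examples
#' # self-concordance of a table with itself is 1 for every feature
#' @export
concordanceTable <- function(extracted, truth) {
  ev <- featureValues(extracted); tv <- featureValues(truth)
  onlyE <- setdiff(rownames(ev), rownames(tv))
  onlyT <- setdiff(rownames(tv), rownames(ev))
  if (length(onlyE) || length(onlyT))
    stop("patient id mismatch; only in extracted: {",
         paste(onlyE, collapse = ", "), "}; only in truth: {",
         paste(onlyT, collapse = ", "), "}", call. = FALSE)
  ids <- rownames(tv)
  ev <- ev[ids, , drop = FALSE]
  n <- length(ids)
  if (n < 3L) stop("need at least 3 patients", call. = FALSE)

  feats <- canonicalFeatureNames()
  rankPairs <- vector("list", length(feats))
  names(rankPairs) <- feats
  rows <- lapply(feats, function(f) {
    x <- tv[, f]; y <- ev[, f]
    rho <- spearmanRho(x, y)
    cls <- classifyStrength(rho)
    tt <- sccTTest(if (is.nan(rho)) NaN else rho, n)
    rankPairs[[f]] <<- cbind(truth_rank = rankWithTies(x),
                             extracted_rank = rankWithTies(y))
    data.frame(feature = f, family = featureFamily(f),
               scc = as.numeric(rho), direction = cls$direction,
               strength = cls$strength, t = tt$t, p = tt$p, n = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rankPairs") <- rankPairs
  out
}

#' Select the top concordant features per family
#'
#' Within each family, rows are sorted by `|scc|` descending (ties broken
#' by canonical name order) and the top k taken; defaults (12, 6, 6) for
#' the GLCM, GLRLM and histogram families. Undefined coefficients rank
#' last. Requesting more than a family holds returns the whole family
#' with a warning.
#'
#' @param rows a concordance data.frame from [concordanceTable()].
#' @param perFamily integer(3): counts for (gcm, grlm, hist).
#' @return character vector of selected canonical feature names.
#' @export
selectFeatures <- function(rows, perFamily = c(12L, 6L, 6L)) {
  if (length(perFamily) != 3L || any(perFamily < 0L))
    stop("'perFamily' must be three counts >= 0", call. = FALSE)
  fams <- c("gcm", "grlm", "hist")
  out <- character(0L)
  for (i in seq_along(fams)) {
    sub <- rows[rows$family == fams[i], , drop = FALSE]
    k <- perFamily[i]
    if (k > nrow(sub)) {
      warning(sprintf("requested %d features from family '%s' of size %d; returning all",
                      k, fams[i], nrow(sub)))
      k <- nrow(sub)
    }
    if (k == 0L) next
    mag <- abs(sub$scc)
    mag[is.nan(mag)] <- -Inf
    canon <- match(sub$feature, canonicalFeatureNames(fams[i]))
    ord <- order(-mag, canon)
    out <- c(out, sub$feature[ord[seq_len(k)]])
  }
  out
}
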