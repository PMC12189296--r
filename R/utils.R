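#' @include AllClasses.R
NULL

# Run code under a temporary RNG seed, restoring global RNG state on exit.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopIfNot01 <- function(x, what) {
  if (any(x < -1e-9 | x > 1 + 1e-9))
    stop(sprintf("%s must lie in [0, 1]; apply autoWindow() first", what), call. = FALSE)
}

# 0-based (row, col) -> 1-based matrix index, with bounds check.
seedToIndex <- function(rc, dm, what = "seed") {
  r <- rc[1L] + 1L; c <- rc[2L] + 1L
  if (r < 1L || r > dm[1L] || c < 1L || c > dm[2L])
    stop(sprintf("%s (%g, %g) is out of bounds for a %d x %d slice",
                 what, rc[1L], rc[2L], dm[1L], dm[2L]), call. = FALSE)
  c(r, c)
}

#' Canonical radiomic feature names
#'
#' The 38 canonical feature column names in fixed order: 19 GLCM-family
#' features (including convexity), 7 GLRLM-family features, and 12
#' histogram-family features.
#'
#' @param family optional, one of `"gcm"`, `"grlm"`, `"hist"` to return a
#'   single family; default all 38.
#' @return character vector of feature names.
#' @examples
#' length(canonicalFeatureNames())        # 38
#' canonicalFeatureNames("grlm")
#' @export
canonicalFeatureNames <- function(family = c("all", "gcm", "grlm", "hist")) {
  family <- match.arg(family)
  gcm <- c("gcm_rxx", "gcm_cpro", "gcm_cshd", "gcm_corr", "gcm_conv",
           "gcm_contr", "gcm_disim", "gcm_dvar", "gcm_dentro", "gcm_ener",
           "gcm_entro", "gcm_homo", "gcm_imc1", "gcm_imc2", "gcm_imn",
           "gcm_max_prob", "gcm_savg", "gcm_svar", "gcm_sentro")
  grlm <- c("grlm_sr", "grlm_lr", "grlm_gn", "grlm_rln", "grlm_rper",
            "grlm_hgr", "grlm_lgr")
  hist <- c("hist_ener", "hist_entro", "hist_skew", "hist_kurt", "hist_max",
            "hist_min", "hist_mean", "hist_median", "hist_mad", "hist_sd",
            "hist_range", "hist_var")
  switch(family, all = c(gcm, grlm, hist), gcm = gcm, grlm = grlm, hist = hist)
}

#' Family of a canonical feature name
#'
#' @param feature character vector of canonical feature names.
#' @return character vector with values `"gcm"`, `"grlm"` or `"hist"`.
#' @examples
#' featureFamily(c("gcm_conv", "hist_mean"))
#' @export
featureFamily <- function(feature) {
  fam <- rep(NA_character_, length(feature))
  fam[feature %in% canonicalFeatureNames("gcm")] <- "gcm"
  fam[feature %in% canonicalFeatureNames("grlm")] <- "grlm"
  fam[feature %in% canonicalFeatureNames("hist")] <- "hist"
  if (anyNA(fam))
    stop("unknown feature name(s): ",
         paste(feature[is.na(fam)], collapse = ", "), call. = FALSE)
  fam
}

# xlogx with the 0 * log(0) = 0 convention, base-2 logarithm.
xlog2x <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}
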