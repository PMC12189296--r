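# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles (explicit loops, no shared code with the
# package internals) so that agreement is evidence of correctness.

# ---- naive GLCM -----------------------------------------------------------

naiveGLCM <- function(q, N, offsets = c(0, 45, 90, 135), distance = 1L) {
  steps <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
                "90" = c(-1L, 0L), "135" = c(-1L, -1L))
  counts <- matrix(0, N, N)
  for (ang in offsets) {
    d <- steps[[as.character(ang)]] * distance
    for (r in seq_len(nrow(q))) for (cc in seq_len(ncol(q))) {
      r2 <- r + d[1L]; c2 <- cc + d[2L]
      if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
      a <- q[r, cc]; b <- q[r2, c2]
      if (is.na(a) || is.na(b)) next
      counts[a, b] <- counts[a, b] + 1
      counts[b, a] <- counts[b, a] + 1
    }
  }
  counts / sum(counts)
}

# term-by-term evaluation of every co-occurrence feature on a normalized
# symmetric matrix f (corrected-dialect forms)
naiveGLCMFeatures <- function(f) {
  N <- nrow(f)
  marg <- rowSums(f)
  mu <- 0; for (x in 1:N) mu <- mu + x * marg[x]
  s2 <- 0; for (x in 1:N) s2 <- s2 + (x - mu)^2 * marg[x]
  fs <- setNames(numeric(2 * N - 1), 2:(2 * N))
  fd <- setNames(numeric(N), 0:(N - 1))
  for (x in 1:N) for (y in 1:N) {
    fs[as.character(x + y)] <- fs[as.character(x + y)] + f[x, y]
    fd[as.character(abs(x - y))] <- fd[as.character(abs(x - y))] + f[x, y]
  }
  l2 <- function(p) if (p > 0) log2(p) else 0
  out <- c(gcm_rxx = 0, gcm_cpro = 0, gcm_cshd = 0, gcm_corr = 0,
           gcm_contr = 0, gcm_disim = 0, gcm_dvar = 0, gcm_dentro = 0,
           gcm_ener = 0, gcm_entro = 0, gcm_homo = 0, gcm_imc1 = 0,
           gcm_imc2 = 0, gcm_imn = 0, gcm_max_prob = 0, gcm_savg = 0,
           gcm_svar = 0, gcm_sentro = 0)
  for (x in 1:N) for (y in 1:N) {
    v <- f[x, y]
    out["gcm_rxx"] <- out["gcm_rxx"] + x * y * v
    out["gcm_cpro"] <- out["gcm_cpro"] + v * (x + y - 2 * mu)^4
    out["gcm_cshd"] <- out["gcm_cshd"] + v * (x + y - 2 * mu)^3
    out["gcm_contr"] <- out["gcm_contr"] + v * (x - y)^2
    out["gcm_disim"] <- out["gcm_disim"] + v * abs(x - y)
    out["gcm_ener"] <- out["gcm_ener"] + v^2
    out["gcm_entro"] <- out["gcm_entro"] - v * l2(v)
    out["gcm_homo"] <- out["gcm_homo"] + v / (1 + abs(x - y))
    out["gcm_imn"] <- out["gcm_imn"] + v / (1 + (x - y)^2)
    out["gcm_max_prob"] <- max(out["gcm_max_prob"], v)
    if (s2 > 0) {
      out["gcm_corr"] <- out["gcm_corr"] + v * (x - mu) * (y - mu) / s2
      out["gcm_imc1"] <- out["gcm_imc1"] + v * (x - mu) * (y - mu) / s2
      out["gcm_imc2"] <- out["gcm_imc2"] + v * (x - mu) * (y - mu) / (s2 + 1 / s2)
    }
  }
  savg <- 0; for (k in names(fs)) savg <- savg + as.numeric(k) * fs[k]
  davg <- 0; for (k in names(fd)) davg <- davg + as.numeric(k) * fd[k]
  for (k in names(fs)) {
    out["gcm_savg"] <- savg
    out["gcm_svar"] <- out["gcm_svar"] + fs[k] * (as.numeric(k) - savg)^2
    out["gcm_sentro"] <- out["gcm_sentro"] - fs[k] * l2(fs[k])
  }
  for (k in names(fd)) {
    out["gcm_dvar"] <- out["gcm_dvar"] + fd[k] * (as.numeric(k) - davg)^2
    out["gcm_dentro"] <- out["gcm_dentro"] - fd[k] * l2(fd[k])
  }
  out
}

# ---- naive GLRLM ----------------------------------------------------------

naiveGLRLM <- function(q, N, directions = c(0, 45, 90, 135)) {
  steps <- list("0" = c(0L, 1L), "45" = c(-1L, 1L),
                "90" = c(1L, 0L), "135" = c(1L, 1L))
  nr <- nrow(q); nc <- ncol(q)
  runs <- list()
  for (ang in directions) {
    d <- steps[[as.character(ang)]]
    # line starts: cells with no predecessor along d
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      pr <- r - d[1L]; pc <- cc - d[2L]
      if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc) next
      # walk the line, collecting maximal equal-value runs
      cur <- NA; len <- 0L
      rr <- r; c2 <- cc
      while (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc) {
        v <- q[rr, c2]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1L
        } else {
          if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
          cur <- v; len <- if (is.na(v)) 0L else 1L
        }
        rr <- rr + d[1L]; c2 <- c2 + d[2L]
      }
      if (!is.na(cur)) runs[[length(runs) + 1L]] <- c(cur, len)
    }
  }
  runs <- do.call(rbind, runs)
  Nr <- max(runs[, 2L])
  R <- matrix(0, N, Nr)
  for (i in seq_len(nrow(runs))) R[runs[i, 1L], runs[i, 2L]] <-
      R[runs[i, 1L], runs[i, 2L]] + 1
  R
}

naiveGLRLMFeatures <- function(R, nPixels) {
  N <- nrow(R); Nr <- ncol(R)
  total <- sum(R)
  out <- c(grlm_sr = 0, grlm_lr = 0, grlm_gn = 0, grlm_rln = 0,
           grlm_rper = total / nPixels, grlm_hgr = 0, grlm_lgr = 0)
  for (x in 1:N) for (y in 1:Nr) {
    p <- R[x, y] / total
    out["grlm_sr"] <- out["grlm_sr"] + p / y^2
    out["grlm_lr"] <- out["grlm_lr"] + p * y^2
    out["grlm_hgr"] <- out["grlm_hgr"] + p * x^2
    out["grlm_lgr"] <- out["grlm_lgr"] + p / x^2
  }
  for (x in 1:N) out["grlm_gn"] <- out["grlm_gn"] + sum(R[x, ])^2 / total
  for (y in 1:Nr) out["grlm_rln"] <- out["grlm_rln"] + sum(R[, y])^2 / total
  out
}

# ---- naive Spearman -------------------------------------------------------

# ranks from first principles: 1 + (# smaller) + (# equal - 1) / 2
naiveRanks <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1L))
}

naiveSpearman <- function(x, y) {
  rx <- naiveRanks(x); ry <- naiveRanks(y)
  mx <- sum(rx) / length(rx); my <- sum(ry) / length(ry)
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2)) * sqrt(sum((ry - my)^2))
  num / den
}

# ---- Monte-Carlo random-walker oracle -------------------------------------

# Absorbing random walk on the 4-connected lattice with transition
# probabilities proportional to Gaussian intensity weights; returns the
# empirical probability of absorption at the fg seed, per start pixel,
# with its standard error.
mcWalkOracle <- function(slice, fg0, bg0, beta = 130, nWalks = 1e5) {
  nr <- nrow(slice); nc <- ncol(slice); P <- nr * nc
  idx <- matrix(seq_len(P), nr, nc)
  g <- as.vector(slice)
  nbr <- matrix(0L, P, 4L); wgt <- matrix(0, P, 4L)
  for (p in seq_len(P)) {
    r <- (p - 1L) %% nr + 1L; cc <- (p - 1L) %/% nr + 1L
    k <- 0L
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      r2 <- r + d[1L]; c2 <- cc + d[2L]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      k <- k + 1L
      q <- idx[r2, c2]
      nbr[p, k] <- q
      wgt[p, k] <- exp(-beta * (g[p] - g[q])^2) + 1e-10
    }
    if (k < 4L) wgt[p, (k + 1L):4L] <- 0
  }
  cum <- t(apply(wgt, 1L, function(w) cumsum(w) / sum(w)))
  sFg <- idx[fg0[1L] + 1L, fg0[2L] + 1L]
  sBg <- idx[bg0[1L] + 1L, bg0[2L] + 1L]

  pHat <- matrix(NA_real_, nr, nc)
  se <- matrix(NA_real_, nr, nc)
  for (p in seq_len(P)) {
    if (p == sFg) { pHat[p] <- 1; se[p] <- 0; next }
    if (p == sBg) { pHat[p] <- 0; se[p] <- 0; next }
    pos <- rep.int(p, nWalks)
    hitFg <- logical(nWalks)
    active <- seq_len(nWalks)
    while (length(active)) {
      cur <- pos[active]
      u <- stats::runif(length(active))
      step <- 1L + (u > cum[cbind(cur, 1L)]) + (u > cum[cbind(cur, 2L)]) +
        (u > cum[cbind(cur, 3L)])
      nxt <- nbr[cbind(cur, step)]
      pos[active] <- nxt
      hitFg[active[nxt == sFg]] <- TRUE
      active <- active[nxt != sFg & nxt != sBg]
    }
    ph <- mean(hitFg)
    pHat[p] <- ph
    se[p] <- sqrt(max(ph * (1 - ph), 1 / nWalks) / nWalks)
  }
  list(p = pHat, se = se)
}

# ---- convex hull pixel count by exhaustive point-in-hull test -------------

# a pixel center q is inside the hull of points P iff q is not strictly
# separable: test via sign of cross products around the hull polygon
naiveHullPixelCount <- function(idx) {
  hull <- grDevices::chull(idx[, 2L], idx[, 1L])
  hx <- idx[hull, 2L]; hy <- idx[hull, 1L]
  nh <- length(hull)
  inHull <- function(px, py) {
    sgn <- 0
    for (i in seq_len(nh)) {
      j <- i %% nh + 1L
      cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
      if (abs(cr) < 1e-9) next
      s <- sign(cr)
      if (sgn == 0) sgn <- s else if (s != sgn) return(FALSE)
    }
    TRUE
  }
  cnt <- 0L
  for (r in min(idx[, 1L]):max(idx[, 1L]))
    for (cc in min(idx[, 2L]):max(idx[, 2L]))
      if (inHull(cc, r)) cnt <- cnt + 1L
  cnt
}
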