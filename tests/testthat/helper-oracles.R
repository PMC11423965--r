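# Brute-force oracles for the texture-matrix features: explicit pixel,
# pair, run, zone and neighbourhood enumeration with scalar loops, kept
# deliberately naive and independent of the package's vectorised
# implementations. Intended for small patches (e.g. 8 x 8).

olog2 <- function(p) if (p > 0) log2(p) else 0

# ---- GLCM ------------------------------------------------------------

oracle_glcm_matrix <- function(lev, Ng, dr, dc) {
  P <- matrix(0, Ng, Ng)
  nr <- nrow(lev); nc <- ncol(lev)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        P[lev[r, c], lev[r2, c2]] <- P[lev[r, c], lev[r2, c2]] + 1
        P[lev[r2, c2], lev[r, c]] <- P[lev[r2, c2], lev[r, c]] + 1
      }
    }
  }
  P / sum(P)
}

oracle_glcm_stats <- function(P) {
  Ng <- nrow(P)
  px <- numeric(Ng)
  for (i in 1:Ng) for (j in 1:Ng) px[i] <- px[i] + P[i, j]
  mu <- 0
  for (i in 1:Ng) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:Ng) sig2 <- sig2 + (i - mu)^2 * px[i]

  pd <- numeric(Ng)          # |i-j| = 0 .. Ng-1 at index k+1
  ps <- numeric(2 * Ng)      # i+j = 2 .. 2Ng at index k
  for (i in 1:Ng) for (j in 1:Ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + P[i, j]
    ps[i + j] <- ps[i + j] + P[i, j]
  }
  da <- 0
  for (k in 0:(Ng - 1)) da <- da + k * pd[k + 1]

  acc <- ssq <- cp <- cs <- ct <- contrast <- 0
  id <- idm <- idmn <- idn <- invvar <- jen <- jent <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    acc <- acc + i * j * p
    cp <- cp + (i + j - 2 * mu)^4 * p
    cs <- cs + (i + j - 2 * mu)^3 * p
    ct <- ct + (i + j - 2 * mu)^2 * p
    contrast <- contrast + (i - j)^2 * p
    ssq <- ssq + (i - mu)^2 * p
    id <- id + p / (1 + abs(i - j))
    idm <- idm + p / (1 + (i - j)^2)
    idmn <- idmn + p / (1 + (i - j)^2 / Ng^2)
    idn <- idn + p / (1 + abs(i - j) / Ng)
    if (i != j) invvar <- invvar + p / (i - j)^2
    jen <- jen + p^2
    jent <- jent - p * olog2(p)
  }
  dent <- dvar <- 0
  for (k in 0:(Ng - 1)) {
    dent <- dent - pd[k + 1] * olog2(pd[k + 1])
    dvar <- dvar + (k - da)^2 * pd[k + 1]
  }
  sa <- sent <- 0
  for (k in 2:(2 * Ng)) {
    sa <- sa + k * ps[k]
    sent <- sent - ps[k] * olog2(ps[k])
  }
  hx <- 0
  for (i in 1:Ng) hx <- hx - px[i] * olog2(px[i])
  hxy1 <- hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    hxy1 <- hxy1 - P[i, j] * olog2(px[i] * px[j])
    hxy2 <- hxy2 - px[i] * px[j] * olog2(px[i] * px[j])
  }

  occ <- which(px > 0)
  if (length(occ) > 1) {
    corr <- (acc - mu^2) / sig2
    Q <- matrix(0, length(occ), length(occ))
    for (a in seq_along(occ)) for (b in seq_along(occ)) {
      for (k in occ) {
        Q[a, b] <- Q[a, b] +
          P[occ[a], k] * P[occ[b], k] / (px[occ[a]] * px[k])
      }
    }
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(ev[2], 0))
    imc1 <- if (hx > 0) (jent - hxy1) / hx else 0
    imc2 <- sqrt(max(1 - exp(-2 * (hxy2 - jent)), 0))
  } else {
    corr <- 1; mcc <- 1; imc1 <- 0; imc2 <- 0
  }

  c(Autocorrelation = acc, ClusterProminence = cp, ClusterShade = cs,
    ClusterTendency = ct, Contrast = contrast, Correlation = corr,
    DifferenceAverage = da, DifferenceEntropy = dent,
    DifferenceVariance = dvar, Id = id, Idm = idm, Idmn = idmn, Idn = idn,
    Imc1 = imc1, Imc2 = imc2, InverseVariance = invvar, JointAverage = mu,
    JointEnergy = jen, JointEntropy = jent, MaximumProbability = max(P),
    MCC = mcc, SumAverage = sa, SumEntropy = sent, SumSquares = ssq)
}

oracle_glcm <- function(q) {
  dirs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1))
  acc <- NULL
  for (d in dirs) {
    st <- oracle_glcm_stats(oracle_glcm_matrix(q$levels, q$Ng, d[1], d[2]))
    acc <- if (is.null(acc)) st else acc + st
  }
  out <- acc / length(dirs)
  names(out) <- paste0("glcm_", names(out))
  out
}

# ---- GLRLM -----------------------------------------------------------

# Walk every maximal line in direction (dr, dc) pixel by pixel.
oracle_runs_one_dir <- function(lev, dr, dc) {
  nr <- nrow(lev); nc <- ncol(lev)
  runs <- list()
  starts <- which(matrix(TRUE, nr, nc), arr.ind = TRUE)
  is_start <- function(r, c) {
    pr <- r - dr; pc <- c - dc
    pr < 1 || pr > nr || pc < 1 || pc > nc
  }
  for (k in seq_len(nrow(starts))) {
    r <- starts[k, 1]; c <- starts[k, 2]
    if (!is_start(r, c)) next
    cur <- lev[r, c]; len <- 1
    repeat {
      r2 <- r + dr; c2 <- c + dc
      inside <- r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc
      if (inside && lev[r2, c2] == cur) {
        len <- len + 1
      } else {
        runs[[length(runs) + 1]] <- c(cur, len)
        if (!inside) break
        cur <- lev[r2, c2]; len <- 1
      }
      r <- r2; c <- c2
    }
  }
  do.call(rbind, runs)
}

oracle_glrlm_stats <- function(runs, Ng, np) {
  nrun <- nrow(runs)
  lv <- runs[, 1]; ln <- runs[, 2]
  gi <- numeric(Ng); rj <- numeric(max(ln))
  for (k in seq_len(nrun)) {
    gi[lv[k]] <- gi[lv[k]] + 1
    rj[ln[k]] <- rj[ln[k]] + 1
  }
  mu_i <- sum(lv) / nrun
  mu_r <- sum(ln) / nrun
  ent <- 0
  combo <- table(paste(lv, ln))
  for (cc in as.numeric(combo)) ent <- ent - (cc / nrun) * olog2(cc / nrun)
  c(ShortRunEmphasis = mean(1 / ln^2),
    LongRunEmphasis = mean(ln^2),
    GrayLevelNonUniformity = sum(gi^2) / nrun,
    GrayLevelNonUniformityNormalized = sum(gi^2) / nrun^2,
    RunLengthNonUniformity = sum(rj^2) / nrun,
    RunLengthNonUniformityNormalized = sum(rj^2) / nrun^2,
    RunPercentage = nrun / np,
    GrayLevelVariance = mean((lv - mu_i)^2),
    RunVariance = mean((ln - mu_r)^2),
    RunEntropy = ent,
    LowGrayLevelRunEmphasis = mean(1 / lv^2),
    HighGrayLevelRunEmphasis = mean(lv^2),
    ShortRunLowGrayLevelEmphasis = mean(1 / (lv^2 * ln^2)),
    ShortRunHighGrayLevelEmphasis = mean(lv^2 / ln^2),
    LongRunLowGrayLevelEmphasis = mean(ln^2 / lv^2),
    LongRunHighGrayLevelEmphasis = mean(lv^2 * ln^2))
}

oracle_glrlm <- function(q) {
  dirs <- list(c(0, 1), c(-1, 1), c(1, 0), c(1, 1))
  acc <- NULL
  for (d in dirs) {
    runs <- oracle_runs_one_dir(q$levels, d[1], d[2])
    st <- oracle_glrlm_stats(runs, q$Ng, length(q$levels))
    acc <- if (is.null(acc)) st else acc + st
  }
  out <- acc / length(dirs)
  names(out) <- paste0("glrlm_", names(out))
  out
}

# ---- GLSZM -----------------------------------------------------------

# Flood fill with an explicit stack (8-connectivity).
oracle_zones <- function(lev) {
  nr <- nrow(lev); nc <- ncol(lev)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (seen[r0, c0]) next
    val <- lev[r0, c0]
    stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- cur[1] + dr; c <- cur[2] + dc
        if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
            !seen[r, c] && lev[r, c] == val) {
          seen[r, c] <- TRUE
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
    zones[[length(zones) + 1]] <- c(val, size)
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(q) {
  z <- oracle_zones(q$levels)
  lv <- z[, 1]; sz <- z[, 2]
  nz <- nrow(z); np <- length(q$levels)
  gi <- numeric(q$Ng)
  for (k in seq_len(nz)) gi[lv[k]] <- gi[lv[k]] + 1
  sj <- numeric(max(sz))
  for (k in seq_len(nz)) sj[sz[k]] <- sj[sz[k]] + 1
  ent <- 0
  combo <- table(paste(lv, sz))
  for (cc in as.numeric(combo)) ent <- ent - (cc / nz) * olog2(cc / nz)
  out <- c(SmallAreaEmphasis = mean(1 / sz^2),
           LargeAreaEmphasis = mean(sz^2),
           GrayLevelNonUniformity = sum(gi^2) / nz,
           GrayLevelNonUniformityNormalized = sum(gi^2) / nz^2,
           SizeZoneNonUniformity = sum(sj^2) / nz,
           SizeZoneNonUniformityNormalized = sum(sj^2) / nz^2,
           ZonePercentage = nz / np,
           GrayLevelVariance = mean((lv - mean(lv))^2),
           ZoneVariance = mean((sz - mean(sz))^2),
           ZoneEntropy = ent,
           LowGrayLevelZoneEmphasis = mean(1 / lv^2),
           HighGrayLevelZoneEmphasis = mean(lv^2),
           SmallAreaLowGrayLevelEmphasis = mean(1 / (lv^2 * sz^2)),
           SmallAreaHighGrayLevelEmphasis = mean(lv^2 / sz^2),
           LargeAreaLowGrayLevelEmphasis = mean(sz^2 / lv^2),
           LargeAreaHighGrayLevelEmphasis = mean(lv^2 * sz^2))
  names(out) <- paste0("glszm_", names(out))
  out
}

# ---- NGTDM -----------------------------------------------------------

oracle_ngtdm <- function(q) {
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  np <- nr * nc
  s <- numeric(q$Ng); n <- numeric(q$Ng)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    tot <- 0; cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc) {
        tot <- tot + lev[r2, c2]; cnt <- cnt + 1
      }
    }
    i <- lev[r, c]
    s[i] <- s[i] + abs(i - tot / cnt)
    n[i] <- n[i] + 1
  }
  pres <- which(n > 0)
  p <- n / np
  ngp <- length(pres)
  psum <- sum(p[pres] * s[pres])
  coarse <- if (psum > 0) 1 / psum else 1e6
  contrast <- busy <- compl <- strength <- 0
  if (ngp > 1) {
    for (i in pres) for (j in pres) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      compl <- compl + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
        (p[i] + p[j])
      strength <- strength + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / np
    den <- 0
    for (i in pres) for (j in pres) den <- den + abs(i * p[i] - j * p[j])
    busy <- if (den > 0) psum / den else 0
    compl <- compl / np
    strength <- if (sum(s) > 0) strength / sum(s) else 0
  }
  c(ngtdm_Coarseness = coarse, ngtdm_Contrast = contrast,
    ngtdm_Busyness = busy, ngtdm_Complexity = compl,
    ngtdm_Strength = strength)
}

# ---- GLDM ------------------------------------------------------------

oracle_gldm <- function(q, alpha = 0) {
  lev <- q$levels
  nr <- nrow(lev); nc <- ncol(lev)
  np <- nr * nc
  D <- matrix(0, q$Ng, 9)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    dep <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc &&
          abs(lev[r2, c2] - lev[r, c]) <= alpha) {
        dep <- dep + 1
      }
    }
    D[lev[r, c], dep] <- D[lev[r, c], dep] + 1
  }
  gi <- rowSums(D); dj <- colSums(D)
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(q$Ng)) mu_i <- mu_i + i * gi[i] / np
  for (j in 1:9) mu_j <- mu_j + j * dj[j] / np
  sde <- lde <- glv <- dv <- de <- sdl <- sdh <- ldl <- ldh <- 0
  for (i in seq_len(q$Ng)) for (j in 1:9) {
    d <- D[i, j]; p <- d / np
    sde <- sde + d / j^2
    lde <- lde + d * j^2
    glv <- glv + p * (i - mu_i)^2
    dv <- dv + p * (j - mu_j)^2
    de <- de - p * olog2(p)
    sdl <- sdl + d / (i^2 * j^2)
    sdh <- sdh + d * i^2 / j^2
    ldl <- ldl + d * j^2 / i^2
    ldh <- ldh + d * i^2 * j^2
  }
  lgl <- hgl <- 0
  for (i in seq_len(q$Ng)) {
    lgl <- lgl + gi[i] / i^2
    hgl <- hgl + gi[i] * i^2
  }
  out <- c(SmallDependenceEmphasis = sde / np,
           LargeDependenceEmphasis = lde / np,
           GrayLevelNonUniformity = sum(gi^2) / np,
           DependenceNonUniformity = sum(dj^2) / np,
           DependenceNonUniformityNormalized = sum(dj^2) / np^2,
           GrayLevelVariance = glv,
           DependenceVariance = dv,
           DependenceEntropy = de,
           LowGrayLevelEmphasis = lgl / np,
           HighGrayLevelEmphasis = hgl / np,
           SmallDependenceLowGrayLevelEmphasis = sdl / np,
           SmallDependenceHighGrayLevelEmphasis = sdh / np,
           LargeDependenceLowGrayLevelEmphasis = ldl / np,
           LargeDependenceHighGrayLevelEmphasis = ldh / np)
  names(out) <- paste0("gldm_", names(out))
  out
}

oracle_all_matrix_features <- function(q) {
  c(oracle_glcm(q), oracle_glrlm(q), oracle_glszm(q),
    oracle_ngtdm(q), oracle_gldm(q))
}
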