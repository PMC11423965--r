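#' Gray-level co-occurrence matrix features
#'
#' Builds the symmetric co-occurrence matrix at offset distance 1 for the
#' four 2-D angles (0, 45, 90, 135 degrees), normalises each to a
#' probability matrix, computes the 24 IBSI GLCM statistics per angle, and
#' averages each feature over the angles (feature-level aggregation, not
#' matrix merging).
#'
#' Degenerate conventions (documented, so constant patches stay finite):
#' with a single occupied gray level, Correlation and MCC are 1 and
#' Imc1/Imc2 are 0.
#'
#' @param q a [quantize()]d patch.
#' @param distance pixel offset (default 1).
#' @return named numeric vector of length 24.
#' @export
glcm_features <- function(q, distance = 1L) {
  stopifnot(inherits(q, "quantized_patch"))
  offs <- glcm_offsets(distance)
  mats <- lapply(offs, function(o) cooccurrence_matrix(q$levels, q$Ng, o))
  per_angle <- lapply(mats, glcm_stats_one)
  out <- Reduce(`+`, per_angle) / length(per_angle)
  names(out) <- paste0("glcm_", names(out))
  out
}

# (row, col) offsets for angles 0, 45, 90, 135 degrees at given distance.
glcm_offsets <- function(d = 1L) {
  list(c(0L, d), c(-d, d), c(-d, 0L), c(-d, -d))
}

# Symmetric normalised co-occurrence matrix for one offset.
cooccurrence_matrix <- function(lev, Ng, off) {
  nr <- nrow(lev); nc <- ncol(lev)
  r <- max(1, 1 - off[1]):min(nr, nr - off[1])
  c <- max(1, 1 - off[2]):min(nc, nc - off[2])
  a <- lev[r, c]; b <- lev[r + off[1], c + off[2]]
  m <- matrix(tabulate((a - 1L) * Ng + b, Ng * Ng), Ng, Ng, byrow = TRUE)
  m <- m + t(m)
  m / sum(m)
}

glcm_stats_one <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)            # == py by symmetry
  mu <- sum(seq_len(Ng) * px)
  sig2 <- sum((seq_len(Ng) - mu)^2 * px)
  sig <- sqrt(sig2)

  dvec <- as.vector(abs(i - j))
  pvec <- as.vector(P)
  pd <- as.vector(rowsum(pvec, dvec))            # p_{|x-y|}, k = 0..Ng-1
  kd <- sort(unique(dvec))
  svec <- as.vector(i + j)
  ps <- as.vector(rowsum(pvec, svec))            # p_{x+y}, k = 2..2Ng
  ks <- sort(unique(svec))

  da <- sum(kd * pd)
  hx <- -sum(xlog2(px) * px)
  hxy <- -sum(xlog2(P) * P)
  pxpy <- outer(px, px)
  hxy1 <- -sum(P * xlog2(pxpy))
  hxy2 <- -sum(pxpy * xlog2(pxpy))

  occupied <- which(px > 0)
  if (length(occupied) > 1) {
    corr <- (sum(i * j * P) - mu^2) / sig2
    Po <- P[occupied, occupied, drop = FALSE]
    pxo <- px[occupied]
    M1 <- Po / pxo                                # rows / px(i)
    M2 <- sweep(Po, 2, pxo, "/")                  # cols / py(k)
    Q <- M1 %*% t(M2)
    ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(ev[2], 0))
    imc1 <- if (max(hx, hx) > 0) (hxy - hxy1) / hx else 0
    imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - hxy)), 0))
  } else {
    corr <- 1
    mcc <- 1
    imc1 <- 0
    imc2 <- 0
  }

  c(Autocorrelation = sum(i * j * P),
    ClusterProminence = sum((i + j - 2 * mu)^4 * P),
    ClusterShade = sum((i + j - 2 * mu)^3 * P),
    ClusterTendency = sum((i + j - 2 * mu)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(pd) * pd),
    DifferenceVariance = sum((kd - da)^2 * pd),
    Id = sum(P / (1 + abs(i - j))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + (i - j)^2 / Ng^2)),
    Idn = sum(P / (1 + abs(i - j) / Ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum((P / (i - j)^2)[i != j]),
    JointAverage = mu,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MaximumProbability = max(P),
    MCC = mcc,
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(xlog2(ps) * ps),
    SumSquares = sig2)
}
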