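# Independent brute-force oracles, deliberately naive: plain double loops
# and direct summations, sharing no code with the package internals.

# GLCM by exhaustive pair enumeration over every voxel and offset.
oracle_glcm <- function(patch, offsets, symmetric = TRUE, levels) {
  d <- dim(patch)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
      z2 <- z + o[1]; y2 <- y + o[2]; x2 <- x + o[3]
      if (z2 < 1 || z2 > d[1] || y2 < 1 || y2 > d[2] ||
          x2 < 1 || x2 > d[3]) next
      a <- patch[z, y, x] + 1L
      b <- patch[z2, y2, x2] + 1L
      counts[a, b] <- counts[a, b] + 1
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# Haralick features by direct elementwise summation over the matrix.
oracle_haralick <- function(p) {
  L <- nrow(p)
  contrast <- 0; entropy <- 0; energy <- 0; homog <- 0
  mi <- 0; mj <- 0
  for (i in 1:L) for (j in 1:L) {
    mi <- mi + (i - 1) * p[i, j]
    mj <- mj + (j - 1) * p[i, j]
  }
  vi <- 0; vj <- 0; cov <- 0
  for (i in 1:L) for (j in 1:L) {
    pr <- p[i, j]
    contrast <- contrast + pr * (i - j)^2
    if (pr > 0) entropy <- entropy - pr * log2(pr)
    energy <- energy + pr^2
    homog <- homog + pr / (1 + abs(i - j))
    vi <- vi + (i - 1 - mi)^2 * pr
    vj <- vj + (j - 1 - mj)^2 * pr
    cov <- cov + (i - 1 - mi) * (j - 1 - mj) * pr
  }
  corr <- if (vi > 0 && vj > 0) cov / sqrt(vi * vj) else 0
  c(contrast = contrast, correlation = corr, entropy = entropy,
    energy = energy, homogeneity = homog)
}

# Pearson r and two-sided p from the covariance / t-transform definitions.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), df = n - 2))
}

# RECIST rule table by exhaustive case analysis (independent phrasing).
oracle_recist <- function(ds, mm, gone) {
  if (gone) return("CR")
  pr <- ds <= -30
  pd <- (ds >= 20) && (mm >= 5)
  if (pr) "PR" else if (pd) "PD" else "SD"
}
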