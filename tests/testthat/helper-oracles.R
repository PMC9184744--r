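# Independent brute-force oracles used to cross-check the implementation.
# These deliberately use the most direct formulation (double loops, exhaustive
# scans) and share no code with the package internals.

# Double-loop, overlap-normalized, mean-subtracted autocorrelation.
oracleAcf <- function(cts, maxLagBins) {
  n <- length(cts)
  m <- sum(cts) / n
  v <- sum((cts - m)^2) / n
  vapply(0:maxLagBins, function(l) {
    s <- 0
    for (i in 1:(n - l)) s <- s + (cts[i] - m) * (cts[i + l] - m)
    (s / (n - l)) / v
  }, 0)
}

# Double-loop symmetric-lag cross-correlation (a_i paired with b_{i+l}).
oracleCcf <- function(a, b, maxLagBins) {
  n <- length(a)
  am <- sum(a) / n; bm <- sum(b) / n
  va <- sum((a - am)^2) / n; vb <- sum((b - bm)^2) / n
  vapply(-maxLagBins:maxLagBins, function(l) {
    s <- 0; cnt <- 0
    for (i in 1:n) {
      j <- i + l
      if (j >= 1 && j <= n) {
        s <- s + (a[i] - am) * (b[j] - bm)
        cnt <- cnt + 1
      }
    }
    (s / cnt) / sqrt(va * vb)
  }, 0)
}

# Exhaustive Otsu scan: between-class variance over a 256-bin histogram of
# the observed range, maximized over all candidate thresholds (bin edges).
oracleOtsu <- function(img) {
  rng <- range(img)
  breaks <- seq(rng[1], rng[2], length.out = 257L)
  mids <- (breaks[-1] + breaks[-257]) / 2
  cnt <- vapply(seq_len(256L), function(i) {
    if (i < 256L) sum(img >= breaks[i] & img < breaks[i + 1])
    else sum(img >= breaks[256] & img <= breaks[257])
  }, 0)
  best <- -Inf; bestK <- 1L
  n <- sum(cnt)
  for (k in 1:255) {
    w0 <- sum(cnt[1:k]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / sum(cnt[1:k])
    mu1 <- sum(cnt[(k + 1):256] * mids[(k + 1):256]) / sum(cnt[(k + 1):256])
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) {
      best <- sb
      bestK <- k
    }
  }
  breaks[bestK + 1L]
}

# Brute-force Euclidean distance transform: for each foreground pixel, the
# minimum distance to any background pixel centre (image border padded as
# background).
oracleEdt <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pm <- matrix(FALSE, nr + 2L, nc + 2L)
  pm[2:(nr + 1L), 2:(nc + 1L)] <- mask
  bg <- which(!pm, arr.ind = TRUE)
  out <- matrix(0, nr + 2L, nc + 2L)
  fg <- which(pm, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2))
  }
  out[2:(nr + 1L), 2:(nc + 1L)]
}

# Independent plain NSAF (no shared peptides): (SpC/L) / sum(SpC/L).
oracleNsaf <- function(counts, lengths) {
  saf <- counts / lengths
  saf / sum(saf)
}

# Maximum-cardinality bipartite matching (augmenting paths) on an adjacency
# matrix of admissible (pre, post) pairs.
oracleMaxMatching <- function(adj) {
  n1 <- nrow(adj); n2 <- ncol(adj)
  matchPost <- rep(0L, n2)
  augment <- function(i, seen) {
    for (j in seq_len(n2)) {
      if (adj[i, j] && !seen[j]) {
        seen[j] <- TRUE
        if (matchPost[j] == 0L) {
          matchPost[j] <<- i
          return(TRUE)
        }
        prev <- matchPost[j]
        matchPost[j] <<- i
        if (augment(prev, seen)) return(TRUE)
        matchPost[j] <<- prev
      }
    }
    FALSE
  }
  size <- 0L
  for (i in seq_len(n1)) if (augment(i, rep(FALSE, n2))) size <- size + 1L
  size
}

# Textbook pooled-variance two-sample t-test.
oracleTTest <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Circular distance between two angles in radians.
circDist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  min(d, 2 * pi - d)
}

# A horizontal ribbon mask of a given odd pixel width.
ribbonMask <- function(widthPx, nr = 64L, nc = 120L, pixelSize = 100) {
  m <- matrix(FALSE, nr, nc)
  r0 <- floor(nr / 2) - floor(widthPx / 2)
  m[r0 + seq_len(widthPx) - 1L, ] <- TRUE
  MaskImage(m, pixelSize)
}

# A pure sampled cosine profile with the given period, phase (nm) and span.
cosineProfile <- function(period = 190, phaseNm = 0, binSize = 10,
                          lengthNm = 2000, amplitude = 1, offset = 2) {
  x <- seq(binSize / 2, lengthNm - binSize / 2, by = binSize)
  new("Profile1D", binSize = binSize, origin = 0,
      counts = offset + amplitude * cos(2 * pi * (x - phaseNm) / period),
      label = "cosine")
}
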