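# Independent brute-force oracles and small fixtures used across the tests.
# These deliberately share no code with the package implementation.

mkLayer <- function(z, threshold = NA_real_, band = c(NA_real_, NA_real_)) {
  new("LayerNetwork", z = z, band = band, threshold = threshold)
}

completeGraph <- function(n, w = 1) {
  m <- matrix(w, n, n)
  diag(m) <- 0
  m
}

cycleGraph <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    m[i, j] <- m[j, i] <- 1
  }
  m
}

pathGraph <- function(n) {
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) m[i, i + 1L] <- m[i + 1L, i] <- 1
  m
}

randomWeightedGraph <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (runif(1) < p) m[i, j] <- m[j, i] <- runif(1, 0.5, 2)
    }
  }
  m
}

# --- Welch magnitude-squared coherence, plain loop version -----------------

oracleMscSpectrum <- function(x, y, segLen = 64L) {
  n <- length(x)
  step <- segLen %/% 2L
  starts <- seq.int(1L, n - segLen + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * (0:(segLen - 1L)) / segLen))
  nf <- segLen %/% 2L + 1L
  Sxx <- Syy <- numeric(nf)
  Sxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + segLen - 1L)]
    ys <- y[s:(s + segLen - 1L)]
    X <- fft((xs - mean(xs)) * win)[1:nf]
    Y <- fft((ys - mean(ys)) * win)[1:nf]
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + Y * Conj(X)
  }
  k <- length(starts)
  list(
    coh = Mod(Sxy / k)^2 / ((Sxx / k) * (Syy / k)),
    freqs = (0:(nf - 1L)) / (segLen) # in cycles per sample; scale by fs outside
  )
}

oracleBandCoherence <- function(x, y, trSeconds, edges, segLen = 64L) {
  sp <- oracleMscSpectrum(x, y, segLen)
  freqs <- sp$freqs / trSeconds
  nb <- nrow(edges)
  vapply(seq_len(nb), function(b) {
    keep <- freqs >= edges[b, 1] - 1e-12 & freqs < edges[b, 2] - 1e-12
    if (b == nb) keep <- keep | abs(freqs - edges[b, 2]) <= 1e-12
    mean(sp$coh[keep])
  }, 1)
}

# --- quantum information oracles ------------------------------------------

oracleMatrixLog2 <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  lg <- numeric(length(e$values))
  pos <- e$values > 1e-12
  lg[pos] <- log2(e$values[pos])
  e$vectors %*% diag(lg) %*% t(e$vectors)
}

oracleKL <- function(A, B) sum(diag(A %*% (oracleMatrixLog2(A) - oracleMatrixLog2(B))))

oracleJSD <- function(La, Lb) {
  Lm <- (La + Lb) / 2
  0.5 * oracleKL(La, Lm) + 0.5 * oracleKL(Lb, Lm)
}

oracleRescaledLaplacian <- function(A) (diag(rowSums(A)) - A) / sum(A)

# --- graph descriptor oracles ---------------------------------------------

oracleBarrat <- function(A) {
  n <- nrow(A)
  bin <- A > 0
  deg <- rowSums(bin)
  str <- rowSums(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(bin[i, ])
    tot <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a == b) next
        j <- nb[a]
        h <- nb[b]
        if (bin[j, h]) tot <- tot + (A[i, j] + A[i, h]) / 2
      }
    }
    cc[i] <- tot / (str[i] * (deg[i] - 1))
  }
  list(perNode = cc, meanOverDeg2 = if (any(deg >= 2)) mean(cc[deg >= 2]) else 0)
}

oracleModularity <- function(A, membership) {
  m2 <- sum(A)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

oracleDegreeAssortativity <- function(A) {
  bin <- A > 0
  deg <- rowSums(bin)
  xs <- ys <- numeric(0)
  n <- nrow(A)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (bin[i, j]) {
        xs <- c(xs, deg[i], deg[j])
        ys <- c(ys, deg[j], deg[i])
      }
    }
  }
  suppressWarnings(cor(xs, ys))
}

# --- PageRank eigen oracle -------------------------------------------------

oracleStationary <- function(R) {
  e <- eigen(t(R))
  v <- Re(e$vectors[, which.max(Re(e$values))])
  v / sum(v)
}

# --- misc ------------------------------------------------------------------

oracleSpearman <- function(x, y) cor(rank(x), rank(y))
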