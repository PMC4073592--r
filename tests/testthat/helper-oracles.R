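# Naive reference implementations, kept deliberately loop-based and
# independent of the package's vectorized code paths.

# delay embedding by explicit loops
oracleEmbed <- function(v, delay, dim) {
  n <- length(v) - (dim - 1) * delay
  out <- matrix(NA_real_, n, dim)
  for (t in seq_len(n))
    for (k in seq_len(dim))
      out[t, k] <- v[t + (k - 1) * delay]
  out
}

# element-by-element Euclidean cross distances
oracleDist <- function(A, B) {
  D <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      D[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
  D
}

# maximal run lengths along diagonals/verticals by cell-by-cell scanning
oracleLines <- function(M, kind) {
  lens <- integer()
  if (kind == "diagonal") {
    for (d in seq(-(nrow(M) - 1), ncol(M) - 1)) {
      run <- 0L
      for (i in seq_len(nrow(M))) {
        j <- i + d
        on <- j >= 1 && j <= ncol(M) && M[i, j]
        if (on) run <- run + 1L
        else if (run > 0L) { lens <- c(lens, run); run <- 0L }
      }
      if (run > 0L) lens <- c(lens, run)
    }
  } else {
    for (j in seq_len(ncol(M))) {
      run <- 0L
      for (i in seq_len(nrow(M))) {
        if (M[i, j]) run <- run + 1L
        else if (run > 0L) { lens <- c(lens, run); run <- 0L }
      }
      if (run > 0L) lens <- c(lens, run)
    }
  }
  lens
}

# the full pipeline: embed, distance, threshold, seven measures
oracleCRQA <- function(x, y, delay, dim, radius, minline = 2) {
  A <- oracleEmbed(x, delay, dim)
  B <- oracleEmbed(y, delay, dim)
  M <- oracleDist(A, B) <= radius
  np <- sum(M)
  dl <- oracleLines(M, "diagonal")
  vl <- oracleLines(M, "vertical")
  qd <- dl[dl >= minline]
  qv <- vl[vl >= minline]
  entr <- if (length(qd)) {
    p <- as.numeric(table(qd)) / length(qd)
    -sum(p * log(p))
  } else 0
  list(RR = 100 * np / length(M),
       DET = if (np > 0) 100 * sum(qd) / np else 0,
       L = if (length(qd)) mean(qd) else NaN,
       Lmax = if (length(qd)) max(qd) else NaN,
       ENTR = entr,
       LAM = if (np > 0) 100 * sum(qv) / np else 0,
       TT = if (length(qv)) mean(qv) else NaN)
}

# AMI curve from scratch (equal-width bins over the series range)
oracleAMI <- function(v, maxLag, bins = 10) {
  brk <- seq(min(v), max(v), length.out = bins + 1)
  bin <- findInterval(v, brk, rightmost.closed = TRUE, all.inside = TRUE)
  sapply(0:maxLag, function(l) {
    n <- length(v) - l
    joint <- matrix(0, bins, bins)
    for (t in seq_len(n))
      joint[bin[t], bin[t + l]] <- joint[bin[t], bin[t + l]] + 1
    joint <- joint / n
    pa <- rowSums(joint); pb <- colSums(joint)
    s <- 0
    for (a in seq_len(bins)) for (b in seq_len(bins))
      if (joint[a, b] > 0)
        s <- s + joint[a, b] * log(joint[a, b] / (pa[a] * pb[b]))
    s
  })
}

# first prominent minimum of an AMI curve (curve[1] is lag 0): lower by
# 1% of the curve range than every value within +-3 lags
firstLocalMin <- function(curve) {
  tie <- 0.01 * (max(curve) - min(curve))
  maxLag <- length(curve) - 1
  for (l in 1:maxLag) {
    ok <- TRUE
    for (nb in max(0, l - 3):min(maxLag, l + 3)) {
      if (nb == l) next
      if (!(curve[l + 1] < curve[nb + 1] - tie)) { ok <- FALSE; break }
    }
    if (ok) return(l)
  }
  NA_integer_
}

# per-measure absolute differences normalized to [0, 1]; NaN pairs count 0
measureDiff <- function(a, b, n) {
  nrm <- c(RR = 100, DET = 100, L = n, Lmax = n, ENTR = log(n),
           LAM = 100, TT = n)
  vapply(names(nrm), function(k) {
    va <- a[[k]]; vb <- b[[k]]
    if (is.nan(va) && is.nan(vb)) return(0)
    abs(va - vb) / nrm[[k]]
  }, numeric(1))
}

# stationary event rate of the self-exciting binary chain
markovRate <- function(p, prep) p / (1 - (1 - p) * prep)
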