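# Independent brute-force oracles: literal formula evaluation by explicit
# loops, sharing no code with the package's compiled kernels.

oracle_reflect <- function(i, n) {
  while (i < 0 || i >= n) {
    if (i < 0) i <- -i
    if (i >= n) i <- 2 * n - 2 - i
  }
  i
}

oracle_quantize <- function(g, ng) pmin(floor(g * ng / 256), ng - 1)

oracle_fos <- function(w) {
  n <- length(w)
  m <- sum(w) / n
  v <- sum((w - m)^2) / n
  s <- sqrt(v)
  if (v == 0) return(c(m, 0, 0, 0, 0))
  c(m, v, s,
    sum(((w - m) / s)^4) / n - 3,
    sum(((w - m) / s)^3) / n)
}

oracle_theta_offset <- function(theta, d = 1) {
  switch(as.character(theta),
         "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
}

# enumerate every pixel pair at the offset, evaluate each Haralick formula
# over the full Ng x Ng probability matrix
oracle_glcm <- function(w, d = 1, theta = 135, ng = 16, symmetric = FALSE) {
  K <- nrow(w)
  q <- matrix(oracle_quantize(w, ng), K, K)
  off <- oracle_theta_offset(theta, d)
  P <- matrix(0, ng, ng)
  for (r in seq_len(K)) for (c in seq_len(K)) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 < 1 || r2 > K || c2 < 1 || c2 > K) next
    i <- q[r, c] + 1; j <- q[r2, c2] + 1
    P[i, j] <- P[i, j] + 1
    if (symmetric) P[j, i] <- P[j, i] + 1
  }
  stopifnot(sum(P) > 0)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  xlog <- function(v) ifelse(v > 0, v * log(v), 0)
  f <- numeric(17)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    p <- P[i, j]
    f[1] <- f[1] + i * j * p
    f[2] <- f[2] + (i - j)^2 * p
    f[3] <- f[3] + (i + j - mux - muy)^4 * p
    f[4] <- f[4] + (i + j - mux - muy)^3 * p
    f[5] <- f[5] + abs(i - j) * p
    f[6] <- f[6] + p^2
    f[8] <- f[8] + p / (1 + (i - j)^2)
    f[10] <- f[10] + (i - mux)^2 * p
    f[17] <- f[17] + p / (1 + (i - j)^2 / ng^2)
  }
  f[7] <- -sum(xlog(P))
  f[9] <- max(P)
  psum <- numeric(2 * ng)
  pdiff <- numeric(ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    psum[i + j] <- psum[i + j] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  f[11] <- sum(seq_len(2 * ng) * psum)
  f[12] <- sum((seq_len(2 * ng) - f[11])^2 * psum)
  f[13] <- -sum(xlog(psum))
  dmean <- sum((0:(ng - 1)) * pdiff)
  f[14] <- sum(((0:(ng - 1)) - dmean)^2 * pdiff)
  f[15] <- -sum(xlog(pdiff))
  hx <- -sum(xlog(px)); hy <- -sum(xlog(py))
  hxy1 <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng))
    if (P[i, j] > 0 && px[i] * py[j] > 0)
      hxy1 <- hxy1 - P[i, j] * log(px[i] * py[j])
  f[16] <- if (max(hx, hy) > 0) (f[7] - hxy1) / max(hx, hy) else 0
  f
}

# literal Laws vectors, outer products averaged with the transpose,
# nested-loop correlation over the reflect-padded window
oracle_lem <- function(w) {
  K <- nrow(w)
  v <- list(l5 = c(1, 4, 6, 4, 1), e5 = c(-1, -2, 0, 2, 1),
            s5 = c(-1, 0, 2, 0, -1), r5 = c(1, -4, 6, -4, 1))
  pairs <- list(c("e5", "l5"), c("s5", "l5"), c("r5", "l5"), c("e5", "e5"),
                c("s5", "e5"), c("r5", "e5"), c("s5", "s5"), c("r5", "s5"),
                c("r5", "r5"))
  mss <- mas <- numeric(9)
  for (m in seq_along(pairs)) {
    M <- outer(v[[pairs[[m]][1]]], v[[pairs[[m]][2]]])
    M <- (M + t(M)) / 2
    resp <- matrix(0, K, K)
    for (r in 0:(K - 1)) for (c in 0:(K - 1)) {
      acc <- 0
      for (a in -2:2) for (b in -2:2)
        acc <- acc + M[a + 3, b + 3] *
          w[oracle_reflect(r + a, K) + 1, oracle_reflect(c + b, K) + 1]
      resp[r + 1, c + 1] <- acc
    }
    mss[m] <- sum(resp^2) / (K * K)
    mas[m] <- sum(abs(resp)) / (K * K)
  }
  c(mss, mas)
}

# scan-line run extraction, then literal run-length formulas
oracle_glrlm <- function(w, theta = 0, ng = 16) {
  K <- nrow(w)
  q <- matrix(oracle_quantize(w, ng), K, K)
  lines <- switch(as.character(theta),
    "0" = lapply(seq_len(K), function(r) q[r, ]),
    "90" = lapply(seq_len(K), function(c) q[, c]),
    "45" = lapply(seq(-K + 1, K - 1), function(o) {
      cells <- which(col(q) - (K + 1 - row(q)) == o, arr.ind = TRUE)
      cells <- cells[order(-cells[, 1]), , drop = FALSE]
      q[cells]
    }),
    "135" = lapply(seq(-K + 1, K - 1), function(o) {
      cells <- which(col(q) - row(q) == o, arr.ind = TRUE)
      cells <- cells[order(cells[, 1]), , drop = FALSE]
      q[cells]
    }))
  counts <- matrix(0, ng, K)
  for (ln in lines) {
    r <- rle(as.vector(ln))
    for (k in seq_along(r$lengths))
      counts[r$values[k] + 1, r$lengths[k]] <-
        counts[r$values[k] + 1, r$lengths[k]] + 1
  }
  nr <- sum(counts); np <- K * K
  f <- numeric(11)
  for (i in seq_len(ng)) for (j in seq_len(K)) {
    p <- counts[i, j]
    if (p == 0) next
    f[1] <- f[1] + p / j^2;        f[2] <- f[2] + p * j^2
    f[6] <- f[6] + p / i^2;        f[7] <- f[7] + p * i^2
    f[8] <- f[8] + p / (i^2 * j^2); f[9] <- f[9] + p * i^2 / j^2
    f[10] <- f[10] + p * j^2 / i^2; f[11] <- f[11] + p * i^2 * j^2
  }
  f[3] <- sum(rowSums(counts)^2)
  f[4] <- sum(colSums(counts)^2)
  out <- f / nr
  out[5] <- nr / np
  out
}

# bitwise evaluation in the documented order (clockwise from top-left)
oracle_lbp <- function(w3) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  gc <- w3[2, 2]
  s <- vapply(offs, function(o) as.integer(w3[2 + o[1], 2 + o[2]] - gc >= 0),
              integer(1))
  basic <- sum(s * 2^(0:7))
  u <- abs(s[8] - s[1]) + sum(abs(diff(s)))
  c(basic, if (u <= 2) sum(s) else 9)
}

oracle_all54 <- function(w5, w3, cfg = list()) {
  d <- cfg$glcm_d %||% 1; th <- cfg$glcm_theta %||% 135
  ng <- cfg$glcm_levels %||% 16; sym <- cfg$glcm_symmetric %||% FALSE
  rth <- cfg$glrlm_theta %||% 0; rng <- cfg$glrlm_levels %||% 16
  c(w5[3, 3], oracle_fos(w5), oracle_glcm(w5, d, th, ng, sym),
    oracle_lem(w5), oracle_glrlm(w5, rth, rng), oracle_lbp(w3))
}

# tie-adjusted pairwise concordance: mean over positive-negative pairs of
# [s_pos > s_neg] + 0.5 [tie]
oracle_auc <- function(scores, truth) {
  sp <- scores[truth]; sn <- scores[!truth]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

random_window <- function(k = 5) {
  matrix(sample(0:255, k * k, replace = TRUE), k, k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
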