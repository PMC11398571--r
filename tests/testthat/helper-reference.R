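# Naive double-loop reference implementations used as independent oracles
# for the vectorized scorers. They mirror the documented contract arithmetic
# (integer mismatch counts, per-side normalization, deferred division) with
# explicit loops and linear-scan neighbor selection, so agreement with the
# package implementations is required to be exact.

ref_distances <- function(x) {
  n <- nrow(x)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- 0
    for (a in seq_len(ncol(x))) if (x[i, a] != x[j, a]) d <- d + 1
    D[i, j] <- d
  }
  D
}

# pick m candidates by ascending (distance, index), one linear scan per pick
ref_select <- function(cands, d, m) {
  sel <- integer(0)
  remaining <- cands
  dr <- d
  for (s in seq_len(m)) {
    best <- 1L
    for (j in seq_along(remaining)) {
      if (dr[j] < dr[best] ||
          (dr[j] == dr[best] && remaining[j] < remaining[best])) best <- j
    }
    sel <- c(sel, remaining[best])
    remaining <- remaining[-best]
    dr <- dr[-best]
  }
  sel
}

ref_relieff <- function(x, y, nn) {
  n <- nrow(x)
  f <- ncol(x)
  D <- ref_distances(x)
  n0 <- sum(y == 0)
  n1 <- sum(y == 1)
  nn_use <- min(nn, n0 - 1, n1 - 1, n0, n1)
  acc <- numeric(f)
  for (i in seq_len(n)) {
    same <- integer(0)
    opp <- integer(0)
    for (j in seq_len(n)) {
      if (j == i) next
      if (y[j] == y[i]) same <- c(same, j) else opp <- c(opp, j)
    }
    sel_h <- ref_select(same, D[i, same], min(nn_use, length(same)))
    sel_m <- ref_select(opp, D[i, opp], min(nn_use, length(opp)))
    for (a in seq_len(f)) {
      for (j in sel_h) if (x[j, a] != x[i, a]) acc[a] <- acc[a] - 1
      for (j in sel_m) if (x[j, a] != x[i, a]) acc[a] <- acc[a] + 1
    }
  }
  acc / (n * nn_use)
}

ref_surf <- function(x, y, far) {
  n <- nrow(x)
  f <- ncol(x)
  D <- ref_distances(x)
  m <- n - 1
  W <- numeric(f)
  for (i in seq_len(n)) {
    s <- 0
    ssq <- 0
    for (j in seq_len(n)) if (j != i) {
      s <- s + D[i, j]
      ssq <- ssq + D[i, j] * D[i, j]
    }
    Ti <- s / m
    v <- (ssq - s * s / m) / (m - 1)
    if (v < 0) v <- 0
    dead <- sqrt(v) / 2
    nh <- nm <- fh <- fm <- integer(0)
    for (j in seq_len(n)) {
      if (j == i) next
      if (D[i, j] < Ti - dead) {
        if (y[j] == y[i]) nh <- c(nh, j) else nm <- c(nm, j)
      } else if (D[i, j] > Ti + dead) {
        if (y[j] == y[i]) fh <- c(fh, j) else fm <- c(fm, j)
      }
    }
    for (a in seq_len(f)) {
      mm <- 0; hm <- 0
      for (j in nm) if (x[j, a] != x[i, a]) mm <- mm + 1
      for (j in nh) if (x[j, a] != x[i, a]) hm <- hm + 1
      cN <- 0
      if (length(nm) > 0) cN <- mm / length(nm)
      if (length(nh) > 0) cN <- cN - hm / length(nh)
      contrib <- cN
      if (far) {
        fhm <- 0; fmm <- 0
        for (j in fh) if (x[j, a] != x[i, a]) fhm <- fhm + 1
        for (j in fm) if (x[j, a] != x[i, a]) fmm <- fmm + 1
        cF <- 0
        if (length(fh) > 0) cF <- fhm / length(fh)
        if (length(fm) > 0) cF <- cF - fmm / length(fm)
        contrib <- (cN + cF) / 2
      }
      W[a] <- W[a] + contrib
    }
  }
  W / n
}

# random small dataset with at least two instances per class
random_dataset <- function(n, f, seed) {
  set.seed(seed)
  repeat {
    x <- matrix(sample(0:2, n * f, TRUE), n, f)
    y <- sample(0:1, n, TRUE)
    if (min(sum(y == 0), sum(y == 1)) >= 2) break
  }
  snp_dataset(x, y, paste0("F", seq_len(f)), "F1")
}
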