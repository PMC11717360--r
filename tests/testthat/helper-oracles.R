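# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (loops, definitions applied
# literally) so they share no code path with the package implementation.

# --- peak-finding oracle: MATLAB findpeaks semantics by direct definition ---
oracle_find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L   # plateau
      if (j < n && x[j + 1L] < x[i]) cand <- c(cand, i)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(cand)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- numeric(length(cand))
  for (k in seq_along(cand)) {
    p <- cand[k]; h <- x[p]
    lo <- 1L
    for (j in seq(p - 1L, 1L)) if (x[j] > h) { lo <- j + 1L; break }
    hi <- n
    for (j in seq(p + 1L, n)) if (x[j] > h) { hi <- j - 1L; break }
    lmin <- min(x[lo:(p - 1L)])
    rmin <- min(x[(p + 1L):hi])
    prom[k] <- h - max(lmin, rmin)
  }
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) {
    return(data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  ord <- order(-x[cand], cand)
  acc <- integer(0)
  for (k in ord) {
    ok <- TRUE
    for (a in acc) if (abs(cand[a] - cand[k]) < min_distance) { ok <- FALSE; break }
    if (ok) acc <- c(acc, k)
  }
  acc <- acc[order(cand[acc])]
  data.frame(index = cand[acc], height = x[cand[acc]], prominence = prom[acc])
}

# random slope-like test series: smoothed random walk, length n
random_walk_series <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n))
  stats::filter(x, rep(1 / 5, 5), sides = 2) -> y
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

# --- Savitzky-Golay oracle: local polynomial LSQ fit at one position ---
oracle_savgol_at <- function(x, pos, order, frame) {
  n <- length(x)
  half <- (frame - 1) / 2
  if (pos <= half) {            # startup transient: fit the first frame
    idx <- 1:frame; t0 <- pos
  } else if (pos > n - half) {  # ending transient: fit the last frame
    idx <- (n - frame + 1):n; t0 <- pos
  } else {
    idx <- (pos - half):(pos + half); t0 <- pos
  }
  fit <- lm(y ~ poly(t, order, raw = TRUE),
            data = data.frame(t = idx - t0, y = x[idx]))
  unname(predict(fit, newdata = data.frame(t = 0)))
}

# --- Mann-Whitney U oracle: count discordant pairs ---
oracle_u_stat <- function(a, b) {
  u <- 0
  for (ai in a) for (bi in b) u <- u + (ai > bi) + 0.5 * (ai == bi)
  u
}

# --- Spearman oracle: explicit rank formula with average ties ---
oracle_spearman_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  num / sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# --- dense-grid HPDI oracle: water-filling on the prevalence posterior ---
oracle_hpdi_grid <- function(k, n, alpha, level, npts = 1e6) {
  g <- seq(0, 1, length.out = npts)
  th <- alpha + g * (1 - alpha)
  d <- dbeta(th, k + 1, n - k + 1)
  w <- d / sum(d)
  ord <- order(-d)
  cum <- cumsum(w[ord])
  inset <- ord[seq_len(which(cum >= level)[1])]
  c(min(g[inset]), max(g[inset]))
}

# --- toy hypnogram builders ---
hyp_from_runs <- function(..., epoch_length = 30) {
  runs <- list(...)
  stages <- unlist(lapply(runs, function(r) rep(r[[1]], r[[2]])))
  hypnogram(stages, epoch_length = epoch_length)
}

# two textbook cycles: [N1 x4, N2 x60, SWS x40, REM x20] twice (30 s epochs)
toy_two_cycle_hyp <- function() {
  one <- c(rep("N1", 4), rep("N2", 60), rep("SWS", 40), rep("REM", 20))
  hypnogram(c(one, one), epoch_length = 30)
}
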