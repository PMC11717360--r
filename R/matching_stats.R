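# Fractal-to-classical cycle matching and the statistical toolkit:
# Spearman and partial rank correlations, Mann-Whitney / Wilcoxon tests,
# Cohen's d, person-centered effect sizes and Bayesian population
# prevalence (MAP + highest posterior density interval).

#' Match fractal to classical cycles by temporal overlap
#'
#' Greedy one-to-one assignment by descending overlap on the shared epoch
#' grid; a pair is valid if the overlap covers at least `min_overlap` of the
#' shorter cycle. The matching criterion is an operationalization of
#' "approximately coinciding" cycle timings and is deliberately exposed as a
#' parameter.
#'
#' @param fractal,classical cycle `data.frame`s with `start_epoch` /
#'   `end_epoch` columns (half-open, same epoch grid).
#' @param min_overlap minimum overlap as a fraction of the shorter cycle.
#' @return List of class `cycle_match`: `$pairs`
#'   (`fractal_cycle`, `classical_cycle`, `overlap_epochs`),
#'   `$matched_fraction` (of fractal cycles), `$one_to_one`.
#' @export
match_cycles <- function(fractal, classical, min_overlap = 0.5) {
  nf <- nrow(fractal); nc <- nrow(classical)
  pairs <- data.frame(fractal_cycle = integer(0), classical_cycle = integer(0),
                      overlap_epochs = numeric(0))
  if (nf && nc) {
    cand <- expand.grid(f = seq_len(nf), c = seq_len(nc))
    ov <- pmax(0, pmin(fractal$end_epoch[cand$f], classical$end_epoch[cand$c]) -
                  pmax(fractal$start_epoch[cand$f], classical$start_epoch[cand$c]))
    shorter <- pmin(fractal$end_epoch[cand$f] - fractal$start_epoch[cand$f],
                    classical$end_epoch[cand$c] - classical$start_epoch[cand$c])
    keep <- ov >= min_overlap * shorter & ov > 0
    cand <- cand[keep, , drop = FALSE]; ov <- ov[keep]
    ord <- order(-ov, cand$f, cand$c)
    used_f <- logical(nf); used_c <- logical(nc)
    for (i in ord) {
      f <- cand$f[i]; c <- cand$c[i]
      if (!used_f[f] && !used_c[c]) {
        used_f[f] <- TRUE; used_c[c] <- TRUE
        pairs <- rbind(pairs, data.frame(fractal_cycle = f, classical_cycle = c,
                                         overlap_epochs = ov[i]))
      }
    }
    pairs <- pairs[order(pairs$fractal_cycle), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs,
                 matched_fraction = if (nf) nrow(pairs) / nf else NA_real_,
                 one_to_one = nf == nc && nf > 0 && nrow(pairs) == nf),
            class = "cycle_match")
}

#' @export
print.cycle_match <- function(x, ...) {
  cat("Cycle match:", nrow(x$pairs), "pair(s), matched fraction",
      round(x$matched_fraction, 3),
      if (x$one_to_one) "(one-to-one)\n" else "\n")
  invisible(x)
}

rank_avg <- function(x) rank(x, ties.method = "average")

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value from the large-sample t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 4.
#' @return `list(rho, p, n)`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  rho <- stats::cor(rank_avg(x), rank_avg(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Partial Spearman correlation
#'
#' Rank-transforms all three variables and computes the partial Pearson
#' correlation of x and y given z on the ranks; p from the t approximation
#' with n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length >= 5; `z` is the covariate.
#' @return `list(rho, p, n)`.
#' @export
partial_spearman <- function(x, y, z) {
  if (length(unique(c(length(x), length(y), length(z)))) != 1) {
    stop("x, y and z must have equal length", call. = FALSE)
  }
  ok <- !is.na(x) & !is.na(y) & !is.na(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete triples", call. = FALSE)
  if (stats::sd(z) == 0) stop("degenerate covariate: zero variance", call. = FALSE)
  rx <- rank_avg(x); ry <- rank_avg(y); rz <- rank_avg(z)
  rxy <- stats::cor(rx, ry); rxz <- stats::cor(rx, rz); ryz <- stats::cor(ry, rz)
  denom <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (denom == 0) stop("covariate collinear with x or y", call. = FALSE)
  rho <- (rxy - rxz * ryz) / denom
  rho <- max(-1, min(1, rho))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 3) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 3)
  }
  list(rho = rho, p = p, n = n)
}

#' Mann-Whitney U test (two independent samples)
#'
#' Exact U statistic; p-value by exact enumeration for small samples (both
#' n < 25, no ties) and by the normal approximation with continuity and tie
#' corrections otherwise.
#'
#' @param a,b numeric samples.
#' @return `list(U, p)`.
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0
  ex <- length(a) < 25 && length(b) < 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = ex, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

#' Paired-samples Wilcoxon signed-rank test
#'
#' @param a,b equal-length paired samples.
#' @return `list(W, p)`.
#' @export
wilcoxon_paired <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  if (length(a) != length(b)) stop("paired samples must have equal length",
                                   call. = FALSE)
  d <- a - b
  ties <- anyDuplicated(abs(d[d != 0])) > 0 || any(d == 0)
  ex <- length(a) < 25 && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, exact = ex,
                                            correct = TRUE))
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Cohen's d with pooled standard deviation
#'
#' @param a,b numeric samples.
#' @return `d = (mean(a) - mean(b)) / pooled sd`.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per sample",
                                           call. = FALSE)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

check_prevalence_args <- function(k, n, alpha) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
}

#' Maximum a posteriori Bayesian population prevalence
#'
#' Under the prevalence model the per-test success probability is
#' `theta = alpha + gamma * (1 - alpha)`, where `gamma` is the population
#' prevalence of the effect (uniform prior) and `alpha` the false-positive
#' rate of the test. Given k significant of n independent tests the MAP
#' estimate is `(k/n - alpha) / (1 - alpha)`, clamped to `[0, 1]`.
#'
#' @param k number of significant tests.
#' @param n total number of tests.
#' @param alpha false-positive rate of each test.
#' @return MAP prevalence, a proportion in `[0, 1]`.
#' @export
prevalence_map <- function(k, n, alpha = 0.05) {
  check_prevalence_args(k, n, alpha)
  min(1, max(0, (k / n - alpha) / (1 - alpha)))
}

#' Highest posterior density interval for Bayesian prevalence
#'
#' The posterior on `theta` is Beta(k+1, n-k+1) truncated to `[alpha, 1]`,
#' mapped to prevalence through `gamma = (theta - alpha) / (1 - alpha)`. The
#' HPD interval at mass `level` is found by bisecting on the posterior
#' density threshold, locating the two density crossings by root search and
#' measuring the enclosed mass exactly with the Beta CDF.
#'
#' @param k,n,alpha as in [prevalence_map()].
#' @param level posterior mass of the interval, in (0, 1); as `level -> 0`
#'   the interval collapses onto the MAP point.
#' @param tol convergence tolerance on the enclosed mass.
#' @return `list(lower, upper, level)` on the prevalence scale.
#' @export
prevalence_hpdi <- function(k, n, alpha = 0.05, level = 0.96, tol = 1e-8) {
  check_prevalence_args(k, n, alpha)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)", call. = FALSE)
  a <- k + 1; b <- n - k + 1
  z <- 1 - stats::pbeta(alpha, a, b)          # truncated posterior mass
  if (z <= 0) stop("posterior mass entirely below alpha", call. = FALSE)
  theta_of <- function(g) alpha + g * (1 - alpha)
  dens <- function(g) stats::dbeta(theta_of(g), a, b) * (1 - alpha) / z
  mass <- function(glo, ghi) {
    (stats::pbeta(theta_of(ghi), a, b) - stats::pbeta(theta_of(glo), a, b)) / z
  }
  # posterior mode on the gamma scale
  theta_mode <- if (a + b > 2) (a - 1) / (a + b - 2) else 0.5
  gmode <- min(1, max(0, (theta_mode - alpha) / (1 - alpha)))
  dmax <- dens(gmode)
  interval_at <- function(cc) {
    lo <- if (dens(0) >= cc) 0 else
      stats::uniroot(function(g) dens(g) - cc, c(0, gmode), tol = 1e-12)$root
    hi <- if (dens(1) >= cc) 1 else
      stats::uniroot(function(g) dens(g) - cc, c(gmode, 1), tol = 1e-12)$root
    c(lo, hi)
  }
  clo <- 0; chi <- dmax
  for (it in 1:200) {
    cc <- (clo + chi) / 2
    iv <- interval_at(cc)
    m <- mass(iv[1], iv[2])
    if (abs(m - level) < tol) break
    if (m > level) clo <- cc else chi <- cc
  }
  iv <- interval_at((clo + chi) / 2)
  list(lower = iv[1], upper = iv[2], level = level)
}

#' Person-centered effect size: sample prevalence of significant tests
#'
#' Fraction of per-subject p-values below `alpha` ("how many participants
#' individually show the effect").
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param alpha significance threshold.
#' @return Proportion in `[0, 1]`.
#' @export
person_centered_prevalence <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]",
                                             call. = FALSE)
  mean(p < alpha, na.rm = TRUE)
}
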