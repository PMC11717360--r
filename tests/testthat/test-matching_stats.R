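# Cycle matching, rank statistics, effect sizes, Bayesian prevalence.

cycles_df <- function(starts, ends) {
  data.frame(cycle = seq_along(starts), start_epoch = starts, end_epoch = ends)
}

test_that("identical cycle lists match one-to-one", {
  a <- cycles_df(c(0, 180, 360), c(180, 360, 540))
  m <- match_cycles(a, a)
  expect_equal(m$matched_fraction, 1)
  expect_true(m$one_to_one)
  expect_identical(m$pairs$fractal_cycle, m$pairs$classical_cycle)
})

test_that("a nested cycle pairs with its container only", {
  f <- cycles_df(50, 150)                     # inside classical cycle 1
  c <- cycles_df(c(0, 200), c(180, 380))
  m <- match_cycles(f, c)
  expect_identical(nrow(m$pairs), 1L)
  expect_identical(m$pairs$classical_cycle, 1L)
})

test_that("an extra wake-induced fractal peak leaves one cycle unmatched", {
  # 5 fractal cycles vs 4 classical: the 3rd classical cycle is covered by
  # two short fractal cycles; greedy overlap keeps the better one
  f <- cycles_df(c(0, 180, 360, 450, 540), c(180, 360, 450, 540, 720))
  c <- cycles_df(c(0, 180, 360, 540), c(180, 360, 540, 720))
  m <- match_cycles(f, c)
  expect_identical(nrow(m$pairs), 4L)
  expect_equal(m$matched_fraction, 0.8)
  expect_false(m$one_to_one)
  # hand-derived best assignment: f3 (90 epochs in c3) beats f4's overlap
  expect_true(all(c(1, 2, 3, 5) %in% m$pairs$fractal_cycle))
})

test_that("matching is symmetric in the two lists", {
  set.seed(81)
  for (i in 1:10) {
    bounds_a <- sort(sample(0:400, 5)); bounds_b <- sort(sample(0:400, 6))
    a <- cycles_df(head(bounds_a, -1), tail(bounds_a, -1))
    b <- cycles_df(head(bounds_b, -1), tail(bounds_b, -1))
    m1 <- match_cycles(a, b)
    m2 <- match_cycles(b, a)
    p1 <- paste(m1$pairs$fractal_cycle, m1$pairs$classical_cycle)
    p2 <- paste(m2$pairs$classical_cycle, m2$pairs$fractal_cycle)
    expect_setequal(p1, p2)
  }
})

test_that("below-threshold overlap does not pair", {
  f <- cycles_df(0, 100)
  c <- cycles_df(60, 260)          # overlap 40 of shorter 100 < 50%
  expect_identical(nrow(match_cycles(f, c)$pairs), 0L)
  expect_identical(nrow(match_cycles(f, c, min_overlap = 0.3)$pairs), 1L)
})

test_that("spearman handles monotone, reversed and random inputs", {
  x <- c(1, 4, 9, 12, 20)
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, x^3)$p, 0)
  expect_equal(spearman(x, rev(x))$rho, -1)
  set.seed(91)
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50)
    got <- spearman(a, b)
    expect_equal(got$rho, oracle_spearman_rho(a, b), tolerance = 1e-12)
    expect_equal(got$rho, cor(a, b, method = "spearman"), tolerance = 1e-12)
    # ties handled by average ranks
    at <- round(a); bt <- round(b)
    expect_equal(spearman(at, bt)$rho, cor(at, bt, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(spearman(1:5, 1:4), "equal length")
  expect_error(spearman(1:3, 3:1), "at least 4")
})

test_that("partial spearman removes a shared covariate", {
  set.seed(92)
  # independent covariate: partial ~ plain
  x <- rnorm(400); y <- 0.5 * x + rnorm(400); z <- rnorm(400)
  expect_lt(abs(partial_spearman(x, y, z)$rho - spearman(x, y)$rho), 0.05)
  # y == z: nothing left after conditioning
  expect_lt(abs(partial_spearman(x, y, y)$rho), 1e-6)
  # textbook 3-variable fixture against the closed-form oracle on ranks
  x3 <- c(12, 8, 15, 9, 11, 14, 7, 10)
  y3 <- c(20, 14, 24, 16, 18, 22, 13, 17)
  z3 <- c(5, 3, 7, 4, 4, 6, 2, 5)
  rx <- rank(x3); ry <- rank(y3); rz <- rank(z3)
  want <- (cor(rx, ry) - cor(rx, rz) * cor(ry, rz)) /
    sqrt((1 - cor(rx, rz)^2) * (1 - cor(ry, rz)^2))
  expect_equal(partial_spearman(x3, y3, z3)$rho, want, tolerance = 1e-12)
  expect_error(partial_spearman(x3, y3, rep(1, 8)), "degenerate covariate")
})

test_that("rank tests match exhaustive small-sample enumeration", {
  expect_equal(mann_whitney(c(1, 2, 3), c(4, 5, 6))$U, 0)
  set.seed(93)
  for (i in 1:10) {
    a <- rnorm(sample(4:8, 1)); b <- rnorm(sample(4:8, 1))
    got <- mann_whitney(a, b)
    expect_equal(got$U, oracle_u_stat(a, b))
    # exact p by enumeration over all reassignments of the pooled sample
    pool <- c(a, b); na <- length(a)
    combs <- combn(length(pool), na)
    us <- apply(combs, 2, function(ix) oracle_u_stat(pool[ix], pool[-ix]))
    u_obs <- oracle_u_stat(a, b)
    m <- length(a) * length(b)
    p_exact <- mean(pmin(us, m - us) <= min(u_obs, m - u_obs))
    expect_equal(got$p, p_exact, tolerance = 1e-10)
  }
})

test_that("paired wilcoxon and cohens_d behave on canonical inputs", {
  a <- c(5.1, 4.8, 6.0, 5.5, 5.9, 4.2, 5.0, 6.1)
  expect_equal(cohens_d(a, a), 0)
  b <- a + c(0.4, 0.6, 0.2, 0.5, 0.3, 0.7, 0.45, 0.55)
  w <- wilcoxon_paired(a, b)
  expect_equal(w$W, 0)                       # all differences negative
  expect_lt(w$p, 0.01)
  expect_error(wilcoxon_paired(a, b[-1]), "equal length")
  expect_error(mann_whitney(numeric(0), a), "empty")
  # d with pooled sd against the direct formula
  x <- c(10, 12, 14, 16); y <- c(9, 11, 13, 15, 17)
  sp <- sqrt((3 * var(x) + 4 * var(y)) / 7)
  expect_equal(cohens_d(x, y), (mean(x) - mean(y)) / sp)
})

test_that("MAP prevalence follows the thresholded-binomial model", {
  expect_equal(prevalence_map(47, 940, 0.05), 0)        # k/n = alpha
  expect_equal(prevalence_map(940, 940, 0.05), 1)
  expect_equal(prevalence_map(0, 100, 0.05), 0)
  # monotone in k
  ks <- seq(0, 940, by = 47)
  expect_true(all(diff(sapply(ks, prevalence_map, n = 940)) >= 0))
  expect_error(prevalence_map(10, 0), "positive")
  expect_error(prevalence_map(-1, 10), "\\[0, n\\]")
  expect_error(prevalence_map(5, 10, alpha = 1.2), "\\(0, 1\\)")
})

test_that("HPDI matches a dense-grid posterior oracle and shrinks with n", {
  for (case in list(c(763, 940), c(111, 205), c(30, 40))) {
    got <- prevalence_hpdi(case[1], case[2], 0.05, 0.96)
    want <- oracle_hpdi_grid(case[1], case[2], 0.05, 0.96)
    expect_lt(abs(got$lower - want[1]), 1e-3)
    expect_lt(abs(got$upper - want[2]), 1e-3)
  }
  # level -> 0 collapses onto the MAP point
  tiny <- prevalence_hpdi(763, 940, 0.05, 1e-4)
  mp <- prevalence_map(763, 940, 0.05)
  expect_lt(tiny$upper - tiny$lower, 0.005)
  expect_lt(abs((tiny$lower + tiny$upper) / 2 - mp), 0.005)
  # width shrinks with n at fixed k/n
  w <- sapply(c(1, 4, 16), function(f) {
    h <- prevalence_hpdi(111 * f, 205 * f, 0.05, 0.96)
    h$upper - h$lower
  })
  expect_true(all(diff(w) < 0))
})

test_that("person-centered prevalence counts sub-alpha p-values", {
  expect_equal(person_centered_prevalence(c(0.01, 0.2, 0.03), 0.05), 2 / 3)
  expect_equal(person_centered_prevalence(c(0.2, 0.8), 0.05), 0)
  set.seed(94)
  p <- runif(10000)                          # global null
  expect_lt(abs(person_centered_prevalence(p, 0.05) - 0.05), 0.01)
  expect_error(person_centered_prevalence(c(0.5, 1.2)), "\\[0, 1\\]")
})
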