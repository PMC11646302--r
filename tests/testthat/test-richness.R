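# Expected values for the iChao2 hand example, computed from the published
# formulas before the implementation was written:
#   T = 6, S_obs = 9, Q = (3, 2, 1, 1)
#   chao2  = 9 + (5/6) * 3^2 / (2*2)            = 10.875
#   ichao2 = 10.875 + (3/24) * (1/1) *
#            max(3 - (3/10) * 2 * 1 / 1, 0)     = 10.875 + 0.3 = 11.175

test_that("iChao2 matches independent formula evaluation on a hand tally", {
  inc <- matrix(FALSE, 9, 6)
  inc[1, 1] <- TRUE                     # Q1: three uniques
  inc[2, 2] <- TRUE
  inc[3, 3] <- TRUE
  inc[4, 1:2] <- TRUE                   # Q2: two duplicates
  inc[5, 3:4] <- TRUE
  inc[6, 1:3] <- TRUE                   # Q3: one
  inc[7, 1:4] <- TRUE                   # Q4: one
  inc[8, 1:5] <- TRUE
  inc[9, 2:6] <- TRUE
  est <- ichao2(incidence_matrix(inc))
  expect_identical(c(est$S_obs, est$Q1, est$Q2, est$Q3, est$Q4, est$T),
                   c(9, 3, 2, 1, 1, 6))
  expect_equal(est$chao2, 10.875)
  expect_equal(est$ichao2, 11.175)
})

test_that("iChao2 corner cases follow the estimator's corrections", {
  # Q1 = 0: estimate collapses to S_obs
  inc <- matrix(TRUE, 5, 6)
  est <- ichao2(incidence_matrix(inc))
  expect_equal(est$chao2, 5)
  expect_equal(est$ichao2, 5)
  # Q3 = 0: added term vanishes, ichao2 = chao2
  inc2 <- rbind(matrix(c(TRUE, rep(FALSE, 5)), 3, 6, byrow = TRUE),
                matrix(c(TRUE, TRUE, rep(FALSE, 4)), 2, 6, byrow = TRUE))
  est2 <- ichao2(incidence_matrix(inc2))
  expect_equal(est2$ichao2, est2$chao2)
  # Q2 = 0 uses the bias-corrected chao2 form: S + ((T-1)/T) Q1(Q1-1)/2
  inc3 <- matrix(FALSE, 4, 6); inc3[cbind(1:4, 1:4)] <- TRUE
  est3 <- ichao2(incidence_matrix(inc3))
  expect_equal(est3$chao2, 4 + (5 / 6) * 4 * 3 / 2)
  # T < 4: ichao2 unavailable
  est4 <- ichao2(incidence_matrix(matrix(TRUE, 3, 3)))
  expect_true(is.na(est4$ichao2))
  expect_equal(est4$chao2, 3)
})

test_that("ichao2 >= chao2 >= S_obs on random incidence matrices", {
  set.seed(13)
  for (i in 1:50) {
    inc <- matrix(runif(30 * 8) < runif(1, 0.05, 0.5), 30, 8)
    inc <- inc[rowSums(inc) > 0, , drop = FALSE]
    if (nrow(inc) == 0) next
    est <- ichao2(incidence_matrix(inc))
    expect_gte(est$chao2, est$S_obs)
    if (!is.na(est$ichao2)) expect_gte(est$ichao2, est$chao2)
  }
})

test_that("read rarefaction matches the exact hypergeometric expectation", {
  counts <- c(50, 30, 12, 5, 2, 1)
  N <- sum(counts)
  crv <- rarefy_reads(counts, step_fraction = 0.1, iterations = 200, seed = 3)
  # independent oracle: E[S(d)] = sum_i (1 - C(N - n_i, d) / C(N, d))
  for (r in seq_len(nrow(crv))) {
    d <- crv$effort[r]
    exp_rich <- sum(1 - exp(lchoose(N - counts, d) - lchoose(N, d)))
    se <- max(crv$sd[r] / sqrt(crv$n_iter[r]), 1e-9)
    expect_lt(abs(crv$mean[r] - exp_rich), max(3 * se, 1e-9),
              label = sprintf("depth %d", d))
  }
  # full-depth point equals observed richness with sd 0
  expect_equal(crv$mean[nrow(crv)], 6)
  expect_equal(crv$sd[nrow(crv)], 0)
  # mean curve non-decreasing (shared-permutation draws are nested)
  expect_true(all(diff(crv$mean) >= 0))
  # single OTU: richness 1 at every nonzero depth
  one <- rarefy_reads(c(100), step_fraction = 0.25, iterations = 5, seed = 1)
  expect_true(all(one$mean == 1))
  # determinism under a fixed seed
  expect_identical(rarefy_reads(counts, 0.1, 20, seed = 8),
                   rarefy_reads(counts, 0.1, 20, seed = 8))
})

test_that("Michaelis-Menten fit recovers exact curves and beats a grid search", {
  d <- seq(1e3, 1e6, length.out = 60)
  exact <- data.frame(effort = d, mean = 500 * d / (1e5 + d))
  fit <- fit_mm(exact)
  expect_equal(fit$Rmax, 500, tolerance = 1e-6)
  expect_equal(fit$K, 1e5, tolerance = 1e-6)

  # noisy curve: the fit's SSE must be <= the best coarse-grid SSE, and the
  # optimum must sit within one grid cell of the grid argmin
  set.seed(4)
  noisy <- data.frame(effort = d, mean = 500 * d / (1e5 + d) + rnorm(60, 0, 3))
  fit2 <- fit_mm(noisy)
  sse <- function(R, K) sum((noisy$mean - R * noisy$effort / (K + noisy$effort))^2)
  Rgrid <- seq(400, 600, by = 2); Kgrid <- seq(5e4, 2e5, by = 1e3)
  g <- outer(Rgrid, Kgrid, Vectorize(sse))
  best <- arrayInd(which.min(g), dim(g))
  expect_lte(sse(fit2$Rmax, fit2$K), min(g) + 1e-9)
  expect_lt(abs(fit2$Rmax - Rgrid[best[1]]), 2)
  expect_lt(abs(fit2$K - Kgrid[best[2]]), 1e3)

  # parameter recovery with 1%-of-Rmax noise: Rmax within 2%
  for (s in 1:5) {
    set.seed(s)
    y <- 500 * d / (1e5 + d) + rnorm(60, 0, 5)
    f <- fit_mm(data.frame(effort = d, mean = y))
    expect_lt(abs(f$Rmax - 500) / 500, 0.02, label = sprintf("seed %d", s))
  }
})

test_that("doubling gain equals the closed form K/(K + 2D)", {
  D <- 1.4e6
  fit <- structure(list(Rmax = 1000, K = D / 9.5, resid_norm = 0),
                   class = "mm_fit")
  g <- doubling_gain(fit, D)
  expect_equal(g$gain, 0.05)
  expect_false(g$sufficient)           # boundary is insufficient under strict <
  # curve-evaluation path agrees with the algebra to machine precision
  ratio <- predict(fit, 2 * D) / predict(fit, D) - 1
  expect_equal(ratio, fit$K / (fit$K + 2 * D), tolerance = 1e-12)
  expect_equal(doubling_gain(fit, D, threshold = 0.051)$sufficient, TRUE)
  fit$K <- D  # K equal to the achieved depth: gain = D/(D + 2D) = 1/3
  expect_equal(doubling_gain(fit, D)$gain, 1 / 3)
  fit$K <- 1e-9
  expect_true(doubling_gain(fit, D)$sufficient)
})

test_that("sample rarefaction matches exhaustive enumeration on a toy matrix", {
  set.seed(2)
  inc <- incidence_matrix(matrix(runif(8 * 6) < 0.4, 8, 6))
  crv <- rarefy_samples(inc, step = 2, iterations = 400, seed = 10)
  # exhaustive oracle: mean observed richness over all C(6,2) = 15 pairs
  pairs <- utils::combn(6, 2)
  exact2 <- mean(apply(pairs, 2, function(u)
    sum(rowSums(inc[, u, drop = FALSE]) > 0)))
  r2 <- crv[crv$effort == 2, ]
  se <- r2$sd / sqrt(r2$n_iter)
  expect_lt(abs(r2$mean - exact2), max(3 * se, 1e-9))
  # subset size = T reproduces S_obs exactly with sd 0
  rT <- crv[crv$effort == 6, ]
  expect_equal(rT$mean, sum(rowSums(inc) > 0))
  expect_equal(rT$sd, 0)
  # all species in all units -> curve constant at S
  full <- rarefy_samples(incidence_matrix(matrix(TRUE, 5, 6)), step = 2,
                         iterations = 5, seed = 1)
  expect_true(all(full$mean == 5))
  # estimator track present and never below the observed track
  expect_true(all(crv$mean_est >= crv$mean - 1e-9))
})
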