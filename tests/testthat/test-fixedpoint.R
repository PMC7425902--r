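test_that("pooled bandwidth is the collapsed-sample SD", {
  expect_equal(pooled_bandwidth(c(100, 300)), sd(c(100, 300)))
  set.seed(2)
  x <- rlnorm(500, 6, 0.5)
  # two-pass oracle
  m <- sum(x) / length(x)
  oracle <- sqrt(sum((x - m)^2) / (length(x) - 1))
  expect_equal(pooled_bandwidth(x), oracle)
  expect_equal(pooled_bandwidth(3 * x), 3 * pooled_bandwidth(x))
  expect_error(pooled_bandwidth(rep(5, 10)), "constant")
  expect_error(pooled_bandwidth(100), "at least 2")
})

test_that("KDE equals the explicit kernel-sum oracle and normalizes", {
  set.seed(3)
  x <- 300 + rlnorm(200, 6, 0.4)
  bw <- pooled_bandwidth(x)
  grid <- density_grid(x, bw)
  est <- estimate_density(x, bw, grid)
  expect_true(all(est$density >= 0))
  # naive oracle at a handful of points
  for (g in grid[c(5, 100, 256, 400)])
    expect_equal(est$density[which(grid == g)],
                 sum(dnorm(g, x, bw)) / length(x))
  # trapezoid normalization within 1%
  area <- sum(diff(grid) * (est$density[-1] + est$density[-512]) / 2)
  expect_equal(area, 1, tolerance = 0.01)
  # cross-check against the FFT-based estimator in stats
  ref <- density(x, bw = bw, from = min(grid), to = max(grid), n = 512)
  expect_equal(est$density, ref$y, tolerance = 5e-3)
})

test_that("KDE handles tiny near-degenerate samples without NaN", {
  x <- c(500, 500.1, 500.2, 499.9, 500.05)
  est <- estimate_density(x, 1, seq(490, 510, length.out = 128))
  expect_true(all(is.finite(est$density)))
  expect_error(estimate_density(x[1:4], 1, 1:10), "at least 5")
})

test_that("KDE converges to the true density as n grows", {
  meanlog <- 6.3; sdlog <- 0.3
  err <- vapply(c(200, 1000, 5000), function(n) {
    set.seed(n)
    x <- rlnorm(n, meanlog, sdlog)
    bw <- 1.06 * sd(x) * n^(-1 / 5)  # consistency needs a shrinking kernel
    grid <- seq(200, 1500, length.out = 512)
    est <- estimate_density(x, bw, grid)
    max(abs(est$density - dlnorm(grid, meanlog, sdlog)))
  }, 1)
  expect_true(all(diff(err) < 0))
})

test_that("equal-variance Gaussian mixtures cross at the component midpoint", {
  grid <- seq(0, 1000, length.out = 2048)
  d1 <- analytic_density(gauss_mix(0.25), grid, median = 650)
  d2 <- analytic_density(gauss_mix(0.75), grid, median = 350)
  cp <- crossing_point(d1, d2)
  expect_equal(cp$crossing, 500, tolerance = 1)
})

test_that("mixtures of common bases share one crossing; shift families do not", {
  grid <- seq(0, 1000, length.out = 2048)
  dens <- lapply(c(0.2, 0.5, 0.8), function(p)
    analytic_density(gauss_mix(p), grid, median = 700 - 400 * p))
  cross <- combn(3, 2, function(ij)
    crossing_point(dens[[ij[1]]], dens[[ij[2]]])$crossing)
  expect_lt(diff(range(cross)), 1)      # common crossing, analytic case
  expect_equal(mean(cross), 500, tolerance = 1)
  # KDE pipeline recovers it with error shrinking in n (averaged over
  # replicates; a single draw's crossing error is itself noisy)
  err <- vapply(c(200, 1000, 5000), function(n) {
    mean(vapply(1:6, function(r) {
      set.seed(n + r)
      draws <- lapply(c(0.2, 0.5, 0.8), function(p) {
        comp <- runif(n) < p
        ifelse(comp, rnorm(n, 300, 50), rnorm(n, 700, 50))
      })
      bw <- 0.5 * sd(unlist(draws)) * n^(-1 / 5)
      g <- density_grid(unlist(draws), bw)
      kde <- lapply(draws, function(x) estimate_density(x, bw, g))
      cr <- combn(3, 2, function(ij)
        crossing_point(kde[[ij[1]]], kde[[ij[2]]])$crossing)
      mean(abs(cr - 500))
    }, 1))
  }, 1)
  expect_lt(err[3], err[1])
  expect_lt(err[3], 25)
  # pure shift family: crossings sit at pairwise midpoints, which differ
  shifts <- c(0, 100, 250)
  sdens <- lapply(shifts, function(s)
    analytic_density(function(x) dnorm(x, 400 + s, 80), grid,
                     median = 400 + s))
  scross <- combn(3, 2, function(ij)
    crossing_point(sdens[[ij[1]]], sdens[[ij[2]]])$crossing)
  mids <- combn(3, 2, function(ij) mean(400 + shifts[ij]))
  expect_equal(scross, mids, tolerance = 1)
  expect_gt(diff(range(scross)), 50)
})

test_that("three conditions yield exactly three crossings per participant", {
  tr <- sim_experiment_small("learned", n_subjects = 4, seed = 51)
  cs <- crossing_set(tr, "ToT")
  per <- table(cs$crossings$subject)
  expect_true(all(per == 3))
  expect_equal(cs$n_pairs, 3)
})

test_that("sparse conditions exclude a participant with a logged reason", {
  tr <- sim_experiment_small("none", n_subjects = 3, seed = 53)
  # starve one subject's high-TP condition below the inclusion minimum
  drop <- tr$subject == 1 & tr$tp_code %in% 1 & !is.na(tr$tp_code)
  tr$rt_ms[drop][-(1:3)] <- NA
  cs <- crossing_set(tr, "TP")
  expect_false("1" %in% as.character(unique(cs$crossings$subject)))
  expect_match(cs$excluded, "subject 1", all = FALSE)
})

test_that("BIC Bayes factor matches a direct likelihood computation", {
  tr <- sim_experiment_small("learned", n_subjects = 5, seed = 55)
  cs <- crossing_set(tr, "ToT")
  res <- fixed_point_bayes_test(cs)
  expect_gt(res$BF01, 0)
  expect_equal(res$BF10, 1 / res$BF01)
  # independent route: BICs from the two models' maximized likelihoods
  cr <- cs$crossings
  d <- data.frame(y = cr$crossing, pair = factor(cr$pair),
                  s = factor(cr$subject))
  n <- nrow(d)
  ll0 <- logLik(lm(y ~ s, d)); ll1 <- logLik(lm(y ~ s + pair, d))
  bic0 <- -2 * as.numeric(ll0) + attr(ll0, "df") * log(n)
  bic1 <- -2 * as.numeric(ll1) + attr(ll1, "df") * log(n)
  expect_equal(res$BF01, exp((bic1 - bic0) / 2), tolerance = 1e-8)
})

test_that("near-identical crossings across pairs favour the fixed point", {
  set.seed(19)
  cs <- structure(list(
    crossings = data.frame(
      subject = rep(1:8, each = 3),
      pair = rep(c("a", "b", "c"), 8),
      crossing = rep(500 + 10 * (1:8), each = 3) + rnorm(24, 0, 4),
      reason = NA_character_),
    excluded = character(0), factor = "ToT", n_pairs = 3,
    n_participants = 8), class = "crossing_set")
  expect_gt(fixed_point_bayes_test(cs)$BF01, 1)
})

test_that("a large pair effect in the crossings defeats the fixed point", {
  set.seed(77)
  cs <- structure(list(
    crossings = data.frame(
      subject = rep(1:10, each = 3),
      pair = rep(c("a", "b", "c"), 10),
      crossing = rnorm(30, 500, 5) + rep(c(-80, 0, 80), 10),
      reason = NA_character_),
    excluded = character(0), factor = "TP", n_pairs = 3,
    n_participants = 10), class = "crossing_set")
  expect_lt(fixed_point_bayes_test(cs)$BF01, 1)
})

test_that("the end-to-end test discriminates mixture from shift scenarios", {
  # BF01 under the mixture scenario is stochastic, so judge a small panel
  bf_mix <- vapply(1:3, function(i) {
    trl <- simulate_experiment(design_spec(n_subjects = 12),
                               scenario_spec("learned"), seed = 560 + i)
    fixed_point_test(trl, "ToT")$BF01
  }, 1)
  expect_gte(sum(bf_mix > 1), 2)
  # the shift (single-process) scenario rejects decisively
  bf_shift <- vapply(1:3, function(i) {
    trn <- simulate_experiment(design_spec(n_subjects = 12),
                               scenario_spec("natural"), seed = 580 + i)
    fixed_point_test(trn, "TP")$BF01
  }, 1)
  expect_true(all(bf_shift < 1))
})
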