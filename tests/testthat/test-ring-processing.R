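test_that("BAI conversion matches cumulative basal area geometry", {
  expect_equal(bai_from_widths(1), pi)
  expect_equal(bai_from_widths(c(1, 1)), c(pi, 3 * pi))
  expect_equal(bai_from_widths(c(2, 1, 1)), c(4 * pi, 5 * pi, 7 * pi))
  expect_error(bai_from_widths(c(1, 0, 1), tree_id = "t1",
                               years = 2001:2003),
               "non-positive ring width for tree t1 \\(year 2002\\)")
  # conservation: total BAI equals the final basal area
  w <- runif(25, 0.3, 4)
  expect_equal(sum(bai_from_widths(w)), pi * sum(w)^2)
})

test_that("paired width averaging is element-wise", {
  expect_equal(average_paired_widths(c(1, 2), c(3, 2)), c(2, 2))
  expect_equal(average_paired_widths(c(1.2, 0.8), c(1.4, 1.0)), c(1.3, 0.9))
  expect_equal(average_paired_widths(c(2, 2), c(2, 2)), c(2, 2))
  expect_error(average_paired_widths(1:3, 1:2), "length")
})

test_that("Hugershoff fitting recovers known parameters", {
  t <- 1:40
  g <- 2 * t^0.5 * exp(-0.05 * t) + 1
  fit <- fit_hugershoff(g)
  expect_false(fit$fallback)
  expect_equal(unname(fit$par),  c(2, 0.5, 0.05, 1), tolerance = 1e-3)
  expect_equal(fit$fitted, g, tolerance = 1e-6)
  expect_error(fit_hugershoff(g[1:3]), ">= 4")
})

test_that("constant series yield the flat curve", {
  fit <- fit_hugershoff(rep(5, 12))
  expect_equal(fit$fitted, rep(5, 12), tolerance = 1e-6)
})

test_that("fit tracks truth within 10% under multiplicative noise", {
  t <- 1:40
  g <- 2 * t^0.5 * exp(-0.05 * t) + 1
  set.seed(8)
  noisy <- g * exp(rnorm(40, 0, 0.05))
  fit <- fit_hugershoff(noisy)
  expect_true(all(abs(fit$fitted / g - 1) < 0.10))
})

test_that("detrending divides by the fitted age curve", {
  t <- 1:20
  g <- 3 * t^0.8 * exp(-0.1 * t) + 2
  fit <- fit_hugershoff(g)
  expect_equal(detrend_bai(g, fit), rep(1, 20), tolerance = 1e-6)
  expect_equal(detrend_bai(2 * g, fit), rep(2, 20), tolerance = 1e-6)
  # mean-fallback arithmetic on a hand-checked series
  bai <- c(4, 5, 7) * pi
  mfit <- structure(list(par = c(A = 0, b = 0, c = 0, d = mean(bai)),
                         fitted = rep(mean(bai), 3), converged = FALSE,
                         fallback = TRUE), class = "hugershoff_fit")
  expect_equal(detrend_bai(bai, mfit), c(0.75, 0.9375, 1.3125))
  expect_equal(detrend_bai(bai, mfit, mode = "difference"),
               bai - mean(bai))
})

test_that("AR(1) prewhitening estimates phi and whitens residuals", {
  expect_equal(prewhiten_ar1(rep(0, 10)),
               list(residuals = rep(0, 10), phi = 0))
  expect_equal(prewhiten_ar1(rep(3.2, 10))$residuals, rep(0, 10))
  set.seed(15)
  x <- as.numeric(arima.sim(list(ar = 0.6), 2000))
  pw <- prewhiten_ar1(x)
  expect_lt(abs(pw$phi - 0.6), 0.05)
  res <- pw$residuals[-1]
  lag1 <- cor(res[-1], res[-length(res)])
  expect_lt(abs(lag1), 0.05)
  expect_equal(length(pw$residuals), length(x))
  expect_equal(length(prewhiten_ar1(x, keep_first = FALSE)$residuals),
               length(x) - 1)
  # white noise: phi estimate near zero
  set.seed(16)
  w <- rnorm(2000)
  expect_lt(abs(prewhiten_ar1(w)$phi), 0.06)
})

test_that("biweight mean is robust and matches the brute-force oracle", {
  expect_equal(tukey_biweight_mean(c(5, 5, 5)), 5)
  expect_equal(tukey_biweight_mean(c(1, 2, 3)), 2)
  bw <- tukey_biweight_mean(c(1, 2, 3, 1000))
  expect_gt(bw, 1.5)
  expect_lt(bw, 2.5)
  expect_equal(bw, oracle_biweight(c(1, 2, 3, 1000)), tolerance = 1e-3)
  set.seed(4)
  for (i in 1:5) {
    x <- c(rnorm(9), 50)
    expect_equal(tukey_biweight_mean(x), oracle_biweight(x),
                 tolerance = 1e-3)
  }
  # exactly symmetric samples: biweight equals the arithmetic mean
  x <- c(-2.5, -1, -0.2, 0.2, 1, 2.5) + 7
  expect_equal(tukey_biweight_mean(x), mean(x), tolerance = 1e-8)
  expect_error(tukey_biweight_mean(numeric(0)), "at least one")
})

test_that("clone chronologies average replicates per year", {
  one <- build_clone_chronology(list(c(0.1, -0.2, 0.3)),
                                list(2001:2003), "c1", "S")
  expect_equal(one$relative_bai, c(0.1, -0.2, 0.3))
  three <- build_clone_chronology(rep(list(c(0.1, -0.2)), 3),
                                  rep(list(2001:2002), 3), "c1", "S")
  expect_equal(three$relative_bai, c(0.1, -0.2))
  expect_equal(three$n_reps, c(3L, 3L))
  # outlier replicate in one year is down-weighted
  mix <- build_clone_chronology(list(c(0.1), c(0.1), c(5.0)),
                                list(2001, 2001, 2001), "c1", "S")
  expect_gt(mix$relative_bai, 0.05)
  expect_lt(mix$relative_bai, 0.2)
})

test_that("process_rings runs detrend, prewhiten then average in order", {
  set.seed(20)
  clim <- tiny_daily(2004:2016)
  tm <- truth_model(NULL, clone_noise_sd = 0.5, noise_sd = 0.2)
  s <- simulate_sensitivities(
    simulate_genotypes(tiny_map(), 6, 1), tiny_map(), tm, seed = 1)$s
  rings <- simulate_ring_widths(s, clim, tm, 2006:2016, n_replicates = 2,
                                seed = 9)
  chron <- process_rings(rings)
  expect_equal(sort(unique(chron$clone_id)), sort(names(s)))
  expect_equal(unique(table(chron$clone_id)), 11L)
  # residual contract: per-tree mean of the relative BAI is ~0, so the
  # clone series hovers around zero
  expect_lt(max(abs(tapply(chron$relative_bai, chron$clone_id, mean))), 0.2)
  fits <- attr(chron, "fits")
  expect_equal(nrow(fits), 12)

  # order matters: averaging replicate BAI before prewhitening differs from
  # prewhitening each tree then averaging (pinned on a constructed case)
  t <- 1:10
  g <- 100 * t^1.2 * exp(-0.1 * t) + 10
  bai_a <- g * exp(c(0.3, -0.3, 0.3, -0.3, 0.3, -0.3, 0.3, -0.3, 0.3, -0.3))
  bai_b <- g * exp(c(0.3, 0.3, -0.3, -0.3, 0.3, 0.3, -0.3, -0.3, 0.3, 0.3))
  pw <- function(b) prewhiten_ar1(detrend_bai(b, fit_hugershoff(b)))$residuals
  per_tree <- mapply(function(x, y) tukey_biweight_mean(c(x, y)),
                     pw(bai_a), pw(bai_b))
  pooled <- pw((bai_a + bai_b) / 2)
  expect_gt(max(abs(per_tree - pooled)), 0.01)
})
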