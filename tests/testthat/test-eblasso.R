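sim_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  colnames(X) <- sprintf("m%03d", seq_len(p))
  X
}

test_that("degenerate phenotypes give the empty model", {
  X <- sim_design(30, 10, 1)
  expect_warning(f <- eblasso_fit(X, rep(0, 30)), "constant")
  expect_equal(f$intercept, 0)
  expect_true(all(f$beta == 0))
  expect_error(eblasso_fit(X, c(rep(1, 29), NA)), "finite")
  expect_error(eblasso_fit(X[1:5, ], rnorm(5)), "n >= 10")
})

test_that("a strong causal marker is found with the right sign", {
  X <- sim_design(200, 50, 2)
  set.seed(3)
  y <- X[, 17] * 1.0 + rnorm(200, 0, 0.5)
  f <- eblasso_fit(X, y, a = 0.1, b = 0.1)
  expect_gt(f$beta["m017"], 0)
  sig <- significant_qtls(f, 0.01)
  expect_equal(sig$marker[1], "m017")
  expect_equal(sig$beta[1], 1.0, tolerance = 0.25)
})

test_that("null designs rarely yield significant effects", {
  hits <- vapply(1:20, function(r) {
    X <- sim_design(200, 50, 100 + r)
    set.seed(200 + r)
    y <- rnorm(200)
    cv <- cv_select_hyperparams(X, y, seed = r)
    f <- eblasso_fit(X, y, a = cv$a, b = cv$b)
    nrow(significant_qtls(f, 0.01))
  }, 0)
  expect_gte(mean(hits == 0), 0.9)
})

test_that("duplicated causal columns collapse to a single effect", {
  X <- sim_design(150, 30, 4)
  X[, 12] <- X[, 5]
  set.seed(5)
  y <- X[, 5] * 1.2 + rnorm(150, 0, 0.4)
  f <- eblasso_fit(X, y, a = 0.1, b = 0.1)
  retained <- f$selected$marker
  expect_lte(sum(c("m005", "m012") %in% retained), 1)
})

test_that("stronger shrinkage never retains more markers", {
  X <- sim_design(120, 60, 6)
  set.seed(7)
  y <- X[, 3] * 0.8 - X[, 40] * 0.6 + rnorm(120, 0, 0.6)
  grid <- default_hyperparameter_grid() # ordered by decreasing (a+1)/b
  sizes <- vapply(seq_len(nrow(grid)), function(i)
    nrow(eblasso_fit(X, y, a = grid$a[i], b = grid$b[i])$selected), 0)
  strength <- (grid$a + 1) / grid$b
  # along strictly decreasing shrinkage, retained count is non-decreasing
  expect_true(all(diff(sizes[order(-strength)]) >= 0 |
                    diff(strength[order(-strength)]) == 0))
})

test_that("with a nearly flat prior the fit approaches OLS", {
  X <- sim_design(80, 5, 8)
  set.seed(9)
  y <- drop(X %*% c(1, -0.8, 0.5, 0.7, -0.6)) + rnorm(80, 0, 0.05)
  f <- eblasso_fit(X, y, a = 0.01, b = 1e6)
  expect_equal(nrow(f$selected), 5)
  ols <- coef(lm(y ~ X))[-1]
  expect_equal(unname(f$beta[f$selected$marker][colnames(X)]),
               unname(ols), tolerance = 1e-3)
})

test_that("point estimates agree with a Gibbs Bayesian-lasso oracle", {
  X <- sim_design(120, 12, 10)
  set.seed(11)
  y <- X[, 2] * 1.5 - X[, 9] * 1.2 + rnorm(120, 0, 0.4)
  f <- eblasso_fit(X, y, a = 0.1, b = 0.5)
  gibbs <- oracle_bayesian_lasso(X, y, lambda = 2, seed = 12)
  expect_gt(cor(f$beta, gibbs), 0.95)
  expect_equal(unname(f$beta["m002"]), gibbs[2], tolerance = 0.2)
  expect_equal(unname(f$beta["m009"]), gibbs[9], tolerance = 0.2)
})

test_that("the compiled core matches the reference implementation", {
  for (r in 1:3) {
    X <- sim_design(60, 40, 20 + r)
    set.seed(30 + r)
    y <- X[, 3] * 0.8 - X[, 10] * 0.5 + rnorm(60, 0, 0.5)
    Xc <- sweep(X, 2, colMeans(X))
    yc <- y - mean(y)
    G <- crossprod(Xc)
    Xty <- drop(crossprod(Xc, yc))
    yty <- sum(yc^2)
    fc <- dendroqtl:::eblasso_core(G, Xty, yty, 60, 0.1, 0.5)
    fr <- dendroqtl:::eblasso_core_r(G, Xty, yty, 60, 0.1, 0.5)
    expect_equal(sort(fc$active), sort(fr$active))
    expect_equal(fc$beta[order(fc$active)], fr$beta[order(fr$active)],
                 tolerance = 1e-10)
    expect_equal(fc$sigma2, fr$sigma2, tolerance = 1e-10)
  }
})

test_that("cross-validation selects shrinkage sensibly", {
  X <- sim_design(60, 30, 40)
  set.seed(41)
  y <- rnorm(60)
  g1 <- data.frame(a = 0.5, b = 0.1)
  one <- cv_select_hyperparams(X, y, grid = g1, seed = 1)
  expect_equal(c(one$a, one$b), c(0.5, 0.1))
  expect_error(cv_select_hyperparams(X, y, k = 100), "k must be")

  # pure noise: a strong-shrinkage grid point (empty or near-empty model)
  # wins most of the time
  strength <- function(a, b) (a + 1) / b
  top <- sort(strength(default_hyperparameter_grid()$a,
                       default_hyperparameter_grid()$b),
              decreasing = TRUE)[6]
  picks <- vapply(1:20, function(r) {
    Xr <- sim_design(60, 30, 50 + r)
    set.seed(70 + r)
    cv <- cv_select_hyperparams(Xr, rnorm(60), seed = r)
    strength(cv$a, cv$b) >= top
  }, TRUE)
  expect_gte(mean(picks), 0.8)

  # strong single signal: the selected pair retains the causal marker
  set.seed(90)
  y2 <- X[, 8] * 1.5 + rnorm(60, 0, 0.5)
  cv2 <- cv_select_hyperparams(X, y2, seed = 2)
  f2 <- eblasso_fit(X, y2, a = cv2$a, b = cv2$b)
  expect_true("m008" %in% f2$selected$marker)
})

test_that("predictions reconstruct the linear model", {
  X <- sim_design(100, 20, 60)
  set.seed(61)
  y <- 2 + X[, 4] * 1.5 + rnorm(100, 0, 0.3)
  f <- eblasso_fit(X, y, a = 0.1, b = 0.1)
  pr <- predict(f, X)
  expect_gt(cor(pr, y), 0.8)
  expect_equal(mean(pr), mean(y), tolerance = 0.05)
})
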