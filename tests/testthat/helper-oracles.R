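# Independent oracles used to pin down expected values. These deliberately
# share no code with the package implementations.

# Brute-force monthly dry-period index: enumerate every day, mark membership
# in a maximal dry run of length >= k by scanning outwards from each day.
oracle_dry_index <- function(dates, precip, k, wet_cutoff = 0) {
  dry <- precip <= wet_cutoff
  n <- length(dates)
  counted <- logical(n)
  for (i in seq_len(n)) {
    if (!dry[i]) next
    lo <- i
    while (lo > 1 && dry[lo - 1]) lo <- lo - 1
    hi <- i
    while (hi < n && dry[hi + 1]) hi <- hi + 1
    counted[i] <- (hi - lo + 1) >= k
  }
  ym <- format(dates, "%Y-%m")
  tapply(as.integer(counted), ym, sum)
}

# Brute-force biweight location: locate the weighted-mean fixed point by a
# dense grid scan followed by root refinement of g(m) = wmean(m) - m.
oracle_biweight <- function(x, cc = 9) {
  m0 <- median(x)
  S <- median(abs(x - m0))
  if (S <= 0) return(m0)
  g <- function(m) {
    u <- (x - m) / (cc * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) == 0) return(NA_real_)
    sum(w * x) / sum(w) - m
  }
  grid <- seq(m0 - 3 * cc * S, m0 + 3 * cc * S, length.out = 5001)
  gv <- vapply(grid, g, 0)
  i <- which.min(abs(gv))
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  if (is.finite(g(lo)) && is.finite(g(hi)) && sign(g(lo)) != sign(g(hi)))
    uniroot(g, c(lo, hi), tol = 1e-10)$root
  else grid[i]
}

# Gibbs sampler for the Bayesian lasso (scale-mixture representation with a
# fixed rate parameter); used only to cross-check empirical-Bayes point
# estimates on small strong-signal problems.
oracle_bayesian_lasso <- function(X, y, lambda = 1, n_iter = 3000,
                                  burn = 500, seed = 1) {
  set.seed(seed)
  n <- nrow(X)
  p <- ncol(X)
  y <- y - mean(y)
  X <- sweep(X, 2, colMeans(X))
  XtX <- crossprod(X)
  Xty <- drop(crossprod(X, y))
  beta <- rep(0, p)
  sigma2 <- var(y)
  inv_tau2 <- rep(1, p)
  draws <- matrix(0, n_iter - burn, p)
  rinvgauss <- function(mu, lam) {
    # Michael-Schucany-Haas
    z <- rnorm(1)^2
    x <- mu + mu^2 * z / (2 * lam) -
      mu / (2 * lam) * sqrt(4 * mu * lam * z + mu^2 * z^2)
    if (runif(1) <= mu / (mu + x)) x else mu^2 / x
  }
  for (it in seq_len(n_iter)) {
    A <- XtX + diag(inv_tau2, p)
    cA <- chol(A)
    mu_b <- backsolve(cA, forwardsolve(t(cA), Xty))
    beta <- mu_b + backsolve(cA, rnorm(p)) * sqrt(sigma2)
    for (j in seq_len(p)) {
      mj <- sqrt(lambda^2 * sigma2 / beta[j]^2)
      inv_tau2[j] <- max(rinvgauss(mj, lambda^2), 1e-10)
    }
    rss <- sum((y - X %*% beta)^2)
    sigma2 <- 1 / rgamma(1, (n - 1 + p) / 2,
                         (rss + sum(beta^2 * inv_tau2)) / 2)
    if (it > burn) draws[it - burn, ] <- beta
  }
  colMeans(draws)
}

# Small shared fixtures -------------------------------------------------------

tiny_map <- function(label = "P1", offset = 0L)
  map_spec(list(LG01 = seq(0, 30, by = 5), LG02 = seq(0, 30, by = 5)),
           label, offset)

tiny_daily <- function(years = 2006:2010, seed = 7)
  simulate_daily_climate(years, weather_params(), seed)
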