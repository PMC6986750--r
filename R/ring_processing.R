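# Ring-width processing: BAI conversion, Hugershoff age-trend detrending,
# AR(1) prewhitening and robust per-clone chronologies.

#' Convert ring widths to basal area increments
#'
#' Widths accumulate to the stem radius r_t; the basal area increment of year
#' t is `pi * (r_t^2 - r_{t-1}^2)` with r_0 = 0 (pith at the first measured
#' ring).
#'
#' @param widths positive ring widths (mm), innermost ring first.
#' @param tree_id,years optional identifiers used in error messages.
#' @return numeric vector of BAI values (mm^2/year).
#' @export
#' @examples
#' bai_from_widths(c(1, 1)) # pi, 3*pi
bai_from_widths <- function(widths, tree_id = NULL, years = NULL) {
  bad <- which(!is.finite(widths) | widths <= 0)
  if (length(bad)) {
    where <- if (!is.null(years)) paste0(" (year ", years[bad[1]], ")") else ""
    who <- if (!is.null(tree_id)) paste0(" for tree ", tree_id) else ""
    stop("non-positive ring width", who, where, call. = FALSE)
  }
  r <- cumsum(widths)
  pi * (r^2 - c(0, r[-length(r)])^2)
}

#' Average two paired ring-width series from one tree
#'
#' Two radii are measured per tree; their widths are averaged element-wise
#' before BAI conversion.
#'
#' @param a,b equal-length width vectors for the same years.
#' @return element-wise mean.
#' @export
average_paired_widths <- function(a, b) {
  assert_that(length(a) == length(b), "paired width series differ in length")
  (a + b) / 2
}

#' Fit a modified Hugershoff age-trend curve to a BAI series
#'
#' Nonlinear least squares for `g(t) = A t^b exp(-c t) + d` over ring age
#' t = 1..n, with A > 0 and c >= 0. Start values come from a log-linear
#' regression of BAI on (log t, t). If the fit fails to converge or the
#' fitted curve is not strictly positive, the horizontal mean curve is used
#' instead and flagged (`fallback = TRUE`).
#'
#' @param bai positive BAI series, >= 4 values.
#' @return list of class `hugershoff_fit`: `par` (A, b, c, d), `fitted`,
#'   `converged`, `fallback`.
#' @export
fit_hugershoff <- function(bai) {
  n <- length(bai)
  assert_that(n >= 4, "need >= 4 observations to fit a 4-parameter age curve")
  assert_that(all(bai > 0), "BAI must be positive")
  t <- seq_len(n)
  init <- tryCatch({
    cf <- stats::coef(stats::lm(log(bai) ~ log(t) + t))
    c(A = unname(exp(cf[1])), b = unname(cf[2]), c = unname(max(-cf[3], 0)), d = 0)
  }, error = function(e) c(A = mean(bai), b = 0.5, c = 0.05, d = 0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      bai ~ A * t^b * exp(-c * t) + d,
      start = as.list(init),
      lower = c(A = 1e-8, b = -5, c = 0, d = -max(bai)),
      upper = c(A = Inf, b = 10, c = 5, d = max(bai)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    par <- stats::coef(fit)
    g <- hugershoff_curve(par, t)
    if (all(is.finite(g)) && all(g > 0)) {
      return(structure(list(par = par, fitted = g, converged = TRUE,
                            fallback = FALSE), class = "hugershoff_fit"))
    }
  }
  # horizontal-mean fallback: g(t) = mean(bai)
  m <- mean(bai)
  structure(list(par = c(A = 0, b = 0, c = 0, d = m), fitted = rep(m, n),
                 converged = FALSE, fallback = TRUE),
            class = "hugershoff_fit")
}

#' Detrend a BAI series with a fitted age curve
#'
#' Default is ratio detrending (the ring-width-index convention):
#' `index_t = BAI_t / g(t)`. Difference detrending (`BAI_t - g(t)`) is
#' available as an option.
#'
#' @param bai BAI series.
#' @param fit a [fit_hugershoff()] result for the same series.
#' @param mode `"ratio"` or `"difference"`.
#' @return detrended index series.
#' @export
detrend_bai <- function(bai, fit, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  assert_that(inherits(fit, "hugershoff_fit"), "`fit` must come from fit_hugershoff()")
  g <- fit$fitted
  assert_that(length(g) == length(bai), "fit and series lengths differ")
  if (mode == "ratio") {
    assert_that(all(g > 0), "fitted curve must be positive for ratio detrending")
    bai / g
  } else {
    bai - g
  }
}

#' Prewhiten a growth index with an AR(1) model
#'
#' Centers the series, estimates phi by conditional least squares (OLS of x_t
#' on x_{t-1}) and returns the innovations `e_t = x_t - phi x_{t-1}` for
#' t >= 2. The first value is kept as the centered x_1 so the chronology
#' retains one value per ring year (set `keep_first = FALSE` to drop it).
#' phi is clipped into (-0.999, 0.999) with a warning if the CLS estimate
#' falls outside.
#'
#' @param x index series, length >= 3.
#' @param keep_first keep the centered first observation as its own residual.
#' @return list: `residuals`, `phi`.
#' @export
prewhiten_ar1 <- function(x, keep_first = TRUE) {
  n <- length(x)
  assert_that(n >= 3, "need >= 3 observations for AR(1) prewhitening")
  xc <- x - mean(x)
  den <- sum(xc[-n]^2)
  if (den <= .Machine$double.eps * n) { # constant series
    return(list(residuals = rep(0, if (keep_first) n else n - 1), phi = 0))
  }
  phi <- sum(xc[-1] * xc[-n]) / den
  if (abs(phi) >= 1) {
    warning("AR(1) coefficient ", round(phi, 3), " clipped into (-1, 1)")
    phi <- sign(phi) * 0.999
  }
  res <- xc[-1] - phi * xc[-n]
  if (keep_first) res <- c(xc[1], res)
  list(residuals = res, phi = phi)
}

#' Tukey's biweight robust mean
#'
#' Iterative biweight location estimate: with current location m and fixed
#' scale S (the median absolute deviation about the initial median),
#' `u_i = (x_i - m) / (c S)`; points with |u| >= 1 get weight 0, others
#' `(1 - u^2)^2`, and m is updated to the weighted mean until the change is
#' below 1e-8. If S = 0 the median is returned. The dendrochronology-standard
#' tuning constant c = 9 is the default.
#'
#' @param x numeric values (non-finite values dropped).
#' @param c tuning constant.
#' @return the biweight mean.
#' @export
#' @examples
#' tukey_biweight_mean(c(1, 2, 3, 1000)) # outlier ignored
tukey_biweight_mean <- function(x, c = 9) {
  x <- x[is.finite(x)]
  assert_that(length(x) >= 1, "need at least one finite value")
  m <- stats::median(x)
  S <- stats::median(abs(x - m))
  if (S <= 0) return(m)
  for (i in 1:100) {
    u <- (x - m) / (c * S)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w) <= 0) return(m)
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-8) return(m_new)
    m <- m_new
  }
  m
}

#' Build a per-clone chronology from replicate residual series
#'
#' Aligns the replicate trees of one clone by calendar year and takes the
#' Tukey biweight mean across replicates within each year.
#'
#' @param residual_list list of numeric vectors (one per replicate tree).
#' @param years_list list of matching integer year vectors.
#' @param clone_id,site identifiers carried into the output.
#' @return data.frame: `clone_id`, `site`, `year`, `relative_bai`, `n_reps`.
#' @export
build_clone_chronology <- function(residual_list, years_list, clone_id = NA,
                                   site = NA) {
  assert_that(length(residual_list) >= 1, "need at least one replicate tree")
  assert_that(length(residual_list) == length(years_list),
              "residuals and years lists differ in length")
  all_years <- sort(unique(unlist(years_list)))
  assert_that(length(all_years) > 0, "replicates share no years")
  vals <- nrep <- numeric(length(all_years))
  for (i in seq_along(all_years)) {
    y <- all_years[i]
    v <- unlist(lapply(seq_along(residual_list), function(j) {
      k <- match(y, years_list[[j]])
      if (is.na(k)) NULL else residual_list[[j]][k]
    }))
    vals[i] <- tukey_biweight_mean(v)
    nrep[i] <- length(v)
  }
  data.frame(clone_id = clone_id, site = site, year = all_years,
             relative_bai = vals, n_reps = as.integer(nrep),
             stringsAsFactors = FALSE)
}

#' Process a ring-width table into per-clone chronologies
#'
#' Per tree: widths -> BAI -> Hugershoff detrending -> AR(1) prewhitening
#' ("relative BAI"); per clone: Tukey biweight mean across replicate trees
#' within each year. The stage order (detrend, then prewhiten, then average)
#' matters and is fixed.
#'
#' @param rings data.frame with columns `tree_id`, `clone_id`, `site`,
#'   `year`, `width_mm`.
#' @param detrend `"ratio"` or `"difference"` age-trend removal.
#' @param keep_first see [prewhiten_ar1()].
#' @return data.frame chronology (`clone_id`, `site`, `year`, `relative_bai`,
#'   `n_reps`) with attribute `fits`: per-tree data.frame of Hugershoff
#'   convergence/fallback flags and AR(1) phi.
#' @export
process_rings <- function(rings, detrend = c("ratio", "difference"),
                          keep_first = TRUE) {
  detrend <- match.arg(detrend)
  need <- c("tree_id", "clone_id", "site", "year", "width_mm")
  assert_that(all(need %in% names(rings)),
              paste("ring table needs columns:", paste(need, collapse = ", ")))
  rings <- rings[order(rings$tree_id, rings$year), ]
  trees <- split(rings, rings$tree_id)
  res <- lapply(trees, function(tr) {
    assert_that(all(diff(tr$year) == 1),
                paste0("tree ", tr$tree_id[1], ": years are not consecutive"))
    assert_that(nrow(tr) >= 4,
                paste0("tree ", tr$tree_id[1], ": need >= 4 rings"))
    bai <- bai_from_widths(tr$width_mm, tr$tree_id[1], tr$year)
    fit <- fit_hugershoff(bai)
    idx <- detrend_bai(bai, fit, detrend)
    pw <- prewhiten_ar1(idx, keep_first = keep_first)
    yrs <- if (keep_first) tr$year else tr$year[-1]
    list(clone = tr$clone_id[1], site = tr$site[1], years = yrs,
         residuals = pw$residuals, phi = pw$phi, fallback = fit$fallback,
         converged = fit$converged)
  })
  fits <- data.frame(tree_id = names(res),
                     phi = vapply(res, `[[`, 0, "phi"),
                     hugershoff_fallback = vapply(res, `[[`, TRUE, "fallback"),
                     row.names = NULL, stringsAsFactors = FALSE)
  byclone <- split(res, vapply(res, `[[`, "", "clone"))
  chron <- do.call(rbind, lapply(names(byclone), function(cl) {
    r <- byclone[[cl]]
    build_clone_chronology(lapply(r, `[[`, "residuals"),
                           lapply(r, `[[`, "years"),
                           clone_id = cl, site = r[[1]]$site)
  }))
  rownames(chron) <- NULL
  attr(chron, "fits") <- fits
  chron
}
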