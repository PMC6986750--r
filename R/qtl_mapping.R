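# QTL mapping of climate sensitivity traits: genotype encoding, significance
# filtering, phenotypic variance explained, cross-validated prediction
# accuracy and a Haley-Knott interval-mapping validation scan.

#' Encode a raw marker table into a design-ready genotype matrix
#'
#' Heterozygous calls become 0 and homozygous calls 1 (pseudo-testcross 1:1
#' coding). Markers with a missing rate above `max_missing` are excluded;
#' remaining missing entries are imputed with the marker mean; monomorphic
#' columns are dropped. Markers from both parental maps are concatenated into
#' one design matrix.
#'
#' @param marker_df data.frame with columns `marker`, `linkage_group`,
#'   `map_label`, `position_cM` followed by one column per clone holding
#'   `"het"`, `"hom"` or `"missing"` (0/1/NA also accepted).
#' @param clones optional clone ids (e.g. phenotype names); the genotype
#'   columns must cover them exactly or the call is rejected with a diff.
#' @param max_missing missing-rate exclusion cutoff (default 1%).
#' @return list: `X` (clones x markers numeric matrix, imputed), `info`
#'   (marker/linkage_group/map_label/position_cM/missing_rate for kept
#'   markers), `excluded` (marker + reason).
#' @export
encode_genotypes <- function(marker_df, clones = NULL, max_missing = 0.01) {
  meta_cols <- c("marker", "linkage_group", "map_label", "position_cM")
  assert_that(all(meta_cols %in% names(marker_df)),
              paste("marker table needs columns:", paste(meta_cols, collapse = ", ")))
  clone_cols <- setdiff(names(marker_df), meta_cols)
  assert_that(length(clone_cols) >= 2, "marker table has no clone columns")
  if (!is.null(clones)) {
    missing_clones <- setdiff(clones, clone_cols)
    if (length(missing_clones))
      stop("clone ids absent from the marker table: ",
           paste(utils::head(missing_clones, 10), collapse = ", "),
           if (length(missing_clones) > 10) " ..." else "", call. = FALSE)
    clone_cols <- clones
  }
  raw <- t(as.matrix(marker_df[, clone_cols, drop = FALSE])) # clones x markers
  enc <- function(v) {
    if (is.numeric(v)) return(ifelse(is.finite(v), as.numeric(v), NA_real_))
    v <- tolower(trimws(as.character(v)))
    out <- rep(NA_real_, length(v))
    out[v %in% c("het", "0")] <- 0
    out[v %in% c("hom", "1")] <- 1
    bad <- !(v %in% c("het", "hom", "missing", "na", "", "0", "1"))
    if (any(bad))
      stop("unparseable genotype code(s): ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
    out
  }
  X <- apply(raw, 2, enc)
  dimnames(X) <- list(clone_cols, marker_df$marker)
  miss_rate <- colMeans(is.na(X))
  excluded <- data.frame(marker = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  drop_missing <- miss_rate > max_missing
  if (any(drop_missing))
    excluded <- rbind(excluded, data.frame(marker = colnames(X)[drop_missing],
                                           reason = "missing_rate",
                                           stringsAsFactors = FALSE))
  X <- X[, !drop_missing, drop = FALSE]
  # mean imputation of the remaining sporadic missing calls
  nas <- which(is.na(X), arr.ind = TRUE)
  if (nrow(nas)) {
    cm <- colMeans(X, na.rm = TRUE)
    X[nas] <- cm[nas[, 2]]
  }
  mono <- apply(X, 2, stats::var) == 0
  if (any(mono))
    excluded <- rbind(excluded, data.frame(marker = colnames(X)[mono],
                                           reason = "monomorphic",
                                           stringsAsFactors = FALSE))
  X <- X[, !mono, drop = FALSE]
  info <- marker_df[match(colnames(X), marker_df$marker), meta_cols]
  info$missing_rate <- miss_rate[colnames(X)]
  rownames(info) <- NULL
  list(X = X, info = info, excluded = excluded)
}

#' Significant QTLs from an empirical-Bayes fit
#'
#' Retained (non-zero) effects with p below `alpha`, ordered by decreasing
#' absolute effect size.
#'
#' @param fit an [eblasso_fit()] object.
#' @param alpha significance level (0.01 by convention for QTL calls).
#' @return data.frame `marker`, `beta`, `se`, `t`, `p` (possibly empty).
#' @export
significant_qtls <- function(fit, alpha = 0.01) {
  assert_that(inherits(fit, "eblasso"), "`fit` must come from eblasso_fit()")
  d <- fit$selected
  d <- d[!is.na(d$p) & d$p < alpha, , drop = FALSE]
  d <- d[order(-abs(d$beta)), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Phenotypic variance explained by a single QTL
#'
#' `PVE_i = beta_i^2 var(x_i) / var(y)`, in percent.
#'
#' @param beta estimated marker effect.
#' @param x marker genotype vector.
#' @param y phenotype vector.
#' @return PVE in percent.
#' @export
pve_per_qtl <- function(beta, x, y) {
  vy <- stats::var(y)
  assert_that(is.finite(vy) && vy > 0, "phenotype variance is zero")
  100 * beta^2 * stats::var(x) / vy
}

#' Total phenotypic variance explained by a marker set
#'
#' Variance of the fitted values from an OLS regression of the phenotype on
#' the given markers (with intercept), relative to the phenotype variance —
#' identical to the regression R^2. Aliased columns are dropped with a
#' warning.
#'
#' @param X genotype matrix.
#' @param y phenotype.
#' @param markers marker names (columns of X); empty set gives 0.
#' @return PVE in percent.
#' @export
pve_all <- function(X, y, markers) {
  if (length(markers) == 0) return(0)
  assert_that(all(markers %in% colnames(X)), "markers not found in X")
  Xs <- X[, markers, drop = FALSE]
  assert_that(length(y) > length(markers) + 1,
              "need n > number of markers + 1 for the joint regression")
  fit <- stats::lm(y ~ Xs)
  if (anyNA(stats::coef(fit)))
    warning("aliased marker columns dropped from the joint regression")
  100 * stats::var(stats::fitted(fit)) / stats::var(y)
}

#' Cross-validated prediction accuracy of a marker set
#'
#' Out-of-fold OLS predictions from the marker set, assembled over all k
#' folds, correlated with the observed phenotype (Pearson r). Returns NA if
#' predictions are constant.
#'
#' @param X genotype matrix.
#' @param y phenotype.
#' @param markers marker names used as predictors.
#' @param k folds.
#' @param seed fold-assignment seed.
#' @return list: `r`, `p`, `predicted` (out-of-fold predictions), `folds`.
#' @export
cv_prediction_accuracy <- function(X, y, markers, k = 5, seed = 1L) {
  n <- length(y)
  assert_that(length(markers) >= 1, "need at least one marker")
  assert_that(k >= 2 && k <= n, "k must be in [2, n]")
  Xs <- X[, markers, drop = FALSE]
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    df_tr <- data.frame(y = y[tr], Xs[tr, , drop = FALSE])
    fit <- stats::lm(y ~ ., data = df_tr)
    nd <- as.data.frame(Xs[!tr, , drop = FALSE])
    pred[!tr] <- suppressWarnings(stats::predict(fit, newdata = nd))
  }
  if (stats::sd(pred) == 0)
    return(list(r = NA_real_, p = NA_real_, predicted = pred, folds = folds))
  ct <- stats::cor.test(y, pred)
  list(r = unname(ct$estimate), p = ct$p.value, predicted = pred,
       folds = folds)
}

#' Full QTL-mapping result for one phenotype
#'
#' Runs (optionally) cross-validated hyperparameter selection, the
#' empirical-Bayes fit, the significance filter, per-QTL and total PVE and
#' the cross-validated prediction accuracy, and assembles the result table
#' (marker, linkage group, map, position, effect, p, PVE %) ordered by
#' absolute effect size. Selection and p-values come from the
#' empirical-Bayes fit; the reported effects (and hence per-QTL PVE) are
#' re-estimated by a joint OLS refit on the significant set, which de-biases
#' the shrunken posterior means and keeps the per-QTL PVE on the same scale
#' as the joint PVE.
#'
#' @param X encoded genotype matrix (see [encode_genotypes()]).
#' @param info marker info data.frame matching the columns of X.
#' @param y named phenotype vector (names must match rownames of X).
#' @param alpha significance level for QTL calls.
#' @param a,b fixed hyperparameters; if either is NULL they are selected on
#'   `grid` by k-fold cross-validation.
#' @param grid hyperparameter grid for CV.
#' @param k CV folds.
#' @param seed seed for fold assignments (hyperparameter CV and prediction
#'   accuracy).
#' @return list of class `qtl_result`: `qtls` (significant-QTL table),
#'   `fit`, `pve_all_pct`, `cv_r`, `cv_p`, `a`, `b`, `seed`, `cv_table`.
#' @export
map_qtls <- function(X, info, y, alpha = 0.01, a = NULL, b = NULL,
                     grid = default_hyperparameter_grid(), k = 5, seed = 1L) {
  if (!is.null(names(y))) {
    assert_that(all(names(y) %in% rownames(X)),
                "phenotype clones missing from the genotype matrix")
    X <- X[names(y), , drop = FALSE]
  }
  cv_table <- NULL
  if (is.null(a) || is.null(b)) {
    sel <- cv_select_hyperparams(X, y, grid, k = k, seed = seed)
    a <- sel$a
    b <- sel$b
    cv_table <- sel$cv_table
  }
  fit <- eblasso_fit(X, y, a = a, b = b)
  sig <- significant_qtls(fit, alpha)
  qtls <- cbind(info[match(sig$marker, info$marker),
                     c("marker", "linkage_group", "map_label", "position_cM")],
                beta = sig$beta, se = sig$se, p = sig$p)
  if (nrow(qtls) > 0) {
    # reported effects are re-estimated by joint OLS on the significant set
    # (two-stage de-biasing): the shrunken posterior means understate strong
    # effects, and the refit keeps per-QTL PVE coherent with the joint PVE,
    # which is defined through the same regression
    Xs <- X[, qtls$marker, drop = FALSE]
    colnames(Xs) <- qtls$marker
    refit <- stats::lm(y ~ ., data = as.data.frame(Xs))
    cf <- stats::coef(refit)[-1]
    cf[is.na(cf)] <- 0
    sm <- stats::summary.lm(refit)$coefficients
    se <- rep(NA_real_, length(cf))
    names(se) <- names(cf)
    hit <- intersect(rownames(sm), names(cf))
    se[hit] <- sm[hit, "Std. Error"]
    ord <- match(make.names(qtls$marker), names(cf))
    qtls$beta <- unname(cf[ord])
    qtls$se <- unname(se[ord])
    qtls <- qtls[order(-abs(qtls$beta)), , drop = FALSE]
  }
  qtls$pve_pct <- vapply(seq_len(nrow(qtls)), function(i)
    pve_per_qtl(qtls$beta[i], X[, qtls$marker[i]], y), 0)
  rownames(qtls) <- NULL
  pa <- pve_all(X, y, qtls$marker)
  cv <- if (nrow(qtls)) cv_prediction_accuracy(X, y, qtls$marker, k, seed)
        else list(r = NA_real_, p = NA_real_)
  structure(list(qtls = qtls, fit = fit, pve_all_pct = pa, cv_r = cv$r,
                 cv_p = cv$p, a = a, b = b, seed = seed, alpha = alpha,
                 cv_table = cv_table),
            class = "qtl_result")
}

#' @export
print.qtl_result <- function(x, ...) {
  cat("QTL mapping (empirical Bayesian lasso, a =", x$a, ", b =", x$b, ")\n")
  cat(nrow(x$qtls), "significant QTLs at alpha =", x$alpha, "\n")
  if (nrow(x$qtls)) print(x$qtls, row.names = FALSE, digits = 3)
  cat("PVE (all QTLs):", round(x$pve_all_pct, 1), "%\n")
  cat("CV prediction accuracy r =", round(x$cv_r, 3), "\n")
  invisible(x)
}

#' Collapse marker-level QTL calls into QTL regions
#'
#' With densely spaced markers, one causal locus is often represented by two
#' or three retained markers in tight linkage, splitting the effect between
#' them. This groups markers on the same linkage group lying within `window`
#' cM of their neighbor into one region and ranks regions by the joint
#' variance they explain (OLS R^2 of the phenotype on the region's markers).
#'
#' @param markers character vector of marker names (e.g. a significant or
#'   retained set).
#' @param info marker info data.frame (marker, map_label, linkage_group,
#'   position_cM).
#' @param X genotype matrix.
#' @param y phenotype.
#' @param window maximum gap (cM) between neighboring markers of one region.
#' @return data.frame, one row per region: `map_label`, `linkage_group`,
#'   `position_cM` (of the region's strongest marker), `n_markers`,
#'   `markers` (comma-separated), `pve_pct` (joint, in percent), ordered by
#'   decreasing `pve_pct`.
#' @export
qtl_regions <- function(markers, info, X, y, window = 10) {
  if (length(markers) == 0)
    return(data.frame(map_label = character(0), linkage_group = character(0),
                      position_cM = numeric(0), n_markers = integer(0),
                      markers = character(0), pve_pct = numeric(0)))
  i <- match(markers, info$marker)
  assert_that(!anyNA(i), "unknown markers")
  d <- data.frame(marker = markers, map_label = info$map_label[i],
                  linkage_group = info$linkage_group[i],
                  position_cM = info$position_cM[i],
                  stringsAsFactors = FALSE)
  d <- d[order(d$map_label, d$linkage_group, d$position_cM), ]
  grp <- paste(d$map_label, d$linkage_group)
  new_region <- c(TRUE, grp[-1] != grp[-nrow(d)] |
                    diff(d$position_cM) > window)
  d$region <- cumsum(new_region)
  out <- do.call(rbind, lapply(split(d, d$region), function(dd) {
    r2 <- summary(stats::lm(y ~ X[, dd$marker, drop = FALSE]))$r.squared
    # anchor the region at its strongest single marker
    single <- vapply(dd$marker, function(m) stats::cor(y, X[, m])^2, 0)
    best <- which.max(single)
    data.frame(map_label = dd$map_label[1], linkage_group = dd$linkage_group[1],
               position_cM = dd$position_cM[best],
               n_markers = nrow(dd),
               markers = paste(dd$marker, collapse = ","),
               pve_pct = 100 * r2, stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$pve_pct), ]
  rownames(out) <- NULL
  out
}

# Expected QTL genotype at a test position given (possibly imputed) flanking
# marker genotypes, pseudo-testcross coding, Haldane recombination.
expected_genotype <- function(gL, rL, gR = NULL, rR = NULL) {
  tL1 <- gL * (1 - rL) + (1 - gL) * rL
  if (is.null(gR)) return(tL1)
  tR1 <- gR * (1 - rR) + (1 - gR) * rR
  tL0 <- 1 - tL1
  tR0 <- 1 - tR1
  num <- tL1 * tR1
  den <- num + tL0 * tR0
  ifelse(den > 0, num / den, 0.5)
}

#' Haley-Knott interval-mapping LOD scan
#'
#' Regression-based interval mapping used to validate the sparse-regression
#' QTL calls. On a cM grid within each linkage group the expected genotype
#' given the flanking markers (inverse Haldane map function) is regressed on
#' the phenotype; `LOD = (n/2) log10(RSS0 / RSS1)`. Optional cofactor markers
#' enter both the null and full models, except cofactors within `window` cM
#' of the test position on the same linkage group.
#'
#' @param X encoded genotype matrix.
#' @param info marker info (linkage_group, map_label, position_cM) for the
#'   columns of X.
#' @param y named phenotype vector.
#' @param step grid step in cM.
#' @param cofactors optional character vector of cofactor marker names.
#' @param window cofactor exclusion window in cM.
#' @return data.frame: `map_label`, `linkage_group`, `position_cM`, `lod`.
#' @export
interval_mapping_scan <- function(X, info, y, step = 1, cofactors = NULL,
                                  window = 10) {
  assert_that(step > 0, "step must be positive")
  if (!is.null(names(y))) X <- X[names(y), , drop = FALSE]
  n <- length(y)
  if (!is.null(cofactors))
    assert_that(all(cofactors %in% colnames(X)), "unknown cofactor markers")
  groups <- unique(info[, c("map_label", "linkage_group")])
  out <- vector("list", nrow(groups))
  const_y <- stats::sd(y) == 0
  for (gi in seq_len(nrow(groups))) {
    sel <- info$map_label == groups$map_label[gi] &
      info$linkage_group == groups$linkage_group[gi]
    pos <- info$position_cM[sel]
    mk <- info$marker[sel]
    o <- order(pos)
    pos <- pos[o]
    mk <- mk[o]
    grid_pos <- unique(c(seq(min(pos), max(pos), by = step), max(pos)))
    lod <- numeric(length(grid_pos))
    if (!const_y) {
      for (pi in seq_along(grid_pos)) {
        p0 <- grid_pos[pi]
        iL <- findInterval(p0, pos)
        if (iL == 0) {
          eg <- expected_genotype(X[, mk[1]], haldane_r(pos[1] - p0))
        } else if (iL >= length(pos) || pos[iL] == p0) {
          near <- if (pos[iL] == p0) iL else length(pos)
          eg <- expected_genotype(X[, mk[near]], haldane_r(abs(p0 - pos[near])))
        } else {
          eg <- expected_genotype(X[, mk[iL]], haldane_r(p0 - pos[iL]),
                                  X[, mk[iL + 1]], haldane_r(pos[iL + 1] - p0))
        }
        cof <- cofactors
        if (!is.null(cof)) {
          ci <- match(cof, info$marker)
          same <- info$map_label[ci] == groups$map_label[gi] &
            info$linkage_group[ci] == groups$linkage_group[gi] &
            abs(info$position_cM[ci] - p0) <= window
          cof <- cof[!same]
        }
        base <- if (length(cof)) cbind(1, X[, cof, drop = FALSE]) else matrix(1, n, 1)
        rss0 <- sum(stats::lm.fit(base, y)$residuals^2)
        rss1 <- sum(stats::lm.fit(cbind(base, eg), y)$residuals^2)
        lod[pi] <- if (rss1 > 0 && rss0 > 0) max(n / 2 * log10(rss0 / rss1), 0) else 0
      }
    }
    out[[gi]] <- data.frame(map_label = groups$map_label[gi],
                            linkage_group = groups$linkage_group[gi],
                            position_cM = grid_pos, lod = lod,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
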