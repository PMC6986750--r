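mk_marker_df <- function(X, map) {
  codes <- matrix(c("het", "hom")[X + 1L], nrow = nrow(X),
                  dimnames = dimnames(X))
  cbind(map, as.data.frame(t(codes), stringsAsFactors = FALSE))
}

test_that("genotype encoding applies the exclusion and imputation rules", {
  map <- tiny_map()
  X <- simulate_genotypes(map, 139, seed = 2)
  df <- mk_marker_df(X, map)
  # 2 missing of 139 (1.44%) -> excluded; 1 missing (0.72%) -> imputed
  df[df$marker == "m_0001", c("c001", "c002")] <- "missing"
  df[df$marker == "m_0002", "c001"] <- "missing"
  df[df$marker == "m_0003", paste0("c", sprintf("%03d", 1:139))] <-
    "het" # monomorphic
  enc <- encode_genotypes(df)
  expect_true("m_0001" %in% enc$excluded$marker[enc$excluded$reason == "missing_rate"])
  expect_true("m_0003" %in% enc$excluded$marker[enc$excluded$reason == "monomorphic"])
  expect_false("m_0001" %in% colnames(enc$X))
  # imputed value equals the observed mean of the marker
  kept <- enc$X[, "m_0002"]
  obs <- X[-1, "m_0002"]
  expect_equal(unname(kept["c001"]), mean(obs))
  expect_equal(unname(kept[-1]), unname(X[-1, "m_0002"]))
  # clone mismatch is rejected with a diff
  expect_error(encode_genotypes(df, clones = c("c001", "nope")), "nope")
  # unparseable codes are rejected
  bad <- df
  bad[1, "c005"] <- "heterozygote"
  expect_error(encode_genotypes(bad), "unparseable")
})

test_that("per-QTL PVE follows the variance formula", {
  x <- rep(c(0, 1), each = 50)
  y <- rnorm(100)
  y <- y * sqrt(0.5 / var(y)) # var(y) = 0.5 exactly
  expect_equal(pve_per_qtl(1, x, y), 100 * var(x) / 0.5)
  expect_equal(pve_per_qtl(0, x, y), 0)
  expect_error(pve_per_qtl(1, x, rep(1, 100)), "variance is zero")
})

test_that("total PVE equals the OLS R-squared", {
  set.seed(70)
  for (r in 1:10) {
    n <- 60
    X <- matrix(rbinom(n * 6, 1, 0.5), n, 6,
                dimnames = list(NULL, paste0("m", 1:6)))
    y <- drop(X %*% rnorm(6)) + rnorm(n)
    pa <- pve_all(X, y, paste0("m", 1:4))
    r2 <- summary(lm(y ~ X[, 1:4]))$r.squared
    expect_equal(pa, 100 * r2, tolerance = 1e-10)
  }
  X <- matrix(rbinom(200, 1, 0.5), 50, 4,
              dimnames = list(NULL, paste0("m", 1:4)))
  y_lin <- drop(X %*% c(1, 2, -1, 0.5))
  expect_equal(pve_all(X, y_lin, colnames(X)), 100, tolerance = 1e-8)
  expect_equal(pve_all(X, rnorm(50), character(0)), 0)
  # aliased columns are dropped with a warning
  Xa <- cbind(X, m5 = X[, 1])
  expect_warning(pve_all(Xa, y_lin, colnames(Xa)), "aliased")
})

test_that("cross-validated prediction accuracy behaves at both extremes", {
  set.seed(80)
  X <- matrix(rbinom(139 * 5, 1, 0.5), 139, 5,
              dimnames = list(NULL, paste0("m", 1:5)))
  y <- drop(X %*% c(1, -1, 0.5, 0.8, -0.7))
  cv <- cv_prediction_accuracy(X, y, colnames(X), seed = 1)
  expect_gte(cv$r, 0.999)
  # pure noise: mean out-of-fold r near zero over replicates
  rs <- vapply(1:100, function(r) {
    set.seed(100 + r)
    yr <- rnorm(139)
    cv_prediction_accuracy(X, yr, colnames(X), seed = r)$r
  }, 0)
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("significant QTLs are filtered at alpha and sorted by effect", {
  f <- structure(list(selected = data.frame(
    marker = c("a", "b", "c"), beta = c(0.2, -0.9, 0.5),
    se = c(0.1, 0.1, 0.1), t = c(2, -9, 5),
    p = c(0.02, 1e-6, 0.004))), class = "eblasso")
  sig <- significant_qtls(f, 0.01)
  expect_equal(sig$marker, c("b", "c"))
  f0 <- structure(list(selected = data.frame(marker = character(0),
                                             beta = numeric(0),
                                             se = numeric(0), t = numeric(0),
                                             p = numeric(0))),
                  class = "eblasso")
  expect_equal(nrow(significant_qtls(f0)), 0)
})

test_that("interval mapping peaks at a perfectly associated marker", {
  map <- map_spec(list(LG01 = seq(0, 60, by = 5),
                       LG02 = seq(0, 60, by = 5)), "P1")
  X <- simulate_genotypes(map, 150, seed = 90)
  info <- map
  info$missing_rate <- 0
  y <- as.numeric(X[, "m_0005"]) # marker at 20 cM on LG01
  names(y) <- rownames(X)
  prof <- interval_mapping_scan(X, info, y, step = 1)
  expect_true(all(prof$lod >= 0))
  peak <- prof[which.max(prof$lod), ]
  expect_equal(peak$linkage_group, "LG01")
  expect_lt(abs(peak$position_cM - 20), 2)
  # constant phenotype: flat zero profile
  flat <- interval_mapping_scan(X, info, rep(1, 150), step = 5)
  expect_true(all(flat$lod == 0))
  expect_error(interval_mapping_scan(X, info, y, step = 0), "positive")
})

test_that("cofactors absorb background signal outside the test window", {
  map <- map_spec(list(LG01 = seq(0, 60, by = 5),
                       LG02 = seq(0, 60, by = 5)), "P1")
  X <- simulate_genotypes(map, 200, seed = 91)
  info <- map
  set.seed(92)
  y <- X[, "m_0005"] * 1 + X[, "m_0020"] * 1 + rnorm(200, 0, 0.5)
  plain <- interval_mapping_scan(X, info, y, step = 2)
  with_cof <- interval_mapping_scan(X, info, y, step = 2,
                                    cofactors = "m_0020")
  # conditioning on the LG02 cofactor sharpens the LG01 peak
  lg1 <- with_cof$linkage_group == "LG01"
  expect_gt(max(with_cof$lod[lg1]), max(plain$lod[plain$linkage_group == "LG01"]))
  # near the cofactor itself the cofactor is excluded from the model
  lg2pos <- with_cof$linkage_group == "LG02" &
    abs(with_cof$position_cM - map$position_cM[map$marker == "m_0020"]) <= 2
  expect_gt(max(with_cof$lod[lg2pos]), 3)
})

test_that("map_qtls assembles a coherent result table", {
  map <- rbind(tiny_map("P1"), tiny_map("P2", offset = 1000L))
  X <- cbind(simulate_genotypes(tiny_map("P1"), 139, seed = 95),
             simulate_genotypes(tiny_map("P2", offset = 1000L), 139, seed = 96))
  set.seed(97)
  y <- X[, "m_0004"] * 0.8 - X[, "m_1010"] * 0.6 + rnorm(139, 0, 0.5)
  names(y) <- rownames(X)
  info <- map
  info$missing_rate <- 0
  res <- map_qtls(X, info, y, a = 0.1, b = 0.1, seed = 3)
  expect_s3_class(res, "qtl_result")
  # markers are linked (5 cM), so the call may land on a close neighbor;
  # both planted regions must be hit and ordered by effect size
  hit <- function(marker) {
    i <- match(marker, info$marker)
    any(res$qtls$map_label == info$map_label[i] &
          res$qtls$linkage_group == info$linkage_group[i] &
          abs(res$qtls$position_cM - info$position_cM[i]) <= 10)
  }
  expect_true(hit("m_0004"))
  expect_true(hit("m_1010"))
  expect_true(abs(res$qtls$beta[1]) == max(abs(res$qtls$beta)))
  expect_true(all(res$qtls$pve_pct >= 0 & res$qtls$pve_pct <= 100))
  expect_lte(res$pve_all_pct, 100)
  expect_gt(res$cv_r, 0.3)
  # PVE_all from the significant set matches a direct OLS R^2
  expect_equal(res$pve_all_pct,
               100 * summary(lm(y ~ X[, res$qtls$marker]))$r.squared,
               tolerance = 1e-10)
})
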