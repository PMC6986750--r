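test_that("map specifications validate positions", {
  expect_error(map_spec(list(), "P1"), "non-empty")
  expect_error(map_spec(list(LG01 = c(3, 1)), "P1"), "strictly increasing")
  expect_error(map_spec(list(LG01 = c(-1, 2)), "P1"), ">= 0")
  m <- default_map_spec("P1", n_groups = 11, group_length = 60, spacing = 1.5)
  expect_equal(length(unique(m$linkage_group)), 11)
  expect_equal(nrow(m), 11 * 41)
})

test_that("completely linked markers are identical and seeds reproduce", {
  # two groups whose two markers are 1e-9 cM apart: recombination ~ 0
  map <- map_spec(list(LG01 = c(0, 1e-9)), "P1")
  X <- simulate_genotypes(map, 500, seed = 11)
  expect_equal(X[, 1], X[, 2], ignore_attr = TRUE)
  X2 <- simulate_genotypes(map, 500, seed = 11)
  expect_identical(X, X2)
  expect_false(identical(X, simulate_genotypes(map, 500, seed = 12)))
  expect_error(simulate_genotypes(map[0, ], 10, 1), "empty")
})

test_that("recombination fraction follows the Haldane map function", {
  map <- map_spec(list(LG01 = c(0, 10)), "P1")
  n <- 2000
  X <- simulate_genotypes(map, n, seed = 21)
  r_obs <- mean(X[, 1] != X[, 2])
  r_exp <- (1 - exp(-0.2)) / 2
  expect_lt(abs(r_obs - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
})

test_that("markers segregate 1:1 and recombination grows with distance", {
  map <- map_spec(list(LG01 = seq(0, 60, by = 15)), "P1")
  n <- 600
  X <- simulate_genotypes(map, n, seed = 31)
  het <- colMeans(X == 0)
  expect_true(all(abs(het - 0.5) < 3 * sqrt(0.25 / n)))
  # pairwise recombination from the first marker increases with distance
  r <- vapply(2:ncol(X), function(j) mean(X[, 1] != X[, j]), 0)
  expect_true(all(diff(r) > -0.05)) # monotone up to sampling noise
  expect_true(all(r < 0.5 + 3 * sqrt(0.25 / n)))
})

test_that("daily climate covers every day and honors degenerate chains", {
  clim <- simulate_daily_climate(2006:2008, weather_params(), seed = 5)
  expect_equal(nrow(clim),
               as.integer(as.Date("2008-12-31") - as.Date("2006-01-01")) + 1)
  expect_true(all(diff(clim$date) == 1))
  expect_true(all(clim$precip_mm >= 0))
  expect_error(simulate_daily_climate(2006, weather_params(), 1),
               "at least 2")
  expect_error(weather_params(p_ww = rep(1.5, 12)), "in \\[0,1\\]")

  # absorbing wet state: after day one every day is wet, dry index all zero
  wetpar <- weather_params(p_ww = rep(1, 12), p_dw = rep(1, 12))
  wet <- simulate_daily_climate(2006:2007, wetpar, seed = 5)
  expect_true(all(wet$precip_mm[-1] > 0))
  for (k in c(1, 4, 7)) {
    m <- monthly_dry_index(wet[-1, ], k)
    expect_true(all(m == 0))
  }

  # absorbing dry state: no day is ever wet
  drypar <- weather_params(p_ww = rep(0, 12), p_dw = rep(0, 12))
  dry <- simulate_daily_climate(2006:2007, drypar, seed = 5)
  expect_true(all(dry$precip_mm == 0))
})

test_that("stationary wet fraction matches the chain's stationary law", {
  # p_ww = p_dw = 0.5 makes days iid Bernoulli(0.5)
  par <- weather_params(p_ww = rep(0.5, 12), p_dw = rep(0.5, 12))
  clim <- simulate_daily_climate(2001:2010, par, seed = 9)
  f <- mean(clim$precip_mm > 0)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / nrow(clim)))
})

test_that("planted sensitivities follow the genotype model", {
  map <- tiny_map()
  X <- simulate_genotypes(map, 100, seed = 3)
  # no QTLs, no noise -> all zero
  tm0 <- truth_model(NULL, clone_noise_sd = 0)
  s0 <- simulate_sensitivities(X, map, tm0, seed = 1)
  expect_true(all(s0$s == 0))
  # one QTL, effect 1, no noise -> sensitivity equals the marker column
  q <- data.frame(map_label = "P1", linkage_group = "LG01", position_cM = 10,
                  effect = 1)
  tm1 <- truth_model(q, clone_noise_sd = 0)
  s1 <- simulate_sensitivities(X, map, tm1, seed = 1)
  j <- s1$qtl_markers$marker
  expect_equal(unname(s1$s), unname(X[, j]))
  expect_equal(s1$qtl_markers$marker_position_cM, 10)
})

test_that("planted PVE bookkeeping is consistent over replicates", {
  map <- tiny_map()
  # alpha for 12% PVE of a var(s)=1 latent trait: alpha = 2 sqrt(0.12)
  q <- data.frame(map_label = "P1", linkage_group = "LG01", position_cM = 15,
                  effect = 2 * sqrt(0.12))
  tm <- truth_model(q, clone_noise_sd = sqrt(1 - 0.12))
  pve <- vapply(1:200, function(r) {
    X <- simulate_genotypes(map, 139, seed = 1000 + r)
    simulate_sensitivities(X, map, tm, seed = r)$qtl_markers$realized_pve_pct
  }, 0)
  expect_lt(abs(mean(pve) - 12), 2)
})

test_that("ring widths reproduce the age trend and respond to climate", {
  map <- tiny_map()
  clim <- tiny_daily(2004:2016)
  # deterministic: no noise, zero sensitivity -> BAI equals the age curve
  tm <- truth_model(NULL, clone_noise_sd = 0, noise_sd = 0)
  s <- stats::setNames(rep(0, 3), c("c1", "c2", "c3"))
  rings <- simulate_ring_widths(s, clim, tm, 2006:2016, n_replicates = 1,
                                seed = 2)
  one <- rings[rings$clone_id == "c1", ]
  bai <- bai_from_widths(one$width_mm)
  g <- dendroqtl:::hugershoff_curve(tm$growth_curve, 1:11)
  expect_equal(bai, g, tolerance = 1e-3) # widths rounded to 4 decimals
  expect_identical(rings,
                   simulate_ring_widths(s, clim, tm, 2006:2016, 1, seed = 2))
  expect_error(simulate_ring_widths(s, clim, tm, 1990:2000, 1, seed = 2),
               "climate")

  # strong link, low noise: sign of the growth-index correlation follows s_c
  tm2 <- truth_model(NULL, clone_noise_sd = 0, noise_sd = 0.05,
                     link_scale = 1)
  s2 <- stats::setNames(rep(c(1, -1), each = 20), sprintf("c%02d", 1:40))
  rings2 <- simulate_ring_widths(s2, clim, tm2, 2006:2016, n_replicates = 1,
                                 seed = 3)
  idx <- monthly_dry_index(clim, 4)
  z <- idx[as.character(2006:2016), "03"]
  chron <- process_rings(rings2)
  ok <- vapply(unique(chron$clone_id), function(cl) {
    d <- chron[chron$clone_id == cl, ]
    r <- cor(d$relative_bai, z[as.character(d$year)])
    sign(r) == sign(s2[cl])
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})

test_that("simulate_dataset writes coherent files plus ground truth", {
  out <- file.path(tempdir(), "simds")
  sim <- simulate_dataset(out, n_clones = 20, n_replicates = 2,
                          ring_years = 2006:2013,
                          map1 = tiny_map("P1"),
                          map2 = tiny_map("P2", offset = 1000L),
                          truth = truth_model(
                            data.frame(map_label = "P1",
                                       linkage_group = "LG01",
                                       position_cM = 10, effect = 0.7)),
                          missing_rate = 0.01, seed = 42)
  expect_true(all(file.exists(unlist(sim$paths))))
  truth <- jsonlite::read_json(sim$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$qtl_markers$effect, 0.7)
  expect_equal(nrow(validate_inputs(sim$paths$rings, sim$paths$markers,
                                    sim$paths$climate)), 0)
  unlink(out, recursive = TRUE)
})
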