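# Synthetic-data generators: linkage maps, pseudo-testcross genotypes, daily
# weather, per-clone drought sensitivities and ring-width tables with planted
# QTL signal. Every generator is a pure function of (arguments, seed).

#' Build a linkage-map specification
#'
#' A map is a set of linkage groups, each with strictly increasing marker
#' positions in centimorgans. Two maps are used in a pseudo-testcross design,
#' one per heterozygous parent; markers on a map segregate 1:1 through that
#' parent only.
#'
#' @param positions named list; one numeric vector of marker positions (cM)
#'   per linkage group. Names are the group labels.
#' @param map_label label of the map / heterozygous parent (e.g. "P1").
#' @param marker_offset integer offset used when auto-naming markers
#'   (`m_0001`, ...), so two maps get disjoint marker names.
#' @return data.frame with columns `marker`, `linkage_group`, `map_label`,
#'   `position_cM`.
#' @export
map_spec <- function(positions, map_label, marker_offset = 0L) {
  assert_that(is.list(positions) && length(positions) > 0,
              "`positions` must be a non-empty named list of position vectors")
  if (is.null(names(positions)) || any(names(positions) == ""))
    names(positions) <- sprintf("LG%02d", seq_along(positions))
  for (g in names(positions)) {
    p <- positions[[g]]
    assert_that(length(p) >= 1 && all(is.finite(p)) && all(p >= 0),
                paste0("group ", g, ": positions must be finite and >= 0"))
    assert_that(all(diff(p) > 0) || length(p) == 1,
                paste0("group ", g, ": positions must be strictly increasing"))
  }
  n <- sum(lengths(positions))
  data.frame(
    marker = sprintf("m_%04d", marker_offset + seq_len(n)),
    linkage_group = rep(names(positions), lengths(positions)),
    map_label = map_label,
    position_cM = unlist(positions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Default two-parent map specification
#'
#' Evenly spaced markers on `n_groups` linkage groups, mirroring the scale of
#' a dense conifer pseudo-testcross map (11 groups, ~1.5 cM spacing, ~450
#' markers per parental map at the default size).
#'
#' @param map_label map label.
#' @param n_groups number of linkage groups.
#' @param group_length group length in cM.
#' @param spacing marker spacing in cM.
#' @param marker_offset see [map_spec()].
#' @return a map specification data.frame.
#' @export
default_map_spec <- function(map_label = "P1", n_groups = 11,
                             group_length = 60, spacing = 1.5,
                             marker_offset = 0L) {
  pos <- rep(list(seq(0, group_length, by = spacing)), n_groups)
  names(pos) <- sprintf("LG%02d", seq_len(n_groups))
  map_spec(pos, map_label, marker_offset)
}

#' Haldane map function and its inverse
#'
#' `haldane_r()` converts a map distance in cM to a recombination fraction,
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @param d_cM map distance in centimorgans.
#' @return recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_cM) 0.5 * (1 - exp(-2 * d_cM / 100))

#' Simulate pseudo-testcross genotypes along a linkage map
#'
#' Each marker segregates 1:1 (heterozygous = 0, homozygous = 1 in the
#' offspring of the heterozygous parent). Along a linkage group the genotype
#' sequence is a Markov chain: adjacent markers recombine with the Haldane
#' fraction of their cM distance. Linkage groups and clones are independent.
#'
#' @param map map specification from [map_spec()].
#' @param n_clones number of clones (>= 2).
#' @param seed integer seed.
#' @return integer matrix `n_clones x n_markers` with values 0 (het) and
#'   1 (hom); rownames are clone ids, colnames marker names.
#' @export
simulate_genotypes <- function(map, n_clones, seed) {
  assert_that(is.data.frame(map) && nrow(map) > 0, "map specification is empty")
  assert_that(n_clones >= 2, "need at least 2 clones")
  with_seed(seed, {
    X <- matrix(0L, nrow = n_clones, ncol = nrow(map),
                dimnames = list(sprintf("c%03d", seq_len(n_clones)),
                                map$marker))
    for (g in unique(map$linkage_group)) {
      idx <- which(map$linkage_group == g)
      pos <- map$position_cM[idx]
      X[, idx[1]] <- rbinom(n_clones, 1L, 0.5)
      if (length(idx) > 1) {
        r <- haldane_r(diff(pos))
        for (j in seq_along(r)) {
          flip <- rbinom(n_clones, 1L, r[j])
          X[, idx[j + 1]] <- bitwXor(X[, idx[j]], flip)
        }
      }
    }
    X
  })
}

#' Weather-generator parameters
#'
#' A two-state (wet/dry) Markov chain with month-specific transition
#' probabilities, gamma-distributed rainfall amounts on wet days, and a
#' sinusoidal temperature cycle. Defaults imitate a warm-temperate monsoon
#' climate with a dry late winter / early spring and a wet summer (annual mean
#' temperature ~15.7 degC, annual precipitation ~1600 mm).
#'
#' @param p_ww length-12 probability wet day follows wet day, by month.
#' @param p_dw length-12 probability wet day follows dry day, by month.
#' @param rain_shape,rain_mean length-12 gamma shape and mean (mm) of wet-day
#'   rainfall by month.
#' @param temp_mean annual mean temperature (degC).
#' @param temp_amplitude seasonal half-range (degC).
#' @param temp_sd day-to-day temperature noise sd (degC).
#' @return list of class `weather_params`.
#' @export
weather_params <- function(p_ww = c(.45, .45, .5, .55, .55, .65, .6, .6, .65, .55, .5, .45),
                           p_dw = c(.18, .20, .25, .30, .30, .42, .38, .36, .40, .30, .22, .18),
                           rain_shape = rep(0.8, 12),
                           rain_mean = c(6, 7, 10, 11, 12, 14, 13, 12, 15, 12, 8, 6),
                           temp_mean = 15.7, temp_amplitude = 10.5,
                           temp_sd = 1.8) {
  for (v in list(p_ww, p_dw))
    assert_that(length(v) == 12 && all(v >= 0 & v <= 1),
                "transition probabilities must be 12 values in [0,1]")
  assert_that(length(rain_shape) == 12 && all(rain_shape > 0) &&
              length(rain_mean) == 12 && all(rain_mean > 0),
              "rainfall amount parameters must be 12 positive values")
  structure(list(p_ww = p_ww, p_dw = p_dw, rain_shape = rain_shape,
                 rain_mean = rain_mean, temp_mean = temp_mean,
                 temp_amplitude = temp_amplitude, temp_sd = temp_sd),
            class = "weather_params")
}

#' Simulate daily climate
#'
#' Generates a gap-free daily table of mean temperature and precipitation for
#' whole calendar years using the Markov-chain weather model of
#' [weather_params()].
#'
#' @param years integer vector of calendar years (>= 2 years; growth-response
#'   windows need the year before the first ring).
#' @param params a [weather_params()] object.
#' @param seed integer seed.
#' @return data.frame with columns `date` (Date), `tmean_c`, `precip_mm`.
#' @export
simulate_daily_climate <- function(years, params = weather_params(), seed = 1L) {
  assert_that(inherits(params, "weather_params"), "`params` must come from weather_params()")
  years <- sort(unique(as.integer(years)))
  assert_that(length(years) >= 2, "need at least 2 calendar years")
  assert_that(all(diff(years) == 1), "years must be consecutive")
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  mon <- as.integer(format(dates, "%m"))
  n <- length(dates)
  with_seed(seed, {
    wet <- logical(n)
    wet[1] <- runif(1) < params$p_dw[mon[1]] / (1 + params$p_dw[mon[1]] - params$p_ww[mon[1]])
    u <- runif(n)
    for (i in 2:n) {
      pr <- if (wet[i - 1]) params$p_ww[mon[i]] else params$p_dw[mon[i]]
      wet[i] <- u[i] < pr
    }
    precip <- numeric(n)
    nw <- sum(wet)
    if (nw > 0) {
      sh <- params$rain_shape[mon[wet]]
      precip[wet] <- rgamma(nw, shape = sh, scale = params$rain_mean[mon[wet]] / sh)
      precip[wet] <- pmax(precip[wet], 0.1) # a wet day records measurable rain
    }
    doy <- as.integer(format(dates, "%j"))
    tmean <- params$temp_mean -
      params$temp_amplitude * cos(2 * pi * (doy - 15) / 365.25) +
      rnorm(n, 0, params$temp_sd)
    data.frame(date = dates, tmean_c = round(tmean, 2),
               precip_mm = round(precip, 2))
  })
}

#' Truth model for planted growth/QTL signal
#'
#' Encodes the generative assumptions used by the synthetic population:
#' which markers carry QTL effects on drought sensitivity, how noisy the
#' clone sensitivities are, the Hugershoff age trend of basal area increment,
#' the AR(1) year-to-year growth noise, and which monthly climate index
#' drives growth.
#'
#' @param qtls data.frame with columns `map_label`, `linkage_group`,
#'   `position_cM`, `effect` (effect size on the latent sensitivity, 0/1
#'   genotype coding).
#' @param clone_noise_sd sd of the non-genetic clone-level sensitivity noise.
#' @param ar1_phi AR(1) coefficient of the tree-level growth noise (|phi|<1).
#' @param noise_sd innovation sd of the tree-level growth noise (log scale).
#' @param growth_curve named numeric (A, b, c, d): expected BAI at ring age t
#'   is A * t^b * exp(-c t) + d (mm^2/year).
#' @param climate_variable which monthly index drives growth: `"dry"`,
#'   `"temperature"` or `"precipitation"`.
#' @param threshold dry-period threshold in days (used when
#'   `climate_variable = "dry"`).
#' @param month month label of the driving index (see [month_window()]).
#' @param link_scale multiplier converting `sensitivity x standardized index`
#'   into log-BAI units.
#' @return list of class `truth_model`.
#' @export
truth_model <- function(qtls, clone_noise_sd = 0.81, ar1_phi = 0.3,
                        noise_sd = 0.25,
                        growth_curve = c(A = 300, b = 1.2, c = 0.08, d = 50),
                        climate_variable = "dry", threshold = 4,
                        month = "c03", link_scale = 0.35) {
  assert_that(abs(ar1_phi) < 1, "|ar1_phi| must be < 1")
  assert_that(all(c("A", "b", "c", "d") %in% names(growth_curve)),
              "growth_curve needs named elements A, b, c, d")
  g <- hugershoff_curve(growth_curve, 1:100)
  assert_that(all(g > 0), "growth curve must be positive over simulated ages")
  if (!is.null(qtls)) {
    assert_that(is.data.frame(qtls) &&
                all(c("map_label", "linkage_group", "position_cM", "effect") %in% names(qtls)),
                "qtls must have map_label, linkage_group, position_cM, effect")
  }
  parse_month_label(month) # validates
  structure(list(qtls = qtls, clone_noise_sd = clone_noise_sd,
                 ar1_phi = ar1_phi, noise_sd = noise_sd,
                 growth_curve = growth_curve,
                 climate_variable = climate_variable, threshold = threshold,
                 month = month, link_scale = link_scale),
            class = "truth_model")
}

#' Default planted QTL architecture
#'
#' Thirteen QTLs on the two parental maps: one major QTL (planted PVE 12.4%
#' of the latent sensitivity variance) and twelve minor ones (0.9-2.9%),
#' totalling ~33.9%. Effects are on the 0/1 genotype coding with marker
#' variance 1/4, latent sensitivity variance ~1, so
#' `effect = sign * 2 * sqrt(PVE)`.
#'
#' @param map1,map2 the two parental map specifications.
#' @return data.frame usable as the `qtls` argument of [truth_model()].
#' @export
default_qtl_architecture <- function(map1 = default_map_spec("P1"),
                                     map2 = default_map_spec("P2", marker_offset = 1000L)) {
  pve <- c(12.4, 2.9, 2.7, 2.5, 2.1, 1.8, 1.8, 1.6, 1.5, 1.5, 1.2, 1.0, 0.9) / 100
  sign <- c(-1, -1, -1, -1, 1, -1, -1, 1, -1, 1, 1, 1, 1)
  maps <- c("P2", "P2", "P2", "P1", "P2", "P1", "P1", "P1", "P2", "P2", "P1", "P1", "P1")
  grp <- c("LG03", "LG08", "LG10", "LG04", "LG06", "LG02", "LG10", "LG09",
           "LG02", "LG05", "LG01", "LG07", "LG11")
  pos <- c(40.9, 58.5, 47.5, 33.6, 22.3, 55.4, 0, 44.7, 23.2, 42, 33.5, 20.5, 18.2)
  out <- data.frame(map_label = maps, linkage_group = grp, position_cM = pos,
                    effect = sign * 2 * sqrt(pve), planted_pve_pct = 100 * pve,
                    stringsAsFactors = FALSE)
  # clamp to the groups and lengths the maps actually have, so shrunken maps
  # (fewer/shorter groups) still get a valid, smaller architecture
  map <- rbind(map1, map2)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    sel <- map$map_label == out$map_label[i] &
      map$linkage_group == out$linkage_group[i]
    keep[i] <- any(sel)
    if (keep[i])
      out$position_cM[i] <- min(out$position_cM[i], max(map$position_cM[sel]))
  }
  out[keep, , drop = FALSE]
}

#' Plant per-clone drought sensitivities on simulated genotypes
#'
#' The latent sensitivity of clone c is `s_c = sum_j alpha_j x_cj + eta_c`
#' with x the 0/1 genotype at the marker nearest each planted QTL and
#' `eta ~ N(0, clone_noise_sd^2)`. The realized per-QTL PVE
#' (`alpha^2 var(x) / var(s)`) is recorded for downstream bookkeeping.
#'
#' @param genotypes 0/1 genotype matrix (clones x markers), both maps
#'   column-bound (see [simulate_genotypes()]).
#' @param map combined map specification matching the genotype columns.
#' @param truth a [truth_model()].
#' @param seed integer seed (clone noise only).
#' @param exact_pve if TRUE, the clone noise is orthogonalized against the
#'   largest-effect QTL's marker and the total variance rescaled so that this
#'   leading QTL's *realized* (sample) variance share equals its planted
#'   share exactly; the minor QTLs' realized shares remain sampled around
#'   their planted values. Useful when a study condition specifies the PVE
#'   the leading effect gives rather than an expectation over draws.
#' @return list with `s` (named numeric of sensitivities), `qtl_markers`
#'   (data.frame: planted QTLs, assigned marker, effect, realized PVE %).
#' @export
simulate_sensitivities <- function(genotypes, map, truth, seed = 1L,
                                   exact_pve = FALSE) {
  qtls <- truth$qtls
  s <- with_seed(seed, rnorm(nrow(genotypes), 0, truth$clone_noise_sd))
  names(s) <- rownames(genotypes)
  tab <- NULL
  if (!is.null(qtls) && nrow(qtls) > 0) {
    marker <- character(nrow(qtls))
    for (i in seq_len(nrow(qtls))) {
      sel <- map$map_label == qtls$map_label[i] &
        map$linkage_group == qtls$linkage_group[i]
      assert_that(any(sel), paste0("no markers on ", qtls$map_label[i], " ",
                                   qtls$linkage_group[i]))
      j <- which(sel)[which.min(abs(map$position_cM[sel] - qtls$position_cM[i]))]
      marker[i] <- map$marker[j]
    }
    Xq <- genotypes[, marker, drop = FALSE]
    g <- drop(Xq %*% qtls$effect)
    if (exact_pve && truth$clone_noise_sd > 0 && stats::var(g) > 0) {
      im <- which.max(abs(qtls$effect))
      xm <- Xq[, im]
      # planned variance share of the leading QTL (expected marker variance
      # 1/4, planned total = genetic + clone noise)
      f_m <- qtls$effect[im]^2 * 0.25 /
        (sum(qtls$effect^2 * 0.25) + truth$clone_noise_sd^2)
      eta <- stats::residuals(stats::lm(s ~ xm))
      # scale the noise so var(y) realizes the leading QTL's share exactly:
      # var(g + k eta) = var(g) + 2 k cov(rest, eta) + k^2 var(eta), with
      # rest the minor-QTL contribution (eta is orthogonal to xm only)
      target_vy <- qtls$effect[im]^2 * stats::var(xm) / f_m
      rest <- g - qtls$effect[im] * xm
      aa <- stats::var(eta)
      bb <- 2 * stats::cov(rest, eta)
      cc <- stats::var(g) - target_vy
      disc <- max(bb^2 - 4 * aa * cc, 0)
      k <- (-bb + sqrt(disc)) / (2 * aa)
      s <- stats::setNames(k * eta, names(s))
    }
    s <- s + g
    vx <- apply(Xq, 2, stats::var)
    tab <- data.frame(qtls[, c("map_label", "linkage_group", "position_cM", "effect")],
                      marker = marker,
                      marker_position_cM = map$position_cM[match(marker, map$marker)],
                      realized_pve_pct = 100 * qtls$effect^2 * vx / stats::var(s),
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  list(s = s, qtl_markers = tab)
}

# Hugershoff age trend g(t) = A t^b exp(-c t) + d
hugershoff_curve <- function(par, t) {
  unname(par["A"] * t^par["b"] * exp(-par["c"] * t) + par["d"])
}

#' Simulate a ring-width table from planted sensitivities and daily climate
#'
#' Expected BAI follows the Hugershoff age trend; the year effect is
#' multiplicative, `exp(link_scale * s_c * z_t + e_t)`, where z is the
#' standardized driving monthly climate index of the truth model and e is
#' AR(1) tree-level noise. Replicate trees (ramets) of a clone share s_c but
#' have independent noise. BAI is converted back to ring widths via the
#' cumulative basal area, so widths are always positive.
#'
#' @param sensitivities named numeric vector of clone sensitivities.
#' @param climate daily climate table covering all ring years plus the prior
#'   year (needed by the lagged trait window).
#' @param truth a [truth_model()].
#' @param ring_years integer vector of consecutive ring-formation years.
#' @param n_replicates ramets per clone.
#' @param site site label.
#' @param seed integer seed.
#' @return data.frame with columns `tree_id`, `clone_id`, `site`, `year`,
#'   `width_mm`.
#' @export
simulate_ring_widths <- function(sensitivities, climate, truth, ring_years,
                                 n_replicates = 3, site = "S1", seed = 1L) {
  ring_years <- sort(as.integer(ring_years))
  cy <- as.integer(format(climate$date, "%Y"))
  assert_that(all(ring_years %in% cy) && (min(ring_years) - 1) %in% cy,
              "climate must cover all ring years plus the prior year")
  z <- driving_index(climate, truth, ring_years)
  ny <- length(ring_years)
  g <- hugershoff_curve(truth$growth_curve, seq_len(ny))
  clones <- names(sensitivities)
  with_seed(seed, {
    out <- vector("list", length(clones) * n_replicates)
    k <- 0L
    for (ci in seq_along(clones)) {
      mu <- truth$link_scale * sensitivities[ci] * z
      for (r in seq_len(n_replicates)) {
        if (truth$noise_sd > 0) {
          e <- as.numeric(stats::arima.sim(list(ar = truth$ar1_phi), ny,
                                           sd = truth$noise_sd * sqrt(1 - truth$ar1_phi^2)))
        } else e <- numeric(ny)
        bai <- g * exp(mu + e)
        radius <- sqrt(cumsum(bai) / pi)
        widths <- diff(c(0, radius))
        k <- k + 1L
        out[[k]] <- data.frame(
          tree_id = sprintf("%s_r%d", clones[ci], r),
          clone_id = clones[ci], site = site, year = ring_years,
          width_mm = round(widths, 4), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
}

# Standardized driving climate index over the ring years, per the truth model.
driving_index <- function(climate, truth, ring_years) {
  lab <- parse_month_label(truth$month)
  m <- switch(truth$climate_variable,
    dry = monthly_dry_index(climate, truth$threshold),
    temperature = monthly_aggregate(climate)$temperature,
    precipitation = monthly_aggregate(climate)$precipitation,
    stop("unknown climate_variable '", truth$climate_variable, "'"))
  yrs <- if (lab$lag == "c") ring_years else ring_years - 1L
  v <- m[as.character(yrs), sprintf("%02d", lab$month)]
  z <- as.numeric(scale(v))
  if (any(!is.finite(z))) z <- rep(0, length(v)) # constant index: no signal
  z
}

#' Generate a complete synthetic data set on disk
#'
#' Writes the three pipeline inputs (ring-width, marker and daily-climate
#' CSVs) plus `truth.json` recording the planted QTLs, effects and realized
#' PVE, so downstream stages can be checked against ground truth.
#'
#' @param out_dir output directory (created if needed).
#' @param n_clones,n_replicates population size.
#' @param ring_years consecutive ring-formation years.
#' @param map1,map2 parental map specifications.
#' @param truth a [truth_model()]; defaults to the 13-QTL architecture.
#' @param params weather parameters.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param site site label.
#' @param seed integer seed; sub-seeds for each generator are derived from it.
#' @return invisibly, a list with the file paths and the in-memory objects.
#' @export
simulate_dataset <- function(out_dir, n_clones = 139, n_replicates = 3,
                             ring_years = 2006:2016,
                             map1 = default_map_spec("P1"),
                             map2 = default_map_spec("P2", marker_offset = 1000L),
                             truth = NULL, params = weather_params(),
                             missing_rate = 0, site = "S1", seed = 1L) {
  if (is.null(truth)) truth <- truth_model(default_qtl_architecture(map1, map2))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(seed)
  map <- rbind(map1, map2)
  geno <- cbind(simulate_genotypes(map1, n_clones, seed),
                simulate_genotypes(map2, n_clones, seed + 1L))
  climate <- simulate_daily_climate((min(ring_years) - 2):max(ring_years),
                                    params, seed + 2L)
  sens <- simulate_sensitivities(geno, map, truth, seed + 3L)
  rings <- simulate_ring_widths(sens$s, climate, truth, ring_years,
                                n_replicates, site, seed + 4L)
  codes <- matrix(c("het", "hom")[geno + 1L], nrow = nrow(geno),
                  dimnames = dimnames(geno))
  if (missing_rate > 0) {
    miss <- with_seed(seed + 5L,
                      matrix(stats::runif(length(codes)) < missing_rate, nrow(codes)))
    codes[miss] <- "missing"
  }
  marker_df <- cbind(map, as.data.frame(t(codes), stringsAsFactors = FALSE))
  paths <- list(rings = file.path(out_dir, "ring_widths.csv"),
                markers = file.path(out_dir, "markers.csv"),
                climate = file.path(out_dir, "daily_climate.csv"),
                truth = file.path(out_dir, "truth.json"))
  utils::write.csv(rings, paths$rings, row.names = FALSE)
  utils::write.csv(marker_df, paths$markers, row.names = FALSE)
  utils::write.csv(climate, paths$climate, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_clones = n_clones, n_replicates = n_replicates,
         ring_years = ring_years, site = site,
         climate_link = list(variable = truth$climate_variable,
                             threshold = truth$threshold, month = truth$month,
                             link_scale = truth$link_scale),
         clone_noise_sd = truth$clone_noise_sd,
         qtl_markers = sens$qtl_markers,
         sensitivities = as.list(sens$s)),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, genotypes = geno, map = map, climate = climate,
                 sensitivities = sens, rings = rings, truth = truth))
}
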