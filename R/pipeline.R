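# Pipeline orchestration: one config drives simulate -> rings -> climate ->
# sensitivity -> qtl, with consistent CSV dialects and a run manifest.

#' Default run configuration
#'
#' Nested list mirroring a YAML config file. With `simulate` present the
#' three inputs are generated; otherwise `inputs` must point at existing
#' ring-width, marker and daily-climate CSVs.
#'
#' @param n_clones,n_replicates,ring_years simulated population shape.
#' @param seed master seed; stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(n_clones = 139, n_replicates = 3,
                           ring_years = 2006:2016, seed = 1L) {
  list(
    site = "S1",
    simulate = list(n_clones = n_clones, n_replicates = n_replicates,
                    ring_years = ring_years, missing_rate = 0,
                    map = list(n_groups = 11, group_length = 60, spacing = 1.5)),
    inputs = NULL,
    climate = list(thresholds = 1:7, wet_cutoff = 0, detrend = TRUE),
    rings = list(detrend = "ratio", keep_first = TRUE),
    phenotype = list(variable = "dry_k4", month = "c03", min_prop = 0.8),
    alpha_traits = 0.05,
    alpha_qtl = 0.01,
    qtl = list(cv_folds = 5, a = NULL, b = NULL, im_step = 1),
    seeds = list(master = as.integer(seed))
  )
}

#' Read a YAML run configuration
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(over[[k]]) && is.list(base[[k]]))
        merge_cfg(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge_cfg(base, cfg)
}

read_ring_table <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

read_marker_table <- function(path)
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)

read_daily_climate <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}

#' Validate pipeline input files
#'
#' Schema, date-gap, genotype-code and clone-id cross-file consistency
#' checks. Violations are collected into a report rather than raised.
#'
#' @param rings,markers,climate paths to the three input CSVs.
#' @return data.frame with columns `file`, `check`, `detail` (zero rows when
#'   everything passes).
#' @export
validate_inputs <- function(rings, markers, climate) {
  viol <- list()
  add <- function(file, check, detail)
    viol[[length(viol) + 1]] <<- data.frame(file = file, check = check,
                                            detail = detail,
                                            stringsAsFactors = FALSE)
  r <- tryCatch(read_ring_table(rings), error = function(e) NULL)
  need_r <- c("tree_id", "clone_id", "site", "year", "width_mm")
  if (is.null(r) || !all(need_r %in% names(r))) {
    add("rings", "schema", paste("missing columns; need",
                                 paste(need_r, collapse = ", ")))
    r <- NULL
  } else if (any(!is.finite(r$width_mm) | r$width_mm <= 0)) {
    bad <- which(!is.finite(r$width_mm) | r$width_mm <= 0)
    add("rings", "domain", paste("non-positive width at rows",
                                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  m <- tryCatch(read_marker_table(markers), error = function(e) NULL)
  meta <- c("marker", "linkage_group", "map_label", "position_cM")
  if (is.null(m) || !all(meta %in% names(m))) {
    add("markers", "schema", paste("missing columns; need",
                                   paste(meta, collapse = ", ")))
    m <- NULL
  } else {
    codes <- unlist(m[, setdiff(names(m), meta)], use.names = FALSE)
    bad <- !(tolower(trimws(as.character(codes))) %in%
               c("het", "hom", "missing", "na", "", "0", "1"))
    if (any(bad)) {
      rows <- unique((which(bad) - 1) %% nrow(m) + 1)
      add("markers", "domain",
          paste0("genotype codes outside {het, hom, missing} at rows ",
                 paste(utils::head(rows, 5), collapse = ", ")))
    }
  }
  cl <- tryCatch(read_daily_climate(climate), error = function(e) NULL)
  need_c <- c("date", "tmean_c", "precip_mm")
  if (is.null(cl) || !all(need_c %in% names(cl))) {
    add("climate", "schema", paste("missing columns; need",
                                   paste(need_c, collapse = ", ")))
  } else {
    d <- sort(cl$date)
    gaps <- which(diff(d) != 1)
    for (g in utils::head(gaps, 5))
      add("climate", "date_gap", paste("missing date(s) after", d[g]))
    if (anyDuplicated(cl$date))
      add("climate", "date_dup", "duplicate dates")
    if (any(cl$precip_mm < 0))
      add("climate", "domain", "negative precipitation")
  }
  if (!is.null(r) && !is.null(m)) {
    ring_clones <- unique(r$clone_id)
    geno_clones <- setdiff(names(m), meta)
    only_r <- setdiff(ring_clones, geno_clones)
    if (length(only_r))
      add("markers", "clone_ids",
          paste("clones in rings but not markers:",
                paste(utils::head(only_r, 10), collapse = ", ")))
  }
  if (length(viol)) do.call(rbind, viol)
  else data.frame(file = character(0), check = character(0),
                  detail = character(0), stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input simulation (or loading), ring-width
#' processing into clone chronologies, monthly climate matrices, climate
#' sensitivity traits and significance counts, phenotype selection, and QTL
#' mapping with an interval-mapping validation scan. All stage outputs are
#' written as CSV under `out_dir`, plus `manifest.json`. Reruns with the same
#' config produce byte-identical outputs.
#'
#' @param config configuration list (see [default_config()] /
#'   [read_config()]).
#' @param out_dir output directory.
#' @return invisibly, a list with every stage's in-memory result and the
#'   manifest.
#' @export
run_full_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seeds$master)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_dir <- file.path(out_dir, "inputs")
    sim <- stage("simulate", {
      sc <- config$simulate
      map1 <- default_map_spec("P1", sc$map$n_groups, sc$map$group_length,
                               sc$map$spacing)
      map2 <- default_map_spec("P2", sc$map$n_groups, sc$map$group_length,
                               sc$map$spacing, marker_offset = 1000L)
      simulate_dataset(sim_dir, n_clones = sc$n_clones,
                       n_replicates = sc$n_replicates,
                       ring_years = min(sc$ring_years):max(sc$ring_years),
                       map1 = map1, map2 = map2,
                       missing_rate = sc$missing_rate %||% 0,
                       site = config$site, seed = seed)
    })
    paths <- sim$paths
  } else {
    paths <- config$inputs
    assert_that(!is.null(paths) && all(c("rings", "markers", "climate") %in% names(paths)),
                "config$inputs must name rings, markers and climate files")
  }
  report <- validate_inputs(paths$rings, paths$markers, paths$climate)
  if (nrow(report))
    stop("input validation failed:\n",
         paste(report$file, report$check, report$detail, sep = " | ",
               collapse = "\n"), call. = FALSE)
  rings <- read_ring_table(paths$rings)
  markers <- read_marker_table(paths$markers)
  climate <- read_daily_climate(paths$climate)

  # --- rings -> chronologies ------------------------------------------------
  chron <- stage("rings", process_rings(rings,
                                        detrend = config$rings$detrend,
                                        keep_first = config$rings$keep_first))
  utils::write.csv(chron, file.path(out_dir, "clone_chronology.csv"),
                   row.names = FALSE)

  # --- climate matrices -----------------------------------------------------
  mats <- stage("climate", build_climate_matrices(
    climate, thresholds = config$climate$thresholds,
    wet_cutoff = config$climate$wet_cutoff,
    detrend = isTRUE(config$climate$detrend)))
  zr <- vapply(config$climate$thresholds, function(k)
    zero_ratio(monthly_dry_index(climate, k, config$climate$wet_cutoff)), 0)
  names(zr) <- sprintf("dry_k%d", config$climate$thresholds)
  for (v in names(mats))
    utils::write.csv(data.frame(year = rownames(mats[[v]]), mats[[v]],
                                check.names = FALSE),
                     file.path(out_dir, paste0("climate_", v, ".csv")),
                     row.names = FALSE)

  # --- sensitivity traits ---------------------------------------------------
  traits <- stage("sensitivity", compute_sensitivity_traits(chron, mats))
  counts <- significance_counts(traits, config$alpha_traits)
  utils::write.csv(traits, file.path(out_dir, "sensitivity_traits.csv"),
                   row.names = FALSE)
  utils::write.csv(counts, file.path(out_dir, "significance_counts.csv"),
                   row.names = FALSE)

  # --- QTL mapping ----------------------------------------------------------
  y <- stage("phenotype", select_qtl_phenotype(
    traits, config$phenotype$variable, config$phenotype$month,
    min_prop = config$phenotype$min_prop))
  enc <- stage("encode", encode_genotypes(markers, clones = names(y)))
  qtl <- stage("qtl", map_qtls(enc$X, enc$info, y,
                               alpha = config$alpha_qtl,
                               a = config$qtl$a, b = config$qtl$b,
                               k = config$qtl$cv_folds, seed = seed))
  lod <- stage("interval_mapping", interval_mapping_scan(
    enc$X, enc$info, y, step = config$qtl$im_step))
  utils::write.csv(qtl$qtls, file.path(out_dir, "qtl_table.csv"),
                   row.names = FALSE)
  utils::write.csv(lod, file.path(out_dir, "lod_profile.csv"),
                   row.names = FALSE)
  summary_df <- data.frame(
    n_significant_qtls = nrow(qtl$qtls), pve_all_pct = qtl$pve_all_pct,
    cv_r = qtl$cv_r, cv_p = qtl$cv_p, a = qtl$a, b = qtl$b, seed = seed)
  utils::write.csv(summary_df, file.path(out_dir, "qtl_summary.csv"),
                   row.names = FALSE)

  # --- manifest -------------------------------------------------------------
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("dendroqtl")),
    seeds = config$seeds,
    rows = list(rings = nrow(rings), markers = nrow(markers),
                climate = nrow(climate), chronology = nrow(chron),
                traits = nrow(traits)),
    excluded_markers = enc$excluded,
    missing_trait_clones = attr(y, "excluded"),
    zero_ratio = as.list(zr),
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(paths = paths, chronology = chron, matrices = mats,
                 traits = traits, counts = counts, phenotype = y,
                 encoded = enc, qtl = qtl, lod = lod, zero_ratio = zr,
                 manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
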