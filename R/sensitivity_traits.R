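# Climate sensitivity traits: per-clone correlations between the relative-BAI
# chronology and lagged monthly climate over a 16-month window.

#' Pair a clone chronology with one lagged monthly climate series
#'
#' For ring year Y, labels `p06`..`p12` pair the growth index with the
#' climate value of (Y - 1, month) and `c01`..`c09` with (Y, month). Years
#' with a missing value on either side are dropped.
#'
#' @param chron data.frame with `year` and `relative_bai` for one clone.
#' @param m year x month climate matrix.
#' @param label a [month_window()] label.
#' @return data.frame with `year`, `growth`, `climate` (complete pairs only).
#' @export
align_lagged_series <- function(chron, m, label) {
  lab <- parse_month_label(label)
  yrs <- chron$year
  cyr <- if (lab$lag == "c") yrs else yrs - 1L
  col <- sprintf("%02d", lab$month)
  clim <- rep(NA_real_, length(yrs))
  hit <- match(as.character(cyr), rownames(m))
  ok <- !is.na(hit)
  clim[ok] <- m[hit[ok], col]
  keep <- is.finite(clim) & is.finite(chron$relative_bai)
  data.frame(year = yrs[keep], growth = chron$relative_bai[keep],
             climate = clim[keep])
}

#' Correlation trait for one clone / month / variable
#'
#' Pearson correlation with a two-sided t-test (df = n - 2). With fewer than
#' 3 pairs or a constant vector on either side the trait is missing
#' (`r = NA`), not an error: such cells are expected when thresholds produce
#' constant monthly indices.
#'
#' @param growth,climate paired numeric vectors.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list: `r`, `p`, `n`.
#' @export
sensitivity_trait <- function(growth, climate, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- length(growth)
  if (n < 3 || stats::sd(growth) == 0 || stats::sd(climate) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(growth, climate, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Compute the full table of climate sensitivity traits
#'
#' For every clone, climate matrix and month label in the 16-month window,
#' the correlation between relative BAI and the lagged monthly climate value.
#'
#' @param chronology per-clone chronology data.frame from [process_rings()].
#' @param matrices named list of year x month matrices (see
#'   [build_climate_matrices()]); names are used as the `variable` column,
#'   with the `threshold` attribute carried along.
#' @param method correlation type, see [sensitivity_trait()].
#' @return long data.frame: `clone_id`, `site`, `variable`, `threshold`,
#'   `month_label`, `r`, `p`, `n`.
#' @export
compute_sensitivity_traits <- function(chronology, matrices,
                                       method = "pearson") {
  labels <- month_window()
  clones <- split(chronology, chronology$clone_id)
  out <- vector("list", length(clones) * length(matrices) * length(labels))
  k <- 0L
  for (cl in names(clones)) {
    ch <- clones[[cl]]
    for (v in names(matrices)) {
      m <- matrices[[v]]
      thr <- attr(m, "threshold")
      for (lab in labels) {
        pairs <- align_lagged_series(ch, m, lab)
        tr <- sensitivity_trait(pairs$growth, pairs$climate, method)
        k <- k + 1L
        out[[k]] <- data.frame(
          clone_id = cl, site = ch$site[1], variable = v,
          threshold = if (is.null(thr)) NA_real_ else thr,
          month_label = lab, r = tr$r, p = tr$p, n = tr$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count clones with significant correlations per variable and month
#'
#' Splits significant traits (p < alpha) by correlation sign, summarising the
#' population-level growth response per (variable, threshold, month) cell.
#'
#' @param traits long trait table from [compute_sensitivity_traits()].
#' @param alpha significance level (0.05 by convention for these descriptive
#'   counts; no multiplicity correction).
#' @return data.frame: `variable`, `threshold`, `month_label`,
#'   `n_positive`, `n_negative`, `n_total`.
#' @export
significance_counts <- function(traits, alpha = 0.05) {
  key <- interaction(traits$variable, traits$threshold, traits$month_label,
                     drop = TRUE)
  res <- do.call(rbind, lapply(split(traits, key), function(d) {
    sig <- !is.na(d$p) & d$p < alpha
    data.frame(variable = d$variable[1], threshold = d$threshold[1],
               month_label = d$month_label[1],
               n_positive = sum(sig & d$r > 0),
               n_negative = sum(sig & d$r < 0),
               n_total = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res[order(res$variable, res$threshold,
            match(res$month_label, month_window())), ]
}

#' Extract the QTL phenotype vector from the trait table
#'
#' Selects the per-clone correlation coefficients for one (variable,
#' threshold, month) cell — the r values themselves are the mapped
#' phenotype. Rejects the cell if too many clones are missing.
#'
#' @param traits long trait table.
#' @param variable matrix name (e.g. `"dry_k4"`).
#' @param month_label month label (e.g. `"c03"`, March of the ring year).
#' @param min_prop minimum fraction of clones with a non-missing trait.
#' @return named numeric vector of r values (clones with missing trait
#'   dropped, recorded in attribute `excluded`).
#' @export
select_qtl_phenotype <- function(traits, variable, month_label,
                                 min_prop = 0.8) {
  lab <- month_label
  parse_month_label(lab)
  d <- traits[traits$variable == variable & traits$month_label == lab, ]
  assert_that(nrow(d) > 0, paste0("no traits for variable '", variable,
                                  "', month '", lab, "'"))
  ok <- is.finite(d$r)
  assert_that(mean(ok) >= min_prop,
              sprintf("only %.0f%% of clones have a non-missing trait (need >= %.0f%%)",
                      100 * mean(ok), 100 * min_prop))
  y <- d$r[ok]
  names(y) <- d$clone_id[ok]
  attr(y, "excluded") <- d$clone_id[!ok]
  y
}
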