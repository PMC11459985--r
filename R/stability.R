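# Feature stability across reconstruction settings: coefficient of
# variation per setting family and four-way categorization.

#' Coefficient of variation, in percent
#'
#' `100 * sd(x) / |mean(x)|` with the sample (n-1) standard deviation.
#' When the mean is within `epsilon * max(|x|)` of zero the COV is
#' undefined and `NA` is returned (such features are excluded from
#' categorization and reported separately).
#'
#' @param values Numeric vector, length >= 2.
#' @param epsilon Relative zero-mean guard.
#' @return COV in percent, or `NA_real_` when undefined.
#' @examples
#' cov_percent(c(1, 2, 3))  # 50
#' @export
cov_percent <- function(values, epsilon = 1e-12) {
  if (length(values) < 2) stop("cov requires at least 2 values")
  m <- mean(values)
  scale <- max(abs(values), na.rm = TRUE)
  if (scale == 0) return(0)  # all-zero series: no variation
  if (abs(m) <= epsilon * scale) return(NA_real_)
  100 * stats::sd(values) / abs(m)
}

#' Stability categories and thresholds
#'
#' Categories by overall COV: stable (COV <= 5%), moderately stable
#' (5% < COV <= 10%), poorly stable (10% < COV <= 20%), unstable
#' (COV > 20%). Boundaries are inclusive on the more stable side.
#'
#' @param cov_value COV in percent (scalar or vector; `NA` passes through).
#' @param thresholds Increasing vector of the three boundaries in percent.
#' @return Character vector of categories.
#' @examples
#' categorize_stability(c(0, 5, 10, 20.01))
#' @export
categorize_stability <- function(cov_value, thresholds = c(5, 10, 20)) {
  stopifnot(length(thresholds) == 3, !is.unsorted(thresholds))
  if (any(cov_value < 0, na.rm = TRUE))
    stop("parameter error: negative COV")
  cut_lab <- c("stable", "moderately_stable", "poorly_stable", "unstable")
  as.character(cut(cov_value, breaks = c(-Inf, thresholds, Inf),
                   labels = cut_lab, right = TRUE))
}

#' Per-feature stability records for one insert configuration
#'
#' For every feature, computes the COV across the settings of each of the
#' four parameter families (subsets, iterations, filter, TOF; a family
#' includes the default-valued setting whenever the default value is in its
#' variation list), an overall COV, and the stability category. The overall
#' COV is either the arithmetic mean of the four family COVs (default) or
#' the COV pooled over all settings.
#'
#' @param features Long data.frame with columns `feature`, `shape_id`,
#'   `setting_id`, `family`, `value` (as produced by [run_pipeline()]).
#' @param shape_id Insert configuration to analyse.
#' @param thresholds Category boundaries in percent.
#' @param overall `"family_mean"` or `"pooled"`.
#' @return data.frame with one row per feature: family COVs, per-family
#'   categories, `cov_overall` and `category`.
#' @export
stability_table <- function(features, shape_id,
                            thresholds = c(5, 10, 20),
                            overall = c("family_mean", "pooled")) {
  overall <- match.arg(overall)
  need <- c("feature", "shape_id", "setting_id", "family", "value")
  stopifnot(all(need %in% names(features)))
  df <- features[features$shape_id == shape_id, ]
  if (nrow(df) == 0) stop("incomplete table: no rows for this shape")
  n_set <- length(unique(df$setting_id))
  fams <- c("subsets", "iterations", "filter", "tof")
  out <- do.call(rbind, lapply(split(df, df$feature), function(g) {
    if (nrow(g) != n_set)
      stop("incomplete table: missing settings for feature ", g$feature[1])
    fam_cov <- vapply(fams, function(fm) {
      v <- g$value[g$family == fm]
      if (length(v) < 2) NA_real_ else cov_percent(v)
    }, 0)
    cov_all <- if (overall == "family_mean") mean(fam_cov)
               else cov_percent(g$value)
    data.frame(feature = g$feature[1],
               cov_subsets = fam_cov[["subsets"]],
               cov_iterations = fam_cov[["iterations"]],
               cov_filter = fam_cov[["filter"]],
               cov_tof = fam_cov[["tof"]],
               cov_overall = cov_all,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(match(out$feature, feature_names())), ]  # catalogue order; unknown names last
  rownames(out) <- NULL
  for (fm in fams)
    out[[paste0("category_", fm)]] <-
      categorize_stability(out[[paste0("cov_", fm)]], thresholds)
  out$category <- categorize_stability(out$cov_overall, thresholds)
  out
}

# Category counts per family for the run report.
category_counts <- function(stab, thresholds = c(5, 10, 20)) {
  cats <- c("stable", "moderately_stable", "poorly_stable", "unstable")
  fams <- c("subsets", "iterations", "filter", "tof")
  cnt <- function(col) {
    v <- factor(stab[[col]], levels = cats)
    as.list(table(v))
  }
  out <- lapply(paste0("category_", fams), cnt)
  names(out) <- fams
  out$overall <- cnt("category")
  out$undefined <- sum(is.na(stab$cov_overall))
  out
}
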