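# Reconstruction-setting grid: one-at-a-time variations around the clinical
# default (24 subsets, 2 iterations, 6.4 mm post-filter, TOF on).

#' A single reconstruction-setting combination
#'
#' @param subsets Number of OSEM subsets.
#' @param iterations Number of OSEM iterations.
#' @param filter_fwhm Gaussian post-filter cut-off, as FWHM in mm (0 = none).
#' @param tof Logical; time-of-flight reconstruction.
#' @param setting_id Identifier string; autogenerated if `NULL`.
#' @param family Which parameter family this setting varies
#'   (`"subsets"`, `"iterations"`, `"filter"`, `"tof"` or `"default"`).
#' @return An object of class `recon_setting`.
#' @export
recon_setting <- function(subsets = 24L, iterations = 2L, filter_fwhm = 6.4,
                          tof = TRUE, setting_id = NULL, family = "default") {
  stopifnot(subsets >= 1, iterations >= 1, is.logical(tof))
  if (filter_fwhm < 0) stop("parameter error: negative filter FWHM")
  if (is.null(setting_id))
    setting_id <- sprintf("s%d_i%d_f%g_tof%s", subsets, iterations,
                          filter_fwhm, ifelse(tof, "y", "n"))
  structure(list(setting_id = setting_id, subsets = as.integer(subsets),
                 iterations = as.integer(iterations),
                 filter_fwhm = filter_fwhm, tof = isTRUE(tof),
                 family = family),
            class = "recon_setting")
}

#' Variation lists of the reconstruction-parameter grid
#'
#' The four families varied one at a time around the default:
#' subsets \{12, 16, 18, 24, 32\}, iterations \{1..6\}, Gaussian filter
#' cut-off \{0..7\} mm, and TOF \{on, off\}, giving 5 + 6 + 8 + 2 = 21
#' settings.
#'
#' @return Named list of the four variation vectors.
#' @export
default_variations <- function() {
  list(subsets = c(12L, 16L, 18L, 24L, 32L),
       iterations = 1:6,
       filter_fwhm = as.numeric(0:7),
       tof = c(TRUE, FALSE))
}

#' Enumerate the reconstruction settings
#'
#' One setting per one-at-a-time variation from the default: every value of
#' each family is combined with the default values of the other three
#' parameters. Family labels record which parameter each setting varies, and
#' a family's list may contain the default value itself (e.g. 24 subsets),
#' in which case that setting reproduces the default image within its
#' family.
#'
#' @param variations Named list as returned by [default_variations()].
#' @param default The default [recon_setting()].
#' @return A list of `recon_setting` objects with unique `setting_id`s.
#' @examples
#' length(enumerate_settings())  # 21
#' @export
enumerate_settings <- function(variations = default_variations(),
                               default = recon_setting()) {
  need <- c("subsets", "iterations", "filter_fwhm", "tof")
  if (!all(need %in% names(variations)))
    stop("config error: variations must name subsets, iterations, filter_fwhm, tof")
  if (any(lengths(variations[need]) == 0))
    stop("config error: empty variation list")
  out <- list()
  for (v in variations$subsets)
    out <- c(out, list(recon_setting(v, default$iterations,
                                     default$filter_fwhm, default$tof,
                                     setting_id = sprintf("subsets_%d", v),
                                     family = "subsets")))
  for (v in variations$iterations)
    out <- c(out, list(recon_setting(default$subsets, v,
                                     default$filter_fwhm, default$tof,
                                     setting_id = sprintf("iterations_%d", v),
                                     family = "iterations")))
  for (v in variations$filter_fwhm)
    out <- c(out, list(recon_setting(default$subsets, default$iterations,
                                     v, default$tof,
                                     setting_id = sprintf("filter_%g", v),
                                     family = "filter")))
  for (v in variations$tof)
    out <- c(out, list(recon_setting(default$subsets, default$iterations,
                                     default$filter_fwhm, v,
                                     setting_id = sprintf("tof_%s",
                                                          ifelse(v, "yes", "no")),
                                     family = "tof")))
  ids <- vapply(out, `[[`, "", "setting_id")
  if (anyDuplicated(ids)) stop("config error: duplicate setting ids")
  out
}

#' Settings as a data frame
#'
#' @param settings List of `recon_setting` objects.
#' @return data.frame with one row per setting.
#' @export
settings_table <- function(settings = enumerate_settings()) {
  data.frame(
    setting_id = vapply(settings, `[[`, "", "setting_id"),
    family = vapply(settings, `[[`, "", "family"),
    subsets = vapply(settings, `[[`, 0L, "subsets"),
    iterations = vapply(settings, `[[`, 0L, "iterations"),
    filter_fwhm = vapply(settings, `[[`, 0, "filter_fwhm"),
    tof = vapply(settings, `[[`, TRUE, "tof"),
    stringsAsFactors = FALSE)
}

#' @export
print.recon_setting <- function(x, ...) {
  cat(sprintf("recon setting %s [%s]: %d subsets, %d iterations, %g mm filter, TOF %s\n",
              x$setting_id, x$family, x$subsets, x$iterations, x$filter_fwhm,
              ifelse(x$tof, "on", "off")))
  invisible(x)
}
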