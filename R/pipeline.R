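# End-to-end pipeline: phantom -> 21 emulated reconstructions -> 4-ROI
# feature extraction -> stability categorization -> Friedman
# distinguishability -> report.

#' Default pipeline configuration
#'
#' Bundles the phantom geometry, the four insert configurations, the
#' reconstruction-setting grid, the noise model, the extraction parameters,
#' the stability thresholds and the significance level into one
#' serializable object.
#'
#' @param geometry A [phantom_geometry()].
#' @param configs List of [insert_config()] objects (default shapes 1-4).
#' @param variations Reconstruction-parameter variation lists.
#' @param default_setting The default [recon_setting()].
#' @param noise A [noise_model()].
#' @param extraction An [extraction_params()].
#' @param thresholds Stability category boundaries in percent.
#' @param alpha Friedman significance level.
#' @param overall_cov `"family_mean"` or `"pooled"` overall COV mode.
#' @param p_method `"chisq"` or `"exact"` Friedman p-values.
#' @param seed Base seed; every noise realization is derived from it.
#' @return Object of class `run_config`.
#' @export
default_run_config <- function(geometry = phantom_geometry(),
                               configs = lapply(1:4, insert_config),
                               variations = default_variations(),
                               default_setting = recon_setting(),
                               noise = noise_model(),
                               extraction = extraction_params(
                                 target_spacing = geometry$voxel_spacing),
                               thresholds = c(5, 10, 20),
                               alpha = 0.05,
                               overall_cov = "family_mean",
                               p_method = "chisq",
                               seed = 1L) {
  structure(list(geometry = geometry, configs = configs,
                 variations = variations, default_setting = default_setting,
                 noise = noise, extraction = extraction,
                 thresholds = thresholds, alpha = alpha,
                 overall_cov = overall_cov, p_method = p_method,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Small deterministic config fingerprint for provenance: a modular
# polynomial hash of the deparsed config (doubles stay exact below 2^53).
config_hash <- function(config) {
  txt <- paste(deparse(config), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# Per-setting noise seed derived from the base seed; kept below 2^31.
derive_seed <- function(base_seed, index) {
  (as.numeric(base_seed) * 7919 + index * 104729) %% 2147483629
}

#' Run the full stability and distinguishability pipeline
#'
#' Builds the phantom with all four inserts mounted, emulates every
#' reconstruction setting (one noise realization per setting, seeded from
#' the base seed), extracts the 78 features from each of the four ROIs on
#' every image, categorizes per-feature stability, and applies the
#' Friedman procedure to the stable features. Deterministic given the
#' config: the same config and seed reproduce every output byte.
#'
#' @param config A [default_run_config()].
#' @param outdir Optional output directory; when given, writes
#'   `features.csv` (+ JSON sidecar with extraction parameters),
#'   `stability_shape<g>.csv`, `friedman_tests.csv` and `report.json`, and
#'   with `write_nifti = TRUE` also one NIfTI volume per setting and the
#'   four masks.
#' @param write_nifti Write emulated volumes and masks as NIfTI.
#' @param verbose Log stage progress and wall time.
#' @return Object of class `run_report`: the feature table, per-shape
#'   stability tables, overall stability, category counts, Friedman tests,
#'   the stable and distinguishable feature lists, and provenance (config
#'   hash, seed).
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL,
                         write_nifti = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("stage %-12s %6.1fs", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }

  geom <- config$geometry
  settings <- stage("settings",
                    enumerate_settings(config$variations,
                                       config$default_setting))
  phantom <- stage("phantom", build_phantom(geom, config$configs))
  masks <- stage("masks", lapply(seq_along(config$configs),
                                 function(i) make_roi_mask(geom, i)))
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  rows <- stage("extract", {
    res <- list()
    for (si in seq_along(settings)) {
      st <- settings[[si]]
      img <- emulate_reconstruction(phantom, st, config$noise,
                                    seed = derive_seed(config$seed, si))
      if (write_nifti && !is.null(outdir))
        write_volume_nifti(img, file.path(outdir,
                                          paste0(st$setting_id, ".nii.gz")))
      for (gi in seq_along(config$configs)) {
        fv <- extract_all(img, masks[[gi]], config$extraction)
        res[[length(res) + 1L]] <- data.frame(
          feature = names(fv),
          shape_id = config$configs[[gi]]$shape_id,
          setting_id = st$setting_id,
          family = st$family,
          value = unname(fv),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, res)
  })

  shapes <- vapply(config$configs, `[[`, 0L, "shape_id")
  stab_by_shape <- stage("stability", lapply(shapes, function(g)
    stability_table(rows, g, config$thresholds, config$overall_cov)))
  names(stab_by_shape) <- paste0("shape", shapes)

  # overall stability: per-feature overall COV averaged over the shapes
  ov <- stab_by_shape[[1]][, c("feature", "cov_overall")]
  for (k in seq_along(stab_by_shape)[-1])
    ov$cov_overall <- ov$cov_overall + stab_by_shape[[k]]$cov_overall
  ov$cov_overall <- ov$cov_overall / length(stab_by_shape)
  ov$category <- categorize_stability(ov$cov_overall, config$thresholds)
  stable <- ov$feature[!is.na(ov$category) & ov$category == "stable"]

  fried <- stage("friedman",
                 select_distinguishable(stable, rows, config$alpha,
                                        config$p_method))

  report <- structure(list(
    features = rows,
    settings = settings_table(settings),
    stability_by_shape = stab_by_shape,
    stability_overall = ov,
    category_counts = lapply(stab_by_shape, category_counts),
    overall_counts = as.list(table(factor(ov$category,
      levels = c("stable", "moderately_stable", "poorly_stable",
                 "unstable")))),
    stable_features = stable,
    friedman_tests = fried$tests,
    distinguishable_features = fried$distinguishable,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      n_features = length(feature_names()),
                      n_settings = length(settings),
                      n_shapes = length(shapes),
                      n_pairs = ncol(utils::combn(shapes, 2)),
                      package_version =
                        as.character(utils::packageVersion("radstab")))
  ), class = "run_report")

  if (!is.null(outdir)) stage("write", write_report(report, config, outdir,
                                                    masks, write_nifti))
  report
}

write_report <- function(report, config, outdir, masks, write_nifti) {
  utils::write.csv(report$features, file.path(outdir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(ng = config$extraction$ng,
                            discretization = config$extraction$discretization,
                            aggregation = "3D merged, 13 directions",
                            distance = config$extraction$distance,
                            spacing_mm = config$extraction$target_spacing,
                            config_hash = report$provenance$config_hash,
                            seed = config$seed),
                       file.path(outdir, "features_params.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  for (nm in names(report$stability_by_shape))
    utils::write.csv(report$stability_by_shape[[nm]],
                     file.path(outdir, paste0("stability_", nm, ".csv")),
                     row.names = FALSE)
  utils::write.csv(report$stability_overall,
                   file.path(outdir, "stability_overall.csv"),
                   row.names = FALSE)
  utils::write.csv(report$friedman_tests,
                   file.path(outdir, "friedman_tests.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summarize_report(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (write_nifti)
    for (i in seq_along(masks))
      write_volume_nifti(masks[[i]],
                         file.path(outdir, sprintf("mask_shape%d.nii.gz", i)))
  invisible(NULL)
}

#' Summary of a run report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return List with the category counts, the stable and distinguishable
#'   feature lists and provenance, suitable for JSON serialization.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "run_report"))
  list(category_counts = report$overall_counts,
       category_counts_per_family = report$category_counts,
       n_stable = length(report$stable_features),
       stable_features = report$stable_features,
       n_distinguishable = length(report$distinguishable_features),
       distinguishable_features = report$distinguishable_features,
       provenance = report$provenance)
}

#' @export
print.run_report <- function(x, ...) {
  cc <- x$overall_counts
  cat("radstab run report\n")
  cat(sprintf("  %d features x %d shapes x %d settings\n",
              x$provenance$n_features, x$provenance$n_shapes,
              x$provenance$n_settings))
  cat(sprintf("  stability: %s stable, %s moderately stable, %s poorly stable, %s unstable\n",
              cc$stable, cc$moderately_stable, cc$poorly_stable, cc$unstable))
  cat(sprintf("  distinguishable (all %d pairs, alpha-significant): %d of %d stable\n",
              x$provenance$n_pairs,
              length(x$distinguishable_features),
              length(x$stable_features)))
  if (length(x$distinguishable_features))
    cat("   ", paste(x$distinguishable_features, collapse = ", "), "\n")
  invisible(x)
}
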