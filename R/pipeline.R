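# End-to-end orchestration: run config -> averaged, corrected, normalized
# spectra -> per-region decompositions -> reports (JSON + CSV) -> feature
# matrix for external multivariate tools.

# resolve a scheme name from a config string
lookup_scheme <- function(name) {
  switch(name,
         amide_I = , amide_i = amide_i_scheme(),
         ss_conformers = , ss = ss_conformer_scheme(),
         stop("unknown scheme: ", name, call. = FALSE))
}

#' Default run configuration
#'
#' A complete configuration for one of the two standard workflows:
#' `"endosperm"` (solid kernel scan: crop 300-2000, linear fluorescence
#' baseline through band-free anchor windows, 1460 normalization, S-S
#' conformer fit plus marker detection) or `"gliadin_liquid"` (amide I
#' decomposition of a liquid-extract spectrum with a local linear baseline
#' over the fit region only).
#'
#' @param preset workflow name.
#' @return nested list; see fields in source. Override entries freely
#'   before passing to [run_pipeline()].
#' @export
default_config <- function(preset = c("endosperm", "gliadin_liquid")) {
  preset <- match.arg(preset)
  if (preset == "endosperm") {
    list(
      preset = preset,
      preprocess = list(
        crop = c(300, 2000),
        baseline = list(kind = "polynomial", degree = 3,
                        anchors = list(c(300, 330), c(580, 610),
                                       c(780, 800), c(1150, 1190),
                                       c(1500, 1540), c(1950, 2000))),
        normalize = list(ref_center = 1460, window = c(1450, 1470))),
      # the fit window extends past 500-550 so the starch 480 shoulder is
      # modelled as its own component instead of leaking into the S-S bands
      regions = list(list(name = "ss_conformers", region = c(468, 558),
                          scheme = "ss_conformers", shape = "gaussian",
                          fwhm_limits = c(5, 20))),
      markers = TRUE,
      seed = 1)
  } else {
    list(
      preset = preset,
      preprocess = list(crop = c(1585, 1715), baseline = NULL,
                        normalize = NULL),
      regions = list(list(name = "amide_I", region = c(1590, 1710),
                          scheme = "amide_I", shape = "gaussian",
                          fwhm_limits = c(6, 30))),
      markers = FALSE,
      seed = 1)
  }
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(config, auto_unbox = TRUE,
                                           digits = 12)), tmp)
  unname(tools::md5sum(tmp))
}

# preprocess one averaged spectrum according to the config block
apply_preprocess <- function(s, pp) {
  info <- list()
  if (!is.null(pp$crop)) s <- crop_spectrum(s, unlist(pp$crop))
  if (!is.null(pp$baseline)) {
    bc <- baseline_correct(s, kind = pp$baseline$kind %||% "linear",
                           anchor_windows = lapply(pp$baseline$anchors, unlist),
                           degree = pp$baseline$degree %||% 3)
    s <- bc$spectrum; info$baseline <- bc$baseline
  }
  if (!is.null(pp$normalize)) {
    nb <- normalize_to_band(s, ref_center = pp$normalize$ref_center %||% 1460,
                            search_window = unlist(pp$normalize$window))
    s <- nb$spectrum; info$normalization <- nb$record
  }
  list(spectrum = s, info = info)
}

#' Run the full analysis pipeline
#'
#' For every sample: average its replicates, crop, baseline-correct,
#' normalize, decompose each configured region, quantify against the
#' region's assignment scheme, optionally detect marker bands and the
#' Tyr/Trp indices, and write JSON and CSV reports plus a combined feature
#' matrix. Warnings are collected (replicate SD above 5%, unassigned
#' components, non-converged fits, fit correlation below the region's
#' quality threshold), not fatal.
#'
#' @param config nested list as from [default_config()], or path to a YAML
#'   file with the same structure. Must additionally carry `samples`: a
#'   list of `list(id =, files =)` replicate groups (or `spectra =` with
#'   in-memory [raman_spectrum] lists).
#' @param outdir output directory; created if missing. `NULL` disables
#'   writing.
#' @param r_thresholds named fit-quality warning thresholds per region
#'   name; defaults to the published criteria 0.9985 (S-S) and 0.9991
#'   (amide I).
#' @return list with one element per sample: preprocessed spectrum, per
#'   region `band_fit` and report, marker results, warnings; plus
#'   `feature_matrix` and `paths` of written files.
#' @export
run_pipeline <- function(config, outdir = NULL,
                         r_thresholds = c(ss_conformers = 0.9985,
                                          amide_I = 0.9991)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(!is.null(config$samples))
  hash <- config_hash(config[setdiff(names(config), "samples")])
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  results <- list()
  feat <- list()
  for (sm in config$samples) {
    warnings_log <- character(0)
    reps <- if (!is.null(sm$spectra)) sm$spectra
      else lapply(sm$files, read_spectrum)
    avg <- withCallingHandlers(
      average_replicates(reps),
      warning = function(w) {
        warnings_log <<- c(warnings_log, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    pp <- apply_preprocess(avg$mean, config$preprocess)
    s <- pp$spectrum
    regions <- list()
    for (rg in config$regions) {
      scheme <- lookup_scheme(rg$scheme)
      fit <- withCallingHandlers(
        fit_bands(s, unlist(rg$region), scheme = scheme,
                  shape = rg$shape %||% "gaussian",
                  fwhm_limits = if (!is.null(rg$fwhm_limits))
                    unlist(rg$fwhm_limits)),
        warning = function(w) {
          warnings_log <<- c(warnings_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      thr <- r_thresholds[rg$name]
      if (!is.na(thr) && is.finite(fit$pearson_r) && fit$pearson_r < thr)
        warnings_log <- c(warnings_log,
                          sprintf("%s: pearson r %.5f below %.4f", rg$name,
                                  fit$pearson_r, thr))
      report <- withCallingHandlers(
        if (identical(scheme$name, "amide_I")) quantify_amide_i(fit, scheme)
        else quantify_ss_conformers(fit, scheme),
        warning = function(w) {
          warnings_log <<- c(warnings_log, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      regions[[rg$name]] <- list(fit = fit, report = report)
    }
    markers <- NULL
    if (isTRUE(config$markers)) {
      markers <- list(
        table = detect_marker_bands(s),
        tyr = tryCatch(tyrosine_doublet_ratio(s), error = function(e) NULL),
        trp = tryCatch(tryptophan_intensity(s), error = function(e) NULL))
    }
    structure_rep <- regions[["amide_I"]]$report
    conformer_rep <- regions[["ss_conformers"]]$report
    feat[[sm$id]] <- cbind(data.frame(sample = sm$id),
                           feature_row(structure_rep, conformer_rep,
                                       markers))
    results[[sm$id]] <- list(spectrum = s, sd_profile = avg$sd,
                             preprocess = pp$info, regions = regions,
                             markers = markers, warnings = warnings_log)
    if (!is.null(outdir))
      write_sample_report(results[[sm$id]], sm$id, outdir, hash)
  }
  fm <- do.call(rbind, lapply(feat, function(d) {
    missing <- setdiff(unique(unlist(lapply(feat, names))), names(d))
    for (m in missing) d[[m]] <- NA
    d
  }))
  paths <- character(0)
  if (!is.null(outdir)) {
    fp <- file.path(outdir, "feature_matrix.csv")
    utils::write.csv(fm, fp, row.names = FALSE)
    paths <- c(paths, fp)
  }
  out <- list(samples = results, feature_matrix = fm, config_hash = hash,
              paths = paths)
  class(out) <- "pipeline_result"
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline run: %d sample(s), config %s\n", length(x$samples),
              substr(x$config_hash, 1, 8)))
  for (id in names(x$samples)) {
    sm <- x$samples[[id]]
    cat(" ", id, ":")
    for (rn in names(sm$regions))
      cat(sprintf(" %s r=%.5f", rn, sm$regions[[rn]]$fit$pearson_r))
    if (length(sm$warnings)) cat(sprintf(" [%d warning(s)]",
                                         length(sm$warnings)))
    cat("\n")
  }
  invisible(x)
}

# serialize one sample's reports to JSON + component CSVs
write_sample_report <- function(res, id, outdir, hash) {
  rep_json <- list(
    sample = id,
    config_hash = hash,
    package_version = as.character(utils::packageVersion("ramandec")),
    warnings = res$warnings)
  for (rn in names(res$regions)) {
    rg <- res$regions[[rn]]
    rep_json[[rn]] <- list(
      pearson_r = rg$fit$pearson_r,
      residual_rms = rg$fit$residual_rms,
      converged = rg$fit$converged,
      components = rg$fit$components,
      fractions = as.list(rg$report$fractions))
    utils::write.csv(rg$fit$components,
                     file.path(outdir, sprintf("%s_%s_components.csv", id, rn)),
                     row.names = FALSE)
  }
  if (!is.null(res$markers)) {
    rep_json$markers <- list(
      tyr_ratio = res$markers$tyr$ratio %||% NA,
      tyr_category = res$markers$tyr$category %||% NA,
      trp_height = res$markers$trp$height %||% NA)
    utils::write.csv(res$markers$table,
                     file.path(outdir, sprintf("%s_markers.csv", id)),
                     row.names = FALSE)
  }
  jsonlite::write_json(rep_json, file.path(outdir, sprintf("%s_report.json", id)),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(NULL)
}
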