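#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full synthetic run.
#' Unknown keys are rejected; the complete configuration is serialised
#' into the run's provenance block so any output is regenerable from it.
#'
#' @param out_dir output directory for the run.
#' @param seed master integer seed; every stage derives its own seed from
#'   it deterministically.
#' @param stages growth stages to process.
#' @param weeds add weed noise objects to the rendered scenes.
#' @param dn_jitter,dsm_noise renderer noise levels (see
#'   \code{\link{render_params}}).
#' @param methods,feature_sets,k_top modelling options (see
#'   \code{\link{run_model_suite}}).
#' @param height_stat plot height statistic, \code{"mean"} or \code{"p90"}.
#' @param mask_vegetation restrict plot index means to vegetation pixels.
#' @param yaml optional path to a YAML file whose keys override the
#'   defaults (same names as the arguments).
#' @return validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(out_dir = tempfile("uavpnc_run_"),
                            seed = 20190418L,
                            stages = c("S1", "S2", "S3"),
                            weeds = FALSE, dn_jitter = 8, dsm_noise = 0.01,
                            methods = c("MLR", "KNN", "RF"),
                            feature_sets = c("VIs", "MPs", "VIs+MPs"),
                            k_top = 5L, height_stat = "mean",
                            mask_vegetation = FALSE, yaml = NULL) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              weeds = weeds, dn_jitter = dn_jitter, dsm_noise = dsm_noise,
              methods = methods, feature_sets = feature_sets,
              k_top = as.integer(k_top), height_stat = height_stat,
              mask_vegetation = mask_vegetation)
  if (!is.null(yaml)) {
    over <- yaml::read_yaml(yaml)
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown configuration keys: ",
                              paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, over)
  }
  if (!all(cfg$stages %in% c("S1", "S2", "S3")))
    stop("stages must be among S1, S2, S3")
  if (!all(cfg$methods %in% c("MLR", "KNN", "RF")))
    stop("unknown modelling method")
  if (!cfg$height_stat %in% c("mean", "p90")) stop("bad height_stat")
  class(cfg) <- "pipeline_config"
  cfg
}

stage_seed <- function(seed, stage, what) {
  ## small deterministic per-stage offsets, kept far below .Machine$integer.max
  off <- match(stage, c("S0", "S1", "S2", "S3")) * 101L +
    match(what, c("truth", "scene", "photo")) * 13L
  (as.integer(seed) %% 2000000000L) + off
}

#' Run the full synthetic pipeline
#'
#' Generates the 48-plot design, samples per-plot ground truth, renders
#' DOM/DSM/mask layers for every requested stage plus the bare-soil DSM,
#' extracts the ten vegetation indices and the morphological parameters
#' per plot, runs the model suite, and writes every artefact plus a
#' provenance block to the output directory.  Identical configuration and
#' seed give identical outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return (invisibly) a list with the run directory, the feature table,
#'   the model report and the per-stage truth; files are written under
#'   \code{config$out_dir}.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- render_params(dn_jitter = config$dn_jitter,
                          dsm_noise = config$dsm_noise,
                          weeds = config$weeds)
  design <- generate_design(design_config(seed = config$seed))
  write_plots(design, file.path(config$out_dir, "plots.geojson"))

  bare <- render_scene(empty_truth(design),
                       seed = stage_seed(config$seed, "S0", "scene"),
                       params = params)
  write_raster(bare$dsm, file.path(config$out_dir, "dsm_S0.tif"))

  features <- list(); truths <- list(); morph_all <- list()
  for (st in config$stages) {
    truth <- sample_truth(design, st,
                          seed = stage_seed(config$seed, st, "truth"))
    scene <- render_scene(truth, seed = stage_seed(config$seed, st, "scene"),
                          params = params)
    truth <- scene$truth
    truths[[st]] <- truth
    write_raster(scene$dom, file.path(config$out_dir, sprintf("dom_%s.tif", st)))
    write_raster(scene$dsm, file.path(config$out_dir, sprintf("dsm_%s.tif", st)))
    write_raster(scene$mask, file.path(config$out_dir, sprintf("truthmask_%s.tif", st)))
    write.csv(truth$plots, file.path(config$out_dir, sprintf("truth_%s.csv", st)),
              row.names = FALSE)

    seg_mask <- suppressWarnings(segment_vegetation_uav(scene$dom))
    write_raster(seg_mask, file.path(config$out_dir, sprintf("mask_%s.tif", st)))
    vi <- plot_vi_table(scene$dom, design,
                        mask = if (config$mask_vegetation) seg_mask else NULL)
    morph <- extract_morphology(scene$dom, scene$dsm, bare$dsm, design,
                                stage = st, height_stat = config$height_stat)
    morph_all[[st]] <- morph
    feat <- merge(vi, morph[, c("plot_id", "H", "CC", "CV")], by = "plot_id")
    feat$stage <- st
    feat$replication <- design$records$replication[
      match(feat$plot_id, design$records$plot_id)]
    feat$PNC <- truth$plots$true_PNC[match(feat$plot_id, truth$plots$plot_id)]
    features[[st]] <- feat

    screen <- pearson_screen(
      feat[, c(vi_registry(), mp_names()), drop = FALSE], feat$PNC)
    write.csv(screen, file.path(config$out_dir,
                                sprintf("correlations_%s.csv", st)),
              row.names = FALSE)
  }
  features <- do.call(rbind, features)
  ord <- order(features$stage, features$plot_id)
  features <- features[ord, c("plot_id", "stage", "replication",
                              vi_registry(), "H", "CC", "CV", "PNC",
                              "valid_px")]
  rownames(features) <- NULL
  write.csv(features, file.path(config$out_dir, "features.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, morph_all),
            file.path(config$out_dir, "morphology.csv"), row.names = FALSE)

  report <- run_model_suite(features, stages = config$stages,
                            methods = config$methods,
                            feature_sets = config$feature_sets,
                            k_top = config$k_top, seed = config$seed)
  report_json <- split(report, report$stage)
  jsonlite::write_json(lapply(report_json, function(d) unclass(d)),
                       file.path(config$out_dir, "model_report.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  prov <- list(package = "uavpnc",
               version = as.character(packageVersion("uavpnc")),
               r_version = R.version.string,
               config = unclass(config))
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(dir = config$out_dir, features = features,
                 report = report, truth = truths, design = design))
}

#' Agreement between extracted and true morphology
#'
#' Per-stage coefficient of determination (squared Pearson correlation of
#' the 1:1 comparison) and RMSE of extracted vs reference plant height and
#' canopy coverage — the accuracy assessment run after every extraction.
#'
#' @param extracted data frame \code{plot_id, stage, H, CC}.
#' @param truth data frame \code{plot_id, stage, true_H, true_CC} (or the
#'   \code{plots} table of a \code{scene_truth} plus its stage).
#' @return data frame \code{stage, variable, R2, RMSE, n}.
#' @export
validate_extraction <- function(extracted, truth) {
  j <- merge(extracted, truth, by = intersect(c("plot_id", "stage"),
                                              intersect(names(extracted),
                                                        names(truth))))
  if (!nrow(j)) stop("join failure: no common plots between tables")
  rows <- list()
  for (st in unique(j$stage)) {
    d <- j[j$stage == st, ]
    for (v in c("H", "CC")) {
      tv <- paste0("true_", v)
      if (!all(c(v, tv) %in% names(d))) next
      ok <- is.finite(d[[v]]) & is.finite(d[[tv]])
      r2 <- if (sum(ok) > 2 && sd(d[[tv]][ok]) > 0 && sd(d[[v]][ok]) > 0)
        cor(d[[v]][ok], d[[tv]][ok])^2 else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stage = st, variable = v, R2 = r2,
        RMSE = sqrt(mean((d[[v]][ok] - d[[tv]][ok])^2)), n = sum(ok),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
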