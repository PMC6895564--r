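#' Pipeline configuration
#'
#' Gathers every input of the five-step analysis (gap-filling segmentation,
#' myofiber detection, CNF detection, fluorescence measurement, export) into
#' one object. Channel inputs may be file paths to 8-bit TIFFs or in-memory
#' [gray_image()]s; the nuclear channel and marker channels are optional and
#' their stages are skipped when absent.
#'
#' @param laminin boundary-channel image or path (required).
#' @param gapfill a [gap_fill_config()] (required).
#' @param dapi optional nuclear channel image or path.
#' @param markers optional named list of marker channel images or paths.
#' @param training data.frame (`roi_id`, `label`) or path to a CSV with those
#'   columns, used to train the classifier; ignored when `classifier` is
#'   given.
#' @param classifier optional pre-trained [train_classifier()] model, reused
#'   across sections.
#' @param corrections ROI ids whose class call is flipped after
#'   classification.
#' @param seed_fibers named list (per marker channel) of dimmest-positive seed
#'   ROI ids for [call_positive()]; channels without seeds get MFIs but no
#'   positivity calls.
#' @param erosion_percent CNF erosion setting (default 80).
#' @param dapi_threshold binarization threshold for the nuclear channel.
#' @param typing_mode `"mouse"` or `"generic"` (see [type_fibers()]); typing
#'   runs when at least two marker channels have positivity calls.
#' @param microns_per_pixel physical scale; unit columns are `NA` when `NULL`.
#' @param out_dir optional output directory for the record CSV, label/filler
#'   masks, and run log.
#' @param seed RNG seed for classifier training.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(laminin, gapfill, dapi = NULL, markers = list(),
                            training = NULL, classifier = NULL,
                            corrections = integer(0), seed_fibers = list(),
                            erosion_percent = 80L, dapi_threshold = 128,
                            typing_mode = "mouse", microns_per_pixel = NULL,
                            out_dir = NULL, seed = 1L) {
  stopifnot(inherits(gapfill, "gapfill_config"))
  if (is.null(training) && is.null(classifier))
    stop("either training labels or a pre-trained classifier is required")
  structure(as.list(environment()), class = "pipeline_config")
}

as_channel <- function(x, scale = NULL) {
  if (is.null(x)) return(NULL)
  if (is.character(x)) read_gray_tiff(x, scale = scale) else x
}

#' Run the full analysis pipeline
#'
#' Executes, in order: gap-filling segmentation of the boundary channel, ROI
#' extraction and shape features, SVM classification (training the model first
#' when labels rather than a model are supplied) with optional corrections,
#' CNF detection when a nuclear channel is present, per-channel MFI and
#' positivity when marker channels are present, fiber typing when at least two
#' channels are called, and assembly/export of the per-fiber records. Under a
#' fixed configuration and seed the outputs are byte-identical across runs.
#'
#' @param cfg a [pipeline_config()].
#' @return list of class `pipeline_result` with `records`, `rois`, `labels`,
#'   `cnf`, `fluor`, `fiber_type`, `gapfill`, and `model`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  laminin <- as_channel(cfg$laminin, cfg$microns_per_pixel)

  gf <- fill_gaps(laminin, cfg$gapfill)
  rois <- extract_rois(gf$segmented)
  feats <- compute_features_table(rois)

  model <- cfg$classifier
  if (is.null(model)) {
    tr <- cfg$training
    if (is.character(tr)) tr <- read.csv(tr)
    if (!all(c("roi_id", "label") %in% names(tr)))
      stop("detect stage: training must have columns roi_id, label")
    tset <- merge(feats, tr[, c("roi_id", "label")], by = "roi_id")
    if (nrow(tset) < nrow(tr))
      stop("detect stage: training refers to unknown roi ids")
    model <- train_classifier(tset, seed = cfg$seed)
  }
  labels <- classify_rois(model, feats)
  labels <- apply_corrections(labels, cfg$corrections)

  cnf_df <- NULL
  if (!is.null(cfg$dapi)) {
    dapi <- as_channel(cfg$dapi)
    cnf_df <- detect_cnf(rois, labels, dapi,
                         erosion_percent = cfg$erosion_percent,
                         dapi_threshold = cfg$dapi_threshold)
  }

  fluor <- NULL
  fiber_type <- NULL
  if (length(cfg$markers) > 0L) {
    myo_ids <- names(labels)[labels == "myofiber"]
    myo_rois <- rois[vapply(rois, function(r) as.character(r$id), "")
                     %in% myo_ids]
    fluor <- list()
    for (ch in names(cfg$markers)) {
      channel <- as_channel(cfg$markers[[ch]])
      mfi <- measure_mfi(myo_rois, channel)
      seeds <- cfg$seed_fibers[[ch]]
      if (!is.null(seeds) && length(seeds) > 0L) {
        cp <- call_positive(mfi, seeds)
        fluor[[ch]] <- list(mfi = mfi, positive = cp$positive,
                            threshold = cp$threshold)
      } else {
        fluor[[ch]] <- list(mfi = mfi, positive = NULL, threshold = NA_real_)
      }
    }
    called <- names(fluor)[vapply(fluor, function(x) !is.null(x$positive),
                                  TRUE)]
    if (length(called) >= 2L) {
      pm <- do.call(cbind, lapply(fluor[called], function(x) x$positive))
      colnames(pm) <- called
      ft <- type_fibers(pm, mode = cfg$typing_mode)
      names(ft) <- rownames(pm)
      fiber_type <- ft
    }
  }

  records <- fiber_records(rois, labels, cnf = cnf_df, fluor = fluor,
                           fiber_type = fiber_type,
                           microns_per_pixel = cfg$microns_per_pixel)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    export_records(records, file.path(cfg$out_dir, "fiber_records.csv"))
    write_label_tiff(gf$segmented, file.path(cfg$out_dir, "segmented.tif"))
    write_label_tiff(gf$filler_mask, file.path(cfg$out_dir, "filler.tif"))
    write_run_log(cfg, file.path(cfg$out_dir, "run_log.txt"))
  }

  structure(list(records = records, rois = rois, labels = labels,
                 cnf = cnf_df, fluor = fluor, fiber_type = fiber_type,
                 gapfill = gf, model = model),
            class = "pipeline_result")
}

# run log: package version, seed, config hash and key parameters
write_run_log <- function(cfg, path) {
  tmp <- tempfile()
  keep <- cfg[!vapply(cfg, function(x)
    inherits(x, "gray_image") || inherits(x, "fiber_classifier"), TRUE)]
  writeLines(deparse(keep), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  writeLines(c(
    sprintf("fiberquant %s", as.character(utils::packageVersion("fiberquant"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("seed: %d", cfg$seed),
    sprintf("config_md5: %s", hash),
    sprintf("gapfill: thick=%g thin=%g steps=%d expansion=%g min_track=%d",
            cfg$gapfill$thick_threshold, cfg$gapfill$thin_threshold,
            cfg$gapfill$n_steps, cfg$gapfill$expansion_ratio,
            cfg$gapfill$min_track_area),
    sprintf("erosion_percent: %d", as.integer(cfg$erosion_percent)),
    sprintf("dapi_threshold: %g", cfg$dapi_threshold),
    sprintf("microns_per_pixel: %s",
            if (is.null(cfg$microns_per_pixel)) "NA" else
              format(cfg$microns_per_pixel))
  ), path)
  invisible(path)
}
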