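## End-to-end workflow: split -> (train | load model) -> predict per block
## -> threshold -> intensity refine -> denoise -> assemble -> export. Every
## stage is an ordinary exported function and can be re-run standalone from
## its intermediate store; the pipeline adds parameter logging and a JSON
## run manifest so a segmentation is reproducible from its config alone.

#' Pipeline configuration
#'
#' Collects every stage parameter with its default. The config serializes
#' to JSON via [write_config()] and round-trips unchanged.
#'
#' @param input path to a TIFF volume (file or slice directory), or an
#'   in-memory [ct_volume()].
#' @param workdir directory for intermediate stores and outputs.
#' @param labels path to a label table, or a [label_set()]; ignored when
#'   `model_path` points to a trained classifier archive.
#' @param model_path optional path to a saved classifier to reuse.
#' @param block_edge,halo block grid parameters.
#' @param spec a [feature_spec()].
#' @param n_trees,rf_seed random-forest parameters.
#' @param threshold probability threshold `t`.
#' @param refine_threshold intensity threshold `t2` separating wax from
#'   tissue (manual; inspect the sidecar histogram).
#' @param denoiser `"regions"`, `"open_close"` or `"close_open_open2"`.
#' @param min_size,connectivity parameters for the regions denoiser.
#' @param export_mesh write the final mask as STL.
#' @param overlay_slice optional slice index for a PNG overlay.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, workdir, labels = NULL, model_path = NULL,
                            block_edge = 256L, halo = 16L,
                            spec = feature_spec(),
                            n_trees = 200L, rf_seed = 17L,
                            threshold = 0.5, refine_threshold = NULL,
                            denoiser = c("regions", "open_close",
                                         "close_open_open2"),
                            min_size = 700L, connectivity = 26L,
                            export_mesh = FALSE, overlay_slice = NULL) {
  denoiser <- match.arg(denoiser)
  structure(list(input = input, workdir = workdir, labels = labels,
                 model_path = model_path, block_edge = as.integer(block_edge),
                 halo = as.integer(halo), spec = spec,
                 n_trees = as.integer(n_trees), rf_seed = as.integer(rf_seed),
                 threshold = threshold, refine_threshold = refine_threshold,
                 denoiser = denoiser, min_size = as.integer(min_size),
                 connectivity = as.integer(connectivity),
                 export_mesh = isTRUE(export_mesh),
                 overlay_slice = overlay_slice),
            class = "pipeline_config")
}

#' Write / read a pipeline config as JSON
#' @param config a [pipeline_config()] (paths only; in-memory inputs are
#'   not serializable).
#' @param path JSON file path.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$spec <- unclass(x$spec)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- x$spec
  spec <- feature_spec(
    gaussian_sigmas = as.numeric(sp$gaussian_sigmas),
    neighbors_radii = sp$neighbors_radii,
    entropy_radius = sp$entropy_radius, entropy_bins = sp$entropy_bins,
    structure_scales = lapply(seq_len(nrow(sp$structure_scales)),
                              function(i) as.numeric(sp$structure_scales[i, ])),
    hessian_sigmas = as.numeric(sp$hessian_sigmas), enabled = sp$enabled)
  pipeline_config(
    input = x$input, workdir = x$workdir, labels = x$labels,
    model_path = x$model_path, block_edge = x$block_edge, halo = x$halo,
    spec = spec, n_trees = x$n_trees, rf_seed = x$rf_seed,
    threshold = as.numeric(x$threshold),
    refine_threshold = if (!is.null(x$refine_threshold))
      as.numeric(x$refine_threshold),
    denoiser = x$denoiser, min_size = x$min_size,
    connectivity = x$connectivity, export_mesh = x$export_mesh,
    overlay_slice = x$overlay_slice)
}

stage_log <- function(run_log, stage, ...) {
  msg <- sprintf(...)
  message(sprintf("[%s] %s", stage, msg))
  c(run_log, stats::setNames(list(msg), stage))
}

#' Run the segmentation pipeline
#'
#' Executes the full workflow on the configured input and writes a
#' `manifest.json` capturing every parameter and per-stage counts. Stages
#' abort with the stage name on failure. With a halo smaller than the
#' feature bank's footprint, blockwise prediction can differ at seams; a
#' warning names the minimum safe halo.
#'
#' @param config a [pipeline_config()].
#' @return list with `mask` (final binary array), `mask_store` path,
#'   `model`, `manifest` path and the per-stage `log`.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  dir.create(cfg$workdir, showWarnings = FALSE, recursive = TRUE)
  run_log <- list()
  fp <- feature_footprint(cfg$spec)
  if (cfg$halo < fp)
    warning(sprintf(
      "halo %d is smaller than the feature footprint; minimum safe halo is %d",
      cfg$halo, fp))

  ## -- split ---------------------------------------------------------------
  vol <- if (inherits(cfg$input, "ct_volume")) cfg$input
         else read_volume(cfg$input)
  raw_store_path <- file.path(cfg$workdir, "store_raw")
  store <- try(split_volume(vol, raw_store_path, cfg$block_edge, cfg$halo,
                            overwrite = TRUE), silent = TRUE)
  if (inherits(store, "try-error"))
    stop("stage split failed: ", attr(store, "condition")$message)
  run_log <- stage_log(run_log, "split", "%d blocks (edge %d, halo %d)",
                       store$meta$block_count, cfg$block_edge, cfg$halo)
  grange <- c(store$meta$global_min, store$meta$global_max)

  ## -- train / load model --------------------------------------------------
  model <- if (!is.null(cfg$model_path) && file.exists(cfg$model_path)) {
    m <- load_model(cfg$model_path)
    run_log <- stage_log(run_log, "train", "loaded model from %s",
                         cfg$model_path)
    m
  } else {
    labels <- if (inherits(cfg$labels, "label_set")) cfg$labels
              else read_labels(cfg$labels)
    samples <- extract_training_set(vol, labels, cfg$spec,
                                    intensity_range = grange)
    m <- train_classifier(samples, n_trees = cfg$n_trees, seed = cfg$rf_seed)
    run_log <- stage_log(run_log, "train",
                         "%d samples on %d slices (%s), %d trees",
                         nrow(samples$x), length(samples$slices_used),
                         paste(sprintf("%s=%d", names(m$n_per_class),
                                       m$n_per_class), collapse = ", "),
                         cfg$n_trees)
    if (!is.null(cfg$model_path)) save_model(m, cfg$model_path)
    m
  }

  ## -- predict per block ---------------------------------------------------
  prob_path <- file.path(cfg$workdir, "store_prob")
  halo_pred <- min(max(cfg$halo, fp), cfg$block_edge)
  prob_store <- map_blocks(
    store,
    function(blk) predict_block(blk, model, cfg$spec,
                                intensity_range = grange),
    out_path = prob_path, halo = halo_pred, out_bits = 32L,
    overwrite = TRUE)
  run_log <- stage_log(run_log, "predict", "probability store at %s (halo %d)",
                       prob_path, halo_pred)
  prob <- assemble_volume(prob_store)$data

  ## -- threshold -> refine -> denoise --------------------------------------
  mask <- threshold_probability(prob, cfg$threshold)
  run_log <- stage_log(run_log, "threshold", "t=%g kept %d voxels",
                       cfg$threshold, sum(mask))
  if (is.null(cfg$refine_threshold))
    stop("stage refine failed: refine_threshold (t2) is not set; ",
         "inspect the store histogram to choose it")
  mask <- refine_by_intensity(mask, vol, cfg$refine_threshold)
  run_log <- stage_log(run_log, "refine", "t2=%g kept %d voxels",
                       cfg$refine_threshold, sum(mask))
  mask <- switch(cfg$denoiser,
    regions = remove_small_regions(mask, cfg$min_size, cfg$connectivity),
    open_close = scheme_open_close(mask),
    close_open_open2 = scheme_close_open_open2(mask))
  run_log <- stage_log(run_log, "denoise", "%s kept %d voxels",
                       cfg$denoiser, sum(mask))

  ## -- assemble + export ---------------------------------------------------
  mask_store_path <- file.path(cfg$workdir, "store_mask")
  write_mask_store(mask, mask_store_path, block_edge = cfg$block_edge,
                   halo = cfg$halo, overwrite = TRUE)
  artifacts <- list(mask_store = mask_store_path)
  if (isTRUE(cfg$export_mesh) && sum(mask) > 0) {
    mesh <- mask_to_mesh(mask, vol$voxel_size_um, provenance = "final mask")
    stl <- file.path(cfg$workdir, "mask.stl")
    write_stl(mesh, stl)
    artifacts$stl <- stl
    run_log <- stage_log(run_log, "mesh", "%d triangles -> %s",
                         nrow(mesh$faces), stl)
  }
  if (!is.null(cfg$overlay_slice)) {
    z <- as.integer(cfg$overlay_slice)
    sl <- array(vol$data[z + 1L, , ], dim(vol$data)[2:3])
    ov <- overlay_masks(sl, list(array(mask[z + 1L, , ], dim(sl))), "red",
                        alpha = 0.45)
    pngf <- file.path(cfg$workdir, sprintf("overlay_z%04d.png", z))
    write_overlay_png(ov, pngf)
    artifacts$overlay <- pngf
    run_log <- stage_log(run_log, "overlay", "slice %d -> %s", z, pngf)
  }

  manifest <- file.path(cfg$workdir, "manifest.json")
  cfgj <- cfg
  if (inherits(cfgj$input, "ct_volume")) cfgj$input <- "<in-memory volume>"
  if (inherits(cfgj$labels, "label_set")) cfgj$labels <- "<in-memory labels>"
  jsonlite::write_json(
    list(config = lapply(unclass(cfgj), function(v)
           if (inherits(v, "feature_spec")) unclass(v) else v),
         feature_fingerprint = spec_fingerprint(cfg$spec),
         log = run_log, artifacts = artifacts),
    manifest, auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  list(mask = mask, mask_store = mask_store_path, model = model,
       manifest = manifest, log = run_log)
}

#' Pick a representative test block
#'
#' Returns the grid index of the block whose intensity variance is closest
#' to the volume-wide variance — a proxy for "representative" used to trial
#' a segmentation on one block before committing to the full volume. Ties
#' break to the first block in enumeration order.
#'
#' @param store a `block_store`.
#' @return integer grid index `(i, j, k)`, 0-based.
#' @export
pick_test_block <- function(store) {
  grid <- store_grid(store)
  idx <- block_indices(grid)
  if (nrow(idx) == 0L) stop("empty store")
  ## volume-wide variance by aggregation of per-block sums
  n <- 0; s <- 0; s2 <- 0
  bvar <- numeric(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    blk <- read_block(store, idx[r, ])
    n <- n + length(blk); s <- s + sum(blk); s2 <- s2 + sum(blk^2)
    bvar[r] <- if (length(blk) > 1) stats::var(as.vector(blk)) else 0
  }
  gvar <- (s2 - s^2 / n) / (n - 1)
  best <- which.min(abs(bvar - gvar))
  idx[best, ]
}
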