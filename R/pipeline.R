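#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline (saliency detection ->
#' segmentation -> presentation strategy -> phosphene rendering) with the
#' package defaults. The configuration round-trips through YAML/JSON.
#'
#' @param strategy `"febr"`, `"fze"`, or `"none"` (LRG of the raw image).
#' @param alpha Manifold-ranking propagation parameter.
#' @param n_target,compactness Superpixel parameters.
#' @param sigma_c Graph color-affinity bandwidth.
#' @param connectivity 4 or 8 for segmentation connectivity analysis.
#' @param min_area_frac,struct_size,largest_only Mask cleanup parameters.
#' @param scales Sobel kernel sizes.
#' @param edge_threshold `"otsu"` or a numeric fixed threshold.
#' @param resolutions Phosphene grid sizes to render.
#' @param sigma_ratio Phosphene spread as a fraction of dot pitch.
#' @param pad_frac FZE zoom-window padding.
#' @param seed Integer seed recorded in the manifest.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(strategy = c("febr", "fze", "none"),
                            alpha = 0.99, n_target = 200, compactness = 10,
                            sigma_c = 0.1, connectivity = 8L,
                            min_area_frac = 0.001, struct_size = 3L,
                            largest_only = FALSE, scales = c(3L, 7L),
                            edge_threshold = "otsu",
                            resolutions = c(8L, 16L, 24L, 32L, 48L, 64L),
                            sigma_ratio = 1 / 6, pad_frac = 0.05,
                            seed = 0L) {
  structure(list(strategy = match.arg(strategy), alpha = alpha,
                 n_target = n_target, compactness = compactness,
                 sigma_c = sigma_c, connectivity = as.integer(connectivity),
                 min_area_frac = min_area_frac,
                 struct_size = as.integer(struct_size),
                 largest_only = largest_only, scales = as.integer(scales),
                 edge_threshold = edge_threshold,
                 resolutions = as.integer(resolutions),
                 sigma_ratio = sigma_ratio, pad_frac = pad_frac,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full presentation pipeline on one image
#'
#' Stage order: saliency (two-stage manifold ranking) -> segmentation
#' (dual-threshold + connectivity + morphology) -> presentation strategy
#' (FEBR / FZE / none) -> LRG phosphene rendering at each configured
#' resolution. When `out_dir` is given, every stage raster is written as
#' 8-bit PNG and a JSON manifest records parameters and MD5 checksums.
#'
#' @param image Image path (PNG/JPEG/PGM) or an in-memory raster in
#'   `[0, 255]`.
#' @param config A `"pipeline_config"`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param name Basename used for output files.
#' @param quiet Suppress stage progress messages.
#' @return List with `saliency` (pixel map), `mask`, `strategy_output`,
#'   `percepts` (one `"phosphene_percept"` per resolution), `thresholds`,
#'   and `manifest` (data frame of written artifacts, when `out_dir` is
#'   set).
#' @export
run_pipeline <- function(image, config = pipeline_config(), out_dir = NULL,
                         name = "scene", quiet = FALSE) {
  if (is.character(image)) {
    name <- sub("\\.[^.]+$", "", basename(image))
    image <- read_image(image)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  gray <- to_gray(image)

  say("[saliency] manifold ranking (alpha=%.3g, n_target=%d)",
      config$alpha, as.integer(config$n_target))
  sal <- saliency_map(image, n_target = config$n_target,
                      compactness = config$compactness,
                      sigma_c = config$sigma_c, alpha = config$alpha,
                      seed = config$seed)
  say("[segment] dual-threshold + connectivity (conn=%d)", config$connectivity)
  seg <- segment_saliency(sal$map, connectivity = config$connectivity,
                          min_area_frac = config$min_area_frac,
                          struct_size = config$struct_size,
                          largest_only = config$largest_only)
  say("[strategy] %s", config$strategy)
  strat <- switch(config$strategy,
    febr = febr(gray, seg$mask, scales = config$scales,
                threshold = config$edge_threshold),
    fze = fze(gray, seg$mask, pad_frac = config$pad_frac,
              scales = config$scales, threshold = config$edge_threshold),
    none = gray)
  say("[lrg] rendering %d resolutions", length(config$resolutions))
  percepts <- lrg_batch(strat, resolutions = config$resolutions,
                        sigma_ratio = config$sigma_ratio)

  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    art <- list()
    wr <- function(raster, tag) {
      p <- file.path(out_dir, sprintf("%s_%s.png", name, tag))
      write_image_png(raster, p)
      art[[length(art) + 1L]] <<- data.frame(
        tag = tag, path = p, md5 = unname(tools::md5sum(p)))
    }
    wr(sal$map * 255, "saliency")
    wr(seg$mask * 255, "mask")
    wr(strat, paste0("strategy-", config$strategy))
    for (N in names(percepts))
      wr(percepts[[N]]$raster, sprintf("percept-%s", N))
    manifest <- do.call(rbind, art)
    meta <- list(name = name, config = unclass(config),
                 thresholds = unclass(seg$thresholds),
                 artifacts = manifest)
    jsonlite::write_json(meta, file.path(out_dir, paste0(name, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  list(saliency = sal$map, mask = seg$mask, strategy_output = strat,
       percepts = percepts, thresholds = seg$thresholds, manifest = manifest)
}
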