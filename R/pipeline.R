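#' Pipeline configuration
#'
#' Bundles one input (a TIFF path or a phantom spec), the stage parameters
#' and an output directory into a single validated object. A configuration
#' plus a seed fully determines every output.
#'
#' @param input path to a single-channel TIFF, or a [phantom_spec()].
#' @param pixel_size nm/px (used for physical-unit outputs).
#' @param enhance an [enhance_params()].
#' @param segment a [segment_params()].
#' @param pairing a [pairing_params()].
#' @param max_width_level `max_level` for [estimate_width()] (`0` disables
#'   width measurement).
#' @param orientation_window window for [orientation_field()] (`0`
#'   disables).
#' @param output_dir directory for exports, or `NULL` for in-memory only.
#' @param seed integer seed (phantom noise).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(input, pixel_size = 108,
                            enhance = enhance_params(),
                            segment = segment_params(),
                            pairing = pairing_params(),
                            max_width_level = 8L,
                            orientation_window = 15L,
                            output_dir = NULL, seed = 1L) {
  stopifnot(pixel_size > 0)
  if (!inherits(input, "phantom_spec") && !is.character(input)) {
    stop("`input` must be a TIFF path or a phantom_spec", call. = FALSE)
  }
  structure(
    list(input = input, pixel_size = pixel_size, enhance = enhance,
         segment = segment, pairing = pairing,
         max_width_level = as.integer(max_width_level),
         orientation_window = as.integer(orientation_window),
         output_dir = output_dir, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the extraction pipeline from a configuration
#'
#' Executes enhancement, binarization, skeleton fragmentation,
#' reconstruction and the enabled measurements; when `output_dir` is set,
#' writes the maps (float TIFF), fragment and trace coordinates (CSV), a
#' per-fiber summary (JSON) and a manifest recording all parameters.
#'
#' @param config a [pipeline_config()].
#' @return list with `image`, `scene` (when the input was a phantom),
#'   `maps`, `mask`, `fragments`, `traces`, `widths` (tibble of per-fiber
#'   widths), `orientations`, and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  scene <- NULL
  if (inherits(config$input, "phantom_spec")) {
    spec <- config$input
    spec$seed <- config$seed
    scene <- make_phantom(spec)
    image <- scene$noisy_image
  } else {
    image <- read_micrograph(config$input)
    if (is.list(image)) {
      return(lapply(seq_along(image), function(k) {
        cfg <- config
        cfg$input <- config$input  # each page processed independently
        run_pipeline_matrix(image[[k]], cfg, scene = NULL, page = k)
      }))
    }
  }
  run_pipeline_matrix(image, config, scene)
}

run_pipeline_matrix <- function(image, config, scene = NULL, page = NULL) {
  res <- extract_fibers(image, config$enhance, config$segment, config$pairing)
  widths <- NULL
  if (config$max_width_level >= 2 && nrow(res$traces) > 0) {
    widths <- purrr::map_dfr(seq_len(nrow(res$traces)), function(i) {
      wp <- suppressWarnings(
        estimate_width(image, res$traces$pixels[[i]],
                       config$max_width_level, config$pixel_size)
      )
      dplyr::mutate(glance(wp), fiber_id = res$traces$fiber_id[i],
                    .before = 1)
    })
  }
  orientations <- NULL
  if (config$orientation_window >= 3) {
    orientations <- orientation_field(attr(res$fragments, "skeleton"),
                                      config$orientation_window)
  }
  manifest <- list(
    package = "fibertrace",
    version = as.character(utils::packageVersion("fibertrace")),
    input = if (inherits(config$input, "phantom_spec")) "phantom"
            else config$input,
    page = page,
    pixel_size_nm = config$pixel_size,
    seed = config$seed,
    enhance = unclass(config$enhance),
    segment = unclass(config$segment),
    pairing = unclass(config$pairing),
    n_fragments = nrow(res$fragments),
    n_traces = nrow(res$traces)
  )
  out <- list(image = image, scene = scene, maps = res$maps,
              mask = res$mask, fragments = res$fragments,
              traces = res$traces, widths = widths,
              orientations = orientations, manifest = manifest)
  if (!is.null(config$output_dir)) write_pipeline_outputs(out, config)
  out
}

write_pipeline_outputs <- function(out, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(config$output_dir, ...)
  rng <- write_map_tiff(out$maps$oft, p("oft_map.tif"))
  write_map_tiff(out$maps$intensity, p("intensity_map.tif"))
  write_map_tiff(out$maps$orientation, p("orientation_map.tif"))
  write_coords_csv(out$fragments, p("fragments.csv"))
  write_coords_csv(out$traces, p("traces.csv"))
  if (!is.null(out$widths)) {
    write.csv(out$widths, p("widths.csv"), row.names = FALSE)
  }
  if (!is.null(out$orientations)) {
    write.csv(out$orientations, p("orientations.csv"), row.names = FALSE)
  }
  fiber_summary <- if (nrow(out$traces) > 0) {
    lapply(seq_len(nrow(out$traces)), function(i) {
      list(fiber_id = out$traces$fiber_id[i],
           n_fragments = out$traces$n_fragments[i],
           length_px = out$traces$length_px[i],
           length_um = out$traces$length_px[i] * config$pixel_size / 1000)
    })
  } else {
    list()
  }
  manifest <- c(out$manifest, list(oft_map_range = rng))
  jsonlite::write_json(list(manifest = manifest, fibers = fiber_summary),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(NULL)
}

#' Run the benchmark sensitivity scans
#'
#' Wraps [sensitivity_scan()] over the shipped benchmark scene for the
#' filter radius, search radius and search fan angle, writing one CSV per
#' scanned parameter when `output_dir` is set.
#'
#' @param scans named list of scan requests; each element is a list with
#'   `vary`, `values`, `psnr_values`, and optionally `seeds`.
#' @param seeds default noise seeds.
#' @param output_dir directory for the CSV surfaces, or `NULL`.
#' @param ... passed to [sensitivity_scan()] (baseline parameters).
#' @return named list of `sensitivity_scan` tibbles.
#' @export
run_benchmark <- function(scans = list(
                            filter_radius = list(vary = "filter_radius",
                                                 values = c(5, 8, 11, 14, 17),
                                                 psnr_values = c(15, 20, 25, 30)),
                            search_radius = list(vary = "search_radius",
                                                 values = c(4, 8, 16, 24, 32),
                                                 psnr_values = c(15, 20, 25, 30)),
                            search_angle = list(vary = "search_angle",
                                                values = c(10, 20, 30, 45, 60),
                                                psnr_values = c(15, 20, 25, 30))
                          ),
                          seeds = 1:3, output_dir = NULL, ...) {
  out <- lapply(scans, function(sc) {
    sensitivity_scan(vary = sc$vary, values = sc$values,
                     psnr_values = sc$psnr_values,
                     seeds = if (is.null(sc$seeds)) seeds else sc$seeds, ...)
  })
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write.csv(tidy(out[[nm]]),
                file.path(output_dir, paste0("scan_", nm, ".csv")),
                row.names = FALSE)
    }
  }
  out
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Nested sections `enhance`, `segment`, `pairing` map onto the
#' corresponding parameter constructors; a `phantom` section (fields of
#' [phantom_spec()], filaments included) replaces a TIFF `input` path.
#'
#' @param path YAML (or JSON) configuration file.
#' @param overrides named list applied on top of the file values
#'   (CLI flags).
#' @return a [pipeline_config()].
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path) else
    yaml::read_yaml(path)
  cfg <- utils::modifyList(cfg, overrides)
  input <- if (!is.null(cfg$phantom)) {
    ph <- cfg$phantom
    ph$filaments <- lapply(ph$filaments, function(f) {
      f[c("from", "to", "center")] <- lapply(f[c("from", "to", "center")],
                                             function(v) unlist(v))
      if (!is.null(f$points)) {
        f$points <- do.call(rbind, lapply(f$points, unlist))
      }
      f[!vapply(f, is.null, logical(1))]
    })
    do.call(phantom_spec, ph)
  } else {
    cfg$input
  }
  pipeline_config(
    input = input,
    pixel_size = cfg$pixel_size %||% 108,
    enhance = do.call(enhance_params, cfg$enhance %||% list()),
    segment = do.call(segment_params, cfg$segment %||% list()),
    pairing = do.call(pairing_params, cfg$pairing %||% list()),
    max_width_level = cfg$max_width_level %||% 8L,
    orientation_window = cfg$orientation_window %||% 15L,
    output_dir = cfg$output_dir,
    seed = cfg$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
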