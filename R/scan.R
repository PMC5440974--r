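#' Run the full extraction pipeline on one image
#'
#' Convenience composition `enhance()` -> `binarize()` ->
#' `skeletonize_and_fragment()` -> `reconstruct()`.
#'
#' @param image numeric intensity matrix.
#' @param epar an [enhance_params()].
#' @param spar a [segment_params()].
#' @param ppar a [pairing_params()].
#' @return list with `maps`, `mask`, `fragments`, `traces`.
#' @export
extract_fibers <- function(image, epar = enhance_params(),
                           spar = segment_params(),
                           ppar = pairing_params()) {
  maps <- enhance(image, epar)
  mask <- binarize(maps$oft, spar)
  fragments <- skeletonize_and_fragment(mask, spar)
  traces <- reconstruct(fragments, ppar)
  list(maps = maps, mask = mask, fragments = fragments, traces = traces)
}

#' Parameter-versus-noise sensitivity scan on a phantom scene
#'
#' For every combination of the varied parameter value, PSNR and seed, a
#' noisy phantom is generated, the full pipeline is run and the detected
#' traces are scored against the ground truth. When the varied parameter
#' only affects reconstruction (`search_radius`, `search_angle`, `d_max`),
#' the enhancement and segmentation stages are computed once per
#' (PSNR, seed) and reused across values.
#'
#' @param spec_fn function `(psnr, seed) -> phantom_spec`; defaults to the
#'   shipped benchmark scene.
#' @param vary one of `"filter_radius"`, `"search_radius"`,
#'   `"search_angle"`, `"d_max"`, `"none"`.
#' @param values numeric vector of values for the varied parameter
#'   (ignored for `"none"`).
#' @param psnr_values numeric vector of PSNRs in dB.
#' @param seeds integer vector of noise seeds.
#' @param epar,spar,ppar baseline stage parameters.
#' @param tol matching tolerance passed to [match_and_score()].
#' @return an object of class `sensitivity_scan`: tibble with one row per
#'   (value, psnr, seed) holding `D`, `G`, `M`, `false_positive_ratio`,
#'   `false_negative_ratio`. A failed pipeline cell is recorded with both
#'   ratios 1.
#' @export
sensitivity_scan <- function(spec_fn = benchmark_scene_spec,
                             vary = c("filter_radius", "search_radius",
                                      "search_angle", "d_max", "none"),
                             values = NULL,
                             psnr_values = 25,
                             seeds = 1:3,
                             epar = enhance_params(),
                             spar = segment_params(),
                             ppar = pairing_params(),
                             tol = 3) {
  vary <- match.arg(vary)
  if (vary == "none") values <- NA_real_
  stopifnot(length(values) > 0, length(psnr_values) > 0, length(seeds) > 0)
  recon_only <- vary %in% c("search_radius", "search_angle", "d_max")
  rows <- list()
  for (psnr in psnr_values) {
    for (seed in seeds) {
      scene <- make_phantom(spec_fn(psnr = psnr, seed = seed))
      shape <- dim(scene$noisy_image)
      cache <- NULL
      if (recon_only) {
        cache <- tryCatch({
          maps <- enhance(scene$noisy_image, epar)
          skeletonize_and_fragment(binarize(maps$oft, spar), spar)
        }, error = function(e) NULL)
      }
      for (v in values) {
        rep <- tryCatch({
          if (recon_only) {
            if (is.null(cache)) stop("segmentation failed")
            pp <- ppar
            pp[[vary]] <- v
            traces <- reconstruct(cache, pp)
          } else {
            ep <- epar
            if (vary == "filter_radius") ep$radius_r <- as.integer(v)
            res <- extract_fibers(scene$noisy_image, ep, spar, ppar)
            traces <- res$traces
          }
          match_and_score(traces, scene$truth_paths, tol = tol, shape = shape)
        }, error = function(e) {
          tibble(D = NA_integer_, G = length(scene$truth_paths),
                 M = NA_integer_, false_positive_ratio = 1,
                 false_negative_ratio = 1)
        })
        rows[[length(rows) + 1]] <- dplyr::mutate(
          tibble::as_tibble(rep), value = v, psnr = psnr, seed = seed,
          .before = 1
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("sensitivity_scan", class(out)), vary = vary)
}

#' Mean error surface of a sensitivity scan
#'
#' @param x a `sensitivity_scan`.
#' @param ... unused.
#' @return tibble averaged over seeds with `value`, `psnr`, `mean_fp`,
#'   `mean_fn`, `mean_total` columns.
#' @export
tidy.sensitivity_scan <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$value, .data$psnr),
    mean_fp = mean(.data$false_positive_ratio),
    mean_fn = mean(.data$false_negative_ratio),
    mean_total = mean(.data$false_positive_ratio +
                        .data$false_negative_ratio),
    .groups = "drop"
  )
}

#' Locate the optimum and plateau of a scan
#'
#' @param x a `sensitivity_scan` over a single PSNR.
#' @param plateau_tol a value is "on the plateau" when its mean combined
#'   error is within this tolerance of the error at the largest scanned
#'   value.
#' @param ... unused.
#' @return one-row tibble with `best_value` (argmin of mean FP+FN; ties
#'   resolved to the median tied value), `best_error`, `plateau_start`
#'   (smallest value on the plateau) and `asymptote` (mean error at the
#'   largest value).
#' @export
glance.sensitivity_scan <- function(x, plateau_tol = 0.02, ...) {
  s <- tidy(x)
  s <- dplyr::arrange(s, .data$value)
  err <- s$mean_total
  best <- which(err == min(err))
  best_value <- stats::median(s$value[best])
  asym <- err[length(err)]
  on_plateau <- err <= asym + plateau_tol
  plateau_start <- s$value[which(on_plateau)[1]]
  # require the plateau to be contiguous up to the largest value
  for (k in rev(seq_along(err))) {
    if (!on_plateau[k]) {
      plateau_start <- if (k < length(err)) s$value[k + 1] else NA_real_
      break
    }
    if (k == 1) plateau_start <- s$value[1]
  }
  tibble(best_value = best_value, best_error = min(err),
         plateau_start = plateau_start, asymptote = asym)
}
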