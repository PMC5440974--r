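#' Specify a synthetic filament phantom
#'
#' A phantom emulates a fluorescence micrograph of stress fibers: a set of
#' parametric filament centerlines is rasterized, convolved with a Gaussian
#' point-spread function, scaled to a peak intensity, and (optionally)
#' corrupted with additive Gaussian noise at a requested peak
#' signal-to-noise ratio (PSNR).
#'
#' Filament paths are lists with a `type` element:
#' * `segment`: fields `from`, `to`, each `(row, col)`;
#' * `polyline`: field `points`, an n x 2 matrix of `(row, col)`;
#' * `arc`: fields `center` `(row, col)`, `radius` (px), `from_deg`,
#'   `to_deg` — position angles in degrees following the package direction
#'   convention (see [angles]), traversed from `from_deg` to `to_deg`.
#'
#' @param image_shape integer `(rows, cols)` in pixels.
#' @param filaments list of filament paths (see Details).
#' @param pixel_size physical pixel size in nm/px.
#' @param psf_sigma point-spread-function standard deviation in nm.
#' @param peak_intensity peak intensity of the clean image (arbitrary units).
#' @param psnr requested PSNR in dB, or `Inf` for a clean image.
#' @param seed integer seed that fully determines the noise realization.
#' @return an object of class `phantom_spec`.
#' @seealso [make_phantom()], [benchmark_scene_spec()]
#' @export
phantom_spec <- function(image_shape = c(256L, 256L),
                         filaments = list(),
                         pixel_size = 108,
                         psf_sigma = 72,
                         peak_intensity = 100,
                         psnr = Inf,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  if (psf_sigma <= 0) stop("`psf_sigma` must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (!is.infinite(psnr) && psnr <= 0) stop("`psnr` must be > 0 dB", call. = FALSE)
  structure(
    list(
      image_shape = as.integer(image_shape), filaments = filaments,
      pixel_size = pixel_size, psf_sigma = psf_sigma,
      peak_intensity = peak_intensity, psnr = psnr, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

# Sample a parametric path at `step`-px arc-length resolution.
# Returns an n x 2 matrix of subpixel (row, col).
sample_path <- function(path, step = 0.25) {
  resample_polyline <- function(pts) {
    out <- list()
    for (k in seq_len(nrow(pts) - 1)) {
      a <- pts[k, ]
      b <- pts[k + 1, ]
      len <- sqrt(sum((b - a)^2))
      n <- max(2L, ceiling(len / step) + 1L)
      s <- seq(0, 1, length.out = n)
      seg <- cbind(a[1] + s * (b[1] - a[1]), a[2] + s * (b[2] - a[2]))
      out[[k]] <- if (k > 1) seg[-1, , drop = FALSE] else seg
    }
    do.call(rbind, out)
  }
  switch(path$type,
    segment = resample_polyline(rbind(path$from, path$to)),
    polyline = resample_polyline(as.matrix(path$points)),
    arc = {
      r <- path$radius
      stopifnot(r > 0)
      span <- deg2rad(abs(path$to_deg - path$from_deg))
      n <- max(2L, ceiling(r * span / step) + 1L)
      a <- deg2rad(seq(path$from_deg, path$to_deg, length.out = n))
      cbind(path$center[1] - r * sin(a), path$center[2] + r * cos(a))
    },
    stop("unknown path type: ", path$type, call. = FALSE)
  )
}

# Nearest-pixel rasterization of subpixel points; duplicates removed,
# order of first appearance kept.
rasterize_points <- function(points) {
  px <- cbind(round(points[, 1]), round(points[, 2]))
  px[!duplicated(px), , drop = FALSE]
}

#' Render a phantom scene
#'
#' Rasterizes every filament path (0.25-px arc-length sampling, nearest-pixel
#' marking), convolves the unit-intensity skeleton with the Gaussian PSF,
#' scales the result to the requested peak intensity and, when `psnr` is
#' finite, adds Gaussian noise via [corrupt()].
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `phantom_scene`: the `spec`, `truth_paths`
#'   (list of subpixel centerlines), `truth_skeleton` (0/1 matrix),
#'   `clean_image`, `noisy_image` (equal to `clean_image` when no noise was
#'   requested) and `achieved_psnr`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$image_shape[1]
  nc <- spec$image_shape[2]
  sigma_px <- spec$psf_sigma / spec$pixel_size
  margin <- ceiling(3 * sigma_px)
  skel <- matrix(0, nr, nc)
  paths <- lapply(spec$filaments, sample_path)
  for (p in paths) {
    if (any(p[, 1] < 1 + margin | p[, 1] > nr - margin |
            p[, 2] < 1 + margin | p[, 2] > nc - margin)) {
      stop("filament path leaves the image bounds (PSF margin ", margin,
           " px)", call. = FALSE)
    }
    px <- rasterize_points(p)
    skel[px] <- 1
  }
  clean <- if (any(skel > 0)) {
    b <- gaussian_blur(skel, sigma_px)
    b * (spec$peak_intensity / max(b))
  } else {
    skel
  }
  if (is.finite(spec$psnr) && any(skel > 0)) {
    cr <- corrupt(clean, spec$psnr, spec$seed)
    noisy <- cr$noisy
    achieved <- cr$achieved_psnr
  } else {
    noisy <- clean
    achieved <- Inf
  }
  structure(
    list(
      spec = spec, truth_paths = paths, truth_skeleton = skel,
      clean_image = clean, noisy_image = noisy, achieved_psnr = achieved
    ),
    class = "phantom_scene"
  )
}

#' Add Gaussian noise at a requested PSNR
#'
#' PSNR is defined as `20 * log10(peak(clean) / sigma_noise)` in dB, so the
#' noise standard deviation is `peak(clean) / 10^(psnr/20)`. Noise is not
#' clipped: negative intensities are allowed and downstream stages tolerate
#' them.
#'
#' @param clean numeric matrix with a positive peak.
#' @param psnr requested PSNR in dB (> 0).
#' @param seed integer; the same seed reproduces the noise bit for bit.
#' @return list with `noisy` (matrix) and `achieved_psnr` (dB).
#' @export
corrupt <- function(clean, psnr, seed) {
  stopifnot(is.matrix(clean))
  if (psnr <= 0) stop("`psnr` must be > 0 dB", call. = FALSE)
  peak <- max(clean)
  if (peak <= 0) stop("`clean` must have a positive peak", call. = FALSE)
  sigma <- peak / 10^(psnr / 20)
  noise <- withr::with_seed(as.integer(seed),
                            matrix(rnorm(length(clean), sd = sigma),
                                   nrow(clean), ncol(clean)))
  list(noisy = clean + noise, achieved_psnr = compute_psnr(clean, clean + noise))
}

#' Peak signal-to-noise ratio between a clean and a degraded image
#'
#' @param clean,noisy numeric matrices of identical shape.
#' @return PSNR in dB: `20 * log10(peak(clean) / sd(noisy - clean))`.
#'   Identical images return `Inf` (a "clean" image).
#' @export
compute_psnr <- function(clean, noisy) {
  stopifnot(is.matrix(clean), identical(dim(clean), dim(noisy)))
  s <- sd(noisy - clean)
  if (s == 0) return(Inf)
  20 * log10(max(clean) / s)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat("<phantom_scene> ", nrow(x$clean_image), "x", ncol(x$clean_image),
      " px, ", length(x$truth_paths), " filaments, PSNR ",
      if (is.finite(x$achieved_psnr)) sprintf("%.2f dB", x$achieved_psnr)
      else "clean", "\n", sep = "")
  invisible(x)
}

#' Ground-truth paths of a phantom as a tibble
#'
#' @param x a `phantom_scene`.
#' @param ... unused.
#' @return tibble with columns `filament_id`, `point_index`, `row`, `col`.
#' @export
tidy.phantom_scene <- function(x, ...) {
  purrr::imap_dfr(x$truth_paths, function(p, i) {
    tibble(filament_id = i, point_index = seq_len(nrow(p)),
           row = p[, 1], col = p[, 2])
  })
}

#' One-row summary of a phantom scene
#' @param x a `phantom_scene`.
#' @param ... unused.
#' @export
glance.phantom_scene <- function(x, ...) {
  tibble(
    n_filaments = length(x$truth_paths),
    n_skeleton_px = sum(x$truth_skeleton),
    peak_intensity = x$spec$peak_intensity,
    requested_psnr = x$spec$psnr,
    achieved_psnr = x$achieved_psnr
  )
}
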