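#' The shipped benchmark scene
#'
#' A fixed synthetic scene used throughout the package's benchmarks: four
#' concentric circular arcs (curved fibers) crossed by five straight radial
#' chords (straight fibers), nine filaments in all, in a 512 x 512 px frame
#' (55 x 55 um at 108 nm/px) with a 72 nm PSF. Arcs are spaced 80 px apart
#' radially and chords 15 degrees apart, so distinct fibers stay well
#' beyond the default pairing gap while every chord crosses every arc —
#' the junction removal at those crossings is what the reconstruction
#' stage has to undo. The geometry is a fixed package constant so
#' benchmark results are reproducible.
#'
#' @param psnr requested PSNR in dB (`Inf` for the clean scene).
#' @param seed integer noise seed.
#' @param peak_intensity peak intensity of the clean image.
#' @return a [phantom_spec()] with nine filaments.
#' @export
benchmark_scene_spec <- function(psnr = Inf, seed = 1L, peak_intensity = 100) {
  center <- c(500, 20)
  arcs <- list(
    list(type = "arc", center = center, radius = 220, from_deg = 8, to_deg = 82),
    list(type = "arc", center = center, radius = 300, from_deg = 6, to_deg = 84),
    list(type = "arc", center = center, radius = 380, from_deg = 5, to_deg = 85),
    list(type = "arc", center = center, radius = 460, from_deg = 6, to_deg = 78)
  )
  chord <- function(ang_deg) {
    a <- deg2rad(ang_deg)
    list(type = "segment",
         from = c(center[1] - 170 * sin(a), center[2] + 170 * cos(a)),
         to = c(center[1] - 480 * sin(a), center[2] + 480 * cos(a)))
  }
  chords <- lapply(c(15, 30, 45, 60, 75), chord)
  phantom_spec(
    image_shape = c(512L, 512L),
    filaments = c(arcs, chords),
    pixel_size = 108, psf_sigma = 72,
    peak_intensity = peak_intensity, psnr = psnr, seed = seed
  )
}

#' The shipped width-benchmark scene
#'
#' A single long, gently curved fiber (a ~490 px circular arc spanning a
#' 256 x 512 px frame) rendered with a Gaussian cross-section of the given
#' standard deviation — the geometry used to characterize the
#' distance-map-gradient width estimator. The fiber's length matters: each
#' distance level then averages the image gradient over several hundred
#' pixels, which is what makes the estimator resistant to noise.
#'
#' @param sigma_px cross-section standard deviation in px (the PSF sigma is
#'   `sigma_px * 108` nm at the default 108 nm/px).
#' @param psnr requested PSNR in dB (`Inf` for clean).
#' @param seed integer noise seed.
#' @return a [phantom_spec()] with one filament.
#' @export
width_benchmark_spec <- function(sigma_px = 3, psnr = Inf, seed = 1L) {
  phantom_spec(
    image_shape = c(256L, 512L),
    filaments = list(list(type = "arc", center = c(600, 256), radius = 520,
                          from_deg = 63, to_deg = 117)),
    pixel_size = 108, psf_sigma = sigma_px * 108,
    peak_intensity = 100, psnr = psnr, seed = seed
  )
}
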