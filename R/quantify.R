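#' Estimate the width of a stress fiber from distance-map gradients
#'
#' Builds the Euclidean distance map around the trace centerline; each
#' integer distance level (nearest-integer binning of the distance) forms a
#' closed loop enveloping the fiber. The mean gradient magnitude of the raw
#' image (central differences) is computed along each level; the level with
#' the highest mean gradient marks the fiber edge, and the width is twice
#' that level.
#'
#' @param image raw intensity matrix.
#' @param trace a one-row `fiber_traces` slice, or an n x 2 `(row, col)`
#'   pixel matrix of the centerline.
#' @param max_level largest distance level considered (px, >= 2).
#' @param pixel_size nm/px for the micrometre conversion.
#' @return an object of class `width_profile`: tibble with one row per
#'   level (`level`, `mean_gradient`, `n_px`) plus attributes
#'   `argmax_level`, `width_px`, `width_um`, `flag` ("ok" or "no edge").
#' @export
estimate_width <- function(image, trace, max_level = 8L, pixel_size = 108) {
  stopifnot(is.matrix(image), max_level >= 2)
  px <- if (is.matrix(trace)) trace else trace$pixels[[1]]
  stopifnot(nrow(px) > 0)
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[cbind(round(px[, 1]), round(px[, 2]))] <- 1L
  dist <- distance_to_set(mask)
  grad <- gradient_magnitude(image)
  lev <- round(dist)
  border <- matrix(FALSE, nrow(image), ncol(image))
  border[c(1, nrow(image)), ] <- TRUE
  border[, c(1, ncol(image))] <- TRUE
  if (any(border & lev >= 1 & lev <= max_level)) {
    warning("trace approaches the image border; border pixels excluded")
  }
  keep <- !border
  prof <- purrr::map_dfr(seq_len(max_level), function(l) {
    sel <- lev == l & keep
    tibble(level = l, mean_gradient = if (any(sel)) mean(grad[sel]) else 0,
           n_px = sum(sel))
  })
  flag <- "ok"
  if (all(prof$mean_gradient == prof$mean_gradient[1])) flag <- "no edge"
  argmax <- prof$level[which.max(prof$mean_gradient)]
  structure(prof, class = c("width_profile", class(prof)),
            argmax_level = argmax, width_px = 2 * argmax,
            width_um = 2 * argmax * pixel_size / 1000, flag = flag)
}

#' @export
print.width_profile <- function(x, ...) {
  cat("<width_profile> width ", attr(x, "width_px"), " px (",
      sprintf("%.3f", attr(x, "width_um")), " um), edge at level ",
      attr(x, "argmax_level"), if (attr(x, "flag") != "ok")
        paste0(" [", attr(x, "flag"), "]") else "", "\n", sep = "")
  NextMethod()
}

#' One-row summary of a width profile
#' @param x a `width_profile`.
#' @param ... unused.
#' @export
glance.width_profile <- function(x, ...) {
  tibble(argmax_level = attr(x, "argmax_level"),
         width_px = attr(x, "width_px"), width_um = attr(x, "width_um"),
         flag = attr(x, "flag"))
}

# Euclidean distance from every pixel to the nearest set pixel (mask == 1).
distance_to_set <- function(mask) {
  d <- EBImage::distmap(1L - mask, metric = "euclidean")
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Central-difference gradient magnitude with one-sided differences at the
# border.
gradient_magnitude <- function(image) {
  nr <- nrow(image)
  nc <- ncol(image)
  gr <- (image[c(2:nr, nr), ] - image[c(1, 1:(nr - 1)), ]) /
    matrix(c(1, rep(2, nr - 2), 1), nr, nc)
  gc <- (image[, c(2:nc, nc)] - image[, c(1, 1:(nc - 1))]) /
    matrix(c(1, rep(2, nc - 2), 1), nr, nc, byrow = TRUE)
  sqrt(gr^2 + gc^2)
}

#' Per-pixel orientation field of a skeleton
#'
#' For every skeleton pixel, the orientation of the best-fit line through
#' the skeleton pixels inside an odd square window centered on it
#' (principal axis of the coordinate scatter), reported in degrees in
#' (-90, 90].
#'
#' @param skeleton 0/1 matrix.
#' @param window odd window side length in px (>= 3).
#' @return tibble with `row`, `col`, `orientation` (degrees; `NA` for a
#'   pixel whose window holds fewer than two skeleton pixels).
#' @export
orientation_field <- function(skeleton, window = 15L) {
  stopifnot(window >= 3, window %% 2 == 1)
  h <- (window - 1L) / 2L
  px <- which(skeleton == 1, arr.ind = TRUE)
  nr <- nrow(skeleton)
  nc <- ncol(skeleton)
  ori <- vapply(seq_len(nrow(px)), function(k) {
    i <- px[k, 1]
    j <- px[k, 2]
    ri <- max(1, i - h):min(nr, i + h)
    cj <- max(1, j - h):min(nc, j + h)
    sub <- which(skeleton[ri, cj, drop = FALSE] == 1, arr.ind = TRUE)
    if (nrow(sub) < 2) return(NA_real_)
    x <- sub[, 2]          # col
    y <- -sub[, 1]         # row downward -> flip for CCW convention
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    wrap_orientation(0.5 * atan2(2 * sxy, sxx - syy) * 180 / pi)
  }, double(1))
  tibble(row = px[, 1], col = px[, 2], orientation = ori)
}

#' Actin density as a function of distance from the cell edge
#'
#' Computes the inward Euclidean distance from the cell boundary and bins
#' it; per bin, density is the coverage ratio of actin pixels over cell
#' pixels. Bins partition the whole cell mask.
#'
#' @param actin_mask 0/1 matrix of actin-positive pixels (subset of
#'   `cell_mask`).
#' @param cell_mask 0/1 matrix of the cell area.
#' @param bin_width bin width in micrometres.
#' @param pixel_size nm/px.
#' @return tibble with `bin_lo`, `bin_hi` (um from the cell edge),
#'   `n_cell_px`, `n_actin_px`, `density`.
#' @export
density_profile <- function(actin_mask, cell_mask, bin_width = 1,
                            pixel_size = 108) {
  stopifnot(identical(dim(actin_mask), dim(cell_mask)))
  if (!any(cell_mask == 1)) stop("empty cell mask", call. = FALSE)
  if (any(actin_mask == 1 & cell_mask == 0)) {
    stop("`actin_mask` must lie inside `cell_mask`", call. = FALSE)
  }
  d <- EBImage::distmap(cell_mask, metric = "euclidean")
  d <- matrix(as.numeric(d), nrow(cell_mask), ncol(cell_mask))
  d_um <- d * pixel_size / 1000
  inside <- cell_mask == 1
  n_bins <- max(1L, ceiling(max(d_um[inside]) / bin_width))
  purrr::map_dfr(seq_len(n_bins), function(b) {
    lo <- (b - 1) * bin_width
    hi <- b * bin_width
    sel <- inside & d_um > lo & d_um <= hi
    if (b == 1) sel <- sel | (inside & d_um <= lo)  # boundary pixels (d = 0)
    tibble(bin_lo = lo, bin_hi = hi, n_cell_px = sum(sel),
           n_actin_px = sum(actin_mask == 1 & sel),
           density = if (any(sel)) sum(actin_mask == 1 & sel) / sum(sel) else NA_real_)
  })
}

#' Score detected traces against ground truth
#'
#' A detected trace matches a truth path when at least 75% of its pixels
#' lie within `tol` of the path *and* at least 50% of the path lies within
#' `tol` of the trace. Matching is one-to-one, assigned greedily by best
#' overlap. The false positive ratio is `1 - M/D` and the false negative
#' ratio `1 - M/G`, with D detected traces, G ground-truth filaments and M
#' matches.
#'
#' @param detected a `fiber_traces` object or list of `(row, col)` pixel
#'   matrices.
#' @param truth_paths list of `(row, col)` matrices (subpixel allowed),
#'   e.g. `phantom_scene$truth_paths`.
#' @param tol matching tolerance in px.
#' @param shape image dimensions `(rows, cols)`; inferred from the pixel
#'   extents when missing.
#' @param min_trace_cover,min_path_cover the two coverage fractions.
#' @return one-row tibble of class `accuracy_report` with `D`, `G`, `M`,
#'   `false_positive_ratio`, `false_negative_ratio`.
#' @export
match_and_score <- function(detected, truth_paths, tol = 3, shape = NULL,
                            min_trace_cover = 0.75, min_path_cover = 0.5) {
  stopifnot(tol > 0)
  det <- if (inherits(detected, "fiber_traces")) detected$pixels else detected
  D <- length(det)
  G <- length(truth_paths)
  if (is.null(shape)) {
    all_px <- do.call(rbind, c(det, truth_paths))
    shape <- c(max(all_px[, 1]) + tol + 2, max(all_px[, 2]) + tol + 2)
  }
  as_mask <- function(px) {
    m <- matrix(0L, shape[1], shape[2])
    m[cbind(pmin(pmax(round(px[, 1]), 1), shape[1]),
            pmin(pmax(round(px[, 2]), 1), shape[2]))] <- 1L
    m
  }
  if (D > 0 && G > 0) {
    dist_truth <- lapply(truth_paths, function(p) distance_to_set(as_mask(p)))
    dist_det <- lapply(det, function(p) distance_to_set(as_mask(p)))
    overlap <- matrix(0, D, G)
    eligible <- matrix(FALSE, D, G)
    for (i in seq_len(D)) {
      ti <- cbind(pmin(pmax(round(det[[i]][, 1]), 1), shape[1]),
                  pmin(pmax(round(det[[i]][, 2]), 1), shape[2]))
      for (g in seq_len(G)) {
        pg <- cbind(pmin(pmax(round(truth_paths[[g]][, 1]), 1), shape[1]),
                    pmin(pmax(round(truth_paths[[g]][, 2]), 1), shape[2]))
        f_trace <- mean(dist_truth[[g]][ti] <= tol)
        f_path <- mean(dist_det[[i]][pg] <= tol)
        overlap[i, g] <- (f_trace + f_path) / 2
        eligible[i, g] <- f_trace >= min_trace_cover && f_path >= min_path_cover
      }
    }
    M <- 0L
    while (any(eligible)) {
      best <- which(overlap == max(overlap[eligible]) & eligible,
                    arr.ind = TRUE)[1, , drop = FALSE]
      M <- M + 1L
      eligible[best[1], ] <- FALSE
      eligible[, best[2]] <- FALSE
    }
  } else {
    M <- 0L
  }
  out <- tibble(
    D = D, G = G, M = M,
    false_positive_ratio = if (D > 0) 1 - M / D else 0,
    false_negative_ratio = if (G > 0) 1 - M / G else if (D > 0) 1 else 0
  )
  structure(out, class = c("accuracy_report", class(out)))
}
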