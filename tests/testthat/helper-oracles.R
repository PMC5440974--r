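# Independent brute-force oracles, written directly from the definitions
# and kept free of the package's compiled code paths.

# ordered angle grid covering (-90, 90]
oracle_angle_grid <- function(step) {
  k <- floor(180 / step + 1e-9)
  -90 + step * seq_len(k)
}

oracle_bilinear <- function(img, r, c) {
  # snap near-integer coordinates (cos(90 deg) is not exactly 0 in
  # floating point) so boundary samples are classified consistently
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  r <- snap(r)
  c <- snap(c)
  nr <- nrow(img)
  nc <- ncol(img)
  if (r < 1 || c < 1 || r > nr || c > nc) return(NA_real_)
  r0 <- min(floor(r), nr - 1)
  c0 <- min(floor(c), nc - 1)
  r0 <- max(r0, 1)
  c0 <- max(c0, 1)
  fr <- r - r0
  fc <- c - c0
  (1 - fr) * (1 - fc) * img[r0, c0] + (1 - fr) * fc * img[r0, c0 + 1] +
    fr * (1 - fc) * img[r0 + 1, c0] + fr * fc * img[r0 + 1, c0 + 1]
}

# direct double-loop LFT at one pixel (1-based coordinates)
oracle_lft_pixel <- function(img, i, j, r, step) {
  best <- -Inf
  best_ang <- NA_real_
  for (a in oracle_angle_grid(step)) {
    sn <- sin(a * pi / 180)
    cs <- cos(a * pi / 180)
    vals <- c()
    for (t in -r:r) {
      v <- oracle_bilinear(img, i - t * sn, j + t * cs)
      if (!is.na(v)) vals <- c(vals, v)
    }
    m <- mean(vals)
    tol <- 1e-9 * (1 + abs(best))
    if (!is.finite(best) || m > best + tol ||
        (m > best - tol && abs(a) < abs(best_ang))) {
      best <- m
      best_ang <- a
    }
  }
  list(intensity = best, orientation = best_ang)
}

# direct double-loop OFT at one pixel
oracle_oft_pixel <- function(rho, theta, i, j, r, step) {
  best_abs <- -1
  best_sum <- NA_real_
  best_ang <- NA_real_
  for (a in oracle_angle_grid(step)) {
    sn <- sin(a * pi / 180)
    cs <- cos(a * pi / 180)
    s <- 0
    for (t in -r:r) {
      rr <- i - t * sn
      cc <- j + t * cs
      rv <- oracle_bilinear(rho, rr, cc)
      if (is.na(rv)) next
      # nearest pixel: the *offset* (not the coordinate) is rounded to the
      # nearest integer; offsets within 1e-9 of a half-integer are snapped
      # and round away from zero, so rotation-partner angles (sin 30 vs
      # cos 60 in floating point) sample the same neighbor
      snap_half <- function(x) {
        y <- round(2 * x) / 2
        ifelse(abs(x - y) < 1e-9, y, x)
      }
      rha <- function(x) trunc(x + sign(x) * 0.5)
      ri <- i + rha(snap_half(-t * sn))
      ci <- j + rha(snap_half(t * cs))
      if (ri < 1 || ci < 1 || ri > nrow(theta) || ci > ncol(theta)) next
      s <- s + rv * cos(2 * (theta[ri, ci] - a) * pi / 180)
    }
    tol <- 1e-9 * (1 + best_abs)
    if (abs(s) > best_abs + tol ||
        (abs(s) > best_abs - tol && abs(a) < abs(best_ang))) {
      best_abs <- abs(s)
      best_sum <- s
      best_ang <- a
    }
  }
  list(oft = best_sum, alpha = best_ang)
}

# exhaustive inter-class-variance maximization over the same 256 bin edges
oracle_otsu <- function(v, levels = 256L) {
  edges <- seq(min(v), max(v), length.out = levels + 1L)
  best <- -Inf
  best_edge <- NA_real_
  for (e in edges[2:levels]) {
    lo <- v[v < e]
    hi <- v[v >= e]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v)
    bc <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bc > best) {
      best <- bc
      best_edge <- e
    }
  }
  best_edge
}

# explicit vector-arithmetic evaluation of the three pairing criteria
oracle_pair <- function(p_i, phi_i, p_j, phi_j, params) {
  unit <- function(phi) c(-sin(phi * pi / 180), cos(phi * pi / 180))
  ang_between <- function(u, v) {
    acos(pmin(pmax(sum(u * v), -1), 1)) * 180 / pi
  }
  d <- sqrt(sum((p_j - p_i)^2))
  sim <- ang_between(unit(phi_i), -unit(phi_j))
  gap_vec <- (p_j - p_i) / d
  cont <- ang_between(unit(phi_i), gap_vec)
  list(
    delta_theta = sim, d_ij = d, delta_theta_gap = cont,
    passes_similarity = sim <= params$phi_max,
    passes_proximity = d <= params$d_max,
    passes_continuity = cont <= params$psi_max
  )
}

# independent rasterization of a circular arc under the package's stated
# rule (0.25-px arc-length steps, nearest-pixel marking, duplicates
# removed), walked incrementally rather than via the path sampler
oracle_arc_pixels <- function(center, radius, from_deg, to_deg) {
  step_rad <- 0.25 / radius
  ang <- seq(from_deg * pi / 180, to_deg * pi / 180, by = step_rad)
  r <- round(center[1] - radius * sin(ang))
  c <- round(center[2] + radius * cos(ang))
  nrow(unique(cbind(r, c)))
}

# random terminus tibble row
random_terminus <- function(fragment_id, rng_rows = 100) {
  tibble::tibble(
    tid = NA_integer_, fragment_id = fragment_id, end = "A",
    row = runif(1, 1, rng_rows), col = runif(1, 1, rng_rows),
    phi = runif(1, -180, 180)
  )
}
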