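#' Segmentation parameters
#'
#' @param multiplier scale applied to the Otsu threshold level (> 0); values
#'   above 1 segment more conservatively.
#' @param min_fragment_length minimum fragment pixel count (>= 2); shorter
#'   skeleton pieces are treated as skeletonization noise and dropped.
#' @return an object of class `segment_params`.
#' @export
segment_params <- function(multiplier = 1, min_fragment_length = 5L) {
  stopifnot(multiplier > 0, min_fragment_length >= 2)
  structure(list(multiplier = multiplier,
                 min_fragment_length = as.integer(min_fragment_length)),
            class = "segment_params")
}

#' Otsu threshold of a numeric map
#'
#' Classic inter-class-variance maximization on a 256-bin histogram spanning
#' the map's min-max range. Works on any finite numeric map, including the
#' signed OFT responses.
#'
#' @param x numeric matrix or vector with finite values.
#' @param levels number of histogram bins.
#' @return the threshold value (a bin edge); `NA` for a constant input.
#' @export
otsu_threshold <- function(x, levels = 256L) {
  v <- as.vector(x)
  stopifnot(all(is.finite(v)))
  lo <- min(v)
  hi <- max(v)
  if (hi == lo) return(NA_real_)
  edges <- seq(lo, hi, length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
              levels)
  n_k <- tabulate(bin, nbins = levels)
  s_k <- vapply(split(v, factor(bin, levels = seq_len(levels))), sum,
                double(1))
  # exact class statistics at every candidate edge (no bin-mid
  # approximation): splitting below edge k+1 keeps bins 1..k in class 0
  w0 <- cumsum(n_k) / length(v)
  mu0 <- cumsum(s_k) / length(v)
  mu_t <- mu0[levels]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  between <- between[-levels]
  # tied maxima (e.g. an empty gap between two modes) are averaged, which
  # centers the threshold in the gap
  k <- which(between == max(between))
  mean(edges[k + 1L])
}

#' Binarize an enhanced map
#'
#' Thresholds at `multiplier` times the Otsu level of the map (256-bin
#' histogram over the min-max range); pixels at or above the threshold are
#' foreground.
#'
#' @param oft_map numeric matrix (typically the OFT map from [enhance()]).
#' @param params a [segment_params()].
#' @return integer 0/1 matrix.
#' @export
binarize <- function(oft_map, params = segment_params()) {
  stopifnot(is.matrix(oft_map), all(is.finite(oft_map)))
  thr <- otsu_threshold(oft_map)
  if (is.na(thr)) {
    warning("constant map: returning an empty mask")
    return(matrix(0L, nrow(oft_map), ncol(oft_map)))
  }
  (oft_map >= params$multiplier * thr) * 1L
}

# 8-neighbor count of each TRUE pixel within a 0/1 matrix.
neighbor_count <- function(m) {
  nr <- nrow(m)
  nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  cnt <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    cnt <- cnt + pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  cnt
}

# Order the pixels of an unbranched 8-connected component into a chain.
# px: n x 2 integer matrix. Returns the ordered matrix (cycles are opened at
# the lexicographically smallest pixel).
order_chain <- function(px) {
  n <- nrow(px)
  if (n == 1) return(px)
  key <- px[, 1] * 1e6 + px[, 2]
  idx <- seq_len(n)
  lookup <- new.env(hash = TRUE, size = n)
  for (i in idx) assign(as.character(key[i]), i, envir = lookup)
  nbrs <- function(i) {
    out <- integer(0)
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      k <- as.character((px[i, 1] + di) * 1e6 + (px[i, 2] + dj))
      j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
      if (!is.null(j)) out <- c(out, j)
    }
    out
  }
  deg <- vapply(idx, function(i) length(nbrs(i)), integer(1))
  ends <- idx[deg == 1]
  start <- if (length(ends) > 0) {
    ends[order(px[ends, 1], px[ends, 2])][1]
  } else {
    idx[order(px[, 1], px[, 2])][1]  # cycle: open at smallest pixel
  }
  visited <- rep(FALSE, n)
  chain <- integer(n)
  cur <- start
  for (s in seq_len(n)) {
    chain[s] <- cur
    visited[cur] <- TRUE
    cand <- nbrs(cur)
    cand <- cand[!visited[cand]]
    if (length(cand) == 0) {
      chain <- chain[seq_len(s)]
      break
    }
    if (length(cand) > 1) {
      # prefer 4-connected continuation, then lexicographic
      d4 <- abs(px[cand, 1] - px[cur, 1]) + abs(px[cand, 2] - px[cur, 2])
      cand <- cand[order(d4, px[cand, 1], px[cand, 2])]
    }
    cur <- cand[1]
  }
  px[chain, , drop = FALSE]
}

# Label 8-connected components of a pixel set. Returns a list of n x 2
# matrices.
split_components <- function(px) {
  if (nrow(px) == 0) return(list())
  n <- nrow(px)
  key <- px[, 1] * 1e6 + px[, 2]
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  label <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (label[i] > 0) next
    comp <- comp + 1L
    queue <- i
    label[i] <- comp
    while (length(queue) > 0) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        k <- as.character((px[cur, 1] + di) * 1e6 + (px[cur, 2] + dj))
        j <- mget(k, envir = lookup, ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && label[j] == 0) {
          label[j] <- comp
          queue <- c(queue, j)
        }
      }
    }
  }
  lapply(seq_len(comp), function(cc) px[label == cc, , drop = FALSE])
}

#' Skeletonize a mask and split it into unbranched filament fragments
#'
#' The mask is thinned to a one-pixel-wide 8-connected skeleton
#' (Zhang-Suen). Junction pixels — skeleton pixels with three or more
#' skeleton neighbors — are deleted together with their skeleton neighbors
#' within one pixel, so branch arms separate cleanly. Remaining connected
#' components are ordered end to end; components shorter than
#' `min_fragment_length` are dropped. For each fragment the center of mass
#' and the two terminus propagation directions (from the center of mass
#' toward each terminus) are computed.
#'
#' @param mask 0/1 matrix.
#' @param params a [segment_params()].
#' @return an object of class `fragment_set`: a tibble with one row per
#'   fragment (`fragment_id`, `n_px`, `com_row`, `com_col`, terminus
#'   positions `row_a`/`col_a`, `row_b`/`col_b`, propagation directions
#'   `dir_a`, `dir_b` in degrees) and a `pixels` list-column of ordered
#'   `(row, col)` matrices. The skeleton is attached as attribute
#'   `skeleton`.
#' @export
skeletonize_and_fragment <- function(mask, params = segment_params()) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "integer"
  skel <- thin_cpp(mask)
  # junction removal: delete junction pixels and their skeleton neighbors
  cnt <- neighbor_count(skel)
  junction <- skel == 1L & cnt >= 3L
  if (any(junction)) {
    grow <- neighbor_count(junction * 1L) > 0L
    skel[junction | (grow & skel == 1L)] <- 0L
  }
  # iterate plain junction deletion until every pixel has degree <= 2
  repeat {
    cnt <- neighbor_count(skel)
    bad <- skel == 1L & cnt >= 3L
    if (!any(bad)) break
    skel[bad] <- 0L
  }
  px <- which(skel == 1L, arr.ind = TRUE)
  colnames(px) <- NULL
  comps <- split_components(px)
  comps <- comps[vapply(comps, nrow, integer(1)) >= params$min_fragment_length]
  chains <- lapply(comps, order_chain)
  # terminus A is the endpoint with the smaller (row, col)
  chains <- lapply(chains, function(ch) {
    a <- ch[1, ]
    b <- ch[nrow(ch), ]
    if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) ch[rev(seq_len(nrow(ch))), ] else ch
  })
  rows <- purrr::imap(chains, function(ch, i) {
    com <- colMeans(ch)
    a <- ch[1, ]
    b <- ch[nrow(ch), ]
    tibble(
      fragment_id = i, n_px = nrow(ch),
      com_row = com[1], com_col = com[2],
      row_a = a[1], col_a = a[2], dir_a = direction_to(com, a),
      row_b = b[1], col_b = b[2], dir_b = direction_to(com, b),
      pixels = list(ch)
    )
  })
  out <- if (length(rows) > 0) dplyr::bind_rows(rows) else {
    tibble(fragment_id = integer(), n_px = integer(), com_row = double(),
           com_col = double(), row_a = integer(), col_a = integer(),
           dir_a = double(), row_b = integer(), col_b = integer(),
           dir_b = double(), pixels = list())
  }
  structure(out, class = c("fragment_set", class(out)), skeleton = skel)
}

# Build a fragment_set directly from ordered pixel chains (used to
# construct controlled inputs for the reconstruction stage).
fragment_set_from_chains <- function(chains) {
  rows <- purrr::imap(chains, function(ch, i) {
    ch <- as.matrix(ch)
    com <- colMeans(ch)
    a <- ch[1, ]
    b <- ch[nrow(ch), ]
    tibble(
      fragment_id = i, n_px = nrow(ch),
      com_row = com[1], com_col = com[2],
      row_a = a[1], col_a = a[2], dir_a = direction_to(com, a),
      row_b = b[1], col_b = b[2], dir_b = direction_to(com, b),
      pixels = list(ch)
    )
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("fragment_set", class(out)),
            skeleton = NULL)
}

#' Fragment pixels as a long tibble
#'
#' @param x a `fragment_set`.
#' @param ... unused.
#' @return tibble with `fragment_id`, `point_index`, `row`, `col`.
#' @export
tidy.fragment_set <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(fragment_id = integer(), point_index = integer(),
                  row = integer(), col = integer()))
  }
  purrr::map2_dfr(x$fragment_id, x$pixels, function(id, px) {
    tibble(fragment_id = id, point_index = seq_len(nrow(px)),
           row = px[, 1], col = px[, 2])
  })
}

#' One-row summary of a fragment set
#' @param x a `fragment_set`.
#' @param ... unused.
#' @export
glance.fragment_set <- function(x, ...) {
  tibble(
    n_fragments = nrow(x),
    total_px = sum(x$n_px),
    skeleton_px = sum(attr(x, "skeleton")),
    median_length_px = if (nrow(x)) stats::median(x$n_px) else NA_real_
  )
}
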