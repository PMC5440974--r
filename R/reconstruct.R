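#' Fragment pairing parameters
#'
#' Bounds for the four geometric pairing criteria and the cost weights used
#' to rank eligible partners.
#'
#' @param phi_max similarity bound in degrees: maximum difference between a
#'   base terminus' propagation direction and the *reverse* of the
#'   candidate's.
#' @param d_max proximity bound in px: maximum allowable gap length
#'   (default 16 px, ~1.7 um at 108 nm/px).
#' @param psi_max continuity bound in degrees: maximum difference between
#'   the base propagation direction and the gap vector direction.
#' @param search_radius fan radius in px for candidate search (defaults to
#'   `d_max`).
#' @param search_angle fan half-sweep in degrees around the propagation
#'   direction.
#' @param c_angle_weight,c_gap_weight cost weights on the normalized
#'   similarity and continuity mismatches (not both zero).
#' @return an object of class `pairing_params`.
#' @export
pairing_params <- function(phi_max = 30, d_max = 16, psi_max = 30,
                           search_radius = d_max, search_angle = 30,
                           c_angle_weight = 0.5, c_gap_weight = 0.5) {
  stopifnot(phi_max > 0, d_max > 0, psi_max > 0, search_radius > 0,
            search_angle > 0, c_angle_weight >= 0, c_gap_weight >= 0,
            c_angle_weight + c_gap_weight > 0)
  structure(list(phi_max = phi_max, d_max = d_max, psi_max = psi_max,
                 search_radius = search_radius, search_angle = search_angle,
                 c_angle_weight = c_angle_weight, c_gap_weight = c_gap_weight),
            class = "pairing_params")
}

#' Termini of a fragment set
#'
#' @param fragments a `fragment_set` from [skeletonize_and_fragment()].
#' @return tibble with one row per terminus: `tid`, `fragment_id`, `end`
#'   ("A"/"B"), `row`, `col`, `phi` (propagation direction, degrees).
#' @export
termini <- function(fragments) {
  if (nrow(fragments) == 0) {
    return(tibble(tid = integer(), fragment_id = integer(),
                  end = character(), row = double(), col = double(),
                  phi = double()))
  }
  dplyr::bind_rows(
    tibble(fragment_id = fragments$fragment_id, end = "A",
           row = fragments$row_a, col = fragments$col_a,
           phi = fragments$dir_a),
    tibble(fragment_id = fragments$fragment_id, end = "B",
           row = fragments$row_b, col = fragments$col_b,
           phi = fragments$dir_b)
  ) |>
    dplyr::arrange(.data$fragment_id, .data$end) |>
    dplyr::mutate(tid = dplyr::row_number(), .before = 1)
}

# Vectorized direction from (r1, c1) to (r2, c2), degrees in (-180, 180].
directions_to <- function(r1, c1, r2, c2) {
  atan2(-(r2 - r1), c2 - c1) * 180 / pi
}

# Vectorized pair evaluation of a single base terminus against candidate
# termini rows. Returns the candidates with evaluation columns appended.
evaluate_pairs_vec <- function(base, cand, params) {
  d_ij <- sqrt((cand$row - base$row)^2 + (cand$col - base$col)^2)
  varphi_ij <- directions_to(base$row, base$col, cand$row, cand$col)
  delta_theta <- fold180(base$phi - reverse_direction(cand$phi))
  delta_theta_gap <- fold180(base$phi - varphi_ij)
  dplyr::mutate(cand,
    d_ij = d_ij, varphi_ij = varphi_ij,
    delta_theta = delta_theta, delta_theta_gap = delta_theta_gap,
    passes_similarity = delta_theta <= params$phi_max,
    passes_proximity = d_ij <= params$d_max,
    passes_continuity = delta_theta_gap <= params$psi_max
  )
}

#' Evaluate the similarity, proximity and continuity criteria for one pair
#'
#' Similarity compares the base propagation direction with the reverse of
#' the candidate's; proximity bounds the tip-to-tip gap; continuity bounds
#' the angle between the base propagation direction and the gap vector. All
#' angular differences are folded into \[0, 180\] degrees.
#'
#' @param t_i,t_j one-row terminus tibbles (see [termini()]); must belong to
#'   different fragments.
#' @param params a [pairing_params()].
#' @return one-row tibble with `d_ij`, `varphi_ij`, `delta_theta`,
#'   `delta_theta_gap` and the three `passes_*` flags.
#' @export
evaluate_pair <- function(t_i, t_j, params = pairing_params()) {
  stopifnot(t_i$fragment_id != t_j$fragment_id)
  evaluate_pairs_vec(t_i, t_j, params) |>
    dplyr::select(dplyr::any_of(c(
      "d_ij", "varphi_ij", "delta_theta", "delta_theta_gap",
      "passes_similarity", "passes_proximity", "passes_continuity"
    )))
}

#' Find termini inside a base terminus' search fan
#'
#' The fan is anchored at the base tip, aimed along its propagation
#' direction: a candidate is inside when its distance is at most
#' `search_radius` and the angle between the propagation direction and the
#' displacement vector is at most `search_angle`. Termini of the base's own
#' fragment are excluded.
#'
#' @param base one-row terminus tibble.
#' @param all_termini tibble of termini (with optional logical `paired`
#'   column; paired termini are excluded).
#' @param params a [pairing_params()].
#' @return the subset of `all_termini` inside the fan.
#' @export
find_candidates <- function(base, all_termini, params = pairing_params()) {
  cand <- all_termini[all_termini$fragment_id != base$fragment_id, ]
  if (!is.null(cand$paired)) cand <- cand[!cand$paired, ]
  if (nrow(cand) == 0) return(cand)
  d <- sqrt((cand$row - base$row)^2 + (cand$col - base$col)^2)
  ang <- fold180(base$phi - directions_to(base$row, base$col, cand$row, cand$col))
  cand[d <= params$search_radius & ang <= params$search_angle & d > 0, ]
}

#' Can fragment `m` bridge the gap between two termini?
#'
#' Identifies `m`'s tip nearest the base terminus (`a`; the other tip is
#' `b`) and checks the similarity and continuity criteria of the base
#' against tip `a` and of the candidate against tip `b`, with the same
#' `phi_max`/`psi_max` bounds. When a bridge is eligible the direct pairing
#' is rejected in favor of pairing through the bridge.
#'
#' @param t_i,t_j one-row terminus tibbles (base and candidate).
#' @param m_termini the two termini rows of the prospective bridge fragment.
#' @param params a [pairing_params()].
#' @return `TRUE` when all four bridge conditions hold.
#' @export
bridge_eligible <- function(t_i, t_j, m_termini, params = pairing_params()) {
  stopifnot(nrow(m_termini) == 2)
  d_i <- sqrt((m_termini$row - t_i$row)^2 + (m_termini$col - t_i$col)^2)
  a <- m_termini[which.min(d_i), ]
  b <- m_termini[which.max(d_i), ]
  fold180(t_i$phi - reverse_direction(a$phi)) <= params$phi_max &&
    fold180(t_i$phi - directions_to(t_i$row, t_i$col, a$row, a$col)) <=
      params$psi_max &&
    fold180(t_j$phi - reverse_direction(b$phi)) <= params$phi_max &&
    fold180(t_j$phi - directions_to(t_j$row, t_j$col, b$row, b$col)) <=
      params$psi_max
}

#' Rank eligible candidates by pairing cost
#'
#' Cost of candidate i is
#' `c_angle_weight * dtheta_i / max_k(dtheta_k) +
#'  c_gap_weight * dtheta_gap_i / max_k(dtheta_gap_k)`,
#' with a zero maximum making that term 0 for all candidates (0/0 := 0).
#' The lowest cost wins; ties are broken by smaller gap `d_ij`, then
#' smaller `fragment_id`.
#'
#' @param evals tibble of passing evaluations with columns `delta_theta`,
#'   `delta_theta_gap`, `d_ij`, `fragment_id`.
#' @param params a [pairing_params()].
#' @return `evals` with a `cost` column, sorted best first.
#' @export
score_candidates <- function(evals, params = pairing_params()) {
  if (nrow(evals) == 0) {
    evals$cost <- double()
    return(evals)
  }
  mt <- max(evals$delta_theta)
  mg <- max(evals$delta_theta_gap)
  term_t <- if (mt > 0) evals$delta_theta / mt else 0
  term_g <- if (mg > 0) evals$delta_theta_gap / mg else 0
  evals$cost <- params$c_angle_weight * term_t + params$c_gap_weight * term_g
  evals[order(evals$cost, evals$d_ij, evals$fragment_id), ]
}

#' Reconstruct whole fiber traces from filament fragments
#'
#' Iterates over base termini in descending order of fragment length. For
#' each unpaired base terminus, candidates inside the search fan are
#' filtered by the similarity/proximity/continuity criteria; when an
#' eligible inner (bridge) fragment exists for a candidate pair, the direct
#' pairing is replaced by pairing to the bridge's near tip; survivors are
#' ranked by cost and the best pairing is accepted, marking both termini
#' paired. Passes repeat until a full pass makes no new pairing. Accepted
#' pairings are then chained into fiber traces; a cyclic chain is broken at
#' its highest-cost link with a warning.
#'
#' @param fragments a `fragment_set`.
#' @param params a [pairing_params()].
#' @return an object of class `fiber_traces`: a tibble with one row per
#'   fiber (`fiber_id`, `n_fragments`, `n_px`, `length_px`,
#'   `fragment_ids` and `pixels` list-columns).
#' @export
reconstruct <- function(fragments, params = pairing_params()) {
  tt <- termini(fragments)
  tt$paired <- FALSE
  tt$partner <- NA_integer_
  pair_cost <- numeric(0)
  pair_a <- integer(0)
  pair_b <- integer(0)

  frag_order <- fragments$fragment_id[order(-fragments$n_px,
                                            fragments$fragment_id)]
  if (nrow(tt) > 0) {
    repeat {
      new_pair <- FALSE
      for (fid in frag_order) {
        for (base_tid in tt$tid[tt$fragment_id == fid]) {
          base <- tt[base_tid, ]
          if (base$paired) next
          cand <- find_candidates(base, tt, params)
          if (nrow(cand) == 0) next
          ev <- evaluate_pairs_vec(base, cand, params)
          ev <- ev[ev$passes_similarity & ev$passes_proximity &
                     ev$passes_continuity, ]
          if (nrow(ev) == 0) next
          # inner-fragment (bridge) resolution
          fan_frags <- unique(cand$fragment_id)
          final <- list()
          for (k in seq_len(nrow(ev))) {
            cj <- ev[k, ]
            bridged <- FALSE
            for (mf in setdiff(fan_frags, c(fid, cj$fragment_id))) {
              mt <- tt[tt$fragment_id == mf, ]
              if (any(mt$paired)) next
              if (bridge_eligible(base, cj, mt, params)) {
                d_i <- sqrt((mt$row - base$row)^2 + (mt$col - base$col)^2)
                tip_a <- mt[which.min(d_i), ]
                rep_ev <- evaluate_pairs_vec(base, tip_a, params)
                if (rep_ev$passes_similarity && rep_ev$passes_proximity &&
                    rep_ev$passes_continuity) {
                  final[[length(final) + 1]] <- rep_ev
                  bridged <- TRUE
                  break
                }
              }
            }
            if (!bridged) final[[length(final) + 1]] <- cj
          }
          ev <- dplyr::bind_rows(final)
          ev <- ev[!duplicated(ev$tid), ]
          ev <- score_candidates(ev, params)
          best <- ev[1, ]
          tt$paired[c(base_tid, best$tid)] <- TRUE
          tt$partner[base_tid] <- best$tid
          tt$partner[best$tid] <- base_tid
          pair_a <- c(pair_a, base_tid)
          pair_b <- c(pair_b, best$tid)
          pair_cost <- c(pair_cost, best$cost)
          new_pair <- TRUE
        }
      }
      if (!new_pair) break
    }
  }
  assemble_traces(fragments, tt, pair_a, pair_b, pair_cost)
}

# Chain fragments through accepted pairings into ordered fiber traces.
assemble_traces <- function(fragments, tt, pair_a, pair_b, pair_cost) {
  n_frag <- nrow(fragments)
  empty <- tibble(fiber_id = integer(), n_fragments = integer(),
                  n_px = integer(), length_px = double(),
                  fragment_ids = list(), pixels = list())
  if (n_frag == 0) {
    return(structure(empty, class = c("fiber_traces", class(empty))))
  }
  other_end <- function(tid) {
    fr <- tt$fragment_id[tid]
    setdiff(tt$tid[tt$fragment_id == fr], tid)
  }
  # break cycles: components whose termini are all paired
  repeat {
    cyc_start <- NULL
    seen <- rep(FALSE, nrow(tt))
    for (t0 in tt$tid) {
      if (seen[t0] || !tt$paired[t0]) next
      cur <- t0
      is_cycle <- TRUE
      repeat {
        seen[cur] <- TRUE
        oe <- other_end(cur)
        seen[oe] <- TRUE
        if (!tt$paired[oe]) {
          is_cycle <- FALSE
          break
        }
        cur <- tt$partner[oe]
        if (cur == t0) break
      }
      if (is_cycle) {
        cyc_start <- t0
        break
      }
    }
    if (is.null(cyc_start)) break
    # collect cycle links and cut the costliest
    links <- integer(0)
    cur <- cyc_start
    repeat {
      oe <- other_end(cur)
      li <- which((pair_a == oe & pair_b == tt$partner[oe]) |
                    (pair_b == oe & pair_a == tt$partner[oe]))
      links <- c(links, li[1])
      cur <- tt$partner[oe]
      if (cur == cyc_start) break
    }
    cut <- links[which.max(pair_cost[links])]
    warning("cyclic pairing chain broken at its highest-cost link")
    a <- pair_a[cut]
    b <- pair_b[cut]
    tt$paired[c(a, b)] <- FALSE
    tt$partner[c(a, b)] <- NA_integer_
    pair_a <- pair_a[-cut]
    pair_b <- pair_b[-cut]
    pair_cost <- pair_cost[-cut]
  }
  frag_pixels <- setNames(fragments$pixels, fragments$fragment_id)
  used <- rep(FALSE, n_frag)
  names(used) <- fragments$fragment_id
  traces <- list()
  starts <- tt$tid[!tt$paired]
  starts <- starts[order(tt$row[starts], tt$col[starts])]
  for (s in starts) {
    fid0 <- as.character(tt$fragment_id[s])
    if (used[fid0]) next
    chain_frags <- integer(0)
    chain_px <- list()
    cur <- s
    repeat {
      fr <- tt$fragment_id[cur]
      used[as.character(fr)] <- TRUE
      px <- frag_pixels[[as.character(fr)]]
      if (tt$end[cur] == "B") px <- px[rev(seq_len(nrow(px))), , drop = FALSE]
      chain_frags <- c(chain_frags, fr)
      chain_px[[length(chain_px) + 1]] <- px
      oe <- other_end(cur)
      if (!tt$paired[oe]) break
      cur <- tt$partner[oe]
    }
    pix <- do.call(rbind, chain_px)
    steps <- sqrt(diff(pix[, 1])^2 + diff(pix[, 2])^2)
    traces[[length(traces) + 1]] <- tibble(
      n_fragments = length(chain_frags), n_px = nrow(pix),
      length_px = sum(steps), fragment_ids = list(chain_frags),
      pixels = list(pix)
    )
  }
  out <- if (length(traces)) dplyr::bind_rows(traces) else empty
  if (nrow(out)) {
    out <- dplyr::mutate(out, fiber_id = dplyr::row_number(), .before = 1)
  }
  structure(out, class = c("fiber_traces", class(out)))
}

#' Fiber trace centerlines as a long tibble
#'
#' @param x a `fiber_traces`.
#' @param ... unused.
#' @return tibble with `fiber_id`, `point_index`, `row`, `col`.
#' @export
tidy.fiber_traces <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(fiber_id = integer(), point_index = integer(),
                  row = integer(), col = integer()))
  }
  purrr::map2_dfr(x$fiber_id, x$pixels, function(id, px) {
    tibble(fiber_id = id, point_index = seq_len(nrow(px)),
           row = px[, 1], col = px[, 2])
  })
}

#' One-row summary of reconstructed fibers
#'
#' @param x a `fiber_traces`.
#' @param pixel_size nm/px, used to convert lengths to micrometres.
#' @param ... unused.
#' @export
glance.fiber_traces <- function(x, pixel_size = 108, ...) {
  tibble(
    n_fibers = nrow(x),
    n_fragments = if (nrow(x)) sum(x$n_fragments) else 0L,
    total_length_px = if (nrow(x)) sum(x$length_px) else 0,
    total_length_um = if (nrow(x)) sum(x$length_px) * pixel_size / 1000 else 0,
    mean_length_px = if (nrow(x)) mean(x$length_px) else NA_real_
  )
}
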