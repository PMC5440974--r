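mk_term <- function(row, col, phi, fragment_id = 1L, tid = NA_integer_) {
  tibble::tibble(tid = tid, fragment_id = fragment_id, end = "A",
                 row = row, col = col, phi = phi)
}

test_that("collinear facing termini pass all three criteria with zero mismatch", {
  t_i <- mk_term(10, 10, 0, 1L)   # pointing +col
  t_j <- mk_term(10, 15, 180, 2L) # pointing -col, facing back
  ev <- evaluate_pair(t_i, t_j)
  expect_true(ev$passes_similarity && ev$passes_proximity &&
                ev$passes_continuity)
  expect_equal(ev$delta_theta, 0)
  expect_equal(ev$delta_theta_gap, 0)
  expect_equal(ev$d_ij, 5)
})

test_that("a right-angle gap fails the continuity criterion", {
  t_i <- mk_term(20, 10, 0, 1L)
  t_j <- mk_term(10, 10, 180, 2L)  # directly above: gap vector at +90
  ev <- evaluate_pair(t_i, t_j)
  expect_false(ev$passes_continuity)
  expect_equal(ev$delta_theta_gap, 90)
})

test_that("pairing criteria match brute-force vector arithmetic on 200 random pairs", {
  set.seed(21)
  params <- pairing_params(phi_max = 30, d_max = 16, psi_max = 30)
  for (k in 1:200) {
    t_i <- mk_term(runif(1, 1, 60), runif(1, 1, 60), runif(1, -180, 180), 1L)
    t_j <- mk_term(runif(1, 1, 60), runif(1, 1, 60), runif(1, -180, 180), 2L)
    ev <- evaluate_pair(t_i, t_j, params)
    o <- oracle_pair(c(t_i$row, t_i$col), t_i$phi,
                     c(t_j$row, t_j$col), t_j$phi, params)
    expect_equal(ev$delta_theta, o$delta_theta, tolerance = 1e-9)
    expect_equal(ev$delta_theta_gap, o$delta_theta_gap, tolerance = 1e-9)
    expect_equal(ev$d_ij, o$d_ij, tolerance = 1e-12)
    expect_identical(ev$passes_similarity, o$passes_similarity)
    expect_identical(ev$passes_proximity, o$passes_proximity)
    expect_identical(ev$passes_continuity, o$passes_continuity)
  }
})

test_that("fan membership agrees with an explicit polar-coordinate check", {
  set.seed(31)
  params <- pairing_params(search_radius = 20, search_angle = 30)
  base <- mk_term(50, 50, 35, 99L, tid = 0L)
  tt <- dplyr::bind_rows(lapply(1:50, function(k) {
    mk_term(runif(1, 1, 100), runif(1, 1, 100), runif(1, -180, 180),
            fragment_id = k, tid = k)
  }))
  tt$paired <- FALSE
  got <- find_candidates(base, tt, params)$tid
  want <- Filter(function(k) {
    d <- sqrt((tt$row[k] - 50)^2 + (tt$col[k] - 50)^2)
    ang <- atan2(-(tt$row[k] - 50), tt$col[k] - 50) * 180 / pi
    dd <- abs(35 - ang) %% 360
    d > 0 && d <= 20 && min(dd, 360 - dd) <= 30
  }, 1:50)
  expect_setequal(got, want)
  expect_length(find_candidates(base, tt[0, ], params)$tid, 0)
})

test_that("a collinear middle fragment is an eligible bridge; a perpendicular one is not", {
  # three collinear horizontal fragments: i at cols 1-10, m at 14-24, j at 28-38
  chains <- list(
    cbind(20, 1:10), cbind(20, 14:24), cbind(20, 28:38)
  )
  fr <- fibertrace:::fragment_set_from_chains(chains)
  tt <- termini(fr)
  t_i <- tt[tt$fragment_id == 1 & tt$end == "B", ]  # right end of i
  t_j <- tt[tt$fragment_id == 3 & tt$end == "A", ]  # left end of j
  m <- tt[tt$fragment_id == 2, ]
  expect_true(bridge_eligible(t_i, t_j, m))
  # perpendicular bridge
  chains_perp <- list(cbind(20, 1:10), cbind(10:20, 19), cbind(20, 28:38))
  fr2 <- fibertrace:::fragment_set_from_chains(chains_perp)
  tt2 <- termini(fr2)
  expect_false(bridge_eligible(tt2[tt2$fragment_id == 1 & tt2$end == "B", ],
                               tt2[tt2$fragment_id == 3 & tt2$end == "A", ],
                               tt2[tt2$fragment_id == 2, ]))
})

test_that("bridge eligibility matches brute-force evaluation on random triples", {
  set.seed(41)
  params <- pairing_params()
  for (k in 1:100) {
    base <- c(runif(1, 10, 50), runif(1, 10, 50))
    dir <- runif(1, -180, 180)
    t_i <- mk_term(base[1], base[2], dir, 1L)
    t_j <- mk_term(base[1] + runif(1, -20, 20), base[2] + runif(1, -20, 20),
                   runif(1, -180, 180), 2L)
    m <- dplyr::bind_rows(
      mk_term(base[1] + runif(1, -15, 15), base[2] + runif(1, -15, 15),
              runif(1, -180, 180), 3L),
      mk_term(base[1] + runif(1, -15, 15), base[2] + runif(1, -15, 15),
              runif(1, -180, 180), 3L)
    )
    got <- bridge_eligible(t_i, t_j, m, params)
    # oracle: identify tips, evaluate the four conditions explicitly
    d_i <- sqrt((m$row - t_i$row)^2 + (m$col - t_i$col)^2)
    a <- m[which.min(d_i), ]
    b <- m[which.max(d_i), ]
    sim_ia <- oracle_pair(c(t_i$row, t_i$col), t_i$phi,
                          c(a$row, a$col), a$phi, params)
    sim_jb <- oracle_pair(c(t_j$row, t_j$col), t_j$phi,
                          c(b$row, b$col), b$phi, params)
    want <- sim_ia$passes_similarity && sim_ia$passes_continuity &&
      sim_jb$passes_similarity && sim_jb$passes_continuity
    expect_identical(got, want)
  }
})

test_that("candidate costs follow the normalized two-term formula", {
  params <- pairing_params(c_angle_weight = 1, c_gap_weight = 1)
  evals <- tibble::tibble(
    tid = 1:2, fragment_id = 2:3,
    delta_theta = c(10, 20), delta_theta_gap = c(4, 2), d_ij = c(8, 3)
  )
  sc <- score_candidates(evals, params)
  expect_equal(sort(sc$cost), c(1.5, 1.5))
  # tie broken by smaller gap distance
  expect_equal(sc$tid[1], 2L)
  # single perfect candidate: 0/0 := 0
  one <- score_candidates(tibble::tibble(tid = 1L, fragment_id = 2L,
                                         delta_theta = 0, delta_theta_gap = 0,
                                         d_ij = 5), params)
  expect_equal(one$cost, 0)
  # candidate maximal in both terms costs exactly the weight sum
  p2 <- pairing_params(c_angle_weight = 0.3, c_gap_weight = 0.6)
  sc2 <- score_candidates(tibble::tibble(tid = 1:2, fragment_id = 2:3,
                                         delta_theta = c(5, 10),
                                         delta_theta_gap = c(1, 3),
                                         d_ij = c(1, 2)), p2)
  expect_equal(max(sc2$cost), 0.9)
})

test_that("an isolated fragment reconstructs to itself", {
  chains <- list(cbind(10, 5:30))
  fr <- fibertrace:::fragment_set_from_chains(chains)
  tr <- reconstruct(fr)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$n_fragments, 1L)
  expect_equal(nrow(tr$pixels[[1]]), 26)
})

test_that("a line split by small gaps closes into a single fiber", {
  # one straight horizontal line fragmented by 3 gaps of 5 px
  chains <- list(cbind(50, 5:30), cbind(50, 36:60), cbind(50, 66:90),
                 cbind(50, 96:120))
  fr <- fibertrace:::fragment_set_from_chains(chains)
  tr <- reconstruct(fr)
  expect_equal(nrow(tr), 1)
  expect_equal(tr$n_fragments, 4L)
  # pixels ordered monotonically along the line
  expect_true(all(diff(tr$pixels[[1]][, 2]) > 0) ||
                all(diff(tr$pixels[[1]][, 2]) < 0))
})

test_that("fragments partition into traces and no terminus pairs twice", {
  scene <- make_phantom(benchmark_scene_spec(psnr = 20, seed = 6))
  res <- extract_fibers(scene$noisy_image)
  tr <- res$traces
  used <- sort(unlist(tr$fragment_ids))
  expect_identical(used, sort(res$fragments$fragment_id))  # exactly once
  expect_equal(sum(tr$n_px), sum(res$fragments$n_px))
})

test_that("tightening the bounds never increases the number of pairings", {
  scene <- make_phantom(benchmark_scene_spec(psnr = 22, seed = 8))
  res <- extract_fibers(scene$noisy_image)
  n_pairings <- function(tr) sum(tr$n_fragments - 1L)
  loose <- reconstruct(res$fragments, pairing_params())
  for (p in list(pairing_params(d_max = 8, search_radius = 8),
                 pairing_params(phi_max = 15),
                 pairing_params(psi_max = 15))) {
    expect_lte(n_pairings(reconstruct(res$fragments, p)), n_pairings(loose))
  }
})

test_that("reconstruction is deterministic and idempotent on its own output", {
  scene <- make_phantom(benchmark_scene_spec(psnr = 25, seed = 2))
  res <- extract_fibers(scene$noisy_image)
  tr1 <- reconstruct(res$fragments)
  tr2 <- reconstruct(res$fragments)
  expect_identical(tidy(tr1), tidy(tr2))
})

test_that("accepted pairings are symmetric under role reversal", {
  scene <- make_phantom(benchmark_scene_spec(psnr = 25, seed = 3))
  res <- extract_fibers(scene$noisy_image)
  tr <- res$traces
  tt <- termini(res$fragments)
  params <- pairing_params()
  for (k in seq_len(nrow(tr))) {
    ids <- tr$fragment_ids[[k]]
    if (length(ids) < 2) next
    for (q in seq_len(length(ids) - 1)) {
      f1 <- ids[q]
      f2 <- ids[q + 1]
      # find the closest terminus pair between consecutive fragments
      t1s <- tt[tt$fragment_id == f1, ]
      t2s <- tt[tt$fragment_id == f2, ]
      dmat <- outer(seq_len(2), seq_len(2), Vectorize(function(i, j) {
        sqrt((t1s$row[i] - t2s$row[j])^2 + (t1s$col[i] - t2s$col[j])^2)
      }))
      w <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
      ev_fwd <- evaluate_pair(t1s[w[1], ], t2s[w[2], ], params)
      ev_rev <- evaluate_pair(t2s[w[2], ], t1s[w[1], ], params)
      expect_true(ev_rev$passes_similarity)
      expect_true(ev_rev$passes_proximity)
      # continuity mismatch seen from the other side agrees within the
      # angular resolution of the propagation directions
      expect_lt(abs(ev_fwd$delta_theta_gap - ev_rev$delta_theta_gap), 25)
    }
  }
})
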