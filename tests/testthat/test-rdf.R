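test_that("RDF bin counts equal the O(N^2) enumeration oracle exactly", {
  set.seed(71)
  for (rep in 1:5) {
    cell <- if (rep <= 3) diag(runif(3, 10, 14)) else random_triclinic_cell()
    frames <- lapply(1:2, function(i) random_frame(30, cell))
    ref <- 1:3; tgt <- 4:30
    r <- compute_rdf(frames, ref, tgt, r_max = 4, bin = 0.05)
    expect_identical(r$raw_counts, oracle_rdf_counts(frames, ref, tgt, 4, 0.05))
  }
})

test_that("a single fixed pair lands in its exact bin", {
  fr <- md_frame(rbind(c(1, 1, 1), c(1, 1, 3.40)), sim_box(c(20, 20, 20)))
  r <- compute_rdf(list(fr), 1L, 2L, r_max = 5)
  hot <- which(r$raw_counts > 0)
  expect_length(hot, 1)
  expect_equal(r$bin_edges[hot], 2.40)      # bin [2.40, 2.45)
  expect_equal(r$raw_counts[hot], 1)
})

test_that("ideal-gas targets normalize to g = 1 and density invariance holds", {
  ig <- ideal_gas_ensemble(400, box_length = 18, n_frames = 60, seed = 8)
  r <- compute_rdf(ig$frames, ig$ref_index, ig$target_indices, r_max = 8)
  expect_lt(abs(mean(r$g[r$r_center >= 2]) - 1), 0.05)
  ig2 <- ideal_gas_ensemble(800, box_length = 18, n_frames = 60, seed = 8)
  r2 <- compute_rdf(ig2$frames, ig2$ref_index, ig2$target_indices, r_max = 8)
  expect_equal(r2$ideal_density, 2 * r$ideal_density, tolerance = 1e-12)
  expect_lt(abs(mean(r2$g[r2$r_center >= 2]) - 1), 0.05)
})

test_that("count conservation: raw counts sum to all pairs within range", {
  set.seed(73)
  frames <- lapply(1:3, function(i) random_frame(25, diag(c(11, 12, 13))))
  ref <- 1:2; tgt <- 3:25
  r <- compute_rdf(frames, ref, tgt, r_max = 5, bin = 0.05)
  total <- 0
  for (fr in frames) for (ri in ref) for (ti in tgt) {
    if (oracle_min_image(fr$coords[ri, ], fr$coords[ti, ], fr$box$cell) < 5) {
      total <- total + 1
    }
  }
  expect_equal(sum(r$raw_counts), total)
})

test_that("coordination numbers match direct neighbour counting", {
  # one bound target always at 2.4 A -> N(3.0) = 1 exactly
  box <- sim_box(c(20, 20, 20))
  frames <- lapply(1:10, function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    md_frame(rbind(c(10, 10, 10), c(10, 10, 10) + 2.4 * u), box, frame_index = i)
  })
  r <- compute_rdf(frames, 1L, 2L, r_max = 6)
  expect_equal(coordination_number(r, 3.0), 1.0, tolerance = 1e-9)

  # random systems: matches the per-frame neighbour-count oracle
  set.seed(79)
  frames <- lapply(1:4, function(i) random_frame(30, diag(c(12, 12, 12))))
  r <- compute_rdf(frames, 1:2, 3:30, r_max = 5.5)
  expect_equal(coordination_number(r, 4.0),
               oracle_coordination(frames, 1:2, 3:30, 4.0),
               tolerance = 1e-9)
})

test_that("first_peak finds planted shells and reports absence honestly", {
  # targets drawn from N(2.40, 0.05) around the reference
  set.seed(83)
  box <- sim_box(c(20, 20, 20))
  frames <- lapply(1:300, function(i) {
    pts <- t(vapply(1:3, function(k) {
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      c(10, 10, 10) + rnorm(1, 2.40, 0.05) * u
    }, numeric(3)))
    md_frame(rbind(c(10, 10, 10), pts), box, frame_index = i)
  })
  r <- compute_rdf(frames, 1L, 2:4, r_max = 6)
  pk <- first_peak(r)
  expect_false(is.null(pk))
  expect_lt(abs(pk$r_peak - 2.40), 0.05 + 1e-9)

  # flat g = 1: no strict rise, no peak
  flat <- r; flat$g <- rep(1, length(r$g))
  expect_null(first_peak(flat))
  # decaying curve below the threshold: absent, not an error
  low <- r; low$g <- seq(0.9, 0.1, length.out = length(r$g))
  expect_null(first_peak(low, min_g = 1))
})

test_that("peak position is robust to half-bin shifts of the distribution", {
  box <- sim_box(c(20, 20, 20))
  mk <- function(dist) lapply(1:50, function(i) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    md_frame(rbind(c(10, 10, 10), c(10, 10, 10) + dist * u), box)
  })
  set.seed(89)
  p1 <- first_peak(compute_rdf(mk(2.425), 1L, 2L, r_max = 5))$r_peak # mid-bin
  p2 <- first_peak(compute_rdf(mk(2.400), 1L, 2L, r_max = 5))$r_peak # at edge
  expect_lte(abs(p1 - p2), 0.05 + 1e-9)
})

test_that("residue averaging excludes the top-ranked curves", {
  set.seed(97)
  base <- compute_rdf(list(random_frame(20, diag(c(12, 12, 12)))), 1L, 2:20,
                      r_max = 4)
  mk <- function(scale) { r <- base; r$g <- base$g * scale + 0.1; r }
  rdfs <- list(G1 = mk(1), G2 = mk(1), G6 = mk(8), G13 = mk(10))
  avg <- residue_averaged_rdf(rdfs, n_exclude = 2)
  expect_setequal(avg$excluded_ids, c("G6", "G13"))
  expect_equal(avg$mean_g, rdfs$G1$g, tolerance = 1e-12)
  expect_equal(avg$sd_g, rep(0, length(base$g)))

  # known per-bin values against hand arithmetic
  r1 <- base; r1$g <- rep(1, length(base$g))
  r2 <- base; r2$g <- rep(2, length(base$g))
  r3 <- base; r3$g <- rep(4, length(base$g))
  avg <- residue_averaged_rdf(list(a = r1, b = r2, c = r3), n_exclude = 1)
  expect_equal(unique(avg$mean_g), 1.5)
  expect_equal(unique(avg$sd_g), sd(c(1, 2)))
  # n_exclude = 0: plain mean of all curves
  avg0 <- residue_averaged_rdf(list(a = r1, b = r2, c = r3), n_exclude = 0)
  expect_equal(unique(avg0$mean_g), mean(c(1, 2, 4)))

  r_bad <- compute_rdf(list(random_frame(20, diag(c(12, 12, 12)))), 1L, 2:20,
                       r_max = 4, bin = 0.1)
  expect_error(residue_averaged_rdf(list(a = r1, b = r_bad, c = r3)),
               "binning")
})

test_that("RDF input contracts are enforced", {
  fr <- random_frame(10, diag(c(10, 10, 10)))
  expect_error(compute_rdf(list(fr), 1:2, 2:5, r_max = 4), "disjoint")
  expect_error(compute_rdf(list(fr), 1L, integer(0), r_max = 4), "empty")
  expect_error(compute_rdf(list(fr), 1L, 2:5, r_max = 6), "half")
  nonper <- md_frame(fr$coords, sim_box())
  expect_error(compute_rdf(list(nonper), 1L, 2:5, r_max = 4), "periodic")
})
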