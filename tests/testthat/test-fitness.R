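# alpha / gamma grading uses frames constructed with exactly planted geometry
test_that("alpha criterion: thresholds inclusive, ramps hit 0 and 1", {
  g <- geometry_frame(d = 3.4, theta = 150)
  a <- alpha_fitness(g$frame, g$sites)
  expect_true(a$pass)
  expect_equal(a$d, 3.4, tolerance = 1e-9)
  expect_equal(a$angle, 150, tolerance = 1e-6)

  # exactly at both thresholds: pass with zero graded score
  g <- geometry_frame(d = 3.5, theta = 140)
  a <- alpha_fitness(g$frame, g$sites)
  expect_true(a$pass)
  expect_equal(a$score, 0, tolerance = 1e-9)

  # at the ideal point: full score
  g <- geometry_frame(d = 3.0, theta = 180)
  a <- alpha_fitness(g$frame, g$sites)
  expect_true(a$pass)
  expect_equal(a$score, 1, tolerance = 1e-9)

  # beyond either threshold: fail, zero score
  expect_false(alpha_fitness(geometry_frame(d = 3.6, theta = 170)$frame, g$sites)$pass)
  expect_false(alpha_fitness(geometry_frame(d = 3.2, theta = 130)$frame, g$sites)$pass)
})

test_that("gamma criterion: inclusive boundary and ramp", {
  g <- geometry_frame(dh = 2.0)
  r <- gamma_fitness(g$frame, g$sites)
  expect_true(r$pass)
  expect_gt(r$score, 0)
  r <- gamma_fitness(geometry_frame(dh = 2.2)$frame, g$sites)
  expect_true(r$pass)
  expect_equal(r$score, 0, tolerance = 1e-9)
  r <- gamma_fitness(geometry_frame(dh = 2.5)$frame, g$sites)
  expect_false(r$pass)
  expect_equal(r$score, 0)
  r <- gamma_fitness(geometry_frame(dh = 1.8)$frame, g$sites)
  expect_equal(r$score, 1, tolerance = 1e-9)
})

test_that("beta passes on inner-sphere ion contact with an NPO", {
  # Pb planted 2.5 A from pro-RP
  g <- geometry_frame(has_pb = TRUE, d_pb_prorp = dspec(2.5, 0), n_na = 0L)
  b <- beta_fitness(g$frame, g$sites)
  expect_true(b$pass)
  expect_equal(b$d_min, 2.5, tolerance = 1e-9)
  expect_gt(b$score, 0)

  # no ion within any cutoff (ions exist but are territorial, > 4 A away)
  g <- geometry_frame(has_pb = FALSE, n_na = 3L)
  b <- beta_fitness(g$frame, g$sites)
  expect_false(b$pass)
  expect_equal(b$score, 0)

  # Na exactly at its inner-shell cutoff of pro-RP (and farther from every
  # other NPO contact): inclusive pass, zero score
  sc <- make_scaffold()
  p <- sc$coords[3, ]; orp <- sc$coords[5, ]
  na_pos <- orp + 3.1 * (orp - p) / sqrt(sum((orp - p)^2))
  atoms <- rbind(sc$atoms, data.frame(
    atom_index = 11L, atom_name = "NA", residue_name = "NA",
    residue_index = 201L, chain_id = "A", element = "NA",
    stringsAsFactors = FALSE))
  fr <- md_frame(rbind(sc$coords, na_pos), sim_box(c(30, 30, 30)))
  b <- beta_fitness(fr, build_site_map(atoms))
  expect_true(b$pass)
  expect_equal(b$d_min, 3.1, tolerance = 1e-9)
  expect_equal(b$score, 0, tolerance = 1e-9)
})

test_that("delta distinguishes first shell, second shell + water, and none", {
  # Pb directly coordinating the leaving group
  g <- geometry_frame(has_pb = TRUE, d_pb_prorp = dspec(2.5, 0),
                      d_pb_o5p = dspec(2.5, 0), n_na = 0L)
  d <- delta_fitness(g$frame, g$sites)
  expect_equal(d$shell, "first")
  expect_equal(d$score, 1)

  # Pb at 4.5 A with its bound water donating an H-bond to O5'
  g <- geometry_frame(has_pb = TRUE, d_pb_prorp = dspec(2.5, 0),
                      d_pb_o5p = dspec(4.5, 0), pb_water_prob = 1,
                      d_waterh_o5p = dspec(1.9, 0), n_na = 0L)
  d <- delta_fitness(g$frame, g$sites)
  expect_equal(d$shell, "second")
  expect_true(d$water_pass)
  expect_equal(d$score, 0.75)

  # no ion within the second shell, no bridge
  g <- geometry_frame(has_pb = FALSE, n_na = 0L)
  d <- delta_fitness(g$frame, g$sites)
  expect_equal(d$shell, "none")
  expect_false(d$water_pass)
  expect_equal(d$score, 0)
})

test_that("alpha and gamma scores are monotone in their criteria", {
  sites <- geometry_frame()$sites
  ds <- seq(3.5, 3.0, by = -0.05)
  sc <- vapply(ds, function(d)
    alpha_fitness(geometry_frame(d = d, theta = 165)$frame, sites)$score,
    numeric(1))
  expect_true(all(diff(sc) >= -1e-12))
  ths <- seq(140, 180, by = 4)
  sc <- vapply(ths, function(th)
    alpha_fitness(geometry_frame(d = 3.2, theta = th)$frame, sites)$score,
    numeric(1))
  expect_true(all(diff(sc) >= -1e-12))
  dh <- seq(2.2, 1.8, by = -0.05)
  sc <- vapply(dh, function(x)
    gamma_fitness(geometry_frame(dh = x)$frame, sites)$score, numeric(1))
  expect_true(all(diff(sc) >= -1e-12))
})

test_that("pass flags and positive scores agree except exactly at thresholds", {
  set.seed(17)
  sites <- geometry_frame()$sites
  for (rep in 1:30) {
    d <- runif(1, 2.8, 4.0); th <- runif(1, 120, 180); dh <- runif(1, 1.6, 2.6)
    g <- geometry_frame(d = d, theta = th, dh = dh)
    a <- alpha_fitness(g$frame, sites)
    ga <- gamma_fitness(g$frame, sites)
    at_thr <- isTRUE(all.equal(d, 3.5)) || isTRUE(all.equal(th, 140))
    if (!at_thr) expect_equal(a$score > 0, a$pass)
    if (!isTRUE(all.equal(dh, 2.2))) expect_equal(ga$score > 0, ga$pass)
  }
})

test_that("active state is the conjunction of alpha and gamma", {
  expect_true(classify_active(TRUE, TRUE))
  expect_false(classify_active(TRUE, FALSE))
  expect_false(classify_active(FALSE, FALSE))
  expect_error(classify_active(TRUE, NA), "undefined")
  expect_error(classify_active(list(alpha_pass = TRUE, gamma_pass = NULL)),
               "undefined")
})

test_that("timeline recovers a noise-free planted active fraction exactly", {
  specs <- list(
    state_spec("on", weight = 0.56, d_o2p_p = dspec(3.2, 0),
               angle_inline = dspec(160, 0, lo = 1, hi = 180),
               d_ho2p_n1 = dspec(2.0, 0), bridging_na_prob = 1),
    state_spec("off", weight = 0.44, d_o2p_p = dspec(4.5, 0, lo = 3.6),
               angle_inline = dspec(120, 0, lo = 1, hi = 180),
               d_ho2p_n1 = dspec(3.0, 0), bridging_na_prob = 1)
  )
  ens <- generate_ensemble(specs, 100, seed = 9)
  tl <- fitness_timeline(ens$frames, build_site_map(ens$atoms))
  expect_equal(sum(tl$active), 56)
  expect_equal(tl$active, ens$truth$intended_active)
})

test_that("timeline is stateless: permuting frames permutes rows identically", {
  ens <- generate_ensemble(gb_minus_specs(), 20, seed = 13)
  sm <- build_site_map(ens$atoms)
  tl <- fitness_timeline(ens$frames, sm)
  set.seed(2)
  perm <- sample(20)
  tl2 <- fitness_timeline(ens$frames[perm], sm)
  rownames(tl) <- rownames(tl2) <- NULL
  expect_equal(tl2, tl[perm, ], ignore_attr = TRUE)
})

test_that("a single ideal-geometry frame scores 1 on alpha and gamma", {
  g <- geometry_frame(d = 3.0, theta = 180, dh = 1.8)
  tl <- fitness_timeline(list(g$frame), g$sites)
  expect_equal(nrow(tl), 1)
  expect_equal(tl$alpha_score, 1, tolerance = 1e-9)
  expect_equal(tl$gamma_score, 1, tolerance = 1e-9)
  expect_true(tl$active)
  expect_equal(nrow(fitness_timeline(list(), g$sites)), 0)
})
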