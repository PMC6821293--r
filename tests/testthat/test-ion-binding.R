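# hand-built minimal frames for the bridging/mode primitives: the scaffold
# site atoms plus ions/waters at controlled positions
bridge_fixture <- function(na_pos = NULL, pb_pos = NULL, waters = NULL) {
  sc <- make_scaffold()
  atoms <- sc$atoms
  coords <- sc$coords
  add <- function(name, resname, resno, element, xyz) {
    atoms <<- rbind(atoms, data.frame(
      atom_index = nrow(atoms) + 1L, atom_name = name, residue_name = resname,
      residue_index = resno, chain_id = "A", element = element,
      stringsAsFactors = FALSE))
    coords <<- rbind(coords, xyz)
  }
  if (!is.null(na_pos)) {
    for (i in seq_len(nrow(na_pos))) add("NA", "NA", 200L + i, "NA", na_pos[i, ])
  }
  if (!is.null(pb_pos)) add("PB", "PB", 101L, "PB", pb_pos)
  if (!is.null(waters)) {
    for (i in seq_along(waters)) {
      w <- waters[[i]]
      add("O", "HOH", 300L + i, "O", w[1, ])
      add("H1", "HOH", 300L + i, "H", w[2, ])
      add("H2", "HOH", 300L + i, "H", w[3, ])
    }
  }
  rownames(coords) <- NULL
  list(frame = md_frame(coords, sim_box(c(30, 30, 30))),
       sites = build_site_map(atoms), atoms = atoms, scaffold = sc)
}

# a point at equal distance r from both of two anchors (on their bisector)
between_at <- function(a, b, r) {
  mid <- (a + b) / 2
  D <- sqrt(sum((b - a)^2))
  h <- sqrt(max(0, r^2 - (D / 2)^2))
  perp <- c(-(b - a)[2], (b - a)[1], 0)
  perp <- perp / sqrt(sum(perp^2))
  mid + h * perp
}

test_that("bridging sodium requires simultaneous contact with O2' and pro-RP", {
  fx0 <- bridge_fixture()
  o2 <- fx0$frame$coords[fx0$sites$roles[["O2p"]], ]
  orp <- fx0$frame$coords[fx0$sites$roles[["proRP"]], ]

  # within 2.4 A of both -> detected
  fx <- bridge_fixture(na_pos = rbind(between_at(o2, orp, 2.4)))
  idx <- detect_bridging_na(fx$frame, fx$sites)
  expect_false(is.na(idx))
  expect_equal(fx$atoms$element[idx], "NA")

  # close to O2' only -> none
  far <- o2 + 5 * c(0, 0, 1)
  fx <- bridge_fixture(na_pos = rbind(o2 + c(0, 0, 2.4) * 0, far))
  fx <- bridge_fixture(na_pos = rbind(far))
  expect_true(is.na(detect_bridging_na(fx$frame, fx$sites)))

  # two qualifying: min max-distance wins; tie -> lower atom index
  fx <- bridge_fixture(na_pos = rbind(between_at(o2, orp, 2.9),
                                      between_at(o2, orp, 2.3)))
  idx <- detect_bridging_na(fx$frame, fx$sites)
  expect_equal(idx, fx$sites$species[["NA"]][2])
  tie <- between_at(o2, orp, 2.5)
  fx <- bridge_fixture(na_pos = rbind(tie, tie))
  expect_equal(detect_bridging_na(fx$frame, fx$sites),
               fx$sites$species[["NA"]][1])
})

test_that("binding-mode labels partition the designed cases", {
  fx0 <- bridge_fixture()
  o2 <- fx0$frame$coords[fx0$sites$roles[["O2p"]], ]
  orp <- fx0$frame$coords[fx0$sites$roles[["proRP"]], ]
  pb_near <- orp + 2.5 * c(0, 0, 1)

  m <- classify_binding_mode(
    bridge_fixture(na_pos = rbind(between_at(o2, orp, 2.4)),
                   pb_pos = pb_near)$frame,
    bridge_fixture(na_pos = rbind(between_at(o2, orp, 2.4)),
                   pb_pos = pb_near)$sites)
  expect_equal(m$label, "NA_BRIDGE_PB")
  expect_true(m$pb_in_site)
  expect_false(is.na(m$bridging_na_index))

  fx <- bridge_fixture(pb_pos = pb_near)
  expect_equal(classify_binding_mode(fx$frame, fx$sites)$label, "PB_ONLY")

  fx <- bridge_fixture(na_pos = rbind(between_at(o2, orp, 2.4)))
  expect_equal(classify_binding_mode(fx$frame, fx$sites)$label, "NA_ONLY")

  fx <- bridge_fixture(pb_pos = orp + 12 * c(0, 0, 1))
  expect_equal(classify_binding_mode(fx$frame, fx$sites)$label, "OTHER")
})

test_that("mode consistency: a bridge label implies a detectable bridging Na", {
  ens <- generate_ensemble(gb_minus_specs(), 60, seed = 21)
  sm <- build_site_map(ens$atoms)
  md <- mode_timeline(ens$frames, sm)
  expect_true(all(md$label %in% c("NA_ONLY", "PB_ONLY", "NA_BRIDGE_PB", "OTHER")))
  expect_equal(sum(table(md$label)), length(ens$frames))
  for (i in which(md$label == "NA_BRIDGE_PB")) {
    expect_false(is.na(detect_bridging_na(ens$frames[[i]], sm)))
  }
})

test_that("solvent and sodium bridges between G13:O6 and pro-SP are detected", {
  fx0 <- bridge_fixture()
  e1 <- fx0$frame$coords[fx0$sites$roles[["G13_O6"]], ]
  e2 <- fx0$frame$coords[fx0$sites$roles[["proSP"]], ]

  # water with one H 1.9 A from G13:O6 and the other 2.0 A from pro-SP
  o <- between_at(e1, e2, 2.7)
  h1 <- o + 0.96 * (e1 - o) / sqrt(sum((e1 - o)^2))
  h2 <- o + 0.96 * (e2 - o) / sqrt(sum((e2 - o)^2))
  fx <- bridge_fixture(waters = list(rbind(o, h1, h2)))
  ev <- detect_bridge(fx$frame, fx$sites)
  expect_equal(ev$bridge_kind, "WATER")
  expect_equal(fx$atoms$element[ev$mediator_index], "O")

  # Na within cutoff of both endpoints; preferred over a water bridge
  fx <- bridge_fixture(na_pos = rbind(between_at(e1, e2, 2.4)),
                       waters = list(rbind(o, h1, h2)))
  expect_equal(detect_bridge(fx$frame, fx$sites)$bridge_kind, "NA")

  # nothing within cutoffs
  expect_null(detect_bridge(fx0$frame, fx0$sites))
})

test_that("occupancy is the plain event fraction with guarded edge cases", {
  expect_equal(occupancy(rep(c(TRUE, FALSE), c(70, 30))), 0.70)
  expect_equal(occupancy(rep(FALSE, 10)), 0)
  expect_error(occupancy(logical(0)), "empty")
  set.seed(41)
  flags <- runif(10000) < 0.7
  ci <- binom_ci99(0.7, 10000)
  expect_gte(occupancy(flags), ci[1])
  expect_lte(occupancy(flags), ci[2])
})

test_that("population summary tabulates modes and guards misalignment", {
  ens <- generate_ensemble(gb_minus_specs(), 80, seed = 33)
  sm <- build_site_map(ens$atoms)
  tl <- fitness_timeline(ens$frames, sm)
  md <- mode_timeline(ens$frames, sm)
  ps <- population_summary(tl, md)
  expect_equal(ps$n_frames[ps$label == "ALL"], 80)
  expect_equal(sum(ps$n_frames[ps$label != "ALL"]), 80)
  expect_equal(ps$n_active[ps$label == "ALL"], sum(tl$active))
  bad <- md; bad$frame_index <- rev(bad$frame_index)
  expect_error(population_summary(tl, bad), "misaligned")

  # single-mode ensemble: ALL row equals the mode row
  ens1 <- generate_ensemble(gb_minus_specs()[1:2], 30, seed = 5)
  sm1 <- build_site_map(ens1$atoms)
  ps1 <- population_summary(fitness_timeline(ens1$frames, sm1),
                            mode_timeline(ens1$frames, sm1))
  expect_equal(nrow(ps1), 2)
  expect_equal(ps1$active_fraction[1], ps1$active_fraction[2])
})

test_that("zero-active ensembles report all-zero fractions", {
  ens <- generate_ensemble(gb_minus_specs(0)[c(2, 4)], 40, seed = 6)
  sm <- build_site_map(ens$atoms)
  ps <- population_summary(fitness_timeline(ens$frames, sm),
                           mode_timeline(ens$frames, sm))
  expect_true(all(ps$active_fraction == 0))
})

test_that("density grids localize planted ions and reject bad parameters", {
  fx0 <- bridge_fixture()
  o2 <- fx0$frame$coords[fx0$sites$roles[["O2p"]], ]
  orp <- fx0$frame$coords[fx0$sites$roles[["proRP"]], ]
  mid <- (o2 + orp) / 2

  # ions always at one fixed point -> all mass in a single voxel
  fx <- bridge_fixture(na_pos = rbind(mid + c(1.3, 0.4, -0.7)))
  dg <- density_grid(rep(list(fx$frame), 5), fx$sites, "NA",
                     extent = 4, voxel = 0.5)
  expect_equal(sum(dg$grid > 0), 1)
  expect_equal(sum(dg$grid), 1)  # one ion per frame, frame-normalized

  # planted at the O2'/proRP midpoint -> argmax voxel at the grid centre
  fx <- bridge_fixture(na_pos = rbind(mid))
  dg <- density_grid(rep(list(fx$frame), 3), fx$sites, "NA",
                     extent = 4, voxel = 0.5)
  ctr <- which(dg$grid == max(dg$grid), arr.ind = TRUE)
  expect_true(all(ctr >= 8 & ctr <= 9))  # 16-voxel axis: centre pair

  expect_error(density_grid(list(fx$frame), fx$sites, "NA", extent = -1), "positive")
  expect_error(density_grid(list(fx$frame), fx$sites, "NA", voxel = 0), "positive")
})
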