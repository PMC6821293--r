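#' @title Synthetic active-site ensemble generator
#' @name synthetic_data
#' @description Generates labeled coordinate ensembles with the geometric and
#'   statistical structure the analyses assume: mixtures of frame states with
#'   specified in-line geometry distributions, bridging vs territorial sodium
#'   ions, a site-bound lead ion, bridging and bulk waters, and planted
#'   occupancy fractions — so every stage of the pipeline is testable without
#'   MD output. Purely geometric: no force field, no dynamics.
NULL

#' Distance distribution specification
#'
#' Truncated-normal draw used for all planted distances and angles. The
#' default lower truncation (0.5 A) prevents unphysical overlaps.
#'
#' @param mean,sd Mean and standard deviation (A, or degrees for angles).
#' @param lo,hi Truncation bounds.
#' @return List with class `dspec`.
#' @export
dspec <- function(mean, sd = 0, lo = 0.5, hi = Inf) {
  stopifnot(sd >= 0, lo < hi, mean >= lo, mean <= hi)
  structure(list(mean = mean, sd = sd, lo = lo, hi = hi), class = "dspec")
}

draw_dspec <- function(spec, what = "distance") {
  if (spec$sd == 0) return(spec$mean)
  for (i in 1:1000) {
    x <- stats::rnorm(1L, spec$mean, spec$sd)
    if (x >= spec$lo && x <= spec$hi) return(x)
  }
  stop("infeasible draw for ", what, ": truncation bounds [", spec$lo, ", ",
       spec$hi, "] not reachable from N(", spec$mean, ", ", spec$sd, ")")
}

#' Frame-state specification for the generator
#'
#' One mixture component: the distance/angle distributions realized in frames
#' of this state, its ion/water content, and the Bernoulli probabilities of
#' the planted motifs. All states mixed into one ensemble must agree on
#' `has_pb`, `n_na`, `n_waters` and `box_length` (one shared topology).
#'
#' @param name State name (recorded in the ground truth).
#' @param weight Mixture weight (normalized across the supplied states).
#' @param d_o2p_p In-line attack distance O2'...P ([dspec()]).
#' @param angle_inline In-line angle O2'-P-O5' in degrees ([dspec()],
#'   truncated to (0, 180]).
#' @param d_ho2p_n1 Nucleophile-activation distance HO2'...G13:N1.
#' @param d_na_o2p,d_na_prorp Bridging-sodium contact distances.
#' @param d_pb_prorp Lead to pro-R_P distance (used when `has_pb`).
#' @param d_pb_o5p Optional lead to O5' distance; when supplied the Pb is
#'   placed to satisfy both Pb distances simultaneously (transition-state-like
#'   placement), otherwise radially off pro-R_P.
#' @param d_bridge_h Water-bridge H...endpoint distances (G13:O6 / pro-S_P).
#' @param d_waterh_o5p Pb-bound-water H...O5' hydrogen-bond distance.
#' @param d_pb_water Pb...water-O coordination distance for that water.
#' @param has_pb Does the system contain the Pb2+ ion?
#' @param bridging_na_prob Probability a Na+ bridges O2' and pro-R_P.
#' @param water_bridge_prob Probability of the G13:O6 / pro-S_P solvent
#'   bridge.
#' @param pb_water_prob Probability of a Pb-coordinated water donating an
#'   H-bond to O5' (requires `has_pb`).
#' @param n_na Total sodium count (the first is the bridging candidate when
#'   `bridging_na_prob > 0`; the rest are territorial).
#' @param n_waters Total water count (bridge/Pb-bound waters are taken from
#'   this pool; the rest are bulk).
#' @param box_length Orthorhombic box edge (A).
#' @return List with class `state_spec`.
#' @export
state_spec <- function(name, weight = 1,
                       d_o2p_p = dspec(3.2, 0.1),
                       angle_inline = dspec(160, 6, lo = 1, hi = 180),
                       d_ho2p_n1 = dspec(2.0, 0.08),
                       d_na_o2p = dspec(2.4, 0.1),
                       d_na_prorp = dspec(2.4, 0.1),
                       d_pb_prorp = dspec(2.5, 0.1),
                       d_pb_o5p = NULL,
                       d_bridge_h = dspec(1.9, 0.1),
                       d_waterh_o5p = dspec(1.9, 0.1),
                       d_pb_water = dspec(2.7, 0.1),
                       has_pb = TRUE,
                       bridging_na_prob = 0,
                       water_bridge_prob = 0,
                       pb_water_prob = 0,
                       n_na = 5L, n_waters = 8L,
                       box_length = 30) {
  stopifnot(weight >= 0, bridging_na_prob >= 0, bridging_na_prob <= 1,
            water_bridge_prob >= 0, water_bridge_prob <= 1,
            pb_water_prob >= 0, pb_water_prob <= 1,
            n_na >= 0, n_waters >= 0, box_length > 0)
  if (bridging_na_prob > 0 && n_na < 1L) stop("bridging Na requires n_na >= 1")
  if (pb_water_prob > 0 && !has_pb) stop("pb_water_prob requires has_pb")
  need_w <- (water_bridge_prob > 0) + (pb_water_prob > 0)
  if (n_waters < need_w) stop("n_waters too small for the requested motifs")
  structure(list(name = name, weight = weight, d_o2p_p = d_o2p_p,
                 angle_inline = angle_inline, d_ho2p_n1 = d_ho2p_n1,
                 d_na_o2p = d_na_o2p, d_na_prorp = d_na_prorp,
                 d_pb_prorp = d_pb_prorp, d_pb_o5p = d_pb_o5p,
                 d_bridge_h = d_bridge_h, d_waterh_o5p = d_waterh_o5p,
                 d_pb_water = d_pb_water, has_pb = has_pb,
                 bridging_na_prob = bridging_na_prob,
                 water_bridge_prob = water_bridge_prob,
                 pb_water_prob = pb_water_prob,
                 n_na = as.integer(n_na), n_waters = as.integer(n_waters),
                 box_length = box_length),
            class = "state_spec")
}

# unit vector helpers -------------------------------------------------------
unitv <- function(v) v / sqrt(sum(v^2))

orthobasis <- function(e1) {
  a <- if (abs(e1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- unitv(a - sum(a * e1) * e1)
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  list(e2 = e2, e3 = e3)
}

random_unit <- function() {
  repeat {
    v <- stats::rnorm(3L)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# point at distance r1 from c1 and r2 from c2, azimuth phi about the c1-c2 axis
place_at_distances <- function(c1, r1, c2, r2, phi = stats::runif(1, 0, 2 * pi)) {
  dvec <- c2 - c1
  D <- sqrt(sum(dvec^2))
  if (D < 1e-9 || D > r1 + r2 || D < abs(r1 - r2)) return(NULL)
  u <- dvec / D
  a <- (r1^2 - r2^2 + D^2) / (2 * D)
  h2 <- r1^2 - a^2
  h <- sqrt(max(0, h2))
  b <- orthobasis(u)
  c1 + a * u + h * (cos(phi) * b$e2 + sin(phi) * b$e3)
}

#' Fixed active-site scaffold
#'
#' Deterministic minimal model of the catalytic centre holding every role the
#' site map needs: the scissile phosphate with its O5' leaving group and
#' pro-R/pro-S oxygens (tetrahedral geometry, P-O 1.48/1.60 A), the
#' nucleophile residue (O2', HO2'; per-frame positions overwritten by the
#' sampler), the general-base guanine Hoogsteen/N1 atoms (residue 13) and the
#' metal-pocket guanine O6/N7 (residue 6), centred in the box.
#'
#' @param box_length Orthorhombic box edge (A), default 30.
#' @return List: `atoms` (topology data.frame), `coords` (base coordinates),
#'   `anchors` (named list of derived geometry used by the sampler).
#' @export
make_scaffold <- function(box_length = 30) {
  ctr <- rep(box_length / 2, 3L)
  t3 <- 1 / sqrt(3)
  o5_dir <- c(t3, t3, t3)            # leaving-group arm of the tetrahedron
  rp_dir <- c(-t3, t3, -t3)          # pro-R_P
  sp_dir <- c(-t3, -t3, t3)          # pro-S_P
  p <- ctr
  o5 <- p + 1.60 * o5_dir
  orp <- p + 1.48 * rp_dir
  osp <- p + 1.48 * sp_dir
  o2_ideal <- p - 3.2 * o5_dir       # in-line approach region
  tdir <- unitv(c(1, -1, 0))
  n1 <- o2_ideal + 2.9 * tdir
  g13_o6 <- n1 + c(0.6, -0.6, 2.1)
  g6_o6 <- orp + 3.8 * unitv(rp_dir + c(0, 0.5, 0))
  g6_n7 <- g6_o6 + c(0, 1.4, 0.6)
  ho2 <- o2_ideal + 0.6 * unitv(n1 - o2_ideal)
  atoms <- data.frame(
    atom_index = 1:10,
    atom_name = c("O2'", "HO2'", "P", "O5'", "OP1", "OP2", "N1", "O6", "O6", "N7"),
    residue_name = c("G", "G", "G", "G", "G", "G", "G", "G", "G", "G"),
    residue_index = c(-1L, -1L, 1L, 1L, 1L, 1L, 13L, 13L, 6L, 6L),
    chain_id = rep("A", 10L),
    element = c("O", "H", "P", "O", "O", "O", "N", "O", "O", "N"),
    stringsAsFactors = FALSE
  )
  coords <- rbind(o2_ideal, ho2, p, o5, orp, osp, n1, g13_o6, g6_o6, g6_n7)
  rownames(coords) <- NULL
  list(atoms = atoms, coords = coords,
       anchors = list(center = ctr, o5_dir = o5_dir, rp_dir = rp_dir,
                      box_length = box_length))
}

build_topology <- function(spec) {
  sc <- make_scaffold(spec$box_length)
  atoms <- sc$atoms
  nxt <- nrow(atoms)
  add <- function(atoms, atom_name, residue_name, residue_index, element) {
    rbind(atoms, data.frame(atom_index = nrow(atoms) + 1L, atom_name = atom_name,
                            residue_name = residue_name,
                            residue_index = residue_index, chain_id = "A",
                            element = element, stringsAsFactors = FALSE))
  }
  if (spec$has_pb) atoms <- add(atoms, "PB", "PB", 101L, "PB")
  if (spec$n_na > 0L) {
    for (i in seq_len(spec$n_na)) atoms <- add(atoms, "NA", "NA", 200L + i, "NA")
  }
  if (spec$n_waters > 0L) {
    for (i in seq_len(spec$n_waters)) {
      res <- 300L + i
      atoms <- add(atoms, "O", "HOH", res, "O")
      atoms <- add(atoms, "H1", "HOH", res, "H")
      atoms <- add(atoms, "H2", "HOH", res, "H")
    }
  }
  list(atoms = atoms, scaffold = sc)
}

# steric guard: TRUE when pos keeps at least min_d from every row of pts
clear_of <- function(pos, pts, min_d = 2.0) {
  all(sqrt(colSums((t(pts) - pos)^2)) >= min_d)
}

# uniform point in the box at least `clearance` from every row of `site_xyz`
place_bulk <- function(site_xyz, box_length, clearance = 4.0) {
  for (i in 1:2000) {
    p <- stats::runif(3L, 0, box_length)
    d <- sqrt(colSums((t(site_xyz) - p)^2))
    if (all(d >= clearance)) return(p)
  }
  stop("cannot place a bulk particle with clearance ", clearance,
       " A in a box of ", box_length, " A")
}

#' Sample one frame from a state specification
#'
#' Realizes the state's scalar draws as 3D coordinates: the nucleophile pair
#' is placed so the drawn O2'...P distance, in-line angle and HO2'...N1
#' distance hold exactly; a bridging Na+ (Bernoulli `bridging_na_prob`) is
#' placed on the two-sphere intersection satisfying both of its drawn contact
#' distances (redrawn on infeasibility, bounded retries); the Pb2+ likewise;
#' bridge and Pb-bound waters per their probabilities; remaining ions and
#' waters are placed uniformly with a 4 A clearance from the site so they
#' cannot fake planted motifs. Ground-truth labels are computed from the
#' scalar draws against default [fitness_params()] thresholds (not from the
#' realized coordinates — agreement between the two is what the fidelity
#' tests measure).
#'
#' Uses the global R RNG; seed via [generate_ensemble()] or `set.seed()`.
#'
#' @param spec [state_spec()].
#' @param topo Optional pre-built topology (internal, for ensembles).
#' @param frame_index,time_ps Frame labels.
#' @return List: `frame` ([md_frame()]), `truth` (one-row data.frame:
#'   `frame_index`, `state`, `intended_active`, `intended_mode`,
#'   `intended_bridge`, plus the planted alpha/gamma draws).
#' @export
sample_frame <- function(spec, topo = NULL, frame_index = 1L, time_ps = NA_real_) {
  if (is.null(topo)) topo <- build_topology(spec)
  atoms <- topo$atoms
  sc <- topo$scaffold
  box <- sim_box(rep(spec$box_length, 3L))
  xyz <- matrix(NA_real_, nrow = nrow(atoms), ncol = 3L)
  xyz[1:10, ] <- sc$coords
  p <- sc$coords[3L, ]; o5 <- sc$coords[4L, ]
  orp <- sc$coords[5L, ]; osp <- sc$coords[6L, ]
  n1 <- sc$coords[7L, ]; g13o6 <- sc$coords[8L, ]

  # nucleophile pair; the drawn O2'-P distance, in-line angle and HO2'-N1
  # distance are realized exactly -- the azimuth of the nucleophile about the
  # P-O5' axis is a free nuisance parameter, re-drawn jointly with the
  # bridging-Na placement so the two-sphere intersection stays feasible
  d_o2 <- draw_dspec(spec$d_o2p_p, "O2'-P distance")
  theta <- draw_dspec(spec$angle_inline, "in-line angle")
  d_h <- draw_dspec(spec$d_ho2p_n1, "HO2'-N1 distance")
  e1 <- unitv(o5 - p)
  b <- orthobasis(e1)
  want_bridge <- spec$bridging_na_prob > 0 &&
    stats::runif(1) < spec$bridging_na_prob
  bridged <- FALSE
  r1 <- r2 <- NA_real_
  o2 <- NULL; na_pos <- NULL
  for (i in 1:500) {
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- cos(theta * pi / 180) * e1 +
      sin(theta * pi / 180) * (cos(phi) * b$e2 + sin(phi) * b$e3)
    cand <- p + d_o2 * dir
    if (!want_bridge) {
      o2 <- cand
      break
    }
    r1 <- draw_dspec(spec$d_na_o2p, "Na-O2' distance")
    r2 <- draw_dspec(spec$d_na_prorp, "Na-proRP distance")
    na_pos <- place_at_distances(cand, r1, orp, r2)
    # keep the ion sterically clear of the scaffold atoms it is not
    # coordinating (its two contact distances are the planted quantities)
    if (!is.null(na_pos) &&
        clear_of(na_pos, sc$coords[c(3, 4, 6, 7, 8, 9, 10), , drop = FALSE])) {
      o2 <- cand
      bridged <- TRUE
      break
    }
    na_pos <- NULL
  }
  if (is.null(o2)) {
    stop("infeasible bridging-Na placement: Na-O2' and Na-proRP draws never ",
         "satisfy the triangle inequality with the sampled in-line geometry")
  }
  xyz[1L, ] <- o2
  xyz[2L, ] <- n1 + d_h * unitv(o2 - n1)

  params <- fitness_params()
  site_rows <- 1:10
  idx_pb <- which(atoms$element == "PB")
  idx_na <- which(atoms$element == "NA")
  idx_wo <- which(atoms$residue_name == "HOH" & atoms$element == "O")

  # lead ion
  pb_pos <- NULL
  if (spec$has_pb) {
    if (!is.null(spec$d_pb_o5p)) {
      for (i in 1:200) {
        d1 <- draw_dspec(spec$d_pb_prorp, "Pb-proRP distance")
        d2 <- draw_dspec(spec$d_pb_o5p, "Pb-O5' distance")
        pb_pos <- place_at_distances(orp, d1, o5, d2)
        if (!is.null(pb_pos) &&
            clear_of(pb_pos, xyz[c(1:3, 6:10), , drop = FALSE])) break
        pb_pos <- NULL
      }
      if (is.null(pb_pos)) stop("infeasible Pb placement: Pb-proRP and Pb-O5' draws never satisfy the triangle inequality")
    } else {
      d1 <- draw_dspec(spec$d_pb_prorp, "Pb-proRP distance")
      pb_pos <- orp + d1 * unitv(orp - p)
    }
    xyz[idx_pb, ] <- pb_pos
  }

  # sodium ions
  if (spec$n_na > 0L) {
    na_done <- 0L
    if (bridged) {
      xyz[idx_na[1L], ] <- na_pos
      na_done <- 1L
    }
    while (na_done < spec$n_na) {
      na_done <- na_done + 1L
      xyz[idx_na[na_done], ] <- place_bulk(xyz[site_rows, ], spec$box_length)
    }
  }

  # waters
  w_done <- 0L
  bridge_drawn <- FALSE
  h1d <- h2d <- NA_real_
  place_water <- function(o_pos, toward1, toward2) {
    h1 <- o_pos + 0.96 * unitv(toward1 - o_pos)
    h2 <- o_pos + 0.96 * unitv(toward2 - o_pos)
    rbind(o_pos, h1, h2)
  }
  if (spec$water_bridge_prob > 0 && stats::runif(1) < spec$water_bridge_prob) {
    pos <- NULL
    for (i in 1:200) {
      h1d <- draw_dspec(spec$d_bridge_h, "bridge H-G13:O6 distance")
      h2d <- draw_dspec(spec$d_bridge_h, "bridge H-proSP distance")
      pos <- place_at_distances(g13o6, h1d + 0.96, osp, h2d + 0.96)
      if (!is.null(pos) &&
          clear_of(pos, xyz[c(1:5, 7, 9, 10), , drop = FALSE])) break
      pos <- NULL
    }
    if (is.null(pos)) stop("infeasible water-bridge placement between G13:O6 and proSP")
    w_done <- w_done + 1L
    o_row <- idx_wo[w_done]
    xyz[o_row:(o_row + 2L), ] <- place_water(pos, g13o6, osp)
    bridge_drawn <- TRUE
  }
  if (spec$pb_water_prob > 0 && stats::runif(1) < spec$pb_water_prob) {
    pos <- NULL
    for (i in 1:200) {
      dw <- draw_dspec(spec$d_pb_water, "Pb-water distance")
      hw <- draw_dspec(spec$d_waterh_o5p, "water H-O5' distance")
      pos <- place_at_distances(pb_pos, dw, o5, hw + 0.96)
      if (!is.null(pos) &&
          clear_of(pos, xyz[c(1:3, 5:10), , drop = FALSE])) break
      pos <- NULL
    }
    if (is.null(pos)) stop("infeasible Pb-bound-water placement")
    w_done <- w_done + 1L
    o_row <- idx_wo[w_done]
    away <- pos + random_unit()
    xyz[o_row:(o_row + 2L), ] <- place_water(pos, o5, away)
  }
  while (w_done < spec$n_waters) {
    w_done <- w_done + 1L
    o_row <- idx_wo[w_done]
    opos <- place_bulk(xyz[site_rows, ], spec$box_length)
    a1 <- opos + random_unit(); a2 <- opos + random_unit()
    xyz[o_row:(o_row + 2L), ] <- place_water(opos, a1, a2)
  }

  intended_active <- d_o2 <= params$alpha_dmax && theta >= params$alpha_angmin &&
    d_h <= params$gamma_dmax
  bridged_ok <- bridged && !is.na(r1) &&
    r1 <= params$inner_shell[["NA"]] && r2 <= params$inner_shell[["NA"]]
  intended_mode <- if (!spec$has_pb) "NA_ONLY" else
    if (bridged_ok) "NA_BRIDGE_PB" else "PB_ONLY"
  intended_bridge <- bridge_drawn && !is.na(h1d) &&
    h1d <= params$water_hbond_dmax && h2d <= params$water_hbond_dmax
  truth <- data.frame(frame_index = as.integer(frame_index), state = spec$name,
                      intended_active = intended_active,
                      intended_mode = intended_mode,
                      intended_bridge = intended_bridge,
                      alpha_d = d_o2, alpha_angle = theta, gamma_d = d_h,
                      stringsAsFactors = FALSE)
  list(frame = md_frame(xyz, box, frame_index = frame_index, time_ps = time_ps),
       truth = truth)
}

# largest-remainder allocation: exact planted fractions at any n
allocate_counts <- function(weights, n) {
  w <- weights / sum(weights)
  raw <- w * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  as.integer(base)
}

#' Generate a labeled synthetic ensemble
#'
#' Draws `n_frames` frames from a mixture of [state_spec()]s. State counts use
#' largest-remainder allocation on the mixture weights (so noise-free planted
#' fractions are recovered exactly), shuffled into a random frame order.
#' Fully reproducible from `seed`.
#'
#' @param specs List of [state_spec()]s agreeing on topology fields
#'   (`has_pb`, `n_na`, `n_waters`, `box_length`).
#' @param n_frames Number of frames (> 0).
#' @param seed Integer RNG seed.
#' @param dt_ps Time step between frames (ps), default 5.
#' @return List of class `synthetic_ensemble`: `atoms`, `frames`, `truth`
#'   (one row per frame), `seed`.
#' @export
generate_ensemble <- function(specs, n_frames, seed = 1L, dt_ps = 5) {
  if (inherits(specs, "state_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1L, n_frames > 0)
  for (f in c("has_pb", "n_na", "n_waters", "box_length")) {
    vals <- unique(vapply(specs, function(s) as.numeric(s[[f]]), numeric(1)))
    if (length(vals) != 1L) {
      stop("all states in one ensemble must share '", f,
           "' (one topology per ensemble); split into separate ensembles")
    }
  }
  wts <- vapply(specs, function(s) s$weight, numeric(1))
  if (sum(wts) <= 0) stop("mixture weights must have positive sum")
  set.seed(as.integer(seed))
  counts <- allocate_counts(wts, n_frames)
  state_seq <- sample(rep.int(seq_along(specs), counts))
  topo <- build_topology(specs[[1L]])
  frames <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    s <- sample_frame(specs[[state_seq[i]]], topo = topo, frame_index = i,
                      time_ps = (i - 1) * dt_ps)
    frames[[i]] <- s$frame
    truth[[i]] <- s$truth
  }
  structure(list(atoms = topo$atoms, frames = frames,
                 truth = do.call(rbind, truth), seed = as.integer(seed)),
            class = "synthetic_ensemble")
}

#' Ideal-gas null ensemble for RDF normalization checks
#'
#' One fixed reference atom at the box centre; `n_targets` point targets
#' placed uniformly in the box each frame. For this null model g(r) = 1 at
#' all distances (within sampling noise) and the coordination number follows
#' the closed form (4/3) pi r^3 rho.
#'
#' @param n_targets Targets per frame.
#' @param box_length Orthorhombic box edge (A).
#' @param n_frames Frames.
#' @param seed RNG seed.
#' @return List: `atoms`, `frames`, `ref_index` (= 1), `target_indices`.
#' @export
ideal_gas_ensemble <- function(n_targets, box_length = 20, n_frames = 100,
                               seed = 1L) {
  stopifnot(n_targets > 0, n_frames > 0)
  set.seed(as.integer(seed))
  atoms <- data.frame(
    atom_index = seq_len(n_targets + 1L),
    atom_name = c("REF", rep("AR", n_targets)),
    residue_name = c("REF", rep("AR", n_targets)),
    residue_index = seq_len(n_targets + 1L),
    chain_id = "A",
    element = c("X", rep("AR", n_targets)),
    stringsAsFactors = FALSE
  )
  box <- sim_box(rep(box_length, 3L))
  ctr <- rep(box_length / 2, 3L)
  frames <- lapply(seq_len(n_frames), function(i) {
    tg <- matrix(stats::runif(3L * n_targets, 0, box_length), ncol = 3L)
    md_frame(rbind(ctr, tg), box, frame_index = i)
  })
  list(atoms = atoms, frames = frames, ref_index = 1L,
       target_indices = seq_len(n_targets) + 1L)
}

#' Study-condition state mixture: deprotonated general base with Pb2+
#'
#' Default mixture emulating the reported deprotonated-general-base system
#' containing the active-site Pb2+: binding-mode shares follow the reported
#' trajectory durations (bridging-Na cluster 1.5 us vs Pb-only 0.49 us), the
#' active fraction within each mode follows the reported populations (56%
#' with the bridging Na+, ~1% without), and the G13:O6 / pro-S_P solvent
#' bridge is planted at 70% occupancy in the bridged states. Active-state
#' geometry draws sit well inside the thresholds (O2'...P 3.15 +/- 0.08 A,
#' angle 162 +/- 6 deg, HO2'...N1 1.95 +/- 0.08 A) and inactive draws well
#' outside, so planted labels are crossed only with negligible tail
#' probability.
#'
#' @param sigma Global scale factor on all geometric noise (0 gives exact,
#'   noise-free planting).
#' @return List of [state_spec()]s.
#' @export
gb_minus_specs <- function(sigma = 1) {
  share_bridge <- 1.5 / 1.99   # reported 1.5 us of 1.99 us with Pb
  act <- function(nm, w, bridge) state_spec(
    nm, weight = w,
    d_o2p_p = dspec(3.15, 0.08 * sigma),
    angle_inline = dspec(162, 6 * sigma, lo = 1, hi = 180),
    d_ho2p_n1 = dspec(1.95, 0.08 * sigma),
    d_na_o2p = dspec(2.4, 0.1 * sigma), d_na_prorp = dspec(2.4, 0.1 * sigma),
    d_pb_prorp = dspec(2.5, 0.1 * sigma),
    bridging_na_prob = if (bridge) 1 else 0,
    water_bridge_prob = if (bridge) 0.70 else 0.20,
    has_pb = TRUE)
  inact <- function(nm, w, bridge) state_spec(
    nm, weight = w,
    d_o2p_p = dspec(4.6, 0.3 * sigma, lo = 3.7),
    angle_inline = dspec(115, 10 * sigma, lo = 1, hi = 138),
    d_ho2p_n1 = dspec(3.2, 0.3 * sigma, lo = 2.5),
    d_na_o2p = dspec(2.4, 0.1 * sigma), d_na_prorp = dspec(2.4, 0.1 * sigma),
    d_pb_prorp = dspec(2.5, 0.1 * sigma),
    bridging_na_prob = if (bridge) 1 else 0,
    water_bridge_prob = if (bridge) 0.70 else 0.20,
    has_pb = TRUE)
  list(
    act("na_bridge_active", share_bridge * 0.56, TRUE),
    inact("na_bridge_inactive", share_bridge * 0.44, TRUE),
    act("pb_only_active", (1 - share_bridge) * 0.01, FALSE),
    inact("pb_only_inactive", (1 - share_bridge) * 0.99, FALSE)
  )
}

#' Study-condition state mixture: deprotonated general base, sodium only
#'
#' Companion system without the Pb2+ ion (separate topology, hence a separate
#' ensemble): active state planted at 0.5% (reported "<1%"), with the active
#' frames accompanied by a bridging Na+ as observed.
#'
#' @inheritParams gb_minus_specs
#' @return List of [state_spec()]s.
#' @export
na_only_specs <- function(sigma = 1) {
  list(
    state_spec("na_only_active", weight = 0.005,
               d_o2p_p = dspec(3.15, 0.08 * sigma),
               angle_inline = dspec(162, 6 * sigma, lo = 1, hi = 180),
               d_ho2p_n1 = dspec(1.95, 0.08 * sigma),
               has_pb = FALSE, bridging_na_prob = 1,
               water_bridge_prob = 0.30),
    state_spec("na_only_inactive", weight = 0.995,
               d_o2p_p = dspec(4.6, 0.3 * sigma, lo = 3.7),
               angle_inline = dspec(115, 10 * sigma, lo = 1, hi = 138),
               d_ho2p_n1 = dspec(3.2, 0.3 * sigma, lo = 2.5),
               has_pb = FALSE, bridging_na_prob = 0,
               water_bridge_prob = 0.30)
  )
}
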