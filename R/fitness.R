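#' Catalytic-strategy thresholds and grading parameters
#'
#' Thresholds for the four catalytic-strategy criteria and the ideal values
#' used by the 0-1 graded fitness ramps. Defaults: in-line attack (alpha)
#' passes when d(O2',P) <= 3.5 A and the O2'-P-O5' angle is >= 140 deg;
#' nucleophile activation (gamma) when d(HO2', G13:N1) <= 2.2 A; phosphate
#' charge stabilization (beta) when a metal ion makes an inner-sphere contact
#' with a non-bridging phosphoryl oxygen (Na-O 3.1 A, Pb-O 3.0 A, the
#' conventional first RDF minima for these ions); leaving-group stabilization
#' (delta) distinguishes first-shell (inner-sphere), second-shell (up to 5.6
#' A) and metal-bound-water hydrogen-bond (H...O5' <= 2.2 A) contacts.
#' Hydrogen bonds are distance-only criteria on the H...acceptor distance.
#'
#' Graded scores are linear ramps from the pass threshold (score 0) to an
#' ideal value (score 1): 3.0 A and 180 deg for alpha (the two ramps
#' multiply), 1.8 A for gamma, 2.0 A for the beta coordination ramp. A frame
#' exactly at a threshold therefore passes with score 0.
#'
#' @param alpha_dmax,alpha_angmin Alpha distance (A) / angle (deg) thresholds.
#' @param gamma_dmax Gamma H...N1 threshold (A).
#' @param inner_shell Named inner-sphere cutoffs per ion species (A).
#' @param second_shell_max Outer edge of the second solvation shell (A).
#' @param water_hbond_dmax Hydrogen-bond H...acceptor cutoff (A).
#' @param grade_ideal List of ideal values for the ramps: `alpha_d`,
#'   `alpha_ang`, `gamma_d`.
#' @param site_roles Roles defining "in the active site" for binding-mode
#'   classification; an ion within `second_shell_max` of any of them is
#'   in-site.
#' @return Object of class `fitness_params`.
#' @export
fitness_params <- function(alpha_dmax = 3.5, alpha_angmin = 140,
                           gamma_dmax = 2.2,
                           inner_shell = c("NA" = 3.1, "PB" = 3.0),
                           second_shell_max = 5.6,
                           water_hbond_dmax = 2.2,
                           grade_ideal = list(alpha_d = 3.0, alpha_ang = 180,
                                              gamma_d = 1.8),
                           site_roles = c("proRP", "proSP", "O5p", "G6_O6")) {
  stopifnot(alpha_dmax > 0, gamma_dmax > 0, second_shell_max > 0,
            water_hbond_dmax > 0, all(inner_shell > 0),
            alpha_angmin > 0, alpha_angmin < 180,
            all(inner_shell < second_shell_max),
            grade_ideal$alpha_d < alpha_dmax,
            grade_ideal$alpha_ang > alpha_angmin,
            grade_ideal$gamma_d < gamma_dmax)
  structure(list(alpha_dmax = alpha_dmax, alpha_angmin = alpha_angmin,
                 gamma_dmax = gamma_dmax, inner_shell = inner_shell,
                 second_shell_max = second_shell_max,
                 water_hbond_dmax = water_hbond_dmax,
                 grade_ideal = grade_ideal, site_roles = site_roles),
            class = "fitness_params")
}

role_xyz <- function(frame, sites, role) {
  idx <- sites$roles[[role]]
  if (is.null(idx) || is.na(idx)) stop("role ", role, " not resolved in site map")
  frame$coords[idx, ]
}

species_xyz <- function(frame, sites, species) {
  idx <- sites$species[[species]]
  if (is.null(idx) || length(idx) == 0L) {
    return(matrix(numeric(0), ncol = 3L))
  }
  frame$coords[idx, , drop = FALSE]
}

#' In-line attack (alpha) fitness of one frame
#'
#' @param frame [md_frame()].
#' @param sites [build_site_map()] result.
#' @param params [fitness_params()].
#' @return List: `pass`, `score` (0-1), and the measured `d` (A) and
#'   `angle` (deg).
#' @export
alpha_fitness <- function(frame, sites, params = fitness_params()) {
  p <- role_xyz(frame, sites, "P_scissile")
  o2 <- role_xyz(frame, sites, "O2p")
  o5 <- role_xyz(frame, sites, "O5p")
  d <- min_image_distance(o2, p, frame$box)
  ang <- angle_deg(o2, p, o5, frame$box)
  pass <- leq(d, params$alpha_dmax) && geq(ang, params$alpha_angmin)
  score <- if (!pass) 0 else {
    clamp01((params$alpha_dmax - d) /
              (params$alpha_dmax - params$grade_ideal$alpha_d)) *
      clamp01((ang - params$alpha_angmin) /
                (params$grade_ideal$alpha_ang - params$alpha_angmin))
  }
  list(pass = pass, score = score, d = d, angle = ang)
}

#' Nucleophile activation (gamma) fitness of one frame
#'
#' Hydrogen-bond readiness of the 2'-OH proton toward the general base
#' (G13:N1). Only defined for protonated-nucleophile ensembles; call with a
#' site map built with `gamma = FALSE` disabled analyses instead.
#'
#' @inheritParams alpha_fitness
#' @return List: `pass`, `score`, `d`.
#' @export
gamma_fitness <- function(frame, sites, params = fitness_params()) {
  if (!sites$gamma_enabled) {
    stop("gamma analysis disabled for this ensemble (no HO2' atom)")
  }
  h <- role_xyz(frame, sites, "HO2p")
  n1 <- role_xyz(frame, sites, "G13_N1")
  d <- min_image_distance(h, n1, frame$box)
  pass <- leq(d, params$gamma_dmax)
  score <- if (!pass) 0 else
    clamp01((params$gamma_dmax - d) /
              (params$gamma_dmax - params$grade_ideal$gamma_d))
  list(pass = pass, score = score, d = d)
}

#' Phosphate charge stabilization (beta) fitness of one frame
#'
#' Passes when any metal ion (Na+ or Pb2+) makes an inner-sphere contact with
#' either non-bridging phosphoryl oxygen; the score is the best linear ramp
#' from the species cutoff (0) down to 2.0 A (1) over qualifying contacts.
#'
#' @inheritParams alpha_fitness
#' @return List: `pass`, `score`, `d_min` (closest qualifying contact, A).
#' @export
beta_fitness <- function(frame, sites, params = fitness_params()) {
  npos <- rbind(role_xyz(frame, sites, "proRP"), role_xyz(frame, sites, "proSP"))
  best <- 0; pass <- FALSE; dmin <- NA_real_
  for (sp in c("NA", "PB")) {
    ions <- species_xyz(frame, sites, sp)
    if (nrow(ions) == 0L) next
    cut <- params$inner_shell[[sp]]
    for (k in 1:2) {
      d <- min_image_distance(npos[k, ], ions, frame$box)
      q <- leq(d, cut)
      if (any(q)) {
        pass <- TRUE
        dmin <- min(dmin, d[q], na.rm = TRUE)
        best <- max(best, clamp01((cut - d[q]) / (cut - 2.0)))
      }
    }
  }
  list(pass = pass, score = if (pass) best else 0, d_min = dmin)
}

#' Leaving-group stabilization (delta) fitness of one frame
#'
#' Two readouts: the solvation shell of the closest metal ion to the O5'
#' leaving group (`first` within the inner-sphere cutoff, `second` within
#' `second_shell_max`, else `none`), and whether a Pb-coordinated water
#' donates a hydrogen bond to O5' (H...O5' within `water_hbond_dmax` with
#' that water's oxygen inner-sphere to a Pb). Score: 1 for first shell, 0.5
#' for second shell, raised to 0.75 when the water criterion holds (a
#' presentation-layer weighting; population statistics use only the flags).
#'
#' @inheritParams alpha_fitness
#' @return List: `shell` (`"none"|"second"|"first"`), `water_pass`, `score`.
#' @export
delta_fitness <- function(frame, sites, params = fitness_params()) {
  o5 <- role_xyz(frame, sites, "O5p")
  shell <- "none"
  for (sp in c("NA", "PB")) {
    ions <- species_xyz(frame, sites, sp)
    if (nrow(ions) == 0L) next
    d <- min_image_distance(o5, ions, frame$box)
    if (any(leq(d, params$inner_shell[[sp]]))) {
      shell <- "first"
    } else if (shell == "none" && any(leq(d, params$second_shell_max))) {
      shell <- "second"
    }
  }
  water_pass <- FALSE
  h_idx <- sites$species$WATER_H
  pb <- species_xyz(frame, sites, "PB")
  if (length(h_idx) > 0L && nrow(pb) > 0L) {
    dh <- min_image_distance(o5, frame$coords[h_idx, , drop = FALSE], frame$box)
    near <- which(leq(dh, params$water_hbond_dmax))
    for (j in near) {
      o_idx <- sites$water_h_parent[[as.character(h_idx[j])]]
      dpo <- min_image_distance(frame$coords[o_idx, ], pb, frame$box)
      if (any(leq(dpo, params$inner_shell[["PB"]]))) {
        water_pass <- TRUE
        break
      }
    }
  }
  score <- switch(shell, first = 1, second = 0.5, none = 0)
  if (water_pass) score <- max(score, 0.75)
  list(shell = shell, water_pass = water_pass, score = score)
}

#' Active-state classification
#'
#' A frame is active when it is simultaneously poised for in-line attack
#' (alpha pass) and for nucleophile activation by the general base (gamma
#' pass). Defined only for ensembles with a protonated nucleophile.
#'
#' @param alpha_pass,gamma_pass Logical flags from [alpha_fitness()] /
#'   [gamma_fitness()], or a single list with `$alpha_pass` and `$gamma_pass`.
#' @return Logical.
#' @export
classify_active <- function(alpha_pass, gamma_pass = NULL) {
  if (is.list(alpha_pass)) {
    gamma_pass <- alpha_pass$gamma_pass
    alpha_pass <- alpha_pass$alpha_pass
  }
  if (is.null(gamma_pass) || anyNA(gamma_pass)) {
    stop("active state undefined without a gamma evaluation")
  }
  alpha_pass & gamma_pass
}

#' Per-frame catalytic-strategy timeline of an ensemble
#'
#' Evaluates all enabled strategies for every frame. Stateless per frame:
#' permuting the input frames permutes the rows identically.
#'
#' @param frames List of [md_frame()] sharing one topology.
#' @param sites [build_site_map()] result.
#' @param params [fitness_params()].
#' @return data.frame keyed by `frame_index` with measured geometry, pass
#'   flags, 0-1 scores and the `active` flag (NA when gamma is disabled).
#' @export
fitness_timeline <- function(frames, sites, params = fitness_params()) {
  n <- length(frames)
  gamma_on <- sites$gamma_enabled
  out <- data.frame(
    frame_index = integer(n), time_ps = numeric(n),
    alpha_d = numeric(n), alpha_angle = numeric(n),
    alpha_pass = logical(n), alpha_score = numeric(n),
    beta_pass = logical(n), beta_score = numeric(n),
    gamma_d = numeric(n), gamma_pass = logical(n), gamma_score = numeric(n),
    delta_shell = character(n), delta_water = logical(n),
    delta_score = numeric(n), active = logical(n)
  )
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    a <- tryCatch(alpha_fitness(fr, sites, params), error = function(e)
      stop("frame ", fr$frame_index, ": ", conditionMessage(e)))
    b <- beta_fitness(fr, sites, params)
    d <- delta_fitness(fr, sites, params)
    g <- if (gamma_on) gamma_fitness(fr, sites, params) else
      list(pass = NA, score = NA_real_, d = NA_real_)
    out$frame_index[i] <- fr$frame_index
    out$time_ps[i] <- fr$time_ps
    out$alpha_d[i] <- a$d; out$alpha_angle[i] <- a$angle
    out$alpha_pass[i] <- a$pass; out$alpha_score[i] <- a$score
    out$beta_pass[i] <- b$pass; out$beta_score[i] <- b$score
    out$gamma_d[i] <- g$d; out$gamma_pass[i] <- g$pass
    out$gamma_score[i] <- g$score
    out$delta_shell[i] <- d$shell; out$delta_water[i] <- d$water_pass
    out$delta_score[i] <- d$score
    out$active[i] <- if (gamma_on) (a$pass && g$pass) else NA
  }
  out
}
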