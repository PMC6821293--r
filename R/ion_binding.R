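#' Detect a bridging sodium ion
#'
#' A bridging Na+ makes simultaneous inner-sphere contact with both the
#' nucleophile O2' and the pro-R_P oxygen of the scissile phosphate. Among
#' qualifying ions the one minimizing the larger of its two contact distances
#' is returned; ties break to the lower atom index (deterministic output).
#'
#' @param frame [md_frame()].
#' @param sites [build_site_map()] result.
#' @param params [fitness_params()].
#' @return The bridging Na atom index, or `NA_integer_` if none qualifies.
#' @export
detect_bridging_na <- function(frame, sites, params = fitness_params()) {
  na_idx <- sites$species[["NA"]]
  if (is.null(na_idx) || length(na_idx) == 0L) return(NA_integer_)
  cut <- params$inner_shell[["NA"]]
  ions <- frame$coords[na_idx, , drop = FALSE]
  d1 <- min_image_distance(role_xyz(frame, sites, "O2p"), ions, frame$box)
  d2 <- min_image_distance(role_xyz(frame, sites, "proRP"), ions, frame$box)
  q <- which(leq(d1, cut) & leq(d2, cut))
  if (length(q) == 0L) return(NA_integer_)
  worst <- pmax(d1[q], d2[q])
  best <- q[order(worst, na_idx[q])][1L]
  na_idx[best]
}

#' Classify the active-site metal binding mode of one frame
#'
#' Modes follow the clustering used for the deprotonated-general-base
#' ensembles: `NA_ONLY` (no Pb2+ in the system), `PB_ONLY` (Pb2+ in the
#' active site, no bridging Na+), `NA_BRIDGE_PB` (Pb2+ in site plus a Na+
#' bridging O2' and pro-R_P), and `OTHER` (Pb2+ present in the system but
#' outside the site). "In the site" means within `second_shell_max` of any
#' of the roles in `params$site_roles`.
#'
#' @inheritParams detect_bridging_na
#' @return List: `label`, `bridging_na_index` (`NA_integer_` when absent),
#'   `pb_in_site`.
#' @export
classify_binding_mode <- function(frame, sites, params = fitness_params()) {
  pb_idx <- sites$species[["PB"]]
  if (is.null(pb_idx) || length(pb_idx) == 0L) {
    return(list(label = "NA_ONLY", bridging_na_index = NA_integer_,
                pb_in_site = FALSE))
  }
  pb <- frame$coords[pb_idx, , drop = FALSE]
  pb_in_site <- FALSE
  for (role in params$site_roles) {
    d <- min_image_distance(role_xyz(frame, sites, role), pb, frame$box)
    if (any(leq(d, params$second_shell_max))) {
      pb_in_site <- TRUE
      break
    }
  }
  if (!pb_in_site) {
    return(list(label = "OTHER", bridging_na_index = NA_integer_,
                pb_in_site = FALSE))
  }
  br <- detect_bridging_na(frame, sites, params)
  list(label = if (is.na(br)) "PB_ONLY" else "NA_BRIDGE_PB",
       bridging_na_index = br, pb_in_site = TRUE)
}

#' Per-frame binding-mode timeline
#'
#' @param frames List of [md_frame()].
#' @inheritParams detect_bridging_na
#' @return data.frame: `frame_index`, `label`, `bridging_na_index`,
#'   `pb_in_site`.
#' @export
mode_timeline <- function(frames, sites, params = fitness_params()) {
  rows <- lapply(frames, function(fr) {
    m <- classify_binding_mode(fr, sites, params)
    data.frame(frame_index = fr$frame_index, label = m$label,
               bridging_na_index = m$bridging_na_index,
               pb_in_site = m$pb_in_site)
  })
  do.call(rbind, rows)
}

#' Detect a solvent or sodium bridge between two sites
#'
#' A Na bridge is a sodium within the Na inner-sphere cutoff of both
#' endpoints. A water bridge is a water with one hydrogen within the
#' hydrogen-bond cutoff of one endpoint and a hydrogen (possibly the other
#' one) within the cutoff of the second endpoint — donor geometry on both
#' sides, distance-only criterion. When both exist, the Na bridge is
#' reported.
#'
#' @inheritParams detect_bridging_na
#' @param endpoints Character pair of role names, default the guanine O6 of
#'   the general base and the pro-S_P oxygen.
#' @return `NULL` when no bridge exists, else a list: `frame_index`,
#'   `bridge_kind` (`"NA"` or `"WATER"`), `mediator_index` (Na atom or
#'   water O atom), `endpoints`.
#' @export
detect_bridge <- function(frame, sites, endpoints = c("G13_O6", "proSP"),
                          params = fitness_params()) {
  stopifnot(length(endpoints) == 2L)
  e1 <- role_xyz(frame, sites, endpoints[1L])
  e2 <- role_xyz(frame, sites, endpoints[2L])
  na_idx <- sites$species[["NA"]]
  if (!is.null(na_idx) && length(na_idx) > 0L) {
    cut <- params$inner_shell[["NA"]]
    ions <- frame$coords[na_idx, , drop = FALSE]
    d1 <- min_image_distance(e1, ions, frame$box)
    d2 <- min_image_distance(e2, ions, frame$box)
    q <- which(leq(d1, cut) & leq(d2, cut))
    if (length(q) > 0L) {
      best <- q[order(pmax(d1[q], d2[q]), na_idx[q])][1L]
      return(list(frame_index = frame$frame_index, bridge_kind = "NA",
                  mediator_index = na_idx[best], endpoints = endpoints))
    }
  }
  h_idx <- sites$species$WATER_H
  if (length(h_idx) > 0L) {
    hw <- frame$coords[h_idx, , drop = FALSE]
    cut <- params$water_hbond_dmax
    d1 <- min_image_distance(e1, hw, frame$box)
    d2 <- min_image_distance(e2, hw, frame$box)
    parent <- sites$water_h_parent[as.character(h_idx)]
    waters <- unique(parent)
    for (w in waters) {
      mine <- parent == w
      if (any(leq(d1[mine], cut)) && any(leq(d2[mine], cut))) {
        return(list(frame_index = frame$frame_index, bridge_kind = "WATER",
                    mediator_index = w, endpoints = endpoints))
      }
    }
  }
  NULL
}

#' Occupancy of a per-frame event series
#'
#' @param flags Logical vector, one entry per frame.
#' @return Fraction of `TRUE` frames, in `[0, 1]`.
#' @export
occupancy <- function(flags) {
  if (length(flags) == 0L) stop("empty series: occupancy undefined")
  if (anyNA(flags)) stop("NA in event series")
  mean(flags)
}

#' Active-state population per binding mode
#'
#' Joins a fitness timeline with per-frame binding-mode labels and tabulates,
#' per mode and pooled (`ALL` row), the frame count, active count and active
#' fraction.
#'
#' @param timeline Output of [fitness_timeline()] (must have a non-NA
#'   `active` column).
#' @param modes Output of [mode_timeline()] over the same frames.
#' @return data.frame: `label`, `n_frames`, `n_active`, `active_fraction`.
#'   Fractions are exact here; TSV output rounds to 0.1%.
#' @export
population_summary <- function(timeline, modes) {
  if (nrow(timeline) != nrow(modes) ||
      !all(timeline$frame_index == modes$frame_index)) {
    stop("timeline and modes are misaligned by frame_index")
  }
  if (anyNA(timeline$active)) stop("active flags undefined (gamma disabled?)")
  labs <- sort(unique(modes$label))
  rows <- lapply(labs, function(l) {
    sel <- modes$label == l
    data.frame(label = l, n_frames = sum(sel),
               n_active = sum(timeline$active[sel]),
               active_fraction = mean(timeline$active[sel]))
  })
  rows <- do.call(rbind, rows)
  rbind(rows,
        data.frame(label = "ALL", n_frames = nrow(modes),
                   n_active = sum(timeline$active),
                   active_fraction = mean(timeline$active)))
}

#' Ion occupancy on a voxel grid around the active site
#'
#' Counts occurrences of an ion species on a cubic voxel grid in a local,
#' lab-axis-aligned frame centred on the midpoint of two roles (by default
#' O2' and pro-R_P, the end points of the bridging-ion motif). Counts are
#' normalized per frame.
#'
#' @param frames List of [md_frame()].
#' @param sites [build_site_map()] result.
#' @param species `"NA"` or `"PB"`.
#' @param center_roles Two role names whose midpoint defines the grid origin.
#' @param extent Half-width of the grid (A); the grid spans `[-extent,
#'   extent)` on each axis.
#' @param voxel Voxel edge (A).
#' @return List of class `density_grid`: `grid` (3D array of mean counts per
#'   frame), `origin`, `voxel`, `extent`, `n_frames`.
#' @export
density_grid <- function(frames, sites, species = "NA",
                         center_roles = c("O2p", "proRP"),
                         extent = 8, voxel = 0.5) {
  if (extent <= 0 || voxel <= 0) stop("extent and voxel must be positive")
  nb <- as.integer(ceiling(2 * extent / voxel))
  grid <- array(0, dim = c(nb, nb, nb))
  for (fr in frames) {
    c1 <- role_xyz(fr, sites, center_roles[1L])
    c2 <- role_xyz(fr, sites, center_roles[2L])
    center <- c1 + 0.5 * drop(min_image_disp(c1, c2, fr$box))
    pts <- species_xyz(fr, sites, species)
    if (nrow(pts) == 0L) next
    rel <- min_image_disp(center, pts, fr$box)
    keep <- rowSums(abs(rel) < extent) == 3L
    rel <- rel[keep, , drop = FALSE]
    if (nrow(rel) == 0L) next
    ix <- floor((rel + extent) / voxel) + 1L
    ix[ix > nb] <- nb
    for (r in seq_len(nrow(ix))) {
      grid[ix[r, 1L], ix[r, 2L], ix[r, 3L]] <-
        grid[ix[r, 1L], ix[r, 2L], ix[r, 3L]] + 1
    }
  }
  structure(list(grid = grid / length(frames), origin = rep(-extent, 3L),
                 voxel = voxel, extent = extent, n_frames = length(frames)),
            class = "density_grid")
}

#' Write a density grid as a plain-text voxel table
#'
#' Header comments record origin, voxel size and extent; rows are
#' `ix iy iz count` for non-empty voxels.
#'
#' @param dg [density_grid()] result.
#' @param path Output path.
#' @export
write_density_grid <- function(dg, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# origin %s", paste(sprintf("%.4f", dg$origin), collapse = " ")),
               sprintf("# voxel %.4f", dg$voxel),
               sprintf("# extent %.4f", dg$extent),
               sprintf("# n_frames %d", dg$n_frames),
               "ix\tiy\tiz\tcount"), con)
  nz <- which(dg$grid > 0, arr.ind = TRUE)
  if (nrow(nz) > 0L) {
    nz <- nz[order(nz[, 1L], nz[, 2L], nz[, 3L]), , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%d\t%.6f", nz[, 1L], nz[, 2L], nz[, 3L],
                       dg$grid[nz]), con)
  }
  invisible(path)
}
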