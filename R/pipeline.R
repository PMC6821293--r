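#' Generate a synthetic ensemble and write it to disk
#'
#' Runs [generate_ensemble()] and writes the trajectory table, the topology,
#' the ground-truth table and a provenance manifest into `out_dir`. Reruns
#' with the same spec and seed are byte-identical.
#'
#' @param specs List of [state_spec()]s (or a single one).
#' @param n_frames Number of frames (> 0).
#' @param seed Integer RNG seed.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the written paths and the ensemble.
#' @export
run_simulate <- function(specs, n_frames, seed, out_dir) {
  if (n_frames <= 0) stop("n_frames must be positive")
  ens <- generate_ensemble(specs, n_frames, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec_txt <- paste(deparse(specs), collapse = "\n")
  spec_hash <- hash_string(spec_txt)
  traj <- file.path(out_dir, "trajectory.tsv")
  write_traj_table(ens$frames, traj,
                   comments = c(sprintf("seed %d", as.integer(seed)),
                                sprintf("n_frames %d", as.integer(n_frames)),
                                sprintf("spec_hash %s", spec_hash)))
  topo <- file.path(out_dir, "topology.tsv")
  write_topology_tsv(ens$atoms, topo)
  truth <- file.path(out_dir, "truth.tsv")
  write_tsv(ens$truth, truth)
  manifest <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(list(
    kind = "simulate",
    seed = as.integer(seed), n_frames = as.integer(n_frames),
    states = vapply(if (inherits(specs, "state_spec")) list(specs) else specs,
                    function(s) s$name, character(1)),
    spec_hash = spec_hash,
    package_version = as.character(utils::packageVersion("dzfit"))
  ), manifest)
  invisible(list(trajectory = traj, topology = topo, truth = truth,
                 manifest = manifest, ensemble = ens))
}

hash_string <- function(txt) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}

load_input <- function(dir) {
  topo_path <- file.path(dir, "topology.tsv")
  traj_path <- file.path(dir, "trajectory.tsv")
  for (p in c(topo_path, traj_path)) {
    if (!file.exists(p)) stop("input missing: ", p)
  }
  atoms <- read_topology_tsv(topo_path)
  frames <- read_traj_table(traj_path, n_atoms = nrow(atoms))
  list(atoms = atoms, frames = frames, topology = topo_path,
       trajectory = traj_path, name = basename(normalizePath(dir)))
}

default_run_config <- function() {
  list(
    inputs = character(0),
    naming = NULL,             # NULL -> default_site_naming()
    params = NULL,             # NULL -> fitness_params()
    analyses = list(fitness = TRUE, modes = TRUE, bridges = TRUE),
    bridge_endpoints = c("G13_O6", "proSP"),
    rdf = list(),              # list of list(name, ref_role, target_species, r_max, bin)
    density = NULL,            # list(species, extent, voxel)
    drop_first = 0L,
    out_dir = "."
  )
}

#' Run the full geometric analysis over one or more ensembles
#'
#' Orchestrates the per-frame analyses over one or several ensemble
#' directories (as written by [run_simulate()], or assembled by hand from a
#' `topology.tsv` / `trajectory.tsv` pair), pools them with per-source
#' bookkeeping, and writes the report set: fitness timeline, binding-mode
#' timeline, population summary, bridge occupancies, requested RDFs and ion
#' density grids, plus a provenance manifest. All outputs are fixed-precision
#' TSVs, byte-identical across reruns on identical inputs.
#'
#' @param config A list (or path to a YAML file) with entries: `inputs`
#'   (character vector of ensemble directories), `naming` (site naming
#'   config, default [default_site_naming()]; set `naming$gamma = FALSE` for
#'   deprotonated-nucleophile ensembles — the population summary is then
#'   skipped since the active state is undefined), `params` (arguments to
#'   [fitness_params()]), `analyses` (logical toggles `fitness`, `modes`,
#'   `bridges`), `bridge_endpoints`, `rdf` (list of selections: `name`,
#'   `ref_role`, `target_species`, `r_max`, optional `bin`), `density`
#'   (optional: `species`, `extent`, `voxel`), `drop_first` (equilibration
#'   frames dropped from the head of every input, default 0), `out_dir`.
#' @return Invisibly, a named list of written file paths.
#' @export
run_analyze <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- default_run_config()
  for (nm in names(config)) {
    # top-level replacement; `analyses` toggles merge key-wise (rdf selections
    # are unnamed lists, which modifyList would silently drop)
    if (nm == "analyses") {
      cfg$analyses <- utils::modifyList(cfg$analyses, config$analyses)
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  if (length(cfg$inputs) == 0L) stop("config error: no inputs given")
  naming <- if (is.null(cfg$naming)) default_site_naming() else cfg$naming
  params <- if (is.null(cfg$params)) fitness_params() else
    if (inherits(cfg$params, "fitness_params")) cfg$params else
      do.call(fitness_params, cfg$params)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  on_fail <- function(e) {
    unlink(written)
    stop("analysis failed: ", conditionMessage(e), call. = FALSE)
  }
  tryCatch({
    inputs <- lapply(cfg$inputs, load_input)
    nm <- vapply(inputs, `[[`, character(1), "name")
    if (anyDuplicated(nm)) nm <- make.unique(nm)
    for (i in seq_along(inputs)) inputs[[i]]$name <- nm[i]

    # validate naming against every topology before any computation
    sites <- lapply(inputs, function(inp) build_site_map(inp$atoms, naming))

    per <- list(); offset <- 0L
    for (i in seq_along(inputs)) {
      frames <- inputs[[i]]$frames
      if (cfg$drop_first > 0L) {
        if (cfg$drop_first >= length(frames)) {
          stop("drop_first leaves no frames for input ", inputs[[i]]$name)
        }
        frames <- frames[-seq_len(cfg$drop_first)]
      }
      tl <- fitness_timeline(frames, sites[[i]], params)
      md <- mode_timeline(frames, sites[[i]], params)
      br <- vapply(frames, function(fr)
        !is.null(detect_bridge(fr, sites[[i]], cfg$bridge_endpoints, params)),
        logical(1))
      src <- inputs[[i]]$name
      tl <- cbind(source = src, tl, stringsAsFactors = FALSE)
      md <- cbind(source = src, md, stringsAsFactors = FALSE)
      tl$pooled_index <- md$pooled_index <- offset + seq_len(nrow(tl))
      offset <- offset + nrow(tl)
      per[[i]] <- list(timeline = tl, modes = md, bridge = br, frames = frames,
                       sites = sites[[i]], name = src)
    }
    timeline <- do.call(rbind, lapply(per, `[[`, "timeline"))
    modes <- do.call(rbind, lapply(per, `[[`, "modes"))

    emit <- function(df, file, digits = 4L) {
      p <- file.path(cfg$out_dir, file)
      write_tsv(df, p, digits)
      written <<- c(written, p)
      p
    }
    out <- list()
    if (isTRUE(cfg$analyses$fitness)) {
      out$fitness_timeline <- emit(timeline, "fitness_timeline.tsv")
    }
    if (isTRUE(cfg$analyses$modes)) {
      out$mode_timeline <- emit(modes, "mode_timeline.tsv")
      if (!anyNA(timeline$active)) {
        pool_tl <- timeline; pool_tl$frame_index <- pool_tl$pooled_index
        pool_md <- modes; pool_md$frame_index <- pool_md$pooled_index
        ps <- population_summary(pool_tl, pool_md)
        ps$active_fraction_pct <- ps$active_fraction * 100
        ps$active_fraction <- NULL
        out$population_summary <-
          emit(ps, "population_summary.tsv", digits = c(active_fraction_pct = 1L))
      }
    }
    if (isTRUE(cfg$analyses$bridges)) {
      rows <- lapply(per, function(p) data.frame(
        source = p$name,
        endpoints = paste(cfg$bridge_endpoints, collapse = "-"),
        n_frames = length(p$bridge), n_bridged = sum(p$bridge),
        occupancy_pct = 100 * occupancy(p$bridge), stringsAsFactors = FALSE))
      occ <- do.call(rbind, rows)
      allb <- unlist(lapply(per, `[[`, "bridge"))
      occ <- rbind(occ, data.frame(
        source = "ALL", endpoints = paste(cfg$bridge_endpoints, collapse = "-"),
        n_frames = length(allb), n_bridged = sum(allb),
        occupancy_pct = 100 * occupancy(allb), stringsAsFactors = FALSE))
      out$occupancy <- emit(occ, "occupancy.tsv", digits = c(occupancy_pct = 1L))
    }
    for (sel in cfg$rdf) {
      rdfs <- list()
      for (p in per) {
        ref <- p$sites$roles[[sel$ref_role]]
        tgt <- p$sites$species[[sel$target_species]]
        if (is.null(ref)) stop("rdf selection: unknown ref role ", sel$ref_role)
        if (length(tgt) == 0L) next   # species absent in this source
        rdfs[[p$name]] <- list(frames = p$frames, ref = ref, tgt = tgt)
      }
      if (length(rdfs) == 0L) stop("rdf selection '", sel$name,
                                   "': target species absent from all inputs")
      frames_all <- do.call(c, lapply(rdfs, `[[`, "frames"))
      # pooled RDF only defined when selections agree across sources
      refs <- unique(vapply(rdfs, `[[`, integer(1), "ref"))
      if (length(rdfs) == 1L || length(refs) == 1L) {
        r <- compute_rdf(frames_all, rdfs[[1L]]$ref, rdfs[[1L]]$tgt,
                         r_max = sel$r_max,
                         bin = if (is.null(sel$bin)) 0.05 else sel$bin)
        pth <- file.path(cfg$out_dir, sprintf("rdf_%s.tsv", sel$name))
        write_rdf_tsv(r, pth)
        written <- c(written, pth)
        out[[sprintf("rdf_%s", sel$name)]] <- pth
      } else {
        for (nmr in names(rdfs)) {
          r <- compute_rdf(rdfs[[nmr]]$frames, rdfs[[nmr]]$ref, rdfs[[nmr]]$tgt,
                           r_max = sel$r_max,
                           bin = if (is.null(sel$bin)) 0.05 else sel$bin)
          pth <- file.path(cfg$out_dir, sprintf("rdf_%s_%s.tsv", sel$name, nmr))
          write_rdf_tsv(r, pth)
          written <- c(written, pth)
          out[[sprintf("rdf_%s_%s", sel$name, nmr)]] <- pth
        }
      }
    }
    if (!is.null(cfg$density)) {
      d <- cfg$density
      for (p in per) {
        if (length(p$sites$species[[d$species]]) == 0L) next
        dg <- density_grid(p$frames, p$sites, species = d$species,
                           extent = if (is.null(d$extent)) 8 else d$extent,
                           voxel = if (is.null(d$voxel)) 0.5 else d$voxel)
        pth <- file.path(cfg$out_dir,
                         sprintf("density_%s_%s.tsv", d$species, p$name))
        write_density_grid(dg, pth)
        written <- c(written, pth)
        out[[sprintf("density_%s_%s", d$species, p$name)]] <- pth
      }
    }
    manifest <- file.path(cfg$out_dir, "manifest.yaml")
    input_files <- unlist(lapply(inputs, function(i) c(i$topology, i$trajectory)))
    yaml::write_yaml(list(
      kind = "analyze",
      inputs = lapply(inputs, function(i) list(
        name = i$name, trajectory = i$trajectory,
        md5 = unname(tools::md5sum(i$trajectory)))),
      drop_first = cfg$drop_first,
      params = unclass(params)[setdiff(names(unclass(params)), NULL)],
      package_version = as.character(utils::packageVersion("dzfit"))
    ), manifest)
    out$manifest <- manifest
    invisible(out)
  }, error = on_fail)
}
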