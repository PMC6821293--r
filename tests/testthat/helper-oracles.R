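# Independent geometric oracles (brute force; never share code with the
# implementation they check) and small fixture builders.

# minimum-image distance by exhaustive enumeration over the 5^3 lattice images
oracle_min_image <- function(a, b, cell) {
  shifts <- as.matrix(expand.grid(sx = -2:2, sy = -2:2, sz = -2:2))
  d <- Inf
  for (k in seq_len(nrow(shifts))) {
    v <- b + drop(shifts[k, , drop = FALSE] %*% cell) - a
    d <- min(d, sqrt(sum(v * v)))
  }
  d
}

oracle_angle <- function(a, vertex, c) {
  u <- a - vertex
  v <- c - vertex
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# O(N^2) pair-count oracle for RDF bins
oracle_rdf_counts <- function(frames, ref_idx, tgt_idx, r_max, bin) {
  nb <- floor(r_max / bin + 1e-9)
  counts <- numeric(nb)
  for (fr in frames) {
    for (ri in ref_idx) {
      for (ti in tgt_idx) {
        d <- oracle_min_image(fr$coords[ri, ], fr$coords[ti, ], fr$box$cell)
        k <- floor(d / bin + 1e-9) + 1
        if (k >= 1 && k <= nb) counts[k] <- counts[k] + 1
      }
    }
  }
  counts
}

# per-frame direct neighbour counting (coordination-number oracle)
oracle_coordination <- function(frames, ref_idx, tgt_idx, r_cut) {
  tot <- 0
  for (fr in frames) {
    for (ri in ref_idx) {
      for (ti in tgt_idx) {
        d <- oracle_min_image(fr$coords[ri, ], fr$coords[ti, ], fr$box$cell)
        if (d <= r_cut) tot <- tot + 1
      }
    }
  }
  tot / (length(frames) * length(ref_idx))
}

random_triclinic_cell <- function() {
  # near-orthorhombic triclinic cells with healthy perpendicular widths
  base <- diag(stats::runif(3, 9, 14))
  base[2, 1] <- stats::runif(1, -1.5, 1.5)
  base[3, 1] <- stats::runif(1, -1.5, 1.5)
  base[3, 2] <- stats::runif(1, -1.5, 1.5)
  base
}

random_frame <- function(n_atoms, cell = NULL) {
  if (is.null(cell)) cell <- random_triclinic_cell()
  L <- max(diag(cell))
  md_frame(matrix(stats::runif(3 * n_atoms, 0, L), ncol = 3), sim_box(cell))
}

# fixed-column PDB text builder
pdb_atom_line <- function(serial, name, resname, resno, x, y, z,
                          element = "", chain = "A", record = "ATOM  ") {
  name4 <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
  sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, name4, resname, chain, resno, x, y, z, element)
}

toy_pdb_text <- function(n_models = 2L, n_atoms = 10L, with_cryst = TRUE,
                         drop_atom_in_model = NA_integer_) {
  lines <- character(0)
  if (with_cryst) {
    lines <- "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1           1"
  }
  for (m in seq_len(n_models)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    n <- if (!is.na(drop_atom_in_model) && m == drop_atom_in_model) n_atoms - 1L else n_atoms
    for (i in seq_len(n)) {
      lines <- c(lines, pdb_atom_line(i, "C1", "GLY", i, i + m / 10, 0, 0, "C"))
    }
    lines <- c(lines, "ENDMDL")
  }
  c(lines, "END")
}

# one frame with exactly planted alpha/gamma geometry (noise-free sampler)
geometry_frame <- function(d = 3.2, theta = 160, dh = 2.0, ...) {
  spec <- state_spec("probe", weight = 1,
                     d_o2p_p = dspec(d, 0),
                     angle_inline = dspec(theta, 0, lo = 1, hi = 180),
                     d_ho2p_n1 = dspec(dh, 0),
                     ...)
  topo <- dzfit:::build_topology(spec)
  s <- sample_frame(spec, topo = topo)
  list(frame = s$frame, truth = s$truth,
       sites = build_site_map(topo$atoms), atoms = topo$atoms)
}

# study-condition ensembles shared across acceptance checks (built once)
.study_cache <- new.env(parent = emptyenv())
study_ensembles <- function(n_pb = 10000L, n_na_only = 5000L, seed = 20260921L) {
  key <- sprintf("pb%d_na%d_s%d", n_pb, n_na_only, seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  pb <- generate_ensemble(gb_minus_specs(), n_pb, seed = seed)
  nao <- generate_ensemble(na_only_specs(), n_na_only, seed = seed + 1L)
  analyse <- function(ens) {
    sm <- build_site_map(ens$atoms)
    list(ensemble = ens, sites = sm,
         timeline = fitness_timeline(ens$frames, sm),
         modes = mode_timeline(ens$frames, sm),
         bridge = vapply(ens$frames,
                         function(fr) !is.null(detect_bridge(fr, sm)),
                         logical(1)))
  }
  res <- list(pb = analyse(pb), na_only = analyse(nao))
  .study_cache[[key]] <- res
  res
}

# pool timelines/modes of several analysed ensembles with frame re-indexing
pool_study <- function(parts) {
  off <- 0L
  tls <- list(); mds <- list()
  for (p in parts) {
    tl <- p$timeline; md <- p$modes
    tl$frame_index <- md$frame_index <- off + seq_len(nrow(tl))
    off <- off + nrow(tl)
    tls[[length(tls) + 1L]] <- tl
    mds[[length(mds) + 1L]] <- md
  }
  list(timeline = do.call(rbind, tls), modes = do.call(rbind, mds))
}

binom_ci99 <- function(p, n) {
  half <- stats::qnorm(0.995) * sqrt(p * (1 - p) / n)
  c(p - half, p + half)
}
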