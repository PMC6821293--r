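#' Radial distribution function around reference sites
#'
#' Standard site-site g(r): minimum-image reference-target pair distances are
#' histogrammed on a uniform grid (default 0.05 A bins) and normalized by the
#' ideal-gas expectation,
#' `g_k = C_k / (n_frames * n_ref * rho_ideal * V_shell(k))`,
#' where `rho_ideal = n_target / V_box` averaged over frames (so
#' constant-pressure ensembles with fluctuating volume are handled).
#'
#' @param frames List of periodic [md_frame()].
#' @param ref_indices Atom indices of the reference site(s).
#' @param target_indices Atom indices of the target species; must be disjoint
#'   from the references.
#' @param r_max Histogram range (A); must not exceed half the smallest
#'   perpendicular cell width of any frame. Rounded down to a whole number of
#'   bins.
#' @param bin Bin width (A), default 0.05.
#' @return Object of class `rdf_result`: `bin_edges`, `r_center`, `g`,
#'   `raw_counts`, `n_frames`, `n_ref_sites`, `n_target`, `ideal_density`.
#' @export
compute_rdf <- function(frames, ref_indices, target_indices, r_max, bin = 0.05) {
  if (length(frames) == 0L) stop("no frames")
  if (length(ref_indices) == 0L || length(target_indices) == 0L) {
    stop("empty reference or target selection")
  }
  if (length(intersect(ref_indices, target_indices)) > 0L) {
    stop("reference and target selections must be disjoint")
  }
  if (bin <= 0 || r_max <= bin) stop("need r_max > bin > 0")
  nb <- as.integer(floor(r_max / bin + 1e-9))
  edges <- (0:nb) * bin
  counts <- numeric(nb)
  rho_sum <- 0
  for (fr in frames) {
    if (!fr$box$periodic) stop("RDF requires periodic frames (ideal density needs a volume)")
    if (edges[nb + 1L] > box_min_width(fr$box) / 2 + 1e-9) {
      stop(sprintf("r_max %.2f exceeds half the minimal box width %.2f",
                   edges[nb + 1L], box_min_width(fr$box) / 2))
    }
    tg <- fr$coords[target_indices, , drop = FALSE]
    for (ri in ref_indices) {
      d <- min_image_distance(fr$coords[ri, ], tg, fr$box)
      k <- floor(d / bin + 1e-9) + 1L   # epsilon: a pair at an exact bin edge belongs to the upper bin
      keep <- k >= 1L & k <= nb
      if (any(keep)) counts <- counts + tabulate(k[keep], nbins = nb)
    }
    rho_sum <- rho_sum + length(target_indices) / box_volume(fr$box)
  }
  rho <- rho_sum / length(frames)
  vshell <- 4 / 3 * pi * diff(edges^3)
  g <- counts / (length(frames) * length(ref_indices) * rho * vshell)
  structure(list(bin_edges = edges, r_center = (edges[-1L] + edges[-(nb + 1L)]) / 2,
                 g = g, raw_counts = counts, n_frames = length(frames),
                 n_ref_sites = length(ref_indices),
                 n_target = length(target_indices), ideal_density = rho),
            class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("<rdf_result> %d bins of %.3f A, %d frames, %d ref x %d target, rho=%.5f\n",
              length(x$g), diff(x$bin_edges[1:2]), x$n_frames, x$n_ref_sites,
              x$n_target, x$ideal_density))
  invisible(x)
}

#' First qualifying peak of a g(r) curve
#'
#' The first local maximum (strict rise into the bin, no rise out of it) with
#' `g >= min_g`; reported at the bin centre. A flat or monotonically decaying
#' curve with no qualifying maximum yields `NULL` (absent), not an error.
#'
#' @param rdf [compute_rdf()] result.
#' @param min_g Minimum peak height, default 1 (the ideal-gas level).
#' @return `NULL`, or list `r_peak`, `g_peak`.
#' @export
first_peak <- function(rdf, min_g = 1.0) {
  g <- rdf$g
  n <- length(g)
  if (n < 2L) return(NULL)
  # a peak needs a strict rise into the bin (so flat curves have none) and
  # no rise out of it
  prev <- c(Inf, g[-n])
  nxt <- c(g[-1L], -Inf)
  is_peak <- g > prev & g >= nxt & g >= min_g
  i <- which(is_peak)
  if (length(i) == 0L) return(NULL)
  i <- i[1L]
  list(r_peak = rdf$r_center[i], g_peak = g[i])
}

#' Running coordination number from a g(r) curve
#'
#' `N(r_cut) = rho_ideal * sum_k g_k V_shell(k)` over bins whose upper edge
#' lies at or below `r_cut` — the mean number of target atoms within `r_cut`
#' of a reference site.
#'
#' @param rdf [compute_rdf()] result.
#' @param r_cut Integration limit (A), at most the histogram range.
#' @return Mean neighbour count.
#' @export
coordination_number <- function(rdf, r_cut) {
  edges <- rdf$bin_edges
  if (r_cut > edges[length(edges)] + 1e-9) stop("r_cut exceeds the histogram range")
  vshell <- 4 / 3 * pi * diff(edges^3)
  use <- edges[-1L] <= r_cut + 1e-9
  sum(rdf$ideal_density * rdf$g[use] * vshell[use])
}

#' Residue-averaged g(r) with the dominant residues excluded
#'
#' Given per-residue RDF curves (all on the same binning), ranks residues by
#' the global maximum of their curve, sets aside the `n_exclude` highest
#' (these are the specific binding sites, reported by id), and returns the
#' per-bin mean and standard deviation over the remaining residues — the
#' background ion-atmosphere profile.
#'
#' @param rdfs Named list of [compute_rdf()] results (names are residue ids).
#' @param n_exclude How many top-ranked residues to exclude (default 2).
#' @return List: `r_center`, `mean_g`, `sd_g`, `excluded_ids`.
#' @export
residue_averaged_rdf <- function(rdfs, n_exclude = 2L) {
  stopifnot(length(rdfs) > n_exclude)
  if (is.null(names(rdfs))) names(rdfs) <- as.character(seq_along(rdfs))
  e1 <- rdfs[[1L]]$bin_edges
  for (r in rdfs) {
    if (length(r$bin_edges) != length(e1) || any(abs(r$bin_edges - e1) > 1e-9)) {
      stop("inconsistent binning across residue RDFs")
    }
  }
  maxg <- vapply(rdfs, function(r) max(r$g), numeric(1))
  ord <- order(maxg, decreasing = TRUE)
  excl <- names(rdfs)[utils::head(ord, n_exclude)]
  keep <- rdfs[setdiff(names(rdfs), excl)]
  gm <- vapply(keep, function(r) r$g, numeric(length(rdfs[[1L]]$g)))
  gm <- matrix(gm, ncol = length(keep))
  list(r_center = rdfs[[1L]]$r_center,
       mean_g = rowMeans(gm),
       sd_g = apply(gm, 1L, stats::sd),
       excluded_ids = excl)
}

#' Write an RDF as TSV (`r_center`, `g`, `raw_count`, running coordination)
#'
#' @param rdf [compute_rdf()] result.
#' @param path Output path.
#' @export
write_rdf_tsv <- function(rdf, path) {
  coord <- cumsum(rdf$raw_counts) / (rdf$n_frames * rdf$n_ref_sites)
  df <- data.frame(r_center = rdf$r_center, g = rdf$g,
                   raw_count = rdf$raw_counts,
                   cumulative_coordination = coord)
  write_tsv(df, path, digits = c(r_center = 4L, g = 6L, raw_count = 0L,
                                 cumulative_coordination = 6L))
}
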