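#' Periodic simulation cell
#'
#' Constructs the periodic-cell descriptor attached to every frame. Cells are
#' stored as a 3x3 matrix of lattice vectors in Angstrom (rows are the a, b, c
#' vectors), so triclinic cells (including the truncated-octahedron cells that
#' MD engines report in triclinic form) are representable; orthorhombic cells
#' are diagonal matrices.
#'
#' @param cell `NULL` for a non-periodic (open boundary) frame, a length-3
#'   numeric of orthorhombic box edges, or a 3x3 matrix of lattice vectors
#'   (Angstrom).
#' @return An object of class `sim_box` with fields `cell` (3x3 matrix or
#'   `NULL`) and `periodic` (logical).
#' @export
#' @examples
#' sim_box(c(30, 30, 30))      # orthorhombic
#' sim_box(NULL)               # open boundaries
sim_box <- function(cell = NULL) {
  if (is.null(cell)) {
    return(structure(list(cell = NULL, periodic = FALSE), class = "sim_box"))
  }
  if (is.numeric(cell) && length(cell) == 3L) {
    cell <- diag(as.numeric(cell), 3L)
  }
  cell <- as.matrix(cell)
  if (!all(dim(cell) == c(3L, 3L)) || !is.numeric(cell) || any(!is.finite(cell))) {
    stop("cell must be NULL, a length-3 numeric, or a finite 3x3 matrix")
  }
  if (abs(det(cell)) < 1e-8) {
    stop("degenerate cell: volume is zero")
  }
  structure(list(cell = cell, periodic = TRUE), class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  if (!x$periodic) {
    cat("<sim_box> non-periodic\n")
  } else {
    cat(sprintf("<sim_box> periodic, volume %.2f A^3\n", box_volume(x)))
  }
  invisible(x)
}

#' Cell volume in cubic Angstrom
#' @param box A `sim_box`.
#' @return Volume in A^3; errors for non-periodic boxes.
#' @export
box_volume <- function(box) {
  stopifnot(inherits(box, "sim_box"))
  if (!box$periodic) stop("box is not periodic; volume undefined")
  abs(det(box$cell))
}

# Smallest perpendicular width of the cell: the relevant bound for the
# minimum-image convention (r_max must not exceed half of it).
box_min_width <- function(box) {
  stopifnot(inherits(box, "sim_box"), box$periodic)
  v <- box_volume(box)
  a <- box$cell[1L, ]; b <- box$cell[2L, ]; cc <- box$cell[3L, ]
  cross <- function(u, w) c(u[2] * w[3] - u[3] * w[2],
                            u[3] * w[1] - u[1] * w[3],
                            u[1] * w[2] - u[2] * w[1])
  areas <- c(sqrt(sum(cross(b, cc)^2)),
             sqrt(sum(cross(cc, a)^2)),
             sqrt(sum(cross(a, b)^2)))
  min(v / areas)
}

is_orthorhombic <- function(box) {
  box$periodic && all(abs(box$cell[row(box$cell) != col(box$cell)]) < 1e-10)
}

#' Coordinate frame (one snapshot of an ensemble)
#'
#' @param coords Numeric matrix, one row per atom, columns x, y, z (Angstrom).
#' @param box A [sim_box()].
#' @param frame_index Integer frame label.
#' @param time_ps Optional time stamp in picoseconds.
#' @return Object of class `md_frame`.
#' @export
md_frame <- function(coords, box = sim_box(), frame_index = 1L, time_ps = NA_real_) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must have 3 columns (x, y, z)")
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  if (any(!is.finite(coords))) stop("coords must be finite")
  stopifnot(inherits(box, "sim_box"))
  structure(list(coords = coords, box = box,
                 frame_index = as.integer(frame_index),
                 time_ps = as.numeric(time_ps)),
            class = "md_frame")
}

#' @export
print.md_frame <- function(x, ...) {
  cat(sprintf("<md_frame %d> %d atoms, %s\n", x$frame_index, nrow(x$coords),
              if (x$box$periodic) "periodic" else "non-periodic"))
  invisible(x)
}
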