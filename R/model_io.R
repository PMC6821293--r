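#' @title Coordinate and topology I/O
#' @name model_io
#' @description Readers for multi-model PDB files and the package's
#'   plain-text trajectory table, the site-map resolver that turns residue
#'   and atom names into the catalytic roles used by all analyses, and the
#'   deterministic TSV writers used for every tabular output.
NULL

# two-letter element overrides for name-derived elements (older PDB dialects
# omit columns 77-78); keys are upper-case atom-name prefixes
.element_overrides <- c(NA. = "NA", PB = "PB", CL = "CL", MG = "MG",
                        ZN = "ZN", MN = "MN", BR = "BR", FE = "FE")

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", atom_name)))
  two <- substr(nm, 1L, 2L)
  out <- character(length(nm))
  key <- ifelse(two == "NA", "NA.", two)
  hit <- key %in% names(.element_overrides)
  out[hit] <- .element_overrides[key[hit]]
  out[!hit] <- substr(nm[!hit], 1L, 1L)
  if (any(out == "")) stop("cannot infer element from atom name '",
                           atom_name[which(out == "")[1L]], "'")
  out
}

parse_num <- function(s, what, lineno) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v))) {
    stop(sprintf("unparseable %s in ATOM record at line %d", what,
                 lineno[which(is.na(v))[1L]]))
  }
  v
}

# CRYST1 a b c alpha beta gamma -> 3x3 lattice-vector matrix (rows a, b, c)
cell_from_cryst1 <- function(a, b, c, alpha, beta, gamma) {
  ar <- alpha * pi / 180; br <- beta * pi / 180; gr <- gamma * pi / 180
  v1 <- c(a, 0, 0)
  v2 <- c(b * cos(gr), b * sin(gr), 0)
  cx <- c * cos(br)
  cy <- c * (cos(ar) - cos(br) * cos(gr)) / sin(gr)
  cz <- sqrt(max(0, c^2 - cx^2 - cy^2))
  rbind(v1, v2, c(cx, cy, cz), deparse.level = 0)
}

#' Read a multi-model PDB file as a coordinate ensemble
#'
#' Parses `ATOM`/`HETATM` records (fixed columns), one [md_frame()] per
#' `MODEL` block (a file without `MODEL` records yields a single frame), and
#' `CRYST1` into the periodic cell when present. All models must contain the
#' same atoms in the same order.
#'
#' @param path Path to a PDB file.
#' @return A list with `atoms` (data.frame: `atom_index`, `atom_name`,
#'   `residue_name`, `residue_index`, `chain_id`, `element`; `atom_index` is
#'   1-based file order) and `frames` (list of [md_frame()]).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  box <- sim_box()
  cr <- grep("^CRYST1", lines)
  if (length(cr) > 0L) {
    f <- lines[cr[1L]]
    vals <- parse_num(c(substr(f, 7, 15), substr(f, 16, 24), substr(f, 25, 33),
                        substr(f, 34, 40), substr(f, 41, 47), substr(f, 48, 54)),
                      "CRYST1 field", rep(cr[1L], 6L))
    box <- sim_box(cell_from_cryst1(vals[1], vals[2], vals[3],
                                    vals[4], vals[5], vals[6]))
  }
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  is_model <- grepl("^MODEL", lines)
  is_end <- grepl("^ENDMDL", lines)
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign each atom line to a model block
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[is_end] <- 0L
  atom_lines <- which(is_atom)
  atom_model <- model_id[atom_lines]
  if (any(is_model) && any(atom_model == 0L)) {
    stop("ATOM record outside MODEL/ENDMDL block at line ", atom_lines[atom_model == 0L][1L])
  }
  models <- sort(unique(atom_model))
  counts <- table(atom_model)
  n0 <- as.integer(counts[1L])
  if (any(counts != n0)) {
    bad <- models[which(counts != n0)[1L]]
    stop(sprintf("inconsistent atom count in model %d: %d atoms, expected %d",
                 bad, as.integer(counts[as.character(bad)]), n0))
  }

  first <- atom_lines[atom_model == models[1L]]
  txt <- lines[first]
  atoms <- data.frame(
    atom_index = seq_along(first),
    atom_name = trimws(substr(txt, 13, 16)),
    residue_name = trimws(substr(txt, 18, 20)),
    residue_index = as.integer(parse_num(substr(txt, 23, 26), "residue number", first)),
    chain_id = trimws(substr(txt, 22, 22)),
    element = trimws(substr(txt, 77, 78)),
    stringsAsFactors = FALSE
  )
  missing_el <- atoms$element == ""
  if (any(missing_el)) {
    atoms$element[missing_el] <- infer_element(atoms$atom_name[missing_el])
  }
  atoms$element <- toupper(atoms$element)

  frames <- vector("list", length(models))
  for (i in seq_along(models)) {
    ln <- atom_lines[atom_model == models[i]]
    txt <- lines[ln]
    x <- parse_num(substr(txt, 31, 38), "x coordinate", ln)
    y <- parse_num(substr(txt, 39, 46), "y coordinate", ln)
    z <- parse_num(substr(txt, 47, 54), "z coordinate", ln)
    frames[[i]] <- md_frame(cbind(x, y, z), box, frame_index = i)
  }
  list(atoms = atoms, frames = frames)
}

#' Write a coordinate ensemble as a multi-model PDB (pass-through writer)
#'
#' Minimal writer used to round-trip synthetic ensembles; atoms beyond the
#' fixed-column widths are not supported.
#'
#' @param atoms Topology data.frame as returned by [read_multimodel_pdb()].
#' @param frames List of [md_frame()].
#' @param path Output path.
#' @export
write_multimodel_pdb <- function(atoms, frames, path) {
  out <- character(0)
  b <- frames[[1L]]$box
  if (b$periodic) {
    cl <- b$cell
    if (!is_orthorhombic(b)) stop("PDB writer supports orthorhombic cells only")
    out <- c(out, sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
                          cl[1, 1], cl[2, 2], cl[3, 3], 90, 90, 90))
  }
  rec <- ifelse(atoms$element %in% c("NA", "PB", "CL", "MG", "ZN") |
                  atoms$residue_name %in% c("HOH", "WAT"), "HETATM", "ATOM  ")
  name4 <- ifelse(nchar(atoms$atom_name) < 4L,
                  sprintf(" %-3s", atoms$atom_name), atoms$atom_name)
  for (i in seq_along(frames)) {
    xyz <- frames[[i]]$coords
    out <- c(out, sprintf("MODEL     %4d", i),
             sprintf("%s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     rec, atoms$atom_index, name4, atoms$residue_name,
                     ifelse(atoms$chain_id == "", "A", atoms$chain_id),
                     atoms$residue_index, xyz[, 1], xyz[, 2], xyz[, 3],
                     atoms$element),
             "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read the plain-text trajectory table
#'
#' Format: UTF-8 text; `#` comment lines anywhere; each frame starts with a
#' header `FRAME <idx> TIME <ps> BOX <ax ay az bx by bz cx cy cz>` followed by
#' one `<atom_index> <x> <y> <z>` row per atom. A BOX of nine zeros marks a
#' non-periodic frame.
#'
#' @param path Path to the table.
#' @param n_atoms Expected atoms per frame.
#' @return List of [md_frame()].
#' @export
read_traj_table <- function(path, n_atoms) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  hdr <- grepl("^FRAME ", lines)
  if (!any(hdr)) stop("no FRAME headers in ", path)
  starts <- which(hdr)
  ends <- c(starts[-1L] - 1L, length(lines))
  frames <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    h <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1L]]
    if (length(h) != 14L || h[1L] != "FRAME" || h[3L] != "TIME" || h[5L] != "BOX") {
      stop("malformed FRAME header for frame block ", i)
    }
    idx <- as.integer(h[2L]); tps <- as.numeric(h[4L])
    cell <- matrix(as.numeric(h[6:14]), nrow = 3L, byrow = TRUE)
    box <- if (all(cell == 0)) sim_box() else sim_box(cell)
    body <- lines[seq(starts[i] + 1L, ends[i])]
    if (length(body) != n_atoms) {
      stop(sprintf("frame %d: expected %d atom rows, found %d", idx, n_atoms,
                   length(body)))
    }
    m <- matrix(as.numeric(unlist(strsplit(trimws(body), "\\s+"))),
                ncol = 4L, byrow = TRUE)
    if (any(is.na(m))) stop("unparseable atom row in frame ", idx)
    frames[[i]] <- md_frame(m[, 2:4], box, frame_index = idx, time_ps = tps)
  }
  frames
}

#' Write the plain-text trajectory table
#'
#' Coordinates and box vectors are written with 4 decimals, making the
#' write/read round trip exact at that precision and reruns byte-identical.
#'
#' @param frames List of [md_frame()].
#' @param path Output path.
#' @param comments Optional character vector written as leading `#` lines
#'   (provenance: seed, spec hash, ...).
#' @export
write_traj_table <- function(frames, path, comments = character(0)) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments) > 0L) writeLines(paste0("# ", comments), con)
  for (fr in frames) {
    cell <- if (fr$box$periodic) fr$box$cell else matrix(0, 3, 3)
    writeLines(sprintf("FRAME %d TIME %.4f BOX %s", fr$frame_index,
                       ifelse(is.na(fr$time_ps), 0, fr$time_ps),
                       paste(sprintf("%.4f", t(cell)), collapse = " ")), con)
    writeLines(sprintf("%d %.4f %.4f %.4f", seq_len(nrow(fr$coords)),
                       fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]), con)
  }
  invisible(path)
}

#' Default site naming for the bundled active-site scaffold
#'
#' Maps catalytic roles to (residue index, atom name) pairs and species to
#' selection rules, following the convention that the nucleophile-bearing
#' residue upstream of the scissile phosphate is numbered -1 and the
#' phosphate-bearing residue +1. The non-bridging phosphoryl oxygens use the
#' OP1/OP2 dialect with OP1 = pro-R and OP2 = pro-S; files using O1P/O2P (or a
#' different stereo-assignment) must say so here — the analysis code never
#' guesses.
#'
#' @return A naming config list understood by [build_site_map()].
#' @export
default_site_naming <- function() {
  list(
    roles = list(
      O2p        = list(residue_index = -1L, atom_name = "O2'"),
      HO2p       = list(residue_index = -1L, atom_name = "HO2'"),
      P_scissile = list(residue_index = 1L,  atom_name = "P"),
      O5p        = list(residue_index = 1L,  atom_name = "O5'"),
      proRP      = list(residue_index = 1L,  atom_name = "OP1"),
      proSP      = list(residue_index = 1L,  atom_name = "OP2"),
      G13_N1     = list(residue_index = 13L, atom_name = "N1"),
      G13_O6     = list(residue_index = 13L, atom_name = "O6"),
      G6_O6      = list(residue_index = 6L,  atom_name = "O6"),
      G6_N7      = list(residue_index = 6L,  atom_name = "N7")
    ),
    species = list(
      "NA"    = list(element = "NA"),
      "PB"    = list(element = "PB"),
      WATER_O = list(residue_name = "HOH", element = "O"),
      WATER_H = list(residue_name = "HOH", element = "H")
    ),
    gamma = TRUE
  )
}

match_rule <- function(atoms, rule) {
  sel <- rep(TRUE, nrow(atoms))
  if (!is.null(rule$residue_index)) sel <- sel & atoms$residue_index == rule$residue_index
  if (!is.null(rule$residue_name)) sel <- sel & atoms$residue_name == rule$residue_name
  if (!is.null(rule$atom_name)) sel <- sel & atoms$atom_name == rule$atom_name
  if (!is.null(rule$element)) sel <- sel & atoms$element == rule$element
  if (!is.null(rule$chain_id)) sel <- sel & atoms$chain_id == rule$chain_id
  # atom indices, not row positions: resolution is invariant under record order
  sort(atoms$atom_index[sel])
}

#' Resolve catalytic roles and ion/water species to atom indices
#'
#' @param atoms Topology data.frame (see [read_multimodel_pdb()]).
#' @param naming Naming config, see [default_site_naming()]. `naming$gamma =
#'   FALSE` disables the nucleophile-activation analysis, in which case the
#'   `HO2p` role (absent in deprotonated-nucleophile ensembles) may be
#'   unresolvable.
#' @return An object of class `site_map`: `roles` (named integer vector),
#'   `species` (named list of integer vectors), `water_h_parent` (named map
#'   from each water-H index to its water-O index, used by the metal-bound
#'   water criteria), `gamma_enabled`.
#' @export
build_site_map <- function(atoms, naming = default_site_naming()) {
  gamma_enabled <- !identical(naming$gamma, FALSE)
  mandatory <- c("O2p", "P_scissile", "O5p", "proRP", "proSP",
                 "G13_N1", "G13_O6", "G6_O6", "G6_N7")
  if (gamma_enabled) mandatory <- c(mandatory, "HO2p")
  roles <- integer(0)
  for (role in union(mandatory, names(naming$roles))) {
    rule <- naming$roles[[role]]
    if (is.null(rule)) {
      if (role %in% mandatory) stop("no naming rule for mandatory role ", role)
      next
    }
    hits <- match_rule(atoms, rule)
    if (length(hits) == 0L) {
      if (!(role %in% mandatory)) next
      near <- atoms$atom_index[atoms$atom_name == rule$atom_name]
      stop(sprintf("role %s unresolved: no atom '%s' in residue %s%s", role,
                   rule$atom_name, rule$residue_index,
                   if (length(near)) paste0("; atoms named '", rule$atom_name,
                                            "' exist at indices ",
                                            paste(near, collapse = ", "))
                   else ""))
    }
    if (length(hits) > 1L) {
      stop(sprintf("role %s ambiguous: atoms %s all match", role,
                   paste(hits, collapse = ", ")))
    }
    roles[[role]] <- hits
  }
  species <- lapply(naming$species, function(rule) match_rule(atoms, rule))
  names(species) <- names(naming$species)
  idx_all <- unlist(species, use.names = FALSE)
  if (anyDuplicated(idx_all)) stop("species selections overlap: atom ",
                                   idx_all[duplicated(idx_all)][1L],
                                   " matched twice")
  water_h_parent <- integer(0)
  if (length(species$WATER_H) > 0L && length(species$WATER_O) > 0L) {
    o_res <- atoms$residue_index[match(species$WATER_O, atoms$atom_index)]
    h_res <- atoms$residue_index[match(species$WATER_H, atoms$atom_index)]
    pos <- match(h_res, o_res)
    if (any(is.na(pos))) stop("water H without a matching water O in residue ",
                              h_res[which(is.na(pos))[1L]])
    water_h_parent <- stats::setNames(species$WATER_O[pos],
                                      as.character(species$WATER_H))
  }
  structure(list(roles = roles, species = species,
                 water_h_parent = water_h_parent,
                 gamma_enabled = gamma_enabled),
            class = "site_map")
}

#' @export
print.site_map <- function(x, ...) {
  cat("<site_map>\n roles: ",
      paste(sprintf("%s=%d", names(x$roles), x$roles), collapse = " "), "\n",
      " species: ",
      paste(sprintf("%s(n=%d)", names(x$species), lengths(x$species)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

# ---- deterministic TSV output -------------------------------------------

#' Write a data.frame as a deterministic TSV
#'
#' Numeric columns are formatted with a fixed number of decimals (default 4)
#' so that repeated runs produce byte-identical files.
#'
#' @param df Data frame.
#' @param path Output path.
#' @param digits Decimals for numeric (double) columns; named vector entries
#'   override per column.
#' @export
write_tsv <- function(df, path, digits = 4L) {
  out <- df
  for (nm in names(out)) {
    col <- out[[nm]]
    if (is.double(col)) {
      d <- if (!is.null(names(digits)) && nm %in% names(digits)) digits[[nm]] else
        if (!is.null(names(digits))) 4L else digits
      out[[nm]] <- ifelse(is.na(col), "NA", sprintf(paste0("%.", d, "f"), col))
    } else if (is.logical(col)) {
      out[[nm]] <- ifelse(is.na(col), "NA", ifelse(col, "TRUE", "FALSE"))
    }
  }
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  # quote = "": atom names like O2' must not open a quoted field
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

write_topology_tsv <- function(atoms, path) write_tsv(atoms, path)

read_topology_tsv <- function(path) {
  at <- read_tsv(path)
  at$chain_id <- as.character(at$chain_id)
  at$chain_id[is.na(at$chain_id)] <- ""
  # "NA" element/residue strings are real sodium labels, not missing values
  at$element <- as.character(at$element); at$element[is.na(at$element)] <- "NA"
  at$residue_name <- as.character(at$residue_name)
  at$residue_name[is.na(at$residue_name)] <- "NA"
  at
}
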