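# Trajectory container and coordinate-file readers/writers.
#
# Internal canonical length unit is the angstrom; formats that use nm (GRO,
# and optionally the plain-text format) are converted on read. Coordinates
# are held as a natoms x 3 x nframes array so per-frame analyses vectorise.

#' Construct a trajectory object
#'
#' A trajectory couples a fixed topology (the atom table, shared by every
#' frame) with an ordered series of coordinate frames. Coordinates are stored
#' in angstrom in a `natoms x 3 x nframes` array; the simulation box is a
#' `nframes x 3` matrix of orthorhombic edge lengths, with the z axis normal
#' to the gold surface.
#'
#' @param atoms Data frame with columns `index`, `name`, `element`,
#'   `residue_index`, `residue_name`, `is_slab`. `is_slab` defaults to
#'   `element == "Au"` and may be overridden via `slab_indices`.
#' @param coords Numeric array `natoms x 3 x nframes` (angstrom), or a single
#'   `natoms x 3` matrix for a one-frame trajectory.
#' @param box Numeric `nframes x 3` matrix (angstrom) or a length-3 vector
#'   recycled to all frames.
#' @param time Numeric vector of frame times in ps (defaults to 0,1,2,...).
#' @param slab_indices Optional explicit atom indices (1-based rows of
#'   `atoms`) forming the gold slab, overriding the element-based rule.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, box, time = NULL, slab_indices = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("index", "name", "residue_index", "residue_name")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop_input("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$index))
    stop_input("atom indices must be unique within the topology")
  if (is.null(atoms$element))
    atoms$element <- infer_element(atoms$name)
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(atoms))
    stop_input("coordinate array has %d atoms but topology has %d",
               dim(coords)[1], nrow(atoms))
  if (!all(is.finite(coords)))
    stop_input("non-finite coordinates in trajectory")
  nf <- dim(coords)[3]
  if (nf < 1L) stop_input("trajectory must contain at least one frame")
  if (is.null(dim(box))) box <- matrix(box, nf, 3L, byrow = TRUE)
  if (nrow(box) != nf) stop_input("box matrix must have one row per frame")
  if (any(box <= 0)) stop_input("box edge lengths must be positive")
  if (is.null(time)) time <- as.numeric(seq_len(nf) - 1L)
  if (is.null(atoms$is_slab)) atoms$is_slab <- atoms$element == "Au"
  if (!is.null(slab_indices)) {
    atoms$is_slab <- FALSE
    atoms$is_slab[slab_indices] <- TRUE
  }
  structure(list(atoms = atoms, coords = coords, box = box,
                 time = as.numeric(time)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms (%d slab), %d frame(s)\n",
              n_atoms(x), sum(x$atoms$is_slab), n_frames(x)))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A `trajectory`.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame
#'
#' @param traj A `trajectory`.
#' @param i Frame number (1-based).
#' @return List with `coordinates` (natoms x 3 matrix, angstrom), `box`
#'   (length-3 vector) and `time` (ps).
#' @export
get_frame <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    stop_input("frame %d out of range 1..%d", i, n_frames(traj))
  list(coordinates = traj$coords[, , i, drop = TRUE],
       box = traj$box[i, ], time = traj$time[i])
}

# Element guess from an atom name: leading letters, Au-aware, first letter
# capitalised. "SD" -> "S", "CA" -> "C", "AU"/"AU1" -> "Au".
infer_element <- function(name) {
  letters_only <- toupper(gsub("[^A-Za-z].*$", "", name))
  el <- substr(letters_only, 1L, 1L)
  el[letters_only %in% c("AU", "AUS", "AUB")] <- "Au"
  el[substr(letters_only, 1L, 2L) == "AU"] <- "Au"
  el
}

#' Partition trajectory atoms into gold slab and peptide residues
#'
#' Every atom is assigned to exactly one of the two partitions: the slab
#' (element Au, or an explicit override recorded at construction) or a
#' peptide residue group. Residue groups are ordered by residue index.
#'
#' @param traj A `trajectory`.
#' @return List with `slab_atoms` (integer row indices into the atom table)
#'   and `peptide_residues`, a list of groups each holding `residue_index`,
#'   `residue_name` and `atom_rows`.
#' @export
partition_atoms <- function(traj) {
  slab <- which(traj$atoms$is_slab)
  if (length(slab) == 0L) stop_input("no slab present: no Au atoms found")
  pep <- which(!traj$atoms$is_slab)
  if (length(pep) == 0L) stop_input("no peptide present: all atoms are slab")
  resid <- traj$atoms$residue_index[pep]
  ord <- sort(unique(resid))
  groups <- lapply(ord, function(ri) {
    rows <- pep[resid == ri]
    list(residue_index = ri,
         residue_name = traj$atoms$residue_name[rows[1]],
         atom_rows = rows)
  })
  list(slab_atoms = slab, peptide_residues = groups)
}

# ---------------------------------------------------------------------------
# Plain-text internal format. One block per frame:
#   FRAME <natoms> <Lx> <Ly> <Lz> <time>
#   <index> <name> <resname> <resid> <x> <y> <z>     (natoms rows)
# Units angstrom unless the caller says nanometer.
# ---------------------------------------------------------------------------

#' Write a trajectory in the plain-text frame format
#'
#' @param traj A `trajectory`.
#' @param path Output file.
#' @param digits Coordinate precision (decimal places).
#' @export
write_trajectory_txt <- function(traj, path, digits = 4L) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  fmtc <- paste0("%.", digits, "f")
  for (i in seq_len(n_frames(traj))) {
    writeLines(sprintf("FRAME %d %s %s %s %s", n_atoms(traj),
                       sprintf(fmtc, traj$box[i, 1]),
                       sprintf(fmtc, traj$box[i, 2]),
                       sprintf(fmtc, traj$box[i, 3]),
                       sprintf(fmtc, traj$time[i])), con)
    xyz <- traj$coords[, , i, drop = TRUE]
    if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3L)
    writeLines(sprintf(paste0("%d %s %s %d ", fmtc, " ", fmtc, " ", fmtc),
                       a$index, a$name, a$residue_name, a$residue_index,
                       xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

read_frames_txt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (hdr[1] != "FRAME")
      stop_input("%s: expected FRAME header at line %d", path, i)
    nat <- as.integer(hdr[2])
    box <- as.numeric(hdr[3:5])
    tm <- if (length(hdr) >= 6) as.numeric(hdr[6]) else NA_real_
    if (i + nat > length(lines))
      stop_input("%s: truncated frame (%d atoms declared)", path, nat)
    body <- do.call(rbind, strsplit(trimws(lines[(i + 1L):(i + nat)]), "\\s+"))
    frames[[length(frames) + 1L]] <- list(
      atoms = data.frame(index = as.integer(body[, 1]), name = body[, 2],
                         residue_name = body[, 3],
                         residue_index = as.integer(body[, 4])),
      xyz = matrix(as.numeric(body[, 5:7]), ncol = 3L),
      box = box, time = tm)
    i <- i + nat + 1L
  }
  if (!length(frames)) stop_input("%s: no frames found", path)
  frames
}

# ---------------------------------------------------------------------------
# GRO (fixed-width, nm) and PDB (angstrom) readers. Multi-frame files are
# concatenated blocks (GRO) or MODEL/ENDMDL sections (PDB).
# ---------------------------------------------------------------------------

read_frames_gro <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop_input("%s: bad atom count at line %d", path, i + 1L)
    rows <- lines[(i + 2L):(i + 1L + nat)]
    resid <- as.integer(substr(rows, 1L, 5L))
    resname <- trimws(substr(rows, 6L, 10L))
    name <- trimws(substr(rows, 11L, 15L))
    index <- as.integer(substr(rows, 16L, 20L))
    x <- as.numeric(substr(rows, 21L, 28L))
    y <- as.numeric(substr(rows, 29L, 36L))
    z <- as.numeric(substr(rows, 37L, 44L))
    boxline <- as.numeric(strsplit(trimws(lines[i + 2L + nat]), "\\s+")[[1]])
    tm <- NA_real_
    title <- lines[i]
    if (grepl("t=", title))
      tm <- suppressWarnings(as.numeric(sub(".*t=\\s*([0-9.eE+-]+).*", "\\1",
                                            title)))
    frames[[length(frames) + 1L]] <- list(
      atoms = data.frame(index = index, name = name, residue_name = resname,
                         residue_index = resid),
      xyz = cbind(x, y, z), box = boxline[1:3], time = tm)
    i <- i + 3L + nat
  }
  if (!length(frames)) stop_input("%s: no frames found", path)
  frames
}

read_frames_pdb <- function(path) {
  lines <- readLines(path)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_brk <- which(startsWith(lines, "ENDMDL"))
  cryst <- grep("^CRYST1", lines, value = TRUE)
  box <- if (length(cryst)) as.numeric(c(substr(cryst[1], 7, 15),
                                         substr(cryst[1], 16, 24),
                                         substr(cryst[1], 25, 33)))
         else c(100, 100, 100)
  parse_block <- function(rows) {
    name <- trimws(substr(rows, 13L, 16L))
    resname <- trimws(substr(rows, 18L, 21L))
    resid <- as.integer(substr(rows, 23L, 26L))
    index <- as.integer(substr(rows, 7L, 11L))
    x <- as.numeric(substr(rows, 31L, 38L))
    y <- as.numeric(substr(rows, 39L, 46L))
    z <- as.numeric(substr(rows, 47L, 54L))
    el <- trimws(substr(rows, 77L, 78L))
    el[!nzchar(el)] <- infer_element(name[!nzchar(el)])
    el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
    list(atoms = data.frame(index = index, name = name,
                            residue_name = resname, residue_index = resid,
                            element = el),
         xyz = cbind(x, y, z), box = box, time = NA_real_)
  }
  if (length(model_brk) == 0L) {
    return(list(parse_block(lines[is_atom])))
  }
  frames <- list()
  start <- 1L
  for (e in model_brk) {
    blk <- lines[start:e]
    rows <- blk[startsWith(blk, "ATOM") | startsWith(blk, "HETATM")]
    if (length(rows)) frames[[length(frames) + 1L]] <- parse_block(rows)
    start <- e + 1L
  }
  frames
}

# Reader registry so callers can plug adapters for formats the package does
# not parse natively (e.g. XTC/DCD converted through an external tool).
.pepsurf_readers <- new.env(parent = emptyenv())

#' Register a trajectory frame reader for a file extension
#'
#' The reader must accept a file path and return a list of frames, each a
#' list with `atoms` (data frame: index, name, residue_name, residue_index),
#' `xyz` (natoms x 3 matrix), `box` (length 3) and `time`. Binary formats
#' such as XTC/DCD are supported through this adapter layer: convert them
#' with an external tool or supply a reader here.
#'
#' @param ext Lower-case file extension without the dot (e.g. "crd").
#' @param fun Reader function, or `NULL` to unregister.
#' @param native_unit Either "angstrom" or "nanometer"; coordinates are
#'   converted to angstrom on load.
#' @export
register_trajectory_reader <- function(ext, fun, native_unit = "angstrom") {
  assign(ext, list(fun = fun, unit = native_unit), envir = .pepsurf_readers)
  invisible(NULL)
}

frame_reader_for <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("txt", "traj", "dat"))
    return(list(fun = read_frames_txt, unit = "angstrom"))
  if (ext == "gro") return(list(fun = read_frames_gro, unit = "nanometer"))
  if (ext == "pdb") return(list(fun = read_frames_pdb, unit = "angstrom"))
  if (exists(ext, envir = .pepsurf_readers))
    return(get(ext, envir = .pepsurf_readers))
  stop_input("no reader for extension '.%s' (register one with %s)",
             ext, "register_trajectory_reader()")
}

#' Load a trajectory from coordinate files
#'
#' Reads a topology file (its first frame defines the atom table) plus zero
#' or more frame files, concatenates frames in file order (then time order
#' within each file as written), converts coordinates to angstrom, and flags
#' gold slab atoms by element.
#'
#' @param topology_path File defining the topology; its frames are included.
#' @param frame_paths Optional character vector of additional frame files.
#' @param length_unit "auto" (by format: GRO in nm, PDB and plain text in
#'   angstrom), "angstrom" or "nanometer". An explicit unit overrides the
#'   format default for every file.
#' @param slab_indices Optional explicit slab atom indices overriding the
#'   element-Au rule.
#' @return A [trajectory()].
#' @export
load_trajectory <- function(topology_path, frame_paths = character(),
                            length_unit = c("auto", "angstrom", "nanometer"),
                            slab_indices = NULL) {
  length_unit <- match.arg(length_unit)
  paths <- c(topology_path, frame_paths)
  all_frames <- list()
  for (p in paths) {
    rd <- frame_reader_for(p)
    unit <- if (length_unit == "auto") rd$unit else length_unit
    fac <- switch(unit, angstrom = 1, nanometer = 10,
                  stop_input("unknown length unit '%s'", unit))
    frames <- rd$fun(p)
    for (fr in frames) {
      fr$xyz <- fr$xyz * fac
      fr$box <- fr$box * fac
      fr$src <- p
      all_frames[[length(all_frames) + 1L]] <- fr
    }
  }
  atoms <- all_frames[[1]]$atoms
  nat <- nrow(atoms)
  for (fr in all_frames) {
    if (nrow(fr$atoms) != nat)
      stop_input("atom-count mismatch: %s has %d atoms, topology has %d",
                 fr$src, nrow(fr$atoms), nat)
  }
  coords <- array(0, c(nat, 3L, length(all_frames)))
  box <- matrix(0, length(all_frames), 3L)
  tm <- numeric(length(all_frames))
  for (i in seq_along(all_frames)) {
    coords[, , i] <- all_frames[[i]]$xyz
    box[i, ] <- all_frames[[i]]$box
    tm[i] <- all_frames[[i]]$time
  }
  if (anyNA(tm)) tm <- as.numeric(seq_along(all_frames) - 1L)
  trajectory(atoms, coords, box, time = tm, slab_indices = slab_indices)
}

#' Write the atom table as TSV
#' @param traj A `trajectory`.
#' @param path Output file.
#' @export
write_atom_table <- function(traj, path) {
  utils::write.table(traj$atoms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a single frame as GRO (nm) or PDB (angstrom)
#'
#' Used mainly to export cluster centroid structures.
#'
#' @param traj A `trajectory`.
#' @param path Output file; format chosen by extension (.gro or .pdb).
#' @param frame Frame number to write.
#' @export
write_frame <- function(traj, path, frame = 1L) {
  fr <- get_frame(traj, frame)
  a <- traj$atoms
  ext <- tolower(tools::file_ext(path))
  con <- file(path, "w")
  on.exit(close(con))
  if (ext == "gro") {
    writeLines(sprintf("pepsurf frame t= %.3f", fr$time), con)
    writeLines(sprintf("%5d", n_atoms(traj)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$residue_index %% 100000L, a$residue_name, a$name,
                       a$index %% 100000L,
                       fr$coordinates[, 1] / 10, fr$coordinates[, 2] / 10,
                       fr$coordinates[, 3] / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", fr$box[1] / 10, fr$box[2] / 10,
                       fr$box[3] / 10), con)
  } else if (ext == "pdb") {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       fr$box[1], fr$box[2], fr$box[3]), con)
    writeLines(sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                       a$index %% 100000L, substr(a$name, 1, 4),
                       substr(a$residue_name, 1, 4),
                       a$residue_index %% 10000L,
                       fr$coordinates[, 1], fr$coordinates[, 2],
                       fr$coordinates[, 3], toupper(a$element)), con)
    writeLines("END", con)
  } else stop_input("write_frame: unsupported extension '.%s'", ext)
  invisible(path)
}
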