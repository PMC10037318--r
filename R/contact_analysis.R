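# Residue-surface contact detection and per-residue contact fractions.
#
# A residue is in contact in a frame when the distance between its reference
# site and the topmost gold layer is less than or equal to its cut-off
# (inclusive boundary). The default distance is the vertical z offset from
# the mean plane of the topmost Au layer; a minimum 3-D distance mode under
# the x/y minimum-image convention is available since either convention is
# defensible for a slab geometry.

#' Default residue reference-site / cut-off table
#'
#' For sulfur-bearing residues (Met, Cys and the protected/oxidised
#' analogues MOX, CTB, COX) the reference site is the sulfur atom with a
#' 4.5 angstrom cut-off. For all other residue types the default site is the
#' centroid of the terminal side-chain heavy atoms, also at 4.5 angstrom.
#' The non-sulfur entries are pragmatic placeholders: published per-residue
#' reference sites and cut-offs exist and should be supplied via
#' [read_reference_table()] when reproducing a specific study.
#'
#' @return Data frame with columns `residue_name`, `site_atoms`
#'   (comma-separated atom names; the site is their centroid) and
#'   `cutoff_angstrom`.
#' @export
default_reference_table <- function() {
  e <- function(res, atoms, cut = 4.5) {
    data.frame(residue_name = res, site_atoms = atoms, cutoff_angstrom = cut)
  }
  rbind(
    e("MET", "SD"), e("CYS", "SG"),
    e("MOX", "SD"), e("CTB", "SG"), e("COX", "SG"),
    e("ALA", "CB"), e("ARG", "NH1,NH2"), e("ASN", "OD1,ND2"),
    e("ASP", "OD1,OD2"), e("GLN", "OE1,NE2"), e("GLU", "OE1,OE2"),
    e("GLY", "CA"), e("HIS", "ND1,NE2"), e("ILE", "CD1"),
    e("LEU", "CD1,CD2"), e("LYS", "NZ"), e("PHE", "CG,CD1,CD2,CE1,CE2,CZ"),
    e("PRO", "CG"), e("SER", "OG"), e("THR", "OG1"),
    e("TRP", "CD2,CE2,CE3,CZ2,CZ3,CH2"), e("TYR", "OH"),
    e("VAL", "CG1,CG2")
  )
}

#' Read / write a residue reference table
#'
#' Tab-separated with columns `residue_name`, `site_atoms` (comma-separated
#' atom names), `cutoff_angstrom`. Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return `read_reference_table`: the table as a data frame.
#' @export
read_reference_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("residue_name", "site_atoms", "cutoff_angstrom")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop_input("reference table lacks column(s): %s",
               paste(miss, collapse = ", "))
  if (any(tab$cutoff_angstrom <= 0))
    stop_input("reference table cut-offs must be positive")
  tab[need]
}

#' @rdname read_reference_table
#' @param table Reference table data frame.
#' @export
write_reference_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' z level of the topmost gold layer
#'
#' Identifies the topmost crystal layer as all slab atoms whose z coordinate
#' lies within `layer_tolerance` of the maximum slab z, and returns their
#' mean z. The default tolerance (0.8 angstrom) sits between thermal jitter
#' and the ~2.35 angstrom Au(111) interlayer spacing, so a thermally
#' roughened top layer is averaged without capturing the layer beneath.
#'
#' @param frame A frame from [get_frame()], or any list with a `coordinates`
#'   matrix in angstrom.
#' @param slab_atoms Integer row indices of slab atoms.
#' @param layer_tolerance Thickness window in angstrom.
#' @return Mean z of the topmost-layer atoms (angstrom).
#' @export
topmost_gold_z <- function(frame, slab_atoms, layer_tolerance = 0.8) {
  if (length(slab_atoms) == 0L) stop_input("empty slab atom set")
  z <- frame$coordinates[slab_atoms, 3]
  top <- max(z)
  mean(z[z >= top - layer_tolerance])
}

resolve_site_rows <- function(residue, ref, atom_names) {
  sites <- trimws(strsplit(ref$site_atoms, ",")[[1]])
  rows <- residue$atom_rows[atom_names[residue$atom_rows] %in% sites]
  if (length(rows) == 0L)
    stop_input("residue %s %d: reference site atom(s) %s not found",
               residue$residue_name, residue$residue_index, ref$site_atoms)
  rows
}

#' Vertical distance between a residue's reference site and the top Au layer
#'
#' The site is the named atom, or the centroid of the named atom set; the
#' distance is z(site) - z(top layer) and may be negative if the site dips
#' below the layer plane.
#'
#' @param frame A frame from [get_frame()].
#' @param residue A residue group from [partition_atoms()].
#' @param ref One row of a reference table (list or single-row data frame
#'   with `site_atoms`).
#' @param top_z Topmost-layer z level from [topmost_gold_z()].
#' @param atom_names Atom name vector for the topology (defaults taken from
#'   `frame$atom_names` if present).
#' @return Signed vertical distance in angstrom.
#' @export
residue_surface_distance <- function(frame, residue, ref, top_z,
                                     atom_names = frame$atom_names) {
  rows <- resolve_site_rows(residue, ref, atom_names)
  mean(frame$coordinates[rows, 3]) - top_z
}

#' Per-residue surface-contact fractions over a trajectory
#'
#' For every peptide residue and frame, computes the distance between the
#' residue's reference site and the topmost gold layer and tests it against
#' the residue-type cut-off (contact when distance <= cut-off; negative
#' distances count as contact). The contact fraction f_i of residue i is the
#' fraction of frames in contact, a number between 0 and 1.
#'
#' @param traj A [trajectory()].
#' @param table Reference table (see [default_reference_table()]).
#' @param method "z" for vertical offset from the topmost-layer mean plane
#'   (default), or "min3d" for the minimum 3-D distance from the site to any
#'   topmost-layer atom under the x/y minimum-image convention.
#' @param layer_tolerance Passed to [topmost_gold_z()].
#' @param keep_matrix Keep the per-frame boolean contact matrix (frames x
#'   residues) in the result.
#' @return A `contact_profile`: residue labels, fractions, frame count, and
#'   optionally the per-frame contact matrix and the distance matrix.
#' @export
compute_contact_fractions <- function(traj, table = default_reference_table(),
                                      method = c("z", "min3d"),
                                      layer_tolerance = 0.8,
                                      keep_matrix = TRUE) {
  method <- match.arg(method)
  parts <- partition_atoms(traj)
  res <- parts$peptide_residues
  types <- vapply(res, function(r) r$residue_name, "")
  missing <- setdiff(unique(types), table$residue_name)
  if (length(missing))
    stop_input("residue type(s) absent from reference table: %s",
               paste(missing, collapse = ", "))
  nf <- n_frames(traj)
  nr <- length(res)
  names_vec <- traj$atoms$name

  # topmost-layer z per frame, vectorised over the slab z matrix
  zslab <- matrix(traj$coords[parts$slab_atoms, 3, ],
                  nrow = length(parts$slab_atoms))
  ztop_max <- apply(zslab, 2L, max)
  in_layer <- sweep(zslab, 2L, ztop_max - layer_tolerance, ">=")
  top_z <- colSums(zslab * in_layer) / colSums(in_layer)

  dist <- matrix(NA_real_, nf, nr)
  for (j in seq_len(nr)) {
    ref <- table[match(types[j], table$residue_name), ]
    rows <- resolve_site_rows(res[[j]], ref, names_vec)
    if (method == "z") {
      site_z <- if (length(rows) == 1L) traj$coords[rows, 3, ]
                else colMeans(matrix(traj$coords[rows, 3, ],
                                     nrow = length(rows)))
      dist[, j] <- site_z - top_z
    } else {
      for (i in seq_len(nf)) {
        site <- colMeans(matrix(traj$coords[rows, , i], ncol = 3L))
        lay <- which(in_layer[, i])
        top_xyz <- matrix(traj$coords[parts$slab_atoms[lay], , i], ncol = 3L)
        dd <- sweep(top_xyz, 2L, site)
        # minimum image in the periodic surface plane only
        for (ax in 1:2) {
          L <- traj$box[i, ax]
          dd[, ax] <- dd[, ax] - L * round(dd[, ax] / L)
        }
        dist[i, j] <- sqrt(min(rowSums(dd^2)))
      }
    }
  }
  cutoffs <- table$cutoff_angstrom[match(types, table$residue_name)]
  contacts <- sweep(dist, 2L, cutoffs, "<=")
  labels <- sprintf("%s%d", types, vapply(res, function(r) r$residue_index, 0))
  out <- list(residue_labels = labels,
              residue_names = types,
              residue_index = vapply(res, function(r) r$residue_index, 0),
              fractions = colMeans(contacts),
              n_frames = nf,
              cutoffs = cutoffs,
              method = method)
  if (keep_matrix) {
    out$per_frame_contacts <- contacts
    out$distances <- dist
  }
  structure(out, class = "contact_profile")
}

#' @export
print.contact_profile <- function(x, ...) {
  cat(sprintf("<contact_profile> %d residues over %d frames (%s distance)\n",
              length(x$fractions), x$n_frames, x$method))
  print(data.frame(residue = x$residue_labels,
                   fraction = round(x$fractions, 4)), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.contact_profile <- function(x, ...) {
  data.frame(position = x$residue_index, residue = x$residue_names,
             contact_fraction = x$fractions)
}

#' Write a contact profile as TSV
#' @param profile A `contact_profile`.
#' @param path Output file.
#' @param header Extra `#`-prefixed header lines.
#' @export
write_contact_profile <- function(profile, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pepsurf contact profile; n_frames=%d; method=%s",
                       profile$n_frames, profile$method), header), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
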