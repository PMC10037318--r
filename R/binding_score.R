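# Residue binding scores: contact fraction combined with the amino acid's
# adsorption free energy at the aqueous Au(111) interface.
#
# The combining operator is the product s_i = f_i * dG_i. The product gives
# 0 for a residue that never touches the surface and the full adsorption
# free energy at permanent contact, and carries kJ/mol units; it is
# nevertheless pluggable via the `combine` argument so alternatives can be
# swapped without touching callers.

#' Default amino-acid adsorption free-energy table (synthetic placeholder)
#'
#' Adsorption free energies (kJ/mol, negative = favourable) for amino acids
#' at the aqueous Au(111) interface. These values are SYNTHETIC defaults
#' with a plausible ordering (sulfur-bearing and aromatic residues strong,
#' small aliphatics weak); they are NOT measured or published numbers.
#' Supply a table of published values via [read_free_energy_table()] for any
#' quantitative use; every entry here carries source tag
#' `"synthetic-default"` as a reminder.
#'
#' @return Data frame with columns `residue_name`, `dG_kJ_per_mol`, `source`.
#' @export
default_free_energy_table <- function() {
  vals <- c(ALA = -3.0, ARG = -8.0, ASN = -4.5, ASP = -5.0, CYS = -16.0,
            GLN = -4.5, GLU = -5.0, GLY = -2.5, HIS = -7.5, ILE = -3.0,
            LEU = -4.0, LYS = -5.5, MET = -12.0, PHE = -7.0, PRO = -4.0,
            SER = -4.0, THR = -9.0, TRP = -9.5, TYR = -10.0, VAL = -3.0,
            MOX = -6.0, CTB = -3.5, COX = -1.0)
  data.frame(residue_name = names(vals), dG_kJ_per_mol = unname(vals),
             source = "synthetic-default")
}

#' Read / write an adsorption free-energy table
#'
#' Tab-separated with columns `residue_name`, `dG_kJ_per_mol` and an
#' optional `source` tag.
#'
#' @param path File path.
#' @return `read_free_energy_table`: the table as a data frame.
#' @export
read_free_energy_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("residue_name", "dG_kJ_per_mol") %in% names(tab)))
    stop_input("free-energy table needs columns residue_name, dG_kJ_per_mol")
  if (!all(is.finite(tab$dG_kJ_per_mol)))
    stop_input("free-energy table contains non-finite values")
  if (is.null(tab$source)) tab$source <- "user"
  tab
}

#' @rdname read_free_energy_table
#' @param table Free-energy table data frame.
#' @export
write_free_energy_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-residue binding scores and cumulative range sums
#'
#' Combines each residue's contact fraction f_i with the adsorption free
#' energy dG of the corresponding amino acid into a binding score
#' s_i = f_i * dG_i (kJ/mol; more negative = stronger effective binding).
#' Cumulative scores are sums of s_i over named residue ranges; the defaults
#' split a 12-mer into the N-terminal half (residues 1-6) and the C-terminal
#' particle-binding half (residues 7-12). When the sequence reaches position
#' 9 the report also carries the position-9 score and its helix-propensity
#' class from [classify_position9()].
#'
#' @param profile A `contact_profile` from [compute_contact_fractions()],
#'   or a data frame with columns `position`, `residue`, `contact_fraction`.
#' @param table Free-energy table (see [default_free_energy_table()]).
#' @param ranges Named list of inclusive 1-based residue index ranges
#'   (length-2 vectors) to sum over; defaults to the two sequence halves
#'   clipped to the sequence length.
#' @param combine Binary function combining (f, dG); default the product.
#' @return A `binding_score_report`.
#' @export
residue_binding_scores <- function(profile, table = default_free_energy_table(),
                                   ranges = NULL, combine = `*`) {
  df <- if (inherits(profile, "contact_profile")) as.data.frame(profile)
        else profile
  stopifnot(all(c("position", "residue", "contact_fraction") %in% names(df)))
  idx <- match(df$residue, table$residue_name)
  if (anyNA(idx))
    stop_input("no adsorption free energy for residue type(s): %s",
               paste(unique(df$residue[is.na(idx)]), collapse = ", "))
  dG <- table$dG_kJ_per_mol[idx]
  s <- combine(df$contact_fraction, dG)
  nres <- max(df$position)
  if (is.null(ranges)) {
    ranges <- list()
    half <- min(6L, nres)
    ranges[["N-half"]] <- c(1L, half)
    if (nres >= 7L) ranges[["C-half"]] <- c(7L, nres)
  }
  rep <- structure(list(
    positions = df$position,
    residue_names = df$residue,
    contact_fractions = df$contact_fraction,
    dG = dG,
    residue_scores = s), class = "binding_score_report")
  rep$cumulative <- vapply(ranges, function(r)
    cumulative_binding_score(rep, r), 0)
  if (nres >= 9L) {
    rep$position9_score <- s[match(9L, df$position)]
    rep$position9_class <- classify_position9(rep$position9_score)
  } else {
    rep$position9_score <- NA_real_
    rep$position9_class <- NA_character_
  }
  rep
}

#' Cumulative binding score over a residue range
#'
#' @param report A `binding_score_report`.
#' @param residue_range Inclusive 1-based `c(first, last)`; a reversed or
#'   zero-length range (first > last) is the empty sum, 0.
#' @return Sum of the member residue scores in kJ/mol.
#' @export
cumulative_binding_score <- function(report, residue_range) {
  stopifnot(length(residue_range) == 2L)
  lo <- residue_range[1]; hi <- residue_range[2]
  if (lo > hi) return(0)
  if (lo < 1L || hi > max(report$positions))
    stop_input("residue range %d-%d outside sequence 1-%d", lo, hi,
               max(report$positions))
  sum(report$residue_scores[report$positions >= lo & report$positions <= hi])
}

#' Helix-propensity class of a position-9 binding score
#'
#' Scores in the single-helix range, -10 to -1 kJ/mol inclusive at both
#' ends, are associated with single-helical nanoparticle superstructures;
#' scores below -10 indicate strong binding (double-helix/aggregate regime)
#' and scores above -1 weak or non-binding.
#'
#' @param score9 Position-9 binding score in kJ/mol.
#' @return One of "strong-binding", "single-helix-range", "weak/non-binding".
#' @export
classify_position9 <- function(score9) {
  if (!is.finite(score9)) stop_input("position-9 score must be finite")
  if (score9 < -10) "strong-binding"
  else if (score9 <= -1) "single-helix-range"
  else "weak/non-binding"
}

#' @export
print.binding_score_report <- function(x, ...) {
  cat("<binding_score_report>\n")
  print(data.frame(position = x$positions, residue = x$residue_names,
                   f = round(x$contact_fractions, 3),
                   dG = x$dG, score = round(x$residue_scores, 3)),
        row.names = FALSE)
  for (nm in names(x$cumulative))
    cat(sprintf("  %s: %.3f kJ/mol\n", nm, x$cumulative[[nm]]))
  if (is.finite(x$position9_score))
    cat(sprintf("  position 9: %.3f kJ/mol (%s)\n", x$position9_score,
                x$position9_class))
  invisible(x)
}

#' @export
as.data.frame.binding_score_report <- function(x, ...) {
  data.frame(position = x$positions, residue = x$residue_names,
             contact_fraction = x$contact_fractions,
             dG_kJ_per_mol = x$dG, score_kJ_per_mol = x$residue_scores)
}

#' Write a binding-score report as TSV and/or JSON
#'
#' @param report A `binding_score_report`.
#' @param path Output file; `.json` writes a JSON document, anything else a
#'   TSV with `#`-prefixed summary header lines.
#' @param header Extra `#`-prefixed header lines (TSV only).
#' @export
write_binding_scores <- function(report, path, header = character()) {
  if (tolower(tools::file_ext(path)) == "json") {
    obj <- list(residues = as.data.frame(report),
                cumulative = as.list(report$cumulative),
                position9_score = report$position9_score,
                position9_class = report$position9_class)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# pepsurf binding scores (kJ/mol)",
                 sprintf("# cumulative %s = %.6f", names(report$cumulative),
                         report$cumulative),
                 if (is.finite(report$position9_score))
                   sprintf("# position9 = %.6f (%s)", report$position9_score,
                           report$position9_class),
                 header), con)
    utils::write.table(as.data.frame(report), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
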