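#' Read a protein structure (CA trace) from a PDB file
#'
#' Parses `ATOM` records with atom name `CA` using fixed-column PDB v3.3
#' fields. Only the first `MODEL` is used, only alternate-location indicator
#' blank or `'A'` is kept, and the first CA encountered wins when a residue
#' carries duplicate CA atoms. `HETATM` records are ignored, so
#' selenomethionine (`MSE`) CA atoms are not read. Residues keep file order;
#' no renumbering is attempted.
#'
#' @param source Path to a PDB file, or a character scalar containing PDB
#'   text (recognised by embedded newlines), or a character vector of lines.
#' @param chain Optional single chain identifier. When unset, the first
#'   chain encountered among CA atoms is used.
#' @param id Structure identifier; defaults to the file stem (or
#'   `"structure"` for inline text).
#'
#' @return A `protein_structure`: a list with `id`, `residue_names`
#'   (3-letter codes), `residue_numbers` (author numbering), and `coords`
#'   (L x 3 matrix of CA positions in Angstrom). Structures whose
#'   consecutive CA distances fall outside (1, 10) Angstrom are flagged via
#'   the `flagged` field (a warning, not a rejection).
#' @export
#' @examples
#' txt <- paste(
#'   "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
#'   "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00",
#'   "ATOM      3  CA  SER A   3       7.600   0.000   0.000  1.00  0.00",
#'   sep = "\n")
#' read_structure(txt)
read_structure <- function(source, chain = NULL, id = NULL) {
  if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
      file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(source))
    src_name <- source
  } else {
    lines <- if (length(source) == 1L) strsplit(source, "\n", fixed = TRUE)[[1]] else source
    if (is.null(id)) id <- "structure"
    src_name <- "<text>"
  }
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]  # first model only

  is_atom <- startsWith(lines, "ATOM")
  atom_lines <- lines[is_atom]
  atom_lineno <- which(is_atom)
  field <- function(x, a, b) substr(x, a, b)
  name <- trimws(field(atom_lines, 13, 16))
  keep <- name == "CA"
  atom_lines <- atom_lines[keep]
  atom_lineno <- atom_lineno[keep]
  altloc <- field(atom_lines, 17, 17)
  keep <- altloc %in% c(" ", "", "A")
  atom_lines <- atom_lines[keep]
  atom_lineno <- atom_lineno[keep]
  if (!length(atom_lines)) {
    stop("empty structure: no CA ATOM records in ", src_name, call. = FALSE)
  }
  chains <- field(atom_lines, 22, 22)
  sel_chain <- if (is.null(chain)) chains[1] else chain
  keep <- chains == sel_chain
  atom_lines <- atom_lines[keep]
  atom_lineno <- atom_lineno[keep]
  if (!length(atom_lines)) {
    stop("empty structure: no CA atoms on chain '", sel_chain, "' in ",
         src_name, call. = FALSE)
  }
  xyz <- vapply(seq_along(atom_lines), function(k) {
    v <- suppressWarnings(as.numeric(c(field(atom_lines[k], 31, 38),
                                       field(atom_lines[k], 39, 46),
                                       field(atom_lines[k], 47, 54))))
    if (anyNA(v)) {
      stop("format error: unparseable coordinates at line ", atom_lineno[k],
           " of ", src_name, call. = FALSE)
    }
    v
  }, numeric(3))
  resname <- trimws(field(atom_lines, 18, 20))
  resseq <- suppressWarnings(as.integer(trimws(field(atom_lines, 23, 26))))
  icode <- field(atom_lines, 27, 27)
  res_key <- paste(resseq, icode)
  first <- !duplicated(res_key)  # one CA per residue, first wins
  coords <- t(xyz)[first, , drop = FALSE]
  new_protein_structure(id, resname[first], resseq[first], coords)
}

new_protein_structure <- function(id, residue_names, residue_numbers, coords,
                                  warn = TRUE) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  storage.mode(coords) <- "double"
  if (nrow(coords) < 3L) {
    stop("structure '", id, "' has fewer than 3 residues", call. = FALSE)
  }
  if (!all(is.finite(coords))) {
    stop("structure '", id, "' has non-finite coordinates", call. = FALSE)
  }
  gaps <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                          coords[-nrow(coords), , drop = FALSE])^2))
  flagged <- any(gaps <= 1.0 | gaps >= 10.0)
  if (flagged && warn) {
    warning("structure '", id, "' has consecutive CA distances outside (1, 10) A",
            call. = FALSE)
  }
  structure(list(id = id,
                 residue_names = as.character(residue_names),
                 residue_numbers = as.integer(residue_numbers),
                 coords = coords,
                 flagged = flagged),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure> ", x$id, ": ", nrow(x$coords), " CA residues",
      if (isTRUE(x$flagged)) " [flagged: irregular CA spacing]", "\n", sep = "")
  invisible(x)
}

#' @export
length.protein_structure <- function(x) nrow(x$coords)

#' Tidy a protein structure into a residue table
#'
#' @param x A `protein_structure`.
#' @param ... Unused.
#' @return A tibble with one row per residue: `id`, `index`, `resname`,
#'   `resnum`, `x`, `y`, `z`.
#' @export
tidy.protein_structure <- function(x, ...) {
  xyz <- x$coords
  tibble::tibble(id = x$id,
                 index = seq_len(nrow(xyz)),
                 resname = x$residue_names,
                 resnum = x$residue_numbers,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

#' Map a 3-letter residue code to its 1-letter IUPAC code
#'
#' The 20 standard amino acids map to their one-letter codes; anything else
#' (including modified residues such as MSE) maps to `"X"`.
#'
#' @param resname Character vector of 3-letter codes.
#' @return Character vector of 1-letter codes.
#' @export
#' @examples
#' three_to_one(c("ALA", "GLY", "MSE"))
three_to_one <- function(resname) {
  out <- unname(AA_THREE_TO_ONE[toupper(resname)])
  out[is.na(out)] <- "X"
  out
}

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Write a multiple structure alignment as gapped FASTA
#'
#' One record per structure, header = structure id, sequence = 1-letter
#' residue codes with `'-'` at gap positions. All records have identical
#' length (the number of alignment columns).
#'
#' @param msta An `msta_alignment`.
#' @param structures List of `protein_structure` objects covering every row.
#' @param path Optional file path; when given the text is also written there.
#' @return The FASTA text, invisibly when `path` is given.
#' @export
write_alignment_fasta <- function(msta, structures, path = NULL) {
  ids <- vapply(structures, function(s) s$id, character(1))
  rows <- match(msta$structure_ids, ids)
  if (anyNA(rows)) {
    stop("consistency error: alignment rows ",
         paste(msta$structure_ids[is.na(rows)], collapse = ", "),
         " have no matching structure", call. = FALSE)
  }
  recs <- character(0)
  for (r in seq_along(msta$structure_ids)) {
    s <- structures[[rows[r]]]
    ent <- msta$table[r, ]
    letters1 <- ifelse(is.na(ent), "-", three_to_one(s$residue_names[ifelse(is.na(ent), 1L, ent)]))
    recs <- c(recs, paste0(">", msta$structure_ids[r]),
              paste(letters1, collapse = ""))
  }
  txt <- paste0(paste(recs, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(recs, path)
    return(invisible(txt))
  }
  txt
}

#' Dump parsed CA coordinates as TSV
#'
#' Debug surface for the reader: columns `id`, `index`, `resname`, `resnum`,
#' `x`, `y`, `z` with full double precision, so that
#' [read_structure_tsv()] reconstructs an equal structure.
#'
#' @param s A `protein_structure`.
#' @param path Optional output path.
#' @return The TSV text (invisibly when `path` is given).
#' @export
write_structure_tsv <- function(s, path = NULL) {
  df <- tidy.protein_structure(s)
  lines <- c(paste(names(df), collapse = "\t"),
             sprintf("%s\t%d\t%s\t%d\t%.17g\t%.17g\t%.17g",
                     df$id, df$index, df$resname, df$resnum,
                     df$x, df$y, df$z))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(txt))
  }
  txt
}

#' Read a structure back from its TSV dump
#'
#' @param source Path or TSV text produced by [write_structure_tsv()].
#' @return A `protein_structure`.
#' @export
read_structure_tsv <- function(source) {
  lines <- if (length(source) == 1L && !grepl("\n", source, fixed = TRUE) &&
               file.exists(source)) {
    readLines(source, warn = FALSE)
  } else if (length(source) == 1L) {
    strsplit(source, "\n", fixed = TRUE)[[1]]
  } else source
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  new_protein_structure(df$id[1], df$resname, df$resnum,
                        cbind(df$x, df$y, df$z))
}

#' Write a CA trace as a minimal PDB file
#'
#' @param s A `protein_structure`.
#' @param path Output path.
#' @param chain Chain identifier to emit (default `"A"`).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path, chain = "A") {
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(s$coords)), s$residue_names, chain, s$residue_numbers,
    s$coords[, 1], s$coords[, 2], s$coords[, 3])
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write superposed family coordinates as a multi-model PDB
#'
#' Every structure is transformed into the first member's frame using the
#' transforms recorded during progressive alignment.
#'
#' @param msta An `msta_alignment` carrying per-row transforms.
#' @param structures List of `protein_structure` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_superposed_pdb <- function(msta, structures, path) {
  ids <- vapply(structures, function(s) s$id, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_along(msta$structure_ids)) {
    s <- structures[[match(msta$structure_ids[r], ids)]]
    T <- msta$transforms[[r]]
    xyz <- transform_coords(s$coords, T)
    writeLines(sprintf("MODEL %8d", r), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), s$residue_names, "A", s$residue_numbers,
      xyz[, 1], xyz[, 2], xyz[, 3]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
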