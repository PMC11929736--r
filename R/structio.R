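# Single atom table underlies a structure: every atom appears exactly once.
# Columns: record ("ATOM"/"HETATM"), serial, name, resname, chain, resseq,
# x, y, z, occ, element.
.atom_cols <- c("record", "serial", "name", "resname", "chain", "resseq",
                "x", "y", "z", "occ", "element")

#' Construct a structure from an atom table
#'
#' A structure is a hierarchical atom model (chains > residues > atoms)
#' stored as a single data frame in file order. Calcium ions are HETATM
#' records with residue name `"CA"`; any other HETATM residue (except
#' water, `"HOH"`) is treated as a bound ligand.
#'
#' @param atoms data frame with columns `record`, `serial`, `name`,
#'   `resname`, `chain`, `resseq`, `x`, `y`, `z`, `occ`, `element`.
#' @param id structure identifier string.
#' @return An object of class `lp_structure`.
#' @export
new_structure <- function(atoms, id = "structure") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.atom_cols, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  if (any(!is.finite(coords))) stop("non-finite atom coordinates")
  if (any(!nzchar(atoms$element))) stop("empty element symbols")
  dup <- duplicated(atoms[, c("chain", "resseq", "resname", "name")])
  if (any(dup))
    stop("duplicate atom name within a residue: ",
         paste(unique(atoms$name[dup]), collapse = ", "))
  structure(list(id = id, atoms = atoms), class = "lp_structure")
}

#' @export
print.lp_structure <- function(x, ...) {
  a <- x$atoms
  cat("<lp_structure> ", x$id, ": ", nrow(a), " atoms, ",
      length(unique(a$chain)), " chain(s), ",
      nrow(ca_ions(x)), " Ca ion(s)", sep = "")
  lig <- unique(a$resname[a$record == "HETATM" &
                            !(a$resname %in% c("CA", "HOH"))])
  if (length(lig)) cat(", ligands: ", paste(lig, collapse = ","), sep = "")
  cat("\n")
  invisible(x)
}

#' Calcium ions of a structure
#'
#' @param s an `lp_structure`.
#' @return Atom table rows for Ca ions (HETATM, residue name `"CA"`).
#' @export
ca_ions <- function(s) {
  a <- s$atoms
  a[a$record == "HETATM" & a$resname == "CA", , drop = FALSE]
}

#' Atom coordinates as a matrix
#' @param x an `lp_structure`, `lp_ligand`, or atom data frame.
#' @return N x 3 numeric matrix (angstrom).
#' @export
coords <- function(x) {
  a <- if (is.data.frame(x)) x else x$atoms
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

# ---- reading ---------------------------------------------------------------

.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("no ATOM or HETATM records in ", path)
  for (i in which(is_atom)) {
    ln <- lines[i]
    for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
      v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
      if (is.na(v))
        stop("malformed coordinate field at line ", i, " of ", path)
    }
  }
  invisible(TRUE)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records (fixed-column PDB). Hydrogens are skipped by
#' default: all downstream contact and clash analysis is heavy-atom based.
#' Alternate locations are resolved to the highest-occupancy conformer,
#' ties broken by altloc letter order. Residue numbering is taken verbatim
#' from the file.
#'
#' @param path PDB file path.
#' @param keep_hydrogens keep H/D atoms (default `FALSE`).
#' @param chain optional chain identifier(s) to restrict to, e.g. `"A"`
#'   to pick one protomer of a homodimer.
#' @param id structure id; defaults to the file base name.
#' @return An [new_structure()] object.
#' @export
read_pdb <- function(path, keep_hydrogens = FALSE, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                          rm.alt = FALSE))
  a <- pdb$atom
  a$alt[is.na(a$alt)] <- ""
  a$chain[is.na(a$chain)] <- " "
  # altloc: keep highest occupancy, ties by altloc letter order
  key <- paste(a$chain, a$resno, a$resid, a$elety, sep = "\r")
  ord <- order(key, -a$o, a$alt)
  a <- a[ord, ]
  a <- a[!duplicated(paste(a$chain, a$resno, a$resid, a$elety, sep = "\r")), ]
  a <- a[order(a$eleno), ]
  if (!keep_hydrogens) a <- a[!(a$elesy %in% c("H", "D")), ]
  if (!is.null(chain)) a <- a[a$chain %in% chain, ]
  if (nrow(a) == 0L) stop("no atoms retained from ", path)
  atoms <- data.frame(record = a$type, serial = a$eleno, name = a$elety,
                      resname = a$resid, chain = a$chain, resseq = a$resno,
                      x = a$x, y = a$y, z = a$z,
                      occ = ifelse(is.na(a$o), 1, a$o),
                      element = toupper(a$elesy),
                      stringsAsFactors = FALSE)
  new_structure(atoms, id = if (is.null(id)) sub("\\.pdb$", "", basename(path)) else id)
}

# ---- writing ---------------------------------------------------------------

.pdb_atom_line <- function(record, serial, name, resname, chain, resseq,
                           x, y, z, occ, element) {
  if (max(abs(c(x, y, z))) >= 10000)
    stop("format overflow: coordinate magnitude >= 10000 A cannot be ",
         "written in fixed-column PDB")
  # atom name column convention: 1-2 letter elements start in column 14
  nm <- if (nchar(name) >= 4L) substr(name, 1, 4) else
    if (nchar(element) == 2L) sprintf("%-4s", name) else
      sprintf(" %-3s", name)
  sprintf("%-6s%5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, resname, substr(chain, 1, 1),
          resseq %% 10000L, x, y, z, occ, 0, element)
}

#' Write a structure to PDB format
#'
#' Fixed-column ATOM/HETATM records; a TER record closes each chain of
#' ATOM records; HETATM ions and ligands follow their chain's ATOM block;
#' END terminates the file. Coordinates with magnitude >= 10000 angstrom
#' cannot be represented and raise a format-overflow error.
#'
#' @param s an `lp_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  if (nrow(a) == 0L) stop("refusing to write empty structure")
  lines <- character(0)
  serial <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    atom_rows <- sub[sub$record == "ATOM", , drop = FALSE]
    het_rows <- sub[sub$record == "HETATM", , drop = FALSE]
    for (i in seq_len(nrow(atom_rows))) {
      serial <- serial + 1L
      r <- atom_rows[i, ]
      lines <- c(lines, .pdb_atom_line("ATOM", serial, r$name, r$resname,
                                       r$chain, r$resseq, r$x, r$y, r$z,
                                       r$occ, r$element))
    }
    if (nrow(atom_rows) > 0L) {
      serial <- serial + 1L
      last <- atom_rows[nrow(atom_rows), ]
      lines <- c(lines, sprintf("%-6s%5d      %-3s %1s%4d", "TER", serial,
                                last$resname, last$chain, last$resseq))
    }
    for (i in seq_len(nrow(het_rows))) {
      serial <- serial + 1L
      r <- het_rows[i, ]
      lines <- c(lines, .pdb_atom_line("HETATM", serial, r$name, r$resname,
                                       r$chain, r$resseq, r$x, r$y, r$z,
                                       r$occ, r$element))
    }
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

# ---- selection -------------------------------------------------------------

#' Select atoms of a structure
#'
#' Filters the atom table by any combination of keyword filters, or by an
#' arbitrary predicate on the atom table. Results keep file order; an
#' empty selection returns a zero-row table.
#'
#' @param s an `lp_structure`.
#' @param chain,resname,resseq,name,element,record optional vectors of
#'   admissible values.
#' @param pred optional function taking the atom data frame and returning
#'   a logical vector.
#' @return Atom data frame (possibly zero rows), in file order.
#' @export
select_atoms <- function(s, chain = NULL, resname = NULL, resseq = NULL,
                         name = NULL, element = NULL, record = NULL,
                         pred = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain))   keep <- keep & a$chain %in% chain
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(resseq))  keep <- keep & a$resseq %in% resseq
  if (!is.null(name))    keep <- keep & a$name %in% name
  if (!is.null(element)) keep <- keep & a$element %in% element
  if (!is.null(record))  keep <- keep & a$record %in% record
  if (!is.null(pred))    keep <- keep & pred(a)
  a[keep, , drop = FALSE]
}

#' Extract a bound ligand as a template
#'
#' Pulls the heavy atoms of a named HETATM residue out of a structure,
#' keeping its coordinates in the structure's frame.
#'
#' @param s an `lp_structure`.
#' @param name ligand residue name (e.g. `"GLC"`, `"TRE"`, `"GOL"`).
#' @return An [new_ligand()] object.
#' @export
extract_ligand <- function(s, name) {
  a <- s$atoms
  rows <- a[a$record == "HETATM" & a$resname == name, , drop = FALSE]
  if (nrow(rows) == 0L) {
    avail <- unique(a$resname[a$record == "HETATM"])
    stop("no HETATM residue named '", name, "'; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "<none>")
  }
  rows <- rows[!(rows$element %in% c("H", "D")), , drop = FALSE]
  new_ligand(name = .ligand_common_name(name),
             atoms = rows[, c("name", "element", "x", "y", "z")],
             resname = name)
}

.ligand_common_name <- function(resname) {
  switch(resname, GOL = "glycerol", GLC = "glucose", TRE = "trehalose",
         tolower(resname))
}

#' Insert a ligand into a structure as a HETATM residue
#'
#' @param s an `lp_structure`.
#' @param lig an `lp_ligand`.
#' @param chain chain id for the inserted residue.
#' @param resseq residue number for the inserted residue.
#' @return A new `lp_structure` containing the ligand.
#' @export
insert_ligand <- function(s, lig, chain = "A", resseq = 301L) {
  la <- lig$atoms
  add <- data.frame(record = "HETATM",
                    serial = max(s$atoms$serial) + seq_len(nrow(la)),
                    name = la$name, resname = lig$resname, chain = chain,
                    resseq = resseq, x = la$x, y = la$y, z = la$z,
                    occ = 1, element = la$element, stringsAsFactors = FALSE)
  new_structure(rbind(s$atoms, add), id = s$id)
}
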