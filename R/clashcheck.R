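# Ligand transplantation and van der Waals steric-clash classification.
#
# The classification mirrors the superposition-only protocol used to
# compare pockets: the reference-bound ligand is carried rigidly into the
# target frame by the calcium-anchored superposition and every
# ligand/receptor heavy-atom pair closer than r1 + r2 - tolerance is a
# clash. No re-docking, torsion sampling or relaxation.

#' Van der Waals radius table
#'
#' Bondi radii for the elements of protein and sugar heavy atoms.
#' All radii must lie in (0.5, 3) angstrom and the table must cover at
#' least C, N, O and S.
#'
#' @param ... named overrides or additions, e.g. `SE = 1.90`.
#' @return Named numeric vector, element symbol to radius (angstrom).
#' @export
vdw_table <- function(...) {
  tab <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
  over <- c(...)
  if (length(over)) tab[names(over)] <- over
  if (!all(c("C", "N", "O", "S") %in% names(tab)))
    stop("vdW table must cover C, N, O, S")
  if (any(tab <= 0.5 | tab >= 3.0))
    stop("vdW radii must lie in (0.5, 3.0) angstrom")
  tab
}

#' Transplant a reference-bound ligand into a target pocket
#'
#' Extracts the named ligand from the reference complex and maps its
#' coordinates into the target frame with the calcium-anchored
#' superposition ([ca_anchor_superpose()]) of the reference onto the
#' target. The ligand is kept rigid in its bound pose.
#'
#' @param reference_complex `lp_structure` containing the ligand and a Ca
#'   site.
#' @param target `lp_structure` with a Ca site.
#' @param ligand_name HETATM residue name of the ligand (e.g. `"TRE"`).
#' @param anchor,shell_radius passed to [ca_anchor_superpose()].
#' @return An `lp_ligand` in the target frame, with attribute `fallback`
#'   set if the superposition degenerated to translation-only.
#' @export
transplant_ligand <- function(reference_complex, target, ligand_name,
                              anchor = NULL, shell_radius = 3.0) {
  lig <- extract_ligand(reference_complex, ligand_name)
  fit <- ca_anchor_superpose(reference_complex, target, anchor = anchor,
                             shell_radius = shell_radius)
  out <- apply_transform(lig, fit$transform)
  attr(out, "fallback") <- isTRUE(fit$fallback)
  attr(out, "anchor_rmsd") <- fit$rmsd
  out
}

#' Count steric clashes between a ligand and a receptor
#'
#' Reports a clash pair for every ligand/receptor heavy-atom pair with
#' distance below `r1 + r2 - tolerance`. By default the receptor atom set
#' excludes the pocket ion(s), waters, and any receptor-bound ligand
#' (HETATM residues), so the probe is tested against the protein only.
#'
#' @param ligand `lp_ligand` in the receptor frame.
#' @param receptor `lp_structure`.
#' @param vdw named radius table from [vdw_table()].
#' @param tolerance clash tolerance in angstrom (default 0.4; 0 gives a
#'   strict hard-sphere test).
#' @param exclude_het drop receptor HETATM records (ions, waters, bound
#'   ligands) from the receptor set (default `TRUE`).
#' @return List of class `lp_clash_report`: `n_clashes`, `worst_overlap`,
#'   `pairs` (data frame), `label` (`"clash(+)"` or `"clash(-)"`),
#'   `tolerance`, `probe`.
#' @export
count_clashes <- function(ligand, receptor, vdw = vdw_table(),
                          tolerance = 0.4, exclude_het = TRUE) {
  stopifnot(tolerance >= 0)
  rec <- receptor$atoms
  if (exclude_het) rec <- rec[rec$record == "ATOM", , drop = FALSE]
  lat <- ligand$atoms
  els <- unique(c(lat$element, rec$element))
  missing_el <- setdiff(els, names(vdw))
  if (length(missing_el))
    stop("element(s) missing from vdW table: ",
         paste(missing_el, collapse = ", "))
  pairs <- data.frame(ligand_atom = character(0), chain = character(0),
                      resname = character(0), resseq = integer(0),
                      receptor_atom = character(0), distance = numeric(0),
                      overlap = numeric(0), stringsAsFactors = FALSE)
  if (nrow(rec) > 0L && nrow(lat) > 0L) {
    D <- .pairwise_dist(as.matrix(lat[, c("x", "y", "z")]),
                        as.matrix(rec[, c("x", "y", "z")]))
    lim <- outer(vdw[lat$element], vdw[rec$element], "+") - tolerance
    idx <- which(D < lim, arr.ind = TRUE)
    if (nrow(idx)) {
      pairs <- data.frame(ligand_atom = lat$name[idx[, 1]],
                          chain = rec$chain[idx[, 2]],
                          resname = rec$resname[idx[, 2]],
                          resseq = rec$resseq[idx[, 2]],
                          receptor_atom = rec$name[idx[, 2]],
                          distance = D[idx],
                          overlap = lim[idx] - D[idx],
                          stringsAsFactors = FALSE)
      pairs <- pairs[order(-pairs$overlap), ]
      rownames(pairs) <- NULL
    }
  }
  out <- list(n_clashes = nrow(pairs),
              worst_overlap = if (nrow(pairs)) max(pairs$overlap) else 0,
              pairs = pairs,
              label = if (nrow(pairs)) "clash(+)" else "clash(-)",
              tolerance = tolerance,
              probe = ligand$name)
  class(out) <- "lp_clash_report"
  out
}

#' @export
print.lp_clash_report <- function(x, ...) {
  cat("<lp_clash_report> probe ", x$probe, ": ", x$label, ", ",
      x$n_clashes, " clash pair(s), worst overlap ",
      round(x$worst_overlap, 3), " A (tolerance ", x$tolerance, ")\n",
      sep = "")
  invisible(x)
}

#' Classify a pocket from its clash report
#'
#' A pocket is `"narrow"` when the disaccharide probe clashes
#' (`clash(+)`) and `"broad"` otherwise.
#'
#' @param report an `lp_clash_report`.
#' @return `"narrow"` or `"broad"`, with the probe name as attribute.
#' @export
classify_pocket <- function(report) {
  out <- if (report$n_clashes >= 1L) "narrow" else "broad"
  attr(out, "probe") <- report$probe
  out
}
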