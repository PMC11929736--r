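# Pocket geometry: calcium coordination bonds, ligand-protein hydrogen
# bonds, and pocket-aperture distances distinguishing narrow from broad
# sugar-binding pockets.
#
# Cutoffs are heavy-atom distance heuristics standard in crystallographic
# practice: coordination 2.8 A (metal-O/N), hydrogen bond 3.5 A
# (donor-acceptor, no angle term). Both are configurable.

.pairwise_dist <- function(A, B) {
  # |A_i - B_j| for N x 3, M x 3 -> N x M
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Calcium coordination contacts
#'
#' Lists every O or N atom (protein or ligand) within `cutoff` of the
#' pocket ion, sorted by distance.
#'
#' @param s an `lp_structure`.
#' @param ion `"auto"` (the single Ca ion) or an atom table row.
#' @param cutoff coordination distance cutoff in angstrom (default 2.8).
#' @return Data frame of class `lp_contacts` with columns `kind`,
#'   `chain`, `resname`, `resseq`, `name`, `element`, `distance`.
#' @export
coordination_contacts <- function(s, ion = "auto", cutoff = 2.8) {
  stopifnot(cutoff > 0)
  if (identical(ion, "auto")) {
    ion <- ca_ions(s)
    if (nrow(ion) == 0L) stop("no Ca ion found in structure ", s$id)
    if (nrow(ion) > 1L) stop("multiple Ca ions; pass one explicitly")
  }
  a <- s$atoms
  cand <- a$element %in% c("O", "N") & a$serial != ion$serial
  a <- a[cand, , drop = FALSE]
  d <- sqrt((a$x - ion$x)^2 + (a$y - ion$y)^2 + (a$z - ion$z)^2)
  keep <- d <= cutoff
  out <- data.frame(kind = rep("coordination", sum(keep)),
                    chain = a$chain[keep], resname = a$resname[keep],
                    resseq = a$resseq[keep], name = a$name[keep],
                    element = a$element[keep], distance = d[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("lp_contacts", class(out))
  out
}

#' Ligand-protein hydrogen bonds
#'
#' Heavy-atom donor/acceptor pairs: ligand O/N atoms against protein
#' (ATOM record) O/N atoms with distance at most `cutoff`. Pairs in which
#' both partners coordinate the pocket ion (both within
#' `coordination_cutoff` of it) are attributed to the coordination sphere
#' and excluded.
#'
#' @param s an `lp_structure` (the receptor).
#' @param ligand an `lp_ligand` placed in the frame of `s`.
#' @param cutoff hydrogen-bond distance cutoff in angstrom (default 3.5).
#' @param coordination_cutoff cutoff used for the ion-coordination
#'   exclusion (default 2.8).
#' @return Data frame of class `lp_contacts` with ligand atom, protein
#'   atom and distance per bond, sorted by distance.
#' @export
hydrogen_bonds <- function(s, ligand, cutoff = 3.5,
                           coordination_cutoff = 2.8) {
  stopifnot(cutoff > 0)
  prot <- select_atoms(s, record = "ATOM", element = c("O", "N"))
  lat <- ligand$atoms[ligand$atoms$element %in% c("O", "N"), , drop = FALSE]
  if (nrow(prot) == 0L || nrow(lat) == 0L) {
    out <- data.frame(kind = character(0), ligand_atom = character(0),
                      chain = character(0), resname = character(0),
                      resseq = integer(0), name = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("lp_contacts", class(out))
    return(out)
  }
  D <- .pairwise_dist(as.matrix(lat[, c("x", "y", "z")]), coords(prot))
  idx <- which(D <= cutoff, arr.ind = TRUE)
  out <- data.frame(kind = rep("hydrogen_bond", nrow(idx)),
                    ligand_atom = lat$name[idx[, 1]],
                    chain = prot$chain[idx[, 2]],
                    resname = prot$resname[idx[, 2]],
                    resseq = prot$resseq[idx[, 2]],
                    name = prot$name[idx[, 2]],
                    distance = D[idx], stringsAsFactors = FALSE)
  ions <- ca_ions(s)
  if (nrow(ions) == 1L && nrow(out) > 0L) {
    dl <- sqrt((lat$x - ions$x)^2 + (lat$y - ions$y)^2 + (lat$z - ions$z)^2)
    dp <- sqrt((prot$x - ions$x)^2 + (prot$y - ions$y)^2 +
                 (prot$z - ions$z)^2)
    coord_pair <- dl[idx[, 1]] <= coordination_cutoff &
      dp[idx[, 2]] <= coordination_cutoff
    out <- out[!coord_pair, , drop = FALSE]
  }
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  class(out) <- c("lp_contacts", class(out))
  out
}

.resolve_one_atom <- function(s, sel) {
  hit <- select_atoms(s, chain = sel$chain, resname = sel$resname,
                      resseq = sel$resseq, name = sel$name)
  if (nrow(hit) == 0L)
    stop("aperture selector matches no atom: ",
         paste(unlist(sel), collapse = "/"))
  if (nrow(hit) > 1L)
    stop("ambiguous aperture selector ", paste(unlist(sel), collapse = "/"),
         "; candidates: ",
         paste(paste(hit$chain, hit$resname, hit$resseq, hit$name,
                     sep = ":"), collapse = ", "))
  hit
}

#' Pocket aperture distances
#'
#' Measures the Euclidean distance between named atom pairs shaping the
#' sugar-binding pocket (the flanking-wall separations in synthetic
#' pockets; user-chosen residue pairs in real structures).
#'
#' @param s an `lp_structure`.
#' @param pairs list of pairs; each element is a list of two selector
#'   lists, each with any of `chain`, `resname`, `resseq`, `name`, and
#'   each resolving to exactly one atom.
#' @return List of class `lp_pocket_metrics`: `pairs` (data frame with a
#'   `distance` column), `summary_min`, `summary_mean`.
#' @export
pocket_apertures <- function(s, pairs) {
  rows <- lapply(pairs, function(pr) {
    a <- .resolve_one_atom(s, pr[[1]])
    b <- .resolve_one_atom(s, pr[[2]])
    data.frame(resname_a = a$resname, resseq_a = a$resseq, atom_a = a$name,
               resname_b = b$resname, resseq_b = b$resseq, atom_b = b$name,
               distance = sqrt(sum((coords(a) - coords(b))^2)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  out <- list(pairs = tab, summary_min = min(tab$distance),
              summary_mean = mean(tab$distance))
  class(out) <- "lp_pocket_metrics"
  out
}

#' @export
print.lp_pocket_metrics <- function(x, ...) {
  cat("<lp_pocket_metrics> ", nrow(x$pairs), " pair(s); min ",
      round(x$summary_min, 2), " A, mean ", round(x$summary_mean, 2),
      " A\n", sep = "")
  print(x$pairs)
  invisible(x)
}
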