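# Rigid-body least-squares superposition, including the calcium-anchored
# variant used to align sugar-binding pockets across structures.

#' Construct a rigid transform
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1).
#' @param translation length-3 numeric vector (angstrom).
#' @return An object of class `lp_transform` mapping row-vector
#'   coordinates `x` to `x %*% t(rotation) + translation`.
#' @export
new_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation is not orthonormal to 1e-8")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det +1)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "lp_transform")
}

#' @export
print.lp_transform <- function(x, ...) {
  cat("<lp_transform>\n rotation:\n")
  print(round(x$rotation, 6))
  cat(" translation:", round(x$translation, 6), "\n")
  invisible(x)
}

#' Invert a rigid transform
#' @param tr an `lp_transform`.
#' @return The inverse `lp_transform`.
#' @export
invert_transform <- function(tr) {
  new_transform(t(tr$rotation), -as.numeric(t(tr$rotation) %*% tr$translation))
}

#' Compose two rigid transforms
#' @param first,second `lp_transform`s; `second` is applied after `first`.
#' @return The composed `lp_transform`.
#' @export
compose_transforms <- function(first, second) {
  new_transform(second$rotation %*% first$rotation,
                as.numeric(second$rotation %*% first$translation) +
                  second$translation)
}

#' Apply a rigid transform
#'
#' Maps every atom coordinate `x` to `R x + t`; topology is unchanged.
#' Works on structures, ligand templates, and bare N x 3 matrices.
#'
#' @param x an `lp_structure`, `lp_ligand`, or N x 3 matrix.
#' @param tr an `lp_transform`.
#' @return Object of the same class with transformed coordinates.
#' @export
apply_transform <- function(x, tr) {
  f <- function(m) sweep(m %*% t(tr$rotation), 2, tr$translation, "+")
  if (is.matrix(x)) return(f(x))
  m <- f(coords(x))
  if (inherits(x, "lp_structure") || inherits(x, "lp_ligand")) {
    x$atoms$x <- m[, 1]; x$atoms$y <- m[, 2]; x$atoms$z <- m[, 3]
    return(x)
  }
  stop("cannot transform object of class ", paste(class(x), collapse = "/"))
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of `P`
#' mapped onto `Q` (closed-form SVD solution; a reflection is corrected by
#' flipping the sign of the smallest singular vector so det is always +1).
#' With fewer than 3 points rotation is under-determined and the fit falls
#' back to a centroid translation with identity rotation, flagged in the
#' result.
#'
#' @param P,Q N x 3 coordinate matrices (same N).
#' @return An object of class `lp_superposition`: list with `transform`
#'   (`lp_transform`), `rmsd`, `n_atoms`, `anchor_kind`, `fallback`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q)))
    stop("dimension mismatch: P is ", nrow(P), "x3, Q is ", nrow(Q), "x3")
  n <- nrow(P)
  if (n == 0L) stop("no points to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  fallback <- n < 3L
  if (fallback) {
    R <- diag(3)
  } else {
    H <- crossprod(sweep(P, 2, cp), sweep(Q, 2, cq))
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    if (d == 0) d <- 1
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  t_vec <- cq - as.numeric(R %*% cp)
  tr <- new_transform(R, t_vec)
  resid <- apply_transform(P, tr) - Q
  res <- list(transform = tr,
              rmsd = sqrt(mean(rowSums(resid^2))),
              n_atoms = n,
              anchor_kind = "custom",
              fallback = fallback)
  class(res) <- "lp_superposition"
  res
}

#' @export
print.lp_superposition <- function(x, ...) {
  cat("<lp_superposition> ", x$n_atoms, " atoms, rmsd ",
      format(x$rmsd, digits = 6), " A, anchor ", x$anchor_kind,
      if (isTRUE(x$fallback)) " (translation-only fallback)", "\n", sep = "")
  invisible(x)
}

# resolve anchor atoms in a structure. An anchor spec is a data frame with
# columns resname, resseq, name; atoms are matched on that triple. The
# "ca_shell" method selects protein/ligand O and N atoms within `radius`
# of the single Ca ion.
.resolve_anchor <- function(s, anchor, radius = 3.0) {
  ion <- ca_ions(s)
  if (nrow(ion) == 0L) stop("no Ca ion in structure ", s$id)
  if (nrow(ion) > 1L)
    stop("anchor ambiguity: ", nrow(ion), " Ca ions in structure ", s$id,
         " (use the chain selector of read_pdb)")
  a <- s$atoms
  if (is.null(anchor)) {
    d <- sqrt((a$x - ion$x)^2 + (a$y - ion$y)^2 + (a$z - ion$z)^2)
    sel <- a[a$element %in% c("O", "N") & d <= radius, , drop = FALSE]
  } else {
    anchor <- as.data.frame(anchor, stringsAsFactors = FALSE)
    key <- paste(a$resname, a$resseq, a$name, sep = "\r")
    want <- paste(anchor$resname, anchor$resseq, anchor$name, sep = "\r")
    sel <- a[match(want, key), , drop = FALSE]
    if (anyNA(sel$serial))
      stop("anchor atoms not found in ", s$id, ": ",
           paste(want[is.na(sel$serial)], collapse = "; "))
  }
  list(ion = ion, shell = sel)
}

#' Calcium-anchored superposition of two pocket structures
#'
#' Superposes `moving` onto `fixed` by a Kabsch fit over an anchor atom
#' set -- by default the pocket Ca ion plus the O/N atoms of its
#' coordination shell (the EPN/WND motif oxygens in the synthetic
#' pockets) -- followed by a final residual translation that maps the two
#' Ca ions exactly onto each other. The reported RMSD is computed over the
#' anchor set after the full transform.
#'
#' Anchor atoms are matched between the two structures by
#' (residue name, residue number, atom name); a custom anchor table with
#' those columns can be supplied for structures whose numbering differs.
#'
#' @param moving,fixed `lp_structure`s, each containing exactly one Ca
#'   ion.
#' @param anchor optional data frame (`resname`, `resseq`, `name`) naming
#'   the anchor atoms; default selects the Ca coordination shell of
#'   `fixed` and requires the same atoms in `moving`.
#' @param shell_radius radius (angstrom) used when auto-selecting the
#'   coordination-shell anchor atoms.
#' @return An `lp_superposition` whose transform maps `moving`
#'   coordinates into the frame of `fixed`.
#' @export
ca_anchor_superpose <- function(moving, fixed, anchor = NULL,
                                shell_radius = 3.0) {
  rf <- .resolve_anchor(fixed, anchor, shell_radius)
  if (is.null(anchor)) {
    anchor <- rf$shell[, c("resname", "resseq", "name")]
  }
  rm_ <- .resolve_anchor(moving, anchor, shell_radius)
  rf <- .resolve_anchor(fixed, anchor, shell_radius)
  P <- rbind(coords(rm_$ion), coords(rm_$shell))
  Q <- rbind(coords(rf$ion), coords(rf$shell))
  if (nrow(P) < 3L) {
    warning("fewer than 3 anchor atoms; translation-only superposition")
    tr <- new_transform(diag(3), as.numeric(coords(rf$ion) - coords(rm_$ion)))
    fit <- list(transform = tr, rmsd = NA_real_, n_atoms = nrow(P),
                anchor_kind = "ca_site", fallback = TRUE)
    class(fit) <- "lp_superposition"
  } else {
    fit <- kabsch(P, Q)
    # exact Ca-on-Ca residual translation
    ca_m <- apply_transform(coords(rm_$ion), fit$transform)
    shift <- as.numeric(coords(rf$ion)) - as.numeric(ca_m)
    fit$transform <- new_transform(fit$transform$rotation,
                                   fit$transform$translation + shift)
    resid <- apply_transform(P, fit$transform) - Q
    fit$rmsd <- sqrt(mean(rowSums(resid^2)))
    fit$anchor_kind <- "ca_site"
  }
  fit
}
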