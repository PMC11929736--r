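# Idealized sugar ligand templates.
#
# Geometry is built from internal coordinates (chair-ring radii/puckering),
# not taken from any deposited structure, so no download is required.
# Bonded distances fall in standard ranges (C-C 1.50-1.56, C-O 1.38-1.46 A);
# torsions and anomeric stereochemistry are simplified and not meant to be
# crystallographically faithful.

#' Construct a ligand template
#'
#' @param name common name (`"glycerol"`, `"glucose"`, `"trehalose"`, or
#'   other).
#' @param atoms data frame with columns `name`, `element`, `x`, `y`, `z`
#'   (heavy atoms only).
#' @param key_atoms character vector of anchor atom names; must resolve to
#'   members of `atoms`.
#' @param resname PDB residue name used when the ligand is inserted into a
#'   structure.
#' @param bonds optional data frame (`a`, `b`) of bonded atom-name pairs.
#' @return An object of class `lp_ligand`.
#' @export
new_ligand <- function(name, atoms, key_atoms = character(0),
                       resname = toupper(substr(name, 1, 3)), bonds = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) < 3L) stop("ligand template needs >= 3 atoms")
  if (anyDuplicated(atoms$name)) stop("duplicate ligand atom names")
  if (!all(key_atoms %in% atoms$name))
    stop("key atoms not present in ligand: ",
         paste(setdiff(key_atoms, atoms$name), collapse = ", "))
  structure(list(name = name, resname = resname, atoms = atoms,
                 key_atoms = key_atoms, bonds = bonds),
            class = "lp_ligand")
}

#' @export
print.lp_ligand <- function(x, ...) {
  cat("<lp_ligand> ", x$name, " (", x$resname, "): ", nrow(x$atoms),
      " heavy atoms\n", sep = "")
  invisible(x)
}

# chair pyranose ring: carbons on a circle of radius rC with alternating
# z = +/- pucker; ring oxygen pulled radially inward so that both C-O ring
# bonds come out at b_co.
.pyranose <- function(suffix = "", anomeric_oxygen = TRUE) {
  b_cc <- 1.52; b_co <- 1.43; pucker <- 0.25
  rC <- sqrt(b_cc^2 - (2 * pucker)^2)
  # solve rO^2 - rC*rO + (rC^2 + 4p^2 - b_co^2) = 0
  cc <- rC^2 + (2 * pucker)^2 - b_co^2
  rO <- (rC + sqrt(rC^2 - 4 * cc)) / 2
  ang <- (0:5) * pi / 3
  zsgn <- rep(c(1, -1), 3)
  ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  rad <- c(rep(rC, 5), rO)
  pos <- cbind(rad * cos(ang), rad * sin(ang), zsgn * pucker)
  rownames(pos) <- ring_names
  atoms <- data.frame(name = ring_names,
                      element = c(rep("C", 5), "O"),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a = ring_names,
                      b = c(ring_names[-1], ring_names[1]),
                      stringsAsFactors = FALSE)
  # exocyclic substituents: hydroxyls O1..O4 on C1..C4 (alternating axial
  # direction), hydroxymethyl C6-O6 on C5
  subst <- function(i, dist) {
    u <- c(cos(ang[i]), sin(ang[i]), 0)
    dir <- u + c(0, 0, 0.9 * zsgn[i])
    pos[i, ] + dist * dir / sqrt(sum(dir^2))
  }
  ox_names <- c("O1", "O2", "O3", "O4")
  keep_ox <- if (anomeric_oxygen) 1:4 else 2:4
  for (i in keep_ox) {
    p <- subst(i, b_co)
    atoms <- rbind(atoms, data.frame(name = ox_names[i], element = "O",
                                     x = p[1], y = p[2], z = p[3]))
    bonds <- rbind(bonds, data.frame(a = ring_names[i], b = ox_names[i]))
  }
  c6 <- subst(5, b_cc)
  u5 <- c(cos(ang[5]), sin(ang[5]), 0)
  o6 <- c6 + b_co * u5
  atoms <- rbind(atoms,
                 data.frame(name = "C6", element = "C",
                            x = c6[1], y = c6[2], z = c6[3]),
                 data.frame(name = "O6", element = "O",
                            x = o6[1], y = o6[2], z = o6[3]))
  bonds <- rbind(bonds, data.frame(a = c("C5", "C6"), b = c("C6", "O6")))
  if (nzchar(suffix)) {
    atoms$name <- paste0(atoms$name, suffix)
    bonds$a <- paste0(bonds$a, suffix)
    bonds$b <- paste0(bonds$b, suffix)
  }
  rownames(atoms) <- NULL
  list(atoms = atoms, bonds = bonds)
}

.glycerol_template <- function() {
  deg <- pi / 180
  c1 <- c(0, 0, 0)
  c2 <- c(1.53, 0, 0)
  c3 <- c2 + 1.53 * c(cos(68 * deg), sin(68 * deg), 0)
  o1 <- c1 + 1.43 * c(-cos(68 * deg), sin(68 * deg), 0)
  dir2 <- c(0, -0.94, -0.342); dir2 <- dir2 / sqrt(sum(dir2^2))
  o2 <- c2 + 1.43 * dir2
  o3 <- c3 + 1.43 * c(1, 0, 0)
  pos <- rbind(c1, c2, c3, o1, o2, o3)
  atoms <- data.frame(name = c("C1", "C2", "C3", "O1", "O2", "O3"),
                      element = c("C", "C", "C", "O", "O", "O"),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      stringsAsFactors = FALSE)
  bonds <- data.frame(a = c("C1", "C2", "C1", "C2", "C3"),
                      b = c("C2", "C3", "O1", "O2", "O3"),
                      stringsAsFactors = FALSE)
  new_ligand("glycerol", atoms, key_atoms = c("O1", "O2"),
             resname = "GOL", bonds = bonds)
}

.glucose_template <- function() {
  g <- .pyranose()
  new_ligand("glucose", g$atoms, key_atoms = c("O3", "O4"),
             resname = "GLC", bonds = g$bonds)
}

.trehalose_template <- function() {
  a <- .pyranose(suffix = "A")
  # glycosidic oxygen: ring A's anomeric hydroxyl becomes the shared O1
  o1_row <- a$atoms$name == "O1A"
  o1 <- as.numeric(a$atoms[o1_row, c("x", "y", "z")])
  atoms_a <- a$atoms[!o1_row, ]
  bonds_a <- a$bonds
  bonds_a$a[bonds_a$a == "O1A"] <- "O1"
  bonds_a$b[bonds_a$b == "O1A"] <- "O1"
  # ring B: point reflection of ring A through the glycosidic oxygen,
  # giving the second C1-O1 bond at the same length
  atoms_b <- a$atoms[!o1_row, ]
  atoms_b[, c("x", "y", "z")] <- rep(2 * o1, each = nrow(atoms_b)) -
    as.matrix(atoms_b[, c("x", "y", "z")])
  atoms_b$name <- sub("A$", "B", atoms_b$name)
  bonds_b <- a$bonds[a$bonds$a != "O1A" & a$bonds$b != "O1A", ]
  bonds_b$a <- sub("A$", "B", bonds_b$a)
  bonds_b$b <- sub("A$", "B", bonds_b$b)
  atoms <- rbind(atoms_a,
                 data.frame(name = "O1", element = "O",
                            x = o1[1], y = o1[2], z = o1[3]),
                 atoms_b)
  bonds <- rbind(bonds_a, bonds_b,
                 data.frame(a = "O1", b = "C1B", stringsAsFactors = FALSE))
  rownames(atoms) <- NULL
  new_ligand("trehalose", atoms, key_atoms = c("O2A", "O3A"),
             resname = "TRE", bonds = bonds)
}

#' Idealized ligand templates
#'
#' Returns the heavy-atom template for one of the three sugars used across
#' the pocket analysis: glycerol (6 atoms), glucose (12 atoms:
#' C1-C6, O1-O6) or trehalose (23 atoms: two glucopyranose rings sharing
#' the glycosidic oxygen). Bonded C-C distances lie in 1.50-1.56 A and
#' C-O distances in 1.38-1.46 A.
#'
#' @param name one of `"glycerol"`, `"glucose"`, `"trehalose"`.
#' @return An `lp_ligand`.
#' @export
ligand_template <- function(name = c("glycerol", "glucose", "trehalose")) {
  name <- match.arg(name)
  switch(name,
         glycerol = .glycerol_template(),
         glucose = .glucose_template(),
         trehalose = .trehalose_template())
}

#' Maximum interatomic span of a ligand
#' @param lig an `lp_ligand`.
#' @return Largest pairwise heavy-atom distance (angstrom).
#' @export
ligand_span <- function(lig) {
  max(stats::dist(coords(lig)))
}

# canonical bound pose used by the synthetic pocket generator: long axis
# (first principal axis) along +z, centered in x/y, base of the ligand at
# z = z_min just above the calcium coordination shell.
.pose_bound <- function(lig, z_min = 2.6) {
  m <- coords(lig)
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  ev <- eigen(crossprod(mc), symmetric = TRUE)$vectors
  # deterministic sign convention, proper rotation
  for (j in 1:3) if (ev[which.max(abs(ev[, j])), j] < 0) ev[, j] <- -ev[, j]
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  # long axis (PC1) -> z, slimmest axis (PC3) -> x so that the flanking
  # walls of a pocket probe the molecule's narrow dimension
  rot <- ev[, c(3, 2, 1)]
  if (det(rot) < 0) rot[, 2] <- -rot[, 2]
  m2 <- mc %*% rot
  m2[, 1] <- m2[, 1] - mean(m2[, 1])
  m2[, 2] <- m2[, 2] - mean(m2[, 2])
  m2[, 3] <- m2[, 3] - min(m2[, 3]) + z_min
  out <- lig
  out$atoms$x <- m2[, 1]; out$atoms$y <- m2[, 2]; out$atoms$z <- m2[, 3]
  out
}
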