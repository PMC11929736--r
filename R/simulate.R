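# Synthetic fixtures for every pipeline stage: parametric binding
# pockets, motif-bearing candidate sequences, and tree-evolved
# alignments. Every generator is a pure function of its parameters and
# seed.

# calcium coordination cage: six oxygens at 2.4 A on the lower (z < 0)
# hemisphere so the +z half-space is free for the ligand, mimicking the
# EPN/WND coordination sphere; two second-shell oxygens at 4.0 A.
.cage_dirs <- function() {
  d <- rbind(c(0.857, 0, -0.515), c(-0.857, 0, -0.515),
             c(0, 0.857, -0.515), c(0, -0.857, -0.515),
             c(0, 0, -1), c(0.606, 0.606, -0.515))
  d / sqrt(rowSums(d^2))
}

.cage_atoms <- function() {
  d <- .cage_dirs()
  cage <- data.frame(
    resname = c("GLU", "GLU", "ASN", "ASN", "ASP", "ASP"),
    resseq = c(1L, 1L, 3L, 11L, 12L, 12L),
    name = c("OE1", "OE2", "OD1", "OD1", "OD1", "OD2"),
    stringsAsFactors = FALSE)
  cage <- cbind(cage, 2.4 * d[c(1, 6, 3, 4, 2, 5), ])
  names(cage)[4:6] <- c("x", "y", "z")
  shell_d <- rbind(c(-0.606, -0.606, -0.515), c(0.3, -0.7, -0.65))
  shell_d <- shell_d / sqrt(rowSums(shell_d^2))
  shell <- data.frame(resname = c("PRO", "TRP"), resseq = c(2L, 10L),
                      name = c("O", "O"), x = 4 * shell_d[, 1],
                      y = 4 * shell_d[, 2], z = 4 * shell_d[, 3],
                      stringsAsFactors = FALSE)
  rbind(cage, shell)
}

#' Generate a synthetic sugar-binding pocket
#'
#' Builds a toy carbohydrate-recognition pocket: a Ca ion at the origin,
#' an EPN/WND-like oxygen cage at coordination distance (2.4 A) on the
#' lower hemisphere, and two flanking walls of carbon atoms at
#' `x = +/- aperture / 2` in a z window placed where only a
#' disaccharide's second ring reaches, so that a transplanted trehalose
#' clashes in narrow pockets while glucose never does. The wall pair
#' closest to the pocket axis sits exactly `aperture` apart, so
#' [pocket_apertures()] with [toy_aperture_pairs()] recovers the
#' requested value.
#'
#' @param aperture flanking-wall separation in angstrom (> 3).
#' @param n_wall_atoms total wall atoms across both walls (even,
#'   default 18).
#' @param bound_ligand optional ligand name (`"glycerol"`, `"glucose"`,
#'   `"trehalose"`) inserted in the canonical bound pose.
#' @param seed integer seed (used when `jitter > 0`).
#' @param jitter standard deviation (angstrom) of optional y/z noise
#'   applied to all but the defining wall pair (default 0:
#'   fully deterministic).
#' @param wall_y,wall_z wall grid levels (angstrom).
#' @param id structure id.
#' @return An `lp_structure` with attributes `anchors` (anchor selector
#'   table) and `aperture` (the requested separation).
#' @export
make_toy_pocket <- function(aperture, n_wall_atoms = 18L,
                            bound_ligand = NULL, seed = 1L, jitter = 0,
                            wall_y = c(-2, 0, 2),
                            wall_z = c(12.7, 13.2, 13.7),
                            id = sprintf("pocket_a%.1f", aperture)) {
  if (aperture < 3) stop("aperture too small to place the Ca cage (< 3 A)")
  if (n_wall_atoms < 2L || n_wall_atoms %% 2L != 0L)
    stop("n_wall_atoms must be an even number >= 2")
  cage <- .cage_atoms()
  prot <- data.frame(record = "ATOM", serial = NA_integer_,
                     name = cage$name, resname = cage$resname,
                     chain = "A", resseq = cage$resseq, x = cage$x,
                     y = cage$y, z = cage$z, occ = 1, element = "O",
                     stringsAsFactors = FALSE)
  # residue-like anchors for the cage: one CA carbon per residue
  ca_dirs <- .cage_dirs()[c(1, 3, 4, 5), ]
  backbone <- data.frame(record = "ATOM", serial = NA_integer_,
                         name = "CA", resname = c("GLU", "ASN", "ASN", "ASP"),
                         chain = "A", resseq = c(1L, 3L, 11L, 12L),
                         x = 6 * ca_dirs[, 1], y = 6 * ca_dirs[, 2],
                         z = 6 * ca_dirs[, 3], occ = 1, element = "C",
                         stringsAsFactors = FALSE)
  # wall grid per wall, ordered so the defining (y = 0, mid z) atom is
  # first and survives any n_wall_atoms truncation
  grid <- expand.grid(y = wall_y, z = wall_z)
  mid <- which(grid$y == wall_y[ceiling(length(wall_y) / 2)] &
                 grid$z == wall_z[ceiling(length(wall_z) / 2)])[1]
  grid <- grid[c(mid, setdiff(seq_len(nrow(grid)), mid)), ]
  m <- n_wall_atoms %/% 2L
  if (m > nrow(grid)) m <- nrow(grid)
  grid <- grid[seq_len(m), , drop = FALSE]
  set.seed(seed)
  jit <- function(v, first_fixed) {
    if (jitter <= 0) return(v)
    n <- length(v)
    v + c(0, stats::rnorm(n - 1, 0, jitter)) * as.numeric(first_fixed)
  }
  walls <- do.call(rbind, lapply(c(1, -1), function(sgn) {
    data.frame(record = "ATOM", serial = NA_integer_, name = "CB",
               resname = "ALA", chain = "A",
               resseq = (if (sgn > 0) 100L else 150L) + seq_len(m),
               x = sgn * aperture / 2,
               y = jit(grid$y, TRUE), z = jit(grid$z, TRUE),
               occ = 1, element = "C", stringsAsFactors = FALSE)
  }))
  ion <- data.frame(record = "HETATM", serial = NA_integer_, name = "CA",
                    resname = "CA", chain = "A", resseq = 200L,
                    x = 0, y = 0, z = 0, occ = 1, element = "CA",
                    stringsAsFactors = FALSE)
  atoms <- rbind(prot, backbone, walls, ion)
  atoms$serial <- seq_len(nrow(atoms))
  s <- new_structure(atoms, id = id)
  if (!is.null(bound_ligand)) {
    lig <- .pose_bound(ligand_template(bound_ligand))
    s <- insert_ligand(s, lig, chain = "A", resseq = 301L)
  }
  attr(s, "anchors") <- rbind(
    data.frame(resname = "CA", resseq = 200L, name = "CA",
               stringsAsFactors = FALSE),
    cage[cage$resseq %in% c(1L, 3L, 11L, 12L), c("resname", "resseq", "name")])
  attr(s, "aperture") <- aperture
  s
}

#' Aperture selector pair for synthetic pockets
#'
#' The defining wall atoms of [make_toy_pocket()] (first atom of each
#' wall), whose separation equals the requested aperture.
#'
#' @return A `pairs` list for [pocket_apertures()].
#' @export
toy_aperture_pairs <- function() {
  list(list(list(resname = "ALA", resseq = 101L, name = "CB"),
            list(resname = "ALA", resseq = 151L, name = "CB")))
}

# ---- candidate sequences ---------------------------------------------------

.non_hydrophobic <- c("S", "T", "N", "Q", "D", "E", "K", "R", "G", "H")

#' Generate candidate sequences with planted motif/groove truth
#'
#' Builds a reference sequence with an EPN motif and a fully hydrophobic
#' groove in its C-terminal (CRD-like) region, then derives candidates
#' from it with background point mutations, the requested sugar motif
#' (EPN/QPD/EPD or none), and the requested fraction of hydrophobic
#' groove residues. Because candidates are substitution-only variants of
#' the reference, position mapping by global alignment is exact and the
#' planted truth labels are authoritative.
#'
#' @param n number of candidates.
#' @param motif_spec data frame with columns `kind` (one of `"EPN"`,
#'   `"QPD"`, `"EPD"`, `"none"`) and `groove_frac` in [0, 1]; recycled
#'   to `n` rows.
#' @param seed integer seed.
#' @param seq_length reference length (default 160).
#' @param mut_rate background substitution rate outside planted positions
#'   (default 0.08).
#' @return List: `records` (named sequences), `reference`, `groove`
#'   ([groove_profile()]), `truth` (data frame with the planted labels).
#' @export
make_candidate_sequences <- function(n, motif_spec, seed = 1L,
                                     seq_length = 160L, mut_rate = 0.08) {
  stopifnot(n >= 1)
  spec <- motif_spec[rep(seq_len(nrow(motif_spec)), length.out = n), ,
                     drop = FALSE]
  set.seed(seed)
  freqs <- .jtt_data()$frequencies
  hydro <- c("A", "V", "L", "I", "F", "M", "W", "Y")
  motif_at <- 100L                       # 0-based
  groove_pos <- as.integer(seq(110, 138, by = 4))   # 0-based, 8 positions
  ref <- sample(.aa_order, seq_length, replace = TRUE, prob = freqs)
  ref[motif_at + 1:3] <- c("E", "P", "N")
  ref[groove_pos + 1L] <- sample(hydro, length(groove_pos), replace = TRUE)
  wnd_at <- 145L
  ref[wnd_at + 1:3] <- c("W", "N", "D")
  protected <- c(motif_at + 0:2, groove_pos, wnd_at + 0:2)
  groove <- groove_profile("reference", groove_pos)
  records <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ref
    free <- setdiff(seq_along(s) - 1L, protected)
    nmut <- round(mut_rate * length(free))
    at <- sample(free, nmut)
    s[at + 1L] <- sample(.aa_order[1:20], nmut, replace = TRUE)
    kind <- spec$kind[i]
    s[motif_at + 1:3] <- switch(kind, EPN = c("E", "P", "N"),
                                QPD = c("Q", "P", "D"),
                                EPD = c("E", "P", "D"),
                                none = c("G", "S", "G"))
    k <- round(spec$groove_frac[i] * length(groove_pos))
    hyd_at <- if (k > 0) sample(groove_pos, k) else integer(0)
    s[groove_pos + 1L] <- sample(.non_hydrophobic, length(groove_pos),
                                 replace = TRUE)
    if (k > 0) s[hyd_at + 1L] <- sample(hydro, k, replace = TRUE)
    records[i] <- paste(s, collapse = "")
    truth[[i]] <- data.frame(
      id = sprintf("cand%02d", i), kind = kind, groove_retained = k,
      is_mincle_like = kind == "EPN" && k >= groove$min_retained,
      stringsAsFactors = FALSE)
  }
  names(records) <- sprintf("cand%02d", seq_len(n))
  list(records = records, reference = paste(ref, collapse = ""),
       groove = groove, truth = do.call(rbind, truth))
}

# ---- sequence evolution ----------------------------------------------------

#' Evolve an alignment along a tree
#'
#' Simulates amino-acid sequences under the model: root states are drawn
#' from the JTT equilibrium frequencies; each site is invariant (rate 0)
#' with probability `p_inv` and otherwise evolves at a sampled
#' discrete-gamma category rate; descent along each branch uses the
#' transition probabilities of the scaled rate matrix. No indels are
#' generated.
#'
#' @param tree `phylo` tree with branch lengths (substitutions/site).
#' @param n_sites number of alignment columns.
#' @param model an `lp_model`.
#' @param seed integer seed.
#' @return An `lp_msa` with one row per tip label.
#' @export
evolve_alignment <- function(tree, n_sites, model = substitution_model(),
                             seed = 1L) {
  stopifnot(n_sites >= 1)
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  rates <- model$category_rates[sample.int(model$n_categories, n_sites,
                                           replace = TRUE)]
  rates[stats::runif(n_sites) < model$p_inv] <- 0
  states <- matrix(NA_integer_, nnode, n_sites)
  root <- .root_node(tree)
  states[root, ] <- sample.int(20, n_sites, replace = TRUE,
                               prob = model$frequencies)
  tr <- ape::reorder.phylo(tree, "postorder")
  rate_groups <- split(seq_len(n_sites), rates)
  for (k in rev(seq_len(nrow(tr$edge)))) {       # preorder
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    for (g in names(rate_groups)) {
      sites <- rate_groups[[g]]
      r <- as.numeric(g)
      if (r == 0 || tr$edge.length[k] == 0) {
        states[ch, sites] <- states[par, sites]
      } else {
        P <- transition_prob(model, tr$edge.length[k], r)
        for (a in unique(states[par, sites])) {
          at <- sites[states[par, sites] == a]
          states[ch, at] <- sample.int(20, length(at), replace = TRUE,
                                       prob = P[a, ])
        }
      }
    }
  }
  seqs <- apply(states[seq_len(ntip), , drop = FALSE], 1, function(row)
    paste(.aa_order[row], collapse = ""))
  names(seqs) <- tree$tip.label
  new_msa(seqs)
}

# ---- coherent end-to-end cohort -------------------------------------------

#' Generate a coherent synthetic cohort for the full pipeline
#'
#' Creates, under `dir`, everything [run_full()] needs: an aligned FASTA
#' of sequences evolved along a two-clade tree (a trMincle-like clade and
#' a mammalian-Mincle-like clade, plus an outgroup), EPN motifs and
#' hydrophobic groove residues planted in every in-clade member, one
#' pocket PDB per non-anchor member (narrow apertures in the
#' trMincle-like clade, broad in the mammalian clade), a trehalose-bound
#' wide reference complex, a structure-similarity score table (low scores
#' in the narrow clade), a groove profile and a run configuration.
#'
#' @param dir output directory (created if needed).
#' @param n_per_clade non-anchor members per clade (default 3).
#' @param n_sites alignment length (default 300).
#' @param narrow_aperture,broad_aperture pocket sizes (default 5 and
#'   12 A).
#' @param seed integer seed.
#' @param model an `lp_model`.
#' @return List: `config` (path of the run configuration JSON), `truth`
#'   (data frame of planted clade/pocket labels per id).
#' @export
simulate_cohort <- function(dir, n_per_clade = 3L, n_sites = 300L,
                            narrow_aperture = 5, broad_aperture = 12,
                            seed = 1L, model = substitution_model()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t_ids <- sprintf("frog%02d", seq_len(n_per_clade))
  m_ids <- sprintf("toad%02d", seq_len(n_per_clade))
  inner_t <- paste(sprintf("%s:0.08", c("trMincle", t_ids)), collapse = ",")
  inner_m <- paste(sprintf("%s:0.08", c("boMincle", m_ids)), collapse = ",")
  nwk <- sprintf("((%s):0.45,(%s):0.45,huDectin1:0.9);", inner_t, inner_m)
  tree <- ape::read.tree(text = nwk)
  msa <- evolve_alignment(tree, n_sites, model, seed = seed)
  # plant the screening hallmarks in every clade member (not the outgroup)
  set.seed(seed + 1L)
  hydro <- c("A", "V", "L", "I", "F", "M", "W", "Y")
  motif_at <- as.integer(round(0.7 * n_sites))           # 0-based
  groove_pos <- motif_at + 6L + 3L * (0:7)
  groove_res <- sample(hydro, length(groove_pos), replace = TRUE)
  mat <- .msa_mat(msa)
  members <- setdiff(rownames(mat), "huDectin1")
  for (idx in match(members, rownames(mat))) {
    mat[idx, motif_at + 1:3] <- c("E", "P", "N")
    mat[idx, groove_pos + 1L] <- groove_res
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  fasta <- file.path(dir, "cohort.fasta")
  write_fasta_aa(seqs, fasta)
  groove <- groove_profile("boMincle", groove_pos)
  groove_path <- file.path(dir, "groove.json")
  write_groove_profile(groove, groove_path)
  # structures: narrow pockets for the trMincle-like clade
  struct_dir <- file.path(dir, "structures")
  dir.create(struct_dir, showWarnings = FALSE)
  truth <- data.frame(id = c(t_ids, m_ids),
                      clade = rep(c("trMincle_group", "mammalian_group"),
                                  each = n_per_clade),
                      pocket = rep(c("narrow", "broad"), each = n_per_clade),
                      stringsAsFactors = FALSE)
  structures <- character(0)
  for (i in seq_len(nrow(truth))) {
    ap <- if (truth$pocket[i] == "narrow") narrow_aperture else broad_aperture
    p <- file.path(struct_dir, paste0(truth$id[i], ".pdb"))
    write_pdb(make_toy_pocket(ap, id = truth$id[i]), p)
    structures[truth$id[i]] <- p
  }
  ref_path <- file.path(dir, "reference_complex.pdb")
  write_pdb(make_toy_pocket(14, bound_ligand = "trehalose",
                            id = "reference_complex"), ref_path)
  # similarity scores: low for the narrow clade, high for the broad one
  set.seed(seed + 2L)
  scores <- data.frame(id = truth$id,
                       score = ifelse(truth$clade == "trMincle_group",
                                      stats::rnorm(nrow(truth), 15, 0.5),
                                      stats::rnorm(nrow(truth), 30, 0.5)),
                       stringsAsFactors = FALSE)
  score_path <- file.path(dir, "scores.tsv")
  utils::write.table(scores, score_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  config <- list(
    fasta = fasta, reference_id = "boMincle", groove = groove_path,
    structures = as.list(structures), reference_complex = ref_path,
    ligand = "TRE",
    anchors = list(trMincle = "trMincle_group",
                   boMincle = "mammalian_group"),
    outgroup = "huDectin1", scores = score_path, seed = seed)
  config_path <- file.path(dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE)
  list(config = config_path, truth = truth)
}
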