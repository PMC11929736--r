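# Independent oracles and small fixture builders shared across tests.

# random proper rotation via QR decomposition
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# brute-force global affine alignment score by enumerating every
# alignment (gap run of length L costs open + (L - 1) * ext)
brute_align_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(av) && j <= length(bv))
      rec(i + 1, j + 1, score + mat[av[i], bv[j]], "d")
    if (i <= length(av))
      rec(i + 1, j, score - (if (last == "u") ext else open), "u")
    if (j <= length(bv))
      rec(i, j + 1, score - (if (last == "l") ext else open), "l")
  }
  rec(1, 1, 0, "d")
  best
}

# brute-force clash pairs: every pair's distance computed directly
brute_clash_pairs <- function(lig_xyz, lig_el, rec_xyz, rec_el, vdw, tol) {
  out <- NULL
  for (i in seq_len(nrow(lig_xyz))) {
    d <- sqrt(rowSums(sweep(rec_xyz, 2, lig_xyz[i, ])^2))
    hit <- which(d < vdw[lig_el[i]] + vdw[rec_el] - tol)
    if (length(hit)) out <- rbind(out, cbind(i, hit))
  }
  out
}

# enumeration oracle for the mixture likelihood: sums over all internal
# state assignments, transition matrices from Matrix::expm
enum_loglik <- function(tree, msa, model) {
  requireNamespace("Matrix", quietly = TRUE)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  states <- lapply(unclass(msa), function(s) match(strsplit(s, "")[[1]], aa))
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  pi <- model$frequencies
  Pm <- function(t, r) {
    if (t * r == 0) return(diag(20))
    as.matrix(Matrix::expm(Matrix::Matrix(model$Q * t * r)))
  }
  n_sites <- length(states[[1]])
  root <- ntip + 1L
  total <- 0
  for (site in seq_len(n_sites)) {
    tipst <- vapply(tree$tip.label, function(l) states[[l]][site], integer(1))
    sitelik_rate <- function(r) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(k)
        Pm(tree$edge.length[k], r))
      grid <- as.matrix(expand.grid(rep(list(1:20), m)))
      tot <- 0
      for (g in seq_len(nrow(grid))) {
        st <- c(tipst, grid[g, ])
        p <- pi[st[root]]
        for (k in seq_len(nrow(tree$edge)))
          p <- p * Ps[[k]][st[tree$edge[k, 1]], st[tree$edge[k, 2]]]
        tot <- tot + p
      }
      tot
    }
    gl <- mean(vapply(model$category_rates,
                      function(r) unname(sitelik_rate(r)), numeric(1)))
    const <- if (length(unique(tipst)) == 1L) unname(pi[tipst[1]]) else 0
    total <- total + log(model$p_inv * const + (1 - model$p_inv) * gl)
  }
  as.numeric(total)
}

# canonical bipartition -> branch length map for an unrooted tree
edge_lengths_by_split <- function(tree) {
  ntip <- length(tree$tip.label)
  below <- phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
  keys <- vapply(below, function(tips) {
    side <- sort(tree$tip.label[tips])
    other <- sort(setdiff(tree$tip.label, side))
    paste(if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other, collapse = ",")
  }, character(1))
  stats::setNames(tree$edge.length, keys)
}

# random tree with positive branch lengths (unrooted)
rand_tree <- function(n_taxa, min_bl = 0.05, max_bl = 0.6) {
  tr <- ape::unroot(ape::rtree(n_taxa, br = NULL))
  tr$edge.length <- runif(nrow(tr$edge), min_bl, max_bl)
  tr
}

# protein chain with a full backbone (N, CA, C, O per residue)
make_backbone <- function(n_res, chain = "A") {
  rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
    data.frame(record = "ATOM", serial = NA_integer_,
               name = c("N", "CA", "C", "O"), resname = "ALA",
               chain = chain, resseq = i,
               x = 3.8 * i + c(0, 0.5, 1.0, 1.2), y = c(0, 1, 0, -1),
               z = 0, occ = 1, element = c("N", "C", "C", "O"),
               stringsAsFactors = FALSE)
  }))
  rows$serial <- seq_len(nrow(rows))
  new_structure(rows, id = paste0("chain", n_res))
}

# structure from bare coordinates (ATOM records, one residue per atom)
atoms_structure <- function(xyz, element = "C", id = "blob") {
  n <- nrow(xyz)
  new_structure(data.frame(record = "ATOM", serial = seq_len(n),
                           name = paste0("X", seq_len(n)), resname = "UNK",
                           chain = "A", resseq = seq_len(n),
                           x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                           occ = 1, element = rep(element, length.out = n),
                           stringsAsFactors = FALSE), id = id)
}

plain_jtt <- function() substitution_model(gamma_shape = 1,
                                           n_categories = 1L, p_inv = 0)
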