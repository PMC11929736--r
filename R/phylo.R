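# Phylogenetic classification: complete-deletion filtering, maximum
# likelihood JTT distances, neighbor joining, Felsenstein-pruning
# log-likelihood under JTT + discrete gamma + invariant sites, NJ-seeded
# branch-length optimization, clade assignment, 1-D score clustering and
# nonparametric bootstrap.

.gap_chars <- c("-", ".", "?", "X")

#' Construct a multiple alignment
#'
#' @param seqs named character vector of equal-length gapped amino-acid
#'   strings (gaps `-`/`.`; missing data `X`/`?`).
#' @return Object of class `lp_msa`.
#' @export
new_msa <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment rows need unique names")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length")
  structure(toupper(seqs), class = "lp_msa")
}

#' @export
print.lp_msa <- function(x, ...) {
  cat("<lp_msa> ", length(x), " sequences x ", nchar(x[1]), " sites\n",
      sep = "")
  invisible(x)
}

.msa_mat <- function(msa) {
  m <- do.call(rbind, strsplit(unclass(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Remove all columns containing gaps or missing data
#'
#' Complete deletion: only columns with no gap (`-`, `.`) and no missing
#' datum (`X`, `?`) in any row are retained, in their original order.
#' Idempotent; warns (and still returns the empty alignment) when no
#' column survives.
#'
#' @param msa an `lp_msa`.
#' @return The filtered `lp_msa`.
#' @export
complete_deletion <- function(msa) {
  m <- .msa_mat(msa)
  keep <- colSums(matrix(m %in% .gap_chars, nrow(m))) == 0
  if (!any(keep)) warning("complete deletion removed every column")
  new_msa(apply(m[, keep, drop = FALSE], 1, paste, collapse = ""))
}

.state_mat <- function(msa) {
  m <- .msa_mat(msa)
  s <- matrix(match(m, .aa_order), nrow(m), dimnames = dimnames(m))
  s
}

#' Maximum likelihood JTT distance between two aligned sequences
#'
#' Maximizes `sum log(pi_a * P(a -> b; d))` over the shared ungapped
#' column pairs by bracketed 1-D search on `d` in [0, 10], using the
#' plain JTT matrix (unit rate).
#'
#' @param a,b equal-length (gapped) amino-acid strings.
#' @param model an `lp_model`.
#' @return Distance in substitutions per site.
#' @export
jtt_distance <- function(a, b, model = substitution_model()) {
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  ai <- match(strsplit(toupper(a), "")[[1]], .aa_order)
  bi <- match(strsplit(toupper(b), "")[[1]], .aa_order)
  keep <- !is.na(ai) & !is.na(bi)
  if (!any(keep))
    stop("no shared ungapped columns; distance undefined")
  ai <- ai[keep]; bi <- bi[keep]
  if (all(ai == bi)) return(0)
  counts <- table(factor(ai, levels = 1:20), factor(bi, levels = 1:20))
  # reversibility makes the likelihood direction-free; symmetrizing the
  # counts fixes the floating-point summation order so d(i,j) = d(j,i)
  counts <- counts + t(counts)
  nz <- which(counts > 0, arr.ind = TRUE)
  w <- counts[nz]
  lpi <- log(model$frequencies)[nz[, 1]]
  f <- function(d) {
    P <- transition_prob(model, d)
    sum(w * (lpi + log(P[nz])))
  }
  opt <- stats::optimize(f, c(1e-8, 10), maximum = TRUE, tol = 1e-10)
  opt$maximum
}

#' Pairwise JTT distance matrix of an alignment
#'
#' @param msa an `lp_msa` (apply [complete_deletion()] first to mirror
#'   the standard pipeline).
#' @param model an `lp_model`.
#' @return Symmetric matrix of ML distances with row/column names.
#' @export
dist_jtt <- function(msa, model = substitution_model()) {
  n <- length(msa)
  D <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- jtt_distance(msa[[i]], msa[[j]], model)
  }
  D
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with fully deterministic behavior: ties in
#' the Q-criterion are broken by the smallest (i, j) index pair in the
#' current node order, and a negative branch length is clamped to zero
#' with the deficit transferred to its sister branch.
#'
#' @param D symmetric distance matrix with zero diagonal and row/column
#'   names (n >= 3 taxa).
#' @return An unrooted `phylo` tree (ape).
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (is.null(rownames(D))) stop("distance matrix needs taxon names")
  if (max(abs(D - t(D))) > 1e-12 || any(abs(diag(D)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")
  fmt <- function(x) sprintf("%.12g", x)
  labs <- rownames(D)
  frags <- labs
  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Qc <- (n - 2) * D - outer(r, r, "+")
    diag(Qc) <- Inf
    best <- c(NA_integer_, NA_integer_); bestq <- Inf
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (Qc[i, j] < bestq - 1e-12) { bestq <- Qc[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- max(0, bi + bj); bj <- 0 }
    newfrag <- paste0("(", frags[i], ":", fmt(bi), ",", frags[j], ":",
                      fmt(bj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frags <- c(frags[keep], newfrag)
    # new node takes the last position; names only used for tips
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], newfrag)
    D <- D2
  }
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)
  nwk <- paste0("(", frags[1], ":", fmt(v[1]), ",", frags[2], ":",
                fmt(v[2]), ",", frags[3], ":", fmt(v[3]), ");")
  ape::read.tree(text = nwk)
}

# ---- pruning likelihood ----------------------------------------------------

# compress alignment columns into patterns; returns state matrix
# (taxa x patterns, NA = missing), weights, and per-pattern constant-site
# likelihood factor (pi_a for constant observed state a, 1 for all-missing,
# 0 otherwise).
.patterns <- function(msa, model) {
  s <- .state_mat(msa)
  key <- apply(s, 2, paste, collapse = ",")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  sp <- s[, first, drop = FALSE]
  const <- apply(sp, 2, function(col) {
    obs <- col[!is.na(col)]
    if (length(obs) == 0L) 1
    else if (length(unique(obs)) == 1L) model$frequencies[obs[1]]
    else 0
  })
  list(states = sp, weights = w, const = const)
}

.check_labels <- function(tree, msa) {
  miss <- setdiff(tree$tip.label, names(msa))
  extra <- setdiff(names(msa), tree$tip.label)
  if (length(miss) || length(extra))
    stop("leaf labels and alignment ids differ; missing from alignment: ",
         paste(miss, collapse = ","), "; missing from tree: ",
         paste(extra, collapse = ","))
}

# down-partials for one rate class. Returns list over nodes of 20 x S
# matrices (tips included).
.down_partials <- function(tree, states, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- ncol(states)
  part <- vector("list", nnode)
  for (i in seq_len(ntip)) {
    m <- matrix(0, 20, S)
    st <- states[tree$tip.label[i], ]
    m[cbind(st[!is.na(st)], which(!is.na(st)))] <- 1
    m[, is.na(st)] <- 1
    part[[i]] <- m
  }
  tr <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    P <- transition_prob(model, tr$edge.length[k], rate)
    contrib <- P %*% part[[ch]]
    part[[par]] <- if (is.null(part[[par]])) contrib else
      part[[par]] * contrib
  }
  part
}

.root_node <- function(tree) length(tree$tip.label) + 1L

#' Log-likelihood of a tree by Felsenstein pruning
#'
#' Per-site likelihood is `p_inv * I(site constant) * pi_state +
#' (1 - p_inv) * mean_k L_k(site)` over the K discrete-gamma rate
#' categories; site logs are summed. Gaps and `X`/`?` are treated as
#' missing data; alignment columns are pattern-compressed.
#'
#' @param tree a `phylo` tree (rooted or unrooted) with branch lengths.
#' @param msa an `lp_msa`; ids must match the tip labels.
#' @param model an `lp_model`.
#' @return Log-likelihood (natural log).
#' @export
tree_loglik <- function(tree, msa, model = substitution_model()) {
  .check_labels(tree, msa)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  pat <- .patterns(msa, model)
  .loglik_patterns(tree, pat, model)
}

.loglik_patterns <- function(tree, pat, model) {
  root <- .root_node(tree)
  pi <- model$frequencies
  K <- model$n_categories
  sl <- 0
  for (r in model$category_rates) {
    part <- .down_partials(tree, pat$states, model, r)
    sl <- sl + colSums(pi * part[[root]]) / K
  }
  site <- model$p_inv * pat$const + (1 - model$p_inv) * sl
  sum(pat$weights * log(site))
}

# outside ("up") partials O[node] for one rate class: O[root] = pi;
# O[child] = t(P_edge) %*% (O[parent] * prod over siblings of P %*% D).
.up_partials <- function(tree, down, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- ncol(down[[1]])
  up <- vector("list", nnode)
  up[[.root_node(tree)]] <- matrix(model$frequencies, 20, S)
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- nrow(tr$edge)
  Pmats <- lapply(seq_len(edges), function(k)
    transition_prob(model, tr$edge.length[k], rate))
  contrib <- lapply(seq_len(edges), function(k)
    Pmats[[k]] %*% down[[tr$edge[k, 2]]])
  children <- split(seq_len(edges), tr$edge[, 1])
  for (k in rev(seq_len(edges))) {        # preorder
    par <- tr$edge[k, 1]; ch <- tr$edge[k, 2]
    sibs <- setdiff(children[[as.character(par)]], k)
    m <- up[[par]]
    for (s2 in sibs) m <- m * contrib[[s2]]
    up[[ch]] <- crossprod(Pmats[[k]], m)
  }
  up
}

#' Optimize branch lengths by coordinate-wise bracketed search
#'
#' Sweeps over the branches, optimizing each in [0, 10] with the others
#' fixed (golden-section/parabolic search), until a full sweep improves
#' the total log-likelihood by less than `tol`. The log-likelihood is
#' non-decreasing across sweeps by construction.
#'
#' @param tree `phylo` tree with branch lengths (e.g. from [nj_tree()]).
#' @param msa an `lp_msa`.
#' @param model an `lp_model`.
#' @param tol convergence threshold on the per-sweep log-likelihood gain
#'   (default 1e-6).
#' @param max_sweeps safety cap on the number of sweeps.
#' @return The tree with optimized branch lengths; the final
#'   log-likelihood is stored in attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, msa, model = substitution_model(),
                                    tol = 1e-6, max_sweeps = 50L) {
  .check_labels(tree, msa)
  pat <- .patterns(msa, model)
  tree$edge.length[tree$edge.length < 0] <- 0
  K <- model$n_categories
  pinv_term <- model$p_inv * pat$const
  cur <- .loglik_patterns(tree, pat, model)
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      ch <- tree$edge[e, 2]
      # fixed parts per category: the down partial below the child (does
      # not involve this edge) and the parent-side outside message,
      # obtained by evaluating the up partial with this edge's length set
      # to 0 so its own P is the identity
      saved <- tree$edge.length[e]
      tree$edge.length[e] <- 0
      Ms <- vector("list", K); Ds <- vector("list", K)
      for (kc in seq_len(K)) {
        r <- model$category_rates[kc]
        down <- .down_partials(tree, pat$states, model, r)
        up <- .up_partials(tree, down, model, r)
        Ds[[kc]] <- down[[ch]]
        Ms[[kc]] <- up[[ch]]
      }
      tree$edge.length[e] <- saved
      f <- function(b) {
        sl <- 0
        for (kc in seq_len(K)) {
          P <- transition_prob(model, b, model$category_rates[kc])
          sl <- sl + colSums(crossprod(P, Ms[[kc]]) * Ds[[kc]]) / K
        }
        sum(pat$weights * log(pinv_term + (1 - model$p_inv) * sl))
      }
      opt <- stats::optimize(f, c(0, 10), maximum = TRUE, tol = 1e-6)
      cand <- if (f(0) >= opt$objective) 0 else opt$maximum
      val <- f(cand)
      if (val > cur) { tree$edge.length[e] <- cand; cur <- val }
    }
    if (cur - prev < tol) break
  }
  attr(tree, "loglik") <- cur
  tree
}

# ---- clades, clustering, bootstrap ----------------------------------------

#' Assign leaves to clades defined by anchor taxa
#'
#' Roots the tree at the outgroup, then assigns every leaf the group of
#' the anchors in its smallest ancestral clade that contains at least one
#' anchor; leaves whose smallest such clade mixes both anchor groups are
#' left unassigned. Anchor leaves map to their own group and the outgroup
#' to `"outgroup"`.
#'
#' @param tree a `phylo` tree.
#' @param anchors named character vector: leaf label -> group name.
#' @param outgroup leaf label used to root the tree.
#' @return Data frame with columns `id` and `group` (`NA` = unassigned).
#' @export
assign_clades <- function(tree, anchors, outgroup) {
  missing_anchor <- setdiff(c(names(anchors), outgroup), tree$tip.label)
  if (length(missing_anchor))
    stop("not in tree: ", paste(missing_anchor, collapse = ", "))
  rt <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  ntip <- length(rt$tip.label)
  parent <- integer(ntip + rt$Nnode)
  parent[rt$edge[, 2]] <- rt$edge[, 1]
  tips_below <- phangorn::Descendants(rt, (ntip + 1):(ntip + rt$Nnode),
                                      type = "tips")
  group_of <- function(lab) {
    if (lab == outgroup) return("outgroup")
    if (lab %in% names(anchors)) return(unname(anchors[lab]))
    node <- which(rt$tip.label == lab)
    repeat {
      node <- parent[node]
      if (node == 0L) return(NA_character_)
      below <- rt$tip.label[tips_below[[node - ntip]]]
      g <- unique(unname(anchors[intersect(below, names(anchors))]))
      if (length(g) == 1L) return(g)
      if (length(g) > 1L) return(NA_character_)
    }
  }
  data.frame(id = tree$tip.label,
             group = vapply(tree$tip.label, group_of, character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Split scores into two clusters at the largest gap
#'
#' One-dimensional clustering used for similarity-score tables: scores
#' are sorted and split at the largest gap between consecutive values
#' (ties broken toward the lower gap position); the threshold is the
#' midpoint of that gap. Output is invariant to input order.
#'
#' @param values data frame with columns `id` and `score`, or a named
#'   numeric vector.
#' @return List: `clusters` (data frame `id`, `score`, `cluster` in
#'   {"low","high"}), `threshold` (`NA` if all scores equal).
#' @export
split_by_score <- function(values) {
  if (!is.data.frame(values))
    values <- data.frame(id = names(values), score = as.numeric(values),
                         stringsAsFactors = FALSE)
  stopifnot(nrow(values) >= 2, all(is.finite(values$score)))
  v <- values[order(values$score, values$id), ]
  gaps <- diff(v$score)
  if (all(gaps == 0)) {
    warning("all scores equal; returning a single cluster")
    v$cluster <- "low"
    return(list(clusters = v, threshold = NA_real_))
  }
  g <- which.max(gaps)            # first maximum = lower gap position
  threshold <- (v$score[g] + v$score[g + 1]) / 2
  v$cluster <- ifelse(v$score < threshold, "low", "high")
  rownames(v) <- NULL
  list(clusters = v, threshold = threshold)
}

#' Bootstrap support for the NJ tree of an alignment
#'
#' Resamples alignment columns with replacement, rebuilds the JTT
#' distance + neighbor-joining tree for each replicate, and reports for
#' each internal edge of the point-estimate tree the fraction of
#' replicates containing that bipartition.
#'
#' @param msa an `lp_msa` (after [complete_deletion()]).
#' @param model an `lp_model`.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed; results are reproducible.
#' @return The point-estimate `phylo` tree with support fractions in
#'   `node.label`.
#' @export
bootstrap_support <- function(msa, model = substitution_model(),
                              n_reps = 100L, seed = 1L) {
  stopifnot(n_reps >= 1)
  m <- .msa_mat(msa)
  build <- function(mat) {
    seqs <- apply(mat, 1, paste, collapse = "")
    nj_tree(dist_jtt(new_msa(seqs), model))
  }
  point <- build(m)
  set.seed(seed)
  counts <- ape::boot.phylo(point, m, build, B = n_reps, quiet = TRUE,
                            rooted = FALSE)
  point$node.label <- counts / n_reps
  point
}
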