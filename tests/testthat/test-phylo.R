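test_that("complete deletion drops gapped columns and is idempotent", {
  a <- new_msa(c(s1 = "MK-TW", s2 = "MKATW", s3 = "MKCTW"))
  cd <- complete_deletion(a)
  expect_equal(nchar(cd[[1]]), 4L)
  expect_equal(unclass(cd)[["s1"]], "MKTW")
  clean <- new_msa(c(s1 = "MKTW", s2 = "MKAW"))
  expect_equal(unclass(complete_deletion(clean)), unclass(clean))
  expect_equal(unclass(complete_deletion(cd)), unclass(cd))
  # X and ? count as missing data
  b <- new_msa(c(s1 = "MXTW", s2 = "MKT?"))
  expect_equal(nchar(complete_deletion(b)[[1]]), 2L)
  expect_warning(complete_deletion(new_msa(c(a = "-X", b = "AA"))),
                 "every column")
})

test_that("JTT distances are zero on identity, symmetric, and recover
           simulated divergence", {
  plain <- plain_jtt()
  expect_equal(jtt_distance("MKTWND", "MKTWND", plain), 0)
  two <- ape::read.tree(text = "(a:0.15,b:0.15);")
  aln <- evolve_alignment(two, 1000, plain, seed = 31)
  d <- jtt_distance(aln[["a"]], aln[["b"]], plain)
  expect_lt(abs(d - 0.3), 0.05)
  expect_equal(d, jtt_distance(aln[["b"]], aln[["a"]], plain),
               tolerance = 1e-10)
  expect_error(jtt_distance("--", "AA", plain), "undefined|shared")
  # cross-check against phangorn's ML distance machinery
  pd <- phangorn::phyDat(t(sapply(unclass(aln),
                                  function(s) strsplit(s, "")[[1]])),
                         type = "AA")
  dm <- as.matrix(phangorn::dist.ml(pd, model = "JTT"))
  expect_equal(d, dm["a", "b"], tolerance = 1e-4)
})

test_that("three-taxon neighbor joining uses the closed form", {
  D <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  pend <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(pend["a"]), (5 + 9 - 10) / 2)
  expect_equal(unname(pend["b"]), (5 + 10 - 9) / 2)
  expect_equal(unname(pend["c"]), (9 + 10 - 5) / 2)
})

test_that("neighbor joining reproduces additive trees exactly", {
  set.seed(14)
  for (i in 1:5) {
    tr <- rand_tree(sample(5:8, 1))
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(D)
    expect_equal(ape::dist.topo(nj, tr), 0, ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)]
                      - D)), 1e-9)
    # agrees with ape's reference implementation on additive input
    expect_equal(ape::dist.topo(nj, ape::nj(D)), 0, ignore_attr = TRUE)
  }
})

test_that("degenerate equal distances resolve deterministically", {
  D <- matrix(1, 5, 5); diag(D) <- 0
  dimnames(D) <- list(letters[1:5], letters[1:5])
  t1 <- ape::write.tree(nj_tree(D))
  t2 <- ape::write.tree(nj_tree(D))
  expect_identical(t1, t2)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric|3 taxa")
})

test_that("pruning equals brute-force state enumeration on small trees", {
  skip_if_not_installed("Matrix")
  set.seed(15)
  topos <- c("(a:%f,b:%f);", "(a:%f,b:%f,c:%f);",
             "((a:%f,b:%f):%f,c:%f,d:%f);")
  for (alpha in c(0.5, 2.4398)) for (pinv in c(0, 0.0727)) {
    m <- substitution_model(gamma_shape = alpha, n_categories = 5,
                            p_inv = pinv)
    for (tp in topos) {
      nb <- lengths(regmatches(tp, gregexpr("%f", tp)))
      tr <- ape::read.tree(text = do.call(sprintf,
                                          c(tp, as.list(runif(nb, 0.05, 1)))))
      aln <- evolve_alignment(tr, 3, m, seed = sample.int(1e6, 1))
      expect_equal(tree_loglik(tr, aln, m), enum_loglik(tr, aln, m),
                   tolerance = 1e-10)
    }
  }
})

test_that("two-leaf zero-length identical site gives log pi exactly", {
  m <- substitution_model(p_inv = 0)
  tr <- ape::read.tree(text = "(a:0,b:0);")
  ll <- tree_loglik(tr, new_msa(c(a = "W", b = "W")), m)
  expect_equal(ll, log(m$frequencies[["W"]]), tolerance = 1e-12)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  m <- substitution_model(gamma_shape = 0.9, n_categories = 4,
                          p_inv = 0.05)
  tr <- ape::read.tree(text = "((a:0.2,b:0.35):0.1,c:0.3,d:0.15);")
  aln <- evolve_alignment(tr, 30, m, seed = 8)
  base <- tree_loglik(tr, aln, m)
  for (og in c("a", "c", "d")) {
    rt <- ape::root(tr, outgroup = og, resolve.root = TRUE)
    expect_equal(tree_loglik(rt, aln, m), base, tolerance = 1e-10)
  }
})

test_that("pruning agrees with phangorn's likelihood engine", {
  m <- substitution_model(gamma_shape = 0.7, n_categories = 5, p_inv = 0)
  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.1,c:0.25,d:0.4);")
  aln <- evolve_alignment(tr, 60, m, seed = 16)
  pd <- phangorn::phyDat(t(sapply(unclass(aln),
                                  function(s) strsplit(s, "")[[1]])),
                         type = "AA")
  fit <- phangorn::pml(tr, pd, model = "JTT", k = 5, shape = 0.7, inv = 0)
  expect_equal(tree_loglik(tr, aln, m), fit$logLik, tolerance = 1e-8)
})

test_that("label mismatches are reported", {
  m <- plain_jtt()
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  expect_error(tree_loglik(tr, new_msa(c(a = "A", b = "A", z = "A")), m),
               "z")
})

test_that("branch-length optimization never decreases the likelihood and
           recovers simulated lengths", {
  set.seed(17)
  plain <- plain_jtt()
  tr <- rand_tree(6, 0.05, 0.4)
  aln <- evolve_alignment(tr, 500, plain, seed = 18)
  nj <- nj_tree(dist_jtt(aln, plain))
  before <- tree_loglik(nj, aln, plain)
  opt <- optimize_branch_lengths(nj, aln, plain)
  after <- attr(opt, "loglik")
  expect_gte(after, before)
  expect_equal(after, tree_loglik(opt, aln, plain), tolerance = 1e-9)
  # same topology as truth here; compare matched bipartition lengths
  expect_equal(ape::dist.topo(opt, tr), 0, ignore_attr = TRUE)
  got <- edge_lengths_by_split(opt)
  want <- edge_lengths_by_split(tr)
  expect_lt(max(abs(got[names(want)] - want)), 0.1)
  # an already-optimal tree is left essentially unchanged
  opt2 <- optimize_branch_lengths(opt, aln, plain)
  expect_lt(max(abs(sort(opt2$edge.length) - sort(opt$edge.length))), 5e-3)
})

test_that("clade assignment follows the anchors and the outgroup", {
  tr <- ape::read.tree(
    text = "((A1:1,X1:1):1,(B1:1,X2:1):1,(OG:1,X3:1):1);")
  anchors <- c(A1 = "G_A", B1 = "G_B")
  cl <- assign_clades(tr, anchors, "OG")
  got <- setNames(cl$group, cl$id)
  expect_equal(unname(got[c("X1", "X2")]), c("G_A", "G_B"))
  expect_equal(unname(got[c("A1", "B1", "OG")]),
               c("G_A", "G_B", "outgroup"))
  expect_true(is.na(got[["X3"]]))     # sister to the outgroup
  expect_error(assign_clades(tr, c(ZZ = "G_A"), "OG"), "ZZ")
})

test_that("clade assignment is invariant to leaf input order", {
  set.seed(19)
  base <- "((A1:1,(X1:1,X4:1):1):1,((B1:1,X2:1):1,X5:1):1,OG:2);"
  tr <- ape::read.tree(text = base)
  anchors <- c(A1 = "G_A", B1 = "G_B")
  ref <- assign_clades(tr, anchors, "OG")
  ref <- setNames(ref$group, ref$id)
  for (i in 1:5) {
    tr2 <- ape::rotateConstr(tr, sample(tr$tip.label))
    got <- assign_clades(tr2, anchors, "OG")
    got <- setNames(got$group, got$id)
    expect_equal(got[names(ref)], ref)
  }
})

test_that("score splitting cuts at the largest gap", {
  res <- split_by_score(data.frame(id = c("w", "x", "y", "z"),
                                   score = c(10, 1, 11, 2)))
  expect_equal(res$threshold, 6)
  got <- setNames(res$clusters$cluster, res$clusters$id)
  expect_equal(unname(got[c("x", "z", "w", "y")]),
               c("low", "low", "high", "high"))
  # order invariance
  res2 <- split_by_score(data.frame(id = c("z", "w", "y", "x"),
                                    score = c(2, 10, 11, 1)))
  expect_equal(res2$threshold, res$threshold)
  expect_warning(out <- split_by_score(c(a = 5, b = 5)), "single cluster")
  expect_true(is.na(out$threshold))
  # gap ties break toward the lower position
  res3 <- split_by_score(c(a = 0, b = 2, c = 4))
  expect_equal(res3$threshold, 1)
})

test_that("bootstrap supports are reproducible and saturate on clean
           separation", {
  plain <- plain_jtt()
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.6,(c:0.05,d:0.05):0.6);")
  aln <- evolve_alignment(ape::unroot(tr), 300, plain, seed = 20)
  bs <- bootstrap_support(aln, plain, n_reps = 30, seed = 5)
  sup <- bs$node.label[!is.na(bs$node.label)]
  expect_equal(unname(sup), rep(1, length(sup)))   # central split always seen
  bs2 <- bootstrap_support(aln, plain, n_reps = 30, seed = 5)
  expect_identical(bs$node.label, bs2$node.label)
  one <- bootstrap_support(aln, plain, n_reps = 1, seed = 9)
  expect_true(all(one$node.label %in% c(0, 1, NA)))
})
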