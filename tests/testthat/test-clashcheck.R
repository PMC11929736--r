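test_that("single-pair clash arithmetic follows r1 + r2 - tolerance", {
  one_c <- function(x) atoms_structure(matrix(c(x, 0, 0), 1, 3))
  probe <- new_ligand("pt", data.frame(name = c("C1", "C2", "C3"),
                                       element = "C", x = c(0, 0, 0),
                                       y = c(0, 50, 100), z = 0),
                      resname = "PRB")
  far <- count_clashes(probe, one_c(3.6), tolerance = 0.4)
  expect_equal(far$n_clashes, 0L)
  expect_equal(far$label, "clash(-)")
  expect_equal(far$worst_overlap, 0)
  near <- count_clashes(probe, one_c(2.5), tolerance = 0.4)
  expect_equal(near$n_clashes, 1L)
  expect_equal(near$label, "clash(+)")
  expect_equal(near$worst_overlap, 0.5, tolerance = 1e-12)
  # boundary: distance exactly at the limit is not a clash
  expect_equal(count_clashes(probe, one_c(3.0), tolerance = 0.4)$n_clashes, 0L)
})

test_that("clash pairs match the brute-force oracle", {
  set.seed(11)
  vdw <- vdw_table()
  for (rep in 1:6) {
    nl <- sample(5:60, 1); nr <- sample(20:150, 1)
    lig_xyz <- matrix(rnorm(3 * nl, sd = 4), nl, 3)
    rec_xyz <- matrix(rnorm(3 * nr, sd = 4), nr, 3)
    lel <- sample(c("C", "N", "O", "S"), nl, replace = TRUE)
    rel <- sample(c("C", "N", "O", "S"), nr, replace = TRUE)
    tol <- sample(c(0, 0.4, 1), 1)
    lig <- new_ligand("rand", data.frame(name = paste0("L", 1:nl),
                                         element = lel, x = lig_xyz[, 1],
                                         y = lig_xyz[, 2], z = lig_xyz[, 3]),
                      resname = "RND")
    rec <- atoms_structure(rec_xyz, element = rel)
    rep_ <- count_clashes(lig, rec, vdw, tolerance = tol)
    oracle <- brute_clash_pairs(lig_xyz, lel, rec_xyz, rel, vdw, tol)
    got <- if (rep_$n_clashes) {
      cbind(match(rep_$pairs$ligand_atom, paste0("L", 1:nl)),
            rep_$pairs$resseq)
    } else NULL
    sort_pairs <- function(m) if (is.null(m)) NULL else
      m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(unname(sort_pairs(got)), unname(sort_pairs(oracle)))
  }
})

test_that("clash counts are monotone in tolerance and vanish at zero radii", {
  p <- make_toy_pocket(5)
  ref <- make_toy_pocket(14, bound_ligand = "trehalose")
  lig <- transplant_ligand(ref, p, "TRE")
  tols <- c(0, 0.2, 0.4, 0.8, 1.5)
  ns <- vapply(tols, function(tl)
    count_clashes(lig, p, tolerance = tl)$n_clashes, integer(1))
  expect_true(all(diff(ns) <= 0))
  tiny <- vdw_table(C = 0.51, N = 0.51, O = 0.51, S = 0.51, P = 0.51,
                    CA = 0.51)
  expect_equal(count_clashes(lig, p, vdw = tiny, tolerance = 0.4)$n_clashes,
               0L)
})

test_that("unknown elements are reported by name", {
  lig <- new_ligand("se", data.frame(name = c("SE1", "C1", "C2"),
                                     element = c("SE", "C", "C"),
                                     x = 0:2, y = 0, z = 0), resname = "SEL")
  expect_error(count_clashes(lig, make_toy_pocket(5)), "SE")
})

test_that("transplantation is exact on self and rigid-motion invariant", {
  ref <- make_toy_pocket(14, bound_ligand = "trehalose")
  bound <- extract_ligand(ref, "TRE")
  self <- transplant_ligand(ref, ref, "TRE")
  expect_lt(max(abs(coords(self) - coords(bound))), 1e-9)
  set.seed(12)
  tr <- new_transform(rand_rotation(), c(-3, 6, 1))
  target <- apply_transform(make_toy_pocket(5), tr)
  lig <- transplant_ligand(ref, target, "TRE")
  base <- count_clashes(transplant_ligand(ref, make_toy_pocket(5), "TRE"),
                        make_toy_pocket(5))
  moved <- count_clashes(lig, target)
  expect_equal(moved$n_clashes, base$n_clashes)
  expect_equal(moved$worst_overlap, base$worst_overlap, tolerance = 1e-6)
  expect_equal(moved$pairs$distance, base$pairs$distance, tolerance = 1e-6)
})

test_that("wide pockets leave clearance around the transplanted probe", {
  ref <- make_toy_pocket(14, bound_ligand = "trehalose")
  wide <- make_toy_pocket(12)
  lig <- transplant_ligand(ref, wide, "TRE")
  rec <- select_atoms(wide, record = "ATOM")
  dmin <- min(lectinpocket:::.pairwise_dist(coords(lig), coords(rec)))
  expect_gte(dmin, 3.4)
  expect_equal(count_clashes(lig, wide)$label, "clash(-)")
})

test_that("a common rigid motion leaves the clash report invariant", {
  set.seed(13)
  p <- make_toy_pocket(6)
  ref <- make_toy_pocket(14, bound_ligand = "trehalose")
  lig <- transplant_ligand(ref, p, "TRE")
  base <- count_clashes(lig, p)
  tr <- new_transform(rand_rotation(), rnorm(3, sd = 10))
  moved <- count_clashes(apply_transform(lig, tr), apply_transform(p, tr))
  expect_equal(moved$n_clashes, base$n_clashes)
  expect_equal(moved$pairs$overlap, base$pairs$overlap, tolerance = 1e-9)
})

test_that("pocket classification follows the clash label", {
  p5 <- make_toy_pocket(5); p12 <- make_toy_pocket(12)
  ref <- make_toy_pocket(14, bound_ligand = "trehalose")
  narrow <- count_clashes(transplant_ligand(ref, p5, "TRE"), p5)
  broad <- count_clashes(transplant_ligand(ref, p12, "TRE"), p12)
  expect_equal(as.character(classify_pocket(narrow)), "narrow")
  expect_equal(as.character(classify_pocket(broad)), "broad")
  expect_equal(attr(classify_pocket(narrow), "probe"), "trehalose")
})
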