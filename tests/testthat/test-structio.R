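test_that("read/write round-trip preserves atoms, names and coordinates", {
  p <- make_toy_pocket(6, bound_ligand = "glucose")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p, f)
  p2 <- read_pdb(f)
  expect_equal(nrow(p2$atoms), nrow(p$atoms))
  expect_equal(p2$atoms$name, p$atoms$name)
  expect_equal(p2$atoms$resname, p$atoms$resname)
  expect_lt(max(abs(coords(p2) - coords(p))), 1e-3)
  # second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(p2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("single ATOM record is echoed back verbatim", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   1       1.000   2.000",
                      "   3.000  1.00  0.00           C"), "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 1L)
  expect_equal(as.numeric(coords(s)), c(1, 2, 3))
})

test_that("TER records separate chains and HETATM carries ions", {
  two <- rbind(make_backbone(3, chain = "A")$atoms,
               make_backbone(2, chain = "B")$atoms)
  two$serial <- seq_len(nrow(two))
  ion <- data.frame(record = "HETATM", serial = nrow(two) + 1L,
                    name = "CA", resname = "CA", chain = "A", resseq = 200L,
                    x = 0, y = 0, z = 0, occ = 1, element = "CA")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(new_structure(rbind(two, ion), id = "dimer"), f)
  lines <- readLines(f)
  expect_equal(sum(startsWith(lines, "TER")), 2L)
  het <- lines[startsWith(lines, "HETATM")]
  expect_equal(length(het), 1L)
  expect_equal(substr(het, 18, 20), "CA ")
})

test_that("parse errors name the offending line and empty files fail", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(paste0("ATOM      1  CA  ALA A   1       1.000   abcde",
                      "   3.000  1.00  0.00           C"), "END"), f)
  expect_error(read_pdb(f), "line 1")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_pdb(f), "no ATOM or HETATM")
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      3  CB AALA A   1       3.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CB BALA A   1       4.000   0.000   0.000  0.50  0.00           C",
    "END"), f)
  s <- read_pdb(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x[s$atoms$name == "CA"], 2)  # higher occupancy
  expect_equal(s$atoms$x[s$atoms$name == "CB"], 3)  # tie -> altloc A
})

test_that("coordinates too large for fixed columns raise overflow error", {
  s <- make_backbone(1)
  s$atoms$x[1] <- 10000
  f <- withr::local_tempfile(fileext = ".pdb")
  expect_error(write_pdb(s, f), "overflow")
})

test_that("select_atoms filters deterministically in file order", {
  s <- make_backbone(100)
  cas <- select_atoms(s, name = "CA")
  expect_equal(nrow(cas), 100L)
  expect_equal(cas$resseq, 1:100)
  expect_identical(select_atoms(s, name = "CA"), cas)
  expect_equal(nrow(select_atoms(s, name = "ZZZ")), 0L)
  # generator-placed carboxylate oxygens of the EPN glutamate
  pk <- make_toy_pocket(5)
  glu_o <- select_atoms(pk, resname = "GLU", name = c("OE1", "OE2"))
  expect_equal(sort(glu_o$name), c("OE1", "OE2"))
  expect_true(all(sqrt(rowSums(coords(glu_o)^2)) - 2.4 < 1e-9))
})

test_that("ligand extraction and re-insertion round-trips", {
  p <- make_toy_pocket(8, bound_ligand = "glucose")
  lig <- extract_ligand(p, "GLC")
  expect_equal(nrow(lig$atoms), 12L)
  bare <- make_toy_pocket(8)
  back <- insert_ligand(bare, lig, resseq = 301L)
  expect_equal(sort(back$atoms$name), sort(p$atoms$name))
  expect_error(extract_ligand(bare, "GLC"), "available")
  expect_error(extract_ligand(bare, "TRE"), "CA")
})

test_that("synthetic pockets always contain exactly one calcium ion", {
  for (a in c(4, 7.5, 12)) {
    f <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(make_toy_pocket(a), f)
    lines <- readLines(f)
    ca <- sum(startsWith(lines, "HETATM") & substr(lines, 18, 19) == "CA")
    expect_equal(ca, 1L)
    expect_equal(nrow(ca_ions(read_pdb(f))), 1L)
  }
})
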