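test_that("sugar motif scanning finds and classifies EPN/QPD/EPD", {
  hits <- find_sugar_motif("AAEPNAA")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$kind, "EPN")
  expect_equal(hits$start, 2L)
  expect_equal(hits$motif_class, "glucose/mannose-type")
  expect_equal(find_sugar_motif("QPD")$motif_class, "galactose-type")
  expect_equal(find_sugar_motif("AEPDA")$motif_class, "unknown-type")
  expect_equal(nrow(find_sugar_motif(strrep("G", 30))), 0L)
  # region restriction is half-open and 0-based
  expect_equal(nrow(find_sugar_motif("EPNAAAA", region = c(1, 7))), 0L)
})

test_that("WND motif scanning reports every occurrence", {
  expect_equal(find_wnd("WND")$start, 0L)
  expect_equal(nrow(find_wnd("WNDWND")), 2L)
  expect_equal(find_wnd("WNDWND")$motif_class,
               rep("calcium-secondary", 2))
  expect_equal(nrow(find_wnd("AAANDAAA")), 0L)
})

test_that("motif hits always satisfy the substring invariant", {
  set.seed(42)
  for (i in 1:25) {
    chars <- sample(strsplit("ACDEFGHIKLMNPQRSTVY", "")[[1]],
                    60, replace = TRUE)
    at <- sample(1:57, 2)
    chars[at[1] + 0:2] <- strsplit(sample(c("EPN", "QPD", "EPD"), 1), "")[[1]]
    chars[at[2] + 0:2] <- c("W", "N", "D")
    s <- paste(chars, collapse = "")
    hits <- rbind(find_sugar_motif(s)[, c("kind", "start")],
                  find_wnd(s)[, c("kind", "start")])
    expect_gte(nrow(hits), 1L)
    for (r in seq_len(nrow(hits)))
      expect_equal(substr(s, hits$start[r] + 1, hits$start[r] + 3),
                   hits$kind[r])
  }
})

test_that("invalid alphabet letters are rejected", {
  expect_error(find_sugar_motif("AB1"), "invalid")
  expect_error(global_align("AEZ", "AE"), "invalid")
  expect_error(find_sugar_motif("epn"), "uppercase")
})

test_that("global alignment matches a brute-force enumeration oracle", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  set.seed(1)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:12) {
    a <- paste(sample(aas, sample(1:5, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:5, 1), replace = TRUE), collapse = "")
    expect_equal(global_align(a, b)$score,
                 brute_align_score(a, b, B62, 11, 1),
                 info = paste(a, b))
  }
})

test_that("alignment score has the expected fixed points", {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  B62 <- e$BLOSUM62
  s <- "MKTWND"
  al <- global_align(s, s)
  expect_equal(al$aligned_a, s)
  expect_equal(al$score,
               sum(diag(B62[strsplit(s, "")[[1]], strsplit(s, "")[[1]]])))
  expect_equal(global_align("A", "")$score, -11)
  # symmetric matrix => symmetric score
  expect_equal(global_align("MKTAY", "MTWY")$score,
               global_align("MTWY", "MKTAY")$score)
})

test_that("position mapping follows alignment columns", {
  ref <- "MKTAYEPNLVWNDQRS"
  expect_equal(unname(map_positions(ref, ref, c(0, 5, 12))), c(0, 5, 12))
  # deletion before all mapped positions shifts every index by -1
  del <- sub("K", "", ref)
  expect_equal(unname(map_positions(del, ref, c(5, 8, 12))), c(4, 7, 11))
  # hand-computed toy alignment: candidate lacks the two C-terminal
  # residues, so those reference positions map to gaps
  expect_equal(unname(map_positions("MKTAYEPNLVWNDQ", ref, c(13, 14, 15))),
               c(13, NA, NA))
})

test_that("candidate classification enforces EPN plus groove retention", {
  gen <- make_candidate_sequences(
    6, data.frame(kind = c("EPN", "QPD", "EPN"),
                  groove_frac = c(1, 1, 0)), seed = 7)
  for (i in seq_along(gen$records)) {
    v <- classify_candidate(gen$records[[i]], gen$groove, gen$reference)
    expect_equal(v$is_mincle_like, gen$truth$is_mincle_like[i])
    expect_equal(v$motif_kind,
                 if (gen$truth$kind[i] == "none") NA_character_
                 else gen$truth$kind[i])
    expect_equal(v$groove_retained_count, gen$truth$groove_retained[i])
  }
  # QPD is reported but never satisfies the EPN requirement
  qpd <- classify_candidate(gen$records[[2]], gen$groove, gen$reference)
  expect_false(qpd$is_mincle_like)
  expect_equal(qpd$motif_kind, "QPD")
})

test_that("classification is invariant under trailing non-matching suffix", {
  gen <- make_candidate_sequences(2, data.frame(kind = "EPN",
                                                groove_frac = 1), seed = 3)
  for (s in gen$records) {
    v1 <- classify_candidate(s, gen$groove, gen$reference)
    v2 <- classify_candidate(paste0(s, "GGGG"), gen$groove, gen$reference)
    expect_equal(v2$is_mincle_like, v1$is_mincle_like)
    expect_equal(v2$groove_retained_count, v1$groove_retained_count)
  }
})
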