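# Sequence screening for mammalian-Mincle hallmarks: the principal-site
# sugar-binding motif (EPN glucose/mannose-type; QPD galactose-type; EPD
# unknown-type), the secondary-calcium WND motif, and retention of
# hydrophobic groove residues mapped from a reference sequence.

.aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")

.check_seq <- function(seq, what = "sequence") {
  if (!nzchar(seq)) stop(what, " is empty")
  if (seq != toupper(seq)) stop(what, " must be uppercase")
  bad <- setdiff(strsplit(seq, "")[[1]], .aa_alphabet)
  if (length(bad))
    stop(what, " contains invalid letters: ", paste(unique(bad), collapse = ""))
  invisible(seq)
}

#' Read amino-acid FASTA records
#'
#' @param path FASTA file (multi-record).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta_aa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("no records in ", path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write amino-acid FASTA records
#' @param seqs named character vector.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_aa <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

.scan_motifs <- function(seq, motifs, classes, region = NULL) {
  n <- nchar(seq)
  lo <- 1L; hi <- n
  if (!is.null(region)) {
    lo <- max(1L, region[1] + 1L)          # region is 0-based [start, end)
    hi <- min(n, region[2])
  }
  hits <- data.frame(kind = character(0), start = integer(0),
                     motif_class = character(0), stringsAsFactors = FALSE)
  for (i in seq_along(motifs)) {
    m <- gregexpr(motifs[i], seq, fixed = TRUE)[[1]]
    m <- m[m > 0]
    m <- m[m >= lo & (m + 2L) <= hi]
    if (length(m))
      hits <- rbind(hits, data.frame(kind = motifs[i], start = m - 1L,
                                     motif_class = classes[i],
                                     stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find the principal-site sugar-binding motif
#'
#' Scans for EPN (glucose/mannose-type), QPD (galactose-type) and EPD
#' (unknown-type) tripeptides. Hits are reported with 0-based start
#' positions, ordered by position.
#'
#' @param seq uppercase amino-acid string.
#' @param region optional 0-based `c(start, end)` half-open index range to
#'   restrict the search; default is the full sequence.
#' @return Data frame with columns `kind`, `start`, `motif_class`.
#' @export
find_sugar_motif <- function(seq, region = NULL) {
  .check_seq(seq)
  .scan_motifs(seq, c("EPN", "QPD", "EPD"),
               c("glucose/mannose-type", "galactose-type", "unknown-type"),
               region)
}

#' Find the WND secondary-calcium motif
#'
#' @param seq uppercase amino-acid string.
#' @param region optional 0-based `c(start, end)` half-open range.
#' @return Data frame with columns `kind`, `start`, `motif_class`
#'   (`"calcium-secondary"`).
#' @export
find_wnd <- function(seq, region = NULL) {
  .check_seq(seq)
  .scan_motifs(seq, "WND", "calcium-secondary", region)
}

#' Global pairwise alignment (Needleman-Wunsch, affine gaps)
#'
#' Optimal global alignment under a substitution matrix with affine gap
#' penalties where a gap of length L costs `gap_open + (L - 1) *
#' gap_extend`. Defaults are the classic protein settings BLOSUM62 /
#' 11 / 1.
#'
#' @param a,b uppercase amino-acid strings.
#' @param matrix substitution matrix name (`"BLOSUM62"`) or numeric
#'   matrix with amino-acid dimnames.
#' @param gap_open,gap_extend positive gap penalties.
#' @return List of class `lp_alignment2`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`.
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11,
                         gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) {
    # forced all-gap alignment against an empty sequence
    n <- max(nchar(a), nchar(b))
    out <- list(aligned_a = if (nzchar(a)) a else strrep("-", n),
                aligned_b = if (nzchar(b)) b else strrep("-", n),
                score = if (n == 0L) 0 else -(gap_open + (n - 1) * gap_extend))
    class(out) <- "lp_alignment2"
    return(out)
  }
  .check_seq(a, "sequence a"); .check_seq(b, "sequence b")
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix,
    gapOpening = gap_open - gap_extend, gapExtension = gap_extend,
    type = "global")
  out <- list(aligned_a = as.character(Biostrings::alignedPattern(pa)),
              aligned_b = as.character(Biostrings::alignedSubject(pa)),
              score = Biostrings::score(pa))
  class(out) <- "lp_alignment2"
  out
}

#' @export
print.lp_alignment2 <- function(x, ...) {
  cat("<lp_alignment2> score ", x$score, "\n ", x$aligned_a, "\n ",
      x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Map reference positions onto a candidate sequence
#'
#' Aligns the reference to the candidate and returns, for each requested
#' 0-based reference index, the corresponding 0-based candidate index, or
#' `NA` where the reference position is aligned to a gap.
#'
#' @param candidate,reference uppercase amino-acid strings.
#' @param ref_positions integer vector of 0-based reference indices.
#' @param ... passed to [global_align()].
#' @return Integer vector (0-based candidate indices, `NA` = gap), named
#'   by `ref_positions`.
#' @export
map_positions <- function(candidate, reference, ref_positions, ...) {
  if (any(ref_positions < 0 | ref_positions >= nchar(reference)))
    stop("ref_positions outside reference length")
  al <- global_align(reference, candidate, ...)
  ra <- strsplit(al$aligned_a, "")[[1]]
  ca <- strsplit(al$aligned_b, "")[[1]]
  ref_idx <- cumsum(ra != "-") - 1L   # 0-based reference index per column
  cand_idx <- cumsum(ca != "-") - 1L
  out <- vapply(ref_positions, function(p) {
    col <- which(ra != "-" & ref_idx == p)[1]
    if (is.na(col) || ca[col] == "-") NA_integer_ else cand_idx[col]
  }, integer(1))
  names(out) <- ref_positions
  out
}

#' Hydrophobic-groove profile
#'
#' Describes the reference positions of the hydrophobic groove-forming
#' residues and the retention criterion. The default hydrophobic set is
#' {A, V, L, I, F, M, W, Y}; the default threshold requires 70% of the
#' positions to be retained (rounded up).
#'
#' @param reference_id id of the reference sequence.
#' @param positions strictly increasing 0-based reference indices.
#' @param hydrophobic_set amino-acid letters counted as hydrophobic.
#' @param min_retained integer retention threshold (at most
#'   `length(positions)`).
#' @return List of class `lp_groove`.
#' @export
groove_profile <- function(reference_id, positions,
                           hydrophobic_set = c("A", "V", "L", "I", "F",
                                               "M", "W", "Y"),
                           min_retained = ceiling(0.7 * length(positions))) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE))
    stop("groove positions must be strictly increasing")
  if (min_retained > length(positions))
    stop("min_retained exceeds number of groove positions")
  structure(list(reference_id = reference_id, positions = positions,
                 hydrophobic_set = hydrophobic_set,
                 min_retained = as.integer(min_retained)),
            class = "lp_groove")
}

#' Read / write a groove profile as JSON
#' @param path JSON file.
#' @return An `lp_groove` (read) or invisibly `path` (write).
#' @export
read_groove_profile <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  groove_profile(j$reference_id, j$positions, j$hydrophobic_set,
                 j$min_retained)
}

#' @rdname read_groove_profile
#' @param groove an `lp_groove`.
#' @export
write_groove_profile <- function(groove, path) {
  jsonlite::write_json(unclass(groove), path, auto_unbox = TRUE)
  invisible(path)
}

#' Screen one candidate sequence for Mincle-like hallmarks
#'
#' A candidate is Mincle-like when (i) it carries the EPN motif in the
#' search region (by default the C-terminal 60% of the sequence, where
#' the CRD lies) and (ii) at least `min_retained` of the groove positions,
#' mapped from the reference by global alignment, hold hydrophobic
#' residues. QPD/EPD hits are reported but do not satisfy the EPN
#' requirement.
#'
#' @param candidate uppercase amino-acid string.
#' @param groove an [groove_profile()].
#' @param reference reference sequence (uppercase string) carrying the
#'   groove positions.
#' @param cterm_frac fraction of the sequence tail searched for motifs
#'   (default 0.6); use 1 for a full-length search.
#' @param ... passed to [global_align()].
#' @return One-row data frame (`CandidateVerdict`): `has_sugar_motif`,
#'   `motif_kind`, `motif_start`, `has_wnd`, `groove_retained_count`,
#'   `is_mincle_like`.
#' @export
classify_candidate <- function(candidate, groove, reference,
                               cterm_frac = 0.6, ...) {
  .check_seq(candidate, "candidate")
  n <- nchar(candidate)
  region <- c(as.integer(floor((1 - cterm_frac) * n)), n)
  hits <- find_sugar_motif(candidate, region)
  wnd <- find_wnd(candidate, region)
  # prefer the EPN hit when several motif kinds occur
  best <- if (any(hits$kind == "EPN")) hits[hits$kind == "EPN", ][1, ]
          else if (nrow(hits)) hits[1, ] else NULL
  mapped <- map_positions(candidate, reference, groove$positions, ...)
  cand_chars <- strsplit(candidate, "")[[1]]
  retained <- sum(!is.na(mapped) &
                    cand_chars[mapped + 1L] %in% groove$hydrophobic_set)
  data.frame(has_sugar_motif = !is.null(best),
             motif_kind = if (is.null(best)) NA_character_ else best$kind,
             motif_start = if (is.null(best)) NA_integer_ else best$start,
             has_wnd = nrow(wnd) > 0L,
             groove_retained_count = retained,
             is_mincle_like = !is.null(best) && best$kind == "EPN" &&
               retained >= groove$min_retained,
             stringsAsFactors = FALSE)
}
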