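# Orchestration: sequence screen, structural screen, phylogeny, and the
# merged evolutionary summary table.

#' Screen a FASTA of candidate sequences
#'
#' Runs [classify_candidate()] on every record, in input order.
#'
#' @param fasta path to a multi-record amino-acid FASTA.
#' @param groove an [groove_profile()] or path to its JSON file.
#' @param reference reference sequence string, or path to a single-record
#'   FASTA.
#' @param out optional TSV output path.
#' @param ... passed to [classify_candidate()].
#' @return Data frame with one verdict row per record (column `id`
#'   first).
#' @export
run_sequence_screen <- function(fasta, groove, reference, out = NULL, ...) {
  seqs <- read_fasta_aa(fasta)
  if (is.character(groove) && length(groove) == 1L && file.exists(groove))
    groove <- read_groove_profile(groove)
  if (file.exists(reference)) reference <- read_fasta_aa(reference)[[1]]
  rows <- lapply(seq_along(seqs), function(i) {
    cbind(data.frame(id = names(seqs)[i], stringsAsFactors = FALSE),
          classify_candidate(gsub("-", "", seqs[[i]]), groove, reference,
                             ...))
  })
  verdicts <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(verdicts, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  verdicts
}

#' Screen a set of structures by ligand transplantation
#'
#' For each target structure: superpose the reference complex onto it by
#' the pocket calcium anchor, transplant the named ligand, count van der
#' Waals clashes and classify the pocket. Structures whose anchor cannot
#' be resolved yield an NA row with a warning instead of aborting the
#' batch.
#'
#' @param structures named character vector of PDB paths (names become
#'   ids; defaults to file base names).
#' @param reference_complex path to the ligand-bound reference PDB.
#' @param ligand HETATM residue name of the probe (default `"TRE"`).
#' @param vdw radius table from [vdw_table()].
#' @param tolerance clash tolerance in angstrom.
#' @param anchor optional anchor table for [ca_anchor_superpose()].
#' @param out optional TSV output path.
#' @return Data frame: `id`, `n_clashes`, `worst_overlap`, `label`,
#'   `pocket_class` per structure.
#' @export
run_structural_screen <- function(structures, reference_complex,
                                  ligand = "TRE", vdw = vdw_table(),
                                  tolerance = 0.4, anchor = NULL,
                                  out = NULL) {
  if (is.null(names(structures)))
    names(structures) <- sub("\\.pdb$", "", basename(structures))
  ref <- read_pdb(reference_complex)
  rows <- lapply(names(structures), function(id) {
    res <- tryCatch({
      tgt <- read_pdb(structures[[id]], id = id)
      lig <- transplant_ligand(ref, tgt, ligand, anchor = anchor)
      rep_ <- count_clashes(lig, tgt, vdw = vdw, tolerance = tolerance)
      data.frame(id = id, n_clashes = rep_$n_clashes,
                 worst_overlap = rep_$worst_overlap, label = rep_$label,
                 pocket_class = as.character(classify_pocket(rep_)),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning("structure ", id, " skipped: ", conditionMessage(e),
              call. = FALSE)
      data.frame(id = id, n_clashes = NA_integer_,
                 worst_overlap = NA_real_, label = NA_character_,
                 pocket_class = NA_character_, stringsAsFactors = FALSE)
    })
    res
  })
  tab <- do.call(rbind, rows)
  if (!is.null(out))
    utils::write.table(tab, out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}

#' Run the full evolutionary pocket analysis
#'
#' Joins the three evidence streams on sequence id: the motif/groove
#' sequence screen, the clash-based structural screen, and the clade
#' assignment from the neighbor-joining JTT tree of the alignment
#' (optionally with ML branch-length optimization), plus optional 1-D
#' clustering of a structure-similarity score table. Writes the summary
#' TSV, the Newick tree and a provenance JSON recording every threshold
#' used.
#'
#' @param config path to a JSON configuration, or an equivalent list,
#'   with fields `fasta` (aligned FASTA), `reference_id` (id of the
#'   reference/anchor sequence in the FASTA), `groove` (groove profile
#'   JSON), `structures` (named list id -> PDB path),
#'   `reference_complex`, `ligand`, `anchors` (named list label ->
#'   group), `outgroup`, optional `scores` (TSV with `id`, `score`),
#'   optional `seed`.
#' @param out_dir output directory (default: alongside the config).
#' @param model an `lp_model`.
#' @param optimize_branches also run [optimize_branch_lengths()] on the
#'   NJ topology (default `FALSE`; clade assignment depends only on the
#'   topology).
#' @param tolerance clash tolerance (angstrom).
#' @return List: `summary` (data frame), `tree` (`phylo`),
#'   `paths` (written files), invisibly also written to `out_dir`.
#' @export
run_full <- function(config, out_dir = NULL, model = substitution_model(),
                     optimize_branches = FALSE, tolerance = 0.4) {
  if (is.character(config)) {
    config_path <- config
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(out_dir)) out_dir <- file.path(dirname(config_path), "out")
  } else if (is.null(out_dir)) {
    stop("out_dir is required when config is given as a list")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- read_fasta_aa(config$fasta)
  if (!config$reference_id %in% names(seqs))
    stop("reference_id not found in FASTA: ", config$reference_id)
  groove <- read_groove_profile(config$groove)
  # sequence screen (on degapped sequences)
  seq_tab <- run_sequence_screen(config$fasta, groove,
                                 gsub("-", "", seqs[[config$reference_id]]))
  # phylogeny on the aligned sequences
  msa <- complete_deletion(new_msa(seqs))
  tree <- nj_tree(dist_jtt(msa, model))
  if (isTRUE(optimize_branches))
    tree <- optimize_branch_lengths(tree, msa, model)
  anchors <- unlist(config$anchors)
  clades <- assign_clades(tree, anchors, config$outgroup)
  names(clades)[names(clades) == "group"] <- "clade_group"
  # structural screen
  structures <- unlist(config$structures)
  struct_tab <- if (length(structures))
    run_structural_screen(structures, config$reference_complex,
                          ligand = config$ligand, tolerance = tolerance)
  else data.frame(id = character(0), n_clashes = integer(0),
                  worst_overlap = numeric(0), label = character(0),
                  pocket_class = character(0), stringsAsFactors = FALSE)
  # optional score clustering
  score_tab <- NULL
  if (!is.null(config$scores) && nzchar(config$scores)) {
    sc <- utils::read.table(config$scores, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    split <- split_by_score(sc)
    score_tab <- split$clusters
    names(score_tab)[names(score_tab) == "cluster"] <- "score_cluster"
  }
  # join on id; ids present in one stream but not another become NA
  summary <- merge(clades, seq_tab, by = "id", all = TRUE, sort = FALSE)
  summary <- merge(summary, struct_tab, by = "id", all = TRUE, sort = FALSE)
  if (!is.null(score_tab))
    summary <- merge(summary, score_tab[, c("id", "score_cluster")],
                     by = "id", all = TRUE, sort = FALSE)
  summary <- summary[order(match(summary$id, names(seqs))), ]
  rownames(summary) <- NULL
  unmatched <- summary$id[rowSums(is.na(summary)) == ncol(summary) - 1L]
  if (length(unmatched))
    warning("ids with no matching data in any stream: ",
            paste(unmatched, collapse = ", "))
  paths <- list(summary = file.path(out_dir, "summary.tsv"),
                tree = file.path(out_dir, "tree.nwk"),
                provenance = file.path(out_dir, "provenance.json"))
  utils::write.table(summary, paths$summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ape::write.tree(tree, paths$tree)
  prov <- list(package = "lectinpocket",
               version = as.character(utils::packageVersion("lectinpocket")),
               seed = config$seed,
               clash_tolerance = tolerance,
               ligand = config$ligand,
               gamma_shape = model$gamma_shape,
               n_categories = model$n_categories,
               p_inv = model$p_inv,
               min_retained = groove$min_retained,
               optimize_branches = isTRUE(optimize_branches),
               n_sequences = length(seqs),
               n_sites_after_complete_deletion = nchar(msa[[1]]))
  jsonlite::write_json(prov, paths$provenance, auto_unbox = TRUE)
  invisible(list(summary = summary, tree = tree, paths = paths))
}
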