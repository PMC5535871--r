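.report_header <- function(con, title, params = list()) {
  writeLines(c(
    sprintf("# %s", title),
    sprintf("# backsplice %s", as.character(utils::packageVersion("backsplice"))),
    vapply(names(params), function(k)
      sprintf("# %s: %s", k, paste(format(params[[k]]), collapse = ",")), "")
  ), con)
}

.write_report <- function(df, path, title, params = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  .report_header(con, title, params)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Catalogue statistics reports
#'
#' Reads a circular-isoform catalogue, deduplicates it per cell line, and
#' writes the standard structural reports: per-exon relative abundance,
#' per-intron inclusion of the unspliced precursor (when a gene model is
#' given), the back-splice junction tally, junctions shared by all cell
#' lines, and the isoforms common to the first two cell lines.
#'
#' @param catalogue catalogue TSV path or a `circ_catalogue`.
#' @param out_dir output directory.
#' @param model optional [gene_model()] (or annotation path plus
#'   `gene_id`) enabling the intron-inclusion report.
#' @param gene_id gene to load when `model` is an annotation path.
#' @return Invisibly, a list of the computed tables.
#' @export
run_catalogue_stats <- function(catalogue, out_dir, model = NULL,
                                gene_id = NULL) {
  cat_df <- if (is.character(catalogue)) read_catalogue(catalogue) else catalogue
  if (is.character(model)) model <- load_gene_model(model, gene_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  res$exon_abundance <- exon_abundance(cat_df)
  .write_report(res$exon_abundance, file.path(out_dir, "exon_abundance.tsv"),
                "relative exon abundance per cell line")
  res$junction_tally <- junction_tally(cat_df)
  .write_report(res$junction_tally, file.path(out_dir, "junction_tally.tsv"),
                "distinct back-splice junctions per cell line")
  res$shared_junctions <- shared_junctions(cat_df)
  .write_report(res$shared_junctions,
                file.path(out_dir, "shared_junctions.tsv"),
                "junctions observed in every cell line")
  if (length(unique(cat_df$cell_line)) >= 2) {
    res$common_isoforms <- common_isoforms(cat_df)
    .write_report(res$common_isoforms,
                  file.path(out_dir, "common_isoforms.tsv"),
                  "isoforms common to the first two cell lines")
  }
  if (!is.null(model)) {
    res$intron_inclusion <- intron_inclusion(cat_df, model)
    .write_report(res$intron_inclusion,
                  file.path(out_dir, "intron_inclusion.tsv"),
                  "precursor intron inclusion (scaled to [0,1])")
  }
  invisible(res)
}

#' Inverted-repeat detection and junction classification reports
#'
#' Runs the full repeat arm of the pipeline: assigns repeats to the
#' exons/introns of the model, detects inverted repeat pairs across
#' intron pairs by affine-gap alignment, predicts the back-splice
#' junctions those pairs could bracket, and (when a catalogue is given)
#' partitions the observed junctions into explained and unexplained.
#'
#' @param annotation annotation path or [gene_model()].
#' @param genome FASTA path or named [Biostrings::DNAStringSet].
#' @param repeats repeat-track path (rmsk/BED6) or data.frame.
#' @param catalogue optional catalogue TSV path or `circ_catalogue` of
#'   observed circles.
#' @param gene_id gene to load when `annotation` is a path.
#' @param scoring an [alignment_scoring()].
#' @param min_overlap_frac repeat-to-feature assignment threshold.
#' @param class_filter repeat class filter for file input.
#' @param out_dir output directory.
#' @return Invisibly, a list with `assignment`, `pairs`, `predictions`
#'   and (if a catalogue was given) `classification`.
#' @export
run_alu_analysis <- function(annotation, genome, repeats, catalogue = NULL,
                             gene_id = NULL,
                             scoring = alignment_scoring(),
                             min_overlap_frac = 1, class_filter = "Alu",
                             out_dir) {
  model <- if (is.character(annotation)) load_gene_model(annotation, gene_id)
           else annotation
  reps <- if (is.character(repeats)) {
    read_repeats(repeats, class_filter = class_filter)
  } else repeats
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  res$assignment <- assign_repeats_to_features(reps, model, min_overlap_frac)
  .write_report(
    data.frame(feature_type = c(rep("intron", length(res$assignment$intron_counts)),
                                rep("exon", length(res$assignment$exon_counts))),
               feature_id = c(names(res$assignment$intron_counts),
                              names(res$assignment$exon_counts)),
               n_repeats = c(res$assignment$intron_counts,
                             res$assignment$exon_counts)),
    file.path(out_dir, "repeat_assignment.tsv"),
    "repeat counts per feature",
    list(min_overlap_frac = min_overlap_frac))
  res$pairs <- find_inverted_pairs(reps, model, genome, scoring,
                                   min_overlap_frac)
  .write_report(res$pairs, file.path(out_dir, "inverted_pairs.tsv"),
                "inverted repeat pairs across intron pairs",
                list(match = scoring$match, mismatch = scoring$mismatch,
                     gap_open = scoring$gap_open,
                     gap_extend = scoring$gap_extend,
                     min_score = scoring$min_score))
  res$predictions <- predict_junctions(res$pairs, model)
  .write_report(res$predictions, file.path(out_dir, "predicted_junctions.tsv"),
                "back-splice junctions predicted from inverted pairs")
  if (!is.null(catalogue)) {
    cat_df <- if (is.character(catalogue)) read_catalogue(catalogue) else catalogue
    observed <- junction_tally(cat_df)
    res$classification <- classify_observed_junctions(observed, res$predictions)
    cls <- rbind(
      if (nrow(res$classification$explained))
        cbind(res$classification$explained, status = "explained"),
      if (nrow(res$classification$unexplained))
        cbind(res$classification$unexplained, status = "unexplained"))
    .write_report(cls, file.path(out_dir, "junction_classification.tsv"),
                  "observed junctions vs inverted-repeat predictions")
  }
  invisible(res)
}

#' Exon-skipping candidate and match reports
#'
#' Derives the candidate circle exon set of every skipped-exon event and
#' intersects the candidates with the observed catalogue (exact exon-set
#' equality).
#'
#' @param events SE events path or data.frame from [read_se_events()].
#' @param annotation annotation path or [gene_model()].
#' @param catalogue catalogue TSV path or `circ_catalogue`.
#' @param gene_id gene to load when `annotation` is a path.
#' @param out_dir output directory.
#' @return Invisibly, the [match_skipping_to_catalogue()] result.
#' @export
run_skipping_analysis <- function(events, annotation, catalogue,
                                  gene_id = NULL, out_dir) {
  ev <- if (is.character(events)) read_se_events(events) else events
  model <- if (is.character(annotation)) load_gene_model(annotation, gene_id)
           else annotation
  cat_df <- if (is.character(catalogue)) read_catalogue(catalogue) else catalogue
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- match_skipping_to_catalogue(ev, cat_df, model)
  .write_report(res$candidates, file.path(out_dir, "skipping_candidates.tsv"),
                "candidate circle exon sets per skipping event")
  .write_report(res$matches, file.path(out_dir, "skipping_matches.tsv"),
                "complete matches between candidates and observed circles",
                list(n_matches = nrow(res$matches)))
  message(sprintf("skipping analysis: %d complete match(es) of %d event(s) vs %d isoform(s)",
                  nrow(res$matches), nrow(ev),
                  nrow(dedup_catalogue(cat_df, "cell_line"))))
  invisible(res)
}

#' Generate and write a synthetic dataset
#'
#' @param out_dir output directory.
#' @param config a [simulation_config()].
#' @return Invisibly, a list with the `sim_locus` and the catalogue.
#' @export
run_simulation <- function(out_dir, config = simulation_config()) {
  locus <- simulate_locus(config)
  circles <- simulate_catalogue(config, locus)
  write_simulation(locus, circles, out_dir)
  invisible(list(locus = locus, circles = circles))
}
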