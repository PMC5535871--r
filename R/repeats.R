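#' Read repeat elements from a UCSC rmsk table or BED6 file
#'
#' Accepts either the full 17-column UCSC RepeatMasker (`rmsk`) table dump
#' (with or without a header line) or headerless BED6 with the repeat name
#' in column 4. Both dialects carry 0-based half-open coordinates, which
#' are kept as-is internally. For BED6 input the repeat class and family
#' are taken from the name when it is written `name#class/family`
#' (RepeatMasker's convention), otherwise left as the name.
#'
#' @param path repeat track file.
#' @param region optional list/vector with `chrom`, `start`, `end`
#'   (0-based half-open); only repeats overlapping it are returned.
#' @param class_filter regular expression matched (case-sensitively)
#'   against the repeat name, class and family; a repeat is kept when any
#'   of the three matches. `NULL` keeps everything. The default keeps
#'   Alu-family SINEs.
#' @return Data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `class`, `family`.
#' @export
read_repeats <- function(path, region = NULL, class_filter = "Alu") {
  if (!file.exists(path)) stop("repeat file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    reps <- data.frame(chrom = character(0), start = numeric(0),
                       end = numeric(0), strand = character(0),
                       name = character(0), class = character(0),
                       family = character(0))
    return(reps)
  }
  first <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 17 || identical(first[1], "bin")) {
    if (identical(first[1], "bin")) lines <- lines[-1]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 13)[1]
    if (!is.na(bad)) {
      stop("unrecognised rmsk line ", bad, ": ", lines[bad])
    }
    reps <- data.frame(
      chrom = vapply(fields, `[`, "", 6),
      start = as.numeric(vapply(fields, `[`, "", 7)),
      end = as.numeric(vapply(fields, `[`, "", 8)),
      strand = vapply(fields, `[`, "", 10),
      name = vapply(fields, `[`, "", 11),
      class = vapply(fields, `[`, "", 12),
      family = vapply(fields, `[`, "", 13),
      stringsAsFactors = FALSE
    )
  } else if (length(first) >= 6) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 6)[1]
    if (!is.na(bad)) {
      stop("unrecognised BED6 line ", bad, ": ", lines[bad])
    }
    nm <- vapply(fields, `[`, "", 4)
    cls <- ifelse(grepl("#", nm), sub("^[^#]*#([^/]*).*$", "\\1", nm), nm)
    fam <- ifelse(grepl("/", nm), sub("^.*/", "", nm), cls)
    reps <- data.frame(
      chrom = vapply(fields, `[`, "", 1),
      start = as.numeric(vapply(fields, `[`, "", 2)),
      end = as.numeric(vapply(fields, `[`, "", 3)),
      strand = vapply(fields, `[`, "", 6),
      name = sub("#.*$", "", nm),
      class = cls, family = fam,
      stringsAsFactors = FALSE
    )
  } else {
    stop("unrecognised repeat-track layout at line 1: ", lines[1])
  }
  if (anyNA(reps$start) || anyNA(reps$end)) {
    stop("non-numeric coordinates in repeat track: ", path)
  }
  if (!is.null(class_filter)) {
    keep <- grepl(class_filter, reps$name) | grepl(class_filter, reps$class) |
      grepl(class_filter, reps$family)
    reps <- reps[keep, , drop = FALSE]
  }
  if (!is.null(region)) {
    region <- as.list(region)
    keep <- reps$chrom == region$chrom &
      reps$start < as.numeric(region$end) & reps$end > as.numeric(region$start)
    reps <- reps[keep, , drop = FALSE]
  }
  rownames(reps) <- NULL
  reps
}

#' Write repeats as an rmsk-style table
#'
#' Emits the 17-column UCSC rmsk layout (header line included; unused
#' numeric columns zero-filled) so that [read_repeats()] round-trips the
#' records.
#'
#' @param reps repeat data.frame as returned by [read_repeats()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_repeats_rmsk <- function(reps, path) {
  cols <- c("bin", "swScore", "milliDiv", "milliDel", "milliIns", "genoName",
            "genoStart", "genoEnd", "genoLeft", "strand", "repName",
            "repClass", "repFamily", "repStart", "repEnd", "repLeft", "id")
  out <- data.frame(
    bin = 0L, swScore = 0L, milliDiv = 0L, milliDel = 0L, milliIns = 0L,
    genoName = reps$chrom, genoStart = format(reps$start, scientific = FALSE,
                                              trim = TRUE),
    genoEnd = format(reps$end, scientific = FALSE, trim = TRUE),
    genoLeft = 0L,
    strand = reps$strand, repName = reps$name, repClass = reps$class,
    repFamily = reps$family, repStart = 0L, repEnd = 0L, repLeft = 0L,
    id = seq_len(nrow(reps))
  )
  names(out) <- cols
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

#' Assign repeats to the exons and introns of a gene model
#'
#' A repeat is assigned to the single exon or intron that contains at
#' least `min_overlap_frac` of its length (default 1: full containment).
#' Repeats that overlap a feature by less than the threshold are reported
#' as `partial` and not counted; repeats outside the locus are dropped.
#' With Alu-length repeats (~300 bp) much shorter than typical introns,
#' full containment avoids double counting across feature boundaries.
#'
#' @param reps repeat data.frame from [read_repeats()].
#' @param model a [gene_model()] with exon intervals.
#' @param min_overlap_frac minimum fraction of the repeat length that must
#'   fall inside a feature for assignment.
#' @return List with `assignments` (one row per assigned repeat: feature
#'   type, feature id, overlap fraction), `intron_counts` (per intron
#'   index), `exon_counts` (per exon label), and `partial` (repeats
#'   overlapping the locus but assigned nowhere).
#' @export
assign_repeats_to_features <- function(reps, model, min_overlap_frac = 1) {
  stopifnot(inherits(model, "gene_model"),
            min_overlap_frac > 0, min_overlap_frac <= 1)
  feats <- rbind(
    data.frame(type = "exon", id = model$exons$label,
               start = model$exons$start, end = model$exons$end),
    data.frame(type = "intron", id = as.character(model$introns$index),
               start = model$introns$start, end = model$introns$end)
  )
  n <- nrow(reps)
  assignments <- data.frame(name = character(0), chrom = character(0),
                            start = numeric(0), end = numeric(0),
                            feature_type = character(0),
                            feature_id = character(0),
                            overlap_frac = numeric(0))
  partial <- assignments
  if (n > 0) {
    if (!is.na(model$chrom)) {
      reps <- reps[reps$chrom == model$chrom, , drop = FALSE]
    }
    for (k in seq_len(nrow(reps))) {
      ov <- pmax(0, pmin(reps$end[k], feats$end) - pmax(reps$start[k], feats$start))
      frac <- ov / (reps$end[k] - reps$start[k])
      best <- which.max(frac)
      if (length(best) && frac[best] >= min_overlap_frac) {
        assignments <- rbind(assignments, data.frame(
          name = reps$name[k], chrom = reps$chrom[k],
          start = reps$start[k], end = reps$end[k],
          feature_type = feats$type[best], feature_id = feats$id[best],
          overlap_frac = frac[best]))
      } else if (length(best) && frac[best] > 0) {
        partial <- rbind(partial, data.frame(
          name = reps$name[k], chrom = reps$chrom[k],
          start = reps$start[k], end = reps$end[k],
          feature_type = feats$type[best], feature_id = feats$id[best],
          overlap_frac = frac[best]))
      }
    }
  }
  intron_counts <- stats::setNames(integer(nrow(model$introns)),
                                   as.character(model$introns$index))
  exon_counts <- stats::setNames(integer(nrow(model$exons)),
                                 model$exons$label)
  if (nrow(assignments)) {
    tab_i <- table(assignments$feature_id[assignments$feature_type == "intron"])
    intron_counts[names(tab_i)] <- as.integer(tab_i)
    tab_e <- table(assignments$feature_id[assignments$feature_type == "exon"])
    exon_counts[names(tab_e)] <- as.integer(tab_e)
  }
  list(assignments = assignments, intron_counts = intron_counts,
       exon_counts = exon_counts, partial = partial)
}

.fetch_seq <- function(genome, chrom, start, end) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  chr <- genome[[chrom]]
  if (end > length(chr)) {
    stop(sprintf("sequence %s is shorter (%d) than annotated repeat end (%d)",
                 chrom, length(chr), end))
  }
  Biostrings::subseq(chr, start + 1L, end)
}

#' Detect inverted repeat pairs across intron pairs
#'
#' For every ordered intron pair `(i, j)` with `i < j` and every pair of
#' repeats assigned to those introns, aligns the genomic (plus-strand)
#' sequence of the first repeat against the reverse complement of the
#' second with [align_global()]. Pairs scoring at or above
#' `scoring$min_score` are inverted repeat pairs: two sequences that are
#' (approximate) reverse complements of one another, and could base-pair
#' to bracket a back-splice between the exons they flank. Same-intron
#' pairs are never considered, since a duplex inside a single intron
#' cannot bracket a back-splice.
#'
#' @param reps repeat data.frame from [read_repeats()].
#' @param model a [gene_model()].
#' @param genome FASTA path or named [Biostrings::DNAStringSet].
#' @param scoring an [alignment_scoring()].
#' @param min_overlap_frac passed to [assign_repeats_to_features()].
#' @return Data.frame with columns `intron_i`, `intron_j`, `rep_a`,
#'   `rep_b`, `start_a`, `start_b`, `score`.
#' @export
find_inverted_pairs <- function(reps, model, genome,
                                scoring = alignment_scoring(),
                                min_overlap_frac = 1) {
  stopifnot(inherits(model, "gene_model"),
            inherits(scoring, "alignment_scoring"))
  if (is.character(genome) && length(genome) == 1) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  asg <- assign_repeats_to_features(reps, model, min_overlap_frac)$assignments
  asg <- asg[asg$feature_type == "intron", , drop = FALSE]
  out <- data.frame(intron_i = integer(0), intron_j = integer(0),
                    rep_a = character(0), rep_b = character(0),
                    start_a = numeric(0), start_b = numeric(0),
                    score = numeric(0))
  if (nrow(asg) == 0) return(out)
  asg$intron <- as.integer(asg$feature_id)
  seqs <- lapply(seq_len(nrow(asg)), function(k)
    as.character(.fetch_seq(genome, asg$chrom[k], asg$start[k], asg$end[k])))
  introns <- sort(unique(asg$intron))
  for (ii in seq_along(introns)) {
    for (jj in seq_along(introns)) {
      if (jj <= ii) next
      ai <- which(asg$intron == introns[ii])
      aj <- which(asg$intron == introns[jj])
      for (p in ai) {
        for (q in aj) {
          sc <- align_global(seqs[[p]],
                             as.character(Biostrings::reverseComplement(
                               Biostrings::DNAString(seqs[[q]]))),
                             scoring)
          if (sc >= scoring$min_score) {
            out <- rbind(out, data.frame(
              intron_i = introns[ii], intron_j = introns[jj],
              rep_a = asg$name[p], rep_b = asg$name[q],
              start_a = asg$start[p], start_b = asg$start[q], score = sc))
          }
        }
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Back-splice junctions predicted from inverted intron pairs
#'
#' An inverted repeat pair in introns `(i, j)` with `i < j` can bracket
#' the contiguous run of exons `i + 1 .. j`, predicting a circle with
#' donor exon `j` and acceptor exon `i + 1`; `i + 1 == j` predicts a
#' single-exon circle. Only canonical introns ever predict junctions, so
#' predicted junctions always involve canonical exon labels.
#'
#' @param pairs data.frame with `intron_i`, `intron_j` columns; either
#'   [find_inverted_pairs()] output or a bare intron-pair table.
#' @param model a [gene_model()] supplying canonical exon labels.
#' @return Data.frame with one row per distinct predicted junction:
#'   `donor`, `acceptor`, `intron_i`, `intron_j`, `n_pairs` (supporting
#'   repeat pairs), `best_score` (`NA` when `pairs` carries no scores).
#' @examples
#' m <- anril_model()
#' predict_junctions(data.frame(intron_i = 1, intron_j = 14), m)
#' @export
predict_junctions <- function(pairs, model) {
  stopifnot(inherits(model, "gene_model"),
            all(c("intron_i", "intron_j") %in% names(pairs)))
  can <- model$exons[is_canonical_label(model$exons$label), , drop = FALSE]
  labels <- can$label[order(as.numeric(can$label))]
  n_intron <- nrow(model$introns)
  if (nrow(pairs) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      intron_i = integer(0), intron_j = integer(0),
                      n_pairs = integer(0), best_score = numeric(0)))
  }
  i <- pmin(pairs$intron_i, pairs$intron_j)
  j <- pmax(pairs$intron_i, pairs$intron_j)
  if (any(i < 1 | j > n_intron | i == j)) {
    stop("intron indices must be distinct and within 1..", n_intron)
  }
  score <- if ("score" %in% names(pairs)) pairs$score else rep(NA_real_, nrow(pairs))
  key <- paste(i, j)
  agg <- lapply(unique(key), function(k) {
    sel <- key == k
    data.frame(donor = labels[j[sel][1]], acceptor = labels[i[sel][1] + 1L],
               intron_i = i[sel][1], intron_j = j[sel][1],
               n_pairs = sum(sel),
               best_score = if (all(is.na(score[sel]))) NA_real_
                            else max(score[sel], na.rm = TRUE))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$intron_i, out$intron_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition observed junctions into explained and unexplained
#'
#' Compares observed back-splice junctions against the junctions
#' predicted from inverted repeat pairs. A junction is explained when an
#' identical `(donor, acceptor)` pair is predicted; the comparison is at
#' junction level only (full exon cycles are not required to match). The
#' two output sets partition the observed set exactly.
#'
#' @param observed data.frame with `donor`, `acceptor` columns (e.g. from
#'   [junction_tally()]).
#' @param predicted data.frame with `donor`, `acceptor` columns (e.g. from
#'   [predict_junctions()]).
#' @return List with `explained` and `unexplained` data.frames of distinct
#'   junctions.
#' @export
classify_observed_junctions <- function(observed, predicted) {
  stopifnot(all(c("donor", "acceptor") %in% names(observed)),
            all(c("donor", "acceptor") %in% names(predicted)))
  obs <- unique(observed[, c("donor", "acceptor"), drop = FALSE])
  okey <- paste(obs$donor, obs$acceptor, sep = ">")
  pkey <- paste(predicted$donor, predicted$acceptor, sep = ">")
  explained <- obs[okey %in% pkey, , drop = FALSE]
  unexplained <- obs[!okey %in% pkey, , drop = FALSE]
  rownames(explained) <- rownames(unexplained) <- NULL
  list(explained = explained, unexplained = unexplained)
}

#' Correlate per-intron repeat counts with intron length
#'
#' Tests whether the number of repeat elements grows with intron length,
#' reporting both the Spearman rank correlation and the Pearson linear
#' correlation with two-sided p-values from [stats::cor.test()].
#'
#' @param introns data.frame with a `length` column (e.g.
#'   `model$introns`), or a numeric length vector.
#' @param counts numeric vector of per-intron repeat counts, same order.
#' @return Data.frame with columns `method`, `estimate`, `p_value`.
#' @export
correlate_repeat_count_with_length <- function(introns, counts) {
  lengths <- if (is.data.frame(introns)) introns$length else as.numeric(introns)
  counts <- as.numeric(counts)
  stopifnot(length(lengths) == length(counts))
  if (length(lengths) < 3) stop("need at least 3 introns")
  if (stats::sd(counts) == 0 || stats::sd(lengths) == 0) {
    stop("correlation undefined for constant input")
  }
  sp <- suppressWarnings(stats::cor.test(lengths, counts, method = "spearman"))
  pe <- stats::cor.test(lengths, counts, method = "pearson")
  data.frame(method = c("spearman", "pearson"),
             estimate = c(unname(sp$estimate), unname(pe$estimate)),
             p_value = c(sp$p.value, pe$p.value))
}

#' Bundled inverted intron pairs for the ANRIL locus
#'
#' The intron pairs of the ANRIL locus reported to contain
#' reverse-complementary Alu repeat pairs (from the published hg19
#' RepeatMasker analysis of this locus), normalised to `intron_i <
#' intron_j`. Feeding these to [predict_junctions()] reproduces the
#' published candidate back-splice junction list.
#'
#' @return Data.frame with columns `intron_i`, `intron_j`.
#' @export
fixture_inverted_intron_pairs <- function() {
  utils::read.table(
    system.file("extdata", "anril_inverted_intron_pairs.tsv",
                package = "backsplice", mustWork = TRUE),
    sep = "\t", header = TRUE, comment.char = "#")
}
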