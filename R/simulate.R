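#' Configuration for the synthetic locus/catalogue simulator
#'
#' Describes a synthetic multi-exon locus with Alu-length repeats planted
#' in its introns -- some as (optionally diverged) reverse-complement
#' pairs across intron pairs -- plus a circular-isoform catalogue whose
#' entries carry ground-truth biogenesis labels. Identical `seed` and
#' configuration produce byte-identical outputs.
#'
#' The default dimensions mimic a locus of the kind the package targets:
#' 19 exons of median ~130 bp, introns whose lengths span roughly two
#' orders of magnitude (so the "long intron, many repeats" structure is
#' representable), 300 bp repeats, and two planted inverted pairs.
#'
#' @param n_exons number of canonical exons.
#' @param exon_len_meanlog,exon_len_sdlog log-normal exon length
#'   parameters (bp).
#' @param intron_len_meanlog,intron_len_sdlog log-normal intron length
#'   parameters (bp).
#' @param flank flanking sequence on each side of the locus (bp).
#' @param repeat_length planted repeat length (bp); Alu-like default 300.
#' @param min_intron_length floor applied to drawn intron lengths;
#'   defaults to `repeat_length + 100` so default placements are feasible.
#' @param background_per_kb expected unrelated background repeats per kb
#'   of intron (Poisson).
#' @param inverted_pairs data.frame with columns `intron_i`, `intron_j`,
#'   `divergence`: one planted reverse-complement repeat pair per row,
#'   with the stated fraction of the second copy's positions redrawn.
#' @param n_alu_circles,n_skipping_circles,n_random_circles catalogue
#'   plan: circles generated by the inverted-repeat mechanism (contiguous
#'   runs bracketed by planted pairs), circles equal to a generated
#'   skipped-exon event's candidate set, and random exon subsets whose
#'   junctions avoid all predicted junctions.
#' @param cell_line cell-line label stamped on simulated circles.
#' @param seed integer seed governing every random draw.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_exons = 19,
                              exon_len_meanlog = log(130),
                              exon_len_sdlog = 0.5,
                              intron_len_meanlog = log(2000),
                              intron_len_sdlog = 1.2,
                              flank = 300,
                              repeat_length = 300,
                              min_intron_length = repeat_length + 100,
                              background_per_kb = 0.05,
                              inverted_pairs = data.frame(
                                intron_i = c(1, 5), intron_j = c(6, 7),
                                divergence = 0),
                              n_alu_circles = 6,
                              n_skipping_circles = 5,
                              n_random_circles = 10,
                              cell_line = "SIM",
                              seed = 1) {
  stopifnot(n_exons >= 2, repeat_length > 0, flank >= 0,
            n_alu_circles >= 0, n_skipping_circles >= 0,
            n_random_circles >= 0, background_per_kb >= 0)
  if (nrow(inverted_pairs) > 0) {
    stopifnot(all(c("intron_i", "intron_j") %in% names(inverted_pairs)))
    if (!"divergence" %in% names(inverted_pairs)) inverted_pairs$divergence <- 0
    stopifnot(all(inverted_pairs$divergence >= 0 & inverted_pairs$divergence <= 1),
              all(inverted_pairs$intron_i != inverted_pairs$intron_j),
              all(inverted_pairs$intron_i >= 1),
              all(inverted_pairs$intron_j <= n_exons - 1))
  }
  structure(
    list(n_exons = n_exons, exon_len_meanlog = exon_len_meanlog,
         exon_len_sdlog = exon_len_sdlog,
         intron_len_meanlog = intron_len_meanlog,
         intron_len_sdlog = intron_len_sdlog, flank = flank,
         repeat_length = repeat_length,
         min_intron_length = min_intron_length,
         background_per_kb = background_per_kb,
         inverted_pairs = inverted_pairs,
         n_alu_circles = n_alu_circles,
         n_skipping_circles = n_skipping_circles,
         n_random_circles = n_random_circles,
         cell_line = cell_line, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

.random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                 collapse = "")

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.mutate_dna <- function(s, divergence) {
  v <- strsplit(s, "", fixed = TRUE)[[1]]
  k <- round(divergence * length(v))
  if (k > 0) {
    pos <- sample.int(length(v), k)
    v[pos] <- sample(c("A", "C", "G", "T"), k, TRUE)
  }
  paste(v, collapse = "")
}

# non-overlapping placement of a width-w window inside [0, len)
.place_window <- function(len, w, occupied, tries = 200) {
  if (w > len) return(NA_real_)
  for (t in seq_len(tries)) {
    s <- floor(runif(1, 0, len - w + 1))
    ok <- !any(s < occupied$end & (s + w) > occupied$start)
    if (ok) return(s)
  }
  NA_real_
}

#' Simulate a locus with planted repeats
#'
#' Lays out exons and introns left to right on a synthetic chromosome,
#' draws a random genome sequence, places unrelated background repeats in
#' introns (Poisson per intron, rate proportional to length), and plants
#' the configured inverted pairs by writing a random repeat sequence into
#' intron `i` and its (optionally diverged) reverse complement into
#' intron `j`. Every placement is recorded with ground-truth labels.
#'
#' @param config a [simulation_config()].
#' @return An object of class `sim_locus`: list with `model` (a
#'   [gene_model()]), `genome` (named [Biostrings::DNAStringSet]),
#'   `repeats` (data.frame in [read_repeats()] layout, plus a `role`
#'   column: `background`, `inverted_a`, `inverted_b`), `truth`
#'   (planted-pair table and the config).
#' @export
simulate_locus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_exons
  exon_len <- pmax(20, round(rlnorm(n, config$exon_len_meanlog,
                                    config$exon_len_sdlog)))
  intron_len <- pmax(config$min_intron_length,
                     round(rlnorm(n - 1, config$intron_len_meanlog,
                                  config$intron_len_sdlog)))
  starts <- numeric(n); ends <- numeric(n)
  pos <- config$flank
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i]
    pos <- ends[i] + if (i < n) intron_len[i] else config$flank
  }
  total <- pos
  chrom <- "chrSim"
  model <- gene_model(data.frame(label = as.character(seq_len(n)),
                                 start = starts, end = ends),
                      gene_id = "SIMGENE", chrom = chrom, strand = "+")
  genome_chars <- sample(c("A", "C", "G", "T"), total, TRUE)

  w <- config$repeat_length
  reps <- data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), strand = character(0),
                     name = character(0), class = character(0),
                     family = character(0), role = character(0),
                     pair_id = integer(0))
  occupied <- lapply(seq_len(n - 1), function(i)
    data.frame(start = numeric(0), end = numeric(0)))

  add_rep <- function(intron, offset, strand, name, role, pair_id) {
    i_start <- model$introns$start[intron] + offset
    reps <<- rbind(reps, data.frame(
      chrom = chrom, start = i_start, end = i_start + w, strand = strand,
      name = name, class = "SINE", family = "Alu", role = role,
      pair_id = pair_id))
    occupied[[intron]] <<- rbind(occupied[[intron]],
                                 data.frame(start = offset, end = offset + w))
    i_start
  }

  # planted inverted pairs
  planted <- config$inverted_pairs
  truth_pairs <- data.frame(pair_id = integer(0), intron_i = integer(0),
                            intron_j = integer(0), divergence = numeric(0),
                            rep_a = character(0), rep_b = character(0))
  if (nrow(planted) > 0) {
    for (p in seq_len(nrow(planted))) {
      ii <- planted$intron_i[p]; jj <- planted$intron_j[p]
      for (intron in c(ii, jj)) {
        if (w > model$introns$length[intron]) {
          stop(sprintf("planted repeat (%d bp) longer than intron %d (%d bp)",
                       w, intron, model$introns$length[intron]))
        }
      }
      off_a <- .place_window(model$introns$length[ii], w, occupied[[ii]])
      off_b <- .place_window(model$introns$length[jj], w, occupied[[jj]])
      if (is.na(off_a) || is.na(off_b)) {
        stop("could not place planted pair ", p, " without overlap")
      }
      seq_a <- .random_dna(w)
      seq_b <- .mutate_dna(.revcomp_chr(seq_a), planted$divergence[p])
      name_a <- sprintf("AluSim_inv%d_a", p)
      name_b <- sprintf("AluSim_inv%d_b", p)
      s_a <- add_rep(ii, off_a, "+", name_a, "inverted_a", p)
      s_b <- add_rep(jj, off_b, "-", name_b, "inverted_b", p)
      genome_chars[(s_a + 1):(s_a + w)] <- strsplit(seq_a, "")[[1]]
      genome_chars[(s_b + 1):(s_b + w)] <- strsplit(seq_b, "")[[1]]
      truth_pairs <- rbind(truth_pairs, data.frame(
        pair_id = p, intron_i = min(ii, jj), intron_j = max(ii, jj),
        divergence = planted$divergence[p], rep_a = name_a, rep_b = name_b))
    }
  }

  # unrelated background repeats: intervals over the random genome sequence
  if (config$background_per_kb > 0) {
    for (i in seq_len(n - 1)) {
      k <- rpois(1, config$background_per_kb * model$introns$length[i] / 1000)
      k <- min(k, floor(model$introns$length[i] / (2 * w)))
      for (b in seq_len(k)) {
        off <- .place_window(model$introns$length[i], w, occupied[[i]])
        if (is.na(off)) break
        add_rep(i, off, sample(c("+", "-"), 1),
                sprintf("AluSim_bg_i%d_%d", i, b), "background", NA_integer_)
      }
    }
  }

  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(genome_chars, collapse = ""), chrom))
  rownames(reps) <- NULL
  structure(
    list(model = model, genome = genome, repeats = reps,
         truth = list(planted_pairs = truth_pairs, config = config)),
    class = "sim_locus"
  )
}

#' Simulate a circle catalogue with known biogenesis mechanisms
#'
#' Generates a catalogue of circular isoforms on a simulated locus, each
#' labelled with the mechanism that produced it: `alu` circles are
#' contiguous exon runs bracketed by planted inverted pairs (their
#' junctions are exactly the junctions [predict_junctions()] derives from
#' the planted pairs); `skipping` circles equal the candidate exon set of
#' a generated skipped-exon event; `random` circles are exon subsets
#' whose junctions avoid every planted-pair junction and whose exon sets
#' differ from every skipping candidate.
#'
#' @param config a [simulation_config()].
#' @param locus a `sim_locus` from [simulate_locus()] (built from
#'   `config` if omitted).
#' @return List with `catalogue` (a `circ_catalogue` with an extra
#'   `mechanism` column), `se_events` (data.frame as from
#'   [read_se_events()]), and `truth` (planted junctions and per-circle
#'   mechanisms).
#' @export
simulate_catalogue <- function(config, locus = simulate_locus(config)) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(locus, "sim_locus"))
  set.seed(config$seed + 1L)
  model <- locus$model
  n <- config$n_exons
  planted <- locus$truth$planted_pairs
  if (config$n_alu_circles > 0 && nrow(planted) == 0) {
    stop("alu-driven circles requested but no inverted pairs are planted")
  }
  predicted <- if (nrow(planted) > 0) {
    predict_junctions(planted, model)
  } else {
    data.frame(donor = character(0), acceptor = character(0))
  }
  pred_keys <- paste(predicted$donor, predicted$acceptor, sep = ">")
  alu_runs <- lapply(seq_len(nrow(planted)), function(p)
    as.character(seq.int(planted$intron_i[p] + 1L, planted$intron_j[p])))

  rows <- list()
  add_circle <- function(run_labels, mechanism) {
    cycle <- run_labels
    donor <- cycle[length(cycle)]; acceptor <- cycle[1]
    rows[[length(rows) + 1L]] <<- data.frame(
      cell_line = config$cell_line, primer_row = mechanism,
      raw_path = paste(c(cycle, cycle[1]), collapse = "-"),
      cycle = paste(cycle, collapse = "-"), donor = donor,
      acceptor = acceptor, key = iso_key(cycle, donor, acceptor),
      note = "", mechanism = mechanism, stringsAsFactors = FALSE)
  }

  if (config$n_alu_circles > 0) {
    take <- rep(seq_len(nrow(planted)),
                length.out = config$n_alu_circles)
    for (p in take) add_circle(alu_runs[[p]], "alu")
  }

  # skipping events and their compatible circles
  se_events <- NULL
  if (config$n_skipping_circles > 0) {
    if (n < 4) stop("need at least 4 exons to generate skipping events")
    chosen <- list()
    guard <- 0
    while (length(chosen) < config$n_skipping_circles) {
      guard <- guard + 1
      if (guard > 5000) stop("could not generate enough distinct skipping events")
      a <- sample.int(n - 2, 1)                      # upstream flank
      b <- sample.int(n - a - 1, 1) + a + 1          # downstream flank, >= a+2
      run <- as.character(seq.int(a + 1L, b - 1L))
      if (any(vapply(alu_runs, function(r) setequal(r, run), logical(1)))) next
      if (any(vapply(chosen, function(r) setequal(r$run, run), logical(1)))) next
      s <- run[ceiling(length(run) / 2)]
      si <- match(s, model$exons$label)
      chosen[[length(chosen) + 1L]] <- list(
        run = run,
        event = data.frame(
          gene = model$gene_id, chrom = model$chrom,
          e1_end = model$exons$end[match(as.character(a), model$exons$label)],
          e2_start = model$exons$start[si], e2_end = model$exons$end[si],
          e3_start = model$exons$start[match(as.character(b), model$exons$label)],
          strand = model$strand, stringsAsFactors = FALSE))
    }
    se_events <- do.call(rbind, lapply(chosen, `[[`, "event"))
    se_events$event_id <- vapply(seq_len(nrow(se_events)), function(i)
      format_se_event(se_events[i, ]), "")
    se_events <- se_events[, c("event_id", "gene", "chrom", "e1_end",
                               "e2_start", "e2_end", "e3_start", "strand")]
    for (ch in chosen) add_circle(ch$run, "skipping")
  }

  if (config$n_random_circles > 0) {
    skip_runs <- if (is.null(se_events)) list() else
      lapply(seq_len(nrow(se_events)), function(i)
        potential_circ_exons(se_events[i, ], model))
    made <- 0; guard <- 0
    while (made < config$n_random_circles) {
      guard <- guard + 1
      if (guard > 20000) stop("could not generate enough random circles")
      m <- sample(2:min(6, n), 1)
      subset <- sort(sample.int(n, m))
      labels <- as.character(subset)
      jx <- paste(labels[length(labels)], labels[1], sep = ">")
      if (jx %in% pred_keys) next
      if (any(vapply(alu_runs, function(r) setequal(r, labels), logical(1)))) next
      if (any(vapply(skip_runs, function(r) setequal(r, labels), logical(1)))) next
      add_circle(labels, "random")
      made <- made + 1
    }
  }

  catalogue <- as_catalogue(do.call(rbind, rows))
  list(catalogue = catalogue, se_events = se_events,
       truth = list(planted_junctions = predicted,
                    mechanisms = catalogue$mechanism,
                    planted_pairs = planted))
}

#' Write a simulated dataset to a directory
#'
#' Emits the full synthetic fixture set: `genome.fa`, `locus.gtf`,
#' `repeats_rmsk.tsv`, `catalogue.tsv`, `se_events.txt` and
#' `ground_truth.json`. All files re-parse losslessly through the
#' package's own readers; the seed is recorded in the ground-truth file.
#'
#' @param locus a `sim_locus`.
#' @param circles output of [simulate_catalogue()] (optional; omit to
#'   write only the locus files).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(locus, circles = NULL, dir) {
  stopifnot(inherits(locus, "sim_locus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(locus$genome, file.path(dir, "genome.fa"))
  write_gene_model_gtf(locus$model, file.path(dir, "locus.gtf"))
  write_repeats_rmsk(locus$repeats, file.path(dir, "repeats_rmsk.tsv"))
  truth <- list(seed = locus$truth$config$seed,
                planted_pairs = locus$truth$planted_pairs)
  if (!is.null(circles)) {
    cat_out <- data.frame(
      cell_line = circles$catalogue$cell_line,
      primer_row = circles$catalogue$primer_row,
      isoform_path = circles$catalogue$raw_path,
      junction = paste(circles$catalogue$donor, circles$catalogue$acceptor,
                       sep = "-"),
      mechanism = circles$catalogue$mechanism)
    utils::write.table(cat_out, file.path(dir, "catalogue.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(circles$se_events)) {
      writeLines(circles$se_events$event_id, file.path(dir, "se_events.txt"))
    }
    truth$mechanisms <- circles$truth$mechanisms
    truth$planted_junctions <- circles$truth$planted_junctions
  }
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
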