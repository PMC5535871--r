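#' Parse a skipped-exon (SE) event identifier
#'
#' Parses the SUPPA `generateEvents` ioe-style identifier dialect
#' `GENE;SE:chrom:a-b:c-d:strand`, where `a` is the end of the upstream
#' flanking exon, `b`-`c` are the bounds of the skipped exon and `d` is
#' the start of the downstream flanking exon. Coordinates are kept as
#' printed and interpreted on the package's 0-based half-open convention,
#' i.e. the skipped exon occupies `[b, c)`.
#'
#' @param text one SE identifier string.
#' @return Data.frame row with columns `event_id`, `gene`, `chrom`,
#'   `e1_end`, `e2_start`, `e2_end`, `e3_start`, `strand`.
#' @examples
#' parse_se_event("CDKN2B-AS1;SE:chr9:22029593-22032673:22032985-22046316:+")
#' @export
parse_se_event <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  m <- regmatches(text, regexec(
    "^([^;]+);SE:([^:]+):([0-9]+)-([0-9]+):([0-9]+)-([0-9]+):([+-])$",
    text))[[1]]
  if (length(m) == 0) {
    stop("malformed SE event (expected GENE;SE:chrom:a-b:c-d:strand): ", text)
  }
  co <- as.numeric(m[4:7])
  names(co) <- c("e1_end", "e2_start", "e2_end", "e3_start")
  if (!(co["e1_end"] < co["e2_start"])) {
    stop("SE event coordinate order violated: e1_end (", co["e1_end"],
         ") must precede e2_start (", co["e2_start"], ")")
  }
  if (!(co["e2_start"] < co["e2_end"])) {
    stop("SE event coordinate order violated: skipped exon bounds ",
         co["e2_start"], "-", co["e2_end"])
  }
  if (!(co["e2_end"] < co["e3_start"])) {
    stop("SE event coordinate order violated: e2_end (", co["e2_end"],
         ") must precede e3_start (", co["e3_start"], ")")
  }
  data.frame(event_id = text, gene = m[2], chrom = m[3],
             e1_end = co[["e1_end"]], e2_start = co[["e2_start"]],
             e2_end = co[["e2_end"]], e3_start = co[["e3_start"]],
             strand = m[8], stringsAsFactors = FALSE)
}

#' Format a skipped-exon event back to its identifier string
#'
#' Inverse of [parse_se_event()]; a parse/format round trip is the
#' identity on well-formed identifiers.
#'
#' @param event one-row data.frame as returned by [parse_se_event()].
#' @return The identifier string.
#' @export
format_se_event <- function(event) {
  sprintf("%s;SE:%s:%s-%s:%s-%s:%s", event$gene, event$chrom,
          format(event$e1_end, scientific = FALSE),
          format(event$e2_start, scientific = FALSE),
          format(event$e2_end, scientific = FALSE),
          format(event$e3_start, scientific = FALSE), event$strand)
}

#' Read skipped-exon events from a text file
#'
#' One SE identifier per line; lines starting with `#` and blank lines
#' are ignored.
#'
#' @param path events file.
#' @return Data.frame with one row per event (see [parse_se_event()]).
#' @export
read_se_events <- function(path) {
  if (!file.exists(path)) stop("events file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no SE events in file: ", path)
  do.call(rbind, lapply(seq_along(lines), function(i) {
    tryCatch(parse_se_event(lines[i]),
             error = function(e) stop("events line ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }))
}

#' Exons a skipping event could circularize
#'
#' A skipped-exon event with flanking splice sites `e1_end` and `e3_start`
#' could, via the excised lariat, give rise to a circle containing every
#' canonical exon of the gene model positioned strictly within the open
#' interval `(e1_end, e3_start)`. Because exons are ordered and
#' non-overlapping this is always a contiguous run of exon labels, and
#' enlarging the interval never removes exons.
#'
#' @param event one-row data.frame from [parse_se_event()].
#' @param model a [gene_model()] on the event's chromosome.
#' @return Character vector of canonical exon labels in gene order
#'   (possibly empty when the flanking exons are adjacent).
#' @examples
#' ev <- parse_se_event(
#'   "CDKN2B-AS1;SE:chr9:22029593-22032673:22032985-22046316:+")
#' potential_circ_exons(ev, anril_model())
#' @export
potential_circ_exons <- function(event, model) {
  stopifnot(inherits(model, "gene_model"))
  if (!is.na(model$chrom) && event$chrom != model$chrom) {
    stop("event chromosome ", event$chrom, " does not match model chromosome ",
         model$chrom)
  }
  can <- model$exons[is_canonical_label(model$exons$label), , drop = FALSE]
  can <- can[order(as.numeric(can$label)), , drop = FALSE]
  inside <- can$start >= event$e1_end & can$end <= event$e3_start
  can$label[inside]
}

#' Match skipping-derived circle candidates against an observed catalogue
#'
#' A candidate exon set completely matches an observed circular isoform
#' when the isoform's cycle contains exactly the candidate exons (set
#' equality on labels; rotation-invariant by construction). Since a
#' skipping-derived circle of exons `a..b` forces the junction `(b, a)`,
#' the junction comparison is redundant given set equality but is reported
#' alongside for inspection.
#'
#' @param events data.frame of SE events from [read_se_events()].
#' @param cat a `circ_catalogue`.
#' @param model a [gene_model()].
#' @return List with `matches` (data.frame: `event_id`, `cell_line`,
#'   `cycle`, `candidate`, `junction_consistent`) and `candidates`
#'   (data.frame: `event_id`, `candidate` as hyphen-joined labels).
#' @export
match_skipping_to_catalogue <- function(events, cat, model) {
  stopifnot(is.data.frame(events), is.data.frame(cat),
            inherits(model, "gene_model"))
  cat <- dedup_catalogue(cat, within = "cell_line")
  cand <- lapply(seq_len(nrow(events)), function(i)
    potential_circ_exons(events[i, ], model))
  candidates <- data.frame(
    event_id = events$event_id,
    candidate = vapply(cand, paste, "", collapse = "-"),
    stringsAsFactors = FALSE)
  cycles <- strsplit(cat$cycle, "-", fixed = TRUE)
  matches <- data.frame(event_id = character(0), cell_line = character(0),
                        cycle = character(0), candidate = character(0),
                        junction_consistent = logical(0))
  for (i in seq_along(cand)) {
    if (length(cand[[i]]) == 0) next
    for (k in seq_along(cycles)) {
      if (setequal(cycles[[k]], cand[[i]])) {
        run <- cand[[i]]
        matches <- rbind(matches, data.frame(
          event_id = events$event_id[i], cell_line = cat$cell_line[k],
          cycle = cat$cycle[k], candidate = candidates$candidate[i],
          junction_consistent = cat$donor[k] == run[length(run)] &&
            cat$acceptor[k] == run[1]))
      }
    }
  }
  rownames(matches) <- NULL
  list(matches = matches, candidates = candidates)
}

#' Bundled skipped-exon events for the ANRIL locus
#'
#' The RefSeq-derived skipped-exon events at the CDKN2B-AS1 locus, as
#' published (SUPPA ioe-style identifiers). Two printed events share one
#' candidate exon set; both are kept as separate events.
#'
#' @return Data.frame of parsed events.
#' @export
fixture_se_events <- function() {
  read_se_events(system.file("extdata", "table2_events.txt",
                             package = "backsplice", mustWork = TRUE))
}
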