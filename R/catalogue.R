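#' Parse a circular-isoform exon path
#'
#' Parses one circular isoform written as a hyphen-joined exon path whose
#' first and last labels coincide (the wrap point), optionally followed by
#' a parenthesised back-splice junction, e.g. `"4-5-6-9-10-4 (10-4)"`.
#' Novel-exon labels may be written `"4N1"` or `"4(N1)"`; the latter is
#' normalised to the former.
#'
#' The derived junction of a raw path is `(donor = second-to-last label,
#' acceptor = first label)`. When a bracketed junction is present it is
#' authoritative: if it disagrees with the derived junction the cycle is
#' rotated so that the bracketed acceptor leads and the bracketed donor
#' trails, and the discrepancy is recorded in the isoform's `note` field.
#' If the bracketed acceptor is absent from the cycle but the donor is
#' present, the cycle is rotated to end at that donor; if neither label is
#' usable the bracket is ignored. Both bracket orders occurring in the
#' literature are supported via `junction_order`.
#'
#' @param text isoform path string.
#' @param cell_line optional cell line the isoform was observed in.
#' @param junction optional junction string (e.g. `"10-4"`) overriding a
#'   bracket inside `text`.
#' @param junction_order order of the two labels in junction strings:
#'   `"donor_acceptor"` (default, the bracket dialect) or
#'   `"acceptor_donor"` (the prose dialect).
#' @return An object of class `circ_isoform`: list with `cell_line`,
#'   `raw_path` (character vector as written), `cycle` (labels in circle
#'   order, acceptor first, donor last), `donor`, `acceptor`, `note`.
#' @examples
#' iso <- parse_isoform_path("4-5-6-9-10-4 (10-4)", "NZM7")
#' iso$cycle
#' iso$donor; iso$acceptor
#' @export
parse_isoform_path <- function(text, cell_line = NA_character_,
                               junction = NULL,
                               junction_order = c("donor_acceptor",
                                                  "acceptor_donor")) {
  junction_order <- match.arg(junction_order)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  m <- regmatches(text, regexec("^(\\S.*?)(?:\\s+\\(([^()]+)\\))?$",
                                text, perl = TRUE))[[1]]
  if (length(m) == 0 || !nzchar(m[2])) stop("malformed isoform string: ", text)
  path_part <- m[2]
  bracket <- if (nzchar(m[3])) m[3] else NULL
  if (!is.null(junction)) bracket <- junction

  raw <- normalize_exon_label(trimws(strsplit(path_part, "-(?![0-9]*\\))",
                                              perl = TRUE)[[1]]))
  raw <- raw[nzchar(raw)]
  if (length(raw) < 2) stop("circle path needs at least two labels: ", text)
  ok <- grepl("^[0-9]+$|^[0-9]+[ab]$|^[0-9]+N[0-9]+$", raw)
  if (!all(ok)) {
    stop("unknown exon label(s) in isoform path: ",
         paste(unique(raw[!ok]), collapse = ", "))
  }
  if (raw[1] != raw[length(raw)]) {
    stop("malformed circle: first label (", raw[1],
         ") differs from last (", raw[length(raw)], ")")
  }
  cycle <- raw[-length(raw)]
  if (anyDuplicated(cycle)) {
    stop("cycle repeats exon label(s): ",
         paste(unique(cycle[duplicated(cycle)]), collapse = ", "))
  }
  donor <- raw[length(raw) - 1L]
  acceptor <- raw[1]
  note <- character(0)

  if (!is.null(bracket)) {
    jl <- normalize_exon_label(trimws(strsplit(bracket, "-(?![0-9]*\\))",
                                               perl = TRUE)[[1]]))
    if (length(jl) != 2) stop("malformed junction annotation: ", bracket)
    if (junction_order == "donor_acceptor") {
      bd <- jl[1]; ba <- jl[2]
    } else {
      bd <- jl[2]; ba <- jl[1]
    }
    if (!(bd == donor && ba == acceptor)) {
      succ <- function(lab) cycle[(match(lab, cycle) %% length(cycle)) + 1L]
      if (bd %in% cycle && ba %in% cycle && identical(succ(bd), ba)) {
        note <- c(note, sprintf(
          "bracketed junction (%s-%s) disagrees with path wrap (%s-%s); cycle rotated to bracket",
          bd, ba, donor, acceptor))
        donor <- bd; acceptor <- ba
      } else if (bd %in% cycle) {
        note <- c(note, sprintf(
          "bracketed acceptor %s not usable; rotated cycle to bracketed donor %s",
          ba, bd))
        donor <- bd; acceptor <- succ(bd)
      } else {
        note <- c(note, sprintf(
          "bracketed junction (%s-%s) not resolvable on cycle; derived junction kept",
          bd, ba))
      }
    }
  }
  canonicalize(structure(
    list(cell_line = cell_line, raw_path = raw, cycle = cycle,
         donor = donor, acceptor = acceptor, note = note),
    class = "circ_isoform"
  ))
}

#' Canonical rotation of a circular isoform
#'
#' Rotates the exon cycle of a `circ_isoform` so that the back-splice
#' acceptor exon leads and the donor exon trails. Canonicalization is
#' idempotent, and every rotation of the same circle with the same junction
#' canonicalizes to the same representative, so isoform equality reduces to
#' equality of `(cycle, donor, acceptor)`.
#'
#' @param iso a `circ_isoform`.
#' @return The same isoform with `cycle` in canonical rotation.
#' @export
canonicalize <- function(iso) {
  stopifnot(inherits(iso, "circ_isoform"))
  i <- match(iso$acceptor, iso$cycle)
  if (is.na(i)) stop("acceptor label ", iso$acceptor, " not in cycle")
  n <- length(iso$cycle)
  iso$cycle <- iso$cycle[((seq_len(n) + i - 2L) %% n) + 1L]
  if (iso$cycle[n] != iso$donor && n > 1L) {
    # junction labels must be cyclically adjacent
    stop("donor ", iso$donor, " does not precede acceptor ", iso$acceptor,
         " on the cycle")
  }
  iso
}

#' @export
print.circ_isoform <- function(x, ...) {
  cat(sprintf("<circ_isoform> [%s] junction (%s-%s)%s\n",
              paste(x$cycle, collapse = "-"), x$donor, x$acceptor,
              if (is.na(x$cell_line)) "" else paste0(" in ", x$cell_line)))
  invisible(x)
}

#' Back-splice junction derived from a raw circle path
#'
#' For a raw path whose first and last labels coincide, the derived
#' junction is `(donor = second-to-last label, acceptor = first label)`.
#' This is the junction implied by the wrap point as written; when the
#' written rotation does not start at the acceptor the authoritative
#' bracketed junction should be supplied to [parse_isoform_path()] instead.
#'
#' @param raw_path character vector of exon labels, first equal to last.
#' @return named character vector `c(donor =, acceptor =)`.
#' @examples
#' derive_junction(c("4", "5", "6", "7", "4"))
#' @export
derive_junction <- function(raw_path) {
  raw_path <- as.character(raw_path)
  if (length(raw_path) < 2) stop("circle path needs at least two labels")
  if (raw_path[1] != raw_path[length(raw_path)]) {
    stop("malformed circle: first and last labels differ")
  }
  c(donor = raw_path[length(raw_path) - 1L], acceptor = raw_path[1])
}

iso_key <- function(cycle, donor, acceptor) {
  paste0(paste(cycle, collapse = "-"), "|", donor, ">", acceptor)
}

#' Read a circular-isoform catalogue from TSV
#'
#' Expects a tab-separated file with header columns `cell_line` and
#' `isoform_path`, plus optional `primer_row` (the detection route) and
#' `junction` (authoritative back-splice junction, donor-acceptor order).
#' Lines starting with `#` are ignored. Each row is parsed with
#' [parse_isoform_path()] and canonicalized; duplicate rows are retained
#' (use [dedup_catalogue()] to collapse repeated detections).
#'
#' @param path TSV file.
#' @return A `circ_catalogue`: data.frame with columns `cell_line`,
#'   `primer_row`, `raw_path`, `cycle` (canonical cycle, hyphen-joined),
#'   `donor`, `acceptor`, `key`, `note`.
#' @export
read_catalogue <- function(path) {
  if (!file.exists(path)) stop("catalogue file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          quote = "", fill = TRUE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("catalogue file is empty: ", path)
  need <- c("cell_line", "isoform_path")
  if (!all(need %in% names(df))) {
    stop("catalogue must have columns: ", paste(need, collapse = ", "))
  }
  if (!"primer_row" %in% names(df)) df$primer_row <- NA_character_
  if (!"junction" %in% names(df)) df$junction <- NA_character_
  rows <- lapply(seq_len(nrow(df)), function(i) {
    jx <- df$junction[i]
    iso <- tryCatch(
      parse_isoform_path(df$isoform_path[i], cell_line = df$cell_line[i],
                         junction = if (is.na(jx) || !nzchar(jx)) NULL else jx),
      error = function(e) stop("catalogue line ", i, ": ", conditionMessage(e),
                               call. = FALSE)
    )
    data.frame(cell_line = df$cell_line[i], primer_row = df$primer_row[i],
               raw_path = paste(iso$raw_path, collapse = "-"),
               cycle = paste(iso$cycle, collapse = "-"),
               donor = iso$donor, acceptor = iso$acceptor,
               key = iso_key(iso$cycle, iso$donor, iso$acceptor),
               note = paste(iso$note, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("circ_catalogue", "data.frame")
  out
}

as_catalogue <- function(df) {
  class(df) <- c("circ_catalogue", "data.frame")
  df
}

#' Collapse repeated detections of the same circle
#'
#' Two catalogue entries are the same isoform when their canonical cycles
#' and junctions coincide; entries found via different primer rows are
#' detection routes, not distinct molecules. Deduplication is a fixpoint:
#' applying it twice changes nothing.
#'
#' @param cat a `circ_catalogue`.
#' @param within `"cell_line"` (default) collapses duplicates within each
#'   cell line but keeps the same circle seen in two lines as two rows;
#'   `"global"` keeps a single row per distinct isoform overall.
#' @return A deduplicated `circ_catalogue`.
#' @export
dedup_catalogue <- function(cat, within = c("cell_line", "global")) {
  within <- match.arg(within)
  stopifnot(is.data.frame(cat))
  id <- if (within == "cell_line") paste(cat$cell_line, cat$key) else cat$key
  as_catalogue(cat[!duplicated(id), , drop = FALSE])
}

#' Isoforms common to two cell lines
#'
#' Intersects the canonical isoform sets of two cell lines. Equality is
#' canonical-cycle plus junction equality, so the same circle written from
#' different primer-row rotations matches. Results are ordered by acceptor
#' ordinal, then donor ordinal.
#'
#' @param cat a `circ_catalogue` covering both lines.
#' @param lines character vector of two cell-line names; defaults to the
#'   first two lines present.
#' @return Data.frame of shared isoforms (`cycle`, `donor`, `acceptor`).
#' @export
common_isoforms <- function(cat, lines = NULL) {
  stopifnot(is.data.frame(cat))
  if (is.null(lines)) lines <- unique(cat$cell_line)[1:2]
  stopifnot(length(lines) == 2)
  cat <- dedup_catalogue(cat, within = "cell_line")
  a <- cat[cat$cell_line == lines[1], , drop = FALSE]
  b <- cat[cat$cell_line == lines[2], , drop = FALSE]
  shared <- a[a$key %in% b$key, c("cycle", "donor", "acceptor", "key"),
              drop = FALSE]
  ord <- order(exon_ordinal(shared$acceptor), exon_ordinal(shared$donor))
  shared <- shared[ord, , drop = FALSE]
  rownames(shared) <- NULL
  shared
}

#' Relative exon abundance across a catalogue
#'
#' Counts, per cell line, how many distinct isoforms contain each exon
#' label, and scales counts to relative abundances by dividing by the
#' per-cell-line maximum, so the most frequently included exon scores 1.
#'
#' @param cat a `circ_catalogue` (deduplicated internally per cell line).
#' @param exons optional character vector of exon labels to report (e.g.
#'   all canonical exons of a model); defaults to the labels observed.
#' @return Data.frame with columns `cell_line`, `exon`, `count`,
#'   `relative`.
#' @export
exon_abundance <- function(cat, exons = NULL) {
  stopifnot(is.data.frame(cat))
  if (nrow(cat) == 0) stop("empty catalogue")
  cat <- dedup_catalogue(cat, within = "cell_line")
  cycles <- strsplit(cat$cycle, "-(?![0-9]*\\))", perl = TRUE)
  if (is.null(exons)) {
    exons <- unique(unlist(cycles))
    exons <- exons[order(exon_ordinal(exons))]
  }
  out <- lapply(unique(cat$cell_line), function(cl) {
    sel <- cat$cell_line == cl
    counts <- vapply(exons, function(e)
      sum(vapply(cycles[sel], function(cy) e %in% cy, logical(1))), numeric(1))
    data.frame(cell_line = cl, exon = exons, count = counts,
               relative = if (max(counts) > 0) counts / max(counts) else counts,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Introns contained in the unspliced precursor of a circle
#'
#' The precursor of a circular isoform spans the genomic segment from its
#' acceptor-side-most exon through its donor-side-most exon; every intron
#' in that span is present in the pre-spliced RNA. With exon ordinals
#' `o`, the result is `{ i : floor(min o) <= i < ceil(max o) }` -- novel
#' exons with fractional ordinals round outwards to the flanking canonical
#' introns.
#'
#' @param iso a `circ_isoform`, or a character vector of cycle labels.
#' @param model a [gene_model()] used to bound intron indices.
#' @return Integer vector of intron indices (possibly empty for a
#'   single-exon circle).
#' @examples
#' m <- anril_model()
#' pre_spliced_introns(parse_isoform_path("4-5-6-7-4 (7-4)"), m)
#' @export
pre_spliced_introns <- function(iso, model) {
  stopifnot(inherits(model, "gene_model"))
  labels <- if (inherits(iso, "circ_isoform")) iso$cycle else as.character(iso)
  ords <- exon_ordinal(labels)
  if (anyNA(ords)) {
    stop("unknown exon label(s): ", paste(labels[is.na(ords)], collapse = ", "))
  }
  known <- c(model$exons$label)
  strange <- setdiff(labels[is_canonical_label(labels)], known)
  if (length(strange)) {
    stop("exon label(s) not in model: ", paste(strange, collapse = ", "))
  }
  lo <- floor(min(ords)); hi <- ceiling(max(ords))
  if (hi - 1 < lo) return(integer(0))
  out <- seq.int(lo, hi - 1L)
  out[out >= 1L & out <= nrow(model$introns)]
}

#' Intron inclusion profile of a catalogue
#'
#' For each intron of the model, counts how many distinct isoforms carry
#' that intron in their unspliced precursor (see
#' [pre_spliced_introns()]), and scales both the counts and the intron
#' lengths into `[0, 1]` by dividing by their respective maxima.
#'
#' @param cat a `circ_catalogue`.
#' @param model a [gene_model()].
#' @param dedup scope of isoform deduplication before counting:
#'   `"cell_line"` (default; one count per distinct circle per cell line,
#'   so the same circle seen independently in two lines contributes two
#'   observations, mirroring the per-cell-line treatment of exon
#'   abundance), `"global"` (one count per distinct circle overall), or
#'   `"none"` (raw detections). Published per-intron totals for this kind
#'   of catalogue depend on the deduplication convention, which sources
#'   rarely state, so it is exposed rather than fixed.
#' @return Data.frame with columns `intron`, `length`, `count`,
#'   `scaled_count`, `scaled_length`.
#' @export
intron_inclusion <- function(cat, model,
                             dedup = c("cell_line", "global", "none")) {
  dedup <- match.arg(dedup)
  stopifnot(is.data.frame(cat), inherits(model, "gene_model"))
  if (dedup != "none") cat <- dedup_catalogue(cat, within = dedup)
  cycles <- strsplit(cat$cycle, "-(?![0-9]*\\))", perl = TRUE)
  idx <- model$introns$index
  counts <- integer(length(idx))
  for (cy in cycles) {
    inc <- pre_spliced_introns(cy, model)
    counts[match(inc, idx)] <- counts[match(inc, idx)] + 1L
  }
  data.frame(
    intron = idx,
    length = model$introns$length,
    count = counts,
    scaled_count = if (max(counts) > 0) counts / max(counts) else counts,
    scaled_length = model$introns$length / max(model$introns$length)
  )
}

#' Tally distinct back-splice junctions
#'
#' Counts, per cell line, how many distinct isoforms use each back-splice
#' junction `(donor, acceptor)`.
#'
#' @param cat a `circ_catalogue`.
#' @return Data.frame with columns `donor`, `acceptor`, `cell_line`, `n`,
#'   ordered by acceptor then donor ordinal. Zero rows for an empty
#'   catalogue.
#' @export
junction_tally <- function(cat) {
  stopifnot(is.data.frame(cat))
  if (nrow(cat) == 0) {
    return(data.frame(donor = character(0), acceptor = character(0),
                      cell_line = character(0), n = integer(0)))
  }
  cat <- dedup_catalogue(cat, within = "cell_line")
  agg <- stats::aggregate(list(n = cat$key),
                          by = list(donor = cat$donor, acceptor = cat$acceptor,
                                    cell_line = cat$cell_line),
                          FUN = length)
  ord <- order(exon_ordinal(agg$acceptor), exon_ordinal(agg$donor),
               agg$cell_line)
  agg <- agg[ord, c("donor", "acceptor", "cell_line", "n"), drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Junctions observed in every cell line of a catalogue
#'
#' @param cat a `circ_catalogue` with two or more cell lines.
#' @return Data.frame of junctions (`donor`, `acceptor`) present in all
#'   cell lines.
#' @export
shared_junctions <- function(cat) {
  tal <- junction_tally(cat)
  if (nrow(tal) == 0) return(tal[, c("donor", "acceptor")])
  n_lines <- length(unique(tal$cell_line))
  jx <- paste(tal$donor, tal$acceptor, sep = ">")
  keep <- names(which(table(jx) == n_lines))
  out <- unique(tal[jx %in% keep, c("donor", "acceptor"), drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Bundled melanoma circANRIL catalogue
#'
#' The circular-isoform catalogue reported for the NZM7 and NZM37
#' patient-derived melanoma cell lines, transcribed verbatim (including
#' repeated detections from different primer rows) from the published
#' per-primer isoform table for this locus.
#'
#' @return A `circ_catalogue` (not deduplicated).
#' @examples
#' cat37 <- fixture_catalogue()
#' table(cat37$cell_line)
#' @export
fixture_catalogue <- function() {
  read_catalogue(system.file("extdata", "table1_catalogue.tsv",
                             package = "backsplice", mustWork = TRUE))
}
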