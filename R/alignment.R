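#' Alignment scoring scheme for inverted-repeat detection
#'
#' Bundles the parameters of the affine-gap global aligner used to decide
#' whether two repeats are (approximate) reverse complements of one another.
#' A gap run of length `L` costs `gap_open + L * gap_extend`: the opening
#' penalty is charged once per run and the extension penalty for every
#' gapped base, including the first. End gaps are penalised.
#'
#' The default substitution and gap penalties are chosen so that two
#' unrelated Alu-length (~300 bp) sequences score far below the default
#' acceptance threshold of -200, while genuine reverse-complement copies
#' score near `match * length`. The threshold itself is deliberately
#' permissive (negative), so that diverged repeat copies still qualify.
#'
#' @param match score added per aligned identical base (> 0).
#' @param mismatch score added per aligned non-identical base (<= 0).
#'   `N` bases always score as mismatches.
#' @param gap_open score added once per gap run (<= 0).
#' @param gap_extend score added per gapped base (<= 0).
#' @param min_score minimum alignment score for a repeat pair to be
#'   accepted as an inverted pair.
#' @return An object of class `alignment_scoring`.
#' @examples
#' alignment_scoring()
#' alignment_scoring(match = 1, mismatch = -1, gap_open = -2,
#'                   gap_extend = -0.5)
#' @export
alignment_scoring <- function(match = 1, mismatch = -2, gap_open = -10,
                              gap_extend = -4, min_score = -200) {
  stopifnot(is.numeric(match), is.numeric(mismatch), is.numeric(gap_open),
            is.numeric(gap_extend), is.numeric(min_score))
  if (match <= 0) stop("`match` must be positive")
  if (mismatch > 0) stop("`mismatch` must be <= 0")
  if (gap_open > 0 || gap_extend > 0) {
    stop("gap penalties must be <= 0")
  }
  structure(
    list(match = match, mismatch = mismatch, gap_open = gap_open,
         gap_extend = gap_extend, min_score = min_score),
    class = "alignment_scoring"
  )
}

#' @export
print.alignment_scoring <- function(x, ...) {
  cat("<alignment_scoring>",
      sprintf("match %+g, mismatch %+g, gap open %+g, gap extend %+g",
              x$match, x$mismatch, x$gap_open, x$gap_extend),
      sprintf("acceptance threshold: score >= %g", x$min_score),
      sep = "\n")
  invisible(x)
}

#' Optimal global alignment score with affine gaps
#'
#' Computes the optimal Needleman-Wunsch/Gotoh global alignment score of two
#' DNA sequences under an affine gap model. Only the score is returned; the
#' use case is thresholding reverse-complement similarity between repeat
#' copies, where the traceback is not needed.
#'
#' @param a,b character scalars or [Biostrings::DNAString] objects over the
#'   alphabet `A,C,G,T,N` (case-insensitive). `N` scores as a mismatch
#'   against every base, including another `N`.
#' @param scoring an [alignment_scoring()] object.
#' @return The optimal global alignment score (a single number).
#' @examples
#' align_global("ACGTACGTAC", "ACGTACGTAC",
#'              alignment_scoring(match = 1, mismatch = -1,
#'                                gap_open = -2, gap_extend = -0.5))
#' @export
align_global <- function(a, b, scoring = alignment_scoring()) {
  stopifnot(inherits(scoring, "alignment_scoring"))
  a <- .as_dna_chr(a)
  b <- .as_dna_chr(b)
  align_affine_cpp(a, b, scoring$match, scoring$mismatch,
                   scoring$gap_open, scoring$gap_extend)
}

.as_dna_chr <- function(x) {
  if (methods::is(x, "DNAString") || methods::is(x, "XString")) {
    x <- as.character(x)
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (nchar(x) == 0L) stop("sequences must be non-empty")
  if (grepl("[^ACGTN]", x)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  x
}
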