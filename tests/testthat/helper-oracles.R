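# Independent oracles and small builders shared across tests.

# Exhaustive affine-gap global alignment: enumerates every alignment path
# (M/X/Y op sequences) and scores gap runs as gap_open + L * gap_extend.
# Independent of the package's dynamic-programming implementation.
bf_align <- function(a, b, sc) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  subst <- function(x, y) {
    if (x == "N" || y == "N") sc$mismatch
    else if (x == y) sc$match else sc$mismatch
  }
  best <- -Inf
  rec <- function(i, j, state, score) {
    if (i > length(av) && j > length(bv)) {
      best <<- max(best, score)
      return(invisible(NULL))
    }
    if (i <= length(av) && j <= length(bv)) {
      rec(i + 1, j + 1, "M", score + subst(av[i], bv[j]))
    }
    if (i <= length(av)) {
      rec(i + 1, j, "X",
          score + sc$gap_extend + if (state == "X") 0 else sc$gap_open)
    }
    if (j <= length(bv)) {
      rec(i, j + 1, "Y",
          score + sc$gap_extend + if (state == "Y") 0 else sc$gap_open)
    }
  }
  rec(1, 1, "S", 0)
  best
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
}

# toy plus-strand model from exon (start, end) pairs
toy_model <- function(...) {
  iv <- list(...)
  gene_model(data.frame(label = as.character(seq_along(iv)),
                        start = vapply(iv, `[`, 0, 1),
                        end = vapply(iv, `[`, 0, 2)),
             gene_id = "toy", chrom = "chrT")
}

# random distinct-label cycle plus all rotations of its raw path
random_cycle <- function(n_labels = 19, k = sample(2:6, 1)) {
  cyc <- as.character(sample.int(n_labels, k))
  list(cycle = cyc, donor = cyc[k], acceptor = cyc[1])
}

rotations_of_cycle <- function(cyc) {
  k <- length(cyc)
  lapply(seq_len(k), function(r) {
    rot <- cyc[((seq_len(k) + r - 2L) %% k) + 1L]
    paste(c(rot, rot[1]), collapse = "-")
  })
}

# brute-force per-base genomic membership: every base in the gene span is
# in exactly one exon or one intron
base_membership <- function(model) {
  span <- range(c(model$exons$start, model$exons$end))
  bases <- seq.int(span[1], span[2] - 1)
  in_exon <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(model$exons))) {
    in_exon <- in_exon | (bases >= model$exons$start[i] &
                          bases < model$exons$end[i])
  }
  in_intron <- rep(FALSE, length(bases))
  for (i in seq_len(nrow(model$introns))) {
    in_intron <- in_intron | (bases >= model$introns$start[i] &
                              bases < model$introns$end[i])
  }
  list(exon = in_exon, intron = in_intron)
}
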