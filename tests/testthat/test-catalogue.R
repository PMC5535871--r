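test_that("isoform paths parse to cycles and junctions as printed", {
  iso <- parse_isoform_path("4-5-6-9-10-4 (10-4)", "NZM7")
  expect_equal(iso$cycle, c("4", "5", "6", "9", "10"))
  expect_equal(c(iso$donor, iso$acceptor), c("10", "4"))

  nov <- parse_isoform_path("6-4(N1)-4(N2)-5-6 (6-4N1)")
  expect_equal(nov$cycle, c("4N1", "4N2", "5", "6"))
  expect_equal(c(nov$donor, nov$acceptor), c("6", "4N1"))

  bare <- parse_isoform_path("2-5-6-2")
  expect_equal(c(bare$donor, bare$acceptor), c("6", "2"))
})

test_that("a bracketed junction overrides the written wrap point", {
  iso <- parse_isoform_path("14-5-6-14 (14-5)")
  expect_equal(c(iso$donor, iso$acceptor), c("14", "5"))
  expect_equal(iso$cycle, c("5", "6", "14"))
  expect_match(iso$note, "rotated")
  # donor-only fallback when the bracketed acceptor is not on the cycle
  odd <- parse_isoform_path("16-6-7-13-14-15-16 (16-4)")
  expect_equal(c(odd$donor, odd$acceptor), c("16", "6"))
  expect_match(odd$note, "not usable")
  # prose order accepted via the flag
  pr <- parse_isoform_path("14-5-6-14", junction = "5-14",
                           junction_order = "acceptor_donor")
  expect_equal(c(pr$donor, pr$acceptor), c("14", "5"))
})

test_that("malformed circles and unknown labels are rejected", {
  expect_error(parse_isoform_path("4-5-6"), "malformed circle")
  expect_error(parse_isoform_path("4-x5-4"), "unknown exon label.*x5")
  expect_error(parse_isoform_path("4"), "at least two")
  expect_error(derive_junction("7"), "at least two")
  expect_equal(derive_junction(c("7", "7")),
               c(donor = "7", acceptor = "7"))
  expect_equal(derive_junction(c("4", "5", "6", "7", "4")),
               c(donor = "7", acceptor = "4"))
})

test_that("canonicalization is idempotent and rotation-invariant", {
  set.seed(101)
  for (trial in 1:50) {
    rc <- random_cycle()
    forms <- vapply(rotations_of_cycle(rc$cycle), function(p) {
      iso <- parse_isoform_path(p, junction = paste0(rc$donor, "-", rc$acceptor))
      paste(paste(iso$cycle, collapse = "-"), iso$donor, iso$acceptor)
    }, "")
    expect_length(unique(forms), 1)
    iso <- parse_isoform_path(rotations_of_cycle(rc$cycle)[[1]],
                              junction = paste0(rc$donor, "-", rc$acceptor))
    expect_identical(canonicalize(iso)[c("cycle", "donor", "acceptor")],
                     iso[c("cycle", "donor", "acceptor")])
  }
})

test_that("deduplication is a fixpoint and never grows the catalogue", {
  cat37 <- fixture_catalogue()
  dd <- dedup_catalogue(cat37)
  expect_lte(nrow(dd), nrow(cat37))
  expect_identical(dedup_catalogue(dd), dd)
  ddg <- dedup_catalogue(cat37, within = "global")
  expect_lte(nrow(ddg), nrow(dd))
})

test_that("cross-line intersection equals brute-force all-pairs comparison", {
  cat37 <- fixture_catalogue()
  shared <- common_isoforms(cat37, c("NZM7", "NZM37"))
  a <- dedup_catalogue(cat37)[dedup_catalogue(cat37)$cell_line == "NZM7", ]
  b <- dedup_catalogue(cat37)[dedup_catalogue(cat37)$cell_line == "NZM37", ]
  brute <- character(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$key[i] == b$key[j]) brute <- c(brute, a$key[i])
    }
  }
  expect_setequal(shared$key, unique(brute))
  # the published shared isoforms are all recovered
  expect_true(all(c("4-5-6-7|7>4", "4-5-6|6>4", "5-6-14|14>5",
                    "4-5-6-7-14|14>4") %in% shared$key))
  # disjoint catalogues intersect empty
  other <- as.data.frame(cat37)
  other$cell_line <- "X"; other$key <- paste0(other$key, "zz")
  two <- rbind(as.data.frame(cat37), other)
  class(two) <- class(cat37)
  expect_equal(nrow(common_isoforms(two, c("NZM7", "X"))), 0)
})

test_that("exon abundance counts match direct iteration and scale to 1", {
  cat37 <- fixture_catalogue()
  ab <- exon_abundance(cat37)
  expect_true(all(ab$relative >= 0 & ab$relative <= 1))
  for (cl in unique(ab$cell_line)) {
    expect_equal(max(ab$relative[ab$cell_line == cl]), 1)
  }
  # counting oracle on NZM37
  dd <- dedup_catalogue(cat37)
  dd <- dd[dd$cell_line == "NZM37", ]
  cyc <- strsplit(dd$cycle, "-", fixed = TRUE)
  for (e in c("4", "5", "14", "9")) {
    expect_equal(ab$count[ab$cell_line == "NZM37" & ab$exon == e],
                 sum(vapply(cyc, function(x) e %in% x, logical(1))))
  }
  # middle exons dominate: 6 is maximal, 5 beats everything else
  n7 <- ab[ab$cell_line == "NZM7", ]
  expect_equal(n7$relative[n7$exon == "6"], 1)
  expect_true(all(n7$relative[n7$exon == "5"] >=
                    n7$relative[!n7$exon %in% c("5", "6")]))
  # single-isoform catalogue
  onecat <- data.frame(cell_line = "Z", primer_row = NA, raw_path = "4-5-6-4",
                       cycle = "4-5-6", donor = "6", acceptor = "4",
                       key = "4-5-6|6>4", note = "")
  class(onecat) <- c("circ_catalogue", "data.frame")
  ab1 <- exon_abundance(onecat, exons = as.character(1:7))
  expect_equal(ab1$relative, c(0, 0, 0, 1, 1, 1, 0))
  expect_error(exon_abundance(onecat[0, ]), "empty")
})

test_that("precursor introns are the ordinal span of the cycle", {
  m <- anril_model()
  expect_equal(pre_spliced_introns(parse_isoform_path("4-5-6-7-4 (7-4)"), m),
               4:6)
  # non-contiguous circles span the whole ordinal range
  expect_equal(pre_spliced_introns(parse_isoform_path("6-10-2-5-6 (10-2)"), m),
               2:9)
  expect_equal(pre_spliced_introns(parse_isoform_path("6-14-5-6 (14-5)"), m),
               5:13)
  # novel fractional ordinals round outwards
  expect_equal(pre_spliced_introns(c("4N1", "4N2", "5", "6"), m), 4:5)
  # single-exon circle has no precursor introns
  expect_equal(pre_spliced_introns(parse_isoform_path("7-7"), m), integer(0))
  expect_error(pre_spliced_introns(c("4", "99"), m), "not in model")
})

test_that("contiguous circle a..b spans exactly introns a..b-1", {
  m <- anril_model()
  set.seed(11)
  for (trial in 1:25) {
    a <- sample.int(17, 1); b <- sample.int(19 - a, 1) + a
    cyc <- as.character(a:b)
    expect_equal(pre_spliced_introns(cyc, m), a:(b - 1))
  }
})

test_that("intron inclusion matches brute force and scales to [0,1]", {
  m <- anril_model()
  cat37 <- fixture_catalogue()
  ii <- intron_inclusion(cat37, m)
  expect_true(all(ii$scaled_count >= 0 & ii$scaled_count <= 1))
  expect_true(all(ii$scaled_length > 0 & ii$scaled_length <= 1))
  expect_equal(max(ii$scaled_count), 1)
  expect_equal(max(ii$scaled_length), 1)
  # brute force over isoform x intron membership
  dd <- dedup_catalogue(cat37, within = "cell_line")
  cyc <- strsplit(dd$cycle, "-", fixed = TRUE)
  brute <- vapply(ii$intron, function(i)
    sum(vapply(cyc, function(x) i %in% pre_spliced_introns(x, m),
               logical(1))), numeric(1))
  expect_equal(ii$count, brute)
  # one-isoform catalogue: introns 4 and 5 only
  one <- data.frame(cell_line = "Z", primer_row = NA, raw_path = "4-5-6-4",
                    cycle = "4-5-6", donor = "6", acceptor = "4",
                    key = "4-5-6|6>4", note = "")
  class(one) <- c("circ_catalogue", "data.frame")
  i1 <- intron_inclusion(one, m)
  expect_equal(i1$count, as.numeric(seq_len(18) %in% 4:5))
  expect_equal(i1$scaled_count[4:5], c(1, 1))
})

test_that("junction tally conserves counts and finds the shared junctions", {
  cat37 <- fixture_catalogue()
  tal <- junction_tally(cat37)
  dd <- dedup_catalogue(cat37)
  expect_equal(sum(tal$n), nrow(dd))
  sj <- shared_junctions(cat37)
  key <- paste(sj$donor, sj$acceptor)
  expect_true(all(c("14 5", "7 4", "10 5", "14 4") %in% key))
  empty <- junction_tally(cat37[0, ])
  expect_equal(nrow(empty), 0)
})
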