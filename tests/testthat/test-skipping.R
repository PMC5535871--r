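test_that("SE identifiers parse field by field and round-trip", {
  ev <- parse_se_event(
    "CDKN2B-AS1;SE:chr9:22029593-22032673:22032985-22046316:+")
  expect_equal(ev$gene, "CDKN2B-AS1")
  expect_equal(ev$chrom, "chr9")
  expect_equal(ev$e1_end, 22029593)
  expect_equal(ev$e2_start, 22032673)
  expect_equal(ev$e2_end, 22032985)
  expect_equal(ev$e3_start, 22046316)
  expect_equal(ev$strand, "+")
  expect_equal(format_se_event(ev), ev$event_id)

  evs <- fixture_se_events()
  expect_equal(nrow(evs), 12)
  for (i in seq_len(nrow(evs))) {
    expect_equal(format_se_event(evs[i, ]), evs$event_id[i])
  }
})

test_that("coordinate-order violations and malformed strings are rejected", {
  expect_error(parse_se_event("G;SE:chr1:500-400:600-700:+"),
               "e1_end")
  expect_error(parse_se_event("G;SE:chr1:100-600:500-700:+"),
               "skipped exon bounds")
  expect_error(parse_se_event("G;SE:chr1:100-200:300-250:+"),
               "e2_end")
  expect_error(parse_se_event("not an event"), "malformed SE event")
  expect_error(parse_se_event("G;SE:chr1:100-200:300-400:."),
               "malformed SE event")
})

test_that("candidate exons are those strictly inside the flanking splice sites", {
  m <- anril_model()
  ev1 <- parse_se_event(
    "CDKN2B-AS1;SE:chr9:22029593-22032673:22032985-22046316:+")
  expect_equal(potential_circ_exons(ev1, m), "3")
  ev8 <- parse_se_event(
    "CDKN2B-AS1;SE:chr9:22056386-22058358:22059053-22061952:+")
  expect_equal(potential_circ_exons(ev8, m), "8")
  # adjacent flanking exons leave nothing in between
  adj <- parse_se_event("toy;SE:chrT:200-220:240-300:+")
  toy <- toy_model(c(100, 200), c(300, 400), c(500, 650))
  adj2 <- data.frame(event_id = "x", gene = "toy", chrom = "chrT",
                     e1_end = 200, e2_start = 210, e2_end = 220,
                     e3_start = 300, strand = "+")
  expect_equal(potential_circ_exons(adj2, toy), character(0))
  wrong <- adj2; wrong$chrom <- "chrZ"
  expect_error(potential_circ_exons(wrong, toy), "chromosome")
})

test_that("candidate sets are contiguous runs and monotone in the interval", {
  m <- anril_model()
  evs <- fixture_se_events()
  for (i in seq_len(nrow(evs))) {
    cand <- as.numeric(potential_circ_exons(evs[i, ], m))
    if (length(cand) > 1) {
      expect_equal(cand, seq(min(cand), max(cand)))
    }
    # widening the window never removes exons
    wide <- evs[i, ]
    wide$e1_end <- wide$e1_end - 5000
    wide$e3_start <- wide$e3_start + 5000
    expect_true(all(cand %in% as.numeric(potential_circ_exons(wide, m))))
  }
})

test_that("catalogue matching is exact set equality, verified by brute force", {
  m <- anril_model()
  evs <- fixture_se_events()
  cat37 <- fixture_catalogue()
  res <- match_skipping_to_catalogue(evs, cat37, m)
  # brute force over candidates x observed isoforms
  dd <- dedup_catalogue(cat37)
  cyc <- strsplit(dd$cycle, "-", fixed = TRUE)
  brute <- 0
  for (i in seq_len(nrow(evs))) {
    cand <- potential_circ_exons(evs[i, ], m)
    if (length(cand) == 0) next
    brute <- brute + sum(vapply(cyc, function(x) setequal(x, cand), logical(1)))
  }
  expect_equal(nrow(res$matches), brute)

  # constructed positive control: a circle equal to the 7..12 candidate
  pos <- data.frame(cell_line = "CTRL", primer_row = NA,
                    raw_path = "7-8-9-10-11-12-7",
                    cycle = "7-8-9-10-11-12", donor = "12", acceptor = "7",
                    key = "7-8-9-10-11-12|12>7", note = "")
  aug <- rbind(as.data.frame(cat37), pos)
  class(aug) <- class(cat37)
  res_pos <- match_skipping_to_catalogue(evs, aug, m)
  expect_equal(nrow(res_pos$matches), brute + 1)
  expect_true(res_pos$matches$junction_consistent[
    res_pos$matches$cell_line == "CTRL"])
})

test_that("match count is invariant to catalogue order and isoform rotation", {
  m <- anril_model()
  evs <- fixture_se_events()
  pos1 <- parse_isoform_path("7-8-9-10-11-12-7 (12-7)", "A")
  pos2 <- parse_isoform_path("10-11-12-7-8-9-10 (12-7)", "B")
  mk <- function(iso) data.frame(
    cell_line = iso$cell_line, primer_row = NA,
    raw_path = paste(iso$raw_path, collapse = "-"),
    cycle = paste(iso$cycle, collapse = "-"),
    donor = iso$donor, acceptor = iso$acceptor,
    key = paste0(paste(iso$cycle, collapse = "-"), "|", iso$donor, ">",
                 iso$acceptor),
    note = "")
  for (ord in list(c(1, 2), c(2, 1))) {
    cc <- rbind(mk(pos1), mk(pos2))[ord, ]
    class(cc) <- c("circ_catalogue", "data.frame")
    res <- match_skipping_to_catalogue(evs, cc, m)
    expect_equal(nrow(res$matches), 2)
  }
})
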