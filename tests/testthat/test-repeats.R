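make_rmsk_file <- function(reps) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  write_repeats_rmsk(reps, f)
  f
}

toy_reps <- function() {
  data.frame(
    chrom = "chrT",
    start = c(1000, 2000, 3000, 4000),
    end = c(1300, 2300, 3300, 4300),
    strand = c("+", "-", "+", "+"),
    name = c("AluSx", "AluY", "AluJb", "L1MA4"),
    class = c("SINE", "SINE", "SINE", "LINE"),
    family = c("Alu", "Alu", "Alu", "L1")
  )
}

test_that("rmsk reading filters by class and region and round-trips", {
  f <- make_rmsk_file(toy_reps())
  alus <- read_repeats(f, class_filter = "Alu")
  expect_equal(nrow(alus), 3)
  all4 <- read_repeats(f, class_filter = NULL)
  expect_equal(nrow(all4), 4)
  expect_equal(all4[, c("chrom", "start", "end", "strand", "name")],
               toy_reps()[, c("chrom", "start", "end", "strand", "name")])
  # region restriction, and a region outside everything
  some <- read_repeats(f, region = list(chrom = "chrT", start = 0, end = 2100),
                       class_filter = NULL)
  expect_equal(nrow(some), 2)
  none <- read_repeats(f, region = list(chrom = "chrT", start = 9e5, end = 9.1e5),
                       class_filter = NULL)
  expect_equal(nrow(none), 0)
})

test_that("BED6 input is accepted with RepeatMasker-style names", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrT\t100\t400\tAluSx#SINE/Alu\t0\t+",
               "chrT\t500\t800\tL1MA4#LINE/L1\t0\t-"), f)
  alus <- read_repeats(f, class_filter = "Alu")
  expect_equal(nrow(alus), 1)
  expect_equal(alus$name, "AluSx")
  expect_equal(alus$class, "SINE")
  expect_equal(alus$family, "Alu")
  bad <- withr::local_tempfile()
  writeLines("chrT\tonly-two", bad)
  expect_error(read_repeats(bad), "unrecognised")
})

test_that("repeats are assigned to containing features; partial overlaps set aside", {
  m <- toy_model(c(0, 1000), c(3000, 4000), c(6000, 7000))
  reps <- data.frame(chrom = "chrT",
                     start = c(1500, 3200, 900, 6100),
                     end = c(1800, 3500, 1200, 6400),
                     strand = "+",
                     name = c("in_intron1", "in_exon2", "straddler", "in_exon3"),
                     class = "SINE", family = "Alu")
  asg <- assign_repeats_to_features(reps, m)
  expect_equal(unname(asg$intron_counts["1"]), 1L)
  expect_equal(unname(asg$exon_counts["2"]), 1L)
  expect_equal(unname(asg$exon_counts["3"]), 1L)
  expect_equal(asg$partial$name, "straddler")
  # at a looser threshold the straddler is assigned to its majority feature
  asg2 <- assign_repeats_to_features(reps, m, min_overlap_frac = 0.5)
  expect_equal(nrow(asg2$partial), 0)
  expect_equal(sum(asg2$intron_counts) + sum(asg2$exon_counts), 4)
})

test_that("planted repeats are recovered per intron exactly", {
  cfg <- simulation_config(seed = 21, background_per_kb = 0.3)
  loc <- simulate_locus(cfg)
  asg <- assign_repeats_to_features(loc$repeats, loc$model)
  truth <- table(factor(
    vapply(seq_len(nrow(loc$repeats)), function(k) {
      hit <- which(loc$repeats$start[k] >= loc$model$introns$start &
                   loc$repeats$end[k] <= loc$model$introns$end)
      as.character(hit)
    }, ""), levels = as.character(1:18)))
  expect_equal(unname(asg$intron_counts), as.integer(truth))
  # zero-repeat configuration
  loc0 <- simulate_locus(simulation_config(
    seed = 22, background_per_kb = 0, inverted_pairs = data.frame(
      intron_i = integer(0), intron_j = integer(0), divergence = numeric(0))))
  asg0 <- assign_repeats_to_features(loc0$repeats, loc0$model)
  expect_true(all(asg0$intron_counts == 0))
  expect_true(all(asg0$exon_counts == 0))
})

test_that("planted inverted pairs are detected; same-intron repeats are not paired", {
  cfg <- simulation_config(seed = 31, background_per_kb = 0,
                           inverted_pairs = data.frame(intron_i = 1,
                                                       intron_j = 6,
                                                       divergence = 0))
  loc <- simulate_locus(cfg)
  pairs <- find_inverted_pairs(loc$repeats, loc$model, loc$genome)
  expect_equal(nrow(pairs), 1)
  expect_equal(pairs$intron_i, 1)
  expect_equal(pairs$intron_j, 6)
  expect_equal(pairs$score, 300)

  # both repeats moved into one intron: no cross-intron pair exists
  reps_same <- loc$repeats
  shift <- loc$model$introns$start[3] - loc$repeats$start[1]
  reps_same$start <- reps_same$start[1] + c(0, 400)
  reps_same$end <- reps_same$start + 300
  expect_equal(nrow(find_inverted_pairs(reps_same, loc$model, loc$genome)), 0)
})

test_that("pair detection is invariant under flipping the whole locus strand", {
  cfg <- simulation_config(seed = 33, background_per_kb = 0.2)
  loc <- simulate_locus(cfg)
  pairs <- find_inverted_pairs(loc$repeats, loc$model, loc$genome)
  # mirror the locus: reverse-complement the genome and mirror coordinates
  L <- Biostrings::width(loc$genome)[1]
  genome_rc <- Biostrings::DNAStringSet(
    stats::setNames(as.character(Biostrings::reverseComplement(loc$genome[[1]])),
                    "chrSim"))
  ex <- loc$model$exons
  flipped <- gene_model(
    data.frame(label = ex$label, start = L - ex$end, end = L - ex$start),
    gene_id = "SIMGENE", chrom = "chrSim", strand = "-")
  reps_f <- loc$repeats
  reps_f$start <- L - loc$repeats$end
  reps_f$end <- L - loc$repeats$start
  pairs_f <- find_inverted_pairs(reps_f, flipped, genome_rc)
  expect_equal(nrow(pairs_f), nrow(pairs))
  expect_setequal(paste(pairs_f$intron_i, pairs_f$intron_j, round(pairs_f$score, 6)),
                  paste(pairs$intron_i, pairs$intron_j, round(pairs$score, 6)))
})

test_that("unrelated random repeat pairs are rejected at default scoring", {
  set.seed(55)
  sc <- alignment_scoring()
  scores <- replicate(100, align_global(random_dna(300),
                                        revcomp_chr(random_dna(300)), sc))
  expect_gte(mean(scores < sc$min_score), 0.99)
})

test_that("junction prediction maps intron pairs to exon circles", {
  m <- anril_model()
  p <- predict_junctions(data.frame(intron_i = 1, intron_j = 14), m)
  expect_equal(c(p$donor, p$acceptor), c("14", "2"))
  p2 <- predict_junctions(data.frame(intron_i = 6, intron_j = 7), m)
  expect_equal(c(p2$donor, p2$acceptor), c("7", "7"))
  p3 <- predict_junctions(data.frame(intron_i = 5, intron_j = 7), m)
  expect_equal(c(p3$donor, p3$acceptor), c("7", "6"))
  # order of the pair does not matter; predicted circles are contiguous runs
  p4 <- predict_junctions(data.frame(intron_i = 14, intron_j = 1), m)
  expect_equal(p4[, c("donor", "acceptor")], p[, c("donor", "acceptor")])
  expect_error(predict_junctions(data.frame(intron_i = 3, intron_j = 3), m),
               "distinct")
})

test_that("classification partitions the observed junction set exactly", {
  obs <- data.frame(donor = c("6", "7", "14", "10"),
                    acceptor = c("2", "6", "5", "4"))
  pred <- data.frame(donor = c("6", "7"), acceptor = c("2", "6"))
  cls <- classify_observed_junctions(obs, pred)
  expect_equal(nrow(cls$explained) + nrow(cls$unexplained), nrow(obs))
  expect_equal(cls$explained$donor, c("6", "7"))
  both <- rbind(cls$explained, cls$unexplained)
  expect_setequal(paste(both$donor, both$acceptor),
                  paste(obs$donor, obs$acceptor))
  none <- classify_observed_junctions(obs, pred[0, ])
  expect_equal(nrow(none$explained), 0)
  expect_equal(nrow(none$unexplained), nrow(obs))
})

test_that("repeat counts correlate with intron length when built that way", {
  lens <- c(100, 200, 400, 800, 1600)
  prop <- c(1, 2, 4, 8, 16)
  r <- correlate_repeat_count_with_length(lens, prop)
  expect_equal(r$estimate[r$method == "spearman"], 1)
  set.seed(77)
  lens2 <- round(exp(runif(50, log(200), log(20000))))
  counts <- rpois(50, lens2 / 2000)
  r2 <- correlate_repeat_count_with_length(lens2, counts)
  expect_gt(r2$estimate[r2$method == "spearman"], 0)
  expect_lt(r2$p_value[r2$method == "spearman"], 0.05)
  # permutation null: correlation near zero on average
  null_rho <- replicate(100, {
    rp <- correlate_repeat_count_with_length(lens2, sample(counts))
    rp$estimate[rp$method == "spearman"]
  })
  expect_lt(abs(mean(null_rho)), 0.1)
  expect_error(correlate_repeat_count_with_length(lens2, rep(1, 50)),
               "constant")
  expect_error(correlate_repeat_count_with_length(c(1, 2), c(1, 2)),
               "at least 3")
})
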