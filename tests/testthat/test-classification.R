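coding_example <- function() {
  transcript_set(data.frame(
    transcript_id = "t_g1", gene_id = "g1", source = "ucsc", chrom = "chr2L",
    start = c(1000, 4500), end = c(1500, 5000), strand = "+",
    stringsAsFactors = FALSE))
}

test_that("class geometries match the defining cases", {
  coding <- coding_example()
  lnc <- transcript_set(rbind(
    make_ts("in_anti", 2000, 2500, strand = "-")$exons,
    make_ts("ex_anti", 1200, 1600, strand = "-")$exons,
    make_ts("inter", 6000, 6800, strand = "+")$exons,
    make_ts("unk", 1200, 1600, strand = "*")$exons))
  res <- classify_transcripts(lnc, coding)
  cls <- stats::setNames(res$lnc_class, res$transcript_id)
  expect_equal(cls[["in_anti"]], "intronic_antisense")
  expect_equal(cls[["ex_anti"]], "exonic_antisense")
  expect_equal(cls[["inter"]], "intergenic")
  expect_equal(cls[["unk"]], "unknown")
  expect_true(is.na(res$anchor_gene_id[res$transcript_id == "inter"]))
  expect_equal(res$overlap_bp[res$transcript_id == "ex_anti"], 300)
})

test_that("exon contact takes precedence and coding strand must be known", {
  coding <- transcript_set(rbind(
    coding_example()$exons,
    data.frame(transcript_id = "t_g2", gene_id = "g2", source = "ucsc",
               chrom = "chr2L", start = c(1400, 3000), end = c(1600, 3500),
               strand = "-", stringsAsFactors = FALSE)))
  # overlaps g2's exon and sits in g1's intron: exonic wins
  lnc <- make_ts("both", 1550, 2600, strand = "+")
  res <- classify_transcripts(lnc, coding)
  expect_equal(res$lnc_class, "exonic_antisense")
  expect_equal(res$anchor_gene_id, "g2")
  bad <- make_ts("t_bad", 100, 700, strand = "*", gene_id = "gbad",
                 source = "ucsc")
  expect_error(classify_transcripts(lnc, bad), "unknown strand")
})

test_that("classification agrees with the per-base oracle on random cases", {
  coding <- tiny_genome()
  rand <- random_tiny_transcripts(300, seed = 21)
  res <- classify_transcripts(rand, coding)
  for (i in seq_len(nrow(res))) {
    id <- res$transcript_id[i]
    expected <- oracle_classify(rand$tx[rand$tx$transcript_id == id, ],
                                rand$exons[rand$exons$transcript_id == id, ],
                                coding)
    expect_equal(res$lnc_class[i], expected, label = id)
  }
})

test_that("flipping every strand swaps sense and antisense counts", {
  coding <- tiny_genome()
  rand <- random_tiny_transcripts(200, seed = 22)
  res <- classify_transcripts(rand, coding)
  flip <- function(s) c("+" = "-", "-" = "+", "*" = "*")[s]
  rand_f <- transcript_set(transform(rand$exons,
                                     strand = unname(flip(strand))))
  coding_f <- transcript_set(transform(coding$exons,
                                       strand = unname(flip(strand))))
  # flipping both lncRNA and gene strands preserves all classes;
  # flipping only the lncRNA strand swaps sense <-> antisense
  res_both <- classify_transcripts(rand_f, coding_f)
  expect_identical(res$lnc_class, res_both$lnc_class)
  res_lnc <- classify_transcripts(rand_f, coding)
  swap <- c(exonic_sense = "exonic_antisense",
            exonic_antisense = "exonic_sense",
            intronic_sense = "intronic_antisense",
            intronic_antisense = "intronic_sense",
            intergenic = "intergenic", unknown = "unknown")
  expect_identical(res_lnc$lnc_class, unname(swap[res$lnc_class]))
})

test_that("planted class labels are recovered exactly", {
  fx <- generate_fixtures(sim_config(seed = 9))
  res <- classify_transcripts(fx$lnc$transcripts, fx$annotation$transcripts)
  expect_identical(unname(fx$lnc$labels[res$transcript_id]), res$lnc_class)
})

test_that("direction assignment needs unanimity among known calls", {
  expect_equal(assign_direction(c("+", "+", "+")), "+")
  expect_equal(assign_direction(c("+", "-")), "*")
  expect_equal(assign_direction(character()), "*")
  expect_equal(assign_direction(c("*", "-", "*")), "-")
})

test_that("exon-count histograms sum to one and reject empty input", {
  ts <- make_ts(c("a", "a", "b", "c"), c(0, 500, 1000, 2000),
                c(100, 600, 1100, 2100))
  h <- summarize_exon_counts(ts)
  expect_equal(h$n[h$exon_count == 1], 2L)
  expect_equal(sum(h$fraction), 1)
  expect_error(summarize_exon_counts(transcript_set(NULL)), "empty")
  one <- summarize_exon_counts(make_ts("z", 0, 100))
  expect_equal(one$fraction, 1)
})

test_that("the synthetic exon-count mass concentrates on one to three exons", {
  fx <- generate_fixtures(sim_config(seed = 9))
  h <- summarize_exon_counts(fx$lnc$transcripts)
  mass13 <- sum(h$fraction[h$exon_count <= 3])
  n <- length(fx$lnc$transcripts)
  se <- sqrt(0.94 * 0.06 / n)
  expect_gte(mass13, 0.94 - 3 * se)
})
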