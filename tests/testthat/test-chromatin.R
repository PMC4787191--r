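peakdf <- function(start, end, mark = "H3K4me3", chrom = "chr2L") {
  data.frame(chrom = chrom, start = start, end = end, strand = "*",
             mark = mark, dataset = "d", stringsAsFactors = FALSE)
}

test_that("promoter windows cover -500..+100 along transcription, clipped", {
  expect_equal(promoter_window(10000, "+"), c(9500, 10101))
  expect_equal(promoter_window(10000, "-"), c(9900, 10501))
  expect_equal(promoter_window(100, "+"), c(0, 201))
  expect_equal(diff(promoter_window(10000, "+")), 601)
  expect_equal(diff(promoter_window(10000, "-")), 601)
  expect_error(promoter_window(10000, "*"), "strand")
})

test_that("H3K4me3 presence is any-overlap with the promoter window", {
  gene <- make_ts("g", 10000, 11000, strand = "+")
  hit <- chromatin_annotate(gene, peakdf(9600, 9700))
  expect_true(hit$h3k4me3_present)
  adj <- chromatin_annotate(gene, peakdf(9400, 9500))  # half-open adjacency
  expect_false(adj$h3k4me3_present)
  other <- chromatin_annotate(gene, peakdf(9600, 9700, mark = "H3K36me3"))
  expect_false(other$h3k4me3_present)
  unk <- chromatin_annotate(make_ts("u", 10000, 11000, strand = "*"),
                            peakdf(9600, 9700))
  expect_true(is.na(unk$h3k4me3_present))  # not assessable, distinct from FALSE
})

test_that("H3K36me3 coverage is over the full transcribed span", {
  gene <- make_ts("g", 1000, 2000, strand = "+")
  a <- chromatin_annotate(gene, peakdf(c(1000, 1500), c(1300, 1900),
                                       mark = "H3K36me3"))
  expect_equal(a$h3k36me3_coverage, 0.7)
  expect_true(a$h3k36me3_present)
  none <- chromatin_annotate(gene, peakdf(5000, 5200, mark = "H3K36me3"))
  expect_equal(none$h3k36me3_coverage, 0)
  expect_false(none$h3k36me3_present)
  full <- chromatin_annotate(gene, peakdf(900, 2100, mark = "H3K36me3"))
  expect_equal(full$h3k36me3_coverage, 1)
})

test_that("Pol II presence covers the promoter but coverage only the span", {
  gene <- make_ts("g", 10000, 11000, strand = "+")
  promoter_only <- chromatin_annotate(gene, peakdf(9600, 9700, mark = "PolII"))
  expect_true(promoter_only$polII_present)
  expect_equal(promoter_only$polII_coverage, 0)
  body <- chromatin_annotate(gene, peakdf(10000, 10600, mark = "PolII"))
  expect_true(body$polII_present)
  expect_equal(body$polII_coverage, 0.6)
  none <- chromatin_annotate(gene, peakdf(1000, 1100, mark = "PolII"))
  expect_false(none$polII_present)
})

test_that("the K4-K36 call is the conjunction of both marks", {
  expect_true(k4k36_call(TRUE, TRUE))
  expect_false(k4k36_call(TRUE, FALSE))
  expect_false(k4k36_call(FALSE, TRUE))
  expect_false(k4k36_call(NA, TRUE))
})

test_that("CAGE completeness uses an inclusive +/-50 bp window at the 5' end", {
  tx_plus <- make_ts("t", 1000, 2000, strand = "+")
  expect_true(cage_complete(tx_plus, peakdf(980, 1020, mark = "CAGE"))[["t"]])
  expect_false(cage_complete(tx_plus, peakdf(1060, 1080, mark = "CAGE"))[["t"]])
  # peak covering base 950 exactly touches the inclusive lower bound
  expect_true(cage_complete(tx_plus, peakdf(950, 960, mark = "CAGE"))[["t"]])
  expect_false(cage_complete(tx_plus, peakdf(940, 950, mark = "CAGE"))[["t"]])
  # minus strand: 5' end is the last covered base
  tx_minus <- make_ts("m", 1000, 2000, strand = "-")
  expect_true(cage_complete(tx_minus, peakdf(2040, 2060, mark = "CAGE"))[["m"]])
  expect_true(is.na(cage_complete(make_ts("u", 1000, 2000, strand = "*"),
                                  peakdf(980, 1020, mark = "CAGE"))[["u"]]))
})

test_that("validation groups follow the quartile and signature definitions", {
  expect_equal(assign_validation_group(15, TRUE, TRUE, TRUE), "G1")
  expect_equal(assign_validation_group(2, TRUE, TRUE, TRUE), "G2")
  expect_equal(assign_validation_group(15, FALSE, FALSE, FALSE), "G3")
  expect_equal(assign_validation_group(2, FALSE, FALSE, FALSE), "G4")
  expect_equal(assign_validation_group(5, TRUE, TRUE, TRUE), "none")
  expect_equal(assign_validation_group(15, TRUE, FALSE, TRUE), "none")
  expect_error(assign_validation_group(0.5, TRUE, TRUE, TRUE), "expressed")
})

test_that("adding peaks never decreases coverage or unsets presence", {
  set.seed(41)
  gene <- make_ts("g", 5000, 8000, strand = "+")
  peaks <- peakdf(6000, 6500, mark = "H3K36me3")
  peaks <- rbind(peaks, peakdf(5900, 6100, mark = "PolII"),
                 peakdf(4600, 4700, mark = "H3K4me3"))
  before <- chromatin_annotate(gene, peaks)
  for (i in 1:20) {
    s <- sample(4000:8500, 1)
    peaks <- rbind(peaks, peakdf(s, s + sample(50:500, 1),
                                 mark = sample(c("H3K4me3", "H3K36me3",
                                                 "PolII"), 1)))
    after <- chromatin_annotate(gene, peaks)
    expect_gte(after$h3k36me3_coverage, before$h3k36me3_coverage)
    expect_gte(after$polII_coverage, before$polII_coverage)
    expect_true(!isTRUE(before$h3k4me3_present) || after$h3k4me3_present)
    expect_true(!before$polII_present || after$polII_present)
    before <- after
  }
})

test_that("H3K4me3 assignment is invariant under splitting a peak", {
  gene <- make_ts("g", 10000, 11000, strand = "+")
  whole <- chromatin_annotate(gene, peakdf(9600, 9900))
  split <- chromatin_annotate(gene, peakdf(c(9600, 9750), c(9750, 9900)))
  expect_identical(whole$h3k4me3_present, split$h3k4me3_present)
  expect_identical(whole$k4k36, split$k4k36)
})

test_that("planted chromatin truth and validation groups are recovered", {
  fx <- generate_fixtures(sim_config(seed = 9))
  ann <- chromatin_annotate(fx$lnc$transcripts, fx$peaks$peaks)
  tr <- fx$chromatin_truth
  m <- merge(ann, tr, by = "gene_id")
  expect_identical(m$h3k4me3_present, m$k4)
  expect_identical(m$h3k36me3_present, m$k36)
  expect_identical(m$polII_present, m$polII)
  expect_identical(m$k4k36, k4k36_call(m$k4, m$k36))
  grouped <- m[!is.na(m$group), ]
  got <- assign_validation_group(grouped$rpkm, grouped$h3k4me3_present,
                                 grouped$h3k36me3_present,
                                 grouped$polII_present)
  expect_identical(got, grouped$group)
  expect_true(all(c("G1", "G2", "G3", "G4") %in% got))
  cage <- cage_complete(fx$lnc$transcripts,
                        fx$peaks$peaks[fx$peaks$peaks$mark == "CAGE", ])
  expect_identical(unname(cage[names(fx$peaks$cage)]),
                   unname(fx$peaks$cage))
})
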