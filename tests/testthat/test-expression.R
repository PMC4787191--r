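q33 <- function(v) intToUtf8(v + 33L)

test_that("trimming removes the 5' head and scans the 3' tail correctly", {
  mk <- function(id, quals) data.frame(read_id = id,
                                       seq = strrep("A", length(quals)),
                                       qual = q33(quals),
                                       stringsAsFactors = FALSE)
  # 50 bases all q30: only the 5' trim applies
  r <- trim_reads(mk("a", rep(30, 50)))
  expect_true(r$kept)
  expect_equal(nchar(r$seq), 40L)
  # 46 bases all q30: exactly 36 remain, kept at the boundary
  r <- trim_reads(mk("b", rep(30, 46)))
  expect_true(r$kept)
  expect_equal(nchar(r$seq), 36L)
  # 45 bases: 35 remain, discarded
  expect_false(trim_reads(mk("c", rep(30, 45)))$kept)
  # 48 bases ending 15,25,18: only the trailing q18 goes, 37 remain
  r <- trim_reads(mk("d", c(rep(30, 45), 15, 25, 18)))
  expect_true(r$kept)
  expect_equal(nchar(r$seq), 37L)
  # fully low-quality tail consumes the read
  r <- trim_reads(mk("e", c(rep(30, 12), rep(10, 38))))
  expect_false(r$kept)
})

test_that("trimming never lengthens a read and leaves a high-quality 3' base", {
  fx <- generate_reads(sim_config(seed = 4))
  out <- trim_reads(fx$reads)
  expect_true(all(nchar(out$seq) <= nchar(fx$reads$seq)))
  expect_identical(out$kept, nchar(out$seq) >= 36L)
  last_q <- vapply(out$qual[nchar(out$qual) > 0],
                   function(q) utf8ToInt(substr(q, nchar(q), nchar(q))) - 33L,
                   numeric(1))
  expect_true(all(last_q > 20))
  # engineered fates are planted truth
  expect_identical(out$kept[match(names(fx$fates), out$read_id)],
                   unname(fx$fates))
})

test_that("RPKM follows the closed form and its linearity laws", {
  expect_equal(compute_rpkm(10, 2000, 5e6), 1)
  expect_equal(compute_rpkm(0, 2000, 5e6), 0)
  expect_equal(compute_rpkm(50, 1008, 2e7), 50 * 1e9 / (2e7 * 1008))
  set.seed(31)
  counts <- sample(1:1000, 20); lens <- sample(200:5000, 20)
  tot <- round(runif(20, 1e6, 1e8))
  base <- compute_rpkm(counts, lens, tot)
  expect_equal(compute_rpkm(2 * counts, lens, tot), 2 * base)
  expect_equal(compute_rpkm(counts, lens, 2 * tot), base / 2)
  expect_error(compute_rpkm(10, 0, 5e6), "length")
  expect_error(compute_rpkm(10, 2000, 0), "total")
})

test_that("expressed and poly(A)-minus calls use strict boundaries", {
  expect_true(flag_expressed(1.01))
  expect_false(flag_expressed(1))
  expect_false(flag_expressed(0))
  expect_true(infer_polya_minus(1.5, 0))
  expect_false(infer_polya_minus(1.5, 0.2))
  expect_false(infer_polya_minus(0.9, 0))
  # poly(A)-minus implies expressed in the ribo-zero library
  set.seed(32)
  rz <- runif(200, 0, 3); pa <- sample(c(0, runif(10, 0, 2)), 200, TRUE)
  pm <- infer_polya_minus(rz, pa)
  expect_true(all(flag_expressed(rz[pm])))
})

test_that("stage profiles average by biotype and count expressed", {
  m <- matrix(c(0, 4, 16, 48), nrow = 2,
              dimnames = list(c("l1", "m1"), c("s1", "s2")))
  bt <- c(l1 = "lncRNA", m1 = "mRNA")
  p <- stage_profile(m, bt)
  expect_equal(p$mean_rpkm[p$biotype == "lncRNA" & p$stage == "s1"], 0)
  expect_equal(p$n_expressed[p$biotype == "mRNA" & p$stage == "s2"], 1)
  expect_error(stage_profile(matrix(numeric(), 0, 0), bt), "non-empty")
  expect_error(stage_profile(m, bt["l1"]), "biotype")
})

test_that("synthetic stage counts recover the planted expression means", {
  fx <- generate_fixtures(sim_config(seed = 9))
  ex <- fx$expression
  alltx <- rbind(fx$annotation$transcripts$tx, fx$lnc$transcripts$tx)
  lens <- stats::setNames(alltx$length, alltx$transcript_id)
  sub <- ex$counts[grepl("^stage_", ex$counts$library), ]
  sub$rpkm <- compute_rpkm(sub$read_count, lens[sub$transcript_id],
                           ex$total_mapped[sub$library])
  for (b in c("lncRNA", "mRNA")) {
    v <- sub$rpkm[ex$biotype[sub$transcript_id] == b]
    target <- ex$stage_mean_rpkm[[b]]
    se <- stats::sd(v) / sqrt(length(v))
    expect_lt(abs(mean(v) - target), 3 * se)
  }
})
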