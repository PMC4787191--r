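test_that("intergenic detection is strand-blind and collapses duplicates", {
  reference <- make_ts("ref", c(1000, 3000), c(1500, 3500), strand = "+")
  asm1 <- transcript_set(rbind(
    make_ts("far", 6000, 6500, strand = "+")$exons,
    make_ts("anti", 1200, 1400, strand = "-")$exons))  # antisense exon overlap
  asm2 <- make_ts("far_dup", 6000, 6500, strand = "+")  # same locus as 'far'
  res <- find_intergenic_candidates(list(asm1, asm2), reference)
  expect_setequal(res$candidates$tx$transcript_id, "far")
  expect_equal(res$n_union, 2L)  # duplicate collapsed before counting
  expect_true("anti" %in% res$removed_ids)
})

test_that("transcripts inside reference spans are not intergenic", {
  reference <- make_ts("ref", c(1000, 9000), c(1500, 9500), strand = "+")
  intronic <- make_ts("inside", 4000, 4500, strand = "+")
  # exon overlaps the reference *span* (intron) -> excluded at this stage
  res <- find_intergenic_candidates(intronic, reference)
  expect_equal(length(res$candidates), 0L)
})

test_that("coding-potential filter applies the strict >= cutoff and cpc labels", {
  cand <- make_ts(c("a", "b", "c"), c(0, 1000, 2000), c(500, 1500, 2500))
  scores <- data.frame(
    transcript_id = c("a", "b", "c"),
    method = c("cpat_probability", "cpat_probability", "cpc_label"),
    value = c("0.38", "0.39", "coding"), stringsAsFactors = FALSE)
  res <- filter_coding_potential(cand, scores, 0.39)
  expect_setequal(res$kept$tx$transcript_id, "a")
  expect_setequal(res$removed_ids, c("b", "c"))
  expect_error(filter_coding_potential(cand, scores[-1, ], 0.39), "a")
})

test_that("read-support filter drops zero and absent counts", {
  cand <- make_ts(c("a", "b", "c"), c(0, 1000, 2000), c(500, 1500, 2500))
  res <- filter_read_support(cand, c(a = 0, b = 1))
  expect_setequal(res$kept$tx$transcript_id, "b")
  expect_setequal(res$removed_ids, c("a", "c"))
})

test_that("sense-overlap removal is exon-level and sense-only", {
  coding <- make_ts("cg", c(1000, 5000), c(1500, 5500), strand = "+")
  cand <- transcript_set(rbind(
    make_ts("sense_hit", 1200, 1700, strand = "+")$exons,
    make_ts("antisense", 1200, 1700, strand = "-")$exons,
    make_ts("intron_sense", 2000, 2500, strand = "+")$exons))
  res <- filter_sense_overlap(cand, coding)
  expect_setequal(res$removed_ids, "sense_hit")
  unknown <- make_ts("u", 1200, 1700, strand = "*")
  expect_warning(res_u <- filter_sense_overlap(unknown, coding), "unknown")
  expect_equal(length(res_u$kept), 1L)
})

test_that("the full funnel recovers planted fates with exact accounting", {
  cfg <- sim_config(seed = 5)
  ann <- generate_annotation(cfg)
  d <- generate_discovery_fixture(cfg, ann)
  res <- run_discovery_funnel(d$assembled, d$reference, d$scores,
                              d$rrna_alignments, d$remap_counts,
                              d$updated_annotation)
  expect_setequal(res$novel$tx$transcript_id, d$truth$survivors)
  rep <- res$report
  expect_equal(rep$count_out, rep$count_in - rep$removed)
  expect_equal(rep$count_in[-1], rep$count_out[-nrow(rep)])
  expect_equal(rep$stage,
               c("intergenic", "min_length", "coding_potential", "rrna",
                 "read_support", "sense_overlap"))
  expect_equal(rep$removed[rep$stage == "min_length"],
               length(d$truth$short))
  expect_equal(rep$removed[rep$stage == "sense_overlap"],
               length(d$truth$sense))
})

test_that("the surviving set is invariant under assembled input order", {
  cfg <- sim_config(seed = 5)
  ann <- generate_annotation(cfg)
  d <- generate_discovery_fixture(cfg, ann)
  res1 <- run_discovery_funnel(d$assembled, d$reference, d$scores,
                               d$rrna_alignments, d$remap_counts,
                               d$updated_annotation)
  res2 <- run_discovery_funnel(rev(d$assembled), d$reference, d$scores,
                               d$rrna_alignments, d$remap_counts,
                               d$updated_annotation)
  # duplicate collapse may keep different representative ids; compare loci
  sig <- function(ts) sort(unname(lncCurate:::.locus_signature(ts)))
  expect_identical(sig(res1$novel), sig(res2$novel))
})

test_that("an empty assembled input yields an empty funnel", {
  cfg <- sim_config(seed = 5)
  ann <- generate_annotation(cfg)
  res <- run_discovery_funnel(transcript_set(NULL), ann$transcripts,
                              data.frame(transcript_id = character(),
                                         method = character(),
                                         value = character()),
                              alignment_records(), numeric(),
                              ann$transcripts)
  expect_equal(length(res$novel), 0L)
  expect_true(all(res$report$count_in == 0))
})
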