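test_that("minimum-length filter keeps the 200 bp boundary", {
  ts <- make_ts(c("a", "b", "c"), c(0, 1000, 2000),
                c(150, 1200, 3008))  # lengths 150, 200, 1008
  res <- filter_min_length(ts, 200)
  expect_setequal(res$kept$tx$transcript_id, c("b", "c"))
  expect_equal(res$decisions$reason[res$decisions$transcript_id == "a"],
               "too_short")
  empty <- filter_min_length(transcript_set(NULL), 200)
  expect_equal(length(empty$kept), 0L)
  expect_equal(length(filter_min_length(ts, 100)$kept), 3L)
})

test_that("dedup rules reproduce every planted branch of the fixtures", {
  ax <- generate_alignment_fixtures(sim_config(seed = 3))
  r1 <- dedup_against_primary(ax$ucsc_candidates, ax$primary,
                              ax$ucsc_alignments, "flybase_ucsc")
  expect_setequal(r1$kept$tx$transcript_id, ax$truth$ucsc_kept)
  d1 <- r1$decisions
  expect_equal(d1$reason[d1$transcript_id == "U_same"], "same_loci")
  expect_equal(d1$reason[d1$transcript_id == "U_60"], "overlap_50")

  r2 <- dedup_against_primary(ax$brown_candidates, ax$primary,
                              ax$brown_alignments, "brown",
                              flybase_ids = ax$flybase_ids)
  expect_setequal(r2$kept$tx$transcript_id, ax$truth$brown_kept)
  d2 <- r2$decisions
  expect_equal(d2$reason[d2$transcript_id == "B_fbdup"],
               "flybase_id_duplicate")
  expect_equal(d2$reason[d2$transcript_id == "B_1ex"], "overlap_50")
  expect_true(d2$kept[d2$transcript_id == "B_3ex"])  # exon-count exception

  r3 <- dedup_against_primary(ax$young_candidates, ax$young_primary,
                              ax$young_alignments, "young_vs_brown")
  expect_setequal(r3$kept$tx$transcript_id, ax$truth$young_kept)
  expect_equal(r3$decisions$reason[r3$decisions$transcript_id == "YB_095"],
               "overlap_90")
})

test_that("dedup respects the E-value gate and is idempotent", {
  ax <- generate_alignment_fixtures(sim_config(seed = 3))
  r1 <- dedup_against_primary(ax$ucsc_candidates, ax$primary,
                              ax$ucsc_alignments, "flybase_ucsc")
  expect_true("U_bigE" %in% r1$kept$tx$transcript_id)  # E = 1e-5 ignored
  again <- dedup_against_primary(r1$kept, ax$primary, ax$ucsc_alignments,
                                 "flybase_ucsc")
  expect_identical(sort(again$kept$tx$transcript_id),
                   sort(r1$kept$tx$transcript_id))
  expect_error(dedup_against_primary(ax$ucsc_candidates, ax$primary,
                                     ax$ucsc_alignments, "no_such_rule"))
})

test_that("coordinate-overlap fallback applies the same thresholds", {
  primary <- make_ts("P", 1000, 2000, source = "flybase")
  cand <- transcript_set(rbind(
    make_ts("c60", 1000, 1600)$exons,      # 600/600 of own length inside P
    make_ts("c40", 1700, 2200)$exons,      # 300/500 = 0.6 also removed
    make_ts("cfar", 5000, 5400)$exons))    # no genomic contact
  res <- dedup_against_primary(cand, primary, alignments = NULL,
                               rule = "flybase_ucsc")
  expect_setequal(res$kept$tx$transcript_id, "cfar")
  expect_match(res$decisions$evidence_id[!res$decisions$kept], "^coord:")
})

test_that("rRNA exclusion requires both thresholds crossed", {
  ts <- make_ts(c("x", "y", "z"), c(0, 1000, 2000), c(800, 1800, 2800))
  aln <- alignment_records(
    query_id = c("x", "y", "z"), subject_id = "rRNA",
    identity_pct = c(99.5, 98, 100), align_length = 700,
    e_value = c(1e-12, 1e-12, 1e-8), bit_score = 100,
    query_length = 800, subject_length = 4000)
  res <- exclude_rrna(ts, aln)
  expect_setequal(res$kept$tx$transcript_id, c("y", "z"))
  expect_equal(res$decisions$reason[res$decisions$transcript_id == "x"],
               "rrna_contamination")
})

test_that("status filter removes the vocabulary and keeps absent ids", {
  ts <- make_ts(c("a", "b", "c"), c(0, 1000, 2000), c(500, 1500, 2500))
  status <- c(a = "protein_coding", c = "lncRNA")
  res <- apply_status_filter(ts, status)
  expect_setequal(res$kept$tx$transcript_id, c("b", "c"))
  expect_equal(res$decisions$reason[res$decisions$transcript_id == "a"],
               "status_removed")
})

test_that("every curation operation partitions its input exactly", {
  ax <- generate_alignment_fixtures(sim_config(seed = 3))
  for (res in list(
    filter_min_length(ax$ucsc_candidates, 200),
    dedup_against_primary(ax$brown_candidates, ax$primary,
                          ax$brown_alignments, "brown",
                          flybase_ids = ax$flybase_ids),
    exclude_rrna(ax$rrna_transcripts, ax$rrna_alignments))) {
    dec <- res$decisions
    expect_equal(sum(dec$kept), length(res$kept))
    expect_identical(dec$kept, dec$reason == "kept")
    expect_equal(anyDuplicated(dec$transcript_id), 0L)
  }
})
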