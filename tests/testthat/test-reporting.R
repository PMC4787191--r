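test_that("qPCR calls compute -delta Ct and apply an inclusive cutoff", {
  r <- qpcr_call("x", c(18, 18, 18, 18), reference_ct = 20, cutoff = 2)
  expect_equal(r$minus_delta_ct, 2)
  expect_true(r$detected)
  r <- qpcr_call("y", c(25, 25, 25, 25), reference_ct = 20, cutoff = 1)
  expect_equal(r$minus_delta_ct, -5)
  expect_false(r$detected)
  r <- qpcr_call("z", c(19.5, 18.5), reference_ct = 20, cutoff = 1)
  expect_equal(r$minus_delta_ct, 1)
  expect_true(r$detected)
  expect_error(qpcr_call("w", numeric(), 20), "replicate")
})

test_that("detection rates round half-up and ignore call order", {
  calls <- data.frame(detected = c(rep(TRUE, 40), FALSE, FALSE))
  expect_equal(detection_rate(calls), 95.24)
  set.seed(51)
  expect_equal(detection_rate(calls[sample(nrow(calls)), , drop = FALSE]),
               95.24)
  expect_equal(detection_rate(data.frame(detected = rep(TRUE, 10))), 100)
  expect_equal(detection_rate(data.frame(detected = FALSE)), 0)
  expect_equal(detection_rate(data.frame(detected = c(TRUE, FALSE, FALSE))),
               33.33)
  expect_error(detection_rate(NULL), "empty")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(95.235, 2), 95.24)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("funnel validation checks arithmetic and chaining", {
  good <- rbind(funnel_stage("a", 754, 29), funnel_stage("b", 725, 134))
  expect_silent(funnel_check(good))
  bad <- data.frame(stage = "x", count_in = 100, removed = 10,
                    count_out = 91)
  expect_error(funnel_check(bad), "x")
  broken <- rbind(funnel_stage("a", 100, 10), funnel_stage("b", 80, 5))
  expect_error(funnel_check(broken), "chain broken")
  expect_silent(funnel_check(good[0, ]))
  expect_error(funnel_check(funnel_stage("neg", 10, -1)), "negative")
})

test_that("summary tables are internally additive on planted data", {
  fx <- generate_fixtures(sim_config(seed = 9))
  cls <- classify_transcripts(fx$lnc$transcripts, fx$annotation$transcripts)
  tabs <- summary_tables(fx$lnc$transcripts, cls)
  d <- tabs$direction
  expect_equal(d$plus + d$minus + d$unknown, d$total)
  expect_equal(sum(d$total), length(fx$lnc$transcripts))
  ty <- tabs$types
  expect_equal(sum(ty$n), length(fx$lnc$transcripts))
  expect_equal(ty$n_single + ty$n_multiple, ty$n)
  known <- ty[ty$lnc_class != "unknown", ]
  expect_equal(known$n_plus + known$n_minus, known$n)
  # planted class counts appear exactly
  planted <- table(fx$lnc$labels)
  expect_equal(stats::setNames(ty$n, ty$lnc_class)[names(planted)],
               stats::setNames(as.integer(planted), names(planted)))
})

test_that("summary_tables rejects incomplete classifications", {
  ts <- make_ts(c("a", "b"), c(0, 1000), c(500, 1500))
  cls <- data.frame(transcript_id = "a", lnc_class = "intergenic",
                    anchor_gene_id = NA, overlap_bp = 0)
  expect_error(summary_tables(ts, cls), "cover")
})
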