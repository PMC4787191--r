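#' @name reporting
#' @title Funnel accounting, summary tables and RT-qPCR calls
#'
#' @description
#' Bookkeeping surfaces of the pipeline: RT-qPCR detection calls and rates,
#' validated funnel reports, and the direction-by-source and
#' type-of-transcript summary tables with internal additivity guaranteed.
NULL

#' Round half-up
#'
#' Decimal rounding with halves away from zero (the convention of the
#' pipeline's printed percentages), unlike base R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded values.
#' @examples
#' round_half_up(95.235, 2)  # 95.24
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' RT-qPCR detection call
#'
#' Computes `-delta Ct = Ct(reference) - mean(Ct(target replicates))` and
#' calls the target detected when it is at or above the cutoff.
#'
#' @param target_id Target label.
#' @param ct_replicates Numeric Ct values of technical replicates (>= 1).
#' @param reference_ct Ct of the reference assay.
#' @param cutoff Detection cutoff on `-delta Ct` (1 for brain assays, 2 for
#'   whole-body assays under the defaults).
#' @return One-row data frame: `target_id`, `minus_delta_ct`, `detected`.
#' @examples
#' qpcr_call("lnc1", c(18, 18, 18, 18), reference_ct = 20, cutoff = 2)
#' @export
qpcr_call <- function(target_id, ct_replicates, reference_ct,
                      cutoff = lnc_thresholds()$qpcr_cutoff_body) {
  if (length(ct_replicates) < 1L) {
    stop("qPCR call requires at least one replicate")
  }
  mdc <- reference_ct - mean(ct_replicates)
  data.frame(target_id = target_id, minus_delta_ct = mdc,
             detected = mdc >= cutoff, stringsAsFactors = FALSE)
}

#' Detection rate of a set of qPCR calls
#'
#' @param calls Data frame of calls (needs a logical `detected` column).
#' @return Percent detected, rounded half-up to 2 decimals.
#' @examples
#' calls <- data.frame(detected = c(rep(TRUE, 40), FALSE, FALSE))
#' detection_rate(calls)  # 95.24
#' @export
detection_rate <- function(calls) {
  if (is.null(calls) || nrow(calls) == 0L) {
    stop("detection rate of an empty call set is undefined")
  }
  round_half_up(100 * sum(calls$detected) / nrow(calls), 2)
}

#' Build one funnel stage
#'
#' @param stage Stage name.
#' @param count_in,removed Transcripts entering and removed at this stage.
#' @return One-row funnel data frame with `count_out = count_in - removed`.
#' @export
funnel_stage <- function(stage, count_in, removed) {
  data.frame(stage = stage, count_in = count_in, removed = removed,
             count_out = count_in - removed, stringsAsFactors = FALSE)
}

#' Validate a funnel report
#'
#' Verifies per-stage arithmetic (`count_out = count_in - removed`,
#' `removed >= 0`) and stage chaining (each stage's output is the next
#' stage's input).  Errors name the offending stage.
#'
#' @param report Funnel data frame (`stage`, `count_in`, `removed`,
#'   `count_out`).
#' @return The report, invisibly, when valid.
#' @examples
#' funnel_check(rbind(funnel_stage("length", 754, 29),
#'                    funnel_stage("coding", 725, 134)))
#' @export
funnel_check <- function(report) {
  if (is.null(report) || nrow(report) == 0L) return(invisible(report))
  for (i in seq_len(nrow(report))) {
    r <- report[i, ]
    if (r$removed < 0) {
      stop("funnel stage '", r$stage, "': negative removal count")
    }
    if (r$count_out != r$count_in - r$removed) {
      stop("funnel stage '", r$stage, "': count_out (", r$count_out,
           ") != count_in - removed (", r$count_in - r$removed, ")")
    }
    if (i > 1L && report$count_out[i - 1L] != r$count_in) {
      stop("funnel chain broken between '", report$stage[i - 1L],
           "' and '", r$stage, "'")
    }
  }
  invisible(report)
}

#' Direction-by-source and transcript-type summary tables
#'
#' Builds the two bookkeeping tables of the curated catalogue: counts of
#' transcripts per source split by transcriptional direction (with totals),
#' and counts per genomic class with exon-count split (single/multiple),
#' strand split and mean length with sample (n-1) standard deviation.
#'
#' @param ts A [transcript_set()] of curated transcripts.
#' @param classification Classification data frame from
#'   [classify_transcripts()] covering every transcript of `ts`.
#' @return List with `direction` (source, plus, minus, unknown, total) and
#'   `types` (lnc_class, n, mean_length, sd_length, n_single, n_multiple,
#'   n_plus, n_minus).
#' @export
summary_tables <- function(ts, classification) {
  stopifnot(inherits(ts, "transcript_set"))
  tx <- ts$tx
  if (!all(tx$transcript_id %in% classification$transcript_id)) {
    stop("classification must cover every transcript")
  }
  cls <- classification$lnc_class[match(tx$transcript_id,
                                        classification$transcript_id)]
  direction <- do.call(rbind, lapply(split(tx, tx$source), function(g) {
    data.frame(source = g$source[1L],
               plus = sum(g$strand == "+"),
               minus = sum(g$strand == "-"),
               unknown = sum(g$strand == "*"),
               total = nrow(g), stringsAsFactors = FALSE)
  }))
  rownames(direction) <- NULL

  types <- do.call(rbind, lapply(split(seq_len(nrow(tx)), cls), function(idx) {
    g <- tx[idx, ]
    data.frame(lnc_class = cls[idx][1L], n = nrow(g),
               mean_length = mean(g$length),
               sd_length = if (nrow(g) > 1L) stats::sd(g$length) else NA_real_,
               n_single = sum(g$n_exons == 1L),
               n_multiple = sum(g$n_exons > 1L),
               n_plus = sum(g$strand == "+"),
               n_minus = sum(g$strand == "-"),
               stringsAsFactors = FALSE)
  }))
  rownames(types) <- NULL
  list(direction = direction, types = types)
}

#' Write a machine-readable report
#'
#' @param counts Named list of scalars/tables to serialize.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(counts, path) {
  jsonlite::write_json(counts, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
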