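#' @name curation
#' @title Non-redundant lncRNA curation
#'
#' @description
#' Stage operations for merging lncRNA sets from multiple annotation sources
#' into a non-redundant curated list: a minimum-length filter, redundancy
#' removal against an already-curated primary set under three source-specific
#' rules, ribosomal-RNA contamination exclusion, and an annotation-status
#' filter.  Every operation returns both the kept [transcript_set()] and a
#' decision table giving each input transcript exactly one fate.
NULL

.removal_statuses <- c("protein_coding", "pseudogene", "rRNA", "snRNA",
                       "snoRNA", "scaRNA", "out_of_date", "TE_region",
                       "dropped_sequence")

.decision_df <- function(ts, kept, reason, evidence = NA_character_) {
  n <- nrow(ts$tx)
  data.frame(transcript_id = ts$tx$transcript_id, source = ts$tx$source,
             kept = unname(rep_len(kept, n)),
             reason = unname(rep_len(as.character(reason), n)),
             evidence_id = unname(rep_len(as.character(evidence), n)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filter transcripts by minimum length
#'
#' Transcripts strictly shorter than `min_len` are removed (a transcript of
#' exactly `min_len` bp is kept).
#'
#' @param ts A [transcript_set()].
#' @param min_len Minimum exonic length in bp.
#' @return List with `kept` (a `transcript_set`) and `decisions` (one row per
#'   input transcript: `transcript_id`, `source`, `kept`, `reason`,
#'   `evidence_id`).
#' @export
filter_min_length <- function(ts, min_len = lnc_thresholds()$min_lnc_length) {
  stopifnot(inherits(ts, "transcript_set"), min_len > 0)
  keep <- ts$tx$length >= min_len
  dec <- .decision_df(ts, keep, ifelse(keep, "kept", "too_short"))
  list(kept = subset_transcripts(ts, ts$tx$transcript_id[keep]),
       decisions = dec)
}

# Alignment-evidence table for dedup: one row per candidate x primary pair
# with overlap fractions and a locus-identity flag.  Built either from
# supplied alignment records (E-value-filtered) or, as a documented fallback,
# from genomic exon-union intersections at the same thresholds.
.dedup_evidence <- function(candidates, primary, alignments, thresholds) {
  cand_sig <- .locus_signature(candidates)
  prim_sig <- .locus_signature(primary)
  if (!is.null(alignments)) {
    # rows about transcripts outside the candidate/primary sets are ignored
    # (a kept subset can be re-deduplicated with the original table);
    # unresolvable ids error earlier, in read_alignments()'s length lookup
    ev <- alignments[alignments$e_value < thresholds$dedup_evalue &
                       alignments$query_id %in% names(cand_sig) &
                       alignments$subject_id %in% names(prim_sig), ,
                     drop = FALSE]
    ev <- ev[c("query_id", "subject_id", "overlap_fraction_query",
               "overlap_fraction_subject")]
  } else {
    rows <- list()
    for (cid in candidates$tx$transcript_id) {
      ce <- .tx_exons(candidates, cid)
      clen <- sum(ce$end - ce$start)
      cand_tx <- candidates$tx[candidates$tx$transcript_id == cid, ]
      near <- primary$tx[primary$tx$chrom == cand_tx$chrom &
                           primary$tx$start < cand_tx$end &
                           primary$tx$end > cand_tx$start, , drop = FALSE]
      for (pid in near$transcript_id) {
        pe <- .tx_exons(primary, pid)
        ov <- .intersection_bp(ce, pe)
        if (ov > 0) {
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = cid, subject_id = pid,
            overlap_fraction_query = ov / clen,
            overlap_fraction_subject = ov / sum(pe$end - pe$start),
            stringsAsFactors = FALSE)
        }
      }
    }
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(query_id = character(), subject_id = character(),
                 overlap_fraction_query = numeric(),
                 overlap_fraction_subject = numeric(),
                 stringsAsFactors = FALSE)
  }
  # locus identity is a coordinate property, computed from the models
  ev$same_loci <- !is.na(prim_sig[ev$subject_id]) &
    cand_sig[ev$query_id] == prim_sig[ev$subject_id]
  # same-loci pairs missed by the evidence route (e.g. absent alignment rows)
  dup <- which(cand_sig %in% prim_sig)
  for (i in dup) {
    cid <- names(cand_sig)[i]
    pid <- names(prim_sig)[match(cand_sig[i], prim_sig)]
    if (!any(ev$query_id == cid & ev$subject_id == pid)) {
      ev <- rbind(ev, data.frame(query_id = cid, subject_id = pid,
                                 overlap_fraction_query = 1,
                                 overlap_fraction_subject = 1,
                                 same_loci = TRUE, stringsAsFactors = FALSE))
    }
  }
  ev
}

#' Remove candidates redundant against a primary set
#'
#' Candidates are screened one at a time against the full primary set (removal
#' never depends on other candidates, so input order cannot change the
#' result).  Only alignments with E-value below `thresholds$dedup_evalue` are
#' considered.  Three source-specific rules are implemented:
#'
#' * `"flybase_ucsc"`: remove a candidate that has the same locus as a primary
#'   transcript, or whose own length is covered at `>= 50 %` by the overlap.
#' * `"brown"`: remove a candidate annotated with an already-included FlyBase
#'   id; otherwise remove when the overlap covers `> 50 %` of *either*
#'   transcript's length, unless the candidate has two or more exons and its
#'   exon count differs from the matched primary transcript's.
#' * `"young_vs_brown"`: remove only on locus identity or when the overlap
#'   covers `>= 90 %` of the candidate's length.
#'
#' When `alignments` is `NULL` a coordinate-overlap fallback computes overlap
#' fractions from genomic exon-union intersections at the same thresholds
#' (flagged in the decision table's `evidence_id` as `coord:` prefixed).
#'
#' @param candidates,primary [transcript_set()] objects.
#' @param alignments Alignment records (see [alignment_records()]) with
#'   candidates as queries and primary transcripts as subjects, or `NULL` for
#'   the coordinate fallback.
#' @param rule One of `"flybase_ucsc"`, `"brown"`, `"young_vs_brown"`.
#' @param thresholds A [lnc_thresholds()].
#' @param flybase_ids Optional named character vector mapping candidate
#'   transcript ids to FlyBase ids (used by the `"brown"` rule's id-duplicate
#'   check against primary transcripts of source `flybase`).
#' @return List with `kept` and `decisions` as in [filter_min_length()].
#' @export
dedup_against_primary <- function(candidates, primary, alignments = NULL,
                                  rule = c("flybase_ucsc", "brown",
                                           "young_vs_brown"),
                                  thresholds = lnc_thresholds(),
                                  flybase_ids = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(candidates, "transcript_set"),
            inherits(primary, "transcript_set"))
  ev <- .dedup_evidence(candidates, primary, alignments, thresholds)
  coord <- is.null(alignments)
  n_ex_prim <- stats::setNames(primary$tx$n_exons, primary$tx$transcript_id)
  n_ex_cand <- stats::setNames(candidates$tx$n_exons,
                               candidates$tx$transcript_id)
  fb_primary <- primary$tx$transcript_id[primary$tx$source == "flybase"]

  ids <- candidates$tx$transcript_id
  reason <- rep("kept", length(ids))
  evidence <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    cid <- ids[i]
    if (rule == "brown" && !is.null(flybase_ids) &&
        !is.na(flybase_ids[cid]) && flybase_ids[cid] %in% fb_primary) {
      reason[i] <- "flybase_id_duplicate"
      evidence[i] <- unname(flybase_ids[cid])
      next
    }
    hits <- ev[ev$query_id == cid, , drop = FALSE]
    if (!nrow(hits)) next
    if (any(hits$same_loci)) {
      reason[i] <- "same_loci"
      evidence[i] <- hits$subject_id[which(hits$same_loci)[1L]]
      next
    }
    if (rule == "flybase_ucsc") {
      hit <- which(hits$overlap_fraction_query >=
                     thresholds$dedup_overlap_default)
      if (length(hit)) {
        reason[i] <- "overlap_50"; evidence[i] <- hits$subject_id[hit[1L]]
      }
    } else if (rule == "brown") {
      frac <- pmax(hits$overlap_fraction_query,
                   hits$overlap_fraction_subject)
      exempt <- n_ex_cand[cid] >= 2L &
        n_ex_cand[cid] != n_ex_prim[hits$subject_id]
      hit <- which(frac > thresholds$dedup_overlap_default & !exempt)
      if (length(hit)) {
        reason[i] <- "overlap_50"; evidence[i] <- hits$subject_id[hit[1L]]
      }
    } else {
      hit <- which(hits$overlap_fraction_query >=
                     thresholds$dedup_overlap_young_vs_brown)
      if (length(hit)) {
        reason[i] <- "overlap_90"; evidence[i] <- hits$subject_id[hit[1L]]
      }
    }
  }
  kept <- reason == "kept"
  if (coord) evidence[!kept] <- paste0("coord:", evidence[!kept])
  dec <- .decision_df(candidates, kept, reason, evidence)
  list(kept = subset_transcripts(candidates, ids[kept]), decisions = dec)
}

#' Exclude ribosomal-RNA contamination
#'
#' A transcript is removed when it aligns to an rRNA sequence with E-value
#' below `thresholds$rrna_evalue` *and* identity strictly above
#' `thresholds$rrna_identity` percent.
#'
#' @param ts A [transcript_set()].
#' @param rrna_alignments Alignment records with transcripts as queries and
#'   rRNA sequences as subjects.
#' @param thresholds A [lnc_thresholds()].
#' @return List with `kept` and `decisions`.
#' @export
exclude_rrna <- function(ts, rrna_alignments,
                         thresholds = lnc_thresholds()) {
  stopifnot(inherits(ts, "transcript_set"))
  hits <- rrna_alignments[rrna_alignments$e_value < thresholds$rrna_evalue &
                            rrna_alignments$identity_pct >
                              thresholds$rrna_identity, , drop = FALSE]
  ids <- ts$tx$transcript_id
  removed <- ids %in% hits$query_id
  evidence <- rep(NA_character_, length(ids))
  evidence[removed] <- hits$subject_id[match(ids[removed], hits$query_id)]
  dec <- .decision_df(ts, !removed,
                      ifelse(removed, "rrna_contamination", "kept"), evidence)
  list(kept = subset_transcripts(ts, ids[!removed]), decisions = dec)
}

#' Filter transcripts by annotation status
#'
#' Removes transcripts whose current annotation status falls in the removal
#' vocabulary (protein-coding, pseudogene, rRNA, snRNA, snoRNA, scaRNA,
#' out-of-date id, TE region, dropped sequence).  Transcripts absent from the
#' status table are kept: absence of evidence is not evidence of removal.
#'
#' @param ts A [transcript_set()].
#' @param status_table Named character vector mapping transcript ids to a
#'   feature-type/status label.
#' @return List with `kept` and `decisions`.
#' @export
apply_status_filter <- function(ts, status_table) {
  stopifnot(inherits(ts, "transcript_set"))
  ids <- ts$tx$transcript_id
  status <- status_table[ids]
  removed <- !is.na(status) & status %in% .removal_statuses
  dec <- .decision_df(ts, !removed,
                      ifelse(removed, "status_removed", "kept"),
                      ifelse(removed, unname(status), NA_character_))
  list(kept = subset_transcripts(ts, ids[!removed]), decisions = dec)
}
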