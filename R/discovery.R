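#' @name discovery
#' @title Novel lncRNA filter funnel
#'
#' @description
#' The discovery funnel screens assembled transcripts for novel lncRNAs in
#' six ordered stages: intergenic candidate detection (strand-blind overlap
#' against the reference annotation, with exact-duplicate collapse across
#' libraries), minimum length, coding potential, rRNA exclusion, read
#' support, and sense overlap against an updated coding annotation.  Each
#' stage's in/removed/out counts are recorded in a funnel report.
NULL

#' Find intergenic candidate transcripts
#'
#' Takes the union of assembled transcripts across libraries (collapsing
#' exact same-locus duplicates, keeping the first occurrence) and retains
#' those whose exons overlap no reference transcript's span on either strand
#' (intergenicity is strand-blind).
#'
#' @param assembled A [transcript_set()] or list of them (one per library).
#' @param reference Reference-annotation [transcript_set()].
#' @return List with `candidates` (a `transcript_set`), `n_union` (candidate
#'   count after duplicate collapse) and `removed_ids`.
#' @export
find_intergenic_candidates <- function(assembled, reference) {
  if (inherits(assembled, "transcript_set")) assembled <- list(assembled)
  stopifnot(all(vapply(assembled, inherits, logical(1), "transcript_set")),
            inherits(reference, "transcript_set"))
  exons <- do.call(rbind, lapply(assembled, `[[`, "exons"))
  # collapse across libraries: drop repeated ids, then repeated loci
  exons <- exons[!duplicated(paste(exons$transcript_id, exons$start,
                                   exons$end)), , drop = FALSE]
  all_tx <- transcript_set(exons)
  sig <- .locus_signature(all_tx)
  first <- !duplicated(sig)
  union_set <- subset_transcripts(all_tx, names(sig)[first])

  ref_spans <- reference$tx
  keep <- vapply(union_set$tx$transcript_id, function(id) {
    e <- .tx_exons(union_set, id)
    near <- ref_spans[ref_spans$chrom == e$chrom[1L], , drop = FALSE]
    if (!nrow(near)) return(TRUE)
    !any(vapply(seq_len(nrow(e)), function(i) {
      any(near$start < e$end[i] & near$end > e$start[i])
    }, logical(1)))
  }, logical(1))
  list(candidates = subset_transcripts(union_set,
                                       union_set$tx$transcript_id[keep]),
       n_union = nrow(union_set$tx),
       removed_ids = union_set$tx$transcript_id[!keep])
}

#' Filter candidates by coding potential
#'
#' Keeps a candidate when its classifier label is `noncoding`, or when its
#' coding probability is strictly below the cutoff (a probability equal to
#' the cutoff is treated as coding and removed).
#'
#' @param candidates A [transcript_set()].
#' @param scores Score records (see [read_coding_scores()]); every candidate
#'   must have one.
#' @param cutoff Coding-probability cutoff.
#' @return List with `kept` (a `transcript_set`) and `removed_ids`.
#' @export
filter_coding_potential <- function(candidates, scores,
                                    cutoff = lnc_thresholds()$coding_prob_cutoff) {
  stopifnot(inherits(candidates, "transcript_set"))
  ids <- candidates$tx$transcript_id
  missing <- setdiff(ids, scores$transcript_id)
  if (length(missing)) {
    stop("candidates without a coding-potential score: ",
         paste(missing, collapse = ", "))
  }
  s <- scores[match(ids, scores$transcript_id), , drop = FALSE]
  keep <- logical(nrow(s))
  is_label <- s$method == "cpc_label"
  keep[is_label] <- s$value[is_label] == "noncoding"
  keep[!is_label] <- as.numeric(s$value[!is_label]) < cutoff
  list(kept = subset_transcripts(candidates, ids[keep]),
       removed_ids = ids[!keep])
}

#' Filter candidates by remapped read support
#'
#' Keeps candidates with at least one supporting read after remapping;
#' candidates absent from the count map are treated as unsupported.
#'
#' @param candidates A [transcript_set()].
#' @param remap_counts Named numeric vector of supporting read counts.
#' @return List with `kept` and `removed_ids`.
#' @export
filter_read_support <- function(candidates, remap_counts) {
  stopifnot(inherits(candidates, "transcript_set"))
  ids <- candidates$tx$transcript_id
  n <- remap_counts[ids]
  n[is.na(n)] <- 0
  keep <- n > 0
  list(kept = subset_transcripts(candidates, ids[keep]),
       removed_ids = ids[!keep])
}

#' Remove candidates overlapping coding exons in the sense direction
#'
#' A candidate is removed when one of its exons overlaps a coding
#' transcript's exon on the same strand (exon-level, not span-level: a sense
#' transcript inside an intron is intronic-sense, a class the curated list
#' retains).  Candidates with unknown strand cannot be assessed and are kept
#' with a warning.
#'
#' @param candidates A [transcript_set()].
#' @param updated_annotation Coding-transcript [transcript_set()].
#' @return List with `kept` and `removed_ids`.
#' @export
filter_sense_overlap <- function(candidates, updated_annotation) {
  stopifnot(inherits(candidates, "transcript_set"),
            inherits(updated_annotation, "transcript_set"))
  ids <- candidates$tx$transcript_id
  strands <- candidates$tx$strand
  if (any(strands == "*")) {
    warning("candidates with unknown strand kept unassessed: ",
            paste(ids[strands == "*"], collapse = ", "))
  }
  coding_exons <- updated_annotation$exons
  removed <- vapply(seq_along(ids), function(i) {
    if (strands[i] == "*") return(FALSE)
    e <- .tx_exons(candidates, ids[i])
    ce <- coding_exons[coding_exons$chrom == e$chrom[1L] &
                         coding_exons$strand == strands[i], , drop = FALSE]
    if (!nrow(ce)) return(FALSE)
    any(vapply(seq_len(nrow(e)), function(j) {
      any(ce$start < e$end[j] & ce$end > e$start[j])
    }, logical(1)))
  }, logical(1))
  list(kept = subset_transcripts(candidates, ids[!removed]),
       removed_ids = ids[removed])
}

#' Run the full novel-lncRNA discovery funnel
#'
#' Applies, in order: intergenic detection, minimum length, coding potential,
#' rRNA exclusion, read support, sense overlap.  Returns the surviving novel
#' set together with a funnel report (one row per stage with in/removed/out
#' counts, validated by [funnel_check()]).
#'
#' @param assembled A [transcript_set()] or list of them (one per library).
#' @param reference Reference-annotation `transcript_set` used for
#'   intergenicity.
#' @param scores Coding-potential score records.
#' @param rrna_alignments Alignment records against rRNA sequences.
#' @param remap_counts Named numeric vector of supporting read counts.
#' @param updated_annotation Updated coding-gene `transcript_set` for the
#'   sense-overlap stage.
#' @param thresholds A [lnc_thresholds()].
#' @return List with `novel` (a `transcript_set`) and `report` (funnel data
#'   frame: `stage`, `count_in`, `removed`, `count_out`).
#' @export
run_discovery_funnel <- function(assembled, reference, scores,
                                 rrna_alignments, remap_counts,
                                 updated_annotation,
                                 thresholds = lnc_thresholds()) {
  stage <- function(name, n_in, n_out) {
    data.frame(stage = name, count_in = n_in, removed = n_in - n_out,
               count_out = n_out, stringsAsFactors = FALSE)
  }
  ig <- find_intergenic_candidates(assembled, reference)
  report <- stage("intergenic", ig$n_union, length(ig$candidates))

  lf <- filter_min_length(ig$candidates, thresholds$min_lnc_length)
  report <- rbind(report, stage("min_length", length(ig$candidates),
                                length(lf$kept)))

  cp <- filter_coding_potential(lf$kept, scores,
                                thresholds$coding_prob_cutoff)
  report <- rbind(report, stage("coding_potential", length(lf$kept),
                                length(cp$kept)))

  rr <- exclude_rrna(cp$kept, rrna_alignments, thresholds)
  report <- rbind(report, stage("rrna", length(cp$kept), length(rr$kept)))

  rs <- filter_read_support(rr$kept, remap_counts)
  report <- rbind(report, stage("read_support", length(rr$kept),
                                length(rs$kept)))

  so <- filter_sense_overlap(rs$kept, updated_annotation)
  report <- rbind(report, stage("sense_overlap", length(rs$kept),
                                length(so$kept)))

  funnel_check(report)
  list(novel = so$kept, report = report)
}
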