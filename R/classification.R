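#' Classify lncRNAs relative to coding genes
#'
#' Each lncRNA transcript is assigned one of six classes by its genomic
#' relationship to coding genes:
#'
#' * `exonic_sense` / `exonic_antisense`: one of its exons overlaps a coding
#'   gene's exon (isoform exon union), sense/antisense by strand match with
#'   the anchor gene;
#' * `intronic_sense` / `intronic_antisense`: no exon contact, but its span
#'   overlaps a coding gene's span (min start to max end over isoforms) by at
#'   least 1 bp;
#' * `intergenic`: no overlap with any coding gene;
#' * `unknown`: the lncRNA's transcriptional direction is unknown, whatever
#'   its location.
#'
#' Exon contact takes precedence over intronic containment when a transcript
#' touches several genes.  The anchor gene is the gene with maximal overlap
#' (exonic bp for exonic calls, span bp otherwise), ties broken by
#' lexicographically smallest gene id.
#'
#' @param lnc A [transcript_set()] of lncRNA transcripts.
#' @param coding A [transcript_set()] of coding-gene transcripts; every gene
#'   must have a known strand.
#' @return Data frame: `transcript_id`, `lnc_class`, `anchor_gene_id`,
#'   `overlap_bp`.
#' @examples
#' coding <- transcript_set(data.frame(
#'   transcript_id = "m1", gene_id = "g1", source = "ucsc", chrom = "chr2L",
#'   start = c(1000, 4500), end = c(1500, 5000), strand = "+"))
#' lnc <- transcript_set(data.frame(
#'   transcript_id = "l1", gene_id = "l1", source = "novel", chrom = "chr2L",
#'   start = 2000, end = 2500, strand = "-"))
#' classify_transcripts(lnc, coding)$lnc_class  # intronic_antisense
#' @export
classify_transcripts <- function(lnc, coding) {
  stopifnot(inherits(lnc, "transcript_set"),
            inherits(coding, "transcript_set"))
  genes <- gene_table(coding)
  if (any(genes$strand == "*")) {
    stop("coding genes with unknown strand: ",
         paste(genes$gene_id[genes$strand == "*"], collapse = ", "))
  }
  gene_exons <- split(coding$exons, coding$exons$gene_id)

  out <- lapply(lnc$tx$transcript_id, function(id) {
    t <- lnc$tx[lnc$tx$transcript_id == id, ]
    e <- .tx_exons(lnc, id)
    near <- genes[genes$chrom == t$chrom & genes$start < t$end &
                    genes$end > t$start, , drop = FALSE]
    cls <- "intergenic"; anchor <- NA_character_; ov <- 0
    if (nrow(near)) {
      exon_bp <- vapply(near$gene_id, function(g) {
        .intersection_bp(e, gene_exons[[g]])
      }, numeric(1))
      if (any(exon_bp > 0)) {
        hit <- which(exon_bp == max(exon_bp))
        hit <- hit[order(near$gene_id[hit])][1L]
        anchor <- near$gene_id[hit]; ov <- exon_bp[hit]
        cls <- if (t$strand == near$strand[hit]) "exonic_sense"
               else "exonic_antisense"
      } else {
        span_bp <- pmin(t$end, near$end) - pmax(t$start, near$start)
        hit <- which(span_bp == max(span_bp))
        hit <- hit[order(near$gene_id[hit])][1L]
        anchor <- near$gene_id[hit]; ov <- span_bp[hit]
        cls <- if (t$strand == near$strand[hit]) "intronic_sense"
               else "intronic_antisense"
      }
    }
    if (t$strand == "*") cls <- "unknown"
    data.frame(transcript_id = id, lnc_class = cls,
               anchor_gene_id = anchor, overlap_bp = as.numeric(ov),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(
    data.frame(transcript_id = character(), lnc_class = character(),
               anchor_gene_id = character(), overlap_bp = numeric(),
               stringsAsFactors = FALSE))))
  rownames(res) <- NULL
  res
}

#' Assign transcriptional direction from stranded evidence
#'
#' Combines strand calls from stranded assemblies: if all non-unknown calls
#' agree the common strand is returned; conflicting calls, or no calls at
#' all, yield unknown.
#'
#' @param calls Character vector of strand values (`"+"`, `"-"`, `"*"`).
#' @return A single strand value.
#' @examples
#' assign_direction(c("+", "+", "+"))  # "+"
#' assign_direction(c("+", "-"))       # "*"
#' @export
assign_direction <- function(calls) {
  stopifnot(all(calls %in% c("+", "-", "*")))
  u <- unique(calls[calls != "*"])
  if (length(u) == 1L) u else "*"
}

#' Exon-count histogram of a transcript set
#'
#' @param ts A non-empty [transcript_set()].
#' @return Data frame: `exon_count`, `n`, `fraction` (fractions sum to 1).
#' @export
summarize_exon_counts <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  if (nrow(ts$tx) == 0L) stop("cannot summarize an empty transcript set")
  tab <- table(ts$tx$n_exons)
  data.frame(exon_count = as.integer(names(tab)),
             n = as.integer(tab),
             fraction = as.integer(tab) / nrow(ts$tx))
}
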