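#' Transcript sets
#'
#' The universal record flowing through every pipeline stage: a set of
#' stranded, exon-structured transcript models with source provenance.
#' Constructed from an exon table; the transcript-level table (span, exonic
#' length, exon count) is always recomputed from the exons, which are the
#' single source of truth.
#'
#' @param exons Data frame with columns `transcript_id`, `gene_id`, `source`,
#'   `chrom`, `start`, `end`, `strand` (0-based half-open exon coordinates).
#'   `gene_id` defaults to `transcript_id` and `source` to `"novel"` when the
#'   columns are absent.
#' @return An object of class `"transcript_set"`: a list with `$tx` (one row
#'   per transcript: `transcript_id`, `gene_id`, `source`, `chrom`, `strand`,
#'   `start`, `end`, `length`, `n_exons`) and `$exons` (the validated,
#'   per-transcript-sorted exon table).
#' @examples
#' ts <- transcript_set(data.frame(
#'   transcript_id = "t1", gene_id = "g1", source = "flybase",
#'   chrom = "chr2L", start = c(0, 500), end = c(200, 800), strand = "+"))
#' ts$tx$length  # 500
#' @export
transcript_set <- function(exons) {
  if (is.null(exons)) {
    exons <- data.frame(transcript_id = character(), gene_id = character(),
                        source = character(), chrom = character(),
                        start = numeric(), end = numeric(),
                        strand = character(), stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(exons))
  if (!"gene_id" %in% names(exons)) exons$gene_id <- exons$transcript_id
  if (!"source" %in% names(exons)) exons$source <- "novel"
  need <- c("transcript_id", "gene_id", "source", "chrom", "start", "end",
            "strand")
  miss <- setdiff(need, names(exons))
  if (length(miss)) stop("exon table lacks columns: ", paste(miss, collapse = ", "))
  exons <- exons[need]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$source <- as.character(exons$source)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  validate_intervals(exons)
  if (nrow(exons) && !all(exons$source %in%
        c("flybase", "ucsc", "young", "brown", "novel"))) {
    stop("source must be one of flybase, ucsc, young, brown, novel")
  }
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  if (nrow(exons)) {
    sp <- split(seq_len(nrow(exons)), exons$transcript_id)
    tx_list <- lapply(sp, function(idx) {
      e <- exons[idx, , drop = FALSE]
      if (length(unique(e$chrom)) > 1L || length(unique(e$strand)) > 1L ||
          length(unique(e$gene_id)) > 1L || length(unique(e$source)) > 1L) {
        stop("transcript '", e$transcript_id[1L],
             "': exons disagree on chrom/strand/gene/source")
      }
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
        stop("transcript '", e$transcript_id[1L], "': exons overlap")
      }
      data.frame(transcript_id = e$transcript_id[1L],
                 gene_id = e$gene_id[1L], source = e$source[1L],
                 chrom = e$chrom[1L], strand = e$strand[1L],
                 start = min(e$start), end = max(e$end),
                 length = sum(e$end - e$start), n_exons = nrow(e),
                 stringsAsFactors = FALSE)
    })
    tx <- do.call(rbind, tx_list)
    rownames(tx) <- NULL
  } else {
    tx <- data.frame(transcript_id = character(), gene_id = character(),
                     source = character(), chrom = character(),
                     strand = character(), start = numeric(), end = numeric(),
                     length = numeric(), n_exons = integer(),
                     stringsAsFactors = FALSE)
  }
  structure(list(tx = tx, exons = exons), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$tx), "transcripts,",
      nrow(x$exons), "exons\n")
  if (nrow(x$tx)) {
    cat("  sources:",
        paste(sprintf("%s (%d)", names(table(x$tx$source)),
                      as.integer(table(x$tx$source))), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.transcript_set <- function(x) nrow(x$tx)

#' Subset a transcript set by transcript id
#'
#' @param ts A `transcript_set`.
#' @param ids Transcript ids to keep (order and duplicates ignored).
#' @return A `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  stopifnot(inherits(ts, "transcript_set"))
  transcript_set(ts$exons[ts$exons$transcript_id %in% ids, , drop = FALSE])
}

#' Combine transcript sets
#'
#' @param ... `transcript_set` objects; transcript ids must not collide.
#' @return A single `transcript_set`.
#' @export
combine_transcripts <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, logical(1), "transcript_set")))
  exons <- do.call(rbind, lapply(sets, `[[`, "exons"))
  ids <- unlist(lapply(sets, function(s) s$tx$transcript_id))
  if (anyDuplicated(ids)) {
    stop("transcript ids collide across sets: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  transcript_set(exons)
}

# Exon rows of one transcript.
.tx_exons <- function(ts, id) {
  ts$exons[ts$exons$transcript_id == id, , drop = FALSE]
}

# Locus signature: identical chrom, strand, span and exon boundary chain.
.locus_signature <- function(ts) {
  if (nrow(ts$tx) == 0L) return(character())
  sig <- vapply(ts$tx$transcript_id, function(id) {
    e <- .tx_exons(ts, id)
    paste0(e$chrom[1L], e$strand[1L], ":",
           paste(e$start, e$end, sep = "-", collapse = ","))
  }, character(1))
  names(sig) <- ts$tx$transcript_id
  sig
}

#' Gene-level table of a transcript set
#'
#' Gene span is the min-start/max-end over the gene's isoforms; gene exons are
#' the isoform exon union.
#'
#' @param ts A `transcript_set`.
#' @return Data frame with one row per gene: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `n_tx`.
#' @export
gene_table <- function(ts) {
  stopifnot(inherits(ts, "transcript_set"))
  tx <- ts$tx
  if (nrow(tx) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), n_tx = integer(),
                      stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(tx)), tx$gene_id)
  out <- lapply(sp, function(idx) {
    g <- tx[idx, , drop = FALSE]
    if (length(unique(g$chrom)) > 1L) {
      stop("gene '", g$gene_id[1L], "': transcripts on different chromosomes")
    }
    st <- unique(g$strand)
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               strand = if (length(st) == 1L) st else "*",
               start = min(g$start), end = max(g$end), n_tx = nrow(g),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
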