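#' Truncation status of a transcript
#'
#' A large fraction of reference transcripts do not extend to the true
#' transcription start or end. Two sources of evidence are used: the explicit
#' Ensembl tags `cds_start_NF` / `cds_end_NF` (CDS start/end not found), and
#' biotypes whose models routinely end abruptly inside exons
#' (`retained_intron`, `processed_transcript`, `nonsense_mediated_decay`),
#' which are treated as truncated at both ends.
#'
#' @param t a [transcript_model()].
#' @return List with logical fields `start_truncated` and `end_truncated`,
#'   in transcript 5'->3' orientation.
#' @export
classify_truncation <- function(t) {
  both <- t$biotype %in% truncating_biotypes()
  list(
    start_truncated = both || "cds_start_NF" %in% t$tags,
    end_truncated = both || "cds_end_NF" %in% t$tags
  )
}

truncating_biotypes <- function() {
  c("retained_intron", "processed_transcript", "nonsense_mediated_decay")
}

#' Pick the extension template of a gene
#'
#' The template used to repair truncated transcripts is the longest (summed
#' exon length) transcript carrying the GENCODE `basic` tag; if no transcript
#' is tagged `basic`, the longest of all transcripts. Ties break to the
#' lexicographically smallest transcript id.
#'
#' @param g a [gene_model()].
#' @return A `txe_transcript`.
#' @export
select_template <- function(g) {
  txs <- g$transcripts
  basic <- Filter(function(t) "basic" %in% t$tags, txs)
  pool <- if (length(basic)) basic else txs
  lens <- vapply(pool, spliced_length, numeric(1))
  ids <- vapply(pool, function(t) t$transcript_id, character(1))
  best <- which(lens == max(lens))
  pool[[best[order(ids[best])[1L]]]]
}

#' Extend a truncated transcript using a template
#'
#' Repairs a transcript flagged as truncated by copying exons from the gene's
#' template transcript: at a truncated end, all template exons lying strictly
#' beyond the transcript's terminal exon (in transcript orientation) are
#' added, and if the terminal exon falls inside a template exon its outer
#' boundary is stretched to the template exon's boundary. Internal exons are
#' never altered, so the original exon chain survives as a subsequence, and
#' the operation is idempotent. If the template is itself truncated at the
#' required end, that end is left untouched with a warning.
#'
#' @param t transcript to repair.
#' @param template template transcript (same gene and strand).
#' @param status truncation status of `t`, from [classify_truncation()];
#'   recomputed when `NULL`.
#' @return The repaired `txe_transcript`; `cds_start_NF`/`cds_end_NF` tags
#'   are dropped and a truncation-marking biotype is reset to
#'   `protein_coding`, so [classify_truncation()] reports the result complete.
#' @export
extend_transcript <- function(t, template, status = NULL) {
  stopifnot(t$gene_id == template$gene_id, t$strand == template$strand)
  if (is.null(status)) status <- classify_truncation(t)
  tmpl_status <- classify_truncation(template)
  ex <- t$exons
  plus <- t$strand == "+"

  # 5' end in transcript orientation
  if (status$start_truncated) {
    if (tmpl_status$start_truncated) {
      warning("template is itself 5'-truncated; ", t$transcript_id,
              " left unextended at its 5' end")
    } else {
      ex <- extend_one_end(ex, template$exons, five_prime = TRUE, plus = plus,
                           tx_id = t$transcript_id)
    }
  }
  if (status$end_truncated) {
    if (tmpl_status$end_truncated) {
      warning("template is itself 3'-truncated; ", t$transcript_id,
              " left unextended at its 3' end")
    } else {
      ex <- extend_one_end(ex, template$exons, five_prime = FALSE, plus = plus,
                           tx_id = t$transcript_id)
    }
  }

  transcript_model(
    transcript_id = t$transcript_id, gene_id = t$gene_id, chrom = t$chrom,
    strand = t$strand, exons = ex,
    biotype = if (t$biotype %in% truncating_biotypes()) "protein_coding" else t$biotype,
    tags = setdiff(t$tags, c("cds_start_NF", "cds_end_NF"))
  )
}

# One-sided extension in genomic coordinates. `five_prime` refers to
# transcript orientation; on the minus strand the 5' end is the genomic right.
extend_one_end <- function(ex, tex, five_prime, plus, tx_id) {
  left_end <- (five_prime && plus) || (!five_prime && !plus)
  if (left_end) {
    term <- 1L
    f <- ex[term, ]
    cont <- which(tex$start <= f$start & tex$end >= f$end)
    if (length(cont)) {
      ex$start[term] <- tex$start[cont[1L]]
    } else if (any(tex$start < f$end & tex$end > f$start)) {
      warning("terminal exon of ", tx_id,
              " partially overlaps a template exon; outer boundary kept")
    }
    add <- tex[tex$end <= ex$start[term], , drop = FALSE]
    exon_table(c(add$start, ex$start), c(add$end, ex$end))
  } else {
    term <- nrow(ex)
    f <- ex[term, ]
    cont <- which(tex$start <= f$start & tex$end >= f$end)
    if (length(cont)) {
      ex$end[term] <- tex$end[cont[1L]]
    } else if (any(tex$start < f$end & tex$end > f$start)) {
      warning("terminal exon of ", tx_id,
              " partially overlaps a template exon; outer boundary kept")
    }
    add <- tex[tex$start >= ex$end[term], , drop = FALSE]
    exon_table(c(ex$start, add$start), c(ex$end, add$end))
  }
}
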