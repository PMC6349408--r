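#' Transcript and gene models
#'
#' A transcript model is an ordered exon chain on one chromosome and strand,
#' together with its biotype and the Ensembl transcript tags (`basic`,
#' `cds_start_NF`, `cds_end_NF`, ...) that drive truncation repair. A gene
#' model is the set of transcript models sharing one `gene_id`; transcripts
#' of a gene must agree on chromosome and strand (genes violating this are
#' rejected rather than silently split).
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons an exon table (see [exon_table()]), 0-based half-open.
#' @param biotype transcript biotype, e.g. `"protein_coding"`.
#' @param tags character vector of transcript tags.
#' @return `transcript_model()` returns a `txe_transcript`; `gene_model()`
#'   a `txe_gene`.
#' @examples
#' tx <- transcript_model("T1", "G1", "chr1", "+", exon_table(c(0, 100), c(50, 150)))
#' spliced_length(tx)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons,
                             biotype = "protein_coding", tags = character()) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            is.character(gene_id), length(gene_id) == 1L,
            nzchar(chrom))
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-'")
  }
  exons <- if (is.data.frame(exons)) exon_table(exons$start, exons$end) else exons
  if (nrow(exons) < 1L) stop("transcript must have at least one exon")
  structure(
    list(
      transcript_id = transcript_id,
      gene_id = gene_id,
      chrom = chrom,
      strand = strand,
      exons = exons,
      biotype = biotype,
      tags = unique(as.character(tags))
    ),
    class = "txe_transcript"
  )
}

#' @rdname transcript_model
#' @param transcripts list of `txe_transcript` objects sharing `gene_id`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate transcript_id within gene ", gene_id, ": ",
         paste(ids[duplicated(ids)], collapse = ", "))
  }
  if (!all(vapply(transcripts, function(t) t$gene_id, character(1)) == gene_id)) {
    stop("all transcripts must carry gene_id ", gene_id)
  }
  chroms <- unique(vapply(transcripts, function(t) t$chrom, character(1)))
  if (length(chroms) != 1L) {
    stop("gene ", gene_id, " spans multiple chromosomes: ",
         paste(chroms, collapse = ", "))
  }
  strands <- unique(vapply(transcripts, function(t) t$strand, character(1)))
  if (length(strands) != 1L) {
    stop("gene ", gene_id, " has transcripts on both strands")
  }
  names(transcripts) <- ids
  structure(
    list(gene_id = gene_id, chrom = chroms, strand = strands,
         transcripts = transcripts),
    class = "txe_gene"
  )
}

#' @rdname transcript_model
#' @param t a `txe_transcript`.
#' @export
spliced_length <- function(t) sum(exon_widths(t$exons))

#' @export
print.txe_transcript <- function(x, ...) {
  cat(sprintf("<txe_transcript> %s (%s) %s:%s, %d exons, %d nt, tags: %s\n",
              x$transcript_id, x$biotype, x$chrom, x$strand,
              nrow(x$exons), spliced_length(x),
              if (length(x$tags)) paste(x$tags, collapse = ",") else "-"))
  invisible(x)
}

#' @export
print.txe_gene <- function(x, ...) {
  cat(sprintf("<txe_gene> %s %s:%s, %d transcripts\n",
              x$gene_id, x$chrom, x$strand, length(x$transcripts)))
  invisible(x)
}

# Exons ordered 5'->3' in transcript orientation (reversed for minus strand).
transcript_order <- function(exons, strand) {
  if (strand == "-") exons[rev(seq_len(nrow(exons))), , drop = FALSE] else exons
}
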