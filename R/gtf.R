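#' Read Ensembl-dialect GTF transcript models
#'
#' Parses exon features of a GTF file into gene models. Attributes are read
#' from the 9th column in the Ensembl dialect (`key "value";` pairs); the
#' repeated `tag` attribute is collected into the transcript's tag set
#' (Ensembl marks truncated transcripts with `cds_start_NF` / `cds_end_NF`
#' tags there, and this information is absent from biomart exports, so the
#' GTF is the authoritative source). Coordinates are converted from the GTF
#' 1-based inclusive convention to the internal 0-based half-open one.
#'
#' @param path path to a GTF file.
#' @return Named list of [gene_model()] objects, one per `gene_id`.
#' @details Exon line order does not matter: exons are sorted by start.
#'   Malformed lines raise errors naming the line number. A transcript_id
#'   appearing under two different gene_ids (e.g. pseudo-autosomal copies)
#'   is rejected.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(list())

  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop("GTF line ", bad, ": expected 9 tab-separated columns, found ",
         nf[which(nf != 9L)[1L]])
  }
  feat <- vapply(fields, `[[`, character(1), 3L)
  exon_i <- which(feat == "exon")
  if (length(exon_i) == 0L) return(list())

  recs <- vector("list", length(exon_i))
  for (j in seq_along(exon_i)) {
    f <- fields[[exon_i[j]]]
    line_no <- idx[exon_i[j]]
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) {
      stop("GTF line ", line_no, ": non-integer coordinates")
    }
    if (end < start) {
      stop("GTF line ", line_no, ": exon end < start")
    }
    if (!f[7L] %in% c("+", "-")) {
      stop("GTF line ", line_no, ": strand must be '+' or '-'")
    }
    at <- parse_gtf_attributes(f[9L], line_no)
    if (is.null(at$gene_id) || is.null(at$transcript_id)) {
      stop("GTF line ", line_no, ": exon feature lacks gene_id or transcript_id")
    }
    recs[[j]] <- list(
      chrom = f[1L], start = start, end = end, strand = f[7L],
      gene_id = at$gene_id, transcript_id = at$transcript_id,
      biotype = at$biotype, tags = at$tags
    )
  }

  tx_ids <- vapply(recs, `[[`, character(1), "transcript_id")
  gene_of_tx <- vapply(recs, `[[`, character(1), "gene_id")
  tx_gene <- tapply(gene_of_tx, tx_ids, function(g) unique(g), simplify = FALSE)
  multi <- names(tx_gene)[lengths(tx_gene) > 1L]
  if (length(multi)) {
    stop("transcript_id used by multiple genes (not supported): ",
         paste(multi, collapse = ", "))
  }

  genes <- list()
  for (gid in unique(gene_of_tx)) {
    g_recs <- recs[gene_of_tx == gid]
    g_tx <- vapply(g_recs, `[[`, character(1), "transcript_id")
    txs <- lapply(unique(g_tx), function(tid) {
      rr <- g_recs[g_tx == tid]
      chroms <- unique(vapply(rr, `[[`, character(1), "chrom"))
      if (length(chroms) != 1L) {
        stop("transcript ", tid, " spans multiple chromosomes: ",
             paste(chroms, collapse = ", "))
      }
      strands <- unique(vapply(rr, `[[`, character(1), "strand"))
      if (length(strands) != 1L) {
        stop("transcript ", tid, " has exons on both strands")
      }
      gstart <- vapply(rr, `[[`, integer(1), "start")
      gend <- vapply(rr, `[[`, integer(1), "end")
      conv <- gtf_to_internal(gstart, gend)
      biotypes <- unlist(lapply(rr, `[[`, "biotype"))
      tags <- unique(unlist(lapply(rr, `[[`, "tags")))
      transcript_model(
        transcript_id = tid, gene_id = gid, chrom = chroms, strand = strands,
        exons = exon_table(conv$start, conv$end),
        biotype = if (length(biotypes)) biotypes[[1L]] else "protein_coding",
        tags = if (is.null(tags)) character() else tags
      )
    })
    genes[[gid]] <- gene_model(gid, txs)
  }
  genes
}

parse_gtf_attributes <- function(attr, line_no) {
  attr <- trimws(attr)
  if (!nzchar(attr)) {
    stop("GTF line ", line_no, ": empty attribute column")
  }
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_]*)\\s+"([^"]*)"', attr, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    stop("GTF line ", line_no, ": malformed attribute column: ", attr)
  }
  pieces <- regmatches(attr, list(m))[[1L]]
  keys <- sub('^([A-Za-z_][A-Za-z0-9_]*)\\s+".*$', "\\1", pieces)
  vals <- sub('^[A-Za-z_][A-Za-z0-9_]*\\s+"([^"]*)".*$', "\\1", pieces)
  # residual text outside recognised key "value" pairs (separators aside)
  leftover <- gsub('([A-Za-z_][A-Za-z0-9_]*)\\s+"[^"]*"\\s*;?\\s*', "", attr, perl = TRUE)
  if (nzchar(trimws(leftover))) {
    stop("GTF line ", line_no, ": malformed attribute column near '",
         trimws(leftover), "'")
  }
  biotype <- vals[match("transcript_biotype", keys)]
  if (is.na(biotype)) biotype <- vals[match("gene_biotype", keys)]
  list(
    gene_id = if ("gene_id" %in% keys) vals[match("gene_id", keys)] else NULL,
    transcript_id = if ("transcript_id" %in% keys) vals[match("transcript_id", keys)] else NULL,
    biotype = if (is.na(biotype)) NULL else biotype,
    tags = vals[keys == "tag"]
  )
}

#' Write transcriptional events as GTF
#'
#' Serialises event records to an Ensembl-dialect GTF with one `transcript`
#' feature and one `exon` feature per exon; the event identifier is stored as
#' `transcript_id` so standard quantifiers treat each event as a transcript.
#' `read_gtf(write_gtf(x))` is the identity on exon structures.
#'
#' @param events list of event records (as produced by [construct_events()],
#'   elements with fields `event_id`, `gene_id`, `chrom`, `strand`, `exons`).
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(events, path) {
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  writeLines("#!genome-build synthetic", con)
  for (ev in events) {
    g <- internal_to_gtf(ev$exons$start, ev$exons$end)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', ev$gene_id, ev$event_id)
    writeLines(sprintf("%s\ttxevents\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                       ev$chrom, min(g$start), max(g$end), ev$strand, attrs), con)
    writeLines(sprintf("%s\ttxevents\texon\t%d\t%d\t.\t%s\t.\t%s",
                       ev$chrom, g$start, g$end, ev$strand, attrs), con)
  }
  invisible(path)
}

#' Event identifier grammar
#'
#' Event identifiers follow
#' `<gene_id>.grp_<k>.<upstream|contained|downstream>.<transcript_id>`,
#' naming the gene, construction group, event type and the representative
#' transcript of the distinct structure. `parse_event_id()` inverts
#' `make_event_id()` even when gene or transcript identifiers contain dots.
#'
#' @param gene_id,transcript_id identifiers.
#' @param group_index construction group (1 or 2).
#' @param event_type one of `"upstream"`, `"contained"`, `"downstream"`.
#' @return `make_event_id()` a string; `parse_event_id()` a list with fields
#'   `gene_id`, `group_index`, `event_type`, `transcript_id`.
#' @export
make_event_id <- function(gene_id, group_index, event_type, transcript_id) {
  stopifnot(event_type %in% c("upstream", "contained", "downstream"))
  sprintf("%s.grp_%d.%s.%s", gene_id, as.integer(group_index), event_type,
          transcript_id)
}

#' @rdname make_event_id
#' @param event_id a string produced by `make_event_id()`.
#' @export
parse_event_id <- function(event_id) {
  m <- regmatches(
    event_id,
    regexec("^(.+)\\.grp_([0-9]+)\\.(upstream|contained|downstream)\\.(.+)$",
            event_id)
  )[[1L]]
  if (length(m) != 5L) stop("not a valid event id: ", event_id)
  list(gene_id = m[2L], group_index = as.integer(m[3L]), event_type = m[4L],
       transcript_id = m[5L])
}

#' Extract the spliced sequence of an event
#'
#' Concatenates the exon sequences of an event in genomic order and
#' reverse-complements the concatenation for minus-strand events, yielding
#' the mature (spliced) sequence suitable for building a quantification
#' index. Requires the Biostrings package.
#'
#' @param event an event record (fields `chrom`, `strand`, `exons`).
#' @param genome a named `Biostrings::DNAStringSet` (or any list-like of
#'   `XString`s indexable by chromosome name).
#' @return A character scalar; its length equals the summed exon widths.
#' @export
extract_event_sequence <- function(event, genome) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("extract_event_sequence requires the Biostrings package")
  }
  if (!event$chrom %in% names(genome)) {
    stop("chromosome absent from genome: ", event$chrom)
  }
  chrom_seq <- genome[[event$chrom]]
  if (any(event$exons$end > length(chrom_seq))) {
    stop("exon beyond chromosome end on ", event$chrom)
  }
  parts <- vapply(seq_len(nrow(event$exons)), function(i) {
    as.character(Biostrings::subseq(
      chrom_seq,
      start = event$exons$start[i] + 1L,
      end = event$exons$end[i]
    ))
  }, character(1))
  s <- paste(parts, collapse = "")
  if (event$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}
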