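#' Construct alternative transcriptional events on a scaffold
#'
#' Uses the group's shared exons as a scaffold and assigns each member
#' transcript's non-scaffold ("variable") exons to one of three independent
#' event types by position relative to the scaffold, in transcript
#' orientation: entirely 5' of the 5'-most scaffold exon -> `upstream`
#' (alternative promoter); entirely 3' of the 3'-most scaffold exon ->
#' `downstream` (alternative 3' end); anything else, including variable exons
#' partially overlapping a boundary scaffold exon, -> `contained` (internal
#' exons). An event of a given type is the scaffold plus the member's
#' variable exons of that type; members producing identical exon chains are
#' collapsed to one event represented by the lexicographically smallest
#' transcript id, and an event set is emitted only when at least two distinct
#' events remain (a singleton event would have constant relative usage 1).
#'
#' @param group a group from [select_transcript_groups()].
#' @param members list of the group's member `txe_transcript`s (a superset is
#'   accepted; non-members are ignored).
#' @return List of up to three `txe_event_set` objects.
#' @export
construct_events <- function(group, members) {
  ids <- vapply(members, function(t) t$transcript_id, character(1))
  members <- members[ids %in% group$member_ids]
  ids <- ids[ids %in% group$member_ids]
  stopifnot(length(members) >= 2L, nrow(group$scaffold) >= 1L)
  members <- members[order(ids)]
  chrom <- members[[1L]]$chrom
  strand <- members[[1L]]$strand
  scaffold <- group$scaffold
  skeys <- exon_keys(scaffold)
  plus <- strand == "+"
  s_first <- if (plus) scaffold[which.min(scaffold$start), ] else scaffold[which.max(scaffold$end), ]
  s_last <- if (plus) scaffold[which.max(scaffold$end), ] else scaffold[which.min(scaffold$start), ]

  per_type <- list(upstream = list(), contained = list(), downstream = list())
  for (t in members) {
    var <- t$exons[!exon_keys(t$exons) %in% skeys, , drop = FALSE]
    if (nrow(var)) {
      type <- ifelse(
        if (plus) var$end <= s_first$start else var$start >= s_first$end,
        "upstream",
        ifelse(if (plus) var$start >= s_last$end else var$end <= s_last$start,
               "downstream", "contained")
      )
    } else {
      type <- character()
    }
    for (ty in names(per_type)) {
      v <- var[type == ty, , drop = FALSE]
      per_type[[ty]][[t$transcript_id]] <- combine_exons(scaffold, v)
    }
  }

  sets <- list()
  for (ty in names(per_type)) {
    distinct <- dedup_event_chains(per_type[[ty]])
    if (length(distinct) < 2L) next
    events <- lapply(names(distinct), function(rep_id) {
      list(
        event_id = make_event_id(group$gene_id, group$group_index, ty, rep_id),
        gene_id = group$gene_id,
        chrom = chrom,
        strand = strand,
        event_type = ty,
        group_index = group$group_index,
        transcript_id = rep_id,
        exons = distinct[[rep_id]]
      )
    })
    sets[[length(sets) + 1L]] <- structure(
      list(gene_id = group$gene_id, group_index = group$group_index,
           event_type = ty, chrom = chrom, strand = strand,
           scaffold = scaffold, events = events, masked = FALSE),
      class = "txe_event_set"
    )
  }
  sets
}

# Scaffold plus variable exons as one chain. Exact disjoint union in the
# common case; a variable exon partially overlapping a scaffold exon
# (alternative splice site at a scaffold boundary) is merged positionally.
combine_exons <- function(scaffold, v) {
  s <- c(scaffold$start, v$start)
  e <- c(scaffold$end, v$end)
  tryCatch(exon_table(s, e), error = function(err) {
    interval_union(data.frame(start = s, end = e))
  })
}

# Collapse identical exon chains; names are representative transcript ids
# (the lexicographically smallest id mapping to each distinct chain).
dedup_event_chains <- function(chains) {
  chains <- chains[order(names(chains))]
  sig <- vapply(chains, function(ex) paste(exon_keys(ex), collapse = ";"),
                character(1))
  chains[!duplicated(sig)]
}

#' @export
print.txe_event_set <- function(x, ...) {
  cat(sprintf("<txe_event_set> %s grp_%d %s: %d events%s\n", x$gene_id,
              x$group_index, x$event_type, length(x$events),
              if (x$masked) " (masked)" else ""))
  invisible(x)
}

#' Mask internal variation in promoter and 3' end events
#'
#' Promoter (`upstream`) and 3'-end (`downstream`) events may still differ at
#' exons other than their terminal one, in which case relative usage of the
#' events would also capture splicing changes. Masking removes that
#' ambiguity: each event keeps its own terminal exon (the first exon in
#' transcript orientation for upstream events, the last for downstream), and
#' every other exon position is replaced by the positional union of the
#' non-terminal exons across all events of the set, so the masked events are
#' exon-identical away from their terminal exon. Internal-exon (`contained`)
#' event sets pass through unchanged. Masking can merge events; duplicates
#' are collapsed again afterwards. The operation is idempotent.
#'
#' @param es a `txe_event_set` from [construct_events()].
#' @return The masked `txe_event_set` (`masked` flag set for
#'   upstream/downstream sets). The returned set can contain a single event
#'   when masking merges all structures; [build_gene_events()] drops such
#'   sets.
#' @export
mask_internal_variation <- function(es) {
  stopifnot(inherits(es, "txe_event_set"))
  if (es$event_type == "contained") {
    return(es)
  }
  plus <- es$strand == "+"
  # terminal exon index in genomic coordinates for each event
  terminal_row <- function(ex) {
    promoter_side <- es$event_type == "upstream"
    left <- (promoter_side && plus) || (!promoter_side && !plus)
    if (left) 1L else nrow(ex)
  }
  rests <- lapply(es$events, function(ev) {
    i <- terminal_row(ev$exons)
    ev$exons[-i, , drop = FALSE]
  })
  m <- interval_union(do.call(rbind, rests))
  chains <- list()
  for (ev in es$events) {
    i <- terminal_row(ev$exons)
    term <- ev$exons[i, , drop = FALSE]
    chains[[ev$transcript_id]] <- interval_union(rbind(term, m))
  }
  distinct <- dedup_event_chains(chains)
  es$events <- lapply(names(distinct), function(rep_id) {
    list(
      event_id = make_event_id(es$gene_id, es$group_index, es$event_type, rep_id),
      gene_id = es$gene_id, chrom = es$chrom, strand = es$strand,
      event_type = es$event_type, group_index = es$group_index,
      transcript_id = rep_id, exons = distinct[[rep_id]]
    )
  })
  es$masked <- TRUE
  es
}

#' Build all event sets of a gene
#'
#' Full pipeline for one gene: classify and repair truncated transcripts
#' against the gene's template ([select_template()]), select up to
#' `max_groups` transcript groups, construct the per-group event sets, and
#' (optionally) mask internal variation of promoter and 3'-end events. Up to
#' six event sets per gene can result (two groups x three event types). The
#' pipeline is deterministic and invariant to transcript input order.
#'
#' @param g a [gene_model()].
#' @param max_groups maximum number of transcript groups (default 2).
#' @param mask logical; apply [mask_internal_variation()] to upstream and
#'   downstream event sets (default `TRUE`). Skipping discovers more
#'   associations at the cost of promoter/3'-end events possibly tagging
#'   splicing changes.
#' @return List of `txe_event_set` objects, each with >= 2 distinct events.
#' @export
build_gene_events <- function(g, max_groups = 2L, mask = TRUE) {
  template <- select_template(g)
  repaired <- lapply(g$transcripts, function(t) {
    st <- classify_truncation(t)
    if (st$start_truncated || st$end_truncated) {
      extend_transcript(t, template, st)
    } else {
      t
    }
  })
  g2 <- gene_model(g$gene_id, repaired)
  groups <- select_transcript_groups(g2, max_groups = max_groups)
  sets <- list()
  for (grp in groups) {
    for (es in construct_events(grp, g2$transcripts[grp$member_ids])) {
      if (mask) es <- mask_internal_variation(es)
      if (length(es$events) >= 2L) sets[[length(sets) + 1L]] <- es
    }
  }
  sets
}

#' Event metadata table
#'
#' Flattens event sets into the tab-separable metadata table used by the
#' usage-quantification step (one row per event).
#'
#' @param event_sets list of `txe_event_set` objects.
#' @return data.frame with columns `event_id`, `gene_id`, `group_index`,
#'   `event_type`, `n_exons`, `spliced_length`.
#' @export
event_meta_table <- function(event_sets) {
  rows <- lapply(event_sets, function(es) {
    do.call(rbind, lapply(es$events, function(ev) {
      data.frame(
        event_id = ev$event_id, gene_id = ev$gene_id,
        group_index = ev$group_index, event_type = ev$event_type,
        n_exons = nrow(ev$exons),
        spliced_length = sum(exon_widths(ev$exons)),
        stringsAsFactors = FALSE
      )
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(event_id = character(), gene_id = character(),
                      group_index = integer(), event_type = character(),
                      n_exons = integer(), spliced_length = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
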