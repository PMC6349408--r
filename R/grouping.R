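#' Select transcript groups sharing exons
#'
#' Some genes contain non-overlapping or very short transcripts, so events
#' cannot be built on a single scaffold covering every transcript. Instead,
#' transcripts are partitioned greedily into up to `max_groups` groups, each
#' with its own scaffold of exons shared (exact coordinates, both boundaries)
#' by every member: group 1 starts from the transcript pair with the largest
#' exon-set intersection and absorbs the remaining transcripts that share the
#' whole current scaffold, so it attains the maximal shared-exon count over
#' all transcript subsets while holding as many members as possible; group 2
#' is built the same way from the leftovers. Ties break to lexicographically
#' smallest transcript ids, so the result is invariant to input order.
#'
#' @param g a [gene_model()] whose transcripts have already been
#'   truncation-repaired (see [extend_transcript()]).
#' @param max_groups maximum number of groups (default 2).
#' @return List of groups, each a list with `gene_id`, `group_index`,
#'   `member_ids`, and `scaffold` (exon table of the shared exons). Genes
#'   yielding no pair with a shared exon return an empty list.
#' @export
select_transcript_groups <- function(g, max_groups = 2L) {
  key_sets <- lapply(g$transcripts, function(t) exon_keys(t$exons))
  remaining <- sort(names(key_sets))
  groups <- list()
  for (k in seq_len(max_groups)) {
    grp <- greedy_group(key_sets, remaining)
    if (is.null(grp)) break
    groups[[k]] <- list(
      gene_id = g$gene_id,
      group_index = k,
      member_ids = grp$members,
      scaffold = keys_to_exons(grp$scaffold)
    )
    remaining <- setdiff(remaining, grp$members)
  }
  groups
}

greedy_group <- function(key_sets, ids) {
  if (length(ids) < 2L) return(NULL)
  # seed: pair with maximal exact-exon intersection
  best_pair <- NULL
  best_size <- 0L
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq((i + 1L), length(ids))) {
      sz <- length(intersect(key_sets[[ids[i]]], key_sets[[ids[j]]]))
      if (sz > best_size) {
        best_size <- sz
        best_pair <- c(ids[i], ids[j])
      }
    }
  }
  if (best_size == 0L) return(NULL)
  members <- best_pair
  scaffold <- intersect(key_sets[[best_pair[1L]]], key_sets[[best_pair[2L]]])
  pool <- setdiff(ids, members)
  while (length(pool)) {
    sizes <- vapply(pool, function(id) length(intersect(scaffold, key_sets[[id]])),
                    integer(1))
    # absorb only transcripts that keep the scaffold intact: group 1 must
    # attain the maximal shared-exon count, with as many members as possible
    if (max(sizes) < length(scaffold)) break
    add <- pool[sizes == max(sizes)][1L] # pool is sorted: lexicographic tie-break
    scaffold <- intersect(scaffold, key_sets[[add]])
    members <- c(members, add)
    pool <- setdiff(pool, add)
  }
  list(members = sort(members), scaffold = scaffold)
}

#' Exhaustive scaffold-size optimum
#'
#' Reference search for the largest exact-coordinate exon intersection over
#' all transcript subsets of size two or more. Because an intersection can
#' only shrink as a subset grows, the optimum is attained by some pair, but
#' the search enumerates every subset regardless so it can serve as an
#' independent check of the greedy grouping heuristic on small genes.
#'
#' @param g a [gene_model()] with at most 15 transcripts.
#' @return Integer: maximal shared-exon count over subsets of size >= 2
#'   (0 when no pair shares an exon).
#' @export
scaffold_optimum <- function(g) {
  n <- length(g$transcripts)
  stopifnot(n <= 15L)
  if (n < 2L) return(0L)
  key_sets <- lapply(g$transcripts, function(t) exon_keys(t$exons))
  best <- 0L
  for (mask in seq_len(2L^n - 1L)) {
    idx <- which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < 2L) next
    inter <- Reduce(intersect, key_sets[idx])
    best <- max(best, length(inter))
  }
  best
}
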