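#' Import event-level abundance tables
#'
#' Reads the per-sample tab-separated abundance tables written by lightweight
#' transcript quantifiers (columns `Name`, `Length`, `EffectiveLength`,
#' `TPM`, `NumReads`) and assembles the TPM estimates into one features x
#' samples matrix, attaching the event metadata needed for relative-usage
#' normalisation.
#'
#' @param files named character vector of file paths; names are sample ids
#'   (basenames without extension are used when unnamed).
#' @param meta event metadata (data.frame with columns `event_id`, `gene_id`,
#'   `group_index`, `event_type`; see [event_meta_table()]).
#' @return A `txe_abundance`: list with `tpm` (matrix), `counts` (matrix of
#'   `NumReads`), `length` (vector) and `meta` (data.frame aligned to rows).
#' @export
import_abundance <- function(files, meta) {
  stopifnot(length(files) >= 1L)
  if (is.null(names(files)) || any(!nzchar(names(files)))) {
    names(files) <- sub("\\.[^.]*$", "", basename(files))
  }
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  tabs <- lapply(files, function(f) {
    tab <- utils::read.delim(f, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    missing_cols <- setdiff(required, colnames(tab))
    if (length(missing_cols)) {
      stop("abundance table ", f, " lacks columns: ",
           paste(missing_cols, collapse = ", "))
    }
    tab
  })
  ref <- sort(tabs[[1L]]$Name)
  for (i in seq_along(tabs)) {
    cur <- sort(tabs[[i]]$Name)
    if (!identical(ref, cur)) {
      diff <- c(setdiff(ref, cur), setdiff(cur, ref))
      stop("inconsistent feature sets across samples (sample ",
           names(files)[i], "): ", paste(unique(diff), collapse = ", "))
    }
  }
  feats <- tabs[[1L]]$Name
  unknown <- setdiff(feats, meta$event_id)
  if (length(unknown)) {
    stop("features absent from event metadata: ",
         paste(unknown, collapse = ", "))
  }
  tpm <- vapply(tabs, function(tab) tab$TPM[match(feats, tab$Name)],
                numeric(length(feats)))
  counts <- vapply(tabs, function(tab) tab$NumReads[match(feats, tab$Name)],
                   numeric(length(feats)))
  tpm <- matrix(tpm, nrow = length(feats),
                dimnames = list(feats, names(files)))
  counts <- matrix(counts, nrow = length(feats),
                   dimnames = list(feats, names(files)))
  if (any(tpm < 0)) stop("negative TPM values")
  structure(
    list(
      tpm = tpm,
      counts = counts,
      length = stats::setNames(tabs[[1L]]$Length, feats),
      meta = meta[match(feats, meta$event_id), , drop = FALSE]
    ),
    class = "txe_abundance"
  )
}

abundance_matrix <- function(tpm, meta) {
  stopifnot(is.matrix(tpm), all(rownames(tpm) %in% meta$event_id), all(tpm >= 0))
  structure(
    list(tpm = tpm, counts = NULL, length = NULL,
         meta = meta[match(rownames(tpm), meta$event_id), , drop = FALSE]),
    class = "txe_abundance"
  )
}

block_ids <- function(meta) {
  paste(meta$gene_id, meta$group_index, meta$event_type, sep = "|")
}

#' Relative usage of transcriptional events
#'
#' Divides each event's TPM estimate by the summed TPM of all events within
#' the same (gene, transcript group, event type) block, separately per
#' sample, so a value is the relative usage of one event compared with the
#' other events of the same type sharing the same scaffold. Block-samples
#' with a zero TPM total have no defined usage and are returned as `NA`
#' (excluded pairwise downstream, never imputed).
#'
#' @param a a `txe_abundance` from [import_abundance()].
#' @return A `txe_usage`: list with `usage` (matrix in `[0,1]` or `NA`) and
#'   `meta`.
#' @export
relative_usage <- function(a) {
  stopifnot(inherits(a, "txe_abundance"))
  blocks <- block_ids(a$meta)
  usage <- a$tpm
  for (b in unique(blocks)) {
    rows <- which(blocks == b)
    tot <- colSums(a$tpm[rows, , drop = FALSE])
    denom <- rep(tot, each = length(rows))
    u <- a$tpm[rows, , drop = FALSE] / matrix(denom, nrow = length(rows))
    u[, tot == 0] <- NA_real_
    usage[rows, ] <- u
  }
  structure(list(usage = usage, meta = a$meta), class = "txe_usage")
}

#' Expression filter at gene level
#'
#' Keeps genes whose mean gene-level TPM exceeds `threshold` in at least one
#' condition. Gene-level TPM is approximated from event-level estimates as
#' the summed TPM of one event-type block (the `contained` block when
#' present, otherwise the first available block), since events of one block
#' partition the gene's transcripts.
#'
#' @param a a `txe_abundance`.
#' @param condition_of named character vector mapping sample id -> condition;
#'   must cover every sample and every condition must have >= 1 sample.
#' @param threshold TPM threshold (default 1; strict inequality).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(a, condition_of, threshold = 1) {
  stopifnot(inherits(a, "txe_abundance"))
  samples <- colnames(a$tpm)
  if (!all(samples %in% names(condition_of))) {
    stop("samples without condition assignment: ",
         paste(setdiff(samples, names(condition_of)), collapse = ", "))
  }
  cond <- condition_of[samples]
  if (any(is.na(cond)) || length(unique(cond)) < 1L) stop("invalid condition map")
  empty <- setdiff(unique(condition_of), cond)
  if (length(empty)) {
    stop("condition without samples: ", paste(empty, collapse = ", "))
  }
  kept <- character()
  for (gid in unique(a$meta$gene_id)) {
    rows <- which(a$meta$gene_id == gid)
    sub_meta <- a$meta[rows, , drop = FALSE]
    btype <- if ("contained" %in% sub_meta$event_type) "contained" else sub_meta$event_type[1L]
    grp <- sub_meta$group_index[sub_meta$event_type == btype][1L]
    use <- rows[sub_meta$event_type == btype & sub_meta$group_index == grp]
    gene_tpm <- colSums(a$tpm[use, , drop = FALSE])
    cond_means <- tapply(gene_tpm, cond, mean)
    if (max(cond_means) > threshold) kept <- c(kept, gid)
  }
  kept
}

#' Rank-based inverse normal transform
#'
#' Maps each feature's defined values to standard-normal quantiles
#' (`qnorm((rank - 0.5) / n)`, ties averaged), the usual preparation of
#' proportion-valued phenotypes for linear association tests. Features
#' constant across samples have no rank information and are marked `NA`
#' throughout (excluded downstream).
#'
#' @param u a `txe_usage` or a numeric matrix (features x samples).
#' @return Object of the same kind with transformed values.
#' @export
inverse_normal_transform <- function(u) {
  mat <- if (inherits(u, "txe_usage")) u$usage else u
  out <- mat
  for (i in seq_len(nrow(mat))) {
    x <- mat[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 3L || length(unique(x[ok])) < 2L) {
      out[i, ] <- NA_real_
      next
    }
    r <- rank(x[ok], ties.method = "average")
    q <- stats::qnorm((r - 0.5) / sum(ok))
    out[i, ok] <- q - mean(q)
    out[i, !ok] <- NA_real_
  }
  if (inherits(u, "txe_usage")) {
    u$usage <- out
    u
  } else {
    out
  }
}
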