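#' Exon interval tables
#'
#' Exon chains are represented internally as data frames with integer columns
#' `start` and `end` in 0-based half-open coordinates (`start < end`), sorted
#' by `start`. GTF input/output converts to and from the 1-based inclusive
#' convention at the boundary; half-open coordinates keep interval arithmetic
#' (containment, unions, adjacency) free of +/-1 bookkeeping.
#'
#' @param start,end integer vectors of equal length (0-based half-open).
#' @return A validated, sorted exon data frame.
#' @export
exon_table <- function(start = integer(), end = integer()) {
  start <- as.integer(start)
  end <- as.integer(end)
  stopifnot(length(start) == length(end))
  if (any(is.na(start)) || any(is.na(end))) {
    stop("exon coordinates must be non-missing integers")
  }
  if (any(end <= start)) {
    stop("invalid exon interval: end <= start (half-open convention)")
  }
  ord <- order(start, end)
  ex <- data.frame(start = start[ord], end = end[ord])
  if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
    stop("exons overlap within one transcript")
  }
  ex
}

#' @rdname exon_table
#' @param ex an exon data frame.
#' @export
exon_widths <- function(ex) ex$end - ex$start

# Canonical string keys for exact-coordinate exon identity.
exon_keys <- function(ex) {
  if (nrow(ex) == 0L) return(character())
  paste0(ex$start, "-", ex$end)
}

keys_to_exons <- function(keys) {
  if (length(keys) == 0L) return(exon_table())
  parts <- strsplit(keys, "-", fixed = TRUE)
  exon_table(
    start = vapply(parts, function(p) as.integer(p[[1L]]), integer(1)),
    end = vapply(parts, function(p) as.integer(p[[2L]]), integer(1))
  )
}

# Merge a set of (possibly overlapping or duplicated) intervals into their
# positional union, returned as a sorted non-overlapping exon table.
interval_union <- function(ex) {
  if (nrow(ex) == 0L) return(exon_table())
  ord <- order(ex$start, ex$end)
  s <- ex$start[ord]
  e <- ex$end[ord]
  out_s <- s[1L]
  out_e <- e[1L]
  for (i in seq_along(s)[-1L]) {
    k <- length(out_s)
    if (s[i] <= out_e[k]) {
      out_e[k] <- max(out_e[k], e[i])
    } else {
      out_s <- c(out_s, s[i])
      out_e <- c(out_e, e[i])
    }
  }
  exon_table(out_s, out_e)
}

# TRUE where interval [s, e) overlaps any interval in `ex`.
overlaps_any <- function(s, e, ex) {
  if (nrow(ex) == 0L) return(rep(FALSE, length(s)))
  vapply(
    seq_along(s),
    function(i) any(s[i] < ex$end & e[i] > ex$start),
    logical(1)
  )
}

# Mirror exon coordinates around an arbitrary pivot; used for strand
# equivalence checks. Returns a valid exon table on the mirrored axis.
mirror_exons <- function(ex, pivot) {
  exon_table(start = pivot - ex$end, end = pivot - ex$start)
}

gtf_to_internal <- function(start, end) list(start = start - 1L, end = end)
internal_to_gtf <- function(start, end) list(start = start + 1L, end = end)
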