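# Shared fixture builders and independent oracles for the suite.

# Random gene structure: transcript 1 is a complete reference carrying the
# `basic` tag (the extension template); the others draw alternative
# promoters/3' ends, skipped exons, extra terminal-region exons and
# truncations at random. Kept within <= 6 transcripts and <= 10 exons.
random_gene_spec <- function(seed, strand = "+") {
  set.seed(seed)
  n_tx <- sample(2:6, 1)
  n_core <- sample(3:6, 1)
  txs <- list(tx_options(basic = TRUE))
  for (i in seq_len(n_tx - 1)) {
    trunc_start <- runif(1) < 0.15
    trunc_end <- !trunc_start && runif(1) < 0.15
    alt_first <- if (!trunc_start && runif(1) < 0.5) sample(1:2, 1) else NA
    alt_last <- if (!trunc_end && runif(1) < 0.5) sample(1:2, 1) else NA
    internal <- seq(2, n_core - 1)
    # a truncated transcript must keep >= 3 exons after losing its terminal
    can_skip <- n_core >= 4 || (!trunc_start && !trunc_end)
    skip <- if (can_skip && runif(1) < 0.4)
      internal[sample.int(length(internal), 1)]
    else integer()
    txs[[i + 1]] <- tx_options(
      alt_first = alt_first,
      skip = skip,
      alt_last = alt_last,
      upstream_extra = !trunc_start && runif(1) < 0.25,
      downstream_extra = !trunc_end && runif(1) < 0.25,
      truncate_start = trunc_start,
      truncate_end = trunc_end,
      basic = FALSE
    )
  }
  gene_structure_spec(txs, n_core_exons = n_core, strand = strand,
                      seed = seed + 1000L)
}

fig1c_spec <- function(seed = 7, strand = "+") {
  gene_structure_spec(
    transcripts = list(
      tx_options(alt_first = 1, alt_last = 1),
      tx_options(alt_first = 2, skip = 2, alt_last = 2)
    ),
    n_core_exons = 3, strand = strand, seed = seed
  )
}

# Independent exhaustive oracle for the largest shared-exon set over all
# transcript subsets of size >= 2 (no code shared with the greedy path).
oracle_scaffold_size <- function(gene) {
  txs <- gene$transcripts
  n <- length(txs)
  if (n < 2) return(0L)
  keysets <- lapply(txs, function(t) paste(t$exons$start, t$exons$end))
  best <- 0L
  for (size in 2:n) {
    for (idx in utils::combn(n, size, simplify = FALSE)) {
      shared <- Reduce(intersect, keysets[idx])
      best <- max(best, length(shared))
    }
  }
  best
}

# Independent check of the masked-terminal property: after deleting each
# event's terminal run of exons not shared by every event of the set, all
# events must coincide exactly.
masked_terminal_ok <- function(es) {
  if (es$event_type == "contained") return(TRUE)
  keys <- lapply(es$events, function(e) paste(e$exons$start, e$exons$end))
  shared <- Reduce(intersect, keys)
  from_5p <- (es$event_type == "upstream") == (es$strand == "+")
  cores <- lapply(keys, function(k) {
    if (!from_5p) k <- rev(k)
    i <- 1
    while (i <= length(k) && !(k[i] %in% shared)) i <- i + 1
    rest <- if (i > length(k)) character() else k[i:length(k)]
    if (!from_5p) rest <- rev(rest)
    rest
  })
  all(vapply(cores, function(k) identical(k, cores[[1]]), logical(1)))
}

# Scaffold containment: every event carries every scaffold exon exactly.
scaffold_contained_ok <- function(es) {
  skeys <- paste(es$scaffold$start, es$scaffold$end)
  all(vapply(es$events, function(e) {
    all(skeys %in% paste(e$exons$start, e$exons$end))
  }, logical(1)))
}

event_set_signature <- function(es) {
  chains <- sort(vapply(es$events, function(e) {
    paste(paste0(e$exons$start, "-", e$exons$end), collapse = ";")
  }, character(1)))
  paste(es$event_type, paste(chains, collapse = "|"))
}

write_gtf_text <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}
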