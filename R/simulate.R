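#' Specify a synthetic gene structure
#'
#' Describes a multi-transcript gene built around a chain of core exons
#' shared by all transcripts, with per-transcript deviations: an alternative
#' first exon (promoter slots 5' of the core), an extra exon between the
#' promoter slots and the core (`upstream_extra`, for exercising masking),
#' skipped internal core exons, and the symmetric features at the 3' end.
#' Transcripts can be deliberately truncated: `truncate_start` removes the
#' transcript's first exon and cuts halfway into the next one, tagging it
#' `cds_start_NF` (symmetrically for `truncate_end`). A truncated end cannot
#' also carry its own alternative terminal exon.
#'
#' @param transcripts list of per-transcript option lists from [tx_options()].
#' @param n_core_exons number of core exons (>= 2; >= 3 when any transcript
#'   skips an exon).
#' @param gene_id,chrom,strand identifiers; minus-strand genes are exact
#'   coordinate mirrors of the plus-strand construction.
#' @param exon_len_range,intron_len_range integer ranges (bp) that exon and
#'   intron lengths are drawn from.
#' @param seed RNG seed; generation is byte-reproducible under it.
#' @return A `txe_gene_spec` list.
#' @export
gene_structure_spec <- function(transcripts, n_core_exons = 4L,
                                gene_id = "G1", chrom = "chr1", strand = "+",
                                exon_len_range = c(80L, 200L),
                                intron_len_range = c(200L, 1000L),
                                seed = 1L) {
  stopifnot(length(transcripts) >= 1L, n_core_exons >= 2L,
            strand %in% c("+", "-"))
  for (i in seq_along(transcripts)) {
    tx <- transcripts[[i]]
    if (length(tx$skip)) {
      if (n_core_exons < 3L) {
        stop("skipped exon requires n_core_exons >= 3")
      }
      if (any(tx$skip < 2L | tx$skip > n_core_exons - 1L)) {
        stop("skip indices must be internal core exons (2..",
             n_core_exons - 1L, ")")
      }
    }
    if (tx$truncate_start && (!is.na(tx$alt_first) || tx$upstream_extra)) {
      stop("transcript ", i, ": truncate_start excludes alt_first/upstream_extra")
    }
    if (tx$truncate_end && (!is.na(tx$alt_last) || tx$downstream_extra)) {
      stop("transcript ", i, ": truncate_end excludes alt_last/downstream_extra")
    }
  }
  structure(
    list(transcripts = transcripts, n_core_exons = as.integer(n_core_exons),
         gene_id = gene_id, chrom = chrom, strand = strand,
         exon_len_range = as.integer(exon_len_range),
         intron_len_range = as.integer(intron_len_range),
         seed = as.integer(seed)),
    class = "txe_gene_spec"
  )
}

#' @rdname gene_structure_spec
#' @param alt_first,alt_last promoter / 3'-end slot index (`NA` = start/end
#'   at the core chain). Transcripts sharing a slot share that terminal exon.
#' @param skip integer vector of internal core exons this transcript skips.
#' @param upstream_extra,downstream_extra logical; include the shared extra
#'   exon between the terminal slots and the core.
#' @param truncate_start,truncate_end logical; emit the transcript truncated
#'   at that end (with the matching `cds_*_NF` tag).
#' @param basic logical; carry the GENCODE `basic` tag (default: complete
#'   transcripts only, making them eligible as extension template).
#' @export
tx_options <- function(alt_first = NA, skip = integer(), alt_last = NA,
                       upstream_extra = FALSE, downstream_extra = FALSE,
                       truncate_start = FALSE, truncate_end = FALSE,
                       basic = NA) {
  list(alt_first = alt_first, skip = as.integer(skip), alt_last = alt_last,
       upstream_extra = upstream_extra, downstream_extra = downstream_extra,
       truncate_start = truncate_start, truncate_end = truncate_end,
       basic = basic)
}

#' Generate a synthetic gene with ground truth
#'
#' Realises a [gene_structure_spec()] as a [gene_model()] and records, by
#' plain set arithmetic over the structure specification (independently of the event-building
#' code), which event sets [build_gene_events()] must produce: the expected
#' number of distinct events per type, with and without masking.
#'
#' @param spec a `txe_gene_spec`.
#' @return List with `gene` (a `txe_gene`) and `truth`, the expected outcome
#'   of [build_gene_events()] derived symbolically from the options:
#'   `template_id`, `n_groups`, and per group (`groups[[k]]`) the
#'   `member_ids` plus expected distinct-event counts for `upstream`,
#'   `contained` and `downstream`, each with `masked` and `unmasked`
#'   variants; a type yields an event set iff its count is >= 2.
#' @export
make_gene <- function(spec) {
  stopifnot(inherits(spec, "txe_gene_spec"))
  set.seed(spec$seed)
  txs <- spec$transcripts
  n_tx <- length(txs)
  n_core <- spec$n_core_exons
  rlen <- function(n, range) {
    if (n == 0L) return(integer())
    as.integer(sample(seq(range[1L], range[2L]), n, replace = TRUE))
  }
  slots_first <- max(c(0L, unlist(lapply(txs, function(t) {
    if (is.na(t$alt_first)) NULL else t$alt_first
  }))))
  slots_last <- max(c(0L, unlist(lapply(txs, function(t) {
    if (is.na(t$alt_last)) NULL else t$alt_last
  }))))

  first_lens <- rlen(slots_first, spec$exon_len_range)
  ue_len <- rlen(1L, spec$exon_len_range)
  core_lens <- rlen(n_core, spec$exon_len_range)
  de_len <- rlen(1L, spec$exon_len_range)
  last_lens <- rlen(slots_last, spec$exon_len_range)
  n_introns <- slots_first + n_core + slots_last + 3L
  introns <- rlen(n_introns, spec$intron_len_range)

  pos <- 1000L
  ii <- 1L
  place <- function(len) {
    ex <- c(pos, pos + len)
    pos <<- pos + len + introns[ii]
    ii <<- ii + 1L
    ex
  }
  first_loci <- lapply(first_lens, place)
  ue_locus <- place(ue_len)
  core_loci <- lapply(core_lens, place)
  de_locus <- place(de_len)
  last_loci <- lapply(last_lens, place)

  models <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    tx <- txs[[i]]
    loci <- core_loci[setdiff(seq_len(n_core), tx$skip)]
    if (!is.na(tx$alt_first)) loci <- c(first_loci[tx$alt_first], loci)
    if (tx$upstream_extra) loci <- c(list(ue_locus), loci)
    if (tx$downstream_extra) loci <- c(loci, list(de_locus))
    if (!is.na(tx$alt_last)) loci <- c(loci, list(last_loci[[tx$alt_last]]))
    starts <- vapply(loci, `[[`, integer(1), 1L)
    ends <- vapply(loci, `[[`, integer(1), 2L)
    ord <- order(starts)
    starts <- starts[ord]
    ends <- ends[ord]
    tags <- character()
    if (tx$truncate_start) {
      if (length(starts) < 3L) stop("too few exons to truncate transcript ", i)
      starts <- starts[-1L]
      ends <- ends[-1L]
      starts[1L] <- starts[1L] + (ends[1L] - starts[1L]) %/% 2L
      tags <- c(tags, "cds_start_NF")
    }
    if (tx$truncate_end) {
      if (length(starts) < 3L) stop("too few exons to truncate transcript ", i)
      starts <- starts[-length(starts)]
      ends <- ends[-length(ends)]
      ends[length(ends)] <- ends[length(ends)] -
        (ends[length(ends)] - starts[length(starts)]) %/% 2L
      tags <- c(tags, "cds_end_NF")
    }
    truncated <- tx$truncate_start || tx$truncate_end
    is_basic <- if (is.na(tx$basic)) !truncated else tx$basic
    if (is_basic) tags <- c(tags, "basic")
    models[[i]] <- list(id = sprintf("T%02d", i), starts = starts, ends = ends,
                        tags = tags)
  }

  if (spec$strand == "-") {
    pivot <- pos + 1000L
    models <- lapply(models, function(m) {
      s <- pivot - m$ends
      e <- pivot - m$starts
      ord <- order(s)
      m$starts <- s[ord]
      m$ends <- e[ord]
      m
    })
  }
  gene <- gene_model(spec$gene_id, lapply(models, function(m) {
    transcript_model(m$id, spec$gene_id, spec$chrom, spec$strand,
                     exon_table(m$starts, m$ends), biotype = "protein_coding",
                     tags = m$tags)
  }))

  truth <- gene_spec_truth(spec, models)
  tmpl_i <- match(truth$template_id, vapply(models, `[[`, character(1), "id"))
  tmpl_opts <- txs[[tmpl_i]]
  if (tmpl_opts$truncate_start || tmpl_opts$truncate_end) {
    stop("the extension template resolves to a truncated transcript; ",
         "tag a complete transcript 'basic'")
  }
  for (tx in txs) {
    if (tx$truncate_start &&
        min(setdiff(seq(2L, n_core), tx$skip)) %in% tmpl_opts$skip) {
      stop("template skips the core exon a truncation cuts into; unsupported")
    }
    if (tx$truncate_end &&
        max(setdiff(seq_len(n_core - 1L), tx$skip)) %in% tmpl_opts$skip) {
      stop("template skips the core exon a truncation cuts into; unsupported")
    }
  }
  list(gene = gene, truth = truth)
}

# Expected event sets, derived by running the whole pipeline symbolically on
# locus labels (promoter slots, extra loci, core exon indices) rather than
# coordinates: truncation repair substitutes the template's loci beyond the
# cut, grouping greedily seeds with the best pair and absorbs transcripts
# preserving the scaffold, variable loci split by position against the
# scaffold's terminal loci, and masking keeps each event's terminal locus
# while unioning the rest. Distinct loci map to distinct coordinates, so the
# symbolic event counts equal the coordinate implementation's.
gene_spec_truth <- function(spec, models) {
  txs <- spec$transcripts
  n_core <- spec$n_core_exons
  full_len <- vapply(models, function(m) sum(m$ends - m$starts), integer(1))
  basic <- vapply(seq_along(txs), function(i) "basic" %in% models[[i]]$tags,
                  logical(1))
  pool <- if (any(basic)) which(basic) else seq_along(txs)
  tmpl <- pool[order(-full_len[pool],
                     vapply(models[pool], `[[`, character(1), "id"))][1L]

  sf <- max(c(0L, unlist(lapply(txs, function(t) {
    if (is.na(t$alt_first)) NULL else t$alt_first
  }))))
  locus_set <- function(i) {
    tx <- txs[[i]]
    l <- setdiff(seq_len(n_core), tx$skip) + sf + 1L # core loci
    if (!is.na(tx$alt_first)) l <- c(tx$alt_first, l)
    if (tx$upstream_extra) l <- c(sf + 1L, l)
    if (tx$downstream_extra) l <- c(l, sf + n_core + 2L)
    if (!is.na(tx$alt_last)) l <- c(l, sf + n_core + 2L + tx$alt_last)
    sort(as.integer(l))
  }
  tmpl_loci <- locus_set(tmpl)
  repaired <- lapply(seq_along(txs), function(i) {
    l <- locus_set(i)
    if (txs[[i]]$truncate_start) {
      l <- l[-1L]
      l <- sort(union(tmpl_loci[tmpl_loci < l[1L]], l))
    }
    if (txs[[i]]$truncate_end) {
      l <- l[-length(l)]
      l <- sort(union(l, tmpl_loci[tmpl_loci > l[length(l)]]))
    }
    l
  })
  ids <- vapply(models, `[[`, character(1), "id")
  names(repaired) <- ids

  pick_group <- function(members_pool) {
    if (length(members_pool) < 2L) return(NULL)
    best <- 0L
    seed <- NULL
    for (i in seq_len(length(members_pool) - 1L)) {
      for (j in seq(i + 1L, length(members_pool))) {
        a <- members_pool[i]
        b <- members_pool[j]
        sz <- length(intersect(repaired[[a]], repaired[[b]]))
        if (sz > best) {
          best <- sz
          seed <- c(a, b)
        }
      }
    }
    if (best == 0L) return(NULL)
    scaffold <- intersect(repaired[[seed[1L]]], repaired[[seed[2L]]])
    extra <- setdiff(members_pool, seed)
    take <- extra[vapply(extra, function(id) {
      all(scaffold %in% repaired[[id]])
    }, logical(1))]
    list(members = sort(c(seed, take)), scaffold = scaffold)
  }

  count_events <- function(grp) {
    s <- grp$scaffold
    s_first <- min(s)
    s_last <- max(s)
    var <- lapply(grp$members, function(id) setdiff(repaired[[id]], s))
    split_sets <- function(side) {
      unique(lapply(var, function(v) {
        switch(side,
               up = v[v < s_first],
               cont = v[v > s_first & v < s_last],
               down = v[v > s_last])
      }))
    }
    mask_count <- function(sets, from_left) {
      events <- lapply(sets, function(v) sort(union(s, v)))
      term <- vapply(events, function(e) {
        if (from_left) min(e) else max(e)
      }, integer(1))
      m <- sort(unique(unlist(lapply(seq_along(events), function(k) {
        setdiff(events[[k]], term[k])
      }))))
      length(unique(lapply(seq_along(events), function(k) {
        sort(union(term[k], m))
      })))
    }
    up <- split_sets("up")
    cont <- split_sets("cont")
    down <- split_sets("down")
    list(
      upstream = list(unmasked = length(up), masked = mask_count(up, TRUE)),
      contained = list(unmasked = length(cont), masked = length(cont)),
      downstream = list(unmasked = length(down),
                        masked = mask_count(down, FALSE))
    )
  }

  groups <- list()
  remaining <- sort(ids)
  repeat {
    grp <- pick_group(remaining)
    if (is.null(grp) || length(groups) >= 2L) break
    groups[[length(groups) + 1L]] <- c(
      list(member_ids = grp$members), count_events(grp)
    )
    remaining <- setdiff(remaining, grp$members)
  }

  list(template_id = models[[tmpl]]$id, n_groups = length(groups),
       groups = groups)
}

#' Specify and simulate a usage QTL
#'
#' Plants a genetic effect on the relative usage of one event of a gene:
#' each copy of the alternative allele shifts the target event's usage by
#' `shift` (proportion units), and the remaining events are renormalised
#' complementarily (scaled proportionally) so usage always sums to one.
#' Event TPMs are usage times the gene-level TPM. With `noise_sd = 0` the
#' least-squares slope of the target event's relative usage on dosage equals
#' `shift` exactly.
#'
#' @param n_samples number of samples (default 84, a typical cohort size for
#'   this design).
#' @param maf minor allele frequency of the simulated variant (default 0.3).
#' @param shift per-allele usage shift of the target event (default 0.10).
#' @param baseline baseline usage of the events (sums to 1; default
#'   `c(0.6, 0.4)`, a two-event promoter choice).
#' @param target index of the event carrying the effect (default 2).
#' @param noise_sd standard deviation of Gaussian noise added to the target
#'   event's usage before renormalisation (default 0).
#' @param gene_tpm gene-level expression in TPM (default 50).
#' @param gene_id gene identifier used in event ids.
#' @param seed RNG seed.
#' @return A `txe_usage_qtl_spec` list.
#' @export
usage_qtl_spec <- function(n_samples = 84L, maf = 0.3, shift = 0.10,
                           baseline = c(0.6, 0.4), target = 2L,
                           noise_sd = 0, gene_tpm = 50, gene_id = "G1",
                           seed = 1L) {
  stopifnot(n_samples >= 3L, maf > 0, maf < 1, length(baseline) >= 2L,
            target >= 1L, target <= length(baseline))
  if (abs(sum(baseline) - 1) > 1e-9) stop("baseline usage must sum to 1")
  for (d in 0:2) {
    u <- baseline[target] + shift * d
    if (u < 0 || u > 1) {
      stop("shift drives target usage outside [0, 1] at dosage ", d)
    }
  }
  structure(
    list(n_samples = as.integer(n_samples), maf = maf, shift = shift,
         baseline = baseline, target = as.integer(target),
         noise_sd = noise_sd, gene_tpm = gene_tpm, gene_id = gene_id,
         seed = as.integer(seed)),
    class = "txe_usage_qtl_spec"
  )
}

#' @rdname usage_qtl_spec
#' @param spec a `txe_usage_qtl_spec`.
#' @return `simulate_usage_qtl()` returns a list with `dosage` (named
#'   vector), `abundance` (a `txe_abundance`), and `truth` (target event id
#'   and planted shift).
#' @export
simulate_usage_qtl <- function(spec) {
  stopifnot(inherits(spec, "txe_usage_qtl_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  k <- length(spec$baseline)
  samples <- sprintf("s%03d", seq_len(n))
  dosage <- stats::rbinom(n, 2L, spec$maf)
  names(dosage) <- samples
  u_target <- spec$baseline[spec$target] + spec$shift * dosage
  if (spec$noise_sd > 0) {
    u_target <- pmin(pmax(u_target + stats::rnorm(n, 0, spec$noise_sd), 0), 1)
  }
  usage <- matrix(0, nrow = k, ncol = n)
  usage[spec$target, ] <- u_target
  others <- setdiff(seq_len(k), spec$target)
  scale <- (1 - u_target) / (1 - spec$baseline[spec$target])
  for (j in others) usage[j, ] <- spec$baseline[j] * scale
  tpm <- usage * spec$gene_tpm

  event_ids <- vapply(seq_len(k), function(j) {
    make_event_id(spec$gene_id, 1L, "upstream", sprintf("T%02d", j))
  }, character(1))
  dimnames(tpm) <- list(event_ids, samples)
  meta <- data.frame(
    event_id = event_ids, gene_id = spec$gene_id, group_index = 1L,
    event_type = "upstream", stringsAsFactors = FALSE
  )
  list(
    dosage = dosage,
    abundance = abundance_matrix(tpm, meta),
    truth = list(target_event = event_ids[spec$target], shift = spec$shift)
  )
}

#' Simulate genotype dosages
#'
#' Binomial(2, maf) dosages for independent variants placed on a regular
#' grid, for exercising the association machinery.
#'
#' @param n_variants,n_samples dimensions.
#' @param maf minor allele frequency (scalar or per-variant vector).
#' @param chrom chromosome label.
#' @param start,spacing variant positions `start + (i-1) * spacing`.
#' @param samples optional sample ids (default `s001`...).
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n_variants, n_samples, maf = 0.3,
                               chrom = "chr1", start = 1000000L,
                               spacing = 1000L, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("s%03d", seq_len(n_samples))
  maf <- rep_len(maf, n_variants)
  dosage <- t(vapply(seq_len(n_variants),
                     function(i) stats::rbinom(n_samples, 2L, maf[i]),
                     numeric(n_samples)))
  rownames(dosage) <- sprintf("var%05d", seq_len(n_variants))
  colnames(dosage) <- samples
  genotype_matrix(dosage, chrom = rep(chrom, n_variants),
                  pos = start + (seq_len(n_variants) - 1L) * spacing)
}

#' Specify and simulate a multi-condition phenotype
#'
#' Generates the long-format phenotype table used by the response-QTL
#' machinery: per-donor dosage, and a phenotype composed of donor, genotype,
#' condition, genotype-by-condition and residual contributions with the
#' specified variances. Genotype effects are drawn per dosage level (factor
#' coding) by default, matching the random-effects model fitted by
#' [variance_components()]; `additive = TRUE` draws a single per-allele
#' slope instead (sensitivity mode).
#'
#' @param n_donors donors, each observed in every condition (default 40).
#' @param conditions condition labels (default naive/stimulated).
#' @param var_donor,var_genotype,var_condition,var_interaction,var_residual
#'   variance components (all >= 0).
#' @param maf minor allele frequency (default 0.3).
#' @param additive additive genotype coding (see above).
#' @param seed RNG seed.
#' @return A `txe_condition_spec` list.
#' @export
condition_sim_spec <- function(n_donors = 40L,
                               conditions = c("naive", "stimulated"),
                               var_donor = 0.5, var_genotype = 1,
                               var_condition = 0.5, var_interaction = 1,
                               var_residual = 0.5, maf = 0.3,
                               additive = FALSE, seed = 1L) {
  vars <- c(var_donor, var_genotype, var_condition, var_interaction,
            var_residual)
  stopifnot(n_donors >= 3L, length(conditions) >= 2L, all(vars >= 0),
            maf > 0, maf < 1)
  structure(
    list(n_donors = as.integer(n_donors), conditions = conditions,
         var_donor = var_donor, var_genotype = var_genotype,
         var_condition = var_condition, var_interaction = var_interaction,
         var_residual = var_residual, maf = maf, additive = additive,
         seed = as.integer(seed)),
    class = "txe_condition_spec"
  )
}

#' @rdname condition_sim_spec
#' @param spec a `txe_condition_spec`.
#' @return `simulate_conditions()` returns a list with `table` (long-format
#'   data.frame: `donor_id`, `sample_id`, `condition`, `dosage`,
#'   `phenotype`) and `truth` (the planted variances and effects).
#' @export
simulate_conditions <- function(spec) {
  stopifnot(inherits(spec, "txe_condition_spec"))
  set.seed(spec$seed)
  nd <- spec$n_donors
  conds <- spec$conditions
  nc <- length(conds)
  dosage <- stats::rbinom(nd, 2L, spec$maf)
  donor_eff <- stats::rnorm(nd, 0, sqrt(spec$var_donor))
  cond_eff <- stats::rnorm(nc, 0, sqrt(spec$var_condition))
  if (spec$additive) {
    beta_g <- stats::rnorm(1L, 0, sqrt(spec$var_genotype))
    beta_i <- stats::rnorm(nc, 0, sqrt(spec$var_interaction))
    geno_part <- function(d, c_i) beta_g * d + beta_i[c_i] * d
  } else {
    g_eff <- stats::rnorm(3L, 0, sqrt(spec$var_genotype))
    i_eff <- matrix(stats::rnorm(3L * nc, 0, sqrt(spec$var_interaction)),
                    nrow = 3L)
    geno_part <- function(d, c_i) g_eff[d + 1L] + i_eff[d + 1L, c_i]
  }
  rows <- expand.grid(donor = seq_len(nd), cond = seq_len(nc))
  phenotype <- vapply(seq_len(nrow(rows)), function(r) {
    d <- rows$donor[r]
    ci <- rows$cond[r]
    donor_eff[d] + cond_eff[ci] + geno_part(dosage[d], ci) +
      stats::rnorm(1L, 0, sqrt(spec$var_residual))
  }, numeric(1))
  tab <- data.frame(
    donor_id = sprintf("D%03d", rows$donor),
    sample_id = sprintf("D%03d_%s", rows$donor, conds[rows$cond]),
    condition = conds[rows$cond],
    dosage = dosage[rows$donor],
    phenotype = phenotype,
    stringsAsFactors = FALSE
  )
  list(
    table = tab,
    truth = list(var_donor = spec$var_donor, var_genotype = spec$var_genotype,
                 var_condition = spec$var_condition,
                 var_interaction = spec$var_interaction,
                 var_residual = spec$var_residual)
  )
}

#' Write abundance tables in quantifier layout
#'
#' Writes one tab-separated table per sample with the header
#' `Name Length EffectiveLength TPM NumReads`, the layout read back by
#' [import_abundance()].
#'
#' @param a a `txe_abundance`.
#' @param dir output directory (created if needed).
#' @param lengths optional named feature lengths (default 1000).
#' @return Named vector of file paths, invisibly.
#' @export
write_abundance_tables <- function(a, dir, lengths = NULL) {
  stopifnot(inherits(a, "txe_abundance"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  feats <- rownames(a$tpm)
  len <- if (is.null(lengths)) stats::setNames(rep(1000L, length(feats)), feats)
  else lengths
  files <- character()
  for (s in colnames(a$tpm)) {
    tab <- data.frame(
      Name = feats,
      Length = len[feats],
      EffectiveLength = pmax(len[feats] - 200L, 25L),
      TPM = a$tpm[, s],
      NumReads = round(a$tpm[, s] * len[feats] / 100),
      stringsAsFactors = FALSE
    )
    f <- file.path(dir, paste0(s, ".sf"))
    utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files[s] <- f
  }
  invisible(files)
}
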