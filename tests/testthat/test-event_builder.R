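tx <- function(id, starts, ends, biotype = "protein_coding",
               tags = character(), strand = "+") {
  transcript_model(id, "G", "chr1", strand, exon_table(starts, ends),
                   biotype = biotype, tags = tags)
}

test_that("truncation classification follows tags and biotypes", {
  expect_equal(
    classify_truncation(tx("a", 0, 10, tags = "cds_end_NF")),
    list(start_truncated = FALSE, end_truncated = TRUE)
  )
  expect_equal(
    classify_truncation(tx("a", 0, 10, tags = "cds_start_NF")),
    list(start_truncated = TRUE, end_truncated = FALSE)
  )
  for (bt in c("retained_intron", "processed_transcript",
               "nonsense_mediated_decay")) {
    expect_equal(classify_truncation(tx("a", 0, 10, biotype = bt)),
                 list(start_truncated = TRUE, end_truncated = TRUE))
  }
  expect_equal(classify_truncation(tx("a", 0, 10)),
               list(start_truncated = FALSE, end_truncated = FALSE))
})

test_that("template selection prefers basic transcripts, then length, then id", {
  g <- gene_model("G", list(
    tx("T1", c(0, 100), c(50, 550), tags = "basic"), # 500 nt basic
    tx("T2", c(0, 100), c(80, 1000), tags = "basic"), # 900 nt basic
    tx("T3", c(0, 100), c(90, 2000)) # 2000 nt, not basic
  ))
  expect_equal(select_template(g)$transcript_id, "T2")
  # no basic tag anywhere: fall back to overall longest (brute-force check)
  g2 <- gene_model("G", list(tx("T1", 0, 300), tx("T2", 0, 400)))
  lens <- vapply(g2$transcripts, spliced_length, numeric(1))
  expect_equal(select_template(g2)$transcript_id, names(which.max(lens)))
  # exact tie: lexicographically smallest id
  g3 <- gene_model("G", list(tx("T2", 0, 500), tx("T1", 100, 600)))
  expect_equal(select_template(g3)$transcript_id, "T1")
})

test_that("extension repairs a 5'-truncated transcript from the template", {
  template <- tx("TM", c(0, 200, 400, 600), c(100, 300, 500, 700),
                 tags = "basic")
  trunc <- tx("TT", c(250, 400), c(300, 500), tags = "cds_start_NF")
  r <- extend_transcript(trunc, template)
  # terminal exon stretched to the containing template exon; 5' exons copied
  expect_equal(r$exons, exon_table(c(0, 200, 400), c(100, 300, 500)))
  expect_false(classify_truncation(r)$start_truncated)
  expect_false("cds_start_NF" %in% r$tags)
  # original exon chain survives as a subsequence (internal boundaries intact)
  expect_true(all(c("400-500") %in% paste0(r$exons$start, "-", r$exons$end)))
  # idempotent
  r2 <- extend_transcript(r, template)
  expect_identical(r2$exons, r$exons)
  # complete transcript passes through unchanged
  ok <- tx("OK", c(0, 200), c(100, 300))
  expect_identical(extend_transcript(ok, template)$exons, ok$exons)
})

test_that("extension is symmetric at the 3' end and on the minus strand", {
  template <- tx("TM", c(0, 200, 400), c(100, 300, 500), tags = "basic")
  t3 <- tx("TT", c(0, 200), c(100, 250), tags = "cds_end_NF")
  r <- extend_transcript(t3, template)
  expect_equal(r$exons, exon_table(c(0, 200, 400), c(100, 300, 500)))
  # minus strand: 5' truncation is at the genomic right
  tm_m <- tx("TM", c(0, 200, 400), c(100, 300, 500), tags = "basic",
             strand = "-")
  # on the minus strand a 5' truncation cuts the genomic-right side
  tt_m <- tx("TT", c(0, 200), c(100, 280), tags = "cds_start_NF", strand = "-")
  rm <- extend_transcript(tt_m, tm_m)
  expect_equal(rm$exons, exon_table(c(0, 200, 400), c(100, 300, 500)))
})

test_that("a template truncated at the required end leaves the transcript as is", {
  template <- tx("TM", c(200, 400), c(300, 500), tags = c("basic", "cds_start_NF"))
  trunc <- tx("TT", 400, 500, tags = "cds_start_NF")
  expect_warning(r <- extend_transcript(trunc, template), "template")
  expect_identical(r$exons, trunc$exons)
})

test_that("greedy grouping matches the exhaustive-subset oracle on fixtures", {
  # three transcripts share {e2,e3}; one also has e1
  g <- gene_model("G", list(
    tx("T1", c(0, 200, 400), c(100, 300, 500)),
    tx("T2", c(200, 400), c(300, 500)),
    tx("T3", c(200, 400, 600), c(300, 500, 700))
  ))
  grps <- select_transcript_groups(g)
  expect_length(grps, 1L)
  expect_setequal(grps[[1]]$member_ids, c("T1", "T2", "T3"))
  expect_equal(nrow(grps[[1]]$scaffold), 2L)
  expect_equal(nrow(grps[[1]]$scaffold), oracle_scaffold_size(g))

  # two disjoint transcript pairs -> two groups
  g2 <- gene_model("G", list(
    tx("T1", c(0, 200), c(100, 300)),
    tx("T2", c(0, 200, 400), c(100, 300, 500)),
    tx("T3", c(5000, 5200), c(5100, 5300)),
    tx("T4", c(5000, 5200, 5400), c(5100, 5300, 5500))
  ))
  grps2 <- select_transcript_groups(g2)
  expect_length(grps2, 2L)
  expect_setequal(grps2[[1]]$member_ids, c("T1", "T2"))
  expect_setequal(grps2[[2]]$member_ids, c("T3", "T4"))

  # degenerate genes
  expect_length(select_transcript_groups(gene_model("G", list(tx("T1", 0, 10)))), 0L)
  expect_length(select_transcript_groups(gene_model("G", list(
    tx("T1", 0, 10), tx("T2", 20, 30)
  ))), 0L)
})

test_that("grouping is deterministic under transcript input permutation", {
  gt <- make_gene(random_gene_spec(404))
  txs <- gt$gene$transcripts
  set.seed(1)
  for (i in 1:5) {
    g_perm <- gene_model(gt$gene$gene_id, sample(txs))
    expect_identical(select_transcript_groups(g_perm),
                     select_transcript_groups(gt$gene))
    sets_a <- build_gene_events(g_perm)
    sets_b <- build_gene_events(gt$gene)
    expect_identical(lapply(sets_a, event_set_signature),
                     lapply(sets_b, event_set_signature))
  }
})

test_that("constructed events carry the scaffold and split by position", {
  gt <- make_gene(fig1c_spec())
  sets <- build_gene_events(gt$gene, mask = FALSE)
  expect_length(sets, 3L)
  expect_setequal(vapply(sets, `[[`, character(1), "event_type"),
                  c("upstream", "contained", "downstream"))
  for (s in sets) {
    expect_length(s$events, 2L)
    expect_true(scaffold_contained_ok(s))
  }
  # all members identical upstream of the scaffold: no upstream set
  g <- gene_model("G", list(
    tx("T1", c(0, 200, 400), c(100, 300, 500)),
    tx("T2", c(0, 200, 400, 600), c(100, 300, 500, 700))
  ))
  types <- vapply(build_gene_events(g, mask = FALSE), `[[`, character(1),
                  "event_type")
  expect_false("upstream" %in% types)
  expect_equal(types, "downstream")
})

test_that("minus-strand construction mirrors the plus strand exactly", {
  for (seed in c(2, 23, 57)) {
    gp <- make_gene(random_gene_spec(seed, strand = "+"))
    gm <- make_gene(random_gene_spec(seed, strand = "-"))
    sp <- build_gene_events(gp$gene)
    sm <- build_gene_events(gm$gene)
    expect_equal(length(sp), length(sm))
    # recover the mirror pivot from the two coordinate systems
    all_p <- do.call(rbind, lapply(gp$gene$transcripts, function(t) t$exons))
    all_m <- do.call(rbind, lapply(gm$gene$transcripts, function(t) t$exons))
    pivot <- max(all_p$end) + min(all_m$start)
    sig_p <- sort(vapply(sp, event_set_signature, character(1)))
    sig_m <- sort(vapply(lapply(sm, function(es) {
      es$events <- lapply(es$events, function(e) {
        e$exons <- exon_table(pivot - e$exons$end, pivot - e$exons$start)
        e
      })
      es
    }), event_set_signature, character(1)))
    expect_equal(sig_m, sig_p)
  }
})

test_that("masking unions internal variable exons and keeps terminal exons", {
  # A: own first exon; B: different first exon plus an extra internal
  # upstream exon that A lacks
  spec <- gene_structure_spec(
    transcripts = list(tx_options(alt_first = 1),
                       tx_options(alt_first = 2, upstream_extra = TRUE)),
    n_core_exons = 3, seed = 5
  )
  gt <- make_gene(spec)
  unmasked <- Filter(function(s) s$event_type == "upstream",
                     build_gene_events(gt$gene, mask = FALSE))[[1]]
  masked <- mask_internal_variation(unmasked)
  expect_true(masked$masked)
  # the extra exon is now present in both events
  extra_keys <- setdiff(
    paste(unmasked$events[[2]]$exons$start, unmasked$events[[2]]$exons$end),
    paste(unmasked$events[[1]]$exons$start, unmasked$events[[1]]$exons$end)
  )
  k1 <- paste(masked$events[[1]]$exons$start, masked$events[[1]]$exons$end)
  k2 <- paste(masked$events[[2]]$exons$start, masked$events[[2]]$exons$end)
  expect_true(length(setdiff(extra_keys, c(k1, k2))) < length(extra_keys))
  expect_true(masked_terminal_ok(masked))
  # first exons still differ
  expect_false(identical(masked$events[[1]]$exons[1, ],
                         masked$events[[2]]$exons[1, ]))
  # fixed point: events differing only in the first exon stay unchanged
  plain <- Filter(function(s) s$event_type == "upstream",
                  build_gene_events(make_gene(fig1c_spec())$gene,
                                    mask = FALSE))[[1]]
  masked_plain <- mask_internal_variation(plain)
  expect_identical(lapply(masked_plain$events, `[[`, "exons"),
                   lapply(plain$events, `[[`, "exons"))
  # idempotence
  twice <- mask_internal_variation(masked)
  expect_identical(lapply(twice$events, `[[`, "exons"),
                   lapply(masked$events, `[[`, "exons"))
  # contained sets pass through untouched
  cont <- Filter(function(s) s$event_type == "contained",
                 build_gene_events(gt$gene, mask = FALSE))
  if (length(cont)) {
    expect_identical(mask_internal_variation(cont[[1]]), cont[[1]])
  }
})

test_that("full pipeline equals the manual stage-by-stage composition", {
  spec <- gene_structure_spec(
    transcripts = list(
      tx_options(alt_first = 1, alt_last = 1),
      tx_options(alt_first = 2, skip = 2),
      tx_options(truncate_start = TRUE),
      tx_options(alt_last = 2)
    ),
    n_core_exons = 4, seed = 21
  )
  gt <- make_gene(spec)
  auto <- build_gene_events(gt$gene)

  template <- select_template(gt$gene)
  repaired <- lapply(gt$gene$transcripts, function(t) {
    extend_transcript(t, template, classify_truncation(t))
  })
  g2 <- gene_model("G1", repaired)
  manual <- list()
  for (grp in select_transcript_groups(g2)) {
    for (es in construct_events(grp, g2$transcripts[grp$member_ids])) {
      es <- mask_internal_variation(es)
      if (length(es$events) >= 2) manual[[length(manual) + 1]] <- es
    }
  }
  expect_identical(lapply(auto, event_set_signature),
                   lapply(manual, event_set_signature))
  # a gene of identical transcripts yields nothing
  g_same <- gene_model("G", list(tx("T1", c(0, 200), c(100, 300)),
                                 tx("T2", c(0, 200), c(100, 300))))
  expect_length(build_gene_events(g_same), 0L)
})

test_that("generated genes produce the ground-truth event sets", {
  for (seed in c(1, 5, 12, 33, 77)) {
    gt <- make_gene(random_gene_spec(seed))
    for (mask in c(TRUE, FALSE)) {
      sets <- build_gene_events(gt$gene, mask = mask)
      for (k in seq_along(gt$truth$groups)) {
        grp <- gt$truth$groups[[k]]
        for (ty in c("upstream", "contained", "downstream")) {
          got <- 0L
          for (s in sets) {
            if (s$group_index == k && s$event_type == ty) got <- length(s$events)
          }
          want <- grp[[ty]][[if (mask) "masked" else "unmasked"]]
          if (want < 2L) want <- 0L # singleton types are not emitted
          expect_equal(got, want,
                       info = sprintf("seed %d grp %d type %s mask %s",
                                      seed, k, ty, mask))
        }
      }
      # no event sets outside the ground-truth groups
      expect_true(all(vapply(sets, `[[`, integer(1), "group_index") <=
                        length(gt$truth$groups)))
    }
  }
})
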