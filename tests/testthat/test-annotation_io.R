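test_that("read_gtf parses genes, transcripts, tags and biotypes", {
  f <- write_gtf_text(c(
    "#!genome-build test",
    paste0("chr1\tens\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";'),
    paste0("chr1\tens\texon\t301\t400\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";'),
    paste0("chr1\tens\texon\t501\t600\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1"; transcript_biotype "protein_coding"; tag "basic";'),
    paste0("chr1\tens\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T2"; transcript_biotype "protein_coding"; tag "cds_end_NF"; tag "mRNA_end_NF";'),
    paste0("chr1\tens\texon\t301\t350\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T2"; transcript_biotype "protein_coding"; tag "cds_end_NF"; tag "mRNA_end_NF";')
  ))
  genes <- read_gtf(f)
  expect_length(genes, 1L)
  g <- genes$G1
  expect_s3_class(g, "txe_gene")
  expect_length(g$transcripts, 2L)
  expect_equal(nrow(g$transcripts$T1$exons), 3L)
  expect_equal(nrow(g$transcripts$T2$exons), 2L)
  # repeated tag attributes all collected
  expect_true(all(c("cds_end_NF", "mRNA_end_NF") %in% g$transcripts$T2$tags))
  expect_true("basic" %in% g$transcripts$T1$tags)
  expect_equal(g$transcripts$T1$biotype, "protein_coding")
  # GTF 1-based inclusive -> 0-based half-open
  expect_equal(g$transcripts$T1$exons$start[1], 100L)
  expect_equal(g$transcripts$T1$exons$end[1], 200L)
})

test_that("exon line order does not change the parsed model", {
  mk_lines <- function(order) {
    body <- c(
      paste0("chr2\tens\texon\t1001\t1100\t.\t-\t.\t",
             'gene_id "G2"; transcript_id "T9";'),
      paste0("chr2\tens\texon\t2001\t2100\t.\t-\t.\t",
             'gene_id "G2"; transcript_id "T9";'),
      paste0("chr2\tens\texon\t3001\t3100\t.\t-\t.\t",
             'gene_id "G2"; transcript_id "T9";')
    )
    body[order]
  }
  a <- read_gtf(write_gtf_text(mk_lines(1:3)))
  b <- read_gtf(write_gtf_text(mk_lines(c(3, 1, 2))))
  expect_identical(a, b)
})

test_that("malformed input raises errors naming the problem", {
  expect_error(read_gtf(write_gtf_text(
    "chr1\tens\texon\t100\t200\t.\t+\t."
  )), "line 1.*9")
  expect_error(read_gtf(write_gtf_text(
    "chr1\tens\texon\t300\t200\t.\t+\t.\tgene_id \"G\"; transcript_id \"T\";"
  )), "end < start")
  expect_error(read_gtf(write_gtf_text(
    "chr1\tens\texon\t100\t200\t.\t+\t.\tnot an attribute column"
  )), "malformed attribute")
  expect_error(read_gtf(write_gtf_text(c(
    "chr1\tens\texon\t100\t200\t.\t+\t.\tgene_id \"G\"; transcript_id \"T\";",
    "chr2\tens\texon\t100\t200\t.\t+\t.\tgene_id \"G\"; transcript_id \"T\";"
  ))), "multiple chromosomes")
  # same transcript_id under two genes (pseudo-autosomal style) is rejected
  expect_error(read_gtf(write_gtf_text(c(
    "chrX\tens\texon\t100\t200\t.\t+\t.\tgene_id \"GA\"; transcript_id \"T\";",
    "chrY\tens\texon\t100\t200\t.\t+\t.\tgene_id \"GB\"; transcript_id \"T\";"
  ))), "multiple genes")
})

test_that("write_gtf round-trips event exon structures and strand", {
  for (strand in c("+", "-")) {
    gt <- make_gene(fig1c_spec(seed = 11, strand = strand))
    sets <- build_gene_events(gt$gene)
    evs <- unlist(lapply(sets, function(s) s$events), recursive = FALSE)
    f <- tempfile(fileext = ".gtf")
    write_gtf(evs, f)
    if (strand == "-") {
      body <- grep("^#", readLines(f), value = TRUE, invert = TRUE)
      expect_true(all(grepl("\t-\t", body)))
    }
    back <- read_gtf(f)$G1$transcripts
    for (e in evs) {
      expect_identical(back[[e$event_id]]$exons, e$exons)
      expect_identical(back[[e$event_id]]$strand, strand)
    }
  }
  # empty collection -> valid file with only comments
  f0 <- tempfile(fileext = ".gtf")
  write_gtf(list(), f0)
  expect_length(read_gtf(f0), 0L)
})

test_that("written events agree with an independent GTF reader", {
  skip_if_not_installed("rtracklayer")
  gt <- make_gene(fig1c_spec(seed = 3))
  evs <- unlist(lapply(build_gene_events(gt$gene), function(s) s$events),
                recursive = FALSE)
  f <- tempfile(fileext = ".gtf")
  write_gtf(evs, f)
  gr <- rtracklayer::import(f, format = "gtf")
  gr <- gr[gr$type == "exon"]
  for (e in evs) {
    sub <- gr[gr$transcript_id == e$event_id]
    expect_equal(sort(BiocGenerics::start(sub)) - 1L, e$exons$start)
    expect_equal(sort(BiocGenerics::end(sub)), e$exons$end)
  }
})

test_that("event ids round-trip through the identifier grammar", {
  cases <- expand.grid(
    gene = c("G1", "ENSG00000139083.6"),
    type = c("upstream", "contained", "downstream"),
    tx = c("T02", "ENST00000344691.3"),
    grp = 1:2, stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(cases))) {
    id <- make_event_id(cases$gene[i], cases$grp[i], cases$type[i], cases$tx[i])
    p <- parse_event_id(id)
    expect_equal(p$gene_id, cases$gene[i])
    expect_equal(p$group_index, cases$grp[i])
    expect_equal(p$event_type, cases$type[i])
    expect_equal(p$transcript_id, cases$tx[i])
  }
  expect_error(parse_event_id("G1.grp_1.sideways.T1"), "not a valid event id")
})

test_that("sequence extraction splices, reverse-complements and checks bounds", {
  skip_if_not_installed("Biostrings")
  genome <- Biostrings::DNAStringSet(c(chrT = "AACGTTTTGGTT"))
  ev <- function(strand, starts, ends) {
    list(chrom = "chrT", strand = strand, exons = exon_table(starts, ends))
  }
  expect_equal(extract_event_sequence(ev("+", 1, 5), genome), "ACGT")
  expect_equal(extract_event_sequence(ev("-", 1, 5), genome), "ACGT")
  # two exons spliced over a gap, then reverse-complemented as a whole
  expect_equal(extract_event_sequence(ev("+", c(1, 8), c(3, 10)), genome), "ACGG")
  expect_equal(extract_event_sequence(ev("-", c(1, 8), c(3, 10)), genome), "CCGT")
  expect_error(extract_event_sequence(ev("+", 1, 50), genome), "beyond")
  expect_error(
    extract_event_sequence(list(chrom = "nope", strand = "+",
                                exons = exon_table(1, 5)), genome),
    "absent"
  )
  # length equals exon-width sum on random events
  set.seed(42)
  wide <- Biostrings::DNAStringSet(c(chrW = paste(
    sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")))
  for (i in 1:50) {
    n_ex <- sample(1:5, 1)
    s <- sort(sample(0:4900, n_ex))
    e <- pmin(s + sample(5:40, n_ex, replace = TRUE), 5000)
    ok <- c(TRUE, s[-1] >= e[-n_ex])
    ex <- exon_table(s[ok], e[ok])
    sq <- extract_event_sequence(
      list(chrom = "chrW", strand = sample(c("+", "-"), 1), exons = ex), wide)
    expect_equal(nchar(sq), sum(exon_widths(ex)))
  }
})

test_that("coordinate conversion is its own inverse at the I/O boundary", {
  set.seed(1)
  s <- sample.int(1e6, 200)
  e <- s + sample.int(500, 200)
  gtf <- internal_to_gtf(s, e)
  back <- gtf_to_internal(gtf$start, gtf$end)
  expect_identical(back$start, s)
  expect_identical(back$end, e)
})
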