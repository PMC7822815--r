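make_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

attr_str <- function(gene, tx, biotype = "protein_coding") {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
          gene, tx, biotype)
}

test_that("read_gtf parses records and converts to 0-based half-open", {
  p <- make_gtf(c(
    paste("chr1", "test", "exon", 101, 200, ".", "+", ".",
          attr_str("g1", "t1"), sep = "\t"),
    paste("chr1", "test", "exon", 301, 400, ".", "+", ".",
          attr_str("g1", "t1"), sep = "\t"),
    paste("chr1", "test", "exon", 501, 600, ".", "+", ".",
          attr_str("g1", "t1"), sep = "\t")))
  gm <- read_gtf(p)
  expect_equal(nrow(gm$genes), 1)
  expect_equal(nrow(gm$transcripts), 1)
  expect_equal(nrow(gm$exons), 3)
  ## 1-based [101,200] becomes [100,200)
  expect_equal(gm$exons$start, c(100, 300, 500))
  expect_equal(gm$exons$end, c(200, 400, 600))
  expect_equal(gm$transcripts$tss, 100)
})

test_that("two transcripts sharing an exon yield one gene, two models", {
  p <- make_gtf(c(
    paste("chr1", "t", "exon", 101, 200, ".", "+", ".",
          attr_str("g1", "t1"), sep = "\t"),
    paste("chr1", "t", "exon", 301, 400, ".", "+", ".",
          attr_str("g1", "t1"), sep = "\t"),
    paste("chr1", "t", "exon", 101, 200, ".", "+", ".",
          attr_str("g1", "t2"), sep = "\t"),
    paste("chr1", "t", "exon", 501, 650, ".", "+", ".",
          attr_str("g1", "t2"), sep = "\t")))
  gm <- read_gtf(p)
  expect_equal(nrow(gm$genes), 1)
  expect_setequal(gm$transcripts$transcript_id, c("t1", "t2"))
  shared <- gm$exons[gm$exons$start == 100, ]
  expect_equal(nrow(shared), 2)
  expect_equal(unique(shared$end), 200)
})

test_that("GTF round-trip reproduces identical gene models", {
  set.seed(42)
  gm <- random_gene("G7", max_tx = 4, max_exons = 6)
  p <- tempfile(fileext = ".gtf")
  write_gtf(gm, p)
  gm2 <- read_gtf(p)
  o1 <- gm$exons[order(gm$exons$transcript_id, gm$exons$start), ]
  o2 <- gm2$exons[order(gm2$exons$transcript_id, gm2$exons$start), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  expect_equal(gm$genes$biotype, gm2$genes$biotype)
  t1 <- gm$transcripts[order(gm$transcripts$transcript_id), ]
  t2 <- gm2$transcripts[order(gm2$transcripts$transcript_id), ]
  expect_equal(t1$cds_start, t2$cds_start)
  expect_equal(t1$tss, t2$tss)
})

simple_gm <- function(exdf, cds = NULL, strand = "+",
                      biotype = "protein_coding") {
  exdf$gene_id <- "g1"; exdf$chrom <- "chr1"; exdf$strand <- strand
  tx <- do.call(rbind, lapply(split(exdf, exdf$transcript_id), function(d)
    data.frame(transcript_id = d$transcript_id[1], gene_id = "g1",
               chrom = "chr1", strand = strand,
               tss = if (strand == "+") min(d$start) else max(d$end) - 1,
               cds_start = if (is.null(cds)) NA_integer_ else cds[1],
               cds_end = if (is.null(cds)) NA_integer_ else cds[2])))
  gene_models(data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
                         biotype = biotype), tx, exdf)
}

test_that("flatten_exons splits at covering-set changes", {
  ## no overlap: bins equal exons
  gm <- simple_gm(data.frame(transcript_id = "t1",
                             start = c(0, 200), end = c(100, 300)))
  b <- flatten_exons(gm)
  expect_equal(b$start, c(0, 200))
  expect_equal(b$end, c(100, 300))
  ## nested 3' extension: split at the shared boundary
  gm <- simple_gm(data.frame(transcript_id = c("t1", "t2"),
                             start = c(0, 0), end = c(100, 150)))
  b <- flatten_exons(gm)
  expect_equal(b$start, c(0, 100))
  expect_equal(b$end, c(100, 150))
  ## internal containment: three bins
  gm <- simple_gm(data.frame(transcript_id = c("t1", "t2"),
                             start = c(0, 50), end = c(100, 80)))
  b <- flatten_exons(gm)
  expect_equal(b$start, c(0, 50, 80))
  expect_equal(b$end, c(50, 80, 100))
})

test_that("flatten_exons matches the per-base oracle on random genes", {
  set.seed(7)
  for (i in 1:60) {
    gm <- random_gene(max_tx = 6, max_exons = 10, span = 1500)
    b <- flatten_exons(gm)
    o <- oracle_flatten(gm$exons)
    expect_equal(b$start, o$start)
    expect_equal(b$end, o$end)
    ## bins disjoint and total length equals exon-union length
    expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
    expect_equal(sum(b$end - b$start), sum(o$end - o$start))
  }
})

test_that("functional types follow per-base CDS classification", {
  ## exon fully upstream of CDS on + strand
  gm <- simple_gm(data.frame(transcript_id = "t1",
                             start = c(0, 200, 400), end = c(100, 300, 500)),
                  cds = c(220, 450))
  b <- flatten_exons(gm)
  expect_equal(b$functional_type[b$start == 0], "five_prime_utr")
  ## bin spanning the CDS start mixes UTR and CDS bases
  expect_equal(b$functional_type[b$start == 200], "multi_type")
  ## noncoding gene: everything noncoding
  gm2 <- simple_gm(data.frame(transcript_id = "t1",
                              start = 0, end = 100), biotype = "noncoding")
  expect_equal(flatten_exons(gm2)$functional_type, "noncoding")
})

test_that("functional types agree with the brute-force oracle", {
  set.seed(11)
  for (i in 1:25) {
    gm <- random_gene(max_tx = 4, max_exons = 8, span = 800)
    b <- flatten_exons(gm)
    for (j in seq_len(nrow(b))) {
      expect_equal(
        b$functional_type[j],
        oracle_functional_type(b$start[j], b$end[j], gm$transcripts,
                               gm$exons, gm$genes$biotype))
    }
  }
})

test_that("3'-terminal flag marks bins holding a transcript end", {
  gm <- simple_gm(data.frame(transcript_id = "t1",
                             start = c(0, 200), end = c(100, 300)))
  b <- flatten_exons(gm)
  expect_equal(b$is_three_prime_terminal, c(FALSE, TRUE))
  gmm <- simple_gm(data.frame(transcript_id = "t1",
                              start = c(0, 200), end = c(100, 300)),
                   strand = "-")
  bm <- flatten_exons(gmm)
  ## minus strand: the 3' end is the genomic-leftmost base
  expect_equal(bm$is_three_prime_terminal[bm$start == 0], TRUE)
  expect_equal(bm$is_three_prime_terminal[bm$start == 200], FALSE)
})

test_that("catalog_junctions enumerates, dedups and filters", {
  ## single 3-exon transcript: two junctions
  gm <- simple_gm(data.frame(transcript_id = "t1",
                             start = c(0, 200, 400),
                             end = c(100, 300, 500)))
  j <- catalog_junctions(gm)
  expect_equal(nrow(j), 2)
  expect_equal(j$donor, c(99, 299))
  expect_equal(j$acceptor, c(200, 400))
  ## shared junction deduplicated, canonical
  gm2 <- simple_gm(data.frame(
    transcript_id = c("t1", "t1", "t2", "t2"),
    start = c(0, 200, 0, 200), end = c(100, 300, 100, 300)))
  j2 <- catalog_junctions(gm2)
  expect_equal(nrow(j2), 1)
  expect_true(j2$canonical)
  ## a 40-bp intron is excluded at the default 50-bp minimum
  gm3 <- simple_gm(data.frame(transcript_id = "t1",
                              start = c(0, 140), end = c(100, 240)))
  expect_equal(nrow(catalog_junctions(gm3)), 0)
  expect_equal(nrow(catalog_junctions(gm3, min_intron = 40)), 1)
  ## flanking exon below 25 bp excluded
  gm4 <- simple_gm(data.frame(transcript_id = "t1",
                              start = c(0, 200), end = c(20, 300)))
  expect_equal(nrow(catalog_junctions(gm4)), 0)
})

test_that("junction count equals the naive dedup of consecutive pairs", {
  set.seed(5)
  for (i in 1:30) {
    gm <- random_gene(max_tx = 6, max_exons = 8, span = 4000)
    j <- catalog_junctions(gm, min_exon = 1, min_intron = 1)
    naive <- unique(do.call(rbind, lapply(
      split(gm$exons, gm$exons$transcript_id), function(d) {
        d <- d[order(d$start), ]
        if (nrow(d) < 2) return(NULL)
        data.frame(donor = d$end[-nrow(d)] - 1, acceptor = d$start[-1])
      })))
    expect_equal(nrow(j), if (is.null(naive)) 0L else nrow(naive))
  }
})

test_that("minus-strand junctions are strand-aware", {
  gm <- simple_gm(data.frame(transcript_id = "t1",
                             start = c(0, 200, 400),
                             end = c(100, 300, 500)), strand = "-")
  j <- catalog_junctions(gm)
  ## transcription runs right to left: first junction joins the rightmost
  ## exon (donor = its genomic start) to the middle exon's genomic end - 1
  expect_equal(j$donor, c(400, 200))
  expect_equal(j$acceptor, c(299, 99))
  expect_true(all(j$intron_length == 100))
})

test_that("get_interval_seq is strand-aware", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTAA"))
  expect_equal(get_interval_seq(genome, "chr1", 0, 4, "+"), "ACGT")
  expect_equal(get_interval_seq(genome, "chr1", 0, 4, "-"), "ACGT")
  expect_equal(get_interval_seq(genome, "chr1", 4, 8, "-"), "ACGT")
  expect_equal(get_interval_seq(genome, "chr1", 6, 10, "+"), "GTAA")
  expect_equal(get_interval_seq(genome, "chr1", 6, 10, "-"), "TTAC")
  expect_error(get_interval_seq(genome, "chrX", 0, 4), "chromosome")
})
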