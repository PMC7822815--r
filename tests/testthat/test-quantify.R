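two_cond_samples <- function(ids) {
  sample_info(ids, rep(c("siMM", "siRR"), length.out = length(ids)),
              rep(seq_along(ids), length.out = length(ids)))
}

test_that("count_bins counts each fragment once per overlapped bin", {
  bins <- data.frame(bin_id = c("b1", "b2", "b3"), gene_id = "g1",
                     chrom = "chr1", start = c(0, 100, 200),
                     end = c(100, 200, 300), strand = "+")
  reads <- list(
    list(qname = "r1", chrom = "chr1", pos = 10, cigar = "50M"),
    list(qname = "r2", chrom = "chr1", pos = 80, cigar = "40M"),
    list(qname = "r3", chrom = "chr1", pos = 41, cigar = "50M110N40M"))
  bam <- write_toy_bam(reads, c(chr1 = 1000))
  m <- count_bins(c(s1 = bam), bins,
                  sample_info("s1", "siMM", 1))
  ## r1 inside b1; r2 spans b1+b2; r3 blocks in b1 and b3, gap over b2
  expect_equal(unname(m$counts[, "s1"]), c(3, 1, 1))
})

test_that("count_bins respects MAPQ filtering and missing index errors", {
  bins <- data.frame(bin_id = "b1", gene_id = "g1", chrom = "chr1",
                     start = 0, end = 100, strand = "+")
  reads <- list(
    list(qname = "r1", chrom = "chr1", pos = 10, cigar = "50M", mapq = 5),
    list(qname = "r2", chrom = "chr1", pos = 10, cigar = "50M", mapq = 60))
  bam <- write_toy_bam(reads, c(chr1 = 1000))
  m <- count_bins(c(s1 = bam), bins, sample_info("s1", "siMM", 1))
  expect_equal(unname(m$counts[1, 1]), 1)
  file.remove(paste0(bam, ".bai"))
  expect_error(count_bins(c(s1 = bam), bins,
                          sample_info("s1", "siMM", 1)), "index")
})

test_that("extract_junctions counts gaps and assigns novel junctions", {
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               biotype = "protein_coding"),
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", tss = 0, cds_start = NA, cds_end = NA),
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               start = c(0, 200, 400), end = c(100, 300, 500),
               strand = "+"))
  catalog <- catalog_junctions(gm)
  ## 10 reads across the annotated first junction (gap 100..199 1-based
  ## 101..200), 6 reads with a novel gap inside the gene, 1 read with two
  ## gaps chaining both annotated junctions
  reads <- c(
    lapply(1:10, function(i)
      list(qname = paste0("a", i), chrom = "chr1", pos = 51,
           cigar = "50M100N50M")),
    lapply(1:6, function(i)
      list(qname = paste0("n", i), chrom = "chr1", pos = 51,
           cigar = "50M120N50M")),
    list(list(qname = "d1", chrom = "chr1", pos = 51,
              cigar = "50M100N100M100N50M")))
  bam <- write_toy_bam(reads, c(chr1 = 1000))
  m <- extract_junctions(c(s1 = bam), catalog, gm,
                         sample_info("s1", "siMM", 1), min_reads = 1)
  f <- m$features
  expect_equal(unname(m$counts[f$junction_id == "g1:99-200", 1]), 11)
  expect_equal(unname(m$counts[f$junction_id == "g1:299-400", 1]), 1)
  nov <- f[!f$canonical, ]
  expect_equal(nrow(nov), 1)
  expect_equal(nov$gene_id, "g1")
  expect_equal(unname(m$counts[f$junction_id == nov$junction_id, 1]), 6)
})

test_that("short gaps are ignored and tallied, min_reads filters", {
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               biotype = "protein_coding"),
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", tss = 0, cds_start = NA, cds_end = NA),
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               start = c(0, 200), end = c(100, 300), strand = "+"))
  catalog <- catalog_junctions(gm)
  reads <- list(
    list(qname = "s1r", chrom = "chr1", pos = 51, cigar = "50M30N50M"),
    list(qname = "s2r", chrom = "chr1", pos = 51, cigar = "50M100N50M"))
  bam <- write_toy_bam(reads, c(chr1 = 1000))
  m <- extract_junctions(c(s1 = bam), catalog, gm,
                         sample_info("s1", "siMM", 1), min_reads = 1)
  expect_equal(attr(m, "short_gaps"), 1L)
  expect_equal(nrow(m$counts), 1)
  ## min_reads = 5 drops the singleton junction
  m2 <- extract_junctions(c(s1 = bam), catalog, gm,
                          sample_info("s1", "siMM", 1), min_reads = 5)
  expect_equal(nrow(m2$counts), 0)
})

test_that("extract_junctions equals a brute-force CIGAR interpreter", {
  set.seed(21)
  gm <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               biotype = "protein_coding"),
    data.frame(transcript_id = "t1", gene_id = "g1", chrom = "chr1",
               strand = "+", tss = 0, cds_start = NA, cds_end = NA),
    data.frame(gene_id = "g1", transcript_id = "t1", chrom = "chr1",
               start = c(0, 5000), end = c(100, 5100), strand = "+"))
  catalog <- catalog_junctions(gm)
  n <- 2000
  reads <- lapply(seq_len(n), function(i) {
    pos <- sample.int(2000, 1)
    gaps <- sample(0:2, 1)
    cigar <- "30M"
    for (k in seq_len(gaps))
      cigar <- paste0(cigar, sample(60:400, 1), "N", sample(20:50, 1), "M")
    list(qname = paste0("r", i), chrom = "chr1", pos = pos, cigar = cigar)
  })
  bam <- write_toy_bam(reads, c(chr1 = 10000))
  m <- extract_junctions(c(s1 = bam), catalog, gm,
                         sample_info("s1", "siMM", 1),
                         min_intron = 50, min_reads = 1)
  ## oracle tally over raw CIGARs (gaps >= 50, inside the gene span)
  tal <- table(unlist(lapply(reads, function(r)
    oracle_cigar_gaps(r$chrom, r$pos, r$cigar))))
  keys <- do.call(rbind, strsplit(names(tal), " "))
  glen <- as.integer(keys[, 3]) - as.integer(keys[, 2]) + 1
  inside <- as.integer(keys[, 2]) - 2 >= 0 & as.integer(keys[, 3]) < 5100
  tal <- tal[glen >= 50 & inside]
  keys <- keys[glen >= 50 & inside, , drop = FALSE]
  expect_equal(nrow(m$counts), nrow(keys))
  jid <- sprintf("g1:%d-%d", as.integer(keys[, 2]) - 2L,
                 as.integer(keys[, 3]))
  expect_equal(unname(m$counts[jid, 1]), unname(as.integer(tal)))
})

test_that("cpm_normalize follows its closed form", {
  counts <- matrix(c(0L, 1L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  m <- count_matrix(counts, sample_info("s1", "siMM", 1),
                    library_sizes = c(s1 = 1e6))
  v <- cpm_normalize(m)
  expect_equal(unname(v["a", 1]), log2(0.5))
  expect_equal(unname(v["b", 1]), log2(1.5))
  ## doubling the library size lowers every value by exactly one
  m2 <- count_matrix(counts, sample_info("s1", "siMM", 1),
                     library_sizes = c(s1 = 2e6))
  expect_equal(cpm_normalize(m2), v - 1)
  m0 <- count_matrix(counts, sample_info("s1", "siMM", 1))
  m0$library_sizes[1] <- 0
  expect_error(cpm_normalize(m0), "library")
})

test_that("retained-intron detection applies both thresholds per condition", {
  samples <- sample_info(paste0(rep(c("siMM", "siRR"), each = 3), "_",
                                1:3),
                         rep(c("siMM", "siRR"), each = 3),
                         rep(1:3, 2))
  sn <- samples$sample_id
  f5 <- matrix(100, 3, 6, dimnames = list(paste0("i", 1:3), sn))
  f3 <- f5
  cov <- matrix(0, 3, 6, dimnames = list(paste0("i", 1:3), sn))
  ## i1: zero coverage everywhere -> not detected
  ## i2: above both thresholds in 2 of 3 siRR replicates only
  cov["i2", c("siRR_1", "siRR_2")] <- 50
  ## i3: above thresholds in both conditions
  cov["i3", ] <- 50
  calls <- detect_retained_introns(cov, f5, f3, samples)
  expect_equal(calls$specificity,
               c("not_detected", "siRR_specific", "shared"))
  ## relative threshold: high absolute but low relative coverage fails
  cov2 <- cov; cov2["i1", ] <- 8   # 8 < 0.1 * 100
  calls2 <- detect_retained_introns(cov2, f5, f3, samples)
  expect_equal(calls2$specificity[1], "not_detected")
  ## absolute threshold: relative pass but below c_abs fails
  f5b <- f5 / 10; f3b <- f3 / 10
  cov3 <- cov; cov3["i1", ] <- 4   # 4 >= 0.1*10 but < 5
  calls3 <- detect_retained_introns(cov3, f5b, f3b, samples)
  expect_equal(calls3$specificity[1], "not_detected")
})

test_that("introns without flanks are skipped with a message", {
  samples <- sample_info(paste0(rep(c("siMM", "siRR"), each = 2), "_",
                                1:2),
                         rep(c("siMM", "siRR"), each = 2), rep(1:2, 2))
  sn <- samples$sample_id
  cov <- matrix(50, 2, 4, dimnames = list(c("i1", "i2"), sn))
  f5 <- matrix(100, 2, 4, dimnames = list(c("i1", "i2"), sn))
  f3 <- f5
  f5["i2", ] <- NA
  f3["i2", ] <- NA
  expect_message(calls <- detect_retained_introns(cov, f5, f3, samples),
                 "skipped")
  expect_equal(calls$specificity[2], "not_detected")
})

test_that("count table TSV round-trips", {
  counts <- matrix(1:6, 3, 2,
                   dimnames = list(paste0("f", 1:3), c("s1", "s2")))
  samples <- two_cond_samples(c("s1", "s2"))
  m <- count_matrix(counts, samples)
  p <- tempfile(fileext = ".tsv")
  write_counts_tsv(m, p)
  m2 <- read_counts_tsv(p, samples)
  expect_equal(m2$counts, m$counts)
})

test_that("count_matrix enforces its invariants", {
  counts <- matrix(-1L, 1, 1, dimnames = list("f1", "s1"))
  expect_error(count_matrix(counts, sample_info("s1", "siMM", 1)),
               "non-negative")
  counts2 <- matrix(5L, 1, 2, dimnames = list("f1", c("s1", "s2")))
  expect_error(count_matrix(counts2,
                            sample_info(c("s1", "s2"), "siMM", c(1, 1))),
               "unique")
  expect_error(count_matrix(matrix(10L, 1, 1,
                                   dimnames = list("f1", "s1")),
                            sample_info("s1", "siMM", 1),
                            library_sizes = -5),
               "library_sizes")
})
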