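test_that("JASPAR-style PWM text parses into log-odds matrices", {
  p <- tempfile()
  writeLines(c(">M1 RBFOX2",
               "A [ 0 0 0 97 0 0 ]",
               "C [ 0 0 97 0 0 0 ]",
               "G [ 0 97 0 0 0 97 ]",
               "T [ 97 0 0 0 97 0 ]"), p)
  pwms <- read_pwm_jaspar(p)
  expect_equal(names(pwms), "RBFOX2")
  pw <- pwms$RBFOX2
  expect_equal(dim(pw$matrix), c(4, 6))
  expect_equal(rownames(pw$matrix), c("A", "C", "G", "T"))
  ## consensus base log-odds: log2(((97+.25)/98)/0.25)
  expect_equal(unname(pw$matrix["T", 1]), log2((97.25 / 98) / 0.25),
               tolerance = 1e-12)
  ## threshold at 80% of the maximum attainable score
  expect_equal(pw$hit_threshold,
               0.8 * sum(apply(pw$matrix, 2, max)), tolerance = 1e-12)
  writeLines(c(">bad X", "A [ 1 ]", "C [ 1 ]", "G [ 1 ]"), p)
  expect_error(read_pwm_jaspar(p), "four bases")
})

test_that("scan_pwm scores every offset and flags hits", {
  pwms <- default_pwms()
  pw <- pwms$RBFOX2
  seqr <- paste0("AAAAAAAAAAAA", "TGCATG", "AAAAAAAA")
  hits <- scan_pwm(seqr, pw)
  expect_equal(nrow(hits), nchar(seqr) - 6 + 1)
  expect_equal(hits$offset[which.max(hits$score)], 12)
  expect_true(hits$hit[hits$offset == 12])
  expect_equal(max(hits$score), sum(apply(pw$matrix, 2, max)))
  ## too-short sequence yields an empty result
  expect_equal(nrow(scan_pwm("ACG", pw)), 0)
  ## N contributes zero
  h2 <- scan_pwm("TGCNTG", pw)
  expect_equal(h2$score,
               sum(mapply(function(b, j) pw$matrix[b, j],
                          c("T", "G", "C", "T", "G"), c(1, 2, 3, 5, 6))))
})

test_that("scan_pwm equals the brute-force oracle on random inputs", {
  set.seed(41)
  for (i in 1:100) {
    w <- sample(4:9, 1)
    counts <- matrix(sample(0:30, 4 * w, replace = TRUE), 4)
    p <- tempfile()
    writeLines(c(">M X",
                 paste("A [", paste(counts[1, ], collapse = " "), "]"),
                 paste("C [", paste(counts[2, ], collapse = " "), "]"),
                 paste("G [", paste(counts[3, ], collapse = " "), "]"),
                 paste("T [", paste(counts[4, ], collapse = " "), "]")), p)
    pw <- read_pwm_jaspar(p)[[1]]
    seqr <- paste(sample(c("A", "C", "G", "T", "N"), sample(10:60, 1),
                         replace = TRUE, prob = c(rep(0.24, 4), 0.04)),
                  collapse = "")
    got <- scan_pwm(seqr, pw)$score
    expect_equal(got, oracle_scan_pwm(seqr, pw$matrix), tolerance = 1e-10)
  }
})

test_that("minus-strand scanning equals scanning the reverse complement", {
  pwms <- default_pwms()
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")))
  fwd <- get_interval_seq(genome, "chr1", 50, 150, "+")
  rev <- get_interval_seq(genome, "chr1", 50, 150, "-")
  expect_equal(rev, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd))))
  expect_equal(scan_pwm(rev, pwms$RBFOX2)$score,
               oracle_scan_pwm(rev, pwms$RBFOX2$matrix), tolerance = 1e-10)
})

## a junction row with the fields motif_features needs
feat_jrow <- function(donor, acceptor, strand = "+", chrom = "chr1",
                      del = 100, ael = 100) {
  data.frame(junction_id = "j1", gene_id = "g1", chrom = chrom,
             donor = donor, acceptor = acceptor, strand = strand,
             intron_length = abs(acceptor - donor) - 1,
             donor_exon_length = del, acceptor_exon_length = ael)
}

test_that("planted RBFOX2 element 12 nt into the intron is recovered", {
  set.seed(4)
  base <- sample(c("A", "C"), 1200, replace = TRUE)
  seqs <- paste(base, collapse = "")
  ## donor at 399 (exon [300,400)), consensus at intron offset 12
  seqs <- paste0(substr(seqs, 1, 400 + 12), "TGCATG",
                 substr(seqs, 400 + 12 + 7, 1200))
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  pwms <- default_pwms()
  mf <- motif_features(feat_jrow(399, 800), genome, pwms["RBFOX2"])
  expect_gt(mf$RBFOX2_intron_5p_freq, 0)
  expect_equal(mf$RBFOX2_intron_5p_strength,
               sum(apply(pwms$RBFOX2$matrix, 2, max)), tolerance = 1e-10)
})

test_that("motif frequency is hits per kilobase of window", {
  ## two consensus plants in the 100-nt downstream exon window
  seqs <- paste(rep("A", 1200), collapse = "")
  seqs <- paste0(substr(seqs, 1, 800), "TGCATG",
                 substr(seqs, 807, 840), "TGCATG",
                 substr(seqs, 847, 1200))
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  pwms <- default_pwms()
  mf <- motif_features(feat_jrow(399, 800), genome, pwms["RBFOX2"])
  expect_equal(mf$RBFOX2_downstream_exon_freq, 2 / (100 / 1000))
  ## zero hits give zero frequency
  expect_equal(mf$RBFOX2_intron_3p_freq, 0)
})

test_that("windows are clipped at short features with sentinels", {
  seqs <- paste(rep("A", 600), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = seqs))
  pwms <- default_pwms()
  ## 4-nt donor exon: window shorter than any motif -> sentinel strength
  mf <- motif_features(feat_jrow(99, 500, del = 4), genome,
                       pwms["RBFOX2"])
  expect_equal(mf$RBFOX2_upstream_exon_strength, -50)
  expect_equal(mf$RBFOX2_upstream_exon_freq, 0)
})

test_that("peak distances match the brute-force nearest-interval oracle", {
  set.seed(13)
  for (i in 1:40) {
    n <- sample(1:15, 1)
    st <- sort(sample.int(5000, n))
    en <- st + sample(50:200, n, replace = TRUE)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st + 1, en))
    pos <- sample.int(5500, 8)
    jx <- data.frame(junction_id = paste0("j", 1:4), gene_id = "g",
                     chrom = "chr1", donor = pos[1:4],
                     acceptor = pos[5:8], strand = "+")
    pd <- peak_distances(jx, list(mark = pk))
    for (k in 1:4) {
      expect_equal(pd$mark_donor_dist[k],
                   oracle_nearest_dist(pos[k], st, en))
      expect_equal(pd$mark_acceptor_dist[k],
                   oracle_nearest_dist(pos[4 + k], st, en))
    }
  }
})

test_that("peak distances: inside = 0, edges exact, missing chrom = Inf", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1201, 1300))
  jx <- data.frame(junction_id = c("a", "b"), gene_id = "g",
                   chrom = c("chr1", "chr9"), donor = c(1000, 1000),
                   acceptor = c(1250, 1250), strand = "+")
  pd <- peak_distances(jx, list(m = pk))
  expect_equal(pd$m_donor_dist[1], 200)
  expect_equal(pd$m_acceptor_dist[1], 0)
  expect_equal(pd$m_donor_dist[2], Inf)
})

test_that("adding peaks never increases a distance; translation invariance", {
  set.seed(19)
  st <- sort(sample.int(4000, 6)); en <- st + 100
  pk1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st + 1, en))
  extra <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2501, 2600))
  pk2 <- GenomicRanges::sort(c(pk1, extra))
  jx <- data.frame(junction_id = paste0("j", 1:5), gene_id = "g",
                   chrom = "chr1", donor = sample.int(4500, 5),
                   acceptor = sample.int(4500, 5), strand = "+")
  d1 <- peak_distances(jx, list(m = pk1))
  d2 <- peak_distances(jx, list(m = pk2))
  expect_true(all(d2$m_donor_dist <= d1$m_donor_dist))
  ## translating peaks and sites together leaves distances unchanged
  sh <- 750
  pk_s <- GenomicRanges::shift(pk1, sh)
  jx_s <- jx; jx_s$donor <- jx$donor + sh; jx_s$acceptor <- jx$acceptor + sh
  d3 <- peak_distances(jx_s, list(m = pk_s))
  expect_equal(d3$m_donor_dist, d1$m_donor_dist)
  expect_equal(d3$m_acceptor_dist, d1$m_acceptor_dist)
})

test_that("open-chromatin association tests peak overlap of site groups", {
  ## identical overlap rates: OR = 1
  res <- open_chromatin_association(c(0, 0, 500, 500), c(0, 0, 500, 500))
  expect_equal(res$odds_ratio, 1)
  ## complete separation, Haldane-corrected OR, exact Fisher p
  res2 <- open_chromatin_association(rep(0, 10), rep(900, 10))
  expect_equal(res2$odds_ratio, (10.5 * 10.5) / (0.5 * 0.5))
  expect_equal(res2$p, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-10)
  expect_error(open_chromatin_association(numeric(0), c(1, 2)), "empty")
})

test_that("distance comparison between site groups uses Mann-Whitney", {
  set.seed(8)
  a <- rexp(60, 1 / 200); b <- rexp(60, 1 / 2000)
  res <- site_distance_test(a, b)
  expect_lt(res$p, 1e-4)
  expect_lt(res$median_a, res$median_b)
  expect_equal(res$p, wilcox.test(a, b, exact = FALSE)$p.value)
})

test_that("planted peak association is detected (OR > 5, p < 0.01)", {
  cfg <- sim_config(seed = 5)
  ann <- simulate_annotation(cfg)
  peaks <- simulate_peaks(ann)
  catalog <- catalog_junctions(ann$gm)
  pd <- peak_distances(catalog, peaks["fusion_TF"])
  is_diff <- catalog$junction_id %in% ann$truth$diff_junctions
  res <- open_chromatin_association(pd$fusion_TF_donor_dist[is_diff],
                                    pd$fusion_TF_donor_dist[!is_diff],
                                    max_dist = 600)
  expect_gt(res$odds_ratio, 5)
  expect_lt(res$p, 0.01)
})

test_that("BED peaks round-trip through the reader", {
  p <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t650", "chr2\t0\t50"), p)
  gr <- read_bed(p)
  expect_equal(length(gr), 3)
  expect_equal(GenomicRanges::start(gr), c(101, 501, 1))
  expect_equal(GenomicRanges::end(gr), c(200, 650, 50))
})
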