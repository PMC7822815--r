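## Independent brute-force oracles used to freeze expected values. Each is
## written as directly as possible and stays independent of the package
## code paths it checks.

## per-base exon flattening: walk every base of the gene span and record
## the covering-transcript set; bins are maximal runs of a constant
## non-empty set
oracle_flatten <- function(exons) {
  lo <- min(exons$start); hi <- max(exons$end)
  txs <- sort(unique(exons$transcript_id))
  ## per-base covering set encoded as a bitmask over transcripts
  mask <- numeric(hi - lo)
  for (i in seq_len(nrow(exons))) {
    bit <- 2^(match(exons$transcript_id[i], txs) - 1)
    idx <- (exons$start[i] - lo + 1):(exons$end[i] - lo)
    mask[idx] <- mask[idx] + ifelse(floor(mask[idx] / bit) %% 2 == 1, 0, bit)
  }
  runs <- rle(mask)
  pos <- lo + cumsum(c(0, runs$lengths))
  keep <- runs$values != 0
  decode <- vapply(runs$values[keep], function(v)
    paste(txs[which(floor(v / 2^(seq_along(txs) - 1)) %% 2 == 1)],
          collapse = ","), character(1))
  data.frame(start = pos[-length(pos)][keep], end = pos[-1][keep],
             covering = decode, stringsAsFactors = FALSE)
}

## per-base functional classification of one interval against a gene
oracle_functional_type <- function(s, e, gene_tx, gene_exons, biotype) {
  if (biotype == "noncoding") return("noncoding")
  cats <- character(0)
  for (k in seq_len(nrow(gene_tx))) {
    tx <- gene_tx[k, ]
    te <- gene_exons[gene_exons$transcript_id == tx$transcript_id, ,
                     drop = FALSE]
    for (b in s:(e - 1)) {
      inside <- any(te$start <= b & te$end > b)
      if (!inside) next
      if (is.na(tx$cds_start)) { cats <- c(cats, "noncoding"); next }
      if (tx$strand == "+") {
        cc <- if (b < tx$cds_start) "five_prime_utr"
              else if (b >= tx$cds_end) "three_prime_utr" else "cds"
      } else {
        cc <- if (b >= tx$cds_end) "five_prime_utr"
              else if (b < tx$cds_start) "three_prime_utr" else "cds"
      }
      cats <- c(cats, cc)
    }
  }
  cats <- unique(cats)
  if (length(cats) == 0) NA_character_
  else if (length(cats) == 1) cats else "multi_type"
}

## hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

## two-sided Fisher p as the hypergeometric tail sum: sum the probabilities
## of all tables with the same margins whose probability does not exceed
## the observed one (with the standard relative tolerance)
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

## per-offset PWM scoring by explicit double loop
oracle_scan_pwm <- function(seq, mat) {
  w <- ncol(mat)
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  if (n < w) return(numeric(0))
  vapply(0:(n - w), function(off) {
    s <- 0
    for (j in 1:w) {
      b <- chars[off + j]
      s <- s + if (b %in% rownames(mat)) mat[b, j] else 0
    }
    s
  }, numeric(1))
}

## nearest-interval distance by scanning every interval
oracle_nearest_dist <- function(pos, starts, ends) {
  if (length(starts) == 0) return(Inf)
  d <- Inf
  for (i in seq_along(starts)) {
    di <- if (pos >= starts[i] && pos < ends[i]) 0
          else min(abs(pos - starts[i]), abs(pos - (ends[i] - 1)))
    d <- min(d, di)
  }
  d
}

## longest AUG-initiated stop-terminated ORF by explicit 3-frame walk
oracle_main_orf <- function(seq, min_codons = 100) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  best <- NULL
  for (st in seq_len(max(0, n - 5))) {
    if (paste(chars[st:(st + 2)], collapse = "") != "ATG") next
    pos <- st
    while (pos + 5 <= n) {
      cod <- paste(chars[(pos + 3):(pos + 5)], collapse = "")
      if (cod %in% c("TAA", "TAG", "TGA")) break
      pos <- pos + 3
    }
    if (pos + 5 > n) next                       # ran off the end: no stop
    len_aa <- (pos + 3 - st) / 3
    if (is.null(best) || len_aa > best$len)
      best <- list(start = st - 1L, stop = pos + 5L, len = len_aa)
  }
  if (is.null(best) || best$len < min_codons) return(list(coding = FALSE))
  c(best, coding = TRUE)
}

## random multi-transcript gene models for property tests
random_gene <- function(gene_id = "G1", max_tx = 10, max_exons = 20,
                        span = 5000, coding = TRUE) {
  n_tx <- sample.int(max_tx, 1)
  ex <- list()
  for (t in seq_len(n_tx)) {
    ne <- sample.int(max_exons, 1)
    bounds <- sort(sample.int(span, 2 * ne))
    ex[[t]] <- data.frame(
      gene_id = gene_id, transcript_id = paste0(gene_id, ".t", t),
      chrom = "chr1",
      start = bounds[seq(1, 2 * ne, 2)], end = bounds[seq(2, 2 * ne, 2)],
      strand = "+", stringsAsFactors = FALSE)
  }
  exons <- do.call(rbind, ex)
  lo <- min(exons$start); hi <- max(exons$end)
  cand_s <- lo + floor((hi - lo) / 4)
  cand_e <- hi - floor((hi - lo) / 4)
  tx <- do.call(rbind, lapply(split(exons, exons$transcript_id),
    function(d) {
      ## snap CDS bounds onto exonic bases of this transcript
      cs <- ce <- NA_integer_
      if (coding) {
        ov <- d[d$end > cand_s & d$start < cand_e, , drop = FALSE]
        if (nrow(ov) > 0) {
          cs <- max(min(ov$start), cand_s)
          ce <- min(max(ov$end), cand_e)
        }
      }
      data.frame(
        transcript_id = d$transcript_id[1], gene_id = gene_id,
        chrom = "chr1", strand = "+", tss = min(d$start),
        cds_start = cs, cds_end = ce, stringsAsFactors = FALSE)
    }))
  gene_models(
    data.frame(gene_id = gene_id, chrom = "chr1", strand = "+",
               biotype = if (coding) "protein_coding" else "noncoding",
               stringsAsFactors = FALSE),
    tx, exons)
}

## minimal SAM writer + BAM conversion for alignment-level tests
write_toy_bam <- function(reads, chrom_lens, dir = tempfile("bam")) {
  dir.create(dir, showWarnings = FALSE)
  sam <- file.path(dir, "toy.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(chrom_lens), "\tLN:", chrom_lens))
  body <- vapply(reads, function(r)
    paste(r$qname, r$flag %||% 0L, r$chrom, r$pos, r$mapq %||% 60L,
          r$cigar, "*", 0, 0,
          paste(rep("A", sum(as.integer(
            regmatches(r$cigar,
                       gregexpr("[0-9]+(?=[MIS=X])", r$cigar,
                                perl = TRUE))[[1]]))), collapse = ""),
          "*", sep = "\t"),
    character(1))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE)
  bam
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## brute-force CIGAR interpreter: returns the (chrom, 1-based intron
## start/end) keys of every N gap of a read
oracle_cigar_gaps <- function(chrom, pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  ref <- pos
  gaps <- character(0)
  for (op in ops) {
    len <- as.integer(sub("[A-Z=]", "", op))
    code <- sub("[0-9]+", "", op)
    if (code %in% c("M", "D", "=", "X")) ref <- ref + len
    else if (code == "N") {
      gaps <- c(gaps, paste(chrom, ref, ref + len - 1))
      ref <- ref + len
    }
  }
  gaps
}

## independent enumeration oracle: decide the mode of a junction placement
## from first principles on a gene whose annotated structure is known
oracle_mode <- function(donor, acceptor, donors, acceptors, pairs,
                        exon_df, tx_sets) {
  if (paste(donor, acceptor) %in% pairs) return("canonical")
  dc <- donor %in% donors; ac <- acceptor %in% acceptors
  lo <- min(donor, acceptor) + 1; hi <- max(donor, acceptor)
  skip <- exon_df[exon_df$start >= lo & exon_df$end <= hi, , drop = FALSE]
  if (dc && ac) {
    if (nrow(skip) == 0) return("complex")
    if (nrow(skip) >= 2) {
      keys <- paste(skip$start, skip$end)
      for (x in seq_along(keys)) for (y in seq_along(keys)) {
        if (x >= y) next
        inx <- vapply(tx_sets, function(s) keys[x] %in% s, logical(1))
        iny <- vapply(tx_sets, function(s) keys[y] %in% s, logical(1))
        if (any(inx) && any(iny) && !any(inx & iny))
          return("mutually_exclusive")
      }
    }
    return("cassette_skipping")
  }
  if (dc || ac) {
    if (nrow(skip) > 0) return("complex")
    return(if (ac) "alt_5ss" else "alt_3ss")
  }
  "complex"
}
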