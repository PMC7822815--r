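#' Construct a gene-model container
#'
#' Holds gene annotations as three linked data frames (genes, transcripts,
#' exons) using 0-based half-open genomic coordinates throughout. GTF input
#' and output convert from/to the 1-based inclusive convention at the I/O
#' boundary only.
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `biotype` (`"protein_coding"` or `"noncoding"`).
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `tss` (0-based position of the first transcribed
#'   base, strand-aware), `cds_start`, `cds_end` (0-based half-open span of
#'   the CDS, `NA` for non-coding transcripts).
#' @param exons data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, transcripts, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "biotype") %in% names(genes)),
            all(c("transcript_id", "gene_id", "chrom", "strand", "tss",
                  "cds_start", "cds_end") %in% names(transcripts)),
            all(c("gene_id", "transcript_id", "chrom", "start", "end",
                  "strand") %in% names(exons)))
  if (any(exons$start >= exons$end))
    stop("exon intervals must satisfy start < end (0-based half-open)")
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  ## transcripts of one gene must share chrom and strand
  chk <- merge(transcripts[, c("transcript_id", "gene_id", "chrom", "strand")],
               genes[, c("gene_id", "chrom", "strand")],
               by = "gene_id", suffixes = c("", ".gene"))
  bad <- chk$chrom != chk$chrom.gene | chk$strand != chk$strand.gene
  if (any(bad))
    stop("transcripts disagree with gene chrom/strand: ",
         paste(chk$transcript_id[bad], collapse = ", "))
  ## exons within a transcript must be disjoint
  sp <- split(exons, exons$transcript_id)
  for (tx in sp) {
    o <- order(tx$start)
    if (any(tx$start[o][-1] < tx$end[o][-nrow(tx)]))
      stop("overlapping exons within transcript ", tx$transcript_id[1])
  }
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from a GTF file (Ensembl dialect)
#'
#' Parses exon and CDS records, groups transcripts under genes, and converts
#' coordinates to the package's internal 0-based half-open convention. The
#' transcript TSS is the strand-aware first transcribed base; the CDS span,
#' when present, is the union span of a transcript's CDS records.
#'
#' @param path GTF file path.
#' @return A [gene_models] object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    stop("GTF records lack gene_id/transcript_id attributes: ", path)
  type <- as.character(md$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0) stop("no exon records in ", path)
  exons <- data.frame(
    gene_id = as.character(S4Vectors::mcols(ex)$gene_id),
    transcript_id = as.character(S4Vectors::mcols(ex)$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex),
    strand = as.character(GenomicRanges::strand(ex)),
    stringsAsFactors = FALSE)
  cds <- gr[type == "CDS"]
  cds_span <- NULL
  if (length(cds) > 0) {
    cd <- data.frame(tx = as.character(S4Vectors::mcols(cds)$transcript_id),
                     start = GenomicRanges::start(cds) - 1L,
                     end = GenomicRanges::end(cds))
    cds_span <- do.call(rbind, lapply(split(cd, cd$tx), function(d)
      data.frame(transcript_id = d$tx[1], cds_start = min(d$start),
                 cds_end = max(d$end))))
  }
  tx_first <- exons[!duplicated(exons$transcript_id), ]
  tx_sp <- split(exons, exons$transcript_id)
  tss <- vapply(tx_sp, function(d)
    if (d$strand[1] == "+") min(d$start) else max(d$end) - 1L, integer(1))
  transcripts <- data.frame(
    transcript_id = names(tx_sp),
    gene_id = vapply(tx_sp, function(d) d$gene_id[1], character(1)),
    chrom = vapply(tx_sp, function(d) d$chrom[1], character(1)),
    strand = vapply(tx_sp, function(d) d$strand[1], character(1)),
    tss = tss, cds_start = NA_integer_, cds_end = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cds_span)) {
    i <- match(transcripts$transcript_id, cds_span$transcript_id)
    transcripts$cds_start <- cds_span$cds_start[i]
    transcripts$cds_end <- cds_span$cds_end[i]
  }
  gene_ids <- unique(exons$gene_id)
  genes <- data.frame(
    gene_id = gene_ids,
    chrom = exons$chrom[match(gene_ids, exons$gene_id)],
    strand = exons$strand[match(gene_ids, exons$gene_id)],
    biotype = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(md$gene_biotype)) {
    b <- tapply(as.character(md$gene_biotype), as.character(md$gene_id),
                function(v) v[!is.na(v)][1])
    genes$biotype <- ifelse(unname(b[gene_ids]) == "protein_coding",
                            "protein_coding", "noncoding")
  }
  ## fall back: a gene is protein_coding iff any transcript has a CDS
  has_cds <- tapply(!is.na(transcripts$cds_start), transcripts$gene_id, any)
  fb <- ifelse(unname(has_cds[genes$gene_id]), "protein_coding", "noncoding")
  genes$biotype[is.na(genes$biotype)] <- fb[is.na(genes$biotype)]
  ## validate exons against declared gene records, when present
  grec <- gr[type == "gene"]
  if (length(grec) > 0) {
    gs <- data.frame(gene_id = as.character(S4Vectors::mcols(grec)$gene_id),
                     start = GenomicRanges::start(grec) - 1L,
                     end = GenomicRanges::end(grec))
    i <- match(exons$gene_id, gs$gene_id)
    out <- !is.na(i) & (exons$start < gs$start[i] | exons$end > gs$end[i])
    if (any(out))
      stop("exon outside declared gene span for gene(s): ",
           paste(unique(exons$gene_id[out]), collapse = ", "))
  }
  gene_models(genes, transcripts, exons)
}

#' Write gene models to a GTF file
#'
#' Emits gene, transcript, exon and CDS records in Ensembl attribute dialect;
#' internal 0-based half-open coordinates are converted to GTF's 1-based
#' inclusive convention. `read_gtf(write_gtf(gm))` reproduces `gm`.
#'
#' @param gm A [gene_models] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path) {
  ex <- gm$exons
  rows <- list()
  g <- gm$genes
  gspan <- do.call(rbind, lapply(split(ex, ex$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], start = min(d$start), end = max(d$end))))
  gi <- match(g$gene_id, gspan$gene_id)
  rows$gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(gspan$start[gi] + 1L, gspan$end[gi]),
    strand = g$strand, type = "gene", gene_id = g$gene_id,
    transcript_id = NA_character_,
    gene_biotype = g$biotype, phase = NA_integer_)
  rows$exon <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), strand = ex$strand,
    type = "exon", gene_id = ex$gene_id, transcript_id = ex$transcript_id,
    gene_biotype = g$biotype[match(ex$gene_id, g$gene_id)],
    phase = NA_integer_)
  tx <- gm$transcripts
  has_cds <- !is.na(tx$cds_start)
  if (any(has_cds)) {
    ## CDS emitted exon-wise: intersect each exon with the CDS span
    cx <- merge(ex, tx[has_cds, c("transcript_id", "cds_start", "cds_end")],
                by = "transcript_id")
    cx$cs <- pmax(cx$start, cx$cds_start)
    cx$ce <- pmin(cx$end, cx$cds_end)
    cx <- cx[cx$cs < cx$ce, ]
    if (nrow(cx) > 0) {
      ## reading-frame phase per CDS piece, in transcription order
      cx <- cx[order(cx$transcript_id,
                     ifelse(cx$strand == "+", 1, -1) * cx$cs), ]
      cum <- unlist(lapply(split(cx$ce - cx$cs, cx$transcript_id),
                           function(l) cumsum(c(0, l[-length(l)]))),
                    use.names = FALSE)
      rows$cds <- GenomicRanges::GRanges(
        cx$chrom, IRanges::IRanges(cx$cs + 1L, cx$ce), strand = cx$strand,
        type = "CDS", gene_id = cx$gene_id, transcript_id = cx$transcript_id,
        gene_biotype = g$biotype[match(cx$gene_id, g$gene_id)],
        phase = (3L - cum %% 3L) %% 3L)
    }
  }
  all_gr <- suppressWarnings(do.call(c, unname(rows)))
  rtracklayer::export(all_gr, path, format = "gtf")
  invisible(path)
}

## per-gene worker: maximal sub-intervals with a constant covering-transcript set
.flatten_gene <- function(ex) {
  bp <- sort(unique(c(ex$start, ex$end)))
  s <- bp[-length(bp)]; e <- bp[-1]
  keep <- logical(length(s)); cover <- character(length(s))
  for (i in seq_along(s)) {
    hit <- ex$transcript_id[ex$start <= s[i] & ex$end >= e[i]]
    keep[i] <- length(hit) > 0
    cover[i] <- paste(sort(unique(hit)), collapse = ",")
  }
  s <- s[keep]; e <- e[keep]; cover <- cover[keep]
  if (length(s) == 0) return(NULL)
  ## merge adjacent atomic intervals with an identical covering set
  grp <- cumsum(c(TRUE, !(s[-1] == e[-length(e)] &
                          cover[-1] == cover[-length(cover)])))
  data.frame(start = tapply(s, grp, min), end = tapply(e, grp, max),
             covering = tapply(cover, grp, `[`, 1), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Flatten transcript exons into disjoint counting bins
#'
#' Splits the per-base union of a gene's exons at every change in the set of
#' covering transcripts, producing maximal disjoint sub-intervals
#' (DEXSeq-style flattening). Bins are numbered 5' to 3' on the gene strand
#' and annotated with a functional exon type and a 3'-terminal flag.
#'
#' @param gm A [gene_models] object.
#' @param gene_ids Optional character vector restricting to a gene subset.
#' @param annotate Assign functional exon types (default `TRUE`; disable
#'   for speed when only the bin structure is needed).
#' @return data.frame with columns `bin_id` (`"geneID:NNN"`), `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `origin` (always `"canonical_exon"`
#'   here; retained-intron bins are appended by the quantification stage),
#'   `functional_type` (`NA` when `annotate = FALSE`) and
#'   `is_three_prime_terminal`.
#' @export
flatten_exons <- function(gm, gene_ids = NULL, annotate = TRUE) {
  ex <- gm$exons
  if (!is.null(gene_ids)) ex <- ex[ex$gene_id %in% gene_ids, ]
  out <- lapply(split(ex, ex$gene_id), function(d) {
    b <- .flatten_gene(d)
    strand <- d$strand[1]
    o <- if (strand == "+") order(b$start) else order(-b$start)
    b <- b[o, , drop = FALSE]
    ## 3'-terminal flag: bin contains the last transcribed base of >=1 transcript
    ends3 <- vapply(split(d, d$transcript_id), function(t)
      if (strand == "+") max(t$end) - 1 else min(t$start), numeric(1))
    data.frame(
      bin_id = sprintf("%s:%03d", d$gene_id[1], seq_len(nrow(b))),
      gene_id = d$gene_id[1], chrom = d$chrom[1],
      start = as.integer(b$start), end = as.integer(b$end), strand = strand,
      origin = "canonical_exon",
      is_three_prime_terminal = vapply(seq_len(nrow(b)), function(i)
        any(ends3 >= b$start[i] & ends3 < b$end[i]), logical(1)),
      stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, out)
  rownames(bins) <- NULL
  bins$functional_type <- if (annotate) assign_functional_type(bins, gm)
    else NA_character_
  bins[, c("bin_id", "gene_id", "chrom", "start", "end", "strand", "origin",
           "functional_type", "is_three_prime_terminal")]
}

## categories contributed by one transcript to one bin sub-interval
.tx_categories <- function(s, e, tx_row, tx_exons) {
  ov <- tx_exons[tx_exons$start < e & tx_exons$end > s, , drop = FALSE]
  if (nrow(ov) == 0) return(character(0))
  if (is.na(tx_row$cds_start)) return("noncoding")
  segs_s <- pmax(ov$start, s); segs_e <- pmin(ov$end, e)
  cats <- character(0)
  for (i in seq_along(segs_s)) {
    a <- segs_s[i]; b <- segs_e[i]
    cs <- tx_row$cds_start; ce <- tx_row$cds_end
    if (tx_row$strand == "+") {
      if (a < cs) cats <- c(cats, "five_prime_utr")
      if (b > ce) cats <- c(cats, "three_prime_utr")
    } else {
      if (b > ce) cats <- c(cats, "five_prime_utr")
      if (a < cs) cats <- c(cats, "three_prime_utr")
    }
    if (b > cs && a < ce) cats <- c(cats, "cds")
  }
  unique(cats)
}

#' Assign functional exon types to flattened bins
#'
#' Classifies every base of a bin relative to the CDS of each covering
#' transcript (5'-UTR, CDS, 3'-UTR; transcripts without a CDS contribute
#' "noncoding"). A bin whose bases fall into exactly one category across all
#' covering transcripts receives that category; more than one category gives
#' `multi_type`; bins of genes without any coding transcript are `noncoding`.
#'
#' @param bins data.frame of bins as from [flatten_exons] (the
#'   `functional_type` column is ignored if present).
#' @param gm A [gene_models] object.
#' @return Character vector of functional types, parallel to `bins` rows.
#' @export
assign_functional_type <- function(bins, gm) {
  tx <- gm$transcripts
  ex <- gm$exons
  g <- gm$genes
  vapply(seq_len(nrow(bins)), function(i) {
    gid <- bins$gene_id[i]
    if (g$biotype[match(gid, g$gene_id)] == "noncoding") return("noncoding")
    s <- bins$start[i]; e <- bins$end[i]
    gtx <- tx[tx$gene_id == gid, , drop = FALSE]
    gex <- ex[ex$gene_id == gid, , drop = FALSE]
    cats <- character(0)
    any_overlap <- FALSE
    for (k in seq_len(nrow(gtx))) {
      te <- gex[gex$transcript_id == gtx$transcript_id[k], , drop = FALSE]
      cc <- .tx_categories(s, e, gtx[k, ], te)
      if (length(cc)) any_overlap <- TRUE
      cats <- union(cats, cc)
    }
    if (!any_overlap)
      stop("bin ", bins$bin_id[i], " not contained in gene exon union")
    if (length(cats) == 1) cats else "multi_type"
  }, character(1))
}

#' Build the canonical exon-exon junction catalog
#'
#' One junction per distinct consecutive-exon pair across a gene's
#' transcripts, deduplicated by (donor, acceptor). The donor is the last
#' exonic base of the 5' exon and the acceptor the first exonic base of the
#' 3' exon, both strand-aware 0-based genomic positions. Junctions whose
#' flanking exon is shorter than `min_exon` or whose intron is shorter than
#' `min_intron` are excluded.
#'
#' @param gm A [gene_models] object.
#' @param min_exon Minimum flanking exon length in bp (default 25).
#' @param min_intron Minimum intron length in bp (default 50).
#' @return data.frame with columns `junction_id`, `gene_id`, `chrom`,
#'   `donor`, `acceptor`, `strand`, `intron_length`, `donor_exon_length`,
#'   `acceptor_exon_length`, `canonical` (all `TRUE` here).
#' @export
catalog_junctions <- function(gm, min_exon = 25, min_intron = 50) {
  ex <- gm$exons
  res <- lapply(split(ex, ex$transcript_id), function(d) {
    if (nrow(d) < 2) return(NULL)
    strand <- d$strand[1]
    d <- d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    up <- d[-nrow(d), , drop = FALSE]; dn <- d[-1, , drop = FALSE]
    if (strand == "+") {
      donor <- up$end - 1L; acceptor <- dn$start
      intron <- dn$start - up$end
    } else {
      donor <- up$start; acceptor <- dn$end - 1L
      intron <- up$start - dn$end
    }
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               donor = donor, acceptor = acceptor, strand = strand,
               intron_length = intron,
               donor_exon_length = up$end - up$start,
               acceptor_exon_length = dn$end - dn$start,
               stringsAsFactors = FALSE)
  })
  j <- do.call(rbind, res)
  if (is.null(j) || nrow(j) == 0)
    return(data.frame(junction_id = character(0), gene_id = character(0),
                      chrom = character(0), donor = integer(0),
                      acceptor = integer(0), strand = character(0),
                      intron_length = integer(0),
                      donor_exon_length = integer(0),
                      acceptor_exon_length = integer(0),
                      canonical = logical(0)))
  key <- paste(j$gene_id, j$donor, j$acceptor)
  ## keep the longest flanking exons seen for a deduplicated junction
  o <- order(key, -pmin(j$donor_exon_length, j$acceptor_exon_length))
  j <- j[o, ][!duplicated(key[o]), , drop = FALSE]
  j <- j[j$intron_length >= min_intron &
         j$donor_exon_length >= min_exon &
         j$acceptor_exon_length >= min_exon, , drop = FALSE]
  ## transcription order within gene
  j <- j[order(j$gene_id, ifelse(j$strand == "+", 1, -1) * j$donor), ,
         drop = FALSE]
  if (nrow(j) > 0) {
    j$canonical <- TRUE
    j$junction_id <- sprintf("%s:%d-%d", j$gene_id, j$donor, j$acceptor)
  } else {
    j$canonical <- logical(0)
    j$junction_id <- character(0)
  }
  rownames(j) <- NULL
  j[, c("junction_id", "gene_id", "chrom", "donor", "acceptor", "strand",
        "intron_length", "donor_exon_length", "acceptor_exon_length",
        "canonical")]
}

#' Fetch a strand-corrected genomic sequence
#'
#' @param genome A named `DNAStringSet` (e.g. from
#'   [Biostrings::readDNAStringSet]); names are chromosome names.
#' @param chrom,start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`; minus-strand intervals are
#'   reverse-complemented so the result reads 5' to 3'.
#' @return Character scalar sequence.
#' @export
get_interval_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  n <- length(genome[[chrom]])
  start <- max(0L, start); end <- min(n, end)
  if (start >= end) return("")
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
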