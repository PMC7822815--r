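#' Construct a count matrix with sample metadata
#'
#' @param counts Non-negative integer matrix, rows = features (bins or
#'   junctions, rownames required), columns = samples.
#' @param samples data.frame with columns `sample_id`, `condition`,
#'   `replicate`, `fraction` (`"total"` or `"nascent"`); one row per column
#'   of `counts`, matched by `sample_id` to colnames.
#' @param features Optional data.frame of per-feature metadata (first column
#'   must match rownames of `counts`).
#' @param library_sizes Optional per-sample totals (e.g. sequenced
#'   fragments); defaults to column sums. For bin matrices the column sums
#'   can exceed the fragment total because a fragment increments every bin
#'   it overlaps.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, features = NULL,
                         library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    if (nrow(counts) > 0) stop("counts must have feature rownames")
    rownames(counts) <- character(0)
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  stopifnot(all(c("sample_id", "condition", "replicate", "fraction")
                %in% names(samples)))
  if (anyDuplicated(samples[, c("condition", "replicate", "fraction")]))
    stop("(condition, replicate, fraction) must be unique across samples")
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (any(is.na(samples$sample_id)))
    stop("colnames(counts) must match samples$sample_id")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes < 0) || (nrow(counts) > 0 && any(library_sizes <= 0)))
    stop("library_sizes must be positive")
  names(library_sizes) <- colnames(counts)
  structure(list(counts = counts, samples = samples, features = features,
                 library_sizes = library_sizes), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  invisible(x)
}

#' Build a sample sheet
#'
#' @param sample_id,condition,replicate,fraction Vectors recycled to equal
#'   length; see [count_matrix].
#' @return data.frame sample sheet.
#' @export
sample_info <- function(sample_id, condition, replicate = 1L,
                        fraction = "total") {
  data.frame(sample_id = sample_id, condition = condition,
             replicate = as.integer(replicate), fraction = fraction,
             stringsAsFactors = FALSE)
}

.read_alignments <- function(bam, mapq_min = 10) {
  bf <- Rsamtools::BamFile(bam)
  if (is.na(Rsamtools::index(bf)) || !file.exists(Rsamtools::index(bf)))
    stop("missing BAM index for ", bam)
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE),
    mapqFilter = mapq_min, what = "qname")
  GenomicAlignments::readGAlignments(bf, param = param)
}

.check_chroms <- function(aln, chroms, what) {
  bam_chr <- GenomeInfoDb::seqlevels(aln)
  used <- unique(chroms)
  missing <- setdiff(used, bam_chr)
  if (length(missing) == length(used) && length(used) > 0)
    stop("no ", what, " chromosome found in BAM; offending names: ",
         paste(missing, collapse = ", "))
  invisible(missing)
}

#' Count fragments over flattened bins
#'
#' Each read (or read pair, counted once as a fragment by query name)
#' increments every bin that any of its aligned blocks overlaps by at least
#' one base. Secondary alignments, duplicates and reads below `mapq_min` are
#' excluded.
#'
#' @param bam_paths Named character vector of indexed BAM paths; names are
#'   sample ids.
#' @param bins data.frame of bins from [flatten_exons] (may include retained
#'   intron bins).
#' @param samples Sample sheet as from [sample_info].
#' @param mapq_min Minimum mapping quality (default 10).
#' @return A [count_matrix] over `bins$bin_id`.
#' @export
count_bins <- function(bam_paths, bins, samples, mapq_min = 10) {
  bin_gr <- GenomicRanges::GRanges(bins$chrom,
                                   IRanges::IRanges(bins$start + 1L, bins$end))
  counts <- matrix(0L, nrow(bins), length(bam_paths),
                   dimnames = list(bins$bin_id, names(bam_paths)))
  lib <- numeric(length(bam_paths))
  for (i in seq_along(bam_paths)) {
    aln <- .read_alignments(bam_paths[i], mapq_min)
    .check_chroms(aln, bins$chrom, "bin")
    lib[i] <- length(unique(S4Vectors::mcols(aln)$qname))
    blocks <- GenomicAlignments::grglist(aln)
    hits <- GenomicRanges::findOverlaps(blocks, bin_gr, minoverlap = 1L)
    if (length(hits) > 0) {
      qn <- S4Vectors::mcols(aln)$qname[S4Vectors::queryHits(hits)]
      key <- !duplicated(paste(qn, S4Vectors::subjectHits(hits)))
      tab <- table(S4Vectors::subjectHits(hits)[key])
      counts[as.integer(names(tab)), i] <- as.integer(tab)
    }
  }
  count_matrix(counts, samples, features = bins, library_sizes = lib)
}

#' Extract junction counts from spliced alignments
#'
#' Every gap (CIGAR N operation) of an alignment contributes one count to the
#' junction whose flanking exonic bases match the gap. Gaps matching no
#' catalog entry are emitted as non-canonical junction records assigned to
#' the unique gene containing both flanking bases; gaps contained in two
#' genes are tagged ambiguous and excluded, gaps in no gene are dropped.
#' Junctions with fewer than `min_reads` total counts across samples are
#' removed.
#'
#' @param bam_paths Named character vector of indexed BAM paths.
#' @param catalog Canonical junction catalog from [catalog_junctions].
#' @param gm A [gene_models] object (for assigning novel junctions).
#' @param samples Sample sheet.
#' @param min_intron Gaps shorter than this are ignored and tallied in the
#'   `short_gaps` attribute (default 50).
#' @param min_reads Minimum total count across samples (default 5).
#' @param mapq_min Minimum mapping quality (default 10).
#' @return A [count_matrix] whose `$features` holds the junction records
#'   (canonical and novel), with a `short_gaps` attribute.
#' @export
extract_junctions <- function(bam_paths, catalog, gm, samples,
                              min_intron = 50, min_reads = 5, mapq_min = 10) {
  tallies <- list(); short_gaps <- 0L
  for (i in seq_along(bam_paths)) {
    aln <- .read_alignments(bam_paths[i], mapq_min)
    jx <- GenomicAlignments::junctions(aln)
    jx <- unlist(jx, use.names = FALSE)
    if (length(jx) > 0) {
      w <- GenomicRanges::width(jx)
      short_gaps <- short_gaps + sum(w < min_intron)
      jx <- jx[w >= min_intron]
    }
    key <- paste(GenomicRanges::seqnames(jx), GenomicRanges::start(jx),
                 GenomicRanges::end(jx))
    tallies[[names(bam_paths)[i]]] <- table(key)
  }
  all_keys <- sort(unique(unlist(lapply(tallies, names))))
  counts <- sapply(tallies, function(t) {
    v <- integer(length(all_keys)); names(v) <- all_keys
    v[names(t)] <- as.integer(t); v
  })
  if (length(all_keys) == 0)
    return(count_matrix(matrix(0L, 0, length(bam_paths),
                               dimnames = list(NULL, names(bam_paths))),
                        samples, features = catalog[0, ]))
  counts <- matrix(counts, nrow = length(all_keys),
                   dimnames = list(all_keys, names(bam_paths)))
  parts <- do.call(rbind, strsplit(all_keys, " "))
  chrom <- parts[, 1]
  left_ex <- as.integer(parts[, 2]) - 2L   # 0-based base left of the gap
  right_ex <- as.integer(parts[, 3])       # 0-based base right of the gap
  ## match to catalog on both strand orientations
  cat_key <- with(catalog, ifelse(strand == "+",
                                  paste(chrom, donor, acceptor),
                                  paste(chrom, acceptor, donor)))
  obs_key <- paste(chrom, left_ex, right_ex)
  ci <- match(obs_key, cat_key)
  feats <- data.frame(junction_id = NA_character_, gene_id = NA_character_,
                      chrom = chrom, donor = NA_integer_,
                      acceptor = NA_integer_, strand = NA_character_,
                      intron_length = right_ex - left_ex - 1L,
                      canonical = !is.na(ci), stringsAsFactors = FALSE)
  known <- !is.na(ci)
  feats[known, c("junction_id", "gene_id", "donor", "acceptor", "strand")] <-
    catalog[ci[known], c("junction_id", "gene_id", "donor", "acceptor",
                         "strand")]
  ## assign novel junctions to the unique containing gene
  if (any(!known)) {
    gs <- do.call(rbind, lapply(split(gm$exons, gm$exons$gene_id), function(d)
      data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
                 strand = d$strand[1], start = min(d$start),
                 end = max(d$end), stringsAsFactors = FALSE)))
    for (r in which(!known)) {
      hit <- gs[gs$chrom == chrom[r] & gs$start <= left_ex[r] &
                gs$end > right_ex[r], , drop = FALSE]
      if (nrow(hit) == 1) {
        feats$gene_id[r] <- hit$gene_id
        feats$strand[r] <- hit$strand
        if (hit$strand == "+") {
          feats$donor[r] <- left_ex[r]; feats$acceptor[r] <- right_ex[r]
        } else {
          feats$donor[r] <- right_ex[r]; feats$acceptor[r] <- left_ex[r]
        }
        feats$junction_id[r] <- sprintf("%s:%d-%d", hit$gene_id,
                                        feats$donor[r], feats$acceptor[r])
      } else if (nrow(hit) > 1) {
        feats$gene_id[r] <- "ambiguous"
      }
    }
  }
  keep <- !is.na(feats$junction_id) & rowSums(counts) >= min_reads
  feats <- feats[keep, , drop = FALSE]
  counts <- counts[keep, , drop = FALSE]
  rownames(counts) <- feats$junction_id
  rownames(feats) <- NULL
  out <- count_matrix(counts, samples, features = feats)
  attr(out, "short_gaps") <- short_gaps
  out
}

#' Log2 counts-per-million normalization
#'
#' `log2((count + pseudocount) / library_size * 1e6)`.
#'
#' @param m A [count_matrix].
#' @param pseudocount Added to every count (default 0.5).
#' @return Numeric matrix of log2-CPM values.
#' @export
cpm_normalize <- function(m, pseudocount = 0.5) {
  if (any(m$library_sizes <= 0)) stop("zero library size")
  log2(sweep(m$counts + pseudocount, 2, m$library_sizes, "/") * 1e6)
}

#' Detect retained introns from coverage
#'
#' An intron is detected in a condition if, in at least `k` of that
#' condition's replicates, its mean per-base coverage is at least `c_abs`
#' and at least `theta` times the smaller of the two flanking exon-bin
#' coverages. Introns detected in exactly one condition are condition
#' specific.
#'
#' @param intron_cov Matrix (introns x samples) of mean per-base intron
#'   coverage; rownames are intron ids.
#' @param flank5_cov,flank3_cov Matrices of flanking exon-bin coverage with
#'   the same shape; a row of `NA` marks an intron lacking a flank and is
#'   skipped.
#' @param samples Sample sheet (two conditions expected).
#' @param c_abs Absolute coverage threshold (default 5).
#' @param theta Relative-to-flank threshold (default 0.1).
#' @param k Replicates required within a condition (default 2).
#' @return data.frame with per-condition detection flags and a `specificity`
#'   column (`"<condition>_specific"`, `"shared"` or `"not_detected"`).
#' @export
detect_retained_introns <- function(intron_cov, flank5_cov, flank3_cov,
                                    samples, c_abs = 5, theta = 0.1, k = 2) {
  conds <- unique(samples$condition)
  if (length(conds) != 2) stop("exactly two conditions expected")
  skip <- apply(is.na(flank5_cov), 1, all) | apply(is.na(flank3_cov), 1, all)
  if (any(skip))
    message(sum(skip), " intron(s) without two flanking exon bins skipped")
  flank_min <- pmin(flank5_cov, flank3_cov)
  pass <- intron_cov >= c_abs & intron_cov >= theta * flank_min
  det <- sapply(conds, function(cc) {
    cols <- samples$sample_id[samples$condition == cc]
    rowSums(pass[, cols, drop = FALSE], na.rm = TRUE) >= k
  })
  det[skip, ] <- FALSE
  specificity <- ifelse(det[, 1] & det[, 2], "shared",
                 ifelse(det[, 1], paste0(conds[1], "_specific"),
                 ifelse(det[, 2], paste0(conds[2], "_specific"),
                        "not_detected")))
  out <- data.frame(intron_id = rownames(intron_cov),
                    det, specificity, stringsAsFactors = FALSE,
                    row.names = NULL)
  names(out)[2:3] <- paste0("detected_", conds)
  out
}

#' Write/read a count table as TSV
#'
#' Feature ids in the first column, one column per sample.
#' @param m A [count_matrix].
#' @param path Output TSV path.
#' @return `path` invisibly.
#' @export
write_counts_tsv <- function(m, path) {
  df <- data.frame(feature_id = rownames(m$counts), m$counts,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @param samples Sample sheet matching the TSV's sample columns.
#' @export
read_counts_tsv <- function(path, samples) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  count_matrix(counts, samples)
}
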