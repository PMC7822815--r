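#' Read splicing-factor PWMs from JASPAR-style matrix text
#'
#' Parses records of the form `>ID NAME` followed by four rows
#' `A [ 1 2 3 ]` (and C, G, T/U). Counts are converted to probabilities
#' with a pseudocount of 0.25 per base and then to log2-odds against the
#' background; the default hit threshold is 80% of the maximum attainable
#' score.
#'
#' @param path Matrix text file.
#' @param background Base frequencies over A, C, G, T (default uniform).
#' @param threshold_frac Fraction of the maximum score used as hit
#'   threshold (default 0.8).
#' @return Named list of `pwm` objects (`factor`, `matrix` 4 x width
#'   log-odds with rownames ACGT, `background`, `hit_threshold`).
#' @export
read_pwm_jaspar <- function(path, background = rep(0.25, 4),
                            threshold_frac = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (length(starts) == 0) stop("no PWM records in ", path)
  names(background) <- c("A", "C", "G", "T")
  out <- list()
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[k]])
    nm <- strsplit(hdr, "\\s+")[[1]]
    fac <- if (length(nm) >= 2) nm[2] else nm[1]
    body <- lines[(starts[k] + 1):(bounds[k + 1] - 1)]
    rows <- lapply(body, function(l) {
      base <- toupper(sub("^\\s*([ACGTUacgtu]).*", "\\1", l))
      if (base == "U") base <- "T"
      rest <- sub("^\\s*[ACGTUacgtu]", "", l)
      nums <- regmatches(rest, gregexpr("[0-9.]+", rest))[[1]]
      list(base = base, counts = as.numeric(nums))
    })
    bases <- vapply(rows, `[[`, character(1), "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("PWM record ", fac, " lacks rows for all four bases")
    cm <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(cm) <- bases
    cm <- cm[c("A", "C", "G", "T"), , drop = FALSE]
    probs <- sweep(cm + 0.25, 2, colSums(cm) + 1, "/")
    lo <- log2(sweep(probs, 1, background, "/"))
    maxs <- sum(apply(lo, 2, max))
    out[[fac]] <- structure(
      list(factor = fac, matrix = lo, background = background,
           hit_threshold = threshold_frac * maxs), class = "pwm")
  }
  out
}

#' Scan a sequence with a position weight matrix
#'
#' Scores every offset on the given strand by summing per-position log-odds;
#' `N` positions contribute 0. Offsets are 0-based.
#'
#' @param seq Character sequence over A, C, G, T, N (U accepted as T).
#' @param pwm A `pwm` object (see [read_pwm_jaspar]).
#' @return data.frame `offset`, `score`, `hit` (score at or above the PWM's
#'   hit threshold); zero rows when the sequence is shorter than the motif.
#' @export
scan_pwm <- function(seq, pwm) {
  w <- ncol(pwm$matrix)
  s <- chartr("acgtuU", "ACGTTT", seq)
  n <- nchar(s)
  if (n < w)
    return(data.frame(offset = integer(0), score = numeric(0),
                      hit = logical(0)))
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))  # NA for N
  n_off <- n - w + 1L
  score <- numeric(n_off)
  for (j in seq_len(w)) {
    v <- pwm$matrix[, j][code[j:(j + n_off - 1L)]]
    v[is.na(v)] <- 0
    score <- score + v
  }
  data.frame(offset = seq_len(n_off) - 1L, score = score,
             hit = score >= pwm$hit_threshold)
}

## strand-aware windows for one junction; needs flanking exon lengths
.junction_windows <- function(j, w_e = 100, w_i = 100) {
  d <- j$donor; a <- j$acceptor
  del <- j$donor_exon_length; ael <- j$acceptor_exon_length
  we_d <- min(w_e, del); we_a <- min(w_e, ael)
  il <- j$intron_length
  wi <- min(w_i, il)
  if (j$strand == "+") {
    list(upstream_exon = c(d - we_d + 1L, d + 1L),
         intron_5p = c(d + 1L, d + 1L + wi),
         intron_3p = c(a - wi, a),
         downstream_exon = c(a, a + we_a))
  } else {
    ## transcription runs right to left; windows stay 0-based half-open in
    ## genomic coordinates, sequences are reverse-complemented on extraction
    list(upstream_exon = c(d, d + we_d),
         intron_5p = c(d - wi, d),
         intron_3p = c(a + 1L, a + 1L + wi),
         downstream_exon = c(a + 1L - we_a, a + 1L))
  }
}

#' Motif frequency and strength features per junction
#'
#' For each junction, four strand-aware windows are scanned with every PWM:
#' the last `w_e` nt of the donor exon, the first and last `w_i` nt of the
#' intron, and the first `w_e` nt of the acceptor exon (windows clipped at
#' feature boundaries). Frequency is hits per kilobase; strength is the
#' maximum log-odds score (sentinel -50 when no offset is evaluable).
#'
#' @param junctions Junction data.frame carrying `donor`, `acceptor`,
#'   `strand`, `chrom`, `intron_length`, `donor_exon_length`,
#'   `acceptor_exon_length`.
#' @param genome Named `DNAStringSet`.
#' @param pwms Named list of `pwm` objects.
#' @param w_e,w_i Exonic/intronic window widths in nt (defaults 100).
#' @return data.frame with `junction_id` and one `<factor>_<region>_freq` /
#'   `<factor>_<region>_strength` column pair per factor and region.
#' @export
motif_features <- function(junctions, genome, pwms, w_e = 100, w_i = 100) {
  regions <- c("upstream_exon", "intron_5p", "intron_3p", "downstream_exon")
  cols <- as.vector(outer(names(pwms), regions, function(f, r)
    paste0(f, "_", r)))
  out <- matrix(NA_real_, nrow(junctions), 2 * length(cols),
                dimnames = list(NULL, c(paste0(cols, "_freq"),
                                        paste0(cols, "_strength"))))
  for (i in seq_len(nrow(junctions))) {
    wins <- .junction_windows(junctions[i, ], w_e, w_i)
    for (r in regions) {
      iv <- wins[[r]]
      seqr <- get_interval_seq(genome, junctions$chrom[i], iv[1], iv[2],
                               junctions$strand[i])
      len <- nchar(seqr)
      for (f in names(pwms)) {
        hits <- scan_pwm(seqr, pwms[[f]])
        nm <- paste0(f, "_", r)
        if (nrow(hits) == 0 || len == 0) {
          out[i, paste0(nm, "_freq")] <- 0
          out[i, paste0(nm, "_strength")] <- -50
        } else {
          out[i, paste0(nm, "_freq")] <- sum(hits$hit) / (len / 1000)
          out[i, paste0(nm, "_strength")] <- max(hits$score)
        }
      }
    }
  }
  data.frame(junction_id = junctions$junction_id, out, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Distance from splice sites to the nearest peak per mark
#'
#' Unsigned bp distance from each junction's donor and acceptor position to
#' the nearest peak edge of each mark (0 when the site lies inside a peak,
#' `Inf` when the chromosome is absent from the track).
#'
#' @param junctions Junction data.frame with `chrom`, `donor`, `acceptor`.
#' @param peaks Named list of `GRanges` peak tracks (one per mark), e.g.
#'   from [read_bed].
#' @return data.frame with `junction_id` and `<mark>_donor_dist` /
#'   `<mark>_acceptor_dist` columns.
#' @export
peak_distances <- function(junctions, peaks) {
  out <- data.frame(junction_id = junctions$junction_id,
                    stringsAsFactors = FALSE)
  for (mk in names(peaks)) {
    pk <- peaks[[mk]]
    for (side in c("donor", "acceptor")) {
      pos <- junctions[[side]]
      gr <- GenomicRanges::GRanges(junctions$chrom,
                                   IRanges::IRanges(pos + 1L, pos + 1L))
      d <- rep(Inf, length(gr))
      shared <- as.character(GenomicRanges::seqnames(gr)) %in%
        GenomeInfoDb::seqlevels(pk)
      if (any(shared)) {
        hits <- suppressWarnings(
          GenomicRanges::distanceToNearest(gr[shared], pk))
        di <- rep(Inf, sum(shared))
        ## distanceToNearest reports the gap (0 also for adjacency); the
        ## distance to the peak edge coordinate is gap + 1 unless the site
        ## lies inside a peak
        dd <- S4Vectors::mcols(hits)$distance
        inside <- IRanges::overlapsAny(gr[shared], pk)
        di[S4Vectors::queryHits(hits)] <- dd + 1
        di[inside] <- 0
        d[shared] <- di
      }
      out[[paste0(mk, "_", side, "_dist")]] <- d
    }
  }
  out
}

#' Read a BED file of peak intervals
#'
#' @param path BED path (3+ columns, 0-based half-open).
#' @return Sorted `GRanges`.
#' @export
read_bed <- function(path) {
  GenomicRanges::sort(rtracklayer::import(path, format = "bed"))
}

#' Association of splice sites with open chromatin
#'
#' Tests whether differential splice sites overlap peaks (distance at most
#' `max_dist`) more often than non-differential sites, with a two-sided
#' Fisher exact test via [categorical_enrichment].
#'
#' @param diff_dist,nondiff_dist Numeric distances to the nearest peak for
#'   differential and non-differential sites (disjoint site sets).
#' @param max_dist Overlap cutoff in bp (default 0: inside a peak).
#' @return One-row data.frame with counts, `odds_ratio` and `p`.
#' @export
open_chromatin_association <- function(diff_dist, nondiff_dist,
                                       max_dist = 0) {
  if (length(diff_dist) == 0 || length(nondiff_dist) == 0)
    stop("empty site set")
  ids <- c(paste0("d", seq_along(diff_dist)),
           paste0("n", seq_along(nondiff_dist)))
  lab <- c(ifelse(diff_dist <= max_dist, "in_peak", "out"),
           ifelse(nondiff_dist <= max_dist, "in_peak", "out"))
  names(lab) <- ids
  enr <- categorical_enrichment(ids[seq_along(diff_dist)], ids, lab,
                                test = "fisher")
  enr[enr$label == "in_peak", c("a", "b", "c", "d", "odds_ratio", "p")]
}

#' Compare splice-site-to-peak distances between two site groups
#'
#' Two-sided Mann-Whitney U test on the distance distributions (e.g.
#' canonical versus alternative 5' splice sites of differential junctions).
#'
#' @param dist_a,dist_b Numeric distance vectors.
#' @return list with `median_a`, `median_b`, `p`.
#' @export
site_distance_test <- function(dist_a, dist_b) {
  p <- stats::wilcox.test(dist_a, dist_b, exact = FALSE)$p.value
  list(median_a = stats::median(dist_a), median_b = stats::median(dist_b),
       p = p)
}
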