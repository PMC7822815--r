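#' Simulation configuration with planted truth
#'
#' Defaults define the reference synthetic conditions used throughout the
#' package's validation: 200 multi-transcript genes, 3 vs 3 replicates at a
#' mean depth of 300 fragments per gene with negative-binomial dispersion
#' 0.05, a planted junction-usage shift of 2 on the log2-odds scale in 15%
#' of genes, retained introns in 10% of genes, epigenetic peaks near
#' differential donors at rate 0.8 versus 0.1 background, planted
#' splicing-factor motifs at the same rates, and a 4-fold nascent-RNA
#' deficit for half of the differential junctions.
#'
#' @param n_genes Number of genes (default 200).
#' @param n_exons Range of exons per gene (default 4 to 8).
#' @param exon_meanlog,exon_sdlog Lognormal exon-length parameters
#'   (default log(150), 0.35).
#' @param intron_meanlog,intron_sdlog Lognormal intron-length parameters
#'   (default log(400), 0.5).
#' @param n_replicates Replicates per condition (default 3).
#' @param depth Mean fragments per gene (default 300).
#' @param dispersion NB dispersion (default 0.05).
#' @param frac_diff_junctions Fraction of genes with a planted differential
#'   junction (default 0.15).
#' @param usage_effect Planted shift of the junction-usage log2-odds
#'   (default 2).
#' @param frac_retained_introns Fraction of genes with a planted retained
#'   intron (default 0.1).
#' @param peak_assoc_prob,background_prob Peak placement probability near
#'   differential donors and background peaks per kb (defaults 0.8, 0.1).
#' @param assoc_window Maximum planted peak distance from a differential
#'   donor in bp (default 500).
#' @param motif_plant_prob,motif_background_prob Probability of planting a
#'   factor's consensus in a differential junction's windows versus
#'   elsewhere (defaults 0.8, 0.1).
#' @param delayed_frac Fraction of differential junctions with delayed
#'   splicing (default 1: the differential class as a whole is delayed).
#' @param delay_factor Nascent abundance reduction factor for delayed
#'   junctions (default 4).
#' @param tss_diff_frac Fraction of genes with an alternative TSS
#'   transcript activated in the contrast condition (default 0.1).
#' @param tss_effect Fold activation of the alternative TSS (default 4).
#' @param concentration Dirichlet concentration for per-sample isoform
#'   usage (default 20).
#' @param conditions Condition labels (default `c("siMM", "siRR")`).
#' @param read_len Read length used to convert fragments to coverage
#'   (default 100).
#' @param seed RNG seed (default 1).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200, n_exons = c(4, 8),
                       exon_meanlog = log(150), exon_sdlog = 0.35,
                       intron_meanlog = log(400), intron_sdlog = 0.5,
                       n_replicates = 3, depth = 300, dispersion = 0.05,
                       frac_diff_junctions = 0.15, usage_effect = 2,
                       frac_retained_introns = 0.1,
                       peak_assoc_prob = 0.8, background_prob = 0.1,
                       assoc_window = 500,
                       motif_plant_prob = 0.8, motif_background_prob = 0.1,
                       delayed_frac = 1, delay_factor = 4,
                       tss_diff_frac = 0.1, tss_effect = 4,
                       concentration = 20,
                       conditions = c("siMM", "siRR"), read_len = 100,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(frac_diff_junctions >= 0, frac_diff_junctions <= 1,
            peak_assoc_prob >= 0, peak_assoc_prob <= 1,
            delayed_frac >= 0, delayed_frac <= 1,
            is.finite(usage_effect))
  structure(cfg, class = "sim_config")
}

## emulated binding consensus per splicing factor (RBFOX2 is the canonical
## UGCAUG element; the others are field-typical short consensi)
.factor_consensus <- c(HNRNPA3 = "TAGGGT", MBNL1 = "TGCTGC",
                       PTBP1 = "TTCTCT", RBFOX2 = "TGCATG",
                       SRSF7 = "GACGAC", YBX1 = "CCTGCG")

#' Built-in splicing-factor PWMs
#'
#' Near-deterministic count matrices (97 counts for the consensus base, 1
#' elsewhere) for the six shortlist splicing factors, written as
#' JASPAR-style text and parsed back through [read_pwm_jaspar] so that the
#' PWM I/O path is exercised.
#'
#' @param path Optional path for the matrix text (temp file by default).
#' @return Named list of `pwm` objects.
#' @export
default_pwms <- function(path = tempfile(fileext = ".pwm")) {
  lines <- character(0)
  for (f in names(.factor_consensus)) {
    cons <- strsplit(.factor_consensus[[f]], "")[[1]]
    lines <- c(lines, paste0(">", f, " ", f))
    for (b in c("A", "C", "G", "T")) {
      cnt <- ifelse(cons == b, 97, 1)
      lines <- c(lines, paste0(b, " [ ", paste(cnt, collapse = " "), " ]"))
    }
  }
  writeLines(lines, path)
  read_pwm_jaspar(path)
}

.rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

.splice_in <- function(seq, at, insert) {
  ## overwrite (not insert) `insert` starting at 0-based position `at`
  if (at + nchar(insert) > nchar(seq)) return(seq)
  paste0(substr(seq, 1, at), insert,
         substr(seq, at + nchar(insert) + 1, nchar(seq)))
}

## write a clean ORF (ATG + sense codons + TAA, padded with C) through the
## spliced CDS pieces of the reference transcript so that the spliced
## sequence carries a real reading frame; pieces are genomic 0-based
## half-open intervals in transcription order
.plant_orf <- function(seq, pieces_start, pieces_end, strand) {
  lens <- pieces_end - pieces_start
  L <- sum(lens)
  if (L < 9) return(seq)
  n_codons <- floor(L / 3) - 2
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA", "ATG"))
  orf <- paste0("ATG", paste(sample(sense, n_codons, replace = TRUE),
                             collapse = ""), "TAA")
  orf <- paste0(orf, paste(rep("C", L - nchar(orf)), collapse = ""))
  off <- 0L
  for (i in seq_along(lens)) {
    piece <- substr(orf, off + 1, off + lens[i])
    if (strand == "-")
      piece <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(piece)))
    seq <- .splice_in(seq, pieces_start[i], piece)
    off <- off + lens[i]
  }
  seq
}

#' Simulate an annotated genome with planted splicing truth
#'
#' Generates one contig per gene with multi-transcript models: every gene
#' has a full-length transcript plus a cassette-skipping transcript, a
#' subset carries an alternative-5'-splice-site transcript, and
#' `tss_diff_frac` of genes carry an alternative-TSS transcript starting at
#' exon 2. A subset of the skip junctions is designated differential;
#' splicing-factor consensus motifs are planted in the feature windows of
#' differential junctions at `motif_plant_prob` (background
#' `motif_background_prob`), and retained-intron truth marks one intron in
#' `frac_retained_introns` of genes. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config].
#' @return list with `gm` ([gene_models]), `genome` (`DNAStringSet`),
#'   `truth` (planted differential junction ids, per-gene skip transcript,
#'   RI truth, delayed ids, motif plants, TSS truth), and `pwms`.
#' @export
simulate_annotation <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  genes <- list(); transcripts <- list(); exons <- list()
  seqs <- list()
  truth_diff <- character(0); skip_tx <- character(0)
  n_diff <- round(cfg$frac_diff_junctions * cfg$n_genes)
  diff_genes <- if (n_diff > 0)
    sprintf("G%04d", sample.int(cfg$n_genes, n_diff)) else character(0)
  n_ri <- round(cfg$frac_retained_introns * cfg$n_genes)
  ri_genes <- sprintf("G%04d", sample.int(cfg$n_genes, n_ri))
  n_tss <- round(cfg$tss_diff_frac * cfg$n_genes)
  tss_genes <- sprintf("G%04d", sample.int(cfg$n_genes, n_tss))
  ri_rows <- list(); plant_rows <- list()
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    chrom <- paste0("chr_", gid)
    strand <- sample(c("+", "-"), 1)
    ne <- sample(seq(cfg$n_exons[1], cfg$n_exons[2]), 1)
    elen <- pmax(40L, round(stats::rlnorm(ne, cfg$exon_meanlog,
                                          cfg$exon_sdlog)))
    ilen <- pmax(80L, round(stats::rlnorm(ne - 1, cfg$intron_meanlog,
                                          cfg$intron_sdlog)))
    offset <- 1000L
    starts <- offset + c(0L, cumsum(elen[-ne] + ilen))
    ends <- starts + elen
    glen <- ends[ne] + 1000L
    seqs[[chrom]] <- .rand_seq(glen)
    ## transcript 1: all exons; CDS spans exon 2 .. second-to-last exon
    tid1 <- paste0(gid, ".t1")
    ex1 <- data.frame(gene_id = gid, transcript_id = tid1, chrom = chrom,
                      start = starts, end = ends, strand = strand)
    cds_start <- starts[2]; cds_end <- ends[ne - 1]
    ## plant a real reading frame through the CDS exons (2 .. ne-1),
    ## pieces in transcription order
    cds_idx <- if (strand == "+") 2:(ne - 1) else (ne - 1):2
    seqs[[chrom]] <- .plant_orf(seqs[[chrom]], starts[cds_idx],
                                ends[cds_idx], strand)
    ## transcript 2: skips one internal exon (the cassette)
    skip_i <- sample(2:(ne - 1), 1)
    tid2 <- paste0(gid, ".t2")
    ex2 <- ex1[-skip_i, ]; ex2$transcript_id <- tid2
    txs <- list(ex1, ex2)
    cds <- data.frame(transcript_id = c(tid1, tid2),
                      cds_start = cds_start, cds_end = cds_end)
    ## half of the genes: an alt-5'ss transcript (donor shifted into intron)
    if (stats::runif(1) < 0.5 && min(ilen) > 140) {
      alt_i <- sample(seq_len(ne - 1), 1)
      tid3 <- paste0(gid, ".t3")
      ex3 <- ex1; ex3$transcript_id <- tid3
      if (strand == "+") ex3$end[alt_i] <- ex3$end[alt_i] + 30L
      else ex3$start[alt_i + 1] <- ex3$start[alt_i + 1] - 30L
      txs <- c(txs, list(ex3))
      cds <- rbind(cds, data.frame(transcript_id = tid3,
                                   cds_start = cds_start,
                                   cds_end = cds_end))
    }
    ## alternative-TSS transcript starting at exon 2 in transcription
    ## order (drop the transcription-first exon, strand-aware)
    if (gid %in% tss_genes) {
      tida <- paste0(gid, ".talt")
      exa <- if (strand == "+") ex1[-1, ] else ex1[-ne, ]
      exa$transcript_id <- tida
      txs <- c(txs, list(exa))
      cds <- rbind(cds, data.frame(transcript_id = tida,
                                   cds_start = cds_start,
                                   cds_end = cds_end))
    }
    gex <- do.call(rbind, txs)
    exons[[gid]] <- gex
    tsub <- do.call(rbind, lapply(txs, function(d) {
      data.frame(transcript_id = d$transcript_id[1], gene_id = gid,
                 chrom = chrom, strand = strand,
                 tss = if (strand == "+") min(d$start) else max(d$end) - 1L,
                 stringsAsFactors = FALSE)
    }))
    tsub$cds_start <- cds$cds_start[match(tsub$transcript_id,
                                          cds$transcript_id)]
    tsub$cds_end <- cds$cds_end[match(tsub$transcript_id,
                                      cds$transcript_id)]
    transcripts[[gid]] <- tsub
    genes[[gid]] <- data.frame(gene_id = gid, chrom = chrom,
                               strand = strand, biotype = "protein_coding",
                               stringsAsFactors = FALSE)
    ## skip junction id (donor/acceptor of the exon pair around skip_i)
    if (strand == "+") {
      donor <- ends[skip_i - 1] - 1L; acceptor <- starts[skip_i + 1]
    } else {
      donor <- starts[skip_i + 1]; acceptor <- ends[skip_i - 1] - 1L
    }
    jid <- sprintf("%s:%d-%d", gid, donor, acceptor)
    skip_tx[gid] <- tid2
    names(jid) <- gid
    if (gid %in% diff_genes) truth_diff <- c(truth_diff, jid)
    attr(skip_tx, "junctions") <- c(attr(skip_tx, "junctions"), jid)
    ## one intron row per gene; retention planted only for ri_genes
    ri_i <- sample(setdiff(seq_len(ne - 1), skip_i - 1), 1)
    ri_rows[[gid]] <- data.frame(
      gene_id = gid, chrom = chrom,
      start = ends[ri_i], end = starts[ri_i + 1], strand = strand,
      condition = if (gid %in% ri_genes)
        sample(c(cfg$conditions, "shared"), 1, prob = c(0.4, 0.4, 0.2))
      else "none",
      stringsAsFactors = FALSE)
    ## plant splicing-factor motifs around the skip junction
    is_diff <- gid %in% diff_genes
    pprob <- if (is_diff) cfg$motif_plant_prob else cfg$motif_background_prob
    for (fi in seq_along(.factor_consensus)) {
      f <- names(.factor_consensus)[fi]
      if (stats::runif(1) < pprob) {
        ## planted 12 nt downstream of the donor inside the intron, each
        ## factor at its own offset so plants do not overwrite each other
        off <- 12L + (fi - 1L) * 10L
        pos <- if (strand == "+") ends[skip_i - 1] + off
               else starts[skip_i + 1] - off - 6L
        ins <- .factor_consensus[[f]]
        if (strand == "-") ins <- as.character(
          Biostrings::reverseComplement(Biostrings::DNAString(ins)))
        seqs[[chrom]] <- .splice_in(seqs[[chrom]], pos, ins)
        plant_rows[[length(plant_rows) + 1]] <-
          data.frame(gene_id = gid, junction_id = jid, factor = f,
                     region = "intron_5p", stringsAsFactors = FALSE)
      }
    }
  }
  gm <- gene_models(do.call(rbind, genes), do.call(rbind, transcripts),
                    do.call(rbind, exons))
  skip_jids <- attr(skip_tx, "junctions")
  attr(skip_tx, "junctions") <- NULL
  delayed <- if (length(truth_diff) > 0)
    sample(truth_diff, round(cfg$delayed_frac * length(truth_diff)))
  else character(0)
  truth <- list(
    diff_junctions = unname(truth_diff),
    diff_genes = sort(names(truth_diff)),
    skip_transcript = skip_tx,
    skip_junctions = skip_jids,
    ri = if (length(ri_rows)) do.call(rbind, ri_rows) else NULL,
    delayed = unname(delayed),
    motif_plants = if (length(plant_rows)) do.call(rbind, plant_rows)
      else NULL,
    tss_genes = sort(intersect(tss_genes, gm$genes$gene_id)))
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  list(gm = gm, genome = genome, truth = truth, cfg = cfg)
}

## Dirichlet draw via gammas
.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha)
  x / sum(x)
}

#' Simulate bin, junction and transcript counts with planted usage shifts
#'
#' Per gene: a fixed lognormal expression factor; a gene-level isoform
#' usage profile drawn once from a Dirichlet with concentration
#' `cfg$concentration` around the base proportions (creating realistic
#' usage heterogeneity across genes while keeping replicate noise at the
#' negative-binomial + multinomial counting level); per-sample fragment
#' totals from a negative binomial; fragments allocated to isoforms
#' multinomially. In the contrast condition, the skip-transcript odds of
#' differential genes are multiplied by `2^usage_effect` and
#' alternative-TSS transcripts of planted TSS genes are activated
#' `tss_effect`-fold. Junction and bin counts are sums of the counts of
#' the transcripts carrying them. The nascent matrices are an independent
#' draw in which planted delayed junctions are binomially thinned by
#' `1/delay_factor`. Retained-intron coverage tables (one intron row per
#' gene; planted subset per truth) are also emitted.
#'
#' @param ann Output of [simulate_annotation].
#' @return list with `bins`, `bin_counts`, `junctions` (catalog),
#'   `junction_counts`, `tx_counts`, `nascent_counts`, `total_counts`
#'   (junction-level), `ri` (coverage matrices), `samples`.
#' @export
simulate_counts <- function(ann) {
  cfg <- ann$cfg
  set.seed(cfg$seed + 1)
  gm <- ann$gm
  conds <- cfg$conditions
  samples <- sample_info(
    sample_id = paste0(rep(conds, each = cfg$n_replicates), "_",
                       seq_len(cfg$n_replicates)),
    condition = rep(conds, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), 2))
  ns <- nrow(samples)
  bins <- flatten_exons(gm)
  catalog <- catalog_junctions(gm)
  ## per-transcript junction and bin membership
  tx_ids <- gm$transcripts$transcript_id
  tx_gene <- gm$transcripts$gene_id
  jx_by_tx <- lapply(tx_ids, function(t) {
    sub <- gm$exons[gm$exons$transcript_id == t, , drop = FALSE]
    one <- gene_models(gm$genes[gm$genes$gene_id == sub$gene_id[1], ,
                                drop = FALSE],
                       gm$transcripts[gm$transcripts$transcript_id == t, ,
                                      drop = FALSE], sub)
    catalog_junctions(one, min_exon = 1, min_intron = 1)$junction_id
  })
  names(jx_by_tx) <- tx_ids
  bins_by_tx <- lapply(tx_ids, function(t) {
    sub <- gm$exons[gm$exons$transcript_id == t, , drop = FALSE]
    b <- bins[bins$gene_id == sub$gene_id[1], , drop = FALSE]
    b$bin_id[vapply(seq_len(nrow(b)), function(i)
      any(sub$start <= b$start[i] & sub$end >= b$end[i]), logical(1))]
  })
  names(bins_by_tx) <- tx_ids
  ## fixed per-gene parameters: expression factor and usage profile
  gene_par <- list()
  for (gid in gm$genes$gene_id) {
    gt <- tx_ids[tx_gene == gid]
    base_pi <- rep(1, length(gt))
    names(base_pi) <- gt
    base_pi[paste0(gid, ".t1")] <- 4
    base_pi <- base_pi / sum(base_pi)
    pi_g <- .rdirichlet(cfg$concentration * base_pi)
    names(pi_g) <- gt
    pi_cond <- list(pi_g, pi_g)
    if (gid %in% ann$truth$diff_genes) {
      sk <- ann$truth$skip_transcript[gid]
      p2 <- pi_g
      odds <- p2[sk] / (1 - p2[sk]) * 2^cfg$usage_effect
      p2[sk] <- odds / (1 + odds)
      rest <- names(p2) != sk
      p2[rest] <- p2[rest] / sum(p2[rest]) * (1 - p2[sk])
      pi_cond[[2]] <- p2
    }
    if (gid %in% ann$truth$tss_genes) {
      ta <- paste0(gid, ".talt")
      p2 <- pi_cond[[2]]
      p2[ta] <- p2[ta] * cfg$tss_effect
      pi_cond[[2]] <- p2 / sum(p2)
    }
    gene_par[[gid]] <- list(expr = stats::rlnorm(1, 0, 0.5),
                            pi = pi_cond)
  }
  draw_tx_counts <- function() {
    txc <- matrix(0L, length(tx_ids), ns,
                  dimnames = list(tx_ids, samples$sample_id))
    for (gid in gm$genes$gene_id) {
      gt <- tx_ids[tx_gene == gid]
      par <- gene_par[[gid]]
      for (s in seq_len(ns)) {
        ci <- match(samples$condition[s], conds)
        nfrag <- stats::rnbinom(1, mu = cfg$depth * par$expr,
                                size = 1 / cfg$dispersion)
        txc[gt, s] <- stats::rmultinom(1, nfrag, par$pi[[ci]])
      }
    }
    txc
  }
  ## analytic true junction-usage effect from the planted proportions:
  ## expected junction count is proportional to the summed proportions of
  ## the transcripts carrying it; usage is feature-vs-rest-of-gene log-odds
  true_usage <- do.call(rbind, lapply(gm$genes$gene_id, function(gid) {
    jids <- catalog$junction_id[catalog$gene_id == gid]
    if (length(jids) == 0) return(NULL)
    gt <- tx_ids[tx_gene == gid]
    u <- sapply(1:2, function(ci) {
      pi_c <- gene_par[[gid]]$pi[[ci]]
      ec <- vapply(jids, function(j)
        sum(pi_c[gt[vapply(gt, function(t) j %in% jx_by_tx[[t]],
                           logical(1))]]), numeric(1))
      tot <- sum(ec)
      log2(ec / (tot - ec))
    })
    data.frame(junction_id = jids, true_lfc = u[, 2] - u[, 1],
               stringsAsFactors = FALSE)
  }))
  rownames(true_usage) <- NULL
  tx_counts_m <- draw_tx_counts()
  nascent_tx <- draw_tx_counts()
  agg_members <- function(txc, membership, ids) {
    out <- matrix(0L, length(ids), ns, dimnames = list(ids,
                                                       samples$sample_id))
    for (t in tx_ids) {
      mem <- intersect(membership[[t]], ids)
      if (length(mem) > 0)
        out[mem, ] <- out[mem, , drop = FALSE] +
          rep(txc[t, ], each = length(mem))
    }
    out
  }
  jc <- agg_members(tx_counts_m, jx_by_tx, catalog$junction_id)
  bc <- agg_members(tx_counts_m, bins_by_tx, bins$bin_id)
  nas <- agg_members(nascent_tx, jx_by_tx, catalog$junction_id)
  ## delayed junctions: binomial thinning of the nascent counts
  for (j in intersect(ann$truth$delayed, rownames(nas)))
    nas[j, ] <- stats::rbinom(ns, nas[j, ], 1 / cfg$delay_factor)
  ## retained-intron coverage tables
  ri <- NULL
  if (!is.null(ann$truth$ri)) {
    rid <- sprintf("%s:RI:%d-%d", ann$truth$ri$gene_id, ann$truth$ri$start,
                   ann$truth$ri$end)
    ## flanking exon coverage derived from gene fragment totals over the
    ## exonic union length
    gene_frag <- rowsum(tx_counts_m, tx_gene)
    exlen <- tapply(bins$end - bins$start, bins$gene_id, sum)
    cov_gene <- gene_frag * cfg$read_len /
      as.numeric(exlen[rownames(gene_frag)])
    f5 <- cov_gene[ann$truth$ri$gene_id, , drop = FALSE]
    f3 <- f5 * matrix(stats::runif(length(f5), 0.8, 1.2), nrow(f5))
    icov <- matrix(abs(stats::rnorm(length(rid) * ns, 0, 0.3)),
                   length(rid), ns,
                   dimnames = list(rid, samples$sample_id))
    for (i in seq_along(rid)) {
      active <- ann$truth$ri$condition[i]
      if (active == "none") next
      cols <- if (active == "shared") seq_len(ns)
              else which(samples$condition == active)
      icov[i, cols] <- 0.5 * pmin(f5[i, cols], f3[i, cols])
    }
    rownames(f5) <- rownames(f3) <- rid
    colnames(f5) <- colnames(f3) <- samples$sample_id
    ri <- list(intron_ids = rid, intron_cov = icov, flank5_cov = f5,
               flank3_cov = f3)
  }
  list(bins = bins, bin_counts = count_matrix(bc, samples, features = bins),
       true_usage = true_usage,
       junctions = catalog,
       junction_counts = count_matrix(jc, samples, features = catalog),
       tx_counts = count_matrix(tx_counts_m, samples),
       nascent_counts = count_matrix(nas, samples, features = catalog),
       total_counts = count_matrix(jc, samples, features = catalog),
       ri = ri, samples = samples)
}

#' Simulate epigenetic peak tracks associated with differential donors
#'
#' For each mark, a 200-bp peak is placed within `assoc_window` bp of every
#' differential junction donor with probability `peak_assoc_prob`;
#' background peaks arrive uniformly at `background_prob` per kb of contig.
#'
#' @param ann Output of [simulate_annotation].
#' @param marks Mark names (default the four study tracks).
#' @return Named list of sorted `GRanges`, one per mark.
#' @export
simulate_peaks <- function(ann, marks = c("fusion_TF", "pol2", "H3K9Ac",
                                          "DHS")) {
  cfg <- ann$cfg
  set.seed(cfg$seed + 2)
  catalog <- catalog_junctions(ann$gm)
  di <- match(ann$truth$diff_junctions, catalog$junction_id)
  di <- di[!is.na(di)]
  contig_len <- Biostrings::width(ann$genome)
  names(contig_len) <- names(ann$genome)
  out <- list()
  for (mk in marks) {
    chr <- character(0); st <- integer(0); en <- integer(0)
    for (i in di) {
      if (stats::runif(1) < cfg$peak_assoc_prob) {
        u <- sample.int(cfg$assoc_window, 1) - 1L
        s0 <- max(0L, catalog$donor[i] - u - 100L)
        chr <- c(chr, catalog$chrom[i]); st <- c(st, s0)
        en <- c(en, s0 + 200L)
      }
    }
    for (cc in names(contig_len)) {
      nbg <- stats::rpois(1, cfg$background_prob * contig_len[cc] / 1000)
      if (nbg > 0) {
        s0 <- sample.int(max(1L, contig_len[cc] - 200L), nbg)
        chr <- c(chr, rep(cc, nbg)); st <- c(st, s0); en <- c(en, s0 + 200L)
      }
    }
    gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(st + 1L, en))
    out[[mk]] <- GenomicRanges::sort(gr)
  }
  out
}

#' Simulate transcripts with planted premature termination codons
#'
#' Constructs spliced transcript sequences with a 5' UTR, an ATG-initiated
#' ORF of known length, and a 3' region with exon-exon junctions placed so
#' that the stop codon is a PTC (more than 50 nt upstream of the last
#' junction) at the requested rate; the remainder place the stop in the
#' last exon.
#'
#' @param n Number of transcripts.
#' @param ptc_rate Fraction with a planted PTC (default 0.15).
#' @param orf_codons Protein length in amino acids (default 150).
#' @param seed RNG seed.
#' @return data.frame `transcript_id`, `sequence`, `junctions`
#'   (list-column), `diff_status` (randomly assigned), `true_ptc`.
#' @export
simulate_ptc_transcripts <- function(n, ptc_rate = 0.15, orf_codons = 150,
                                     seed = 1) {
  set.seed(seed)
  sense <- setdiff(names(Biostrings::GENETIC_CODE),
                   c("TAA", "TAG", "TGA", "ATG"))
  rows <- lapply(seq_len(n), function(i) {
    utr5 <- gsub("ATG", "ACG", .rand_seq(60))
    body <- paste(sample(sense, orf_codons - 1, replace = TRUE),
                  collapse = "")
    orf <- paste0("ATG", body, "TAA")
    is_ptc <- stats::runif(1) < ptc_rate
    utr3 <- gsub("ATG", "ACG", .rand_seq(400))
    seqs <- paste0(utr5, orf, utr3)
    data.frame(transcript_id = sprintf("T%04d", i), sequence = seqs,
               diff_status = sample(c("differential", "nondifferential"), 1),
               true_ptc = is_ptc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$junctions <- lapply(seq_len(n), function(i) {
    stop_end <- 60 + (orf_codons + 1) * 3
    if (out$true_ptc[i]) c(60, stop_end + 200) else c(60, stop_end - 30)
  })
  out
}

#' Spliced transcript sequences and junction positions from gene models
#'
#' @param gm A [gene_models] object.
#' @param genome Named `DNAStringSet`.
#' @return data.frame `transcript_id`, `gene_id`, `sequence`, `junctions`
#'   (list-column of transcript-coordinate junction positions),
#'   `junction_ids` (list-column of genomic junction ids).
#' @export
transcript_sequences <- function(gm, genome) {
  rows <- lapply(split(gm$exons, gm$exons$transcript_id), function(d) {
    strand <- d$strand[1]
    d <- d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    seqs <- vapply(seq_len(nrow(d)), function(i)
      get_interval_seq(genome, d$chrom[i], d$start[i], d$end[i], strand),
      character(1))
    lens <- nchar(seqs)
    jx <- if (nrow(d) > 1) cumsum(lens)[-nrow(d)] else numeric(0)
    jids <- if (nrow(d) > 1) {
      up <- d[-nrow(d), ]; dn <- d[-1, ]
      if (strand == "+")
        sprintf("%s:%d-%d", d$gene_id[1], up$end - 1L, dn$start)
      else sprintf("%s:%d-%d", d$gene_id[1], up$start, dn$end - 1L)
    } else character(0)
    data.frame(transcript_id = d$transcript_id[1], gene_id = d$gene_id[1],
               sequence = paste(seqs, collapse = ""),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  sp <- split(gm$exons, gm$exons$transcript_id)
  out$junctions <- lapply(out$transcript_id, function(t) {
    d <- sp[[t]]
    strand <- d$strand[1]
    d <- d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    lens <- d$end - d$start
    if (nrow(d) > 1) cumsum(lens)[-nrow(d)] else numeric(0)
  })
  out$junction_ids <- lapply(out$transcript_id, function(t) {
    d <- sp[[t]]
    strand <- d$strand[1]
    d <- d[order(if (strand == "+") d$start else -d$start), , drop = FALSE]
    if (nrow(d) < 2) return(character(0))
    up <- d[-nrow(d), ]; dn <- d[-1, ]
    if (strand == "+")
      sprintf("%s:%d-%d", d$gene_id[1], up$end - 1L, dn$start)
    else sprintf("%s:%d-%d", d$gene_id[1], up$start, dn$end - 1L)
  })
  out
}

#' Simulate null or shifted negative-binomial junction count tables
#'
#' Direct feature-level generator for calibration and power studies:
#' genes of `features_per_gene` junctions with fixed usage proportions,
#' per-feature counts drawn independently from a negative binomial. When
#' `delta_log2 != 0`, the first feature of each gene designated as shifted
#' has its usage odds multiplied by `2^delta_log2` in the contrast
#' condition (an exact planted usage shift).
#'
#' @param n_genes Number of genes.
#' @param features_per_gene Junctions per gene (default 4).
#' @param depth Mean fragments per gene (default 300).
#' @param dispersion NB dispersion (default 0.05).
#' @param n_replicates Per condition (default 3).
#' @param delta_log2 Planted usage log2-odds shift (default 0: null).
#' @param frac_shifted Fraction of genes with a shifted feature
#'   (default 1 when `delta_log2 != 0`).
#' @param seed RNG seed.
#' @return list with `m` ([count_matrix]), `grouping` (feature to gene),
#'   `shifted` (ids of planted features), `samples`.
#' @export
simulate_null_usage <- function(n_genes, features_per_gene = 4,
                                depth = 300, dispersion = 0.05,
                                n_replicates = 3, delta_log2 = 0,
                                frac_shifted = if (delta_log2 != 0) 1 else 0,
                                seed = 1) {
  set.seed(seed)
  conds <- c("c1", "c2")
  samples <- sample_info(
    sample_id = paste0(rep(conds, each = n_replicates), "_",
                       seq_len(n_replicates)),
    condition = rep(conds, each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2))
  ns <- nrow(samples)
  k <- features_per_gene
  ids <- sprintf("g%05d:f%d", rep(seq_len(n_genes), each = k),
                 rep(seq_len(k), n_genes))
  grouping <- rep(sprintf("g%05d", seq_len(n_genes)), each = k)
  names(grouping) <- ids
  shifted_genes <- sample(seq_len(n_genes),
                          round(frac_shifted * n_genes))
  counts <- matrix(0L, length(ids), ns,
                   dimnames = list(ids, samples$sample_id))
  true_lfc <- numeric(length(ids))
  for (g in seq_len(n_genes)) {
    pi_g <- .rdirichlet(rep(10, k))
    expr <- stats::rlnorm(1, 0, 0.5)
    pi2 <- pi_g
    if (g %in% shifted_genes && delta_log2 != 0) {
      odds <- pi2[1] / (1 - pi2[1]) * 2^delta_log2
      pi2[1] <- odds / (1 + odds)
      pi2[-1] <- pi2[-1] / sum(pi2[-1]) * (1 - pi2[1])
    }
    rows <- (g - 1) * k + seq_len(k)
    true_lfc[rows] <- log2(pi2 / (1 - pi2)) - log2(pi_g / (1 - pi_g))
    for (s in seq_len(ns)) {
      p <- if (samples$condition[s] == conds[2]) pi2 else pi_g
      counts[rows, s] <- stats::rnbinom(k, mu = depth * expr * p,
                                        size = 1 / dispersion)
    }
  }
  names(true_lfc) <- ids
  list(m = count_matrix(counts, samples), grouping = grouping,
       shifted = if (length(shifted_genes))
         sprintf("g%05d:f1", sort(shifted_genes)) else character(0),
       true_lfc = true_lfc, samples = samples)
}
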