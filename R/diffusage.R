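## shared moderated two-sample machinery: values is a features x samples
## matrix; variance is pooled within groups and shrunk toward the family
## mean variance with a fixed prior df (determinism over estimation).
## Because the shrinkage target is the (essentially noise-free) family
## mean rather than a scattered prior, the shrunken variance has
## Satterthwaite effective df (d0+d)^2/d, which is the t reference that
## keeps null p-values uniform.
.moderated_t <- function(values, idx1, idx2, prior_df = 4) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(values[, idx1, drop = FALSE])
  m2 <- rowMeans(values[, idx2, drop = FALSE])
  lfc <- m2 - m1
  ss <- rowSums((values[, idx1, drop = FALSE] - m1)^2) +
        rowSums((values[, idx2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- ss / df
  s2_0 <- mean(s2[is.finite(s2)])
  s2_mod <- (prior_df * s2_0 + df * s2) / (prior_df + df)
  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  stat <- lfc / se
  df_eff <- (prior_df + df)^2 / df
  p <- 2 * stats::pt(-abs(stat), df_eff)
  ## degenerate noise-free input: zero SE
  zero <- se == 0
  stat[zero] <- ifelse(lfc[zero] == 0, 0, sign(lfc[zero]) * Inf)
  p[zero] <- ifelse(lfc[zero] == 0, 1, 0)
  list(lfc = lfc, stat = stat, p = p)
}

#' Gene-relative differential-usage statistic
#'
#' For feature f of gene g in sample s the usage value is the log-odds of
#' the feature against the rest of its gene,
#' `u = log2(count + 0.5) - log2(geneTotal - count + 0.5)`; the reported
#' `usage_log2fc` is the difference of condition means of `u`. Because `u`
#' is a within-gene ratio, proportional gene-level expression changes cancel
#' and only usage shifts remain. The test statistic divides `usage_log2fc`
#' by a moderated standard error (per-feature pooled variance shrunk toward
#' the family mean with prior df 4); p-values come from a t distribution
#' with residual plus prior degrees of freedom. A label-permutation variant
#' (`method = "permutation"`) provides an independent second calling method
#' for consensus bookkeeping.
#'
#' @param m A [count_matrix] of bins or junctions.
#' @param grouping Named character vector mapping feature_id to gene_id.
#' @param samples Sample sheet (defaults to `m$samples`).
#' @param conditions Length-2 character vector (reference, contrast);
#'   defaults to order of appearance in `samples$condition`.
#' @param min_count Features with smaller total count are excluded
#'   (default 10).
#' @param method `"moderated"` (default) or `"permutation"`.
#' @param prior_df Prior degrees of freedom for variance moderation
#'   (default 4).
#' @param permutations Maximum permutations for the permutation method
#'   (default 1000; all distinct label assignments are enumerated when
#'   fewer).
#' @param seed RNG seed for sampled permutations.
#' @return data.frame with `feature_id`, `gene_id`, `usage_log2fc`, `stat`,
#'   `p`, `q` (BH within this family) and `direction`.
#' @export
usage_statistic <- function(m, grouping, samples = m$samples,
                            conditions = NULL, min_count = 10,
                            method = c("moderated", "permutation"),
                            prior_df = 4, permutations = 1000, seed = 1) {
  method <- match.arg(method)
  counts <- m$counts
  if (is.null(conditions)) conditions <- unique(samples$condition)
  stopifnot(length(conditions) == 2)
  idx1 <- which(samples$condition == conditions[1])
  idx2 <- which(samples$condition == conditions[2])
  if (length(idx1) < 2 || length(idx2) < 2)
    stop("at least 2 replicates per condition required")
  gene <- unname(grouping[rownames(counts)])
  keep <- !is.na(gene) & rowSums(counts) >= min_count
  counts <- counts[keep, , drop = FALSE]; gene <- gene[keep]
  ## genes with a single surviving feature: usage undefined
  tab <- table(gene)
  keep2 <- gene %in% names(tab)[tab >= 2]
  counts <- counts[keep2, , drop = FALSE]; gene <- gene[keep2]
  if (nrow(counts) == 0)
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      usage_log2fc = numeric(0), stat = numeric(0),
                      p = numeric(0), q = numeric(0),
                      direction = character(0)))
  gene_tot <- rowsum(counts, gene)[gene, , drop = FALSE]
  u <- log2(counts + 0.5) - log2(gene_tot - counts + 0.5)
  if (method == "moderated") {
    mt <- .moderated_t(u, idx1, idx2, prior_df)
    lfc <- mt$lfc; stat <- mt$stat; p <- mt$p
  } else {
    lfc <- rowMeans(u[, idx2, drop = FALSE]) -
           rowMeans(u[, idx1, drop = FALSE])
    cols <- c(idx1, idx2); n1 <- length(idx1)
    combs <- utils::combn(length(cols), n1)
    if (ncol(combs) > permutations) {
      set.seed(seed)
      combs <- combs[, sample.int(ncol(combs), permutations), drop = FALSE]
    }
    exceed <- integer(nrow(u))
    for (b in seq_len(ncol(combs))) {
      g1 <- cols[combs[, b]]; g2 <- setdiff(cols, g1)
      lfc_b <- rowMeans(u[, g2, drop = FALSE]) -
               rowMeans(u[, g1, drop = FALSE])
      exceed <- exceed + (abs(lfc_b) >= abs(lfc) - 1e-12)
    }
    p <- exceed / ncol(combs)
    stat <- lfc
  }
  data.frame(feature_id = rownames(counts), gene_id = gene,
             usage_log2fc = unname(lfc), stat = unname(stat), p = unname(p),
             q = bh_fdr(unname(p)),
             direction = ifelse(lfc >= 0, "up", "down"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Step-up adjusted q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differential features at fold-change and FDR thresholds
#'
#' A feature is differential iff `|usage_log2fc| > log2(fc)` and `q < q_max`
#' (both strict: "more than" 2-fold change and q below the cutoff).
#'
#' @param stats Output of [usage_statistic] for one feature family.
#' @param fc Fold-change threshold (default 2).
#' @param q_max FDR threshold (default 0.1).
#' @param method Label recorded for features called here.
#' @return data.frame with `feature_id`, `is_differential`, `methods`.
#' @export
call_differential <- function(stats, fc = 2, q_max = 0.1,
                              method = "moderated") {
  called <- abs(stats$usage_log2fc) > log2(fc) & stats$q < q_max
  data.frame(feature_id = stats$feature_id,
             is_differential = called,
             methods = ifelse(called, method, ""),
             stringsAsFactors = FALSE)
}

#' Combine differential calls across methods
#'
#' @param calls_by_method Named list of [call_differential] outputs over the
#'   same feature universe.
#' @param mode `"union"` (default) tags every contributing method;
#'   `"intersection"` keeps features called by all methods.
#' @return data.frame with `feature_id`, `is_differential`, `methods`
#'   (comma-separated contributing methods).
#' @export
consensus <- function(calls_by_method, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  ids <- sort(calls_by_method[[1]]$feature_id)
  for (cl in calls_by_method)
    if (!identical(sort(cl$feature_id), ids))
      stop("mismatched feature universes across methods")
  flags <- sapply(calls_by_method, function(cl)
    cl$is_differential[match(ids, cl$feature_id)])
  flags <- matrix(flags, nrow = length(ids),
                  dimnames = list(ids, names(calls_by_method)))
  is_diff <- if (mode == "union") rowSums(flags) > 0 else
    rowSums(flags) == ncol(flags)
  methods <- apply(flags, 1, function(r)
    paste(colnames(flags)[r], collapse = ","))
  methods[!is_diff] <- ""
  data.frame(feature_id = ids, is_differential = unname(is_diff),
             methods = unname(methods), stringsAsFactors = FALSE)
}

#' Group transcripts by transcription start site
#'
#' TSS positions of one gene are merged into a group when within
#' `merge_window` bp of the previous position (single-linkage along the
#' sorted positions).
#'
#' @param gm A [gene_models] object.
#' @param merge_window Merge window in bp (default 10).
#' @return data.frame `transcript_id`, `gene_id`, `tss_group` (id
#'   `"gene@NNN"`), `tss_position` (group representative).
#' @export
tss_groups <- function(gm, merge_window = 10) {
  tx <- gm$transcripts
  out <- lapply(split(tx, tx$gene_id), function(d) {
    o <- order(d$tss)
    d <- d[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, diff(d$tss) > merge_window))
    data.frame(transcript_id = d$transcript_id, gene_id = d$gene_id,
               tss_group = sprintf("%s@%03d", d$gene_id, grp),
               tss_position = tapply(d$tss, grp, min)[grp],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Differential TSS expression and usage
#'
#' Transcript counts are aggregated by TSS group. The expression arm tests
#' per-group total abundance between conditions (moderated t on log2-CPM);
#' the usage arm applies [usage_statistic] with TSS groups as the features
#' of their genes. Default call thresholds follow the respective arms:
#' at least 2-fold change with p < 0.005 and q < 0.1 for expression,
#' at least 2-fold usage change with p < 0.0007 and q < 0.1 for usage.
#'
#' @param tx_counts A [count_matrix] over transcript ids.
#' @param gm A [gene_models] object.
#' @param samples Sample sheet (defaults to `tx_counts$samples`).
#' @param conditions Length-2 condition pair (reference, contrast).
#' @param merge_window TSS merge window in bp (default 10).
#' @param expr_p,expr_q Expression-arm thresholds (defaults 0.005, 0.1).
#' @param usage_p,usage_q Usage-arm thresholds (defaults 0.0007, 0.1).
#' @param fc Fold-change threshold for both arms (default 2, inclusive).
#' @return list with `expression` and `usage` data.frames (each with a
#'   logical `called` column) and the `groups` table.
#' @export
tss_differential <- function(tx_counts, gm, samples = tx_counts$samples,
                             conditions = NULL, merge_window = 10,
                             expr_p = 0.005, expr_q = 0.1,
                             usage_p = 0.0007, usage_q = 0.1, fc = 2) {
  grp <- tss_groups(gm, merge_window)
  counts <- tx_counts$counts
  gi <- grp$tss_group[match(rownames(counts), grp$transcript_id)]
  keep <- !is.na(gi)
  agg <- rowsum(counts[keep, , drop = FALSE], gi[keep])
  m <- count_matrix(agg, samples, library_sizes = tx_counts$library_sizes)
  if (is.null(conditions)) conditions <- unique(samples$condition)
  idx1 <- which(samples$condition == conditions[1])
  idx2 <- which(samples$condition == conditions[2])
  logcpm <- cpm_normalize(m)
  mt <- .moderated_t(logcpm, idx1, idx2)
  expr <- data.frame(tss_group = rownames(agg),
                     gene_id = grp$gene_id[match(rownames(agg),
                                                 grp$tss_group)],
                     log2fc = unname(mt$lfc), stat = unname(mt$stat),
                     p = unname(mt$p), q = bh_fdr(unname(mt$p)),
                     stringsAsFactors = FALSE)
  expr$called <- abs(expr$log2fc) >= log2(fc) & expr$p < expr_p &
    expr$q < expr_q
  gmap <- grp$gene_id[match(rownames(agg), grp$tss_group)]
  names(gmap) <- rownames(agg)
  us <- usage_statistic(m, gmap, samples, conditions)
  us$called <- abs(us$usage_log2fc) >= log2(fc) & us$p < usage_p &
    us$q < usage_q
  list(expression = expr, usage = us, groups = grp)
}

#' Summarize 3'-terminal exon bins overlapping binding peaks
#'
#' Counts 3'-terminal bins that overlap a peak and, of those, how many are
#' differentially used at the stringent thresholds (at least `fc`-fold
#' usage change and `q < q_max`).
#'
#' @param stats [usage_statistic] output over bins.
#' @param bins Bin table with `is_three_prime_terminal`.
#' @param peak_overlap Named logical vector by `bin_id`.
#' @param fc Fold-change threshold (default 2).
#' @param q_max FDR threshold (default 1e-4).
#' @return One-row data.frame: `n_terminal_peak_overlap`, `n_differential`.
#' @export
terminal_exon_check <- function(stats, bins, peak_overlap, fc = 2,
                                q_max = 1e-4) {
  term <- bins$bin_id[bins$is_three_prime_terminal]
  ov <- term[term %in% names(peak_overlap)[peak_overlap]]
  i <- match(ov, stats$feature_id)
  diff <- !is.na(i) & abs(stats$usage_log2fc[i]) >= log2(fc) &
    stats$q[i] < q_max
  data.frame(n_terminal_peak_overlap = length(ov),
             n_differential = sum(diff))
}
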