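## canonical site sets and distinct exon intervals for one gene
.gene_context <- function(gm, gene_id) {
  ex <- gm$exons[gm$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown gene: ", gene_id)
  cat <- catalog_junctions(
    gene_models(gm$genes[gm$genes$gene_id == gene_id, , drop = FALSE],
                gm$transcripts[gm$transcripts$gene_id == gene_id, ,
                               drop = FALSE], ex),
    min_exon = 1, min_intron = 1)
  exu <- unique(ex[, c("start", "end")])
  ## exon co-occurrence across transcripts, keyed by interval
  ekey <- paste(ex$start, ex$end)
  tx_sets <- split(ekey, ex$transcript_id)
  list(exons = ex, exon_intervals = exu, catalog = cat,
       donors = unique(cat$donor), acceptors = unique(cat$acceptor),
       pairs = paste(cat$donor, cat$acceptor), tx_sets = tx_sets,
       span = c(min(ex$start), max(ex$end)))
}

#' Classify a junction into an alternative-splicing mode
#'
#' Decision order: an annotated (donor, acceptor) pair is `canonical`. A
#' novel pair of two annotated boundaries whose spanned intron fully
#' contains at least one annotated exon is `cassette_skipping`, or
#' `mutually_exclusive` when the skipped exons include two exons that never
#' co-occur in any transcript. A junction with a canonical acceptor but
#' novel donor is `alt_5ss`; canonical donor but novel acceptor `alt_3ss`
#' (strand-aware). Two or more simultaneous deviations (both sites novel,
#' or a shifted site combined with exon skipping) are `complex`. Intron
#' retention is a bin-level call, never assigned to junctions.
#'
#' @param junctions data.frame with `junction_id`, `gene_id`, `donor`,
#'   `acceptor`, `strand`.
#' @param gm A [gene_models] object.
#' @return data.frame `junction_id`, `mode`, `evidence` (comma-separated
#'   skipped exon intervals, when applicable).
#' @export
classify_junctions <- function(junctions, gm) {
  ctxs <- list()
  out <- data.frame(junction_id = junctions$junction_id,
                    mode = NA_character_, evidence = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(junctions))) {
    gid <- junctions$gene_id[i]
    if (is.null(ctxs[[gid]])) ctxs[[gid]] <- .gene_context(gm, gid)
    ctx <- ctxs[[gid]]
    d <- junctions$donor[i]; a <- junctions$acceptor[i]
    if (min(d, a) < ctx$span[1] || max(d, a) >= ctx$span[2])
      stop("junction ", junctions$junction_id[i], " outside gene span")
    if (paste(d, a) %in% ctx$pairs) {
      out$mode[i] <- "canonical"
      next
    }
    donor_canon <- d %in% ctx$donors
    acc_canon <- a %in% ctx$acceptors
    lo <- min(d, a) + 1L; hi <- max(d, a)
    skipped <- ctx$exon_intervals[ctx$exon_intervals$start >= lo &
                                  ctx$exon_intervals$end <= hi, ,
                                  drop = FALSE]
    skipping <- nrow(skipped) > 0
    if (skipping)
      out$evidence[i] <- paste(sprintf("%d-%d", skipped$start, skipped$end),
                               collapse = ",")
    if (donor_canon && acc_canon) {
      if (!skipping) { out$mode[i] <- "complex"; next }
      mode <- "cassette_skipping"
      if (nrow(skipped) >= 2) {
        keys <- paste(skipped$start, skipped$end)
        for (x in seq_along(keys)) for (y in seq_along(keys)) {
          if (x >= y) next
          co <- any(vapply(ctx$tx_sets, function(s)
            keys[x] %in% s && keys[y] %in% s, logical(1)))
          pres <- any(vapply(ctx$tx_sets, function(s) keys[x] %in% s,
                             logical(1))) &&
                  any(vapply(ctx$tx_sets, function(s) keys[y] %in% s,
                             logical(1)))
          if (!co && pres) mode <- "mutually_exclusive"
        }
      }
      out$mode[i] <- mode
    } else if (donor_canon || acc_canon) {
      if (skipping) out$mode[i] <- "complex"
      else out$mode[i] <- if (acc_canon) "alt_5ss" else "alt_3ss"
    } else {
      out$mode[i] <- "complex"
    }
  }
  out
}

#' Functional exon types at a junction's splice sites
#'
#' Maps the donor and acceptor positions to the functional type of the
#' flattened bin containing them; sites falling outside every bin (purely
#' intronic with no retained-intron bin) are flagged `intergenic_intronic`
#' and should be excluded from type-distribution tables.
#'
#' @param junctions Junction data.frame (`junction_id`, `gene_id`, `donor`,
#'   `acceptor`).
#' @param bins Bin table from [flatten_exons].
#' @return data.frame `junction_id`, `donor_exon_type`, `acceptor_exon_type`.
#' @export
splice_site_types <- function(junctions, bins) {
  site_type <- function(gene_id, pos) {
    b <- bins[bins$gene_id == gene_id & bins$start <= pos & bins$end > pos, ,
              drop = FALSE]
    if (nrow(b) == 0) "intergenic_intronic" else b$functional_type[1]
  }
  data.frame(
    junction_id = junctions$junction_id,
    donor_exon_type = mapply(site_type, junctions$gene_id, junctions$donor),
    acceptor_exon_type = mapply(site_type, junctions$gene_id,
                                junctions$acceptor),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Categorical enrichment of a differential set against its universe
#'
#' For each label L, forms the 2x2 table `[diff & L, diff & !L;
#' nondiff & L, nondiff & !L]`, reports the cross-product odds ratio
#' (Haldane 0.5 correction applied to all cells when any cell is zero) and
#' a two-sided Fisher exact or chi-square (no continuity correction)
#' p-value, with BH adjustment across labels.
#'
#' @param diff Character vector of differential feature ids (subset of
#'   `universe`).
#' @param universe All feature ids.
#' @param category Named character vector mapping feature id to label.
#' @param test `"fisher"` (default) or `"chi2"`.
#' @return data.frame per label: counts `a`,`b`,`c`,`d`, `odds_ratio`, `p`,
#'   `q`.
#' @export
categorical_enrichment <- function(diff, universe, category,
                                   test = c("fisher", "chi2")) {
  test <- match.arg(test)
  stopifnot(all(diff %in% universe))
  labs <- sort(unique(unname(category[universe])))
  if (length(labs) < 2) stop("at least two labels required")
  is_diff <- universe %in% diff
  lab_of <- unname(category[universe])
  res <- lapply(labs, function(L) {
    a <- sum(is_diff & lab_of == L); b <- sum(is_diff & lab_of != L)
    c_ <- sum(!is_diff & lab_of == L); d <- sum(!is_diff & lab_of != L)
    if (length(diff) == 0) {
      or <- NA_real_; p <- NA_real_
    } else {
      or <- if (any(c(a, b, c_, d) == 0))
        ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
      else (a * d) / (b * c_)
      tab <- matrix(c(a, c_, b, d), 2)
      p <- if (test == "fisher") stats::fisher.test(tab)$p.value
      else suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    data.frame(label = L, a = a, b = b, c = c_, d = d, odds_ratio = or,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- if (all(is.na(out$p))) NA_real_ else bh_fdr(out$p)
  out
}
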