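#' Assemble per-junction predictor vectors
#'
#' Combines motif frequency/strength features ([motif_features]), splice
#' site-to-peak distances ([peak_distances]), intron length and mean gene
#' expression (log2-CPM) into the predictor matrix consumed by
#' [train_meta_classifier]. Infinite distances (chromosome absent from a
#' track) are replaced by a large finite sentinel (1e7).
#'
#' @param junctions Junction catalog rows to featurize.
#' @param genome Named `DNAStringSet`.
#' @param pwms Named list of `pwm` objects.
#' @param peaks Named list of `GRanges` tracks.
#' @param gene_logcpm Named numeric vector of mean gene log2-CPM.
#' @param diff_ids Junction ids labelled `"diff"`; the rest are
#'   `"nondiff"`.
#' @param w_e,w_i Window widths for [motif_features].
#' @return data.frame with `junction_id`, numeric predictors and `label`.
#' @export
eej_feature_vectors <- function(junctions, genome, pwms, peaks,
                                gene_logcpm, diff_ids, w_e = 100,
                                w_i = 100) {
  mf <- motif_features(junctions, genome, pwms, w_e, w_i)
  pd <- peak_distances(junctions, peaks)
  out <- merge(mf, pd, by = "junction_id", sort = FALSE)
  out$intron_length <- junctions$intron_length[
    match(out$junction_id, junctions$junction_id)]
  out$gene_expression <- unname(gene_logcpm[
    junctions$gene_id[match(out$junction_id, junctions$junction_id)]])
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    v[!is.finite(v)] <- 1e7
    v
  })
  out$label <- ifelse(out$junction_id %in% diff_ids, "diff", "nondiff")
  out
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the full synthetic end-to-end pipeline
#'
#' Generates annotation, counts, peaks and sequences with planted truth,
#' then executes every analysis stage: junction and bin differential usage
#' (moderated + permutation methods with union consensus), retained-intron
#' detection, splicing-mode classification and functional-type enrichment,
#' feature construction, the random-forest meta-classifier with partial
#' dependence and importance ranking, delayed-splicing comparison,
#' isoform coding/PTC annotation, and differential TSS analysis. All
#' results are written as TSV/JSON under `out_dir` together with a
#' manifest (parameters, record counts, md5 checksums); reruns with the
#' same configuration are checksum-identical.
#'
#' @param cfg A [sim_config].
#' @param out_dir Output directory (created if needed).
#' @param rf_cfg An [rf_config]; default 50 runs x 100 trees, seeded from
#'   `cfg$seed`.
#' @param run_rf Set `FALSE` to skip the random-forest stage (the manifest
#'   notes the skip and no PD outputs are written).
#' @return Invisible list with all in-memory results and `manifest`.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = tempfile("run_"),
                         rf_cfg = NULL, run_rf = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(rf_cfg)) rf_cfg <- rf_config(50, 100, seed = cfg$seed)
  res <- list()
  ## stage: simulate
  ann <- simulate_annotation(cfg)
  sim <- simulate_counts(ann)
  peaks <- simulate_peaks(ann)
  pwms <- default_pwms(file.path(out_dir, "pwms.txt"))
  res$ann <- ann; res$sim <- sim; res$peaks <- peaks; res$pwms <- pwms
  ## stage: differential usage (junctions, two methods + consensus)
  jgroup <- sim$junctions$gene_id
  names(jgroup) <- sim$junctions$junction_id
  us_j <- usage_statistic(sim$junction_counts, jgroup,
                          conditions = cfg$conditions)
  us_j_perm <- usage_statistic(sim$junction_counts, jgroup,
                               conditions = cfg$conditions,
                               method = "permutation", seed = cfg$seed)
  calls <- consensus(list(
    moderated = call_differential(us_j, method = "moderated"),
    permutation = call_differential(us_j_perm, method = "permutation")),
    mode = "union")
  diff_ids <- calls$feature_id[calls$is_differential]
  res$usage_junctions <- us_j; res$calls <- calls
  ## stage: bin usage
  bgroup <- sim$bins$gene_id
  names(bgroup) <- sim$bins$bin_id
  us_b <- usage_statistic(sim$bin_counts, bgroup,
                          conditions = cfg$conditions)
  res$usage_bins <- us_b
  ## stage: retained introns
  if (!is.null(sim$ri)) {
    res$ri_calls <- detect_retained_introns(
      sim$ri$intron_cov, sim$ri$flank5_cov, sim$ri$flank3_cov,
      sim$samples)
  }
  ## stage: event classification and enrichment
  res$events <- classify_junctions(sim$junctions, ann$gm)
  sst <- splice_site_types(sim$junctions, sim$bins)
  res$site_types <- sst
  type_of <- sst$donor_exon_type
  names(type_of) <- sst$junction_id
  keep <- type_of != "intergenic_intronic"
  res$type_enrichment <- tryCatch(
    categorical_enrichment(intersect(diff_ids, names(type_of)[keep]),
                           names(type_of)[keep], type_of, test = "fisher"),
    error = function(e) NULL)
  ## stage: feature vectors + random forest
  glcpm_m <- cpm_normalize(sim$junction_counts)
  gene_logcpm <- tapply(rowMeans(glcpm_m), jgroup[rownames(glcpm_m)], mean)
  fv <- eej_feature_vectors(sim$junctions, ann$genome, pwms, peaks,
                            gene_logcpm, ann$truth$diff_junctions)
  res$features <- fv
  if (run_rf && sum(fv$label == "diff") >= 20) {
    ens <- train_meta_classifier(fv, rf_cfg)
    res$rf <- ens
    res$importance <- rank_features(ens)
    top <- res$importance$feature[1:3]
    res$pd <- do.call(rbind, lapply(top, function(f)
      partial_dependence(ens, f)))
  }
  ## stage: delayed splicing
  res$delayed <- delayed_splicing(sim$nascent_counts, sim$total_counts,
                                  ann$truth$diff_junctions)
  ## stage: isoform consequences
  txs <- transcript_sequences(ann$gm, ann$genome)
  txs$diff_status <- ifelse(vapply(txs$junction_ids, function(j)
    any(j %in% diff_ids), logical(1)), "differential", "nondifferential")
  res$coding <- annotate_coding(txs)
  res$ptc <- tryCatch(ptc_fraction_test(res$coding),
                      error = function(e) NULL)
  ## stage: TSS
  res$tss <- tss_differential(sim$tx_counts, ann$gm,
                              conditions = cfg$conditions)
  ## write outputs + manifest
  files <- c(
    usage_junctions = .write_tsv(us_j, file.path(out_dir,
                                                 "usage_junctions.tsv")),
    usage_bins = .write_tsv(us_b, file.path(out_dir, "usage_bins.tsv")),
    calls = .write_tsv(calls, file.path(out_dir, "diff_calls.tsv")),
    events = .write_tsv(res$events, file.path(out_dir, "events.tsv")),
    site_types = .write_tsv(sst, file.path(out_dir, "site_types.tsv")),
    features = .write_tsv(fv, file.path(out_dir, "feature_matrix.tsv")),
    tss_expression = .write_tsv(res$tss$expression,
                                file.path(out_dir, "tss_expression.tsv")),
    tss_usage = .write_tsv(res$tss$usage,
                           file.path(out_dir, "tss_usage.tsv")),
    delayed = .write_tsv(res$delayed$summary,
                         file.path(out_dir, "delayed_summary.tsv")),
    coding = .write_tsv(res$coding, file.path(out_dir, "coding_calls.tsv")))
  if (!is.null(res$ri_calls))
    files["ri_calls"] <- .write_tsv(res$ri_calls,
                                    file.path(out_dir, "ri_calls.tsv"))
  if (!is.null(res$importance)) {
    files["importance"] <- .write_tsv(res$importance,
                                      file.path(out_dir, "importance.tsv"))
    files["pd"] <- .write_tsv(res$pd,
                              file.path(out_dir, "partial_dependence.tsv"))
  }
  manifest <- list(
    seed = cfg$seed,
    n_genes = cfg$n_genes,
    stages = c("simulate", "diffusage", "retained_introns", "events",
               "features", if (run_rf) "rf" else NULL, "delayed",
               "consequences", "tss"),
    rf_skipped = !run_rf,
    n_diff_called = length(diff_ids),
    auroc = if (!is.null(res$rf)) res$rf$auroc_mean else NA,
    checksums = as.list(unname(tools::md5sum(unname(files)))))
  names(manifest$checksums) <- names(files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}
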