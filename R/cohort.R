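## symmetric FastICA (logcosh contrast, SVD whitening), deterministic under
## seed; observations are rows of X, variables columns.
.fastica <- function(X, k, seed = 1, maxit = 500, tol = 1e-7) {
  n <- nrow(X); p <- ncol(X)
  if (k >= min(n, p)) stop("k must be smaller than min(observations, variables)")
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = 0, nv = k)
  d <- sv$d[seq_len(k)]
  K <- sv$v %*% diag(sqrt(n) / d, k)       # p x k whitening
  Z <- X %*% K                              # n x k, unit variance, decorrelated
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k)
  sW <- svd(W)
  W <- sW$u %*% t(sW$v)                     # orthonormal init
  for (it in seq_len(maxit)) {
    Y <- Z %*% W
    G <- tanh(Y)
    Gp <- 1 - G^2
    W1 <- crossprod(Z, G) / n - W %*% diag(colMeans(Gp), k)
    sW <- svd(W1)
    W1 <- sW$u %*% t(sW$v)
    delta <- max(abs(abs(diag(crossprod(W1, W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- Z %*% W                              # n x k independent sources
  list(S = S, K = K, W = W)
}

#' Independent-component junction signatures separating sample groups
#'
#' Decomposes a junctions-by-samples log-CPM matrix into `k` statistically
#' independent components (FastICA, logcosh contrast, deterministic seeded
#' initialization). Loadings are unit-normalized per component; per-sample
#' weights come from least-squares projection of the data onto the sources.
#' Components are ranked by the two-sided Mann-Whitney p-value separating
#' the two sample groups on their weights, and each component's signature
#' is the junction set with loading |z| > `z_cut`.
#'
#' @param junction_logcpm Numeric matrix, junctions x samples (rownames =
#'   junction ids, colnames = sample ids).
#' @param groups Named character vector (by sample id) with exactly two
#'   levels.
#' @param k Number of components (default: number of groups + 3).
#' @param z_cut Loading z-score cutoff for signature membership
#'   (default 2.5).
#' @param seed RNG seed.
#' @return list with `components` (data.frame `component`, `separation_p`,
#'   ranked), `loadings`, `weights`, and `signatures` (list of junction id
#'   vectors).
#' @export
ica_signatures <- function(junction_logcpm, groups, k = NULL, z_cut = 2.5,
                           seed = 1) {
  glab <- groups[colnames(junction_logcpm)]
  lv <- unique(glab)
  if (length(lv) != 2) stop("exactly two sample groups required")
  if (min(table(glab)) < 3) stop("at least 3 samples per group required")
  if (is.null(k)) k <- length(lv) + 3
  fit <- .fastica(junction_logcpm, k, seed = seed)
  S <- fit$S
  S <- sweep(S, 2, sqrt(colSums(S^2)), "/")  # unit-norm loadings
  Xc <- sweep(junction_logcpm, 2, colMeans(junction_logcpm))
  A <- qr.solve(S, Xc)                       # k x samples
  seps <- vapply(seq_len(k), function(c_)
    stats::wilcox.test(A[c_, glab == lv[1]], A[c_, glab == lv[2]],
                       exact = FALSE)$p.value, numeric(1))
  o <- order(seps)
  sig <- lapply(o, function(c_) {
    z <- (S[, c_] - mean(S[, c_])) / stats::sd(S[, c_])
    rownames(junction_logcpm)[abs(z) > z_cut]
  })
  list(components = data.frame(component = o, separation_p = seps[o]),
       loadings = S[, o, drop = FALSE],
       weights = A[o, , drop = FALSE],
       signatures = sig)
}

#' Overlap odds ratio between two feature sets
#'
#' 2x2 Fisher test of joint membership within a universe, via
#' [categorical_enrichment].
#'
#' @param set_a,set_b Feature id vectors (subsets of `universe`).
#' @param universe All feature ids.
#' @return One-row data.frame with counts, `odds_ratio`, `p`.
#' @export
overlap_odds <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("empty universe")
  lab <- ifelse(universe %in% set_b, "in_b", "out_b")
  names(lab) <- universe
  enr <- categorical_enrichment(intersect(set_a, universe), universe, lab,
                                test = "fisher")
  enr[enr$label == "in_b", c("a", "b", "c", "d", "odds_ratio", "p")]
}

#' Nascent-versus-total delayed-splicing summary
#'
#' For junctions shared between the nascent and total matrices,
#' replicate-averaged log2-CPM abundances are compared between the
#' differential and non-differential classes within each RNA fraction, and
#' between fractions within each class (two-sided Mann-Whitney). A
#' bimodality score per class/fraction is the log-likelihood improvement of
#' a 2-component over a 1-component Gaussian mixture.
#'
#' @param nascent,total [count_matrix] objects over junctions.
#' @param diff_ids Junction ids of the differential class.
#' @return list with `summary` (class x fraction medians, n, bimodality,
#'   `unstable` flag for classes with fewer than 10 shared junctions),
#'   `tests` (comparison, p), and the abundance vectors.
#' @export
delayed_splicing <- function(nascent, total, diff_ids) {
  shared <- intersect(rownames(nascent$counts), rownames(total$counts))
  ab <- list(nascent = rowMeans(cpm_normalize(nascent)[shared, , drop = FALSE]),
             total = rowMeans(cpm_normalize(total)[shared, , drop = FALSE]))
  cls <- ifelse(shared %in% diff_ids, "diff", "nondiff")
  summary <- expand.grid(class = c("diff", "nondiff"),
                         fraction = c("nascent", "total"),
                         stringsAsFactors = FALSE)
  summary$n <- NA_integer_; summary$median <- NA_real_
  summary$bimodality <- NA_real_; summary$unstable <- FALSE
  vectors <- list()
  for (i in seq_len(nrow(summary))) {
    v <- ab[[summary$fraction[i]]][cls == summary$class[i]]
    vectors[[paste(summary$class[i], summary$fraction[i], sep = "_")]] <- v
    summary$n[i] <- length(v)
    summary$median[i] <- stats::median(v)
    summary$unstable[i] <- length(v) < 10
    if (length(v) >= 10)
      summary$bimodality[i] <- .bimodality_score(v)
  }
  comparisons <- list(
    c("diff_nascent", "nondiff_nascent"),
    c("diff_total", "nondiff_total"),
    c("diff_nascent", "diff_total"),
    c("nondiff_nascent", "nondiff_total"))
  tests <- do.call(rbind, lapply(comparisons, function(cp) {
    p <- if (length(vectors[[cp[1]]]) > 0 && length(vectors[[cp[2]]]) > 0)
      stats::wilcox.test(vectors[[cp[1]]], vectors[[cp[2]]],
                         exact = FALSE)$p.value else NA_real_
    data.frame(comparison = paste(cp, collapse = "_vs_"), p = p,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, tests = tests, vectors = vectors)
}

#' @importFrom mclust Mclust mclustBIC
.bimodality_score <- function(x) {
  f2 <- tryCatch(mclust::Mclust(x, G = 2, modelNames = "V",
                                verbose = FALSE),
                 error = function(e) NULL)
  f1 <- mclust::Mclust(x, G = 1, modelNames = "V", verbose = FALSE)
  if (is.null(f2) || is.null(f1)) return(NA_real_)
  as.numeric(f2$loglik - f1$loglik)
}

#' Signed co-expression edges around a seed gene
#'
#' Pearson correlation of each candidate gene against the seed across
#' samples; edges where `|r| >= r_min` are returned with their sign and a
#' BH-adjusted correlation-test p-value. Zero-variance genes are excluded.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param seed_gene Row name of the seed gene.
#' @param candidates Candidate gene row names (default: all other genes).
#' @param r_min Absolute correlation threshold (default 0.5).
#' @return data.frame `gene`, `r`, `sign` (`"positive"`/`"negative"`), `p`,
#'   `q`, filtered to `|r| >= r_min`.
#' @export
coexpression_edges <- function(expr, seed_gene, candidates = NULL,
                               r_min = 0.5) {
  if (ncol(expr) < 5) stop("at least 5 samples required")
  if (is.null(candidates)) candidates <- setdiff(rownames(expr), seed_gene)
  sv <- expr[seed_gene, ]
  keep <- vapply(candidates, function(g) stats::sd(expr[g, ]) > 0,
                 logical(1))
  if (any(!keep))
    message(sum(!keep), " zero-variance gene(s) excluded")
  candidates <- candidates[keep]
  res <- do.call(rbind, lapply(candidates, function(g) {
    ct <- stats::cor.test(sv, expr[g, ])
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  res$q <- bh_fdr(res$p)
  res$sign <- ifelse(res$r >= 0, "positive", "negative")
  res[abs(res$r) >= r_min, c("gene", "r", "sign", "p", "q")]
}
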