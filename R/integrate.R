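#' Configuration for the random-forest meta-classifier
#'
#' Defaults mirror the published analysis scale: 1000 independent runs of
#' 1000 trees each, with per-run balanced downsampling of the majority
#' class. Scaled-down configurations (e.g. 50 runs x 100 trees) preserve
#' the profile shapes and are used throughout the test suite.
#'
#' @param n_runs Number of independent balanced runs (default 1000).
#' @param n_trees Trees per random forest (default 1000).
#' @param features_per_split `mtry`; default `floor(sqrt(p))` chosen at fit
#'   time when `NULL`.
#' @param seed Integer seed; per-run RNG streams are derived from it so
#'   results are independent of execution order.
#' @return list of class `rf_config`.
#' @export
rf_config <- function(n_runs = 1000, n_trees = 1000,
                      features_per_split = NULL, seed = 1) {
  stopifnot(n_runs >= 1, n_trees >= 1)
  structure(list(n_runs = n_runs, n_trees = n_trees,
                 features_per_split = features_per_split, seed = seed),
            class = "rf_config")
}

#' Train the diff-vs-nondiff random-forest meta-classifier
#'
#' Handles the extreme class imbalance between differential and
#' non-differential junctions by repeated balanced runs: each run keeps all
#' minority-class examples plus an equal-size random sample of the majority
#' class, fits a probability forest, and evaluates on the untouched majority
#' remainder together with out-of-bag minority predictions. The reported
#' AUROC is the mean over runs. Fully deterministic given the seed.
#'
#' @param X data.frame of numeric predictors plus a `label` column with two
#'   levels (`"diff"` / `"nondiff"`); a `junction_id` column is carried
#'   along but not used as a predictor.
#' @param cfg An [rf_config].
#' @return An `rf_ensemble`: list with `models`, per-run `auroc`, mean
#'   `auroc_mean`, per-run importances, the training frame and config.
#' @export
train_meta_classifier <- function(X, cfg = rf_config()) {
  lab <- as.character(X$label)
  if (length(unique(lab)) < 2) stop("single-class input")
  feat_cols <- setdiff(names(X), c("label", "junction_id"))
  Xf <- X[, feat_cols, drop = FALSE]
  if (any(!vapply(Xf, is.numeric, logical(1))))
    stop("all predictors must be numeric")
  if (any(is.na(Xf))) stop("missing predictor values (use sentinels)")
  tab <- table(lab)
  minority <- names(tab)[which.min(tab)]
  majority <- setdiff(names(tab), minority)
  if (min(tab) < 20) stop("need at least 20 minority-class examples")
  min_idx <- which(lab == minority)
  maj_idx <- which(lab == majority)
  mtry <- if (is.null(cfg$features_per_split))
    max(1L, floor(sqrt(length(feat_cols)))) else cfg$features_per_split
  set.seed(cfg$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_runs)
  models <- vector("list", cfg$n_runs)
  auroc <- numeric(cfg$n_runs)
  imps <- matrix(NA_real_, cfg$n_runs, length(feat_cols),
                 dimnames = list(NULL, feat_cols))
  for (r in seq_len(cfg$n_runs)) {
    set.seed(run_seeds[r])
    samp_maj <- sample(maj_idx, length(min_idx))
    train_idx <- c(min_idx, samp_maj)
    hold_idx <- setdiff(maj_idx, samp_maj)
    dtr <- cbind(Xf[train_idx, , drop = FALSE],
                 .cls = factor(lab[train_idx],
                               levels = c(majority, minority)))
    fit <- ranger::ranger(
      dependent.variable.name = ".cls", data = dtr,
      num.trees = cfg$n_trees, mtry = mtry, probability = TRUE,
      importance = "permutation", seed = run_seeds[r],
      num.threads = 1)
    ## held-out majority + OOB minority probabilities of the minority class
    oob <- fit$predictions[match(min_idx, train_idx), minority]
    hold_p <- if (length(hold_idx) > 0)
      stats::predict(fit, data = Xf[hold_idx, , drop = FALSE],
                     num.threads = 1)$predictions[, minority]
    else numeric(0)
    probs <- c(oob, hold_p)
    truth <- c(rep(1L, length(oob)), rep(0L, length(hold_p)))
    auroc[r] <- .auc(probs, truth)
    imps[r, ] <- fit$variable.importance[feat_cols]
    models[[r]] <- fit
  }
  structure(list(models = models, auroc = auroc,
                 auroc_mean = mean(auroc, na.rm = TRUE),
                 importances = imps, X = Xf, label = lab,
                 minority = minority, cfg = cfg),
            class = "rf_ensemble")
}

## rank-based (Mann-Whitney) AUROC
.auc <- function(score, truth) {
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.rf_ensemble <- function(x, ...) {
  cat("rf_ensemble:", length(x$models), "runs x", x$cfg$n_trees,
      "trees; mean AUROC", round(x$auroc_mean, 4), "\n")
  invisible(x)
}

#' Partial dependence of the diff-class probability on one feature
#'
#' Standard partial dependence: the feature is set to each grid value for
#' every sample, the predicted minority ("diff") class probability is
#' averaged over samples and trees within a run, and then across runs. The
#' grid is the deduplicated deciles of the observed feature, avoiding
#' extrapolation into unobserved ranges.
#'
#' @param ensemble An `rf_ensemble` from [train_meta_classifier].
#' @param feature Feature name.
#' @param grid_points Number of quantile grid points (default 10).
#' @return data.frame `feature`, `grid`, `prob` (mean over runs),
#'   `dispersion` (across-run SD); a single-row profile with attribute
#'   `constant = TRUE` for a constant feature.
#' @export
partial_dependence <- function(ensemble, feature, grid_points = 10) {
  x <- ensemble$X[[feature]]
  if (is.null(x)) stop("unknown feature: ", feature)
  grid <- unique(stats::quantile(x, probs = seq(0, 1,
                                                length.out = grid_points),
                                 names = FALSE, type = 7))
  constant <- length(grid) == 1
  pr <- matrix(NA_real_, length(ensemble$models), length(grid))
  Xg <- ensemble$X
  for (gi in seq_along(grid)) {
    Xg[[feature]] <- grid[gi]
    for (r in seq_along(ensemble$models)) {
      p <- stats::predict(ensemble$models[[r]], data = Xg,
                          num.threads = 1)$predictions[, ensemble$minority]
      pr[r, gi] <- mean(p)
    }
  }
  out <- data.frame(feature = feature, grid = grid,
                    prob = colMeans(pr),
                    dispersion = apply(pr, 2, stats::sd),
                    stringsAsFactors = FALSE)
  attr(out, "constant") <- constant
  out
}

#' Rank features by mean permutation importance
#'
#' Per-run permutation importances (out-of-bag accuracy decrease) are
#' averaged over the balanced runs and ranked in descending order.
#'
#' @param ensemble An `rf_ensemble`.
#' @return data.frame `feature`, `importance`, `rank` (1 = most important).
#' @export
rank_features <- function(ensemble) {
  imp <- colMeans(ensemble$importances, na.rm = TRUE)
  o <- order(-imp)
  data.frame(feature = names(imp)[o], importance = unname(imp[o]),
             rank = seq_along(imp), stringsAsFactors = FALSE)
}
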