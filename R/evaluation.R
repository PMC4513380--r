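#' Sensitivity, specificity and balanced accuracy from confusion counts
#'
#' Pathogenic is the positive class throughout. Formulas:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' balanced accuracy = (sensitivity + specificity)/2, all on a 0-100
#' percent scale.
#'
#' @param tp,fn,tn,fp Nonnegative confusion counts.
#' @return List: `sensitivity`, `specificity`, `balanced_accuracy`
#'   (percent).
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(counts < 0)) stop("confusion counts must be >= 0", call. = FALSE)
  if (tp + fn == 0) stop("no positive-class examples: sensitivity undefined",
                         call. = FALSE)
  if (tn + fp == 0) stop("no negative-class examples: specificity undefined",
                         call. = FALSE)
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  list(sensitivity = sens, specificity = spec,
       balanced_accuracy = (sens + spec) / 2)
}

#' Balanced accuracy of sensitivity/specificity percentages
#'
#' Direct arithmetic form, for combining metrics already expressed as
#' percentages.
#' @param sensitivity,specificity Percentages on the 0-100 scale.
#' @return Balanced accuracy percent.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  (sensitivity + specificity) / 2
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the unique score values (higher score
#' means more pathogenic); tied scores enter at a single threshold. AUC by
#' the trapezoid rule.
#'
#' @param scores Numeric scores.
#' @param labels Logical (TRUE = pathogenic) or the strings
#'   `"pathogenic"`/`"benign"`.
#' @return List of class `RocCurve`: `points` (data.frame `fpr`, `tpr`,
#'   ordered, starting at (0,0)), `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (is.character(labels)) labels <- labels == "pathogenic"
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  P <- sum(labels); N <- sum(!labels)
  if (P == 0L || N == 0L) {
    stop("ROC requires both classes present", call. = FALSE)
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(l)[grp_end]
  fp <- cumsum(!l)[grp_end]
  pts <- data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "RocCurve")
}

#' Predict with explicit pipeline cutpoints on a scored dataset
#'
#' Applies the ordered pipeline rules to precomputed feature columns:
#' not-in-hotspot is benign; in `wpc+psic` mode a PSIC score strictly below
#' `psic_cutoff` is benign; finally a WPC at or above `wpc_cutoff` is
#' pathogenic.
#'
#' @param dataset data.frame with columns `wpc`, optionally `psic` and
#'   `hotspot` (missing `hotspot` is treated as all TRUE).
#' @param wpc_cutoff WPC percent cutoff.
#' @param psic_cutoff PSIC cutoff (used in `wpc+psic` mode).
#' @param mode `"wpc-only"` or `"wpc+psic"`.
#' @return Logical vector, TRUE = predicted pathogenic.
#' @export
predict_with_cutpoints <- function(dataset, wpc_cutoff, psic_cutoff = NULL,
                                   mode = c("wpc-only", "wpc+psic")) {
  mode <- match.arg(mode)
  hotspot <- if ("hotspot" %in% names(dataset)) as.logical(dataset$hotspot)
             else rep(TRUE, nrow(dataset))
  pred <- hotspot & dataset$wpc >= wpc_cutoff
  if (mode == "wpc+psic") {
    if (is.null(psic_cutoff)) stop("psic_cutoff required in wpc+psic mode",
                                   call. = FALSE)
    pred <- pred & dataset$psic >= psic_cutoff
  }
  pred
}

truth_logical <- function(dataset) {
  t <- dataset$truth_label
  if (is.character(t)) t <- t == "pathogenic"
  as.logical(t)
}

ba_fraction <- function(pred, truth) {
  (mean(pred[truth]) + mean(!pred[!truth])) / 2
}

#' Grid-search cutpoint optimization by balanced accuracy
#'
#' Maximizes the balanced accuracy of the full pipeline rules on a scored,
#' truth-labeled dataset. WPC cutoffs are searched on an integer grid 0-100
#' (matching the precision of the calibrated cutpoints); PSIC cutoffs on a
#' 0.01 grid over the observed score range. Ties are broken toward the
#' smallest WPC cutoff, then the smallest PSIC cutoff.
#'
#' @param dataset data.frame with columns `truth_label`
#'   (`pathogenic`/`benign` or logical), `wpc`, and in `wpc+psic` mode
#'   `psic`; optional `hotspot`.
#' @param mode `"wpc-only"` or `"wpc+psic"`.
#' @return List of class `CutpointSolution`: `wpc_cutoff`, `psic_cutoff`
#'   (NA in wpc-only mode), `balanced_accuracy_at_optimum` (percent),
#'   `mode`.
#' @export
optimize_cutpoints <- function(dataset, mode = c("wpc-only", "wpc+psic")) {
  mode <- match.arg(mode)
  truth <- truth_logical(dataset)
  if (all(truth) || !any(truth)) {
    stop("cutpoint optimization requires both classes present",
         call. = FALSE)
  }
  hotspot <- if ("hotspot" %in% names(dataset)) as.logical(dataset$hotspot)
             else rep(TRUE, nrow(dataset))
  wpc_grid <- 0:100
  n_pos <- sum(truth); n_neg <- sum(!truth)

  eval_wpc_grid <- function(base_mask) {
    # balanced accuracy for every WPC cutoff given a fixed upstream mask
    vapply(wpc_grid, function(wc) {
      pred <- base_mask & dataset$wpc >= wc
      (sum(pred & truth) / n_pos + sum(!pred & !truth) / n_neg) / 2
    }, numeric(1))
  }

  if (mode == "wpc-only") {
    ba <- eval_wpc_grid(hotspot)
    best <- which.max(ba)  # first maximum = smallest cutoff
    return(structure(list(wpc_cutoff = wpc_grid[best],
                          psic_cutoff = NA_real_,
                          balanced_accuracy_at_optimum = 100 * ba[best],
                          mode = mode),
                     class = "CutpointSolution"))
  }
  if (!"psic" %in% names(dataset)) {
    stop("wpc+psic mode requires a psic column", call. = FALSE)
  }
  psic_grid <- seq(floor(min(dataset$psic) * 100) / 100,
                   ceiling(max(dataset$psic) * 100) / 100, by = 0.01)
  best <- list(ba = -Inf, wc = NA_real_, pc = NA_real_)
  for (pc in psic_grid) {
    ba <- eval_wpc_grid(hotspot & dataset$psic >= pc)
    i <- which.max(ba)
    # tie-break: smallest WPC cutoff first, then smallest PSIC cutoff
    if (ba[i] > best$ba + 1e-12 ||
        (abs(ba[i] - best$ba) <= 1e-12 && wpc_grid[i] < best$wc)) {
      best <- list(ba = ba[i], wc = wpc_grid[i], pc = pc)
    }
  }
  structure(list(wpc_cutoff = best$wc, psic_cutoff = best$pc,
                 balanced_accuracy_at_optimum = 100 * best$ba,
                 mode = mode),
            class = "CutpointSolution")
}

#' Gene-grouped k-fold assignment
#'
#' Shuffles gene symbols with a seeded RNG and assigns each gene, in
#' shuffled order, to the fold currently holding the fewest variants, so
#' folds are approximately balanced by variant count and no gene ever spans
#' folds.
#'
#' @param genes Character vector, one gene symbol per variant.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold indices (1..k), parallel to `genes`.
#' @export
gene_grouped_kfold <- function(genes, k = 5L, seed = 1L) {
  ug <- unique(genes)
  if (length(ug) < k) {
    stop("need at least ", k, " genes for ", k, "-fold grouping (have ",
         length(ug), ")", call. = FALSE)
  }
  counts <- table(genes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ug <- sample(ug)
  load <- integer(k)
  fold_of <- setNames(integer(length(ug)), ug)
  for (g in ug) {
    f <- which.min(load)
    fold_of[[g]] <- f
    load[f] <- load[f] + counts[[g]]
  }
  unname(fold_of[genes])
}

#' Gene-grouped cross-validation of the cutpoint training procedure
#'
#' For each fold: optimize cutpoints on the other k-1 folds, evaluate
#' sensitivity/specificity/balanced accuracy on the held-out fold at the
#' trained cutpoints, and trace a held-out ROC curve by sweeping the WPC
#' cutoff with the upstream stages fixed at their trained values
#' (non-hotspot rows rank below PSIC-filtered rows, which rank below all
#' WPC values). Fold curves are vertically averaged on a 101-point FPR
#' grid; fold metrics and cutpoints are averaged arithmetically.
#'
#' @param dataset As for [optimize_cutpoints()], plus a `gene` column.
#' @param k Number of folds (default 5).
#' @param seed Integer seed for the gene shuffle.
#' @param mode `"wpc-only"` or `"wpc+psic"`.
#' @return List: `folds` (per-fold data.frame with cutpoints and held-out
#'   metrics), `mean_balanced_accuracy`, `mean_sensitivity`,
#'   `mean_specificity`, `mean_wpc_cutoff`, `mean_psic_cutoff`, `mean_auc`,
#'   `mean_roc` (data.frame `fpr`, `tpr`).
#' @export
cross_validate <- function(dataset, k = 5L, seed = 1L,
                           mode = c("wpc-only", "wpc+psic")) {
  mode <- match.arg(mode)
  if (!"gene" %in% names(dataset)) stop("dataset needs a gene column",
                                        call. = FALSE)
  fold <- gene_grouped_kfold(dataset$gene, k = k, seed = seed)
  truth <- truth_logical(dataset)
  grid <- seq(0, 1, by = 0.01)
  rows <- list()
  tpr_mat <- matrix(NA_real_, nrow = k, ncol = length(grid))
  aucs <- numeric(k)
  for (f in seq_len(k)) {
    train <- dataset[fold != f, , drop = FALSE]
    test <- dataset[fold == f, , drop = FALSE]
    sol <- optimize_cutpoints(train, mode = mode)
    pred <- predict_with_cutpoints(test, sol$wpc_cutoff, sol$psic_cutoff,
                                   mode = mode)
    tt <- truth[fold == f]
    if (all(tt) || !any(tt)) {
      stop("fold ", f, " is single-class; cannot evaluate", call. = FALSE)
    }
    m <- confusion_metrics(tp = sum(pred & tt), fn = sum(!pred & tt),
                           tn = sum(!pred & !tt), fp = sum(pred & !tt))
    hotspot <- if ("hotspot" %in% names(test)) as.logical(test$hotspot)
               else rep(TRUE, nrow(test))
    score <- test$wpc
    if (mode == "wpc+psic") score[test$psic < sol$psic_cutoff] <- -1
    score[!hotspot] <- -2
    roc <- roc_curve(score, tt)
    aucs[f] <- roc$auc
    tpr_mat[f, ] <- approx(roc$points$fpr, roc$points$tpr, xout = grid,
                           method = "constant", ties = max, rule = 2)$y
    rows[[f]] <- data.frame(fold = f, wpc_cutoff = sol$wpc_cutoff,
                            psic_cutoff = sol$psic_cutoff,
                            sensitivity = m$sensitivity,
                            specificity = m$specificity,
                            balanced_accuracy = m$balanced_accuracy,
                            auc = roc$auc)
  }
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_balanced_accuracy = mean(folds$balanced_accuracy),
       mean_sensitivity = mean(folds$sensitivity),
       mean_specificity = mean(folds$specificity),
       mean_wpc_cutoff = mean(folds$wpc_cutoff),
       mean_psic_cutoff = if (mode == "wpc+psic") mean(folds$psic_cutoff)
                          else NA_real_,
       mean_auc = mean(aucs),
       mean_roc = data.frame(fpr = grid, tpr = colMeans(tpr_mat)))
}
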