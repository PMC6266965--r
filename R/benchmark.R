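#' Per-frequency feature table for the SVM benchmark
#'
#' One row per (spectrum, frequency) pair, carrying the predictors used by the
#' machine-learning benchmark — log10 frequency, log10 magnitude, phase,
#' channel and session ordinal — plus the category label and the spectrum key
#' (used for grouped cross-validation folds).
#'
#' @param cohort An [eis_cohort()].
#' @param labels Label data frame covering every spectrum in the cohort
#'   (defaults to the cohort's ground truth).
#' @return Data frame with columns `log10_freq`, `log10_zmag`, `phase_deg`,
#'   `channel`, `session_ord`, `label` (factor), `key`.
#' @export
build_feature_table <- function(cohort, labels = cohort$truth) {
  stopifnot(inherits(cohort, "eis_cohort"))
  if (!length(cohort$spectra))
    return(data.frame(log10_freq = numeric(), log10_zmag = numeric(),
                      phase_deg = numeric(), channel = integer(),
                      session_ord = numeric(),
                      label = factor(character(), levels = CATEGORIES),
                      key = character(), stringsAsFactors = FALSE))
  if (is.null(labels))
    stop("no labels supplied and the cohort carries no ground truth",
         call. = FALSE)
  lk <- label_keys(labels)
  blocks <- lapply(cohort$spectra, function(s) {
    key <- spectrum_key(s$meta)
    i <- match(key, lk)
    if (is.na(i))
      stop("missing label for spectrum ", key, call. = FALSE)
    k <- length(s$freq_hz)
    data.frame(log10_freq = log10(s$freq_hz), log10_zmag = log10(s$zmag_ohm),
               phase_deg = s$zphz_deg, channel = rep(s$meta$channel, k),
               session_ord = rep(session_rank(s$meta$session), k),
               label = rep(labels$category[i], k), key = rep(key, k),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  out$label <- factor(out$label, levels = CATEGORIES)
  out$label <- droplevels(out$label)
  rownames(out) <- NULL
  out
}

#' Cross-validated Gaussian-kernel SVM benchmark
#'
#' Trains a radial-basis support vector machine (one-vs-one multiclass) on the
#' per-frequency feature rows and evaluates it by stratified k-fold
#' cross-validation.  The "fine Gaussian" preset convention is a kernel scale
#' of `sqrt(P)/4` with `P` predictors; the RBF `gamma` is `1/scale^2`.
#' Features are standardized to zero mean and unit variance using the training
#' fold's statistics.
#'
#' @param rows Feature table from [build_feature_table()].
#' @param folds Number of cross-validation folds.
#' @param kernel_scale Gaussian kernel scale; default `sqrt(P)/4`.
#' @param seed Integer seed for fold assignment.
#' @param cost SVM box constraint.
#' @param grouped If `TRUE`, folds are assigned per spectrum (all rows of one
#'   spectrum land in the same fold), a leakage-controlled alternative to the
#'   default row-level stratification.
#' @param tolerance SMO termination tolerance.  The default (0.01) is looser
#'   than the solver's generic default: the predicted class is the sign of the
#'   decision function and is insensitive to the final duality gap, while
#'   training time on tens of thousands of near-duplicate rows is not.
#' @param cachesize Kernel cache in MB passed to the solver.
#' @return List of class `"cv_report"`: `fold_accuracies`, `overall_accuracy`
#'   (trace/total of the pooled confusion matrix), `confusion` (true x
#'   predicted counts), `n_rows`, `kernel_scale`, `folds`, `seed`.
#' @export
crossval_gaussian_svm <- function(rows, folds = 5, kernel_scale = NULL,
                                  seed = 1, cost = 1, grouped = FALSE,
                                  tolerance = 0.01, cachesize = 512) {
  predictors <- c("log10_freq", "log10_zmag", "phase_deg", "channel",
                  "session_ord")
  if (!all(predictors %in% names(rows)) || !"label" %in% names(rows))
    stop("`rows` must be a feature table from build_feature_table()",
         call. = FALSE)
  if (!nrow(rows)) stop("empty feature table", call. = FALSE)
  y <- droplevels(factor(rows$label))
  if (is.null(kernel_scale)) kernel_scale <- sqrt(length(predictors)) / 4
  gamma <- 1 / kernel_scale^2
  if (nlevels(y) < 2L) {
    warning("single-class input: degenerate benchmark with accuracy 1",
            call. = FALSE)
    conf <- matrix(length(y), 1, 1, dimnames = list(levels(y), levels(y)))
    return(structure(list(fold_accuracies = rep(1, folds),
                          overall_accuracy = 1, confusion = conf,
                          n_rows = nrow(rows), kernel_scale = kernel_scale,
                          folds = folds, seed = seed), class = "cv_report"))
  }
  X <- as.matrix(rows[predictors])
  set.seed(seed)
  fold_of <- integer(nrow(rows))
  if (grouped) {
    keys <- unique(rows$key)
    kf <- sample(rep_len(seq_len(folds), length(keys)))
    fold_of <- kf[match(rows$key, keys)]
  } else {
    for (lv in levels(y)) {   # stratified: balanced folds within each class
      idx <- which(y == lv)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  }
  lev <- levels(y)
  conf <- matrix(0L, nlevels(y), nlevels(y), dimnames = list(true = lev,
                                                             predicted = lev))
  fold_acc <- numeric(folds)
  for (kfold in seq_len(folds)) {
    tr <- fold_of != kfold; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- e1071::svm(Xtr, y[tr], kernel = "radial", gamma = gamma,
                      cost = cost, scale = FALSE, tolerance = tolerance,
                      cachesize = cachesize)
    pred <- predict(fit, Xte)
    fold_acc[kfold] <- mean(pred == y[te])
    conf <- conf + as.matrix(table(factor(y[te], levels = lev),
                                   factor(pred, levels = lev)))
  }
  structure(list(fold_accuracies = fold_acc,
                 overall_accuracy = sum(diag(conf)) / sum(conf),
                 confusion = conf, n_rows = nrow(rows),
                 kernel_scale = kernel_scale, folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d rows, %d-fold CV, kernel scale %.3g\n",
              x$n_rows, x$folds, x$kernel_scale))
  cat(sprintf("  overall accuracy: %.4f (folds: %s)\n", x$overall_accuracy,
              paste(sprintf("%.3f", x$fold_accuracies), collapse = ", ")))
  print(x$confusion)
  invisible(x)
}
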