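#' Threshold-dependent performance measures from confusion counts
#'
#' Sensitivity is the percentage of correctly predicted interacting residues,
#' specificity the percentage of correctly predicted non-interacting ones,
#' accuracy the percentage of all correct calls, and MCC the Matthews
#' correlation coefficient. Counts may be fractional (see
#' [metrics_from_rates()]). When any factor of the MCC denominator is zero
#' the MCC is defined as 0; when a class is absent the affected rates are
#' returned as `NA` rather than silently zeroed.
#'
#' @param tp,fp,tn,fn Non-negative (possibly fractional) confusion counts.
#' @return One-row tibble: `sen`, `spe`, `acc` (percentages), `mcc`.
#' @export
#' @examples
#' metrics_from_counts(tp = 50, fp = 50, tn = 50, fn = 50)  # chance: MCC 0
metrics_from_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  npos <- tp + fn
  nneg <- tn + fp
  sen <- if (npos > 0) 100 * tp / npos else NA_real_
  spe <- if (nneg > 0) 100 * tn / nneg else NA_real_
  acc <- 100 * (tp + tn) / (npos + nneg)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  tibble::tibble(sen = sen, spe = spe, acc = acc, mcc = mcc)
}

#' Reconstruct accuracy and MCC from printed sensitivity/specificity
#'
#' Published per-threshold tables report Sen and Spe as rounded percentages
#' together with the class sizes; this utility rebuilds the (fractional)
#' confusion counts `tp = sen * n_pos / 100`, `tn = spe * n_neg / 100` and
#' recomputes accuracy and MCC, so printed values can be checked without
#' integer-rounding artifacts. Rounding to 2 decimals is applied only at
#' display.
#'
#' @param sen_pct,spe_pct Percentages in `[0, 100]`.
#' @param n_pos,n_neg Positive / negative class sizes (> 0).
#' @return One-row tibble `sen`, `spe`, `acc`, `mcc`.
#' @export
#' @examples
#' metrics_from_rates(77.03, 82.89, 1029, 1029)  # Acc 79.96, MCC 0.60
metrics_from_rates <- function(sen_pct, spe_pct, n_pos, n_neg) {
  if (sen_pct < 0 || sen_pct > 100 || spe_pct < 0 || spe_pct > 100) {
    stop("rates must be percentages in [0, 100]", call. = FALSE)
  }
  if (n_pos <= 0 || n_neg <= 0) stop("class sizes must be > 0", call. = FALSE)
  tp <- sen_pct * n_pos / 100
  tn <- spe_pct * n_neg / 100
  metrics_from_counts(tp = tp, fp = n_neg - tn, tn = tn, fn = n_pos - tp)
}

#' Threshold sweep of metrics for scored items
#'
#' Applies `score >= threshold -> positive` at each threshold and computes
#' the confusion metrics.
#'
#' @param labels Logical (TRUE = interacting) or 0/1 vector.
#' @param scores Numeric decision scores.
#' @param thresholds Numeric vector of thresholds.
#' @return Tibble with one row per threshold.
#' @export
threshold_sweep <- function(labels, scores, thresholds = seq(-1, 1, by = 0.1)) {
  labels <- as.logical(labels)
  purrr::map_dfr(thresholds, function(t) {
    call <- scores >= t
    dplyr::bind_cols(
      tibble::tibble(threshold = t),
      metrics_from_counts(tp = sum(call & labels), fp = sum(call & !labels),
                          tn = sum(!call & !labels), fn = sum(!call & labels))
    )
  })
}

#' ROC curve and AUC
#'
#' Computes the ROC over all distinct score cutoffs and the area under it by
#' the trapezoidal rule. For tied-free scores this equals the Mann-Whitney
#' U statistic divided by `n_pos * n_neg`; with ties the rank formulation
#' (ties counted 1/2) still agrees with the trapezoid.
#'
#' @inheritParams threshold_sweep
#' @return List with `roc` (tibble of `fpr`, `tpr` ordered from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("ROC requires both classes", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # step only after the last of a run of tied scores
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  tpr <- cumsum(lab)[last_of_tie] / n_pos
  fpr <- cumsum(!lab)[last_of_tie] / n_neg
  roc <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Stratified five-fold cross-validation
#'
#' Splits the dataset into five folds preserving the class proportions
#' (per-class fold sizes differ by at most one), trains on four folds and
#' tests on the held-out fold, repeating so every fold is tested once.
#' Per-threshold metrics are averaged over the five test folds (the headline
#' protocol); pooled metrics over the concatenated test scores, plus the
#' pooled ROC/AUC, are also reported.
#'
#' @inheritParams mir_svm
#' @param thresholds Threshold sweep (default -1..+1 by 0.1).
#' @param k Number of folds (default 5).
#' @return An object of class `mir_eval`: list with `by_threshold` (fold-
#'   averaged metrics), `pooled` (same sweep on pooled scores), `folds`
#'   (per-fold metric tables), `roc`, `auc`, `scores` (tibble of pooled
#'   label/score/fold) and the run configuration.
#' @export
five_fold_cv <- function(dataset, encoding = c("cpp", "bpp", "ppp"),
                         g = 0.01, c = 2, j = 2, pssms = NULL, seed = 1,
                         thresholds = seq(-1, 1, by = 0.1), k = 5) {
  encoding <- match.arg(encoding)
  y <- dataset$interacting
  if (sum(y) < k || sum(!y) < k) {
    stop(sprintf("need at least %d patterns per class for %d-fold CV", k, k),
         call. = FALSE)
  }
  x <- encode_patterns(dataset, encoding, pssms = pssms)
  set.seed(seed)
  fold <- integer(length(y))
  fold[y] <- sample(rep_len(seq_len(k), sum(y)))
  fold[!y] <- sample(rep_len(seq_len(k), sum(!y)))

  fold_results <- purrr::map(seq_len(k), function(f) {
    tr <- fold != f
    fit <- e1071::svm(x[tr, , drop = FALSE],
                      factor(ifelse(y[tr], "interacting", "non_interacting"),
                             levels = c("interacting", "non_interacting")),
                      type = "C-classification", kernel = "radial",
                      gamma = g, cost = c, scale = FALSE,
                      class.weights = c(interacting = j, non_interacting = 1))
    dv <- attr(stats::predict(fit, x[!tr, , drop = FALSE],
                              decision.values = TRUE), "decision.values")
    sgn <- if (startsWith(colnames(dv)[1], "interacting/")) 1 else -1
    tibble::tibble(fold = f, label = y[!tr], score = as.numeric(dv[, 1]) * sgn)
  })
  scores <- dplyr::bind_rows(fold_results)

  folds <- purrr::map_dfr(fold_results, function(fr) {
    dplyr::mutate(threshold_sweep(fr$label, fr$score, thresholds),
                  fold = fr$fold[1], .before = 1)
  })
  by_threshold <- folds |>
    dplyr::group_by(.data$threshold) |>
    dplyr::summarise(dplyr::across(c("sen", "spe", "acc", "mcc"),
                                   ~ mean(.x, na.rm = TRUE)),
                     .groups = "drop")
  pooled <- threshold_sweep(scores$label, scores$score, thresholds)
  ra <- roc_auc(scores$label, scores$score)
  structure(list(by_threshold = by_threshold, pooled = pooled, folds = folds,
                 roc = ra$roc, auc = ra$auc, scores = scores,
                 config = list(encoding = encoding, g = g, c = c, j = j,
                               seed = seed, k = k,
                               window = unique(nchar(dataset$pattern))[1])),
            class = "mir_eval")
}

#' @export
print.mir_eval <- function(x, ...) {
  best <- x$by_threshold[which.max(x$by_threshold$mcc), ]
  cat(sprintf(
    "<mir_eval> %s, window %d, %d-fold CV | AUC %.3f | max MCC %.2f at threshold %.1f\n",
    toupper(x$config$encoding), x$config$window, x$config$k, x$auc,
    best$mcc, best$threshold))
  invisible(x)
}

#' @method tidy mir_eval
#' @export
tidy.mir_eval <- function(x, ...) x$by_threshold

#' @method glance mir_eval
#' @export
glance.mir_eval <- function(x, ...) {
  best <- x$by_threshold[which.max(x$by_threshold$mcc), ]
  tibble::tibble(auc = x$auc, max_mcc = best$mcc,
                 threshold_at_max = best$threshold,
                 acc_at_max = best$acc, encoding = x$config$encoding,
                 window = x$config$window)
}

#' Export an evaluation report
#'
#' Writes the fold-averaged threshold table as TSV (columns mirroring the
#' published layout: threshold, Sen, Spe, Acc, MCC), the ROC points as CSV,
#' and the full report as JSON.
#'
#' @param report A `mir_eval`.
#' @param prefix Output path prefix; writes `<prefix>_metrics.tsv`,
#'   `<prefix>_roc.csv` and `<prefix>.json`.
#' @param digits Display rounding (half-up, default 2) for the TSV.
#' @return Paths of written files, invisibly.
#' @export
write_eval_report <- function(report, prefix, digits = 2) {
  tsv <- paste0(prefix, "_metrics.tsv")
  csvf <- paste0(prefix, "_roc.csv")
  js <- paste0(prefix, ".json")
  tab <- report$by_threshold
  tab <- dplyr::mutate(tab, dplyr::across(c("sen", "spe", "acc"),
                                          ~ round_half_up(.x, digits)),
                       mcc = round_half_up(.data$mcc, digits))
  readr::write_tsv(tab, tsv)
  readr::write_csv(report$roc, csvf)
  jsonlite::write_json(
    list(config = report$config, auc = report$auc,
         by_threshold = report$by_threshold, pooled = report$pooled),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, csvf, js))
}

# round-half-up, matching how published tables round .005 upward
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}
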