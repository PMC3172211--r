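#' Train an RBF-kernel SVM on a pattern dataset
#'
#' Fits a C-SVC with a radial basis kernel on encoded patterns. The three
#' hyperparameters follow the classic SVM_light parameterization: `g` is the
#' RBF gamma, `c` the trade-off between training error and margin, and `j`
#' the cost factor by which misclassifying a positive (interacting) training
#' example is penalized relative to a negative one — the standard lever for
#' class imbalance in the realistic dataset. Defaults (g 0.01, c 2, j 2) are
#' the tuned values for the 17-residue composition model.
#'
#' @param dataset Pattern dataset tibble from [build_main_dataset()] /
#'   [build_realistic_dataset()], or any pattern tibble with an
#'   `interacting` column.
#' @param encoding Feature encoding: `"cpp"`, `"bpp"` or `"ppp"`.
#' @param g,c,j Positive SVM hyperparameters (see above).
#' @param pssms PSSM list, required for `encoding = "ppp"`.
#' @param seed Integer seed (training itself is deterministic; the seed is
#'   recorded for provenance and used by downstream drivers).
#' @return An object of class `mir_model` wrapping the fitted SVM with its
#'   configuration, encoding, window length and feature dimension.
#' @export
mir_svm <- function(dataset, encoding = c("cpp", "bpp", "ppp"),
                    g = 0.01, c = 2, j = 2, pssms = NULL, seed = 1) {
  encoding <- match.arg(encoding)
  if (g <= 0 || c <= 0 || j <= 0) {
    stop("SVM parameters g, c, j must all be > 0", call. = FALSE)
  }
  y <- factor(ifelse(dataset$interacting, "interacting", "non_interacting"),
              levels = c("interacting", "non_interacting"))
  if (length(unique(y)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  x <- encode_patterns(dataset, encoding, pssms = pssms)
  set.seed(seed)
  fit <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                    gamma = g, cost = c, scale = FALSE,
                    class.weights = c(interacting = j, non_interacting = 1))
  # orient decision values so that interacting scores positive
  lev1 <- colnames(attr(
    stats::predict(fit, x[1, , drop = FALSE], decision.values = TRUE),
    "decision.values"))
  sign <- if (startsWith(lev1, "interacting/")) 1 else -1
  structure(list(fit = fit, encoding = encoding,
                 window = unique(nchar(dataset$pattern))[1],
                 dim = ncol(x),
                 config = list(g = g, c = c, j = j, seed = seed),
                 sign = sign, version = "1"),
            class = "mir_model")
}

#' Continuous decision scores of a trained model
#'
#' Returns the signed margin of each feature vector; positive scores favor
#' the interacting class, and classification at threshold `t` is
#' `score >= t`. Thresholds swept in evaluation default to -1..+1.
#'
#' @param model A `mir_model`.
#' @param x Feature matrix with `model$dim` columns (or a pattern tibble,
#'   which is encoded with the model's own encoding).
#' @param pssms PSSM list if the model uses the PSSM encoding.
#' @return Numeric vector of finite scores, one per row.
#' @export
decision_scores <- function(model, x, pssms = NULL) {
  if (is.data.frame(x)) x <- encode_patterns(x, model$encoding, pssms = pssms)
  if (ncol(x) != model$dim) {
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(x), model$dim), call. = FALSE)
  }
  dv <- attr(stats::predict(model$fit, x, decision.values = TRUE),
             "decision.values")
  as.numeric(dv[, 1]) * model$sign
}

#' Save / load a trained model
#'
#' The on-disk container carries a format version together with the fitted
#' SVM, encoding, window length and configuration, so a reloaded model
#' reproduces scores exactly.
#'
#' @param model A `mir_model`.
#' @param path File path.
#' @return `path` invisibly (save); a `mir_model` (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mir_model")) {
    stop("not a mirsvm model file: ", path, call. = FALSE)
  }
  model
}

#' @export
print.mir_model <- function(x, ...) {
  cat(sprintf(
    "<mir_model> %s encoding, window %d, dim %d (g=%g, c=%g, j=%g)\n",
    toupper(x$encoding), x$window, x$dim,
    x$config$g, x$config$c, x$config$j))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy mir_model
#' @export
tidy.mir_model <- function(x, ...) {
  tibble::tibble(term = c("gamma", "cost", "cost_factor"),
                 estimate = c(x$config$g, x$config$c, x$config$j))
}

#' @method glance mir_model
#' @export
glance.mir_model <- function(x, ...) {
  tibble::tibble(encoding = x$encoding, window = x$window, dim = x$dim,
                 n_support = x$fit$tot.nSV, seed = x$config$seed)
}

#' Grid search over SVM hyperparameters
#'
#' Convenience utility: evaluates each (g, c, j) combination by stratified
#' five-fold cross-validation and reports the maximum MCC over the threshold
#' sweep. Not required for the default models.
#'
#' @inheritParams mir_svm
#' @param g,c,j Numeric vectors of candidate values.
#' @param thresholds Threshold sweep passed to [five_fold_cv()].
#' @return Tibble of combinations with `max_mcc` and `auc`, sorted by MCC.
#' @export
grid_search <- function(dataset, encoding = "cpp", g = c(0.01, 0.1),
                        c = c(1, 2), j = c(1, 2), pssms = NULL, seed = 1,
                        thresholds = seq(-1, 1, by = 0.1)) {
  grid <- expand.grid(g = g, c = c, j = j)
  purrr::pmap_dfr(grid, function(g, c, j) {
    rep <- five_fold_cv(dataset, encoding, g = g, c = c, j = j,
                        pssms = pssms, seed = seed, thresholds = thresholds)
    tibble::tibble(g = g, c = c, j = j,
                   max_mcc = max(rep$by_threshold$mcc), auc = rep$auc)
  }) |>
    dplyr::arrange(dplyr::desc(.data$max_mcc))
}
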