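test_that("confusion-count metrics behave at the anchor points", {
  # chance level: Sen 50 / Spe 50 balanced
  m <- metrics_from_counts(tp = 25, fn = 25, tn = 25, fp = 25)
  expect_equal(m$mcc, 0)
  expect_equal(m$acc, 50)
  # perfect separation
  p <- metrics_from_counts(tp = 40, fn = 0, tn = 60, fp = 0)
  expect_equal(c(p$sen, p$spe, p$acc, p$mcc), c(100, 100, 100, 1))
  # absent class flags rates as NA rather than zeroing them
  z <- metrics_from_counts(tp = 0, fn = 0, tn = 5, fp = 5)
  expect_true(is.na(z$sen))
  expect_equal(z$mcc, 0)
})

test_that("rate reconstruction matches a direct-count oracle", {
  set.seed(31)
  for (i in 1:20) {
    n_pos <- sample(50:2000, 1)
    n_neg <- sample(50:20000, 1)
    tp <- sample(0:n_pos, 1)
    tn <- sample(0:n_neg, 1)
    direct <- metrics_from_counts(tp, n_neg - tn, tn, n_pos - tp)
    recon <- metrics_from_rates(100 * tp / n_pos, 100 * tn / n_neg,
                                n_pos, n_neg)
    expect_equal(recon, direct, tolerance = 1e-12)
  }
  expect_error(metrics_from_rates(110, 50, 10, 10), "0, 100")
  expect_error(metrics_from_rates(50, 50, 0, 10), "> 0")
})

test_that("swapping class labels negates the MCC", {
  m <- metrics_from_counts(tp = 70, fn = 30, tn = 80, fp = 20)
  s <- metrics_from_counts(tp = 20, fn = 80, tn = 30, fp = 70)
  expect_equal(s$mcc, -m$mcc)
})

test_that("raising the threshold trades sensitivity for specificity", {
  set.seed(17)
  labels <- rep(c(TRUE, FALSE), each = 100)
  scores <- rnorm(200, mean = ifelse(labels, 0.5, -0.5))
  sweep <- threshold_sweep(labels, scores, seq(-2, 2, by = 0.1))
  expect_true(all(diff(sweep$sen) <= 0))
  expect_true(all(diff(sweep$spe) >= 0))
  # +Inf threshold: no positive calls
  inf_row <- threshold_sweep(labels, scores, Inf)
  expect_equal(inf_row$sen, 0)
  expect_equal(inf_row$spe, 100)
})

test_that("trapezoidal AUC equals the rank-statistic formulation", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- rnorm(n)
    if (i %% 3 == 0) scores <- round(scores, 1)   # force ties
    ra <- roc_auc(labels, scores)
    expect_equal(ra$auc, rank_auc(labels, scores), tolerance = 1e-9)
  }
})

test_that("AUC anchor cases and invariances hold", {
  labels <- rep(c(TRUE, FALSE), each = 15)
  expect_equal(roc_auc(labels, rep(1, 30))$auc, 0.5)
  expect_equal(roc_auc(labels, ifelse(labels, 2, 1))$auc, 1.0)
  set.seed(7)
  scores <- rnorm(30)
  base <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, exp(scores))$auc, base)       # monotone map
  expect_equal(roc_auc(labels, 3 * scores - 10)$auc, base)
  expect_error(roc_auc(rep(TRUE, 5), rnorm(5)), "both classes")
  # ROC runs from (0,0) to (1,1)
  roc <- roc_auc(labels, scores)$roc
  expect_equal(as.numeric(roc[1, ]), c(0, 0))
  expect_equal(as.numeric(roc[nrow(roc), ]), c(1, 1))
})

test_that("trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  labels <- sample(c(TRUE, FALSE), 80, replace = TRUE, prob = c(0.3, 0.7))
  scores <- rnorm(80) + labels
  expect_equal(roc_auc(labels, scores)$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE, direction = "<"))),
               tolerance = 1e-9)
})

test_that("cross-validation folds are stratified, disjoint and exhaustive", {
  chains <- generate_chains(n_chains = 20, length_range = c(50, 90),
                            mir_fraction = 0.06, seed = 19)
  for (ratio in c(1, 3)) {
    ds <- build_realistic_dataset(chains, 17, ratio = ratio, seed = 19)
    ev <- five_fold_cv(ds, "cpp", g = 50, seed = 19, thresholds = 0)
    counts <- dplyr::count(ev$scores, .data$fold, .data$label)
    per_class <- tidyr::pivot_wider(counts, names_from = "label",
                                    values_from = "n")
    # per-class fold sizes differ by at most one
    expect_lte(diff(range(per_class$`TRUE`)), 1)
    expect_lte(diff(range(per_class$`FALSE`)), 1)
    # union of test folds is the dataset, folds pairwise disjoint
    expect_equal(nrow(ev$scores), nrow(ds))
    expect_equal(sum(ev$scores$label), attr(ds, "n_pos"))
  }
})

test_that("cross-validating a separable set is near-perfect at threshold 0", {
  pats <- separable_patterns(50, seed = 29)
  ev <- five_fold_cv(pats, "cpp", g = 50, c = 2, j = 1, seed = 29)
  at0 <- ev$by_threshold[ev$by_threshold$threshold == 0, ]
  expect_gt(at0$acc, 99)
  expect_gt(ev$auc, 0.999)
  # averaged and pooled metrics agree closely on a homogeneous fixture
  pooled0 <- ev$pooled[ev$pooled$threshold == 0, ]
  expect_lt(abs(at0$acc - pooled0$acc), 1)
})

test_that("too-small classes are rejected for five folds", {
  pats <- separable_patterns(50, seed = 1)[c(1:3, 51:90), ]
  expect_error(five_fold_cv(pats, "cpp"), "per class")
})

test_that("evaluation reports export to TSV, CSV and JSON", {
  pats <- separable_patterns(20, seed = 37)
  ev <- five_fold_cv(pats, "cpp", g = 50, seed = 37,
                     thresholds = seq(-0.3, 0.3, by = 0.1))
  prefix <- file.path(withr::local_tempdir(), "run")
  write_eval_report(ev, prefix)
  tab <- readr::read_tsv(paste0(prefix, "_metrics.tsv"),
                         show_col_types = FALSE)
  expect_equal(names(tab), c("threshold", "sen", "spe", "acc", "mcc"))
  expect_equal(nrow(tab), 7)
  roc <- readr::read_csv(paste0(prefix, "_roc.csv"), show_col_types = FALSE)
  expect_equal(names(roc), c("fpr", "tpr"))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$config$encoding, "cpp")
  expect_equal(js$auc, ev$auc)
})
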