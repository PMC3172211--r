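#' Predict interacting residues in new chains
#'
#' Scores every residue of every chain with a trained model: each residue's
#' window is encoded with the model's own encoding and window length, scored
#' by the SVM, and called interacting when the score reaches the threshold.
#'
#' @param chains Per-residue tibble (an `interacting` column, if present, is
#'   ignored for scoring and kept as `observed`).
#' @param model A `mir_model`.
#' @param threshold Decision threshold (default 0, the balanced operating
#'   point); raise it for higher specificity, lower it for higher
#'   sensitivity.
#' @param pssms PSSM list for PSSM-encoded models.
#' @return Tibble with one row per residue: `chain_id`, `position`,
#'   `residue`, `score`, `interacting` (the call), and `observed` when input
#'   labels were present.
#' @export
predict_mirs <- function(chains, model, threshold = 0, pssms = NULL) {
  if (!all(c("chain_id", "position", "residue") %in% names(chains))) {
    stop("chains must have chain_id, position and residue columns",
         call. = FALSE)
  }
  chains <- chains[order(match(chains$chain_id, unique(chains$chain_id)),
                         chains$position), ]
  observed <- if ("interacting" %in% names(chains)) chains$interacting else NULL
  chains$interacting <- FALSE   # labels play no part in scoring
  patterns <- generate_patterns(chains, model$window)
  scores <- decision_scores(model, patterns, pssms = pssms)
  out <- tibble::tibble(chain_id = patterns$chain_id,
                        position = patterns$position,
                        residue = substr(patterns$pattern,
                                         (model$window + 1) / 2,
                                         (model$window + 1) / 2),
                        score = scores,
                        interacting = scores >= threshold)
  if (!is.null(observed)) out$observed <- observed
  out
}
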