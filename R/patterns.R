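#' Generate overlapping residue windows
#'
#' Each residue of each chain becomes the center of one fixed-length window.
#' Chains are padded with (L-1)/2 dummy residues `X` at both termini so that
#' terminal residues get full-length windows: a chain of length n yields
#' exactly n patterns. A pattern is positive when its center residue is
#' labelled interacting.
#'
#' @param chains Per-residue annotated tibble (see [read_annotated_fasta()]).
#' @param window_length Odd window length L >= 3 (default 17, giving 8 dummy
#'   residues per side).
#' @return A tibble with one row per pattern: `chain_id`, `position` (center,
#'   1-based), `pattern` (string of length L) and `interacting` (logical).
#' @export
#' @examples
#' chains <- tibble::tibble(chain_id = "x", position = 1:3,
#'                          residue = c("A", "C", "D"),
#'                          interacting = c(FALSE, TRUE, FALSE))
#' generate_patterns(chains, window_length = 3)
generate_patterns <- function(chains, window_length = 17) {
  assert_chains(chains)
  L <- window_length
  if (length(L) != 1 || is.na(L) || L < 3 || L %% 2 == 0) {
    stop("window_length must be an odd integer >= 3", call. = FALSE)
  }
  pad <- (L - 1) / 2
  chains$chain_id <- factor(chains$chain_id, levels = unique(chains$chain_id))
  out <- chains |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::group_modify(function(df, key) {
      df <- df[order(df$position), ]
      if (nrow(df) == 0) stop("empty chain", call. = FALSE)
      padded <- paste0(strrep("X", pad),
                       paste0(df$residue, collapse = ""),
                       strrep("X", pad))
      tibble::tibble(
        position = df$position,
        pattern = substring(padded, df$position, df$position + L - 1),
        interacting = df$interacting
      )
    }) |>
    dplyr::ungroup()
  out$chain_id <- as.character(out$chain_id)
  out
}
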