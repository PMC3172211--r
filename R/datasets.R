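#' Assemble a balanced ("main") pattern dataset
#'
#' Keeps every positive (interacting-center) pattern and draws an equal-size
#' uniform sample, without replacement, from the pool of negative patterns.
#' Balancing the classes this way is the standard construction for training
#' residue-level classifiers; the companion [build_realistic_dataset()] keeps
#' the natural imbalance instead.
#'
#' @param chains Per-residue annotated tibble.
#' @param window_length Odd window length L (default 17).
#' @param seed Integer seed controlling the negative sample.
#' @return A pattern tibble (positives first, then sampled negatives) of
#'   class `mir_dataset`, with attributes `n_pos`, `n_neg`, `ratio`, `seed`
#'   and `window`.
#' @export
build_main_dataset <- function(chains, window_length = 17, seed = 1) {
  build_pattern_dataset(chains, window_length, ratio = 1, seed = seed)
}

#' Assemble an imbalanced ("realistic") pattern dataset
#'
#' Keeps every positive pattern and samples `ratio` times as many negatives
#' (default 10), approximating the natural scarcity of interacting residues
#' while keeping training tractable.
#'
#' @inheritParams build_main_dataset
#' @param ratio Target negatives per positive (default 10).
#' @return A pattern tibble of class `mir_dataset`; see
#'   [build_main_dataset()].
#' @export
build_realistic_dataset <- function(chains, window_length = 17, ratio = 10,
                                    seed = 1) {
  build_pattern_dataset(chains, window_length, ratio = ratio, seed = seed)
}

build_pattern_dataset <- function(chains, window_length, ratio, seed) {
  if (ratio <= 0) stop("ratio must be > 0", call. = FALSE)
  patterns <- generate_patterns(chains, window_length)
  pos <- patterns[patterns$interacting, ]
  neg <- patterns[!patterns$interacting, ]
  if (nrow(pos) == 0) stop("no positive patterns in input", call. = FALSE)
  want <- round(ratio * nrow(pos))
  if (nrow(neg) < want) {
    warning(sprintf(
      "only %d negative patterns available (wanted %d); keeping all",
      nrow(neg), want), call. = FALSE)
    samp <- neg
  } else {
    set.seed(seed)
    samp <- neg[sort(sample.int(nrow(neg), want)), ]
  }
  out <- dplyr::bind_rows(pos, samp)
  structure(out, class = c("mir_dataset", class(out)),
            n_pos = nrow(pos), n_neg = nrow(samp),
            ratio = nrow(samp) / nrow(pos), seed = seed,
            window = window_length)
}

#' Write / read a pattern dataset as TSV
#'
#' Plain tab-separated export (`pattern`, `interacting`, `chain_id`,
#' `position`) for inspection and interchange; `read_pattern_dataset()`
#' restores the tibble and its class-count attributes.
#'
#' @param dataset Pattern dataset tibble.
#' @param path File path.
#' @return `path` invisibly (write); a pattern dataset tibble (read).
#' @export
write_pattern_dataset <- function(dataset, path) {
  readr::write_tsv(
    dataset[, c("pattern", "interacting", "chain_id", "position")], path)
  invisible(path)
}

#' @rdname write_pattern_dataset
#' @export
read_pattern_dataset <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           pattern = "c", interacting = "l",
                           chain_id = "c", position = "i"))
  structure(out, class = c("mir_dataset", class(out)),
            n_pos = sum(out$interacting), n_neg = sum(!out$interacting),
            ratio = sum(!out$interacting) / max(1, sum(out$interacting)),
            window = unique(nchar(out$pattern))[1])
}
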