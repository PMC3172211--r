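#' Residue composition of interacting vs non-interacting residues
#'
#' Percentage of each standard amino acid within the interacting and the
#' non-interacting residue groups, plus their difference. A positive
#' difference marks a letter enriched at binding sites (for mannose:
#' Asp/Glu/Asn/Gln/Arg/Ser/Thr/Trp/Tyr are the expected enriched set).
#'
#' @param chains Per-residue annotated tibble.
#' @return Tibble of class `mir_composition`: `residue`,
#'   `interacting_pct`, `non_interacting_pct`, `difference`. Each group's
#'   percentages sum to 100.
#' @export
residue_composition <- function(chains) {
  assert_chains(chains)
  letters_used <- union(aa20(), unique(chains$residue))
  grp <- function(flag) {
    sub <- chains$residue[chains$interacting == flag]
    if (length(sub) == 0) stop("empty residue group", call. = FALSE)
    100 * tabulate(match(sub, letters_used),
                   nbins = length(letters_used)) / length(sub)
  }
  out <- tibble::tibble(
    residue = letters_used,
    interacting_pct = grp(TRUE),
    non_interacting_pct = grp(FALSE)
  )
  out$difference <- out$interacting_pct - out$non_interacting_pct
  structure(out, class = c("mir_composition", class(out)),
            grouping = "residue")
}

#' Default physico-chemical property classes
#'
#' The class map used by [property_composition()]: charged (DEKHR),
#' polar-uncharged (STNQYC), hydrophobic (AVLIMFWP) and glycine on its own.
#' The map is an argument precisely because reasonable alternatives exist.
#'
#' @return Named character vector mapping one-letter codes to class names.
#' @export
default_property_map <- function() {
  m <- c(
    stats::setNames(rep("charged", 5), strsplit("DEKHR", "")[[1]]),
    stats::setNames(rep("polar_uncharged", 6), strsplit("STNQYC", "")[[1]]),
    stats::setNames(rep("hydrophobic", 8), strsplit("AVLIMFWP", "")[[1]]),
    G = "glycine"
  )
  m
}

#' Property-class composition of interacting vs non-interacting residues
#'
#' Aggregates [residue_composition()] into physico-chemical classes; class
#' percentages are the sums of their member letters' percentages.
#'
#' @inheritParams residue_composition
#' @param property_map Named character vector mapping letters to classes
#'   (default [default_property_map()]).
#' @return Tibble of class `mir_composition` with one row per class.
#' @export
property_composition <- function(chains, property_map = default_property_map()) {
  comp <- residue_composition(chains)
  cls <- unname(property_map[comp$residue])
  if (any(is.na(cls) & comp$residue != "X")) {
    bad <- comp$residue[is.na(cls) & comp$residue != "X"]
    stop("unmapped letter(s) in property map: ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  cls[is.na(cls)] <- "other"
  out <- tibble::tibble(class = cls,
                        interacting_pct = comp$interacting_pct,
                        non_interacting_pct = comp$non_interacting_pct) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop")
  out$difference <- out$interacting_pct - out$non_interacting_pct
  structure(out, class = c("mir_composition", class(out)),
            grouping = "property")
}

#' Pattern-level composition of positive vs negative patterns
#'
#' Mean letter composition (in percent) over whole windows, compared between
#' positive (interacting-center) and negative patterns — the window-level
#' counterpart of [residue_composition()].
#'
#' @param patterns Pattern tibble with `pattern` and `interacting` columns.
#' @return Tibble of class `mir_composition` over the 21-letter alphabet.
#' @export
pattern_composition <- function(patterns) {
  cpp <- encode_composition(patterns)
  grp <- function(flag) {
    sub <- cpp[patterns$interacting == flag, , drop = FALSE]
    if (nrow(sub) == 0) stop("empty pattern group", call. = FALSE)
    100 * colMeans(sub)
  }
  out <- tibble::tibble(residue = mir_alphabet(),
                        interacting_pct = grp(TRUE),
                        non_interacting_pct = grp(FALSE))
  out$difference <- out$interacting_pct - out$non_interacting_pct
  structure(out, class = c("mir_composition", class(out)),
            grouping = "pattern")
}

#' Per-position frequency differences between pattern groups
#'
#' For every window position, the frequency of each letter among positive
#' patterns minus its frequency among negative patterns — the numeric table
#' underlying a two-sample sequence logo. Differences at each position sum
#' to zero because both groups' frequencies sum to one.
#'
#' @param pos_patterns,neg_patterns Pattern tibbles (or character vectors of
#'   windows) of a common window length.
#' @return Tibble: `pos` (window position), `center` (logical flag for the
#'   central column), `residue`, `freq_pos`, `freq_neg`, `difference`.
#' @export
positional_frequency_difference <- function(pos_patterns, neg_patterns) {
  wp <- pattern_windows(pos_patterns)
  wn <- pattern_windows(neg_patterns)
  L <- unique(c(nchar(wp), nchar(wn)))
  if (length(L) != 1) {
    stop("patterns have mixed window lengths", call. = FALSE)
  }
  alpha <- mir_alphabet()
  freqs <- function(w) {
    chars <- matrix(unlist(strsplit(w, "")), ncol = L, byrow = TRUE)
    apply(chars, 2, function(col) {
      tabulate(match(col, alpha), nbins = 21) / length(col)
    })  # 21 x L
  }
  fp <- freqs(wp)
  fn <- freqs(wn)
  tibble::tibble(
    pos = rep(seq_len(L), each = 21),
    center = rep(seq_len(L) == (L + 1) / 2, each = 21),
    residue = rep(alpha, L),
    freq_pos = as.vector(fp),
    freq_neg = as.vector(fn),
    difference = as.vector(fp - fn)
  )
}

#' Write a composition table as TSV
#'
#' @param x A composition tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_composition <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}
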