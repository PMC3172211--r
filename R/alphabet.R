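#' Residue alphabet used throughout the package
#'
#' The fixed 21-letter alphabet: the 20 standard amino acids in alphabetical
#' one-letter order, plus the dummy residue `X` used both for terminal window
#' padding and for nonstandard residue codes. All feature encodings index
#' against this order, so vectors are bit-stable across versions.
#'
#' @return Character vector of length 21.
#' @export
#' @examples
#' mir_alphabet()
mir_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
}

# standard 20, no dummy
aa20 <- function() mir_alphabet()[1:20]

# Nonstandard one-letter codes tolerated on input; all map to X.
nonstandard_codes <- c("B", "Z", "U", "O", "J")

# Normalize a vector of single uppercase letters: standard codes pass through,
# nonstandard ones map to X (with one warning), anything else errors.
normalize_residues <- function(letters, where = "sequence") {
  bad_ns <- letters %in% nonstandard_codes
  if (any(bad_ns)) {
    warning(sprintf("%s: %d nonstandard residue code(s) (%s) mapped to X",
                    where, sum(bad_ns),
                    paste(unique(letters[bad_ns]), collapse = ",")),
            call. = FALSE)
    letters[bad_ns] <- "X"
  }
  ok <- letters %in% mir_alphabet()
  if (!all(ok)) {
    pos <- which(!ok)[1]
    stop(sprintf("%s: invalid residue character '%s' at position %d",
                 where, letters[pos], pos), call. = FALSE)
  }
  letters
}

# Three-letter -> one-letter residue names, unknowns to X with a warning.
three_to_one <- function(resid3, where = "structure") {
  one <- suppressWarnings(bio3d::aa321(resid3))
  unknown <- is.na(one) | !(one %in% mir_alphabet())
  if (any(unknown)) {
    warning(sprintf("%s: unknown residue name(s) %s mapped to X",
                    where, paste(unique(resid3[unknown]), collapse = ",")),
            call. = FALSE)
    one[unknown] <- "X"
  }
  one
}

# Validate a per-residue chains tibble (chain_id, position, residue, interacting).
assert_chains <- function(chains) {
  need <- c("chain_id", "position", "residue", "interacting")
  if (!is.data.frame(chains) || !all(need %in% names(chains))) {
    stop("expected a chains data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  invisible(chains)
}
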