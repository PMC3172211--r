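#' Binary profile of patterns (BPP)
#'
#' One-hot encodes each window position over the fixed 21-letter alphabet
#' (see [mir_alphabet()]): a length-L window becomes an L x 21 vector in
#' which each consecutive 21-block contains a single 1 at the index of that
#' position's residue.
#'
#' @param patterns Pattern tibble from [generate_patterns()], or a character
#'   vector of windows.
#' @return Numeric matrix, one row per pattern, `L * 21` columns.
#' @export
encode_binary <- function(patterns) {
  windows <- pattern_windows(patterns)
  L <- unique(nchar(windows))
  if (length(L) != 1) stop("patterns have mixed window lengths", call. = FALSE)
  alpha <- mir_alphabet()
  chars <- matrix(unlist(strsplit(windows, "")), ncol = L, byrow = TRUE)
  idx <- match(chars, alpha)
  if (anyNA(idx)) {
    stop("character outside the 21-letter alphabet in pattern", call. = FALSE)
  }
  out <- matrix(0, nrow = length(windows), ncol = L * 21)
  pos_block <- (rep(seq_len(L), each = length(windows)) - 1) * 21
  out[cbind(rep(seq_along(windows), L), pos_block + idx)] <- 1
  colnames(out) <- paste0("p", rep(seq_len(L), each = 21), "_",
                          rep(alpha, L))
  out
}

#' Composition profile of patterns (CPP)
#'
#' Encodes each window by its amino-acid composition: a 21-component vector
#' (20 standard residues plus the dummy `X`) whose i-th entry is the fraction
#' of window positions holding letter i. The denominator is the full window
#' length, so terminal padding contributes to the `X` component and the
#' components always sum to 1. The encoding is independent of residue order
#' and of window length.
#'
#' @inheritParams encode_binary
#' @return Numeric matrix, one row per pattern, 21 columns named by letter.
#' @export
encode_composition <- function(patterns) {
  windows <- pattern_windows(patterns)
  alpha <- mir_alphabet()
  L <- nchar(windows)
  chars <- strsplit(windows, "")
  out <- t(vapply(seq_along(chars), function(i) {
    idx <- match(chars[[i]], alpha)
    if (anyNA(idx)) {
      stop("character outside the 21-letter alphabet in pattern",
           call. = FALSE)
    }
    tabulate(idx, nbins = 21) / L[i]
  }, numeric(21)))
  colnames(out) <- alpha
  out
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the text PSSM written by PSI-BLAST (`-Q` / `-out_ascii_pssm`):
#' header lines, then one row per residue holding the position, the residue,
#' 20 integer log-odds scores, 20 percentages and two trailing floats. The
#' 20 score columns are reordered from PSI-BLAST's column order (read from
#' the header) to the package's fixed alphabet order; the 21st (`X`) raw
#' score is defined as 0. Normalized rows in `[0, 1]` are produced with
#' [normalize_pssm()].
#'
#' @param path Path to the ASCII PSSM file.
#' @param chain_id Chain identifier to attach (default: file name sans
#'   extension).
#' @param method Normalization method passed to [normalize_pssm()].
#' @return An object of class `mir_pssm`: list with `chain_id`, `residues`
#'   (chain sequence from the PSSM rows), `raw` (n x 21 integer matrix) and
#'   `normalized` (n x 21 matrix in `[0, 1]`).
#' @export
read_pssm <- function(path, chain_id = NULL,
                      method = c("logistic", "minmax")) {
  method <- match.arg(method)
  if (is.null(chain_id)) {
    chain_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  # header line: the one listing the 20 amino-acid column letters
  hdr_i <- which(grepl("^\\s*[A-Z](\\s+[A-Z])+\\s*$", lines))[1]
  if (is.na(hdr_i)) stop("not a PSI-BLAST ASCII PSSM: ", path, call. = FALSE)
  col_order <- strsplit(trimws(lines[hdr_i]), "\\s+")[[1]][1:20]
  rows <- lines[-seq_len(hdr_i)]
  rows <- rows[grepl("^\\s*\\d+\\s+[A-Z]", rows)]
  if (length(rows) == 0) stop("PSSM has no data rows: ", path, call. = FALSE)
  parsed <- strsplit(trimws(rows), "\\s+")
  nf <- lengths(parsed)
  # full dialect: pos + aa + 20 scores + 20 pct + 2 floats = 44 fields;
  # a scores-only variant (pos + aa + 20) is also accepted
  if (!all(nf == 44) && !all(nf == 22)) {
    stop(sprintf("malformed PSSM row (expected 20 score columns, got %d): %s",
                 min(nf) - 2, path), call. = FALSE)
  }
  residues <- vapply(parsed, `[`, character(1), 2)
  raw20 <- t(vapply(parsed, function(p) as.numeric(p[3:22]), numeric(20)))
  if (anyNA(raw20)) stop("non-numeric PSSM score in ", path, call. = FALSE)
  raw <- cbind(raw20[, match(aa20(), col_order), drop = FALSE], 0)
  colnames(raw) <- mir_alphabet()
  structure(list(chain_id = chain_id,
                 residues = normalize_residues(residues,
                                               where = "PSSM residues"),
                 raw = raw,
                 normalized = normalize_pssm(raw, method = method)),
            class = "mir_pssm")
}

#' Normalize PSSM scores to the unit interval
#'
#' PSI-BLAST log-odds scores are mapped into `[0, 1]` before being used as
#' SVM features. The default is the logistic map `1 / (1 + exp(-x))`, a
#' strictly increasing bounded transform that is robust to the very wide
#' dynamic range of raw scores; matrix-wide min-max scaling
#' `(x - min) / (max - min)` is available as an alternative.
#'
#' @param x Numeric vector or matrix of raw scores.
#' @param method `"logistic"` (default) or `"minmax"`.
#' @return Object of the same shape with values in `[0, 1]`.
#' @export
#' @examples
#' normalize_pssm(0)        # 0.5
#' normalize_pssm(c(-3, 0, 3), method = "minmax")
normalize_pssm <- function(x, method = c("logistic", "minmax")) {
  method <- match.arg(method)
  if (any(!is.finite(x))) stop("raw PSSM scores must be finite", call. = FALSE)
  if (method == "logistic") {
    out <- 1 / (1 + exp(-x))
  } else {
    rng <- range(x)
    out <- if (rng[1] == rng[2]) {
      x * 0 + 0.5
    } else {
      (x - rng[1]) / (rng[2] - rng[1])
    }
  }
  out
}

#' PSSM profile of patterns (PPP)
#'
#' Encodes each window by concatenating the normalized 21-component PSSM rows
#' of its positions. Padded positions outside the chain contribute a row that
#' is zero everywhere except for a 1 in the `X` slot, mirroring the one-hot
#' treatment of the dummy residue.
#'
#' @param patterns Pattern tibble from [generate_patterns()]; every
#'   `chain_id` must have a matching entry in `pssms`.
#' @param pssms A single `mir_pssm` or a list of them (possibly named by
#'   chain).
#' @return Numeric matrix, one row per pattern, `L * 21` columns.
#' @export
encode_pssm <- function(patterns, pssms) {
  if (inherits(pssms, "mir_pssm")) pssms <- list(pssms)
  names(pssms) <- vapply(pssms, `[[`, character(1), "chain_id")
  if (!all(c("chain_id", "position", "pattern") %in% names(patterns))) {
    stop("encode_pssm needs a pattern tibble with chain_id and position",
         call. = FALSE)
  }
  L <- unique(nchar(patterns$pattern))
  if (length(L) != 1) stop("patterns have mixed window lengths", call. = FALSE)
  pad <- (L - 1) / 2
  x_row <- c(rep(0, 20), 1)
  out <- matrix(0, nrow = nrow(patterns), ncol = L * 21)
  for (i in seq_len(nrow(patterns))) {
    m <- pssms[[patterns$chain_id[i]]]
    if (is.null(m)) {
      stop("no PSSM for chain ", patterns$chain_id[i], call. = FALSE)
    }
    n <- nrow(m$normalized)
    pos <- patterns$position[i] + (-pad:pad)
    if (patterns$position[i] < 1 || patterns$position[i] > n) {
      stop("pattern center outside chain ", m$chain_id, call. = FALSE)
    }
    rows <- t(vapply(pos, function(p) {
      if (p < 1 || p > n) x_row else m$normalized[p, ]
    }, numeric(21)))
    out[i, ] <- as.vector(t(rows))
  }
  colnames(out) <- paste0("p", rep(seq_len(L), each = 21), "_",
                          rep(mir_alphabet(), L))
  out
}

#' Encode patterns with a named encoding
#'
#' Dispatch helper used by the dataset, model and CLI layers: `"bpp"` is the
#' binary profile, `"cpp"` the composition profile and `"ppp"` the PSSM
#' profile (which requires `pssms`).
#'
#' @inheritParams encode_pssm
#' @param encoding One of `"cpp"`, `"bpp"`, `"ppp"`.
#' @return Numeric feature matrix, one row per pattern.
#' @export
encode_patterns <- function(patterns, encoding = c("cpp", "bpp", "ppp"),
                            pssms = NULL) {
  encoding <- match.arg(encoding)
  switch(encoding,
         cpp = encode_composition(patterns),
         bpp = encode_binary(patterns),
         ppp = {
           if (is.null(pssms)) stop("ppp encoding requires pssms",
                                    call. = FALSE)
           encode_pssm(patterns, pssms)
         })
}

pattern_windows <- function(patterns) {
  if (is.character(patterns)) return(patterns)
  if (is.data.frame(patterns) && "pattern" %in% names(patterns)) {
    return(patterns$pattern)
  }
  stop("expected a pattern tibble or character vector of windows",
       call. = FALSE)
}
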