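#' Read case-annotated FASTA
#'
#' Reads the exchange format for residue-labelled chains: a FASTA file in
#' which lowercase letters mark interacting residues and uppercase letters
#' mark non-interacting ones. Residues are uppercased on input and the case
#' becomes a per-residue logical label.
#'
#' Nonstandard one-letter codes (B, Z, U, O, J) are mapped to the dummy
#' residue `X` with a warning; any other non-alphabet character is an error
#' naming the record and position.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per residue: `chain_id`, `description`,
#'   `position` (1-based), `residue` (uppercase one-letter code) and
#'   `interacting` (logical).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "AsD"), f)
#' read_annotated_fasta(f)
read_annotated_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^;", lines)]
  hdr <- grepl("^>", lines)
  if (length(lines) == 0 || !hdr[1]) {
    stop("not a FASTA file (no '>' header): ", path, call. = FALSE)
  }
  rec_id <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  chain_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  seqs <- vapply(split(lines[!hdr], rec_id[!hdr]),
                 paste0, character(1), collapse = "")
  # records with no sequence lines never appear in the split; detect them
  if (length(seqs) != length(headers) || any(nchar(seqs) == 0)) {
    empty <- setdiff(seq_along(headers), as.integer(names(seqs)))
    if (length(empty) == 0) empty <- which(nchar(seqs) == 0)
    stop("empty FASTA record: ", chain_id[empty[1]], call. = FALSE)
  }
  purrr::map2_dfr(seq_along(chain_id), seqs, function(i, s) {
    chars <- strsplit(s, "")[[1]]
    interacting <- chars == tolower(chars) & chars != toupper(chars)
    res <- normalize_residues(toupper(chars),
                              where = sprintf("record '%s'", chain_id[i]))
    tibble::tibble(chain_id = chain_id[i], description = description[i],
                   position = seq_along(res), residue = res,
                   interacting = interacting)
  })
}

#' Write case-annotated FASTA
#'
#' Inverse of [read_annotated_fasta()]: interacting residues are written in
#' lowercase, others in uppercase, wrapped at 60 characters per line.
#'
#' @param chains Per-residue tibble as returned by [read_annotated_fasta()]
#'   (a `description` column is optional).
#' @param path Output file path.
#' @param header_comments Optional character vector written as `;`-prefixed
#'   comment lines before the first record (used by the CLI for provenance).
#' @return `path`, invisibly.
#' @export
write_annotated_fasta <- function(chains, path, header_comments = NULL) {
  assert_chains(chains)
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comments)) {
    writeLines(paste0("; ", header_comments), con)
  }
  if (nrow(chains) == 0) return(invisible(path))
  for (id in unique(chains$chain_id)) {
    sub <- chains[chains$chain_id == id, ]
    sub <- sub[order(sub$position), ]
    desc <- if ("description" %in% names(sub) && nzchar(sub$description[1])) {
      paste0(" ", sub$description[1])
    } else ""
    letters <- ifelse(sub$interacting, tolower(sub$residue), sub$residue)
    s <- paste0(letters, collapse = "")
    writeLines(paste0(">", id, desc), con)
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}
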