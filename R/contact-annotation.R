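#' Read a PDB structure into an atom table
#'
#' Thin wrapper around [bio3d::read.pdb()] that returns a tidy atom tibble
#' and applies the conventions used for contact annotation: model 1 only,
#' and for alternate locations the highest-occupancy conformer is kept
#' (ties broken by altloc identifier order). Waters (HOH) are dropped.
#'
#' @param path Path to a PDB file.
#' @return A tibble with columns `record` (ATOM/HETATM), `chain_id`,
#'   `resno`, `resid` (3-letter name), `atom`, `element`, `x`, `y`, `z`,
#'   `occupancy`.
#' @export
read_structure <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(at))
  miss <- is.na(elem) | elem == ""
  # fall back to the first alphabetic character of the atom name
  elem[miss] <- substr(gsub("[^A-Za-z].*$", "",
                            gsub("^[0-9]*", "", at$elety[miss])), 1, 1)
  atoms <- tibble::tibble(
    record = at$type, chain_id = at$chain, resno = at$resno,
    resid = at$resid, atom = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt)
  )
  atoms <- atoms[atoms$resid != "HOH", ]
  resolve_altloc(atoms)
}

# Keep, per (chain, residue, atom name), the conformer with highest occupancy;
# ties broken by altloc identifier order. Single-conformer atoms pass through.
resolve_altloc <- function(atoms) {
  if (all(atoms$altloc == "")) return(atoms)
  atoms |>
    dplyr::group_by(.data$chain_id, .data$resno, .data$resid, .data$atom) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$altloc,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain_id, .data$resno)
}

#' Label residues interacting with a bound ligand
#'
#' A residue is labelled interacting when any of its heavy atoms lies within
#' `cutoff` angstroms (inclusive) of any heavy atom of a ligand residue.
#' This is the structural definition of a mannose-interacting residue: the
#' default ligand selection covers alpha- and beta-D-mannose (PDB residue
#' names MAN and BMA) at a 4.0 A cutoff.
#'
#' @param atoms Atom tibble from [read_structure()] or [make_toy_complex()].
#' @param ligand_names Character vector of 3-letter ligand residue names.
#' @param cutoff Distance cutoff in angstroms (> 0); comparison is `<=`.
#' @return A per-residue annotated tibble (`chain_id`, `position`, `residue`,
#'   `interacting`), one block per protein chain in file order. `position`
#'   is the 1-based sequence index; the original PDB residue number is kept
#'   in `resno`.
#' @export
find_interacting_residues <- function(atoms, ligand_names = c("MAN", "BMA"),
                                      cutoff = 4.0) {
  if (cutoff <= 0) stop("cutoff must be > 0", call. = FALSE)
  heavy <- atoms[!(atoms$element %in% c("H", "D")), ]
  prot <- heavy[heavy$record == "ATOM" & !(heavy$resid %in% ligand_names), ]
  lig <- heavy[heavy$resid %in% ligand_names, ]
  if (nrow(prot) == 0) stop("no protein chain in structure", call. = FALSE)
  lig_xyz <- as.matrix(lig[, c("x", "y", "z")])

  chains <- unique(prot$chain_id)
  purrr::map_dfr(chains, function(ch) {
    sub <- prot[prot$chain_id == ch, ]
    resnos <- unique(sub$resno)   # strictly increasing within a chain
    resid3 <- sub$resid[match(resnos, sub$resno)]
    one <- three_to_one(resid3, where = sprintf("chain %s", ch))
    hit <- rep(FALSE, length(resnos))
    if (nrow(lig) > 0) {
      d2 <- cross_dist2(as.matrix(sub[, c("x", "y", "z")]), lig_xyz)
      atom_hit <- matrixStats_rowMin(d2) <= cutoff^2
      hit <- vapply(resnos, function(rn) any(atom_hit[sub$resno == rn]),
                    logical(1))
    }
    tibble::tibble(chain_id = ch, position = seq_along(resnos),
                   resno = resnos, residue = one, interacting = hit,
                   description = "")
  })
}

# squared Euclidean cross-distance matrix, n x m
cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

# rowwise minimum without extra deps
matrixStats_rowMin <- function(m) do.call(pmin, as.data.frame(m))

#' Build a synthetic protein-mannose complex
#'
#' Generates an extended chain (one C-alpha per residue, 3.8 A spacing) and a
#' single pseudo-mannose residue (name MAN) with one atom per requested
#' contact position, placed exactly `offset` angstroms from that residue's
#' atom and farther than `clearance` from every other residue. Used to
#' exercise the contact annotator with a known ground truth.
#'
#' @param n_residues Chain length.
#' @param contact_positions Integer positions (1-based) that must be in
#'   contact; may be empty, in which case the ligand is placed far away.
#' @param offset Exact ligand-to-contact-residue distance in angstroms.
#' @param seed Integer seed controlling the residue sequence and jitter.
#' @param clearance Minimum distance the ligand must keep from non-contact
#'   residues (defaults to the standard 4.0 A cutoff).
#' @return An atom tibble in the same shape as [read_structure()].
#' @export
make_toy_complex <- function(n_residues, contact_positions = integer(),
                             offset = 3.5, seed = 1, clearance = 4.0) {
  contact_positions <- as.integer(contact_positions)
  if (length(contact_positions) &&
      (any(contact_positions < 1) || any(contact_positions > n_residues))) {
    stop("contact_positions must lie in 1..n_residues", call. = FALSE)
  }
  if (offset <= 0) stop("offset must be > 0", call. = FALSE)
  if (length(contact_positions) && offset >= clearance) {
    stop("infeasible geometry: offset must be < clearance for a contact",
         call. = FALSE)
  }
  spacing <- 3.8
  if (length(contact_positions) &&
      sqrt(spacing^2 + offset^2) <= clearance) {
    stop("infeasible geometry: neighbours would also fall within clearance",
         call. = FALSE)
  }
  set.seed(seed)
  seq20 <- sample(aa20(), n_residues, replace = TRUE)
  res3 <- bio3d::aa123(seq20)
  prot <- tibble::tibble(
    record = "ATOM", chain_id = "A", resno = seq_len(n_residues),
    resid = res3, atom = "CA", element = "C",
    x = spacing * (seq_len(n_residues) - 1), y = 0, z = 0,
    occupancy = 1, altloc = ""
  )
  if (length(contact_positions)) {
    lig <- tibble::tibble(
      record = "HETATM", chain_id = "B", resno = 1L, resid = "MAN",
      atom = paste0("C", seq_along(contact_positions)), element = "C",
      x = spacing * (contact_positions - 1), y = offset, z = 0,
      occupancy = 1, altloc = ""
    )
  } else {
    lig <- tibble::tibble(
      record = "HETATM", chain_id = "B", resno = 1L, resid = "MAN",
      atom = "C1", element = "C",
      x = -500, y = -500, z = -500, occupancy = 1, altloc = ""
    )
  }
  dplyr::bind_rows(prot, lig)
}

#' Write an atom table as a PDB file
#'
#' Minimal fixed-width ATOM/HETATM writer, sufficient for the synthetic
#' complexes produced by [make_toy_complex()] to round-trip through
#' [read_structure()].
#'
#' @param atoms Atom tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(atoms, path) {
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$record, seq_len(nrow(atoms)),
    ifelse(nchar(atoms$atom) < 4, paste0(" ", atoms$atom), atoms$atom),
    "", atoms$resid, atoms$chain_id, atoms$resno, "",
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0, atoms$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}
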