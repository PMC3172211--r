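# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# Naive all-pairs contact scan: for every protein residue, the minimum
# distance over (protein heavy atom, ligand heavy atom) pairs via an explicit
# double loop.
brute_force_contacts <- function(atoms, ligand_names = c("MAN", "BMA"),
                                 cutoff = 4.0) {
  heavy <- atoms[!(atoms$element %in% c("H", "D")), ]
  prot <- heavy[heavy$record == "ATOM" & !(heavy$resid %in% ligand_names), ]
  lig <- heavy[heavy$resid %in% ligand_names, ]
  out <- list()
  for (ch in unique(prot$chain_id)) {
    sub <- prot[prot$chain_id == ch, ]
    for (rn in unique(sub$resno)) {
      ratoms <- sub[sub$resno == rn, ]
      hit <- FALSE
      for (i in seq_len(nrow(ratoms))) {
        for (k in seq_len(nrow(lig))) {
          d <- sqrt((ratoms$x[i] - lig$x[k])^2 +
                      (ratoms$y[i] - lig$y[k])^2 +
                      (ratoms$z[i] - lig$z[k])^2)
          if (d <= cutoff) hit <- TRUE
        }
      }
      out[[length(out) + 1]] <- data.frame(chain_id = ch, resno = rn,
                                           interacting = hit)
    }
  }
  do.call(rbind, out)
}

# AUC as the Mann-Whitney U statistic (midranks, so ties count 1/2),
# divided by n_pos * n_neg.
rank_auc <- function(labels, scores) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Minimal labelled-chain tibble from a case-annotated string.
chain_from_string <- function(s, id = "ch1") {
  chars <- strsplit(s, "")[[1]]
  tibble::tibble(chain_id = id, description = "",
                 position = seq_along(chars),
                 residue = toupper(chars),
                 interacting = chars != toupper(chars))
}

# Trivially separable pattern set: positives are serine-rich windows,
# negatives alanine-rich, with mild seeded letter noise.
separable_patterns <- function(n_per_class = 40, L = 17, seed = 1) {
  set.seed(seed)
  mk <- function(base, alt, n) {
    vapply(seq_len(n), function(i) {
      w <- rep(base, L)
      w[sample(L, 3)] <- alt
      paste0(w, collapse = "")
    }, character(1))
  }
  tibble::tibble(
    chain_id = "sep", position = seq_len(2 * n_per_class),
    pattern = c(mk("S", "T", n_per_class), mk("A", "G", n_per_class)),
    interacting = rep(c(TRUE, FALSE), each = n_per_class)
  )
}
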