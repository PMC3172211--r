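#' Generate synthetic annotated chains
#'
#' Simulates protein chains with the compositional structure that residue-
#' level binding-site predictors exploit: interacting positions are laid down
#' in short clusters (binding pockets are local), their residues drawn with
#' up-weighted probabilities for the mannose-contact-enriched set
#' (D, E, N, Q, R, S, T, W, Y), and residues within `flank_width` of an
#' interacting position up-weighted for S, T and G. Everything else is drawn
#' from the background distribution.
#'
#' Defaults emulate the natural scarcity of interacting residues
#' (`mir_fraction` 0.027, about 1 interacting residue per 37 non-interacting)
#' with moderate enrichment. The generator reproduces marginal frequencies,
#' not real evolutionary profiles or 3D geometry.
#'
#' @param n_chains Number of chains.
#' @param length_range Integer min/max chain length (uniform).
#' @param mir_fraction Target fraction of interacting residues.
#' @param center_bias Either a single multiplicative weight applied to the
#'   enriched center letters at interacting positions (1 = no signal), or a
#'   named numeric vector of per-letter multipliers.
#' @param flank_bias As `center_bias`, for the flank letters (S/T/G when
#'   given as a scalar) within `flank_width` of an interacting position.
#' @param flank_width Flank half-width in residues (default 3).
#' @param cluster_range Min/max run length of consecutive interacting
#'   residues per site (default 1-4).
#' @param background Named numeric vector of background letter weights over
#'   the 20 standard residues (default uniform); need not be normalized.
#' @param seed Integer seed; the same seed reproduces identical chains.
#' @return Per-residue annotated tibble.
#' @export
generate_chains <- function(n_chains = 50, length_range = c(80, 250),
                            mir_fraction = 0.027, center_bias = 5,
                            flank_bias = 3, flank_width = 3,
                            cluster_range = c(1, 4),
                            background = NULL, seed = 1) {
  if (mir_fraction <= 0 || mir_fraction >= 1) {
    stop("mir_fraction must be in (0, 1)", call. = FALSE)
  }
  if (any(center_bias <= 0) || any(flank_bias <= 0)) {
    stop("bias weights must be positive", call. = FALSE)
  }
  aa <- aa20()
  if (is.null(background)) background <- stats::setNames(rep(1, 20), aa)
  if (!all(aa %in% names(background)) || any(background <= 0)) {
    stop("background must give a positive weight to all 20 residues",
         call. = FALSE)
  }
  bg <- background[aa] / sum(background[aa])
  # a scalar bias up-weights the canonical enriched set; a named vector
  # gives per-letter multipliers directly
  expand_bias <- function(bias, default_set) {
    if (length(bias) == 1 && is.null(names(bias))) {
      ifelse(aa %in% default_set, bias, 1)
    } else {
      mult <- rep(1, 20)
      mult[match(names(bias), aa)] <- bias
      mult
    }
  }
  w_center <- bg * expand_bias(center_bias,
                               c("D", "E", "N", "Q", "R", "S", "T", "W", "Y"))
  w_flank <- bg * expand_bias(flank_bias, c("S", "T", "G"))

  # sample() treats a length-1 vector as 1:n; avoid that trap
  draw_one <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

  set.seed(seed)
  purrr::map_dfr(seq_len(n_chains), function(ci) {
    n <- draw_one(length_range[1], length_range[2])
    interacting <- rep(FALSE, n)
    # place non-overlapping clusters of consecutive interacting residues
    # until the chain holds round(mir_fraction * n) of them exactly
    target <- max(1, round(mir_fraction * n))
    attempts <- 0
    while (sum(interacting) < target && attempts < 200) {
      attempts <- attempts + 1
      len <- min(draw_one(cluster_range[1], cluster_range[2]),
                 target - sum(interacting))
      start <- sample(seq_len(max(1, n - len + 1)), 1)
      span <- start:(start + len - 1)
      if (!any(interacting[span])) interacting[span] <- TRUE
    }
    flank <- rep(FALSE, n)
    for (p in which(interacting)) {
      lo <- max(1, p - flank_width)
      hi <- min(n, p + flank_width)
      flank[lo:hi] <- TRUE
    }
    flank <- flank & !interacting
    res <- character(n)
    res[interacting] <- sample(aa, sum(interacting), replace = TRUE,
                               prob = w_center)
    res[flank] <- sample(aa, sum(flank), replace = TRUE, prob = w_flank)
    rest <- !interacting & !flank
    res[rest] <- sample(aa, sum(rest), replace = TRUE, prob = bg)
    tibble::tibble(chain_id = sprintf("syn%03d", ci), description = "",
                   position = seq_len(n), residue = res,
                   interacting = interacting)
  })
}

#' Train/held-out fixture pair for end-to-end tests
#'
#' Two disjoint synthetic chain sets sharing one generator configuration.
#' The `easy` difficulty uses strong compositional biases (center 8x,
#' flank 4x), giving a signal a composition-profile SVM separates
#' comfortably; `hard` uses weak biases (1.5x / 1.2x). `null` has no signal
#' at all (all biases 1) and places interacting sites as isolated single
#' residues, so overlapping sibling windows cannot smuggle any apparent
#' skill across cross-validation folds: measured performance on the null
#' fixture is pure noise around zero.
#'
#' @param difficulty `"easy"`, `"hard"` or `"null"`.
#' @param seed Integer seed; train and held-out sets use derived sub-seeds.
#' @param n_train,n_holdout Chain counts.
#' @return List with `train` and `holdout` chain tibbles.
#' @export
make_end_to_end_fixture <- function(difficulty = c("easy", "hard", "null"),
                                    seed = 1, n_train = 100, n_holdout = 20) {
  difficulty <- match.arg(difficulty)
  biases <- switch(difficulty,
                   easy = c(center = 8, flank = 4),
                   hard = c(center = 1.5, flank = 1.2),
                   null = c(center = 1, flank = 1))
  clusters <- if (difficulty == "null") c(1, 1) else c(1, 4)
  gen <- function(n, s, prefix) {
    ch <- generate_chains(n_chains = n, length_range = c(80, 160),
                          mir_fraction = 0.035,
                          center_bias = biases[["center"]],
                          flank_bias = biases[["flank"]],
                          cluster_range = clusters, seed = s)
    ch$chain_id <- paste0(prefix, ch$chain_id)
    ch
  }
  list(train = gen(n_train, seed * 2 + 1, "tr_"),
       holdout = gen(n_holdout, seed * 2 + 2, "ho_"))
}

#' Write matched toy PSSM files for synthetic chains
#'
#' Emits one PSI-BLAST ASCII-dialect PSSM per chain so the PSSM-profile
#' encoding is testable offline: each row is a smoothed one-hot profile
#' (a high score for the observed residue, low elsewhere) plus seeded integer
#' noise — a stand-in for real evolutionary profiles, synthetic by
#' construction.
#'
#' @param chains Per-residue annotated tibble.
#' @param dir Output directory; files are named `<chain_id>.pssm`.
#' @param seed Integer seed for the noise.
#' @return Tibble `chain_id`, `path` of written files, invisibly.
#' @export
write_toy_pssms <- function(chains, dir, seed = 1) {
  assert_chains(chains)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  # PSI-BLAST column order differs from the package alphabet on purpose,
  # so the reader's reordering is exercised
  blast_order <- strsplit("ARNDCQEGHILKMFPSTWVY", "")[[1]]
  out <- purrr::map_dfr(unique(chains$chain_id), function(id) {
    sub <- chains[chains$chain_id == id, ]
    sub <- sub[order(sub$position), ]
    n <- nrow(sub)
    scores <- matrix(sample(-3:0, n * 20, replace = TRUE), nrow = n)
    hit <- match(sub$residue, blast_order)
    ok <- !is.na(hit)
    scores[cbind(which(ok), hit[ok])] <- sample(5:9, sum(ok), replace = TRUE)
    pct <- matrix(5L, nrow = n, ncol = 20)
    path <- file.path(dir, paste0(id, ".pssm"))
    con <- file(path, "wt")
    writeLines(c("", "Last position-specific scoring matrix computed",
                 paste0("            ",
                        paste(sprintf("%3s", c(blast_order, blast_order)),
                              collapse = ""))), con)
    for (i in seq_len(n)) {
      writeLines(paste0(sprintf("%5d %s ", i, sub$residue[i]),
                        paste(sprintf("%3d", scores[i, ]), collapse = ""),
                        paste(sprintf("%4d", pct[i, ]), collapse = ""),
                        sprintf("  %.2f %.2f", 1.0, 0.5)), con)
    }
    close(con)
    tibble::tibble(chain_id = id, path = path)
  })
  invisible(out)
}
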