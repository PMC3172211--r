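test_that("binary profile is a strict 21-per-position one-hot", {
  v <- encode_binary("A")
  expect_equal(ncol(v), 21)
  expect_equal(as.numeric(v), c(1, rep(0, 20)))

  vx <- encode_binary(strrep("X", 5))
  expect_equal(ncol(vx), 5 * 21)
  blocks <- matrix(vx, nrow = 21)
  expect_true(all(blocks[21, ] == 1) && all(blocks[-21, ] == 0))

  pats <- generate_patterns(generate_chains(2, c(40, 60), seed = 1), 17)
  m <- encode_binary(pats)
  expect_equal(ncol(m), 357)
  expect_true(all(rowSums(m) == 17))            # 17 ones per pattern
  for (b in seq_len(17)) {                      # every block one-hot
    blk <- m[, ((b - 1) * 21 + 1):(b * 21), drop = FALSE]
    expect_true(all(rowSums(blk) == 1))
    expect_true(all(blk %in% c(0, 1)))
  }
  expect_error(encode_binary("AB#"), "alphabet")
})

test_that("binary profile is order-sensitive where composition is not", {
  a <- "ACDEFGHIKLMNPQRST"
  b <- "CADEFGHIKLMNPQRST"   # first two letters swapped
  expect_false(isTRUE(all.equal(encode_binary(a), encode_binary(b))))
  expect_equal(encode_composition(a), encode_composition(b))
})

test_that("composition profile is the letter fraction over the window", {
  v <- encode_composition(strrep("A", 17))
  expect_equal(as.numeric(v), c(1, rep(0, 20)))

  # first window of a poly-A chain at L = 17: 8 X then 9 A
  pats <- generate_patterns(chain_from_string(strrep("A", 30)), 17)
  v1 <- encode_composition(pats[1, ])
  expect_equal(unname(v1[1, "A"]), 9 / 17)
  expect_equal(unname(v1[1, "X"]), 8 / 17)

  chains <- generate_chains(3, c(30, 80), seed = 2)
  for (L in c(17, 19, 21, 23, 25)) {
    m <- encode_composition(generate_patterns(chains, L))
    expect_equal(ncol(m), 21)
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("composition is invariant under any permutation of the window", {
  set.seed(5)
  w <- paste0(sample(strsplit("AACCDSSTTXWYGGHII", "")[[1]]), collapse = "")
  perm <- paste0(sample(strsplit(w, "")[[1]]), collapse = "")
  expect_equal(encode_composition(w), encode_composition(perm))
})

test_that("logistic normalization is bounded, centered and monotone", {
  expect_equal(normalize_pssm(0), 0.5)
  expect_lt(normalize_pssm(-1000), 1e-12)
  expect_gt(normalize_pssm(1000), 1 - 1e-12)
  # strictly monotone where double precision can still resolve the increments
  grid <- seq(-30, 30, by = 0.25)
  vals <- normalize_pssm(grid)
  expect_equal(vals, 1 / (1 + exp(-grid)))  # direct evaluation
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 1))
  # monotone (non-strict) even deep into saturation
  wide <- normalize_pssm(seq(-1000, 1000, by = 5))
  expect_true(all(diff(wide) >= 0))
})

test_that("min-max normalization spans [0,1] and handles constant input", {
  m <- matrix(c(-3, 0, 3, 6), 2)
  n <- normalize_pssm(m, method = "minmax")
  expect_equal(range(n), c(0, 1))
  expect_equal(n[1], 0)
  expect_equal(normalize_pssm(matrix(0, 2, 2), method = "minmax"),
               matrix(0.5, 2, 2))
  expect_error(normalize_pssm(Inf), "finite")
})

test_that("PSI-BLAST ASCII PSSMs parse, reorder and normalize", {
  chains <- generate_chains(1, c(25, 25), seed = 6)
  dir <- withr::local_tempdir()
  info <- write_toy_pssms(chains, dir, seed = 1)
  m <- read_pssm(info$path[1])
  expect_s3_class(m, "mir_pssm")
  expect_equal(nrow(m$raw), 25)
  expect_equal(ncol(m$raw), 21)
  expect_equal(m$residues, chains$residue)
  # X slot raw score is 0 -> logistic 0.5
  expect_true(all(m$raw[, "X"] == 0))
  expect_true(all(m$normalized[, "X"] == 0.5))
  expect_true(all(m$normalized >= 0 & m$normalized <= 1))
  # the toy profiles place the high score on the observed residue; the
  # reader must have reordered columns so that row maximum sits there
  hit <- mir_alphabet()[apply(m$raw[, 1:20], 1, which.max)]
  expect_equal(hit, chains$residue)
})

test_that("the packaged 3-residue toy PSSM parses", {
  f <- system.file("extdata", "toy3.pssm", package = "mirsvm")
  m <- read_pssm(f)
  expect_equal(nrow(m$raw), 3)
  expect_equal(m$residues, c("A", "S", "D"))
  expect_equal(unname(m$raw[1, "A"]), 7)   # columns reordered from the header
  expect_equal(unname(m$raw[2, "S"]), 6)
  expect_equal(unname(m$raw[3, "D"]), 6)
})

test_that("malformed PSSM rows are format errors", {
  f <- withr::local_tempfile(fileext = ".pssm")
  writeLines(c("", "header",
               paste0("   ", paste(c(LETTERS[1:20]), collapse = "  ")),
               paste(c("1 A", rep("0", 19)), collapse = " ")), f)
  expect_error(read_pssm(f), "20 score columns")
  writeLines(c("no", "pssm", "here"), f)
  expect_error(read_pssm(f), "not a PSI-BLAST")
})

test_that("PSSM window encoding concatenates rows with one-hot X padding", {
  chains <- generate_chains(1, c(30, 30), seed = 9)
  dir <- withr::local_tempdir()
  info <- write_toy_pssms(chains, dir, seed = 2)
  m <- read_pssm(info$path[1], chain_id = chains$chain_id[1])
  pats <- generate_patterns(chains, 17)
  enc <- encode_pssm(pats, list(m))
  expect_equal(ncol(enc), 357)
  expect_true(all(enc >= 0 & enc <= 1))
  # center 21-block equals the chain's normalized row at the center position
  for (i in c(1, 15, 30)) {
    center_block <- enc[i, (8 * 21 + 1):(9 * 21)]
    expect_equal(unname(center_block), unname(m$normalized[i, ]))
  }
  # first window: 8 padded rows, each one-hot at the X slot
  first_pad <- matrix(enc[1, 1:(8 * 21)], nrow = 21)
  expect_true(all(first_pad[21, ] == 1) && all(first_pad[-21, ] == 0))
})

test_that("degenerate single-residue chain encodes as padding plus one row", {
  ch <- chain_from_string("M", id = "tiny")
  dir <- withr::local_tempdir()
  info <- write_toy_pssms(ch, dir, seed = 3)
  m <- read_pssm(info$path[1], chain_id = "tiny")
  enc <- encode_pssm(generate_patterns(ch, 17), list(m))
  blocks <- matrix(enc[1, ], nrow = 21)
  expect_equal(unname(blocks[, 9]), unname(m$normalized[1, ]))
  expect_true(all(blocks[21, -9] == 1))
  # a center position outside the chain is an error, not padding
  bad <- tibble::tibble(chain_id = "tiny", position = 5L,
                        pattern = strrep("A", 17), interacting = FALSE)
  expect_error(encode_pssm(bad, list(m)), "outside chain")
})
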