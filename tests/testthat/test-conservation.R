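test_that("aligned FASTA reading and writing round-trip", {
  txt <- ">seqA\nMKT-LS\n>seqB\nMRTGLS\n"
  aln <- read_alignment(txt)
  expect_equal(aln$ids, c("seqA", "seqB"))
  expect_equal(dim(aln$seqs), c(2, 6))
  expect_equal(aln$seqs[1, 4], "-")
  f <- tempfile(fileext = ".fasta")
  on.exit(unlink(f))
  write_alignment(aln, f)
  aln2 <- read_alignment(f)
  expect_identical(aln$ids, aln2$ids)
  expect_identical(aln$seqs, aln2$seqs)
})

test_that("ragged rows and foreign characters are rejected", {
  expect_error(read_alignment(">a\nMKT\n>b\nMK\n"),
               class = "wafer_error_length")
  expect_error(read_alignment(">a\nMK3\n>b\nMKT\n"),
               class = "wafer_error_alphabet")
  expect_error(read_alignment("no such file.fasta"),
               class = "wafer_error_io")
})

test_that("information content follows the corrected WebLogo formula", {
  # single-residue column at large n: R = log2(20) - e_n, no clamping
  aln <- make_alignment(1000, 3, conserved = list(`2` = "H"), seed = 3)
  p <- column_profile(aln, 2)
  e_n <- 19 / (2 * 1000 * log(2))
  expect_equal(p$information, log2(20) - e_n, tolerance = 1e-12)
  expect_equal(p$entropy, 0)
  expect_equal(unname(p$frequencies["H"]), 1.0)

  # exactly uniform composition: R clamps at zero
  freqs <- setNames(rep(0.05, 20),
                    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  aln_u <- make_alignment(20, 1, conserved = list(`1` = freqs), seed = 4)
  pu <- column_profile(aln_u, 1)
  expect_equal(pu$entropy, log2(20), tolerance = 1e-12)
  expect_equal(pu$information, 0)

  # without the correction the conserved column reaches the full 20-letter bits
  expect_equal(column_profile(aln, 2, correction = FALSE)$information,
               log2(20), tolerance = 1e-12)
})

test_that("random columns match a direct formula recomputation to 1e-12", {
  set.seed(81)
  aln <- make_alignment(14, 25, seed = 82)
  for (j in 1:25) {
    p <- column_profile(aln, j)
    obs <- aln$seqs[, j]
    f <- table(obs) / length(obs)
    h <- -sum(f * log2(f))
    r <- max(0, log2(20) - (h + 19 / (2 * 14 * log(2))))
    expect_equal(p$information, r, tolerance = 1e-12)
    # heights are frequency-proportional shares of R, ordered, nonnegative
    expect_equal(sum(p$heights), p$information, tolerance = 1e-12)
    expect_true(all(p$heights >= 0))
    expect_true(all(diff(p$frequencies) <= 1e-12))
  }
})

test_that("gap handling: gaps excluded, all-gap flagged missing, >50% flagged", {
  txt <- ">a\nH--\n>b\nH-A\n>c\nH-A\n>d\n--A\n"
  aln <- read_alignment(txt)
  p1 <- column_profile(aln, 1)
  expect_equal(p1$n_ungapped, 3)
  expect_equal(unname(p1$frequencies["H"]), 1.0)
  p2 <- column_profile(aln, 2)
  expect_identical(p2$flag, "all_gap")
  expect_true(is.na(p2$information))
  p3 <- column_profile(aln, 3)
  expect_identical(p3$flag, "ok") # 1/4 gaps: not low confidence
  txt2 <- ">a\nA\n>b\nA\n>c\n-\n>d\n-\n>e\n-\n"
  expect_identical(column_profile(read_alignment(txt2), 1)$flag,
                   "low_confidence") # 3/5 gaps
  expect_error(column_profile(aln, 9), class = "wafer_error_usage")
})

test_that("profiles are invariant under row reordering and weakly decrease under randomization", {
  set.seed(83)
  aln <- make_alignment(30, 5, conserved = list(`1` = "R"), seed = 84)
  perm <- sample(30)
  aln_p <- aln
  aln_p$seqs <- aln$seqs[perm, ]
  aln_p$ids <- aln$ids[perm]
  for (j in 1:5) {
    expect_equal(column_profile(aln, j)$information,
                 column_profile(aln_p, j)$information, tolerance = 1e-12)
  }
  # progressively randomizing a conserved column weakly lowers R
  r_prev <- column_profile(aln, 1)$information
  cur <- aln
  for (k in c(5, 10, 20, 30)) {
    cur$seqs[seq_len(k), 1] <- AA <- sample(setdiff(LETTERS, c("B","J","O","U","X","Z")),
                                            k, replace = TRUE)
    r_now <- column_profile(cur, 1)$information
    expect_lte(r_now, r_prev + 1e-9)
    r_prev <- r_now
  }
})

test_that("alignment columns map onto author residue numbers", {
  toy <- toy_fixture()
  # chain A polymer sequence by increasing author number:
  # 20 glycine fillers, then Ser68, His69, His101, Ser104, Ser163
  chain_seq <- paste(c(rep("G", 20), "S", "H", "H", "S", "S"), collapse = "")
  aln <- read_alignment(sprintf(">toy\n%s\n>other\n%s\n",
                                chain_seq, chain_seq))
  map <- map_columns_to_structure(aln, "toy", toy$model, "A")
  expect_equal(nrow(map), 25)
  expect_equal(map$seq_id, c(1:20, 68, 69, 101, 104, 163))
  expect_equal(map$column, 1:25)

  # an internal gap column maps to nothing, flanks stay mapped
  gapped <- paste0(substr(chain_seq, 1, 10), "-", substr(chain_seq, 11, 25))
  aln_g <- read_alignment(sprintf(">toy\n%s\n>other\n%sA\n",
                                  gapped, chain_seq))
  map_g <- map_columns_to_structure(aln_g, "toy", toy$model, "A")
  expect_false(11 %in% map_g$column)
  expect_equal(nrow(map_g), 25)
  expect_equal(map_g$seq_id, c(1:20, 68, 69, 101, 104, 163))

  # terminal truncation of the row is tolerated
  trunc <- substr(chain_seq, 3, 25)
  aln_t <- read_alignment(sprintf(">toy\n%s\n>other\n%s\n", trunc, trunc))
  map_t <- map_columns_to_structure(aln_t, "toy", toy$model, "A")
  expect_equal(map_t$seq_id, c(3:20, 68, 69, 101, 104, 163))

  # a genuinely different sequence fails with a mapping error
  bad <- paste(rep("W", 25), collapse = "")
  aln_b <- read_alignment(sprintf(">toy\n%s\n>other\n%s\n", bad, bad))
  expect_error(map_columns_to_structure(aln_b, "toy", toy$model, "A"),
               class = "wafer_error_mapping")
  expect_error(map_columns_to_structure(aln, "missing", toy$model, "A"),
               class = "wafer_error_lookup")
})

test_that("conservation report supports class-wise row splits", {
  # two "classes": the first conserves R at column 2, the second does not
  txt <- paste0(">eps1\nARK\n>eps2\nGRK\n>eps3\nCRK\n",
                ">del1\nADK\n>del2\nGEK\n>del3\nCQK\n")
  aln <- read_alignment(txt)
  # correction off: at n = 3 the small-sample penalty would clamp both
  # panels to zero and hide the contrast
  eps <- conservation_report(aln, 1:3, rows = c("eps1", "eps2", "eps3"),
                             correction = FALSE)
  del <- conservation_report(aln, 1:3, rows = c("del1", "del2", "del3"),
                             correction = FALSE)
  expect_equal(eps$consensus[2], "R")
  expect_equal(eps$frequency[2], 1.0)
  expect_true(del$consensus[2] != "R")
  expect_gt(eps$information[2], del$information[2])

  # a single-sequence "alignment": every position is its own consensus
  single <- conservation_report(read_alignment(">only\nMKR\n"), 1:3)
  expect_equal(single$consensus, c("M", "K", "R"))
  expect_equal(single$frequency, rep(1, 3))
})
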