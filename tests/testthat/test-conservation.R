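test_that("background tables validate and carry B/Z/X augmentation", {
  bg <- uniprot_background()
  expect_setequal(bg$symbol, c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                               "I", "L", "K", "M", "F", "P", "S", "T", "W",
                               "Y", "V", "B", "Z", "X"))
  expect_true(all(bg$frequency > 0))
  q <- setNames(bg$frequency, bg$symbol)
  expect_equal(q[["B"]], q[["D"]] + q[["N"]])
  expect_equal(q[["Z"]], q[["E"]] + q[["Q"]])
  expect_equal(q[["X"]], 1)

  # a table missing a residue is rejected
  path <- tempfile(fileext = ".tsv")
  tab <- data.frame(symbol = setdiff(bg$symbol[1:20], "W"),
                    frequency = rep(0.05, 19))
  readr::write_tsv(tab, path)
  expect_error(read_background(path), "missing residue.*W")
})

test_that("leading methionines are masked at the first non-gap column", {
  aln <- make_alignment(c("MARYR", "AR-YR", "--MAR"), ids = c("a", "b", "c"))
  masked <- mask_leading_met(aln)
  expect_equal(masked$met_col, c(1L, NA_integer_, 3L))
})

test_that("column profiles count non-gap symbols under masking", {
  aln <- make_alignment(c("CARYR", "CR-YR", "-G-AR", "M-MAR"))
  # column 1: C, C, -, M(masked) -> P(C)=1, nongap 2/4
  p1 <- column_profile(aln, 1)
  expect_equal(p1$p, c(C = 1))
  expect_equal(p1$nongap_fraction, 0.5)
  expect_equal(p1$n_gap, 2)
  # column 3: R, -, -, M; row 4's leading M was at column 1, so this M counts
  p3 <- column_profile(aln, 3)
  expect_equal(p3$p[order(names(p3$p))], c(M = 0.5, R = 0.5))
  expect_equal(p3$nongap_fraction, 0.5)
  expect_error(column_profile(aln, 9), "out of range")
})

test_that("an all-gap column yields an empty profile, not an error", {
  aln <- make_alignment(c("A-R", "C-R"))
  p <- column_profile(aln, 2)
  expect_equal(length(p$p), 0)
  expect_equal(p$nongap_fraction, 0)
  expect_error(relative_entropy(p, uniprot_background()), "all-gap")
  expect_equal(gap_weighted_score(p, uniprot_background()), 0)
})

test_that("relative entropy matches closed forms and is zero when P equals Q", {
  bg <- uniprot_background()
  uni <- uniform_background()
  all_r <- column_profile(make_alignment(rep("R", 4)), 1)
  # pure arginine against Q(R) = 0.0569: log2(1/0.0569) = 4.1354 bits
  expect_equal(relative_entropy(all_r, bg), log2(1 / 0.0569), tolerance = 1e-12)
  expect_equal(relative_entropy(all_r, bg), 4.1354, tolerance = 1e-4)
  # pure column under a uniform background: log2(20) for any residue
  all_c <- column_profile(make_alignment(rep("C", 4)), 1)
  expect_equal(relative_entropy(all_c, uni), log2(20), tolerance = 1e-12)
  # P identical to Q: one row per residue under the uniform background;
  # masking is off so the lone M is not dropped
  rows <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  aln20 <- make_alignment(rows, ids = sprintf("s%d", 1:20))
  aln20$met_col <- NA_integer_
  flat <- column_profile(aln20, 1)
  expect_equal(relative_entropy(flat, uni), 0, tolerance = 1e-12)
})

test_that("gap weighting multiplies by the non-gap fraction", {
  bg <- uniprot_background()
  half <- column_profile(make_alignment(c("R", "R", "-", "-")), 1)
  expect_equal(gap_weighted_score(half, bg), 0.5 * log2(1 / 0.0569),
               tolerance = 1e-12)
  full <- column_profile(make_alignment(rep("R", 4)), 1)
  expect_equal(gap_weighted_score(full, bg),
               relative_entropy(full, bg))
})

test_that("the threshold is log2(1/Q(ref)) and decreases in Q(ref)", {
  bg <- uniprot_background()
  expect_equal(conservation_threshold(bg), 4.1354, tolerance = 1e-4)
  expect_equal(conservation_threshold(uniform_background(), "W"), log2(20))
  expect_error(conservation_threshold(bg, "J"), "not present")
  # monotonicity over a grid of arginine frequencies
  grid <- seq(0.02, 0.2, by = 0.02)
  thr <- vapply(grid, function(qr) {
    tab <- uniform_background()
    tab$frequency[tab$symbol == "R"] <- qr
    conservation_threshold(tab)
  }, numeric(1))
  expect_true(all(diff(thr) < 0))
})

test_that("scan results honour per-column invariants on random alignments", {
  bg <- uniprot_background()
  withr::with_seed(101, {
    for (i in 1:10) {
      aln <- random_alignment(8, 25)
      s <- scan_alignment(aln, bg)
      ok <- !is.na(s$d_kl)
      # X columns can push d_kl negative only through Q(X)=1; exclude-free
      # columns must be non-negative and gap weighting can only shrink
      expect_true(all(s$g_w[ok] <= pmax(s$d_kl[ok], 0) + 1e-12))
      expect_true(all(s$gap_weight >= 0 & s$gap_weight <= 1))
      gapless <- ok & s$gap_weight == 1
      expect_equal(s$g_w[gapless], s$d_kl[gapless])
    }
  })
})

test_that("relative entropy is non-negative without ambiguity codes", {
  bg <- uniprot_background()
  withr::with_seed(77, {
    for (i in 1:10) {
      aln <- random_alignment(8, 25, alphabet = c("A", "R", "N", "D", "C",
                                                  "Q", "E", "G", "H", "I",
                                                  "L", "K", "M", "F", "P",
                                                  "S", "T", "W", "Y", "V"))
      s <- scan_alignment(aln, bg)
      expect_true(all(s$d_kl >= -1e-12, na.rm = TRUE))
    }
  })
})

test_that("column ordering by score is invariant to row permutation", {
  bg <- uniprot_background()
  withr::with_seed(55, {
    aln <- random_alignment(10, 30)
    base <- scan_alignment(aln, bg)
    for (i in 1:5) {
      perm <- aln[sample(nrow(aln)), ]
      s <- scan_alignment(perm, bg)
      expect_equal(s$g_w, base$g_w, tolerance = 1e-12)
      expect_equal(order(s$g_w), order(base$g_w))
    }
  })
})

test_that("scan reports majority symbol and gap-excluded purity", {
  # column of 13 C, 3 Y, 4 gaps: 69% C excluding gaps markedly higher than
  # the 65% including gaps
  rows <- c(rep("C", 13), rep("Y", 3), rep("-", 4))
  aln <- make_alignment(rows, ids = sprintf("s%02d", 1:20))
  s <- scan_alignment(aln, uniprot_background())
  expect_equal(s$majority_symbol, "C")
  expect_equal(s$purity, 13 / 16)
})

test_that("a planted all-cysteine column is conserved under the bundled background", {
  fam <- simulate_family(n_sequences = 20, length = 40,
                         planted = data.frame(column = 10, residue = "C",
                                              purity = 1),
                         gap_rate = 0, seed = 5)
  s <- scan_alignment(fam$alignment, uniprot_background())
  planted_col <- fam$truth$column[fam$truth$label == "planted"]
  expect_true(s$conserved[s$column == planted_col])
  # and its score is the cysteine analogue of the threshold
  expect_equal(s$g_w[s$column == planted_col], log2(1 / 0.0123),
               tolerance = 1e-12)
})

test_that("background-only alignments drawn from Q produce no conserved calls", {
  bg <- uniprot_background()
  q <- setNames(bg$frequency[1:20], bg$symbol[1:20])
  withr::with_seed(31, {
    m <- matrix(sample(names(q), 50 * 100, replace = TRUE, prob = q),
                nrow = 50)
    aln <- make_alignment(apply(m, 1, paste0, collapse = ""),
                          ids = sprintf("s%02d", 1:50))
  })
  s <- scan_alignment(aln, bg)
  expect_equal(sum(s$conserved), 0)
})
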