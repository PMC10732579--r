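test_that("glutamate pure mapping matrix is rank 28 over 32 isotopomers", {
  expect_equal(ncol(A_glu), 32L)
  expect_equal(matrix_rank(A_glu), 28L)
})

test_that("aspartate pure mapping matrix rank matches the SVD oracle", {
  # independent oracle: rebuild the matrix from raw fragment combinatorics
  # (no shared code path) and take its SVD rank
  L <- as.matrix(expand.grid(rep(list(0:1), 4)))[, 4:1]
  L <- L[order(apply(L, 1, paste, collapse = "")), ]
  fams <- list(`134/88` = list(list(2:4, 1)), `134/74` = list(list(1:2, 1)),
               `134/43` = list(list(3:4, 1)),
               `132/88` = list(list(1:3, 15 / 16), list(2:4, 1 / 16)))
  rows <- list()
  for (fn in names(fams)) for (cmp in fams[[fn]]) {
    for (r in seq_len(nrow(L))) {
      key <- sprintf("%s:%d/%d", fn, sum(L[r, ]), sum(L[r, cmp[[1]]]))
      if (is.null(rows[[key]])) rows[[key]] <- numeric(16)
      rows[[key]][r] <- rows[[key]][r] + cmp[[2]]
    }
  }
  Ao <- do.call(rbind, rows)
  d <- svd(Ao)$d
  oracle_rank <- sum(d > max(dim(Ao)) * .Machine$double.eps * d[1])
  expect_equal(oracle_rank, 15L)
  expect_equal(matrix_rank(A_asp), oracle_rank)
  expect_equal(nrow(A_asp), nrow(Ao))
})

test_that("family-block column sums are one for both matrix variants", {
  for (A in list(A_glu, A_asp, A_glu_na, A_asp_na)) {
    fam <- attr(A, "family")
    for (f in unique(fam)) {
      cs <- colSums(unclass(A)[fam == f, , drop = FALSE])
      expect_true(all(abs(cs - 1) < 1e-9))
    }
    expect_true(all(A >= 0 & A <= 1))
  }
})

test_that("a single-component family gives one unit entry per labeling", {
  fam <- attr(A_glu, "family")
  blk <- unclass(A_glu)[fam == "146/74", ]
  expect_true(all(colSums(blk == 1) == 1))
  expect_true(all(colSums(blk) == 1))
})

test_that("matrix entries do not depend on family listing order", {
  mol_rev <- glu
  mol_rev$families <- rev(mol_rev$families)
  A_rev <- mapping_matrix(mol_rev)
  expect_equal(unclass(A_rev)[rownames(A_glu), ], unclass(A_glu)[rownames(A_glu), ])
})

test_that("natural shift distribution matches closed forms", {
  # empty formula: all mass at shift zero
  expect_equal(unname(natural_shift_distribution(c(H = 0L))[1]), 1)
  expect_equal(unname(natural_shift_distribution(c(H = 1L))[1]), 1 - 0.000156)
  expect_equal(sum(natural_shift_distribution("C5H8NO4")), 1, tolerance = 1e-12)
  # one carbon
  d <- natural_shift_distribution("C")
  expect_equal(unname(d), c(0.98918, 0.01082))
  # oracle: direct per-atom product for the monoisotopic probability
  pH <- 0.000156; pC <- 0.01082; pN <- 0.00366; p17 <- 0.00038; p18 <- 0.00204
  p0_oracle <- (1 - pC)^5 * (1 - pH)^8 * (1 - pN) * (1 - p17 - p18)^4
  expect_equal(unname(natural_shift_distribution("C5H8NO4")[1]), p0_oracle,
               tolerance = 1e-14)
  # excluding labeled carbons removes them from the binomial
  d2 <- natural_shift_distribution("C5H8NO4", excluded_carbons = 2)
  expect_equal(unname(d2[1]), p0_oracle / (1 - pC)^2, tolerance = 1e-14)
  expect_error(natural_shift_distribution("C2HO", excluded_carbons = 3),
               "exceeds")
})

test_that("precursor shift mass of unlabeled glutamate matches the oracle", {
  # the total probability of any precursor shift >= 1 is the complement of
  # the all-monoisotopic product over the full precursor ion
  fam <- attr(A_glu_na, "family")
  tr <- attr(A_glu_na, "transitions")
  blk <- fam == "146/74"
  col <- unclass(A_glu_na)[blk, "00000"]
  p_shift0 <- sum(col[tr$i[blk] == 0])
  pH <- 0.000156; pC <- 0.01082; pN <- 0.00366; p17 <- 0.00038; p18 <- 0.00204
  p0_oracle <- (1 - pC)^5 * (1 - pH)^8 * (1 - pN) * (1 - p17 - p18)^4
  # matrix columns are renormalized after truncation; the tail is < 1e-8 here
  expect_equal(p_shift0, p0_oracle, tolerance = 1e-6)
  expect_equal(sum(col[tr$i[blk] >= 1]), 1 - p0_oracle, tolerance = 1e-5)
})

test_that("15N confusion shifts unlabeled 146/74 density into the (1,1) pair", {
  # the C1-2 product ion contains the nitrogen: a 15N atom shifts both
  # precursor and product by one unit, landing on 147/75
  col <- unclass(A_glu_na)[, "00000"]
  expect_gt(col[["146/74:147/75"]], 0.00366 * 0.9)
  # against a nitrogen-free product (146/41, C2HO): 15N sits in the neutral
  # loss, so it lands on 147/41 rather than 147/42
  expect_gt(col[["146/41:147/41"]], col[["146/41:147/42"]])
})

test_that("zeroed abundances reduce the augmented matrix to the pure one", {
  A0 <- mapping_matrix(glu, na_correct = TRUE,
                       abundances = no_isotope_abundances())
  expect_setequal(rownames(A0), rownames(A_glu))
  expect_true(all(abs(unclass(A0)[rownames(A_glu), ] - unclass(A_glu)) < 1e-12))
})

test_that("natural-abundance augmentation never destroys information", {
  expect_gte(matrix_rank(A_glu_na), 28L)
  expect_gte(matrix_rank(A_asp_na), matrix_rank(A_asp))
})

test_that("identifiable set splits glutamate 18/14 with M+2/M+3 remainder", {
  ids <- identifiable_set(A_glu)
  expect_length(ids$identifiable, 18L)
  expect_length(ids$non_identifiable, 14L)
  weights <- nchar(gsub("0", "", ids$non_identifiable))
  expect_true(all(weights %in% c(2L, 3L)))
  # full-rank toy matrix: everything identifiable
  toy <- structure(diag(4), dimnames = list(letters[1:4], LETTERS[1:4]),
                   class = c("mapping_matrix", "matrix", "array"))
  expect_length(identifiable_set(toy)$identifiable, 4L)
  # aspartate: the four mirror-pair m+2 isotopomers are the blind spot
  expect_setequal(identifiable_set(A_asp)$non_identifiable,
                  c("0101", "0110", "1001", "1010"))
})

test_that("matrix CSV export round-trips", {
  p <- withr::local_tempfile(fileext = ".csv")
  write_matrix_csv(A_glu, p)
  back <- read.csv(p, check.names = FALSE)
  expect_equal(back$transition, rownames(A_glu))
  expect_equal(as.matrix(back[, -1]), unclass(A_glu),
               ignore_attr = TRUE, tolerance = 1e-12)
})
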