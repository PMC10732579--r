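test_that("multiplet aggregation follows the neighbour-coupling rule", {
  ms <- multiplet_summary(dist_of("00111" = 1))
  expect_equal(unname(ms$components$C4[["Q"]]), 1)
  ms2 <- multiplet_summary(dist_of("00011" = 1))
  expect_equal(unname(ms2$components$C4[["D45"]]), 1)
  expect_equal(unname(ms2$components$C4[["S"]]), 0)
  expect_equal(unname(ms2$total[["C3"]]), 0)
})

test_that("uniform distribution splits C4 evenly over its four components", {
  # oracle: of the 16 labelings with C4 = 1, the (C3, C5) neighbour patterns
  # (0,0), (1,0), (0,1), (1,1) occur 4 times each
  u <- setNames(rep(1 / 32, 32), glu_labs)
  ms <- multiplet_summary(u)
  expect_equal(unname(ms$components$C4), rep(4 / 32, 4), ignore_attr = TRUE)
})

test_that("multiplet aggregation conserves labeled mass per carbon", {
  set.seed(31)
  for (rep in 1:10) {
    x <- rexp(32); x <- x / sum(x); names(x) <- glu_labs
    ms <- multiplet_summary(x)
    for (k in 1:5) {
      expect_equal(unname(sum(ms$components[[k]])), unname(ms$total[[k]]))
    }
    L <- enumerate_labelings(5L)
    expect_equal(unname(ms$total), as.numeric(x %*% L), tolerance = 1e-12)
  }
})

test_that("F_C3 estimators compute their closed forms", {
  # Glu4Q = 0.5 and Glu4/Glu3 = 1 => 0.5
  d <- dist_of("00111" = 0.25, "00011" = 0.25, "00100" = 0.25, "00000" = 0.25)
  ms <- multiplet_summary(d)
  expect_equal(unname(ms$total[["C4"]] / ms$total[["C3"]]), 1)
  expect_equal(fc3_nmr(ms), 0.5)
  expect_equal(fc3_direct(dist_of("11011" = 0.08, "11000" = 0.02,
                                  "00000" = 0.90)), 0.8)
  expect_equal(fc3_direct(dist_of("11000" = 0.1, "00000" = 0.9)), 0)
  expect_error(fc3_direct(dist_of("00000" = 1)), "undefined")
  expect_error(fc3_nmr(dist_of("00000" = 1)), "undefined")
})

test_that("anaplerosis is the C4/C3 ratio above one", {
  d <- dist_of("00111" = 0.5, "00011" = 0.5)  # C4 = 1, C3 = 0.5
  expect_equal(anaplerosis(d), 1)
  expect_equal(anaplerosis(dist_of("00110" = 1)), 0)
  expect_error(anaplerosis(dist_of("00011" = 1)), "undefined")
  # consistency of the printed triple: y = Glu4/Glu3 - 1 implies
  # Glu4Q = fc3 / (Glu4/Glu3) stays a valid fraction
  expect_lte(0.865 / 1.351, 1)
})

test_that("PC and FH contrasts read the named isotopomers", {
  d <- dist_of("1110" = 0.1, "0111" = 0.1, "1101" = 0.05, "1011" = 0.05,
               "0000" = 0.7, n = 4L)
  expect_equal(unname(pc_index(d)["pc_index"]), 0.1)
  g <- dist_of("01111" = 0.2, "10111" = 0.15, "00000" = 0.65)
  expect_equal(unname(pc_index(d, g)["glu_contrast"]), 0.05)
  f <- fh_asymmetry(dist_of("1110" = 0.08, "0111" = 0.02, "0000" = 0.9, n = 4L))
  expect_equal(unname(f["fh_asymmetry"]), 0.06)
})

test_that("m+1 balance separates carboxylation from multi-turn PDH label", {
  expect_equal(m1_balance(dist_of("1000" = 0.1, "0100" = 0.1, "0010" = 0.1,
                                  "0001" = 0.1, "0000" = 0.6, n = 4L)), 0.5)
  expect_equal(m1_balance(dist_of("0001" = 0.2, "0000" = 0.8, n = 4L)), 1.0)
  expect_error(m1_balance(dist_of("0000" = 1, n = 4L)), "undefined")
})

test_that("readouts respond correctly to unlabeled dilution", {
  x <- dist_of("11011" = 0.2, "11000" = 0.05, "00111" = 0.3, "00011" = 0.2,
               "00000" = 0.25)
  dil <- x * 0.5
  dil[["00000"]] <- dil[["00000"]] + 0.5
  # ratio-based metrics depend only on the labeled subset
  expect_equal(fc3_direct(x), fc3_direct(dil))
  expect_equal(fc3_nmr(x), fc3_nmr(dil))
  expect_equal(anaplerosis(x), anaplerosis(dil))
  # signed contrasts scale with the dilution factor instead
  a <- dist_of("1110" = 0.2, "1101" = 0.1, "0000" = 0.7, n = 4L)
  adil <- a * 0.5; adil[["0000"]] <- adil[["0000"]] + 0.5
  expect_equal(unname(pc_index(adil)["pc_index"]),
               unname(pc_index(a)["pc_index"]) * 0.5)
})

test_that("tca_readout aggregates all metrics and tolerates undefined ones", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 0.5, "00" = 0.5), n_turns = 6))
  out <- tca_readout(sim$glutamate, sim$aspartate)
  expect_true(all(c("fc3_eq1", "fc3_eq2", "anaplerosis_y", "pc_index",
                    "fh_asymmetry", "m1_outer_fraction") %in% names(out)))
  out0 <- tca_readout(glu = dist_of("00000" = 1))
  expect_true(is.na(out0[["fc3_eq1"]]))
})
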