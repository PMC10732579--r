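test_that("citrate synthase carbon map matches the worked cases", {
  expect_equal(condense_accoa("1110", "11"), "01111")
  expect_equal(condense_accoa("1101", "11"), "10111")
  expect_equal(condense_accoa("0000", "11"), "00011")
})

test_that("glutamate returns to OAA in order or mirrored", {
  tr <- glutamate_to_oaa("00011")
  expect_equal(sort(names(tr)), c("0011", "1100"))
  expect_equal(unname(tr), c(0.5, 0.5))
  expect_equal(glutamate_to_oaa("00011", scramble = FALSE),
               c("0011" = 1))
  # palindromic chains collapse to a single product
  expect_equal(glutamate_to_oaa("01001"), c("1001" = 1))
})

test_that("stochastic reading of the scrambling step matches its expectation", {
  set.seed(123)
  draws <- sample(names(glutamate_to_oaa("00011")), 10000, replace = TRUE,
                  prob = glutamate_to_oaa("00011"))
  expect_lt(abs(mean(draws == "0011") - 0.5), 0.02)
})

test_that("one turn with pure [1,2-13C]acetyl-CoA gives glutamate 00011", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 1), n_turns = 1))
  expect_equal(unname(sim$glutamate[["00011"]]), 1)
})

test_that("distributions stay normalized over many turns", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 0.6, "10" = 0.2, "00" = 0.2),
                              pc_fraction = 0.2, dilution = 0.1, n_turns = 12))
  expect_equal(sum(sim$glutamate), 1, tolerance = 1e-12)
  expect_equal(sum(sim$aspartate), 1, tolerance = 1e-12)
  expect_true(all(sim$glutamate >= 0))
})

test_that("PC inflow produces aspartate 1110, scrambled to 0111", {
  sc <- tca_scenario(accoa = c("00" = 1), pc_oaa = c("1110" = 1),
                     pc_fraction = 0.3, n_turns = 1, scramble = FALSE)
  sim <- run_tca(sc)
  expect_gt(sim$aspartate[["1110"]], 0)
  expect_equal(unname(sim$aspartate[["0111"]]), 0)
  sc$scramble <- TRUE
  sim2 <- run_tca(sc)
  expect_gt(sim2$aspartate[["0111"]], 0)
})

test_that("fumarate scrambling symmetrizes the mirror pairs", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 0.7, "00" = 0.3), n_turns = 10))
  expect_equal(sim$aspartate[["1110"]], sim$aspartate[["0111"]],
               tolerance = 1e-12)
  expect_equal(sim$aspartate[["1101"]], sim$aspartate[["1011"]],
               tolerance = 1e-12)
  expect_equal(unname(fh_asymmetry(sim$aspartate)["fh_asymmetry"]), 0,
               tolerance = 1e-12)
})

test_that("FH-deficient PC scenario is asymmetric while PDH pair stays even", {
  # first-turn PC signature: inflowing OAA 1110 reaches aspartate unmirrored
  # when fumarate scrambling is off, while neither PDH-pair member is formed
  sim <- run_tca(tca_scenario(accoa = c("00" = 1),
                              pc_oaa = c("1110" = 1), pc_fraction = 0.25,
                              scramble = FALSE, n_turns = 1))
  f <- fh_asymmetry(sim$aspartate)
  expect_gt(f[["fh_asymmetry"]], 0.01)
  expect_lt(abs(f[["pdh_contrast"]]), 1e-6)
})

test_that("direct F_C3 recovers the acetyl-CoA input fraction", {
  for (p in c(0.2, 0.5, 0.8)) {
    sim <- run_tca(tca_scenario(accoa = setNames(c(p, 1 - p), c("11", "00")),
                                n_turns = 10))
    expect_equal(unname(fc3_direct(sim$glutamate)), p, tolerance = 1e-6)
  }
})

test_that("multi-turn PDH label splits m+1 aspartate evenly; 13CO2 does not", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 0.15, "00" = 0.85),
                              n_turns = 10))
  expect_equal(m1_balance(sim$aspartate), 0.5, tolerance = 0.02)
  # carboxylation of unlabeled pyruvate with 13CO2 labels only C4 (then C1
  # by scrambling): all m+1 mass sits on the outer carbons
  co2 <- run_tca(tca_scenario(accoa = c("00" = 1), pc_oaa = c("0001" = 1),
                              pc_fraction = 0.2, n_turns = 6))
  expect_equal(m1_balance(co2$aspartate), 1.0, tolerance = 1e-9)
})

test_that("pc_index vanishes without PC and detects PC inflow", {
  no_pc <- run_tca(tca_scenario(accoa = c("11" = 0.6, "00" = 0.4), n_turns = 10))
  expect_lt(abs(pc_index(no_pc$aspartate)[["pc_index"]]), 1e-9)
  with_pc <- run_tca(tca_scenario(accoa = c("11" = 0.6, "00" = 0.4),
                                  pc_oaa = c("1110" = 1), pc_fraction = 0.2,
                                  n_turns = 10))
  expect_gt(pc_index(with_pc$aspartate)[["pc_index"]], 0.01)
  glu_c <- pc_index(with_pc$aspartate, with_pc$glutamate)
  expect_gt(glu_c[["glu_contrast"]], 0)
})

test_that("tracer purity thins labeled positions binomially", {
  sc <- tca_scenario(accoa = c("11" = 1), n_turns = 1, purity = 0.99)
  expect_equal(unname(sc$accoa[["11"]]), 0.99^2)
  expect_equal(unname(sc$accoa[["10"]]), 0.99 * 0.01)
  expect_equal(sum(sc$accoa), 1)
})

test_that("simulated MRM tables have the right support and are linear", {
  tab <- simulate_mrm(dist_of("11111" = 1), A_glu)
  tr <- attr(A_glu, "transitions")
  expect_true(all(tab$area[tr$i < 5] == 0))
  expect_gt(sum(tab$area[tr$i == 5]), 0)
  # natural abundance puts signal at M+1/m+1 of nitrogen-containing families
  tab_na <- simulate_mrm(dist_of("00000" = 1), A_glu_na)
  r75 <- tab_na$area[tab_na$Q1 == 147 & tab_na$Q3 == 75]
  expect_gt(r75, 0)
  # linearity in the distribution
  x1 <- dist_of("00000" = 1); x2 <- dist_of("11111" = 1)
  mix <- 0.3 * x1 + 0.7 * x2
  a_mix <- simulate_mrm(mix, A_glu)$area
  a_lin <- 0.3 * simulate_mrm(x1, A_glu)$area + 0.7 * simulate_mrm(x2, A_glu)$area
  expect_equal(a_mix, a_lin, tolerance = 1e-12)
  expect_error(simulate_mrm(x1, A_glu, total_area = -1), "positive")
})

test_that("simulate then fit round-trips the distribution end to end", {
  sim <- run_tca(tca_scenario(accoa = c("11" = 0.8, "00" = 0.2),
                              pc_fraction = 0.1, n_turns = 8))
  tab <- simulate_mrm(sim$glutamate, A_glu_na)
  fit <- isotopomer_fit(tab, matrix = A_glu_na)
  ids <- identifiable_set(A_glu_na)$flag
  expect_lt(max(abs(coef(fit)[1, ids] - sim$glutamate[ids])), 1e-8)
  # the TCA readouts survive the round trip
  expect_equal(fc3_direct(coef(fit)[1, ]), fc3_direct(sim$glutamate),
               tolerance = 1e-6)
})
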