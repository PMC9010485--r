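PANEL_M <- default_marker_panel("male")
PANEL_F <- default_marker_panel("female")
MK <- PANEL_M$markers$marker

test_that("expected_recombinants is n * r(d)", {
  expect_equal(expected_recombinants(16544, 1.21), 16544 * 0.0119548,
               tolerance = 1e-4)
  expect_identical(expected_recombinants(1000, 0), 0)
  expect_equal(expected_recombinants(88, -50 * log(1 - 2 * 0.005)),
               0.44, tolerance = 1e-9)
})

test_that("gametic selection fixes the determinant allele exactly", {
  sr <- simulate_screen(2000, PANEL_M, selection = TRUE, seed = 3)
  expect_true(all(sr$det_carrier))
  expect_identical(sr$n_screened, 2000L)
  expect_true(all(sr$phenotype == "C"))
})

test_that("without selection transmission is Mendelian", {
  sr <- simulate_screen(20000, PANEL_M, selection = FALSE, seed = 5)
  f <- mean(sr$det_carrier)
  se <- sqrt(0.25 / 20000)
  expect_lt(abs(f - 0.5), 3 * se)
  # single-marker panel reproduces 1:1 transmission across seeds
  p1 <- marker_panel(data.frame(marker = c("L", "R"),
                                pos_Mb = c(0, 2)), 1)
  for (s in 1:5) {
    sr1 <- simulate_screen(5000, p1, selection = FALSE, seed = s)
    cd <- count_data("m", c("donor", "other"),
                     c(sum(sr1$calls[, 1] == "511L"),
                       sum(sr1$calls[, 1] != "511L")))
    expect_gt(exact_test(cd, "1:1")$p_value, 0.001)
  }
})

test_that("marker-determinant discordance converges to r under selection", {
  n <- 1e5
  sr <- simulate_screen(n, PANEL_M, selection = TRUE, seed = 11)
  for (m in c("M1", "M5", "M8", "M11")) {
    r <- marker_det_r(PANEL_M, m)
    obs <- mean(sr$calls[, m] != PANEL_M$donor_allele)
    se <- sqrt(r * (1 - r) / n)
    expect_lt(abs(obs - r), 3 * se + 1e-12)
  }
})

test_that("the female screen segregates genotypes 1:1 with matching phenotypes", {
  sr <- simulate_female_screen(20000, PANEL_F, seed = 9)
  f <- mean(sr$det_carrier)  # homozygous-donor (barrier) plants
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 20000))
  expect_true(all(sr$phenotype[sr$det_carrier] == "CI"))
  expect_true(all(sr$phenotype[!sr$det_carrier] == "C"))
})

test_that("localize reproduces the published intervals on fixture patterns", {
  # male screen (survivors carry the determinant; C marks carriers)
  male_fix <- rbind(
    R1 = c(rep("511L", 5), rep("W22", 6)),
    R2 = c(rep("511L", 7), rep("W22", 4)),
    R3 = c(rep("W22", 2), rep("511L", 9)))
  colnames(male_fix) <- MK
  loc <- localize(male_fix, phenotypes = c("CI", "C", "C"),
                  panel = PANEL_M)
  expect_identical(c(loc$left, loc$right), c("M5", "M8"))
  # female screen (CI plants carry the homozygous barrier)
  female_fix <- rbind(
    R1 = c(rep("W22", 3), rep("511L", 8)),
    R2 = c(rep("511L", 7), rep("W22", 4)),
    R3 = c(rep("511L", 2), rep("W22", 9)))
  colnames(female_fix) <- MK
  locf <- localize(female_fix, phenotypes = c("CI", "CI", "C"),
                   panel = PANEL_F, carrier_phenotype = "CI")
  expect_identical(c(locf$left, locf$right), c("M3", "M8"))
})

test_that("localize handles edge cases and contradictions", {
  # no recombinants: full panel interval unchanged
  none <- matrix(rep("511L", 11), nrow = 1,
                 dimnames = list(NULL, MK))
  loc <- localize(none[0, , drop = FALSE], phenotypes = character(0),
                  panel = PANEL_M)
  expect_identical(c(loc$left, loc$right), c("M1", "M11"))
  # contradictory recombinants are an error naming the conflict
  contra <- rbind(a = c(rep("511L", 2), rep("W22", 9)),
                  b = c(rep("511L", 9), rep("W22", 2)))
  colnames(contra) <- MK
  expect_error(localize(contra, phenotypes = c("C", "CI"),
                        panel = PANEL_M), "contradictory")
  # double crossovers are counted as complex, not used
  dbl <- rbind(x = c(rep("511L", 3), rep("W22", 4), rep("511L", 4)))
  colnames(dbl) <- MK
  loc2 <- localize(dbl, phenotypes = "C", panel = PANEL_M)
  expect_identical(loc2$n_complex, 1L)
  expect_identical(c(loc2$left, loc2$right), c("M1", "M11"))
})

test_that("localize never excludes the true determinant position", {
  for (s in 1:4) {
    sr <- simulate_screen(5000, PANEL_M, selection = TRUE, seed = s)
    loc <- localize(sr)
    pos <- PANEL_M$markers$pos_Mb[match(c(loc$left, loc$right), MK)]
    expect_true(PANEL_M$determinant_pos_Mb > pos[1] &&
                  PANEL_M$determinant_pos_Mb < pos[2])
  }
  sr <- simulate_female_screen(2600, PANEL_F, seed = 2)
  loc <- localize(sr)
  pos <- PANEL_F$markers$pos_Mb[match(c(loc$left, loc$right), MK)]
  expect_true(PANEL_F$determinant_pos_Mb > pos[1] &&
                PANEL_F$determinant_pos_Mb < pos[2])
})

test_that("backcross program halves donor background each generation", {
  bp <- backcross_program(8, n_background = 2000, seed = 4)
  pg <- bp$per_generation
  expect_identical(nrow(pg), 8L)
  expect_equal(pg$expected_donor_fraction, 0.5^(2:9))
  expect_equal(pg$expected_donor_fraction[8], 0.00195, tolerance = 1e-2)
  expect_true(all(pg$foreground == "heterozygous"))
  # realized tracks expectation within binomial error (donor fraction =
  # het fraction / 2; at generation 1 the het count is ~ Bin(n, 1/2))
  expect_lt(abs(pg$realized_donor_fraction[1] - 0.25),
            3 * sqrt(0.25 / 2000) / 2 + 0.01)
  expect_identical(bp$final_self_homozygous_prob, 0.25)
  expect_equal(backcross_program(1, seed = 1)$per_generation$
                 expected_donor_fraction, 0.25)
})

test_that("panel construction validates its geometry", {
  expect_error(marker_panel(data.frame(marker = c("a", "b"),
                                       pos_Mb = c(2, 1)), 1.5),
               "increasing")
  expect_error(marker_panel(data.frame(marker = c("a", "b"),
                                       pos_Mb = c(1, 2)), 5),
               "inside")
  expect_equal(PANEL_M$markers$pos_Mb[8] - PANEL_M$markers$pos_Mb[5],
               1.21)
  expect_equal(PANEL_F$markers$pos_Mb[8] - PANEL_F$markers$pos_Mb[3],
               1.70)
})
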