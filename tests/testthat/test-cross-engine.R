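test_that("recomb_fraction matches the closed forms and their limits", {
  expect_identical(recomb_fraction(0), 0)
  expect_identical(recomb_fraction(0, "kosambi"), 0)
  expect_equal(recomb_fraction(1e6), 0.5, tolerance = 1e-12)
  expect_equal(recomb_fraction(1e6, "kosambi"), 0.5, tolerance = 1e-12)
  expect_equal(recomb_fraction(1.21), 0.0119548, tolerance = 1e-5)
  expect_true(all(diff(recomb_fraction(seq(0, 200, by = 5))) > 0))
  expect_true(all(recomb_fraction(c(0, 1, 10, 1000)) < 0.5))
  expect_error(recomb_fraction(-1), ">= 0")
})

test_that("gamete_distribution: Mendelian segregation and linkage", {
  f1 <- F1_W22x511L()
  gd <- gamete_distribution(REG, f1)
  expect_equal(sum(gd$weight), 1)
  expect_setequal(gd$Ga2, c("Ga2-S", "ga2"))
  expect_equal(sort(gd$weight), c(0.5, 0.5))
  # homozygote: single gamete, weight 1
  gd0 <- gamete_distribution(REG, FND$`511L`)
  expect_identical(nrow(gd0), 1L)
  expect_identical(gd0$weight, 1)
  # two linked loci in coupling at r = 0.1 (d from the inverse Haldane map)
  d <- -50 * log(1 - 2 * 0.1)
  regL <- linked_registry(d)
  het <- genotype(regL, c(A = "A1", B = "B1"), c(A = "A2", B = "B2"))
  gdL <- gamete_distribution(regL, het)
  w <- stats::setNames(gdL$weight, paste(gdL$A, gdL$B))
  expect_equal(w[["A1 B1"]], 0.45, tolerance = 1e-12)
  expect_equal(w[["A2 B2"]], 0.45, tolerance = 1e-12)
  expect_equal(w[["A1 B2"]], 0.05, tolerance = 1e-12)
  expect_equal(w[["A2 B1"]], 0.05, tolerance = 1e-12)
  # repulsion phase flips parental/recombinant classes
  het_r <- genotype(regL, c(A = "A1", B = "B2"), c(A = "A2", B = "B1"))
  wr <- gamete_distribution(regL, het_r)
  wr <- stats::setNames(wr$weight, paste(wr$A, wr$B))
  expect_equal(wr[["A1 B1"]], 0.05, tolerance = 1e-12)
})

test_that("select_pollen removes incompatible mass and renormalizes", {
  f1 <- F1_W22x511L()
  gd <- gamete_distribution(REG, f1)
  sel <- select_pollen(REG, gd, FND$`511L`)
  expect_equal(sel$rejected_fraction, 0.5)
  expect_identical(unique(sel$gametes$Ga2), "Ga2-S")
  expect_equal(sum(sel$gametes$weight), 1)
  # total incompatibility: empty with rejected fraction 1
  gw <- gamete_distribution(REG, FND$W22)
  sel2 <- select_pollen(REG, gw, FND$`511L`)
  expect_identical(nrow(sel2$gametes), 0L)
  expect_identical(sel2$rejected_fraction, 1)
  # no active barrier: unchanged
  sel3 <- select_pollen(REG, gd, FND$W22)
  expect_identical(sel3$rejected_fraction, 0)
  expect_equal(sel3$gametes, gd)
  # idempotence
  sel4 <- select_pollen(REG, sel$gametes, FND$`511L`)
  expect_equal(sel4$gametes, sel$gametes)
  expect_equal(sel4$rejected_fraction, 0)
})

test_that("cross matches the brute-force enumeration oracle", {
  f1 <- F1_W22x511L()
  cases <- list(
    list(m = FND$W22, d = FND$`511L`),          # F1 production
    list(m = FND$`511L`, d = f1),               # selection on Ga2-S silk
    list(m = f1, d = FND$W22),                  # no barrier on F1 silk
    list(m = f1, d = f1),                       # heterozygote self
    list(m = FND$CS_homo, d = FND$Mo17),        # transgene barrier, rescued
    list(m = FND$CS_hemi, d = FND$ZYM1),        # inert hemizygous transgene
    list(m = FND$Ga1Ga2, d = FND$Ga1Ga2),       # pyramided self
    list(m = FND$Ga1Ga2, d = FND$Mo17),         # fails the Ga1 system
    list(m = FND$NIL_ga2_hybrid, d = FND$ZYM1)  # color marker cross
  )
  for (cs in cases) {
    od <- cross(REG, cs$m, pollen_pool(cs$d))
    oracle <- oracle_cross(REG, cs$m, cs$d)
    if (length(oracle) == 0L) {
      expect_length(od$genotypes, 0)
      expect_identical(od$rejected_pollen_fraction, 1)
    } else {
      expect_same_dist(dist_as_vector(od), oracle)
      expect_equal(sum(od$prob), 1)
    }
  }
})

test_that("paper backcrosses and the Mendelian limit come out exactly", {
  f1 <- F1_W22x511L()
  # selection backcross: only Ga2-S transmitted
  od <- cross(REG, FND$`511L`, pollen_pool(f1))
  expect_length(od$genotypes, 1)
  expect_identical(locus_genotype_label(od$genotypes[[1]], "Ga2"),
                   "Ga2-S/Ga2-S")
  expect_equal(od$rejected_pollen_fraction, 0.5)
  # no barrier: 1:1 at Ga2
  od2 <- cross(REG, FND$W22, pollen_pool(f1))
  lab <- vapply(od2$genotypes, locus_genotype_label, character(1),
                locus = "Ga2")
  expect_setequal(lab, c("Ga2-S/ga2", "ga2/ga2"))
  expect_equal(od2$prob, c(0.5, 0.5))
  # F2 of a neutral heterozygote: 1:2:1
  od3 <- cross(REG, f1, pollen_pool(f1))
  lab3 <- vapply(od3$genotypes, locus_genotype_label, character(1),
                 locus = "Ga2")
  p3 <- stats::setNames(od3$prob, lab3)
  expect_equal(p3[["Ga2-S/Ga2-S"]], 0.25)
  expect_equal(p3[["Ga2-S/ga2"]], 0.5)
  expect_equal(p3[["ga2/ga2"]], 0.25)
})

test_that("cross is invariant to mixed-pool component order", {
  pool_ab <- pollen_pool(list(FND$ZYM1, FND$Mo17), c(0.3, 0.7))
  pool_ba <- pollen_pool(list(FND$Mo17, FND$ZYM1), c(0.7, 0.3))
  for (m in list(FND$CS_homo, FND$W22, FND$`511L`)) {
    a <- dist_as_vector(cross(REG, m, pool_ab))
    b <- dist_as_vector(cross(REG, m, pool_ba))
    expect_same_dist(a, b)
  }
})

test_that("seed_set implements the saturation model and threshold", {
  f1 <- F1_W22x511L()
  # half-compatible donor pool still fills the ear
  ss <- seed_set(REG, FND$`511L`, pollen_pool(f1), ovules = 300)
  expect_identical(ss$klass, "full")
  expect_identical(ss$expected_seeds, 300)
  expect_equal(ss$compatible_fraction, 0.5)
  # complete exclusion
  ss2 <- seed_set(REG, FND$`511L`, pollen_pool(FND$W22), ovules = 300)
  expect_identical(ss2$klass, "low")
  expect_identical(ss2$expected_seeds, 0)
  # contamination produces the sub-threshold trickle
  ss3 <- seed_set(REG, FND$`511L`, pollen_pool(FND$W22), ovules = 300,
                  contamination = 0.01)
  expect_equal(ss3$expected_seeds, 3)
  expect_identical(ss3$klass, "low")
  expect_error(seed_set(REG, FND$`511L`, pollen_pool(FND$W22),
                        ovules = 0), "ovules")
})

test_that("ear_composition reproduces the transgenic color readouts", {
  pools <- pollen_pool(list(FND$ZYM1, FND$Mo17),
                       application = "sequential")
  expect_equal(ear_composition(REG, FND$CS_homo, pools),
               c(yellow = 1))
  mixed <- ear_composition(REG, FND$CS_hemi, pools)
  expect_equal(mixed[["purple"]], 0.5)
  expect_equal(mixed[["yellow"]], 0.5)
  # barrier-free mother, 50:50 mixed pool
  free <- ear_composition(REG, FND$NIL_ga2_hybrid,
                          pollen_pool(list(FND$ZYM1,
                                           FND$NIL_ga2_hybrid)))
  expect_equal(free[["purple"]], 0.5)
  expect_equal(free[["yellow"]], 0.5)
  # barren ear is an empty composition, not an error
  barren <- ear_composition(REG, FND$`511L`, pollen_pool(FND$ZYM1))
  expect_length(barren, 0)
})

test_that("population selfing mixes per-genotype selfs correctly", {
  f1 <- F1_W22x511L()
  bc1 <- cross(REG, f1, pollen_pool(FND$W22))
  bc2 <- self_population(REG, bc1)
  lab <- vapply(bc2$genotypes, locus_genotype_label, character(1),
                locus = "Ga2")
  p <- stats::setNames(bc2$prob, lab)
  expect_equal(p[["Ga2-S/Ga2-S"]], 1 / 8)
  expect_equal(p[["Ga2-S/ga2"]], 1 / 4)
  expect_equal(p[["ga2/ga2"]], 5 / 8)
  expect_identical(attr(bc2, "sterile_fraction"), 0)
})
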