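test_that("classify_haplotype is total and exhaustive over the flag square", {
  expect_identical(classify_haplotype(haplotype("Ga2", TRUE, TRUE)), "S")
  expect_identical(classify_haplotype(haplotype("Ga2", TRUE, FALSE)), "M")
  expect_identical(classify_haplotype(haplotype("Ga2", FALSE, FALSE)), "wt")
  fo <- classify_haplotype(haplotype("Ga2", FALSE, TRUE))
  expect_identical(as.character(fo), "Fonly")
  expect_true(attr(fo, "flagged"))
  # registry alleles map onto the nomenclature
  expect_identical(
    as.character(classify_haplotype(allele_haplotype(REG, "Ga2", "Ga2-S"))), "S")
  expect_identical(
    as.character(classify_haplotype(allele_haplotype(REG, "Ga2", "Ga2-M"))), "M")
  expect_identical(
    as.character(classify_haplotype(allele_haplotype(REG, "Ga2F_Tg", "Ga2F-Tg"))),
    "Fonly")
})

test_that("silk_barrier follows the sporophytic dose rule", {
  f1 <- F1_W22x511L()
  expect_true(silk_barrier(REG, FND$`511L`, "Ga2"))
  expect_false(silk_barrier(REG, f1, "Ga2"))          # heterozygote: recessive
  expect_false(silk_barrier(REG, FND$W22, "Ga2"))
  # transgene dose counts at its own locus
  expect_false(silk_barrier(REG, FND$CS_hemi, "Ga2F_Tg"))
  expect_true(silk_barrier(REG, FND$CS_homo, "Ga2F_Tg"))
  # dose threshold 1 turns the heterozygote barrier on
  reg1 <- ga2_registry(female_dose_threshold = 1)
  f1b <- genotype(reg1, c(Ga2 = "Ga2-S"), c(Ga2 = "ga2"))
  expect_true(silk_barrier(reg1, f1b, "Ga2"))
  expect_error(silk_barrier(REG, FND$W22, "NoSuchLocus"), "unknown locus")
  expect_error(silk_barrier(REG, FND$W22, "R1"), "not a UCI locus")
})

test_that("silk_barrier depends only on the silk genotype", {
  # same silk queried in different pollen contexts: barrier unchanged
  expect_true(silk_barrier(REG, FND$`511L`, "Ga2"))
  for (p in list(FND$W22, FND$Mo17, FND$`511L`))
    expect_true(silk_barrier(REG, FND$`511L`, "Ga2"))
})

test_that("pollen_compatible applies the per-system gametophytic rule", {
  g_ga2 <- c(Ga2 = "ga2", Ga1 = "ga1", Ga2P_Tg = "-", Ga2F_Tg = "-",
             R1 = "r1-yellow")
  g_S <- replace(g_ga2, "Ga2", "Ga2-S")
  g_M <- replace(g_ga2, "Ga2", "Ga2-M")
  g_Ga1 <- replace(g_ga2, "Ga1", "Ga1-S")
  expect_false(pollen_compatible(REG, g_ga2, FND$`511L`))
  expect_true(pollen_compatible(REG, g_S, FND$`511L`))
  # M-haplotype pollen overcomes the transgene-raised barrier (same system)
  expect_true(pollen_compatible(REG, g_M, FND$CS_homo))
  expect_false(pollen_compatible(REG, g_ga2, FND$CS_homo))
  # barrier-free silk accepts everything
  for (g in list(g_ga2, g_S, g_M, g_Ga1))
    expect_true(pollen_compatible(REG, g, FND$W22))
  # pyramided silk needs P in both systems
  expect_false(pollen_compatible(REG, g_Ga1, FND$Ga1Ga2))
  expect_false(pollen_compatible(REG, g_S, FND$Ga1Ga2))
  expect_true(pollen_compatible(REG, replace(g_S, "Ga1", "Ga1-S"),
                                FND$Ga1Ga2))
})

test_that("pollen_compatible is monotone in P flags and barrier loci", {
  base <- c(Ga2 = "ga2", Ga1 = "ga1", Ga2P_Tg = "-", Ga2F_Tg = "-",
            R1 = "r1-yellow")
  p_upgrades <- list(c(Ga2 = "Ga2-M"), c(Ga1 = "Ga1-M"),
                     c(Ga2P_Tg = "Ga2P-Tg"))
  silks <- list(FND$W22, FND$`511L`, FND$Ga1Ga2, FND$CS_homo,
                FND$CS_hemi)
  gametes <- list(base, replace(base, "Ga2", "Ga2-S"),
                  replace(base, "Ga1", "Ga1-M"))
  for (g in gametes) {
    for (silk in silks) {
      ok <- pollen_compatible(REG, g, silk)
      for (up in p_upgrades) {
        g2 <- replace(g, names(up), up)
        if (ok) expect_true(pollen_compatible(REG, g2, silk))
      }
    }
  }
  # adding an active barrier never turns incompatible into compatible:
  # every gamete incompatible with 511L stays incompatible with the
  # Ga1+Ga2 double-barrier silk
  for (g in gametes) {
    if (!pollen_compatible(REG, g, FND$`511L`))
      expect_false(pollen_compatible(REG, g, FND$Ga1Ga2))
  }
})

test_that("with all barriers inactive every gamete is compatible", {
  alleles <- REG$alleles
  silks <- list(FND$W22, FND$Mo17, FND$CS_hemi, F1_W22x511L())
  combos <- expand.grid(Ga2 = alleles$allele[alleles$locus_id == "Ga2"],
                        Ga1 = alleles$allele[alleles$locus_id == "Ga1"],
                        stringsAsFactors = FALSE)
  for (silk in silks) {
    expect_length(active_barrier_systems(REG, silk), 0)
    for (i in seq_len(nrow(combos))) {
      g <- c(Ga2 = combos$Ga2[i], Ga1 = combos$Ga1[i], Ga2P_Tg = "-",
             Ga2F_Tg = "-", R1 = "r1-yellow")
      expect_true(pollen_compatible(REG, g, silk))
    }
  }
})

test_that("genotype construction validates and labels correctly", {
  g <- founder_genotype(REG, Ga2 = c("Ga2-S", "ga2"))
  expect_identical(locus_genotype_label(g, "Ga2"), "Ga2-S/ga2")
  expect_identical(locus_genotype_label(g, "R1"), "r1-yellow/r1-yellow")
  expect_error(founder_genotype(REG, Ga2 = "not-an-allele"),
               "unknown allele")
  expect_error(founder_genotype(REG, Zz = "x"), "unknown locus")
  # unordered aggregation: phase-swapped genotypes share a key
  g2 <- founder_genotype(REG, Ga2 = c("ga2", "Ga2-S"))
  expect_identical(genotype_key(g), genotype_key(g2))
})

test_that("registry validation rejects misconfiguration", {
  expect_error(ga2_registry(female_dose_threshold = 3),
               "female_dose_threshold")
  expect_error(ga2_registry(male_mode = "telepathic"), "male_mode")
  expect_error(ga2_registry(female_mode = "psychic"), "female_mode")
})
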