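# Shared fixtures and the independent brute-force cross oracle.

REG <- ga2_registry()
FND <- uci_founders(REG)

F1_W22x511L <- function(reg = REG, fnd = FND)
  cross(reg, fnd$W22, pollen_pool(fnd$`511L`))$genotypes[[1]]

# minimal registry of two neutral linked loci at distance d (cM)
linked_registry <- function(d_cM) {
  loci <- data.frame(
    locus_id = c("A", "B"), type = "aux", system = NA_character_,
    male_mode = NA_character_, female_mode = NA_character_,
    female_dose_threshold = NA_integer_, chromosome = "1",
    position_cM = c(0, d_cM), stringsAsFactors = FALSE)
  alleles <- data.frame(
    locus_id = c("A", "A", "B", "B"),
    allele = c("A1", "A2", "B1", "B2"),
    P = FALSE, F = FALSE, kernel_color = NA_character_,
    resistant = FALSE, default = c(TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  uci_registry(loci, alleles)
}

# ---------------------------------------------------------------------
# Brute-force oracle: exhaustive enumeration over all gamete pairs for
# unlinked loci, with the compatibility rule re-derived directly from
# the registry tables.  Written independently of the cross engine; only
# genotype_key() is shared (it is representation, not logic).
# ---------------------------------------------------------------------

oracle_allele_flag <- function(reg, locus, allele, flag) {
  a <- reg$alleles
  a[[flag]][a$locus_id == locus & a$allele == allele]
}

oracle_gametes <- function(reg, g) {
  # all 2^L equally likely haploid picks (valid for unlinked loci only)
  loci <- reg$loci$locus_id
  picks <- expand.grid(rep(list(1:2), length(loci)))
  out <- lapply(seq_len(nrow(picks)), function(i) {
    al <- vapply(seq_along(loci), function(j) {
      if (picks[i, j] == 1L) g$h1[[loci[j]]] else g$h2[[loci[j]]]
    }, character(1))
    names(al) <- loci
    al
  })
  list(gametes = out, prob = rep(1 / nrow(picks), nrow(picks)))
}

oracle_active_systems <- function(reg, silk) {
  ld <- reg$loci[reg$loci$type == "uci", ]
  sys <- character(0)
  for (i in seq_len(nrow(ld))) {
    l <- ld$locus_id[i]
    dose <- oracle_allele_flag(reg, l, silk$h1[[l]], "F") +
      oracle_allele_flag(reg, l, silk$h2[[l]], "F")
    if (!is.na(ld$female_mode[i]) && ld$female_mode[i] == "sporophytic" &&
        dose >= ld$female_dose_threshold[i])
      sys <- c(sys, ld$system[i])
  }
  unique(sys)
}

oracle_pollen_ok <- function(reg, gamete, silk) {
  ld <- reg$loci[reg$loci$type == "uci", ]
  for (s in oracle_active_systems(reg, silk)) {
    loci_s <- ld$locus_id[ld$system == s]
    hasP <- any(vapply(loci_s, function(l)
      oracle_allele_flag(reg, l, gamete[[l]], "P"), logical(1)))
    if (!hasP) return(FALSE)
  }
  TRUE
}

# exhaustive offspring distribution of mother x single donor,
# returned as a named probability vector keyed by genotype_key()
oracle_cross <- function(reg, mother, donor) {
  mg <- oracle_gametes(reg, mother)
  pg <- oracle_gametes(reg, donor)
  acc <- list()
  for (i in seq_along(mg$gametes)) {
    for (j in seq_along(pg$gametes)) {
      if (!oracle_pollen_ok(reg, pg$gametes[[j]], mother)) next
      g <- structure(list(h1 = mg$gametes[[i]], h2 = pg$gametes[[j]]),
                     class = "uci_genotype")
      k <- genotype_key(g)
      acc[[k]] <- (acc[[k]] %||% 0) + mg$prob[i] * pg$prob[j]
    }
  }
  if (length(acc) == 0L) return(numeric(0))
  v <- unlist(acc)
  v / sum(v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dist_as_vector <- function(od) {
  stats::setNames(od$prob,
                  vapply(od$genotypes, genotype_key, character(1)))
}

expect_same_dist <- function(engine, oracle, tol = 1e-12) {
  expect_setequal(names(engine), names(oracle))
  expect_equal(engine[names(oracle)], oracle, tolerance = tol,
               ignore_attr = TRUE)
}
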