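#' Is the silk barrier active at a locus?
#'
#' Sporophytic rule: the diploid silk genotype expresses a barrier at a
#' UCI locus iff its allele dose of the female determinant F at that
#' locus reaches the locus's \code{female_dose_threshold} (default 2,
#' which makes the barrier behave recessively and leaves a hemizygous
#' female-determinant transgene inert).  Under a gametophytic female
#' architecture there is no plant-level barrier (selection moves to the
#' ovule; see \code{\link{cross}}), so this returns FALSE.
#'
#' The barrier depends only on the silk genotype, never on the pollen.
#'
#' @param registry a \code{uci_registry}.
#' @param g silk (maternal) genotype.
#' @param locus UCI locus id.
#' @return logical
#' @export
silk_barrier <- function(registry, g, locus) {
  row <- locus_row(registry, locus)
  if (row$type != "uci") stop("locus '", locus, "' is not a UCI locus")
  if (row$female_mode == "gametophytic") return(FALSE)
  dose_of(registry, g, locus, "F") >= row$female_dose_threshold
}

#' Systems with an active silk barrier on a genotype
#'
#' A system's barrier is active if any of its loci passes
#' \code{\link{silk_barrier}}.
#' @param registry a \code{uci_registry}.
#' @param g silk genotype.
#' @return character vector of system ids (possibly empty)
#' @export
active_barrier_systems <- function(registry, g) {
  loci <- registry$loci[registry$loci$type == "uci" &
                          registry$loci$female_mode == "sporophytic", ]
  on <- vapply(loci$locus_id, function(l) silk_barrier(registry, g, l),
               logical(1))
  unique(loci$system[on])
}

#' Does a haploid allele set carry the male determinant in a system?
#' @keywords internal
gamete_has_P <- function(registry, alleles, system) {
  loci <- registry$loci$locus_id[registry$loci$type == "uci" &
                                   !is.na(registry$loci$system) &
                                   registry$loci$system == system]
  any(vapply(loci, function(l)
    allele_flag(registry, l, alleles[[l]], "P"), logical(1)))
}

#' Does a haploid allele set carry the female determinant in a system?
#' @keywords internal
gamete_has_F <- function(registry, alleles, system) {
  loci <- registry$loci$locus_id[registry$loci$type == "uci" &
                                   !is.na(registry$loci$system) &
                                   registry$loci$system == system]
  any(vapply(loci, function(l)
    allele_flag(registry, l, alleles[[l]], "F"), logical(1)))
}

#' Diploid genotype carries P in a system (for sporophytic male action)
#' @keywords internal
genotype_has_P <- function(registry, g, system) {
  gamete_has_P(registry, as.list(g$h1), system) ||
    gamete_has_P(registry, as.list(g$h2), system)
}

#' Gametophytic pollen-silk compatibility
#'
#' A pollen grain is judged by its own haploid content: it is compatible
#' with a silk iff, for every system in which the silk expresses an
#' active barrier, the grain carries a P-bearing allele at some locus of
#' that system.  Silks with no active barrier accept everything (the
#' Mendelian limit).
#'
#' @param registry a \code{uci_registry}.
#' @param gamete named character vector (or list), locus id -> allele.
#' @param silk maternal \code{uci_genotype}.
#' @return logical
#' @export
pollen_compatible <- function(registry, gamete, silk) {
  gamete <- as.list(gamete)
  systems <- active_barrier_systems(registry, silk)
  for (s in systems) {
    if (!gamete_has_P(registry, gamete, s)) return(FALSE)
  }
  TRUE
}

#' Male-determinant action mode of a system
#'
#' "sporophytic" if any UCI locus of the system is registered with
#' sporophytic male action, else "gametophytic".
#' @keywords internal
system_male_mode <- function(registry, system) {
  modes <- registry$loci$male_mode[registry$loci$type == "uci" &
                                     !is.na(registry$loci$system) &
                                     registry$loci$system == system]
  if (any(modes == "sporophytic")) "sporophytic" else "gametophytic"
}

#' Systems under gametophytic female action (architecture variants)
#' @keywords internal
gametophytic_female_systems <- function(registry) {
  loci <- registry$loci[registry$loci$type == "uci" &
                          registry$loci$female_mode == "gametophytic", ]
  unique(loci$system)
}
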