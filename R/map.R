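#' Map distance to recombination fraction
#'
#' Haldane (no interference): r = (1 - exp(-2d/100)) / 2.
#' Kosambi: r = tanh(2d/100) / 2.
#'
#' @param d map distance in centimorgans (>= 0); vectorized.
#' @param map_function "haldane" (default) or "kosambi".
#' @return recombination fraction in [0, 0.5)
#' @export
recomb_fraction <- function(d, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(is.na(d)) || any(d < 0)) stop("map distance must be >= 0")
  switch(map_function,
         haldane = (1 - exp(-2 * d / 100)) / 2,
         kosambi = tanh(2 * d / 100) / 2)
}

#' Recombination fraction between two registered loci
#'
#' Loci on different chromosomes (or with no chromosome assignment)
#' assort independently (r = 0.5); same-chromosome loci use the map
#' function on their cM separation.
#' @keywords internal
locus_pair_r <- function(registry, locus_a, locus_b,
                         map_function = "haldane") {
  a <- locus_row(registry, locus_a)
  b <- locus_row(registry, locus_b)
  if (is.na(a$chromosome) || is.na(b$chromosome) ||
      a$chromosome != b$chromosome) return(0.5)
  recomb_fraction(abs(a$position_cM - b$position_cM), map_function)
}
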