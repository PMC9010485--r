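#' Marker panel for fine-mapping simulation
#'
#' An ordered set of codominant markers spanning a determinant locus,
#' with physical positions converted to map positions by a local
#' cM-per-Mb rate.  Only interval \emph{widths} are anchored to the
#' published physical sizes; absolute positions and the rate are fixture
#' assumptions (configuration, never hardcoded in logic).
#'
#' @param markers data.frame with columns \code{marker},
#'   \code{pos_Mb} (strictly increasing).
#' @param determinant_pos_Mb physical position of the determinant,
#'   strictly inside the panel.
#' @param rate_cM_per_Mb local genetic-to-physical rate (default 0.2).
#' @param donor_allele,other_allele allele labels of the two founders.
#' @param determinant name of the determinant locus.
#' @return object of class \code{marker_panel}.
#' @export
marker_panel <- function(markers, determinant_pos_Mb,
                         rate_cM_per_Mb = 0.2,
                         donor_allele = "511L", other_allele = "W22",
                         determinant = "det") {
  stopifnot(is.data.frame(markers),
            all(c("marker", "pos_Mb") %in% names(markers)))
  if (any(diff(markers$pos_Mb) <= 0))
    stop("marker positions must be strictly increasing")
  if (determinant_pos_Mb <= min(markers$pos_Mb) ||
      determinant_pos_Mb >= max(markers$pos_Mb))
    stop("determinant must lie strictly inside the marker panel")
  markers$pos_cM <- markers$pos_Mb * rate_cM_per_Mb
  structure(list(markers = markers,
                 determinant = determinant,
                 determinant_pos_Mb = determinant_pos_Mb,
                 determinant_pos_cM = determinant_pos_Mb *
                   rate_cM_per_Mb,
                 rate_cM_per_Mb = rate_cM_per_Mb,
                 donor_allele = donor_allele,
                 other_allele = other_allele),
            class = "marker_panel")
}

#' Default M1..M11 panel around a Ga2 determinant
#'
#' Physical positions place M8 - M5 = 1.21 Mb and M8 - M3 = 1.70 Mb, the
#' widths of the published mapping intervals; the male determinant sits
#' between M5 and M8, the female determinant between M3 and M8.
#'
#' @param determinant "male" or "female".
#' @param rate_cM_per_Mb local rate (default 0.2).
#' @return \code{marker_panel}
#' @export
default_marker_panel <- function(determinant = c("male", "female"),
                                 rate_cM_per_Mb = 0.2) {
  determinant <- match.arg(determinant)
  m <- data.frame(
    marker = paste0("M", 1:11),
    pos_Mb = c(0.00, 2.00, 3.51, 3.80, 4.00, 4.40, 4.80, 5.21, 6.20,
               7.50, 9.00))
  pos <- if (determinant == "male") 4.60 else 4.70
  marker_panel(m, determinant_pos_Mb = pos,
               rate_cM_per_Mb = rate_cM_per_Mb,
               determinant = paste0("Ga2", if (determinant == "male")
                 "P" else "F"))
}

#' Recombination fraction between a panel marker and the determinant
#' @param panel \code{marker_panel}.
#' @param marker marker name.
#' @param map_function map function name.
#' @return numeric r
#' @export
marker_det_r <- function(panel, marker, map_function = "haldane") {
  i <- match(marker, panel$markers$marker)
  if (is.na(i)) stop("unknown marker '", marker, "'")
  recomb_fraction(abs(panel$markers$pos_cM[i] - panel$determinant_pos_cM),
                  map_function)
}

#' Expected recombinant count between two loci
#'
#' \code{n * r(d)}.  Under complete gametic selection at the
#' determinant, this is also the expected number of survivors carrying
#' the non-donor allele at a flanking marker at distance d.
#'
#' @param n number screened (>= 0).
#' @param d map distance in cM (>= 0).
#' @param map_function map function name.
#' @return expected count
#' @export
expected_recombinants <- function(n, d, map_function = "haldane") {
  stopifnot(n >= 0)
  n * recomb_fraction(d, map_function)
}

# simulate n meioses of a fully heterozygous parent (donor alleles in
# coupling) along ordered cM positions; returns n x L matrix of logicals
# (TRUE = donor allele), Haldane model, no interference.
sim_meioses <- function(n, pos_cM, map_function = "haldane") {
  L <- length(pos_cM)
  r <- if (L > 1) recomb_fraction(diff(pos_cM), map_function)
       else numeric(0)
  m <- matrix(FALSE, n, L)
  m[, 1] <- stats::runif(n) < 0.5
  for (j in seq_along(r)) {
    switch_ <- stats::runif(n) < r[j]
    m[, j + 1] <- xor(m[, j], switch_)
  }
  m
}

new_screen <- function(panel, calls, det_carrier, phenotype,
                       selection, carrier_phenotype = "C") {
  donor <- cbind(calls == panel$donor_allele, det_carrier)
  recomb <- which(apply(donor, 1, function(x) any(x != x[1])))
  structure(list(n_screened = nrow(calls), panel = panel, calls = calls,
                 det_carrier = det_carrier, phenotype = phenotype,
                 selection = selection, recombinants = recomb,
                 carrier_phenotype = carrier_phenotype),
            class = "uci_screen")
}

#' @export
print.uci_screen <- function(x, ...) {
  cat("<uci_screen> n = ", x$n_screened, ", markers = ",
      nrow(x$panel$markers), ", recombinants = ",
      length(x$recombinants),
      if (x$selection) " (gametic selection on)" else "", "\n", sep = "")
  invisible(x)
}

#' Simulate a selection-based (homogeneous-population) mapping screen
#'
#' Simulates n informative meioses of the donor x wildtype F1 across the
#' marker panel.  With \code{selection = TRUE} only gametes carrying the
#' donor determinant allele survive (complete gametophytic pollen
#' selection), so the determinant allele is fixed among survivors and
#' phenotyping is unnecessary; marker-determinant discordances among
#' survivors occur at rate r(marker, determinant).
#'
#' @param n number of surviving individuals to simulate.
#' @param panel a \code{marker_panel}.
#' @param selection apply gametic selection at the determinant.
#' @param seed RNG seed.
#' @param map_function map function name.
#' @return \code{uci_screen}: per-individual marker calls (character
#'   matrix of founder allele labels), determinant carrier status,
#'   recombinant indices.
#' @export
simulate_screen <- function(n, panel, selection = TRUE, seed = 1,
                            map_function = "haldane") {
  stopifnot(inherits(panel, "marker_panel"), n >= 1)
  pos <- c(panel$markers$pos_cM, panel$determinant_pos_cM)
  ord <- order(pos)
  with_seed(seed, {
    if (selection) {
      got <- 0L; keep <- list()
      while (got < n) {
        batch <- max(1000L, ceiling((n - got) * 2.2))
        m <- sim_meioses(batch, pos[ord], map_function)
        m <- m[, order(ord), drop = FALSE]  # back to input order
        det <- m[, length(pos)]
        m <- m[det, , drop = FALSE]
        keep[[length(keep) + 1L]] <- m
        got <- got + nrow(m)
      }
      m <- do.call(rbind, keep)[seq_len(n), , drop = FALSE]
    } else {
      m <- sim_meioses(n, pos[ord], map_function)
      m <- m[, order(ord), drop = FALSE]
    }
    L <- nrow(panel$markers)
    calls <- matrix(ifelse(m[, seq_len(L)], panel$donor_allele,
                           panel$other_allele), n, L)
    colnames(calls) <- panel$markers$marker
    det_carrier <- m[, L + 1L]
    new_screen(panel, calls, det_carrier,
               phenotype = ifelse(det_carrier, "C", "CI"),
               selection = selection)
  })
}

#' Simulate the genotype-plus-phenotype (female determinant) screen
#'
#' The screened population is the (wildtype x donor) female x donor male
#' backcross: the heterozygous maternal silk has no barrier and the
#' donor father is homozygous, so offspring genotype at every panel
#' locus is maternal gamete + donor allele, segregating heterozygous :
#' homozygous-donor at 1:1.  Each plant is test-pollinated with wildtype
#' pollen: homozygous-barrier plants set no seed ("CI"), heterozygotes
#' set full seed ("C").  Recombinants are genotype-phenotype (and
#' marker-marker) discordances.
#'
#' @param n plants screened.
#' @param panel \code{marker_panel} (female determinant).
#' @param seed RNG seed.
#' @param map_function map function name.
#' @return \code{uci_screen}; \code{calls} hold the maternal gamete
#'   allele (the informative one; the paternal allele is constant
#'   donor), so "511L" calls mean a homozygous-donor plant genotype.
#' @export
simulate_female_screen <- function(n, panel, seed = 1,
                                   map_function = "haldane") {
  sr <- simulate_screen(n, panel, selection = FALSE, seed = seed,
                        map_function = map_function)
  # phenotype from the diploid genotype: maternal donor gamete at the
  # determinant => homozygous barrier => no seed on wildtype pollination
  sr$phenotype <- ifelse(sr$det_carrier, "CI", "C")
  sr$carrier_phenotype <- "CI"
  sr$selection <- FALSE
  sr
}

#' Narrow the determinant interval from recombinant constraints
#'
#' Each informative recombinant (single crossover inside the panel)
#' constrains the determinant to the donor-allele side of its breakpoint
#' if it carries the determinant (phenotype "C" in a pollen screen;
#' genotype-discordant compatible plants in the female screen), or to
#' the non-donor side if it does not ("CI").  The refined interval is
#' the intersection of all constraints; recombinants with multiple
#' crossovers are uninformative for single-interval narrowing and are
#' counted in \code{n_complex}.
#'
#' @param sr a \code{uci_screen}, or a character matrix of marker calls
#'   (columns in panel order) for the recombinants only.
#' @param phenotypes per-recombinant calls "C"/"CI"; defaults to the
#'   screen's own phenotype column.
#' @param panel required if \code{sr} is a plain matrix.
#' @param carrier_phenotype which phenotype call marks a chromosome
#'   carrying the determinant donor allele: "C" in a pollen
#'   (male-determinant) screen, "CI" in the female screen where the
#'   homozygous-barrier plant is the incompatible one.  Defaults to the
#'   screen's own convention.
#' @return list(left, right, left_index, right_index, supporting,
#'   n_complex)
#' @export
localize <- function(sr, phenotypes = NULL, panel = NULL,
                     carrier_phenotype = NULL) {
  if (inherits(sr, "uci_screen")) {
    panel <- sr$panel
    idx <- sr$recombinants
    calls <- sr$calls[idx, , drop = FALSE]
    if (is.null(phenotypes)) phenotypes <- sr$phenotype[idx]
    if (is.null(carrier_phenotype))
      carrier_phenotype <- sr$carrier_phenotype %||% "C"
    ids <- idx
  } else {
    if (is.null(panel)) stop("panel required with a plain call matrix")
    calls <- sr
    if (is.null(phenotypes)) stop("phenotypes required")
    if (is.null(carrier_phenotype)) carrier_phenotype <- "C"
    ids <- seq_len(nrow(calls))
  }
  stopifnot(nrow(calls) == length(phenotypes),
            all(phenotypes %in% c("C", "CI")))
  mk <- panel$markers$marker
  L <- length(mk)
  lo <- 1L; hi <- L          # marker indices bounding the determinant
  lo_by <- NA; hi_by <- NA
  supporting <- integer(0); n_complex <- 0L
  for (i in seq_len(nrow(calls))) {
    donor <- calls[i, ] == panel$donor_allele
    bp <- which(diff(donor) != 0)
    if (length(bp) == 0L) next          # non-recombinant: no constraint
    if (length(bp) > 1L) { n_complex <- n_complex + 1L; next }
    donor_left <- donor[1]
    carrier <- phenotypes[i] == carrier_phenotype
    # determinant on donor side if carrier, else non-donor side
    det_left <- (carrier && donor_left) || (!carrier && !donor_left)
    if (det_left) {
      if (bp + 1L < hi) { hi <- bp + 1L; hi_by <- ids[i] }
    } else {
      if (bp > lo) { lo <- bp; lo_by <- ids[i] }
    }
    supporting <- c(supporting, ids[i])
  }
  if (lo >= hi)
    stop("contradictory recombinants: lower bound ", mk[lo],
         " (individual ", lo_by, ") >= upper bound ", mk[hi],
         " (individual ", hi_by, "); check genotyping/phenotyping",
         call. = FALSE)
  list(left = mk[lo], right = mk[hi], left_index = lo, right_index = hi,
       supporting = supporting, n_complex = n_complex)
}

#' Marker-assisted backcross (NIL construction) simulator
#'
#' Single-seed descent with foreground selection: each backcross
#' generation keeps the donor target segment heterozygous (selection on
#' foreground markers) while each unlinked background donor allele
#' survives with probability 1/2, so the expected donor background
#' fraction after g backcrosses is (1/2)^(g+1).  A final selfing fixes
#' the foreground segment homozygous with probability 1/4 per seed.
#'
#' @param generations number of backcross generations (>= 1).
#' @param n_background number of unlinked background loci simulated.
#' @param seed RNG seed.
#' @return list(per_generation = data.frame(generation,
#'   expected_donor_fraction, realized_donor_fraction, foreground),
#'   final_self_homozygous_prob = 0.25)
#' @export
backcross_program <- function(generations = 8, n_background = 400,
                              seed = 1) {
  stopifnot(generations >= 1, n_background >= 1)
  with_seed(seed, {
    het <- rep(TRUE, n_background)   # F1: all background heterozygous
    rows <- lapply(seq_len(generations), function(g) {
      het <<- het & (stats::runif(n_background) < 0.5)
      data.frame(generation = g,
                 expected_donor_fraction = 0.5^(g + 1),
                 realized_donor_fraction = 0.5 * mean(het),
                 foreground = "heterozygous")
    })
    list(per_generation = do.call(rbind, rows),
         final_self_homozygous_prob = 0.25)
  })
}
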