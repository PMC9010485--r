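#' Locus registry for UCI cross prediction
#'
#' A registry holds the architecture of every locus a genotype may carry
#' (UCI loci plus auxiliary marker/trait loci) together with the allele
#' table that maps allele labels to determinant flags and trait tags.
#'
#' Each UCI locus belongs to a \emph{system} (default: its own id).  The
#' female barrier is scored per locus (allele-dose of F at that locus)
#' but barriers and their male-determinant rescue are matched per system,
#' so a transgene copy of a female determinant raises a barrier that
#' pollen carrying the native male determinant of the same system can
#' overcome.
#'
#' @param loci data.frame with columns \code{locus_id}, \code{type}
#'   ("uci" or "aux"), \code{system}, \code{male_mode} ("gametophytic" or
#'   "sporophytic"), \code{female_mode} ("sporophytic" or "gametophytic"),
#'   \code{female_dose_threshold} (1 or 2), \code{chromosome},
#'   \code{position_cM}.
#' @param alleles data.frame with columns \code{locus_id}, \code{allele},
#'   \code{P}, \code{F} (logical determinant flags), \code{kernel_color}
#'   (\code{NA}, "purple" or "yellow"), \code{resistant} (logical,
#'   herbicide-resistance tag), \code{default} (logical; the allele used
#'   to fill unspecified loci in founder genotypes).
#' @return An object of class \code{uci_registry}.
#' @export
uci_registry <- function(loci, alleles) {
  stopifnot(is.data.frame(loci), is.data.frame(alleles))
  need_l <- c("locus_id", "type", "system", "male_mode", "female_mode",
              "female_dose_threshold", "chromosome", "position_cM")
  need_a <- c("locus_id", "allele", "P", "F", "kernel_color", "resistant",
              "default")
  if (!all(need_l %in% names(loci)))
    stop("registry loci table missing columns: ",
         paste(setdiff(need_l, names(loci)), collapse = ", "))
  if (!all(need_a %in% names(alleles)))
    stop("registry allele table missing columns: ",
         paste(setdiff(need_a, names(alleles)), collapse = ", "))
  if (anyDuplicated(loci$locus_id))
    stop("duplicate locus_id in registry")
  uci <- loci$type == "uci"
  if (!all(loci$male_mode[uci] %in% c("gametophytic", "sporophytic")))
    stop("male_mode must be 'gametophytic' or 'sporophytic'")
  if (!all(loci$female_mode[uci] %in% c("sporophytic", "gametophytic")))
    stop("female_mode must be 'sporophytic' or 'gametophytic'")
  if (!all(loci$female_dose_threshold[uci] %in% c(1L, 2L)))
    stop("female_dose_threshold must be 1 or 2")
  if (any(!is.na(loci$position_cM) & loci$position_cM < 0))
    stop("position_cM must be >= 0")
  if (!all(alleles$locus_id %in% loci$locus_id))
    stop("allele table references unregistered loci")
  for (l in loci$locus_id) {
    a <- alleles[alleles$locus_id == l, ]
    if (nrow(a) == 0L) stop("locus ", l, " has no alleles")
    if (sum(a$default) != 1L)
      stop("locus ", l, " must have exactly one default allele")
  }
  reg <- structure(list(loci = loci, alleles = alleles),
                   class = "uci_registry")
  # fast lookups: locus\rallele -> flag
  key <- paste(alleles$locus_id, alleles$allele, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (locus, allele) in registry")
  reg$P_of <- stats::setNames(alleles$P, key)
  reg$F_of <- stats::setNames(alleles$F, key)
  reg
}

#' @export
print.uci_registry <- function(x, ...) {
  cat("<uci_registry> ", nrow(x$loci), " loci, ",
      nrow(x$alleles), " alleles\n", sep = "")
  print(x$loci[, c("locus_id", "type", "system", "male_mode",
                   "female_mode", "female_dose_threshold", "chromosome",
                   "position_cM")], row.names = FALSE)
  invisible(x)
}

locus_row <- function(registry, locus) {
  i <- match(locus, registry$loci$locus_id)
  if (is.na(i))
    stop("unknown locus '", locus, "': not registered", call. = FALSE)
  registry$loci[i, ]
}

allele_flag <- function(registry, locus, allele, flag = c("P", "F")) {
  flag <- match.arg(flag)
  v <- if (flag == "P") registry$P_of else registry$F_of
  out <- unname(v[paste(locus, allele, sep = "\r")])
  if (anyNA(out))
    stop("unknown allele '", paste(allele[is.na(out)], collapse = ","),
         "' at locus '", locus, "'", call. = FALSE)
  out
}

default_allele <- function(registry, locus) {
  a <- registry$alleles
  a$allele[a$locus_id == locus & a$default][1L]
}

uci_loci <- function(registry) {
  registry$loci$locus_id[registry$loci$type == "uci"]
}

#' Default registry for the Ga2 study system
#'
#' Builds the locus registry used throughout the package: the native
#' \code{Ga2} and \code{Ga1} UCI loci, unlinked transgene surrogates for
#' the Ga2 male determinant (\code{Ga2P_Tg}, carries P only) and female
#' determinant (\code{Ga2F_Tg}, carries F plus a herbicide-resistance
#' tag), and an auxiliary kernel-color locus \code{R1} (purple dominant
#' over yellow).  Both transgene loci belong to system "Ga2".
#'
#' @param male_mode male determinant action, normally "gametophytic";
#'   "sporophytic" is provided for architecture-comparison runs only.
#' @param female_mode female determinant action, normally "sporophytic";
#'   "gametophytic" models ovule-level selection for comparisons.
#' @param female_dose_threshold number of F-bearing alleles at a locus
#'   needed for an active silk barrier (default 2: recessive behaviour).
#' @param map_rate_cM_per_Mb local genetic-to-physical rate used to place
#'   loci; a fixture assumption, not a measured value.
#' @return \code{uci_registry}
#' @export
ga2_registry <- function(male_mode = "gametophytic",
                         female_mode = "sporophytic",
                         female_dose_threshold = 2L,
                         map_rate_cM_per_Mb = 0.2) {
  thr <- as.integer(female_dose_threshold)
  loci <- data.frame(
    locus_id = c("Ga2", "Ga1", "Ga2P_Tg", "Ga2F_Tg", "R1"),
    type = c("uci", "uci", "uci", "uci", "aux"),
    system = c("Ga2", "Ga1", "Ga2", "Ga2", NA),
    male_mode = c(male_mode, male_mode, male_mode, male_mode, NA),
    female_mode = c(female_mode, female_mode, female_mode, female_mode, NA),
    female_dose_threshold = c(thr, thr, thr, thr, NA),
    chromosome = c("5", "4", "TgP", "TgF", "10"),
    position_cM = c(4.7 * map_rate_cM_per_Mb, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
  alleles <- data.frame(
    locus_id = c("Ga2", "Ga2", "Ga2",
                 "Ga1", "Ga1", "Ga1",
                 "Ga2P_Tg", "Ga2P_Tg",
                 "Ga2F_Tg", "Ga2F_Tg",
                 "R1", "R1"),
    allele = c("Ga2-S", "Ga2-M", "ga2",
               "Ga1-S", "Ga1-M", "ga1",
               "Ga2P-Tg", "-",
               "Ga2F-Tg", "-",
               "R1-purple", "r1-yellow"),
    P = c(TRUE, TRUE, FALSE,
          TRUE, TRUE, FALSE,
          TRUE, FALSE,
          FALSE, FALSE,
          FALSE, FALSE),
    F = c(TRUE, FALSE, FALSE,
          TRUE, FALSE, FALSE,
          FALSE, FALSE,
          TRUE, FALSE,
          FALSE, FALSE),
    kernel_color = c(NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                     "purple", "yellow"),
    resistant = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE,
                  FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    default = c(FALSE, FALSE, TRUE,
                FALSE, FALSE, TRUE,
                FALSE, TRUE,
                FALSE, TRUE,
                FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  uci_registry(loci, alleles)
}

#' Founder genotypes of the Ga2 study system
#'
#' @param registry a \code{uci_registry}, normally \code{ga2_registry()}.
#' @return named list of genotypes: the Ga2-S tester 511L; ga2 lines W22,
#'   B104, Zheng58, Chang7-2 and the purple-kernel ZYM1; the M-haplotype
#'   line Mo17; the Ga1-S line SDGa25; the Ga1+Ga2 double homozygote;
#'   near-isogenic Ga2-S and ga2 hybrids; and transgenic stocks (MP_T1:
#'   hemizygous male-determinant transgene in ga2 background; CS_homo /
#'   CS_hemi: homozygous / hemizygous female-determinant transgene).
#' @export
uci_founders <- function(registry = ga2_registry()) {
  g <- function(...) founder_genotype(registry, ...)
  list(
    `511L` = g(Ga2 = "Ga2-S"),
    W22 = g(),
    B104 = g(),
    Zheng58 = g(),
    `Chang7-2` = g(),
    ZYM1 = g(R1 = "R1-purple"),
    Mo17 = g(Ga2 = "Ga2-M"),
    SDGa25 = g(Ga1 = "Ga1-S"),
    Ga1Ga2 = g(Ga1 = "Ga1-S", Ga2 = "Ga2-S"),
    NIL_Ga2S_hybrid = g(Ga2 = "Ga2-S"),
    NIL_ga2_hybrid = g(),
    MP_T1 = g(Ga2P_Tg = c("Ga2P-Tg", "-")),
    MP_N = g(),
    CS_homo = g(Ga2F_Tg = "Ga2F-Tg"),
    CS_hemi = g(Ga2F_Tg = c("Ga2F-Tg", "-"))
  )
}
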