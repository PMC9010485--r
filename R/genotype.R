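#' Haplotype at a UCI locus
#'
#' A UCI-locus haplotype is a pair of boolean determinant flags: P (male
#' determinant, pollen-expressed) and F (female determinant,
#' silk-expressed).
#'
#' @param locus_id locus identifier.
#' @param P logical, carries the male determinant.
#' @param F logical, carries the female determinant.
#' @return object of class \code{uci_haplotype}.
#' @export
haplotype <- function(locus_id, P, F) {
  stopifnot(is.logical(P), is.logical(F), length(P) == 1L,
            length(F) == 1L, !is.na(P), !is.na(F))
  structure(list(locus_id = locus_id, P = P, F = F),
            class = "uci_haplotype")
}

#' Classify a haplotype into the field's S/M/wildtype nomenclature
#'
#' (P, F) -> "S"; (P, no F) -> "M"; (neither) -> "wt"; (F only) ->
#' "Fonly".  The F-only class is representable (it is what a female-
#' determinant transgene insertion is) but has never been observed as a
#' natural haplotype, since it would be self-incompatible; it is returned
#' with attribute \code{flagged = TRUE}.
#'
#' @param h a \code{uci_haplotype}.
#' @return one of "S", "M", "wt", "Fonly" (with \code{flagged} attribute
#'   on "Fonly").
#' @export
classify_haplotype <- function(h) {
  stopifnot(inherits(h, "uci_haplotype"))
  lab <- if (h$P && h$F) "S"
         else if (h$P) "M"
         else if (h$F) "Fonly"
         else "wt"
  if (lab == "Fonly") attr(lab, "flagged") <- TRUE
  lab
}

#' Haplotype carried by a registered allele
#'
#' @param registry a \code{uci_registry}.
#' @param locus locus id.
#' @param allele allele label.
#' @return \code{uci_haplotype}
#' @export
allele_haplotype <- function(registry, locus, allele) {
  haplotype(locus,
            P = allele_flag(registry, locus, allele, "P"),
            F = allele_flag(registry, locus, allele, "F"))
}

#' Construct a diploid multi-locus genotype
#'
#' A genotype is a pair of multi-locus haploid allele sets (h1, h2), one
#' per homolog set, covering every registered locus.  Phase is kept
#' internally (it matters for linked-gamete enumeration) but genotypes
#' are aggregated and compared as unordered pairs.
#'
#' @param registry a \code{uci_registry}.
#' @param h1,h2 named character vectors, locus id -> allele label.  Loci
#'   absent from both are filled with the registry default allele.
#' @return object of class \code{uci_genotype}.
#' @export
genotype <- function(registry, h1, h2) {
  loci <- registry$loci$locus_id
  bad <- setdiff(unique(c(names(h1), names(h2))), loci)
  if (length(bad) > 0)
    stop("unknown locus '", paste(bad, collapse = "', '"),
         "': not registered", call. = FALSE)
  fill <- function(h) {
    out <- vapply(loci, function(l) {
      a <- if (l %in% names(h)) h[[l]] else default_allele(registry, l)
      allele_flag(registry, l, a, "P")  # validates allele
      a
    }, character(1))
    names(out) <- loci
    out
  }
  structure(list(h1 = fill(h1), h2 = fill(h2)), class = "uci_genotype")
}

#' Founder genotype shorthand
#'
#' \code{founder_genotype(reg, Ga2 = "Ga2-S")} builds a genotype
#' homozygous \code{Ga2-S} at Ga2 and homozygous for the default allele
#' everywhere else; pass a length-2 vector for a heterozygous locus.
#'
#' @param registry a \code{uci_registry}.
#' @param ... locus = allele (homozygous) or locus = c(a1, a2).
#' @return \code{uci_genotype}
#' @export
founder_genotype <- function(registry, ...) {
  spec <- list(...)
  h1 <- h2 <- character(0)
  for (l in names(spec)) {
    a <- spec[[l]]
    if (!length(a) %in% 1:2) stop("locus ", l, ": give 1 or 2 alleles")
    h1[l] <- a[1L]
    h2[l] <- a[length(a)]
  }
  genotype(registry, h1, h2)
}

hap_string <- function(h) paste(h, collapse = ",")

#' Canonical key of a genotype (unordered pair of haplotypes)
#' @param g a \code{uci_genotype}.
#' @return character scalar
#' @export
genotype_key <- function(g) {
  paste(sort(c(hap_string(g$h1), hap_string(g$h2)), method = "radix"),
        collapse = "|")
}

#' Genotype label at one locus, e.g. "Ga2-S/ga2"
#' @param g a \code{uci_genotype}.
#' @param locus locus id.
#' @return character scalar (alleles sorted, "/"-separated)
#' @export
locus_genotype_label <- function(g, locus) {
  if (!locus %in% names(g$h1)) stop("unknown locus '", locus, "'")
  paste(sort(c(g$h1[[locus]], g$h2[[locus]]), method = "radix"),
        collapse = "/")
}

#' Count alleles at a locus satisfying a determinant flag
#' @keywords internal
dose_of <- function(registry, g, locus, flag = "F") {
  sum(allele_flag(registry, locus, c(g$h1[[locus]], g$h2[[locus]]), flag))
}

#' @export
print.uci_genotype <- function(x, ...) {
  loci <- names(x$h1)
  lab <- vapply(loci, function(l) locus_genotype_label(x, l), character(1))
  cat("<uci_genotype> ", paste(loci, lab, sep = ":", collapse = "  "),
      "\n", sep = "")
  invisible(x)
}

#' Kernel (or plant) color phenotype of a genotype
#'
#' Purple is dominant: a genotype is "purple" if any allele at any
#' auxiliary color locus carries the purple tag, else "yellow".
#' @param registry a \code{uci_registry}.
#' @param g a \code{uci_genotype}.
#' @return "purple" or "yellow"
#' @export
kernel_color <- function(registry, g) {
  a <- registry$alleles
  purple <- a[!is.na(a$kernel_color) & a$kernel_color == "purple", ]
  for (i in seq_len(nrow(purple))) {
    l <- purple$locus_id[i]
    if (purple$allele[i] %in% c(g$h1[[l]], g$h2[[l]])) return("purple")
  }
  "yellow"
}

#' Does a genotype carry at least one herbicide-resistance-tagged allele?
#' @param registry a \code{uci_registry}.
#' @param g a \code{uci_genotype}.
#' @return logical
#' @export
is_resistant <- function(registry, g) {
  a <- registry$alleles
  res <- a[a$resistant, ]
  for (i in seq_len(nrow(res))) {
    l <- res$locus_id[i]
    if (res$allele[i] %in% c(g$h1[[l]], g$h2[[l]])) return(TRUE)
  }
  FALSE
}
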