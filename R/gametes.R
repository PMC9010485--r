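#' Exact gamete distribution of a genotype
#'
#' Enumerates every distinct gamete (haploid multi-locus allele set) and
#' its probability under standard meiosis with no chiasma interference:
#' loci on different chromosomes assort independently; linked loci
#' recombine with the fraction given by the map function applied to
#' their cM separation (for heterozygous loci with intervening
#' homozygous loci the fraction is taken over the total distance, exact
#' under Haldane's no-interference model).
#'
#' @param registry a \code{uci_registry} (carries the genetic map).
#' @param g a \code{uci_genotype}.
#' @param map_function "haldane" or "kosambi".
#' @return data.frame with one character column per locus plus
#'   \code{weight}; weights sum to 1.
#' @export
gamete_distribution <- function(registry, g, map_function = "haldane") {
  ld <- registry$loci
  chrom <- ifelse(is.na(ld$chromosome),
                  paste0(".solo.", ld$locus_id), ld$chromosome)
  tables <- lapply(unique(chrom), function(ch) {
    idx <- which(chrom == ch)
    idx <- idx[order(ld$position_cM[idx])]
    loci <- ld$locus_id[idx]
    het <- vapply(loci, function(l) g$h1[[l]] != g$h2[[l]], logical(1))
    fixed <- loci[!het]
    hets <- loci[het]
    base <- as.data.frame(as.list(stats::setNames(
      vapply(fixed, function(l) g$h1[[l]], character(1)), fixed)),
      optional = TRUE, stringsAsFactors = FALSE)
    if (length(hets) == 0L) {
      base$weight <- 1
      return(base)
    }
    if (length(hets) > 16L)
      stop("too many linked heterozygous loci to enumerate (",
           length(hets), ")")
    pos <- ld$position_cM[match(hets, ld$locus_id)]
    r <- if (length(hets) > 1L)
      recomb_fraction(diff(pos), map_function) else numeric(0)
    pat <- as.matrix(expand.grid(rep(list(1:2), length(hets)),
                                 KEEP.OUT.ATTRS = FALSE))
    w <- rep(0.5, nrow(pat))
    if (length(r) > 0) {
      for (j in seq_along(r)) {
        same <- pat[, j] == pat[, j + 1L]
        w <- w * ifelse(same, 1 - r[j], r[j])
      }
    }
    out <- data.frame(matrix(NA_character_, nrow(pat), length(hets)),
                      stringsAsFactors = FALSE)
    names(out) <- hets
    for (j in seq_along(hets)) {
      l <- hets[j]
      out[[l]] <- ifelse(pat[, j] == 1L, g$h1[[l]], g$h2[[l]])
    }
    if (ncol(base) > 0)
      out <- cbind(out, base[rep(1L, nrow(out)), , drop = FALSE])
    out$weight <- w
    rownames(out) <- NULL
    out
  })
  res <- Reduce(function(a, b) {
    ia <- rep(seq_len(nrow(a)), times = nrow(b))
    ib <- rep(seq_len(nrow(b)), each = nrow(a))
    out <- cbind(a[ia, setdiff(names(a), "weight"), drop = FALSE],
                 b[ib, setdiff(names(b), "weight"), drop = FALSE])
    out$weight <- a$weight[ia] * b$weight[ib]
    rownames(out) <- NULL
    out
  }, tables)
  res <- res[, c(ld$locus_id, "weight")]
  # aggregate any duplicate allele combinations
  key <- do.call(paste, c(res[ld$locus_id], sep = "\r"))
  if (anyDuplicated(key)) {
    w <- tapply(res$weight, key, sum)
    res <- res[!duplicated(key), , drop = FALSE]
    res$weight <- as.numeric(w[do.call(paste, c(res[ld$locus_id],
                                                sep = "\r"))])
  }
  rownames(res) <- NULL
  res
}
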