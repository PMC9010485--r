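#' Noise model for synthetic field data
#'
#' @param misclassification probability that a plant's seed-set class is
#'   misscored (acts on the class label, mirroring field scoring of
#'   ears, never on the latent genotype).
#' @param contamination stray compatible-pollen fraction.
#' @param genotyping_error per-marker miscall probability.
#' @return object of class \code{noise_model}.
#' @export
noise_model <- function(misclassification = 0, contamination = 0,
                        genotyping_error = 0) {
  v <- c(misclassification, contamination, genotyping_error)
  if (any(v < 0) || any(v >= 0.5))
    stop("noise probabilities must lie in [0, 0.5)")
  structure(list(misclassification = misclassification,
                 contamination = contamination,
                 genotyping_error = genotyping_error),
            class = "noise_model")
}

# flip each element of a class-label vector to a random other class
flip_classes <- function(labels, classes, eps) {
  if (eps <= 0 || length(labels) == 0L) return(labels)
  hit <- stats::runif(length(labels)) < eps
  if (any(hit) && length(classes) > 1L) {
    labels[hit] <- vapply(labels[hit], function(l)
      sample(setdiff(classes, l), 1L), character(1))
  }
  labels
}

#' Generate synthetic class counts for a catalog design
#'
#' Draws n individuals from the design's exact predicted class
#' distribution, then applies per-individual misclassification flips.
#' With all noise at zero the data are exactly model-distributed.
#'
#' @param design_id catalog design id (or a \code{uci_design}).
#' @param n sample size (> 0).
#' @param noise a \code{noise_model}.
#' @param seed RNG seed (recorded in the result's \code{meta}).
#' @param registry optional registry override.
#' @param catalog design catalog.
#' @return \code{uci_counts} with a \code{meta} attribute (design, n,
#'   noise, seed).
#' @export
gen_counts <- function(design_id, n, noise = noise_model(), seed = 1,
                       registry = NULL, catalog = design_catalog()) {
  if (n <= 0) stop("n must be positive")
  d <- if (inherits(design_id, "uci_design")) design_id
       else catalog[[design_id]]
  if (is.null(d)) stop("unknown design '", design_id, "'")
  eo <- stats::predict(d, registry = registry)
  with_seed(derive_seed(seed, d$design_id), {
    lab <- sample(eo$classes, n, replace = TRUE, prob = eo$probabilities)
    lab <- flip_classes(lab, eo$classes, noise$misclassification)
    counts <- vapply(eo$classes, function(k) sum(lab == k), integer(1))
    out <- count_data(d$design_id, eo$classes, counts)
    attr(out, "meta") <- list(design_id = d$design_id, n = n,
                              noise = unclass(noise), seed = seed)
    out
  })
}

#' Generate a synthetic marker-genotyping table
#'
#' Simulates the requested screen population across a marker panel and
#' emits per-plant marker calls with genotyping-error flips, in the long
#' format consumed by the mapping module.
#'
#' @param population "male_screen" (gametic selection on the donor
#'   determinant) or "female_screen" (no selection; genotype +
#'   phenotype).
#' @param n plants.
#' @param panel \code{marker_panel}; default matches the population.
#' @param noise \code{noise_model}.
#' @param seed RNG seed.
#' @return data.frame(plant, marker, allele, phenotype) with a
#'   \code{meta} attribute.
#' @export
gen_marker_table <- function(population = c("male_screen",
                                            "female_screen"),
                             n, panel = NULL, noise = noise_model(),
                             seed = 1) {
  population <- match.arg(population)
  if (is.null(panel))
    panel <- default_marker_panel(if (population == "male_screen")
      "male" else "female")
  sr <- if (population == "male_screen")
    simulate_screen(n, panel, selection = TRUE,
                    seed = derive_seed(seed, population))
  else simulate_female_screen(n, panel,
                              seed = derive_seed(seed, population))
  calls <- sr$calls
  err <- noise$genotyping_error
  if (err > 0) {
    with_seed(derive_seed(seed, paste0(population, ".err")), {
      flip <- matrix(stats::runif(length(calls)) < err, nrow(calls))
      other <- ifelse(calls == panel$donor_allele, panel$other_allele,
                      panel$donor_allele)
      calls[flip] <- other[flip]
    })
  }
  out <- data.frame(
    plant = rep(seq_len(nrow(calls)), times = ncol(calls)),
    marker = rep(colnames(calls), each = nrow(calls)),
    allele = as.vector(calls),
    phenotype = rep(sr$phenotype, times = ncol(calls)),
    stringsAsFactors = FALSE)
  attr(out, "meta") <- list(population = population, n = n,
                            noise = unclass(noise), seed = seed)
  attr(out, "screen") <- sr
  out
}

#' Generate per-ear kernel-class counts
#'
#' Each ear draws \code{ovules} kernels from the exact ear-composition
#' distribution of the mother x pool cross.  On a barren ear (all pool
#' pollen rejected), stray contaminant seeds appear as
#' Binomial(ovules, contamination) kernels drawn from the unselected
#' pool's kernel classes.
#'
#' @param registry a \code{uci_registry}.
#' @param mother maternal genotype.
#' @param pool \code{pollen_pool} (or genotype).
#' @param n_ears number of ears.
#' @param ovules kernels per full ear.
#' @param noise \code{noise_model} (contamination used).
#' @param seed RNG seed.
#' @return data.frame: ear, class, count; with \code{meta} attribute.
#' @export
gen_ear_dataset <- function(registry, mother, pool, n_ears = 3,
                            ovules = 300, noise = noise_model(),
                            seed = 1) {
  pool <- as_pool(pool)
  comp <- ear_composition(registry, mother, pool)
  # unselected pool composition, for contaminant kernel classes
  raw <- vapply(pool$donors, function(d) {
    od <- cross(registry, mother, pollen_pool_unselected(d))
    if (length(od$genotypes) == 0L) return(NA_character_)
    cls <- vapply(od$genotypes, function(g) kernel_color(registry, g),
                  character(1))
    names(which.max(tapply(od$prob, cls, sum)))
  }, character(1))
  with_seed(derive_seed(seed, "ears"), {
    rows <- lapply(seq_len(n_ears), function(e) {
      if (length(comp) > 0) {
        k <- stats::rmultinom(1, ovules, comp)[, 1]
        data.frame(ear = e, class = names(comp), count = as.integer(k),
                   stringsAsFactors = FALSE)
      } else {
        n_cont <- stats::rbinom(1, ovules, noise$contamination)
        cls <- raw[!is.na(raw)]
        if (n_cont == 0L || length(cls) == 0L)
          return(data.frame(ear = e, class = "none", count = 0L,
                            stringsAsFactors = FALSE))
        pick <- sample(cls, n_cont, replace = TRUE,
                       prob = pool$proportions[!is.na(raw)])
        agg <- table(pick)
        data.frame(ear = e, class = names(agg),
                   count = as.integer(agg), stringsAsFactors = FALSE)
      }
    })
    out <- do.call(rbind, rows)
    attr(out, "meta") <- list(n_ears = n_ears, ovules = ovules,
                              noise = unclass(noise), seed = seed)
    out
  })
}

# a pool bypassing selection (used for contaminant class lookup): the
# cross of mother x donor ignoring barriers
pollen_pool_unselected <- function(donor) {
  structure(list(donors = list(donor), proportions = 1,
                 application = "mixed", sequential_weights = 1,
                 unselected = TRUE),
            class = "pollen_pool")
}
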