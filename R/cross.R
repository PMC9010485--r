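#' Pollen pool
#'
#' A pollen pool is a weighted set of donor genotypes.  With
#' \code{application = "mixed"} pollen grains compete on the silk: a
#' component's contribution to fertilization is proportional to its
#' pool proportion times the fraction of its grains passing the silk
#' barriers.  With \code{"sequential"} (e.g. one pollination followed by
#' another) each component is selected separately and the surviving
#' components are combined by \code{sequential_weights} (default equal).
#'
#' @param donors a \code{uci_genotype} or list of them.
#' @param proportions pool proportions, summing to 1 (default equal).
#' @param application "mixed" or "sequential".
#' @param sequential_weights effective fertilization weights used when
#'   \code{application = "sequential"}; default equal.
#' @return object of class \code{pollen_pool}.
#' @export
pollen_pool <- function(donors, proportions = NULL,
                        application = c("mixed", "sequential"),
                        sequential_weights = NULL) {
  application <- match.arg(application)
  if (inherits(donors, "uci_genotype")) donors <- list(donors)
  k <- length(donors)
  if (k == 0L) stop("pollen pool must be nonempty")
  if (is.null(proportions)) proportions <- rep(1 / k, k)
  if (length(proportions) != k || abs(sum(proportions) - 1) > 1e-9)
    stop("proportions must match donors and sum to 1")
  if (is.null(sequential_weights)) sequential_weights <- rep(1 / k, k)
  if (any(sequential_weights < 0) || any(sequential_weights > 1))
    stop("sequential_weights must lie in [0, 1]")
  structure(list(donors = donors, proportions = proportions,
                 application = application,
                 sequential_weights = sequential_weights),
            class = "pollen_pool")
}

as_pool <- function(x) {
  if (inherits(x, "pollen_pool")) x else pollen_pool(x)
}

#' Select pollen gametes on a silk
#'
#' Removes gametes incompatible with the silk's active barriers,
#' renormalizes the survivors, and reports the rejected mass.  Total
#' incompatibility is a valid outcome (empty table, rejected fraction
#' 1), not an error.  Selection is idempotent.
#'
#' @param registry a \code{uci_registry}.
#' @param gametes gamete table from \code{\link{gamete_distribution}}.
#' @param silk maternal genotype.
#' @return list(gametes = renormalized table, rejected_fraction)
#' @export
select_pollen <- function(registry, gametes, silk) {
  systems <- active_barrier_systems(registry, silk)
  if (length(systems) == 0L)
    return(list(gametes = gametes, rejected_fraction = 0))
  loci <- registry$loci$locus_id
  keep <- rep(TRUE, nrow(gametes))
  for (s in systems) {
    sys_loci <- loci[registry$loci$type == "uci" &
                       !is.na(registry$loci$system) &
                       registry$loci$system == s]
    hasP <- rep(FALSE, nrow(gametes))
    for (l in sys_loci)
      hasP <- hasP | allele_flag(registry, l, gametes[[l]], "P")
    keep <- keep & hasP
  }
  surv <- sum(gametes$weight[keep])
  rejected <- 1 - surv
  if (surv <= 0)
    return(list(gametes = gametes[0, , drop = FALSE],
                rejected_fraction = 1))
  out <- gametes[keep, , drop = FALSE]
  out$weight <- out$weight / surv
  rownames(out) <- NULL
  list(gametes = out, rejected_fraction = rejected)
}

# selected paternal gamete mixture for a pool on a silk
# returns list(gametes=df or NULL, surviving=per-component mass,
#              rejected_fraction, weights=per-component mix weight)
paternal_mixture <- function(registry, pool, silk,
                             map_function = "haldane") {
  pool <- as_pool(pool)
  if (isTRUE(pool$unselected)) {
    gam <- do.call(rbind, Map(function(d, p) {
      t <- gamete_distribution(registry, d, map_function)
      t$weight <- t$weight * p
      t
    }, pool$donors, pool$proportions))
    rownames(gam) <- NULL
    return(list(gametes = gam,
                surviving = rep(1, length(pool$donors)),
                rejected_fraction = 0,
                weights = pool$proportions))
  }
  systems <- active_barrier_systems(registry, silk)
  spor <- systems[vapply(systems, function(s)
    system_male_mode(registry, s) == "sporophytic", logical(1))]
  comp <- lapply(pool$donors, function(d) {
    gam <- gamete_distribution(registry, d, map_function)
    # sporophytic male action: the donor plant's diploid genotype decides
    for (s in spor) {
      if (!genotype_has_P(registry, d, s))
        return(list(gametes = gam[0, , drop = FALSE], surviving = 0))
    }
    if (length(spor) > 0) {
      # barriers with sporophytic rescue impose no per-grain filtering
      gamf <- gam
      rej <- 0
      # gametophytic systems still filter grain by grain
      gsys <- setdiff(systems, spor)
      if (length(gsys) > 0) {
        sel <- select_gametophytic(registry, gamf, gsys)
        return(sel)
      }
      return(list(gametes = gamf, surviving = 1))
    }
    sel <- select_pollen(registry, gam, silk)
    list(gametes = sel$gametes, surviving = 1 - sel$rejected_fraction)
  })
  surviving <- vapply(comp, function(x) x$surviving, numeric(1))
  rejected <- sum(pool$proportions * (1 - surviving))
  if (all(surviving <= 0))
    return(list(gametes = NULL, surviving = surviving,
                rejected_fraction = 1, weights = rep(0, length(comp))))
  if (pool$application == "mixed") {
    w <- pool$proportions * surviving
  } else {
    w <- pool$sequential_weights * as.numeric(surviving > 0)
  }
  w <- w / sum(w)
  tabs <- Map(function(x, wi) {
    if (wi <= 0 || nrow(x$gametes) == 0L) return(NULL)
    t <- x$gametes
    t$weight <- t$weight * wi
    t
  }, comp, w)
  gam <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  rownames(gam) <- NULL
  list(gametes = gam, surviving = surviving,
       rejected_fraction = rejected, weights = w)
}

# filter a gamete table on gametophytic systems only
select_gametophytic <- function(registry, gametes, systems) {
  keep <- rep(TRUE, nrow(gametes))
  for (s in systems) {
    sys_loci <- registry$loci$locus_id[registry$loci$type == "uci" &
                                         !is.na(registry$loci$system) &
                                         registry$loci$system == s]
    hasP <- rep(FALSE, nrow(gametes))
    for (l in sys_loci)
      hasP <- hasP | allele_flag(registry, l, gametes[[l]], "P")
    keep <- keep & hasP
  }
  surv <- sum(gametes$weight[keep])
  if (surv <= 0)
    return(list(gametes = gametes[0, , drop = FALSE], surviving = 0))
  out <- gametes[keep, , drop = FALSE]
  out$weight <- out$weight / surv
  list(gametes = out, surviving = surv)
}

new_population <- function(genotypes, prob, rejected = 0) {
  structure(list(genotypes = genotypes, prob = prob,
                 rejected_pollen_fraction = rejected),
            class = c("offspring_distribution", "uci_population"))
}

#' @export
print.offspring_distribution <- function(x, ...) {
  cat("<offspring distribution> ", length(x$genotypes), " genotype(s), ",
      "rejected pollen fraction ", signif(x$rejected_pollen_fraction, 4),
      "\n", sep = "")
  df <- as.data.frame(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.offspring_distribution <- function(x, ...) {
  data.frame(genotype = vapply(x$genotypes, genotype_key, character(1)),
             probability = x$prob, stringsAsFactors = FALSE)
}

#' Exact offspring distribution of a cross
#'
#' Maternal gametes are never selected; paternal gametes pass the silk's
#' barrier systems (per grain under gametophytic male action, per donor
#' plant under the sporophytic-male variant).  Under a gametophytic
#' female architecture variant, selection instead acts pairwise at the
#' ovule: a maternal gamete carrying F in a system accepts only pollen
#' carrying P in that system.  Offspring are aggregated as unordered
#' genotypes.  A fully incompatible pool yields an empty distribution
#' with \code{rejected_pollen_fraction = 1} (a barren ear, not an
#' error).
#'
#' @param registry a \code{uci_registry}.
#' @param mother maternal genotype.
#' @param pool a \code{pollen_pool} (or a genotype, taken as a
#'   single-donor pool).
#' @param map_function "haldane" or "kosambi".
#' @return object of class \code{offspring_distribution}: parallel lists
#'   \code{genotypes} / \code{prob} plus
#'   \code{rejected_pollen_fraction}.
#' @export
cross <- function(registry, mother, pool, map_function = "haldane") {
  pm <- paternal_mixture(registry, as_pool(pool), mother, map_function)
  if (is.null(pm$gametes))
    return(new_population(list(), numeric(0), rejected = 1))
  mg <- gamete_distribution(registry, mother, map_function)
  pg <- pm$gametes
  loci <- registry$loci$locus_id
  femsys <- gametophytic_female_systems(registry)
  if (length(femsys) > 0) {
    # ovule-level selection: per maternal gamete, restrict compatible pollen
    mF <- lapply(femsys, function(s)
      vapply(seq_len(nrow(mg)), function(i)
        gamete_has_F(registry, as.list(unlist(mg[i, loci])), s),
        logical(1)))
    pP <- lapply(femsys, function(s)
      vapply(seq_len(nrow(pg)), function(j)
        gamete_has_P(registry, as.list(unlist(pg[j, loci])), s),
        logical(1)))
  }
  acc <- new.env(parent = emptyenv())
  reps <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(mg))) {
    h1 <- stats::setNames(vapply(loci, function(l) mg[i, l],
                                 character(1)), loci)
    for (j in seq_len(nrow(pg))) {
      w <- mg$weight[i] * pg$weight[j]
      if (w <= 0) next
      if (length(femsys) > 0) {
        ok <- TRUE
        for (k in seq_along(femsys))
          if (mF[[k]][i] && !pP[[k]][j]) { ok <- FALSE; break }
        if (!ok) next
      }
      h2 <- stats::setNames(vapply(loci, function(l) pg[j, l],
                                   character(1)), loci)
      g <- structure(list(h1 = h1, h2 = h2), class = "uci_genotype")
      key <- genotype_key(g)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
      if (is.null(reps[[key]])) reps[[key]] <- g
    }
  }
  keys <- sort(ls(acc), method = "radix")
  prob <- vapply(keys, function(k) acc[[k]], numeric(1))
  tot <- sum(prob)
  if (tot <= 0)
    return(new_population(list(), numeric(0),
                          rejected = pm$rejected_fraction))
  prob <- prob / tot
  new_population(lapply(keys, function(k) reps[[k]]), unname(prob),
                 rejected = pm$rejected_fraction)
}

#' Build a population from explicit genotypes and weights
#' @param genotypes list of \code{uci_genotype}.
#' @param prob probabilities (normalized internally).
#' @return \code{offspring_distribution}
#' @export
population <- function(genotypes, prob = NULL) {
  if (inherits(genotypes, "uci_genotype")) genotypes <- list(genotypes)
  if (is.null(prob)) prob <- rep(1 / length(genotypes), length(genotypes))
  new_population(genotypes, prob / sum(prob))
}

# aggregate a list of (population, weight) into one population
mix_populations <- function(pops, weights) {
  keep <- weights > 0 & vapply(pops, function(p)
    length(p$genotypes) > 0, logical(1))
  pops <- pops[keep]; weights <- weights[keep]
  if (length(pops) == 0L) return(new_population(list(), numeric(0), 1))
  weights <- weights / sum(weights)
  acc <- new.env(parent = emptyenv())
  reps <- new.env(parent = emptyenv())
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    for (j in seq_along(p$genotypes)) {
      key <- genotype_key(p$genotypes[[j]])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) +
        weights[i] * p$prob[j]
      if (is.null(reps[[key]])) reps[[key]] <- p$genotypes[[j]]
    }
  }
  keys <- sort(ls(acc), method = "radix")
  prob <- vapply(keys, function(k) acc[[k]], numeric(1))
  new_population(lapply(keys, function(k) reps[[k]]),
                 unname(prob / sum(prob)))
}

#' Cross populations (mixtures over mother and/or donor genotypes)
#'
#' Each offspring derives from one random mother individual and one
#' random donor individual, so the result is the probability-weighted
#' mixture of the single-pair crosses.  Pairs whose cross is barren
#' contribute no offspring (their weight is dropped and recorded in the
#' returned \code{rejected_pollen_fraction} as the weighted rejected
#' mass).
#'
#' @param registry a \code{uci_registry}.
#' @param mothers a genotype or population.
#' @param donors a genotype or population.
#' @param map_function map function name.
#' @return \code{offspring_distribution}
#' @export
cross_populations <- function(registry, mothers, donors,
                              map_function = "haldane") {
  mothers <- as_population(mothers)
  donors <- as_population(donors)
  pops <- list(); weights <- numeric(0); rej <- 0
  for (i in seq_along(mothers$genotypes)) {
    for (j in seq_along(donors$genotypes)) {
      w <- mothers$prob[i] * donors$prob[j]
      od <- cross(registry, mothers$genotypes[[i]],
                  pollen_pool(donors$genotypes[[j]]), map_function)
      rej <- rej + w * od$rejected_pollen_fraction
      pops <- c(pops, list(od)); weights <- c(weights, w)
    }
  }
  out <- mix_populations(pops, weights)
  out$rejected_pollen_fraction <- rej
  out
}

as_population <- function(x) {
  if (inherits(x, "uci_population")) x
  else if (inherits(x, "uci_genotype")) population(list(x), 1)
  else stop("expected a uci_genotype or population")
}

#' Self-pollinate every individual of a population
#'
#' Plants whose selfing is barren (e.g. a silk barrier their own pollen
#' cannot pass) contribute no offspring; the surviving mixture is
#' renormalized and the sterile fraction recorded in attribute
#' \code{sterile_fraction}.
#'
#' @param registry a \code{uci_registry}.
#' @param popn a population (or single genotype).
#' @param map_function map function name.
#' @return \code{offspring_distribution}
#' @export
self_population <- function(registry, popn, map_function = "haldane") {
  popn <- as_population(popn)
  pops <- lapply(popn$genotypes, function(g)
    cross(registry, g, pollen_pool(g), map_function))
  fertile <- vapply(pops, function(p) length(p$genotypes) > 0, logical(1))
  out <- mix_populations(pops, popn$prob)
  attr(out, "sterile_fraction") <- sum(popn$prob[!fertile])
  out
}

#' Seed-set outcome of a pollination
#'
#' Pollen-excess saturation model: ovules are limiting, so any nonzero
#' compatible pollen fraction fills the ear (\code{expected_seeds = N});
#' a fully incompatible pool yields only stray contaminant seeds
#' (\code{N * contamination}).  The ear is classed "low" iff the
#' expected seed count falls at or below \code{seed_threshold} (the
#' field convention scores ears with fewer than ~5 seeds as failures).
#'
#' @param registry a \code{uci_registry}.
#' @param silk maternal genotype.
#' @param pool pollen pool (or genotype).
#' @param ovules ovule count N (default 300).
#' @param contamination stray compatible-pollen fraction in [0, 1).
#' @param seed_threshold classification threshold (default 5).
#' @param map_function map function name.
#' @return list(compatible_fraction, expected_seeds, klass)
#' @export
seed_set <- function(registry, silk, pool, ovules = 300,
                     contamination = 0, seed_threshold = 5,
                     map_function = "haldane") {
  stopifnot(ovules >= 1, contamination >= 0, contamination < 1)
  pool <- as_pool(pool)
  pm <- paternal_mixture(registry, pool, silk, map_function)
  cf <- sum(pool$proportions * pm$surviving) +
    contamination * (1 - sum(pool$proportions * pm$surviving))
  pool_compatible <- any(pm$surviving > 0)
  expected <- if (pool_compatible) ovules else ovules * contamination
  list(compatible_fraction = cf,
       expected_seeds = expected,
       klass = if (expected <= seed_threshold) "low" else "full")
}

#' Kernel-class composition of an ear
#'
#' Crosses the mother with the pool and maps each offspring genotype to
#' its kernel color (purple dominant).  A barren ear returns an empty
#' named vector.
#'
#' @param registry a \code{uci_registry}.
#' @param mother maternal genotype.
#' @param pool pollen pool (or genotype).
#' @param map_function map function name.
#' @return named numeric vector of kernel-class fractions (sums to 1),
#'   or empty for a barren ear.
#' @export
ear_composition <- function(registry, mother, pool,
                            map_function = "haldane") {
  od <- cross(registry, mother, as_pool(pool), map_function)
  if (length(od$genotypes) == 0L)
    return(stats::setNames(numeric(0), character(0)))
  cls <- vapply(od$genotypes, function(g) kernel_color(registry, g),
                character(1))
  out <- tapply(od$prob, cls, sum)
  stats::setNames(as.numeric(out), names(out))
}
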