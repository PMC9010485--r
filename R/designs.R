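#' Load the experiment-design catalog
#'
#' Designs are data, not code: the catalog ships as a JSON fixture so
#' additional crosses can be added without programming.  Each design
#' carries a pedigree (a sequence of cross/self steps over named founder
#' genotypes), a readout type, ordered class labels, the sample size
#' reported for the original experiment, and (where printed) the
#' observed counts.
#'
#' @param file path to a catalog JSON; default: the bundled catalog.
#' @return list of \code{uci_design} objects, named by design id.
#' @export
design_catalog <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "designs.json", package = "ucicross",
                        mustWork = TRUE)
  raw <- jsonlite::fromJSON(file, simplifyVector = FALSE)
  designs <- lapply(raw, function(d) {
    stopifnot(!is.null(d$design_id), !is.null(d$readout),
              !is.null(d$classes))
    structure(d, class = "uci_design")
  })
  names(designs) <- vapply(designs, function(d) d$design_id, character(1))
  designs
}

#' @export
print.uci_design <- function(x, ...) {
  cat("<uci_design> ", x$design_id, " (n_reported = ", x$n_reported,
      ")\n  ", x$description, "\n  readout: ", x$readout$type,
      "; classes: ", paste(unlist(x$classes), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Reduce class probabilities to a canonical ratio string
#'
#' Probabilities forming a small-integer ratio (common denominator up to
#' 720) are printed as e.g. "1:1" or "7:1"; a degenerate distribution is
#' "1.0"; anything else falls back to rounded decimals.
#'
#' @param probabilities numeric vector summing to 1.
#' @return character scalar
#' @export
ratio_string <- function(probabilities) {
  p <- probabilities
  if (any(abs(p - 1) < 1e-9)) return("1.0")
  for (L in 1:720) {
    v <- p * L
    if (all(abs(v - round(v)) < 1e-7)) {
      v <- round(v)
      g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
                  v[v > 0])
      if (g > 0) v <- v / g
      return(paste(v, collapse = ":"))
    }
  }
  paste(signif(p, 4), collapse = ":")
}

resolve_ref <- function(ref, env, founders) {
  if (!is.null(env[[ref]])) return(env[[ref]])
  if (!is.null(founders[[ref]])) return(population(founders[[ref]]))
  stop("ill-formed pedigree: unknown reference '", ref, "'",
       call. = FALSE)
}

# build a pollen_pool from a list of refs resolved to populations;
# multi-genotype populations expand into weighted components
build_pool <- function(refs, env, founders, application = "mixed",
                       proportions = NULL, sequential_weights = NULL) {
  pops <- lapply(refs, function(r) {
    if (is.list(r)) resolve_ref(r$donor, env, founders)
    else resolve_ref(r, env, founders)
  })
  if (is.null(proportions)) {
    proportions <- rep(1 / length(pops), length(pops))
  } else proportions <- unlist(proportions)
  donors <- list(); props <- numeric(0)
  for (i in seq_along(pops)) {
    p <- pops[[i]]
    donors <- c(donors, p$genotypes)
    props <- c(props, proportions[i] * p$prob)
  }
  if (!is.null(sequential_weights)) {
    sw <- numeric(0)
    for (i in seq_along(pops))
      sw <- c(sw, unlist(sequential_weights)[i] * pops[[i]]$prob)
  } else sw <- NULL
  pollen_pool(donors, props, application = application,
              sequential_weights = sw)
}

eval_pedigree <- function(design, registry, founders, map_function) {
  env <- list()
  for (step in design$pedigree) {
    if (is.null(step$op) || is.null(step$id))
      stop("ill-formed pedigree in ", design$design_id, call. = FALSE)
    if (step$op == "cross") {
      mothers <- resolve_ref(step$mother, env, founders)
      refs <- step$pollen
      if (length(refs) == 1L) {
        donors <- resolve_ref(if (is.list(refs[[1]])) refs[[1]]$donor
                              else refs[[1]], env, founders)
        env[[step$id]] <- cross_populations(registry, mothers, donors,
                                            map_function)
      } else {
        pool <- build_pool(refs, env, founders,
                           application = step$application %||% "mixed",
                           proportions = step$proportions,
                           sequential_weights = step$sequential_weights)
        pops <- lapply(mothers$genotypes, function(m)
          cross(registry, m, pool, map_function))
        env[[step$id]] <- mix_populations(pops, mothers$prob)
      }
    } else if (step$op == "self") {
      env[[step$id]] <- self_population(registry,
                                        resolve_ref(step$parent, env,
                                                    founders),
                                        map_function)
    } else stop("ill-formed pedigree: unknown op '", step$op, "'",
                call. = FALSE)
  }
  env
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_expected_outcome <- function(design_id, classes, probabilities,
                                 detail = NULL, reported = NULL,
                                 note = NULL, barren = FALSE) {
  if (barren) {
    # the pedigree itself produces no offspring under this architecture
    return(structure(list(design_id = design_id, classes = classes,
                          probabilities = rep(NA_real_,
                                              length(classes)),
                          ratio_string = "barren-pedigree",
                          detail = detail, reported = reported,
                          note = paste(c(note,
                                         "pedigree produces no offspring under this architecture"),
                                       collapse = "; ")),
                     class = "expected_outcome"))
  }
  stopifnot(length(classes) == length(probabilities),
            abs(sum(probabilities) - 1) < 1e-9)
  structure(list(design_id = design_id, classes = classes,
                 probabilities = probabilities,
                 ratio_string = ratio_string(probabilities),
                 detail = detail, reported = reported, note = note),
            class = "expected_outcome")
}

#' @export
print.expected_outcome <- function(x, ...) {
  cat("<expected_outcome> ", x$design_id, ": ",
      paste(x$classes, collapse = ":"), " = ", x$ratio_string, "\n",
      sep = "")
  print(data.frame(class = x$classes, probability = x$probabilities),
        row.names = FALSE)
  if (!is.null(x$note)) cat("note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Model prediction for a catalog design
#'
#' Evaluates the design's pedigree by exact enumeration through the
#' cross engine (no sampling) and reduces the readout to an ordered
#' class-probability vector.
#'
#' @param object a \code{uci_design} (from \code{\link{design_catalog}}).
#' @param registry a \code{uci_registry}; default \code{ga2_registry()}.
#'   Pass a variant registry for architecture comparisons.
#' @param founders named genotype list; default
#'   \code{uci_founders(registry)}.
#' @param map_function "haldane" or "kosambi".
#' @param panel marker panel for marker-transmission readouts; default
#'   \code{default_marker_panel("male")}.
#' @param ... unused.
#' @return \code{expected_outcome}
#' @export
predict.uci_design <- function(object, registry = NULL, founders = NULL,
                               map_function = "haldane", panel = NULL,
                               ...) {
  design <- object
  if (is.null(registry)) registry <- ga2_registry()
  if (is.null(founders)) founders <- uci_founders(registry)
  env <- eval_pedigree(design, registry, founders, map_function)
  ro <- design$readout
  classes <- unlist(design$classes)
  note <- design$reported$note %||% NULL
  reported <- design$reported %||% NULL

  class_probs <- function(labels, probs) {
    out <- stats::setNames(rep(0, length(classes)), classes)
    for (i in seq_along(labels)) {
      if (!labels[i] %in% classes)
        stop("design ", design$design_id, ": predicted class '",
             labels[i], "' not among declared classes", call. = FALSE)
      out[labels[i]] <- out[labels[i]] + probs[i]
    }
    out
  }

  if (ro$type %in% c("seedset_as_male", "seedset_as_female",
                     "genotype_ratio")) {
    popn0 <- resolve_ref(ro$population, env, founders)
    if (length(popn0$genotypes) == 0L)
      return(new_expected_outcome(design$design_id, classes, NULL,
                                  reported = reported, note = note,
                                  barren = TRUE))
  }

  if (ro$type == "seedset_as_male") {
    popn <- resolve_ref(ro$population, env, founders)
    tester <- resolve_ref(ro$tester, env, founders)$genotypes[[1]]
    lab <- vapply(popn$genotypes, function(g) {
      ss <- seed_set(registry, tester, pollen_pool(g),
                     map_function = map_function)
      if (ss$klass == "full") classes[1] else classes[2]
    }, character(1))
    p <- class_probs(lab, popn$prob)
  } else if (ro$type == "seedset_as_female") {
    popn <- resolve_ref(ro$population, env, founders)
    tester <- resolve_ref(ro$pollen, env, founders)$genotypes[[1]]
    lab <- vapply(popn$genotypes, function(g) {
      ss <- seed_set(registry, g, pollen_pool(tester),
                     map_function = map_function)
      if (ss$klass == "full") classes[1] else classes[2]
    }, character(1))
    p <- class_probs(lab, popn$prob)
  } else if (ro$type == "genotype_ratio") {
    popn <- resolve_ref(ro$population, env, founders)
    lab <- vapply(popn$genotypes, function(g)
      locus_genotype_label(g, ro$locus), character(1))
    p <- class_probs(lab, popn$prob)
  } else if (ro$type == "marker_transmission") {
    if (is.null(panel)) panel <- default_marker_panel(ro$determinant)
    r <- vapply(unlist(ro$markers), function(m)
      marker_det_r(panel, m), numeric(1))
    p_both <- prod(1 - r)
    p <- stats::setNames(c(p_both, 1 - p_both), classes)
  } else if (ro$type == "ear_composition") {
    mother <- resolve_ref(ro$mother, env, founders)$genotypes[[1]]
    pool <- build_pool(ro$pollen, env, founders,
                       application = ro$application %||% "mixed",
                       proportions = ro$proportions,
                       sequential_weights = ro$sequential_weights)
    comp <- ear_composition(registry, mother, pool, map_function)
    p <- stats::setNames(rep(0, length(classes)), classes)
    for (k in names(comp)) {
      if (!k %in% classes)
        stop("kernel class '", k, "' not declared for ",
             design$design_id, call. = FALSE)
      p[k] <- comp[[k]]
    }
    if (length(comp) == 0L)
      stop("design ", design$design_id, ": barren ear has no ",
           "kernel-class distribution", call. = FALSE)
  } else if (ro$type == "trait_fraction") {
    mother <- resolve_ref(ro$mother, env, founders)$genotypes[[1]]
    pool <- build_pool(ro$pollen, env, founders)
    od <- cross(registry, mother, pool, map_function)
    if (length(od$genotypes) == 0L)
      stop("design ", design$design_id, ": barren cross", call. = FALSE)
    carrier <- vapply(od$genotypes, function(g)
      is_resistant(registry, g), logical(1))
    p <- stats::setNames(c(sum(od$prob[carrier]),
                           sum(od$prob[!carrier])), classes)
  } else if (ro$type == "compatibility_matrix") {
    labels <- character(0); outcomes <- character(0)
    for (cell in ro$cells) {
      mother <- resolve_ref(cell$mother, env, founders)$genotypes[[1]]
      pool <- build_pool(cell$pollen, env, founders,
                         application = cell$application %||% "mixed",
                         proportions = cell$proportions)
      ss <- seed_set(registry, mother, pool, map_function = map_function)
      labels <- c(labels, cell$label)
      outcomes <- c(outcomes,
                    if (ss$klass == "full") classes[1] else classes[2])
    }
    p <- class_probs(outcomes, rep(1 / length(outcomes),
                                   length(outcomes)))
    detail <- data.frame(cell = labels, outcome = outcomes,
                         stringsAsFactors = FALSE)
    return(new_expected_outcome(design$design_id, classes, unname(p),
                                detail = detail, reported = reported,
                                note = note))
  } else stop("unknown readout type '", ro$type, "'", call. = FALSE)

  new_expected_outcome(design$design_id, classes, unname(p),
                       reported = reported, note = note)
}

#' Predict a design by id
#' @param design_id catalog design id.
#' @param ... passed to \code{\link{predict.uci_design}}.
#' @param catalog design catalog (default bundled).
#' @return \code{expected_outcome}
#' @export
predict_design <- function(design_id, ..., catalog = design_catalog()) {
  d <- catalog[[design_id]]
  if (is.null(d)) stop("unknown design '", design_id, "'", call. = FALSE)
  stats::predict(d, ...)
}

#' Compare locus-architecture hypotheses on one design
#'
#' Re-runs \code{predict} under alternative architectures (e.g.
#' sporophytic male action, or a dose-1 female threshold) and tabulates
#' the predicted class distributions, making visible which variants the
#' observed data could discriminate.
#'
#' @param design a \code{uci_design}.
#' @param variants named list; each element is a list of arguments to
#'   \code{\link{ga2_registry}} (e.g. \code{list(male_mode =
#'   "sporophytic")}).  A "default" row is always included.
#' @param ... passed on to \code{predict}.
#' @return data.frame: variant, class, probability, ratio_string.
#' @export
compare_architectures <- function(design, variants, ...) {
  variants <- c(list(default = list()), variants)
  rows <- lapply(names(variants), function(v) {
    reg <- do.call(ga2_registry, variants[[v]])
    eo <- stats::predict(design, registry = reg, ...)
    data.frame(variant = v, class = eo$classes,
               probability = eo$probabilities,
               ratio_string = eo$ratio_string,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
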