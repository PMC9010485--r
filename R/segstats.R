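#' Observed (or simulated) class counts for a design
#'
#' @param design_id design identifier (free text allowed).
#' @param classes ordered class labels.
#' @param counts non-negative integer counts, parallel to classes.
#' @return object of class \code{uci_counts} with \code{n = sum(counts)}.
#' @export
count_data <- function(design_id, classes, counts) {
  counts <- as.integer(counts)
  stopifnot(length(classes) == length(counts), all(counts >= 0))
  structure(list(design_id = design_id, classes = classes,
                 counts = counts, n = sum(counts)),
            class = "uci_counts")
}

#' @export
print.uci_counts <- function(x, ...) {
  cat("<uci_counts> ", x$design_id, ": ",
      paste(x$counts, collapse = ":"), " (",
      paste(x$classes, collapse = ":"), "), n = ", x$n, "\n", sep = "")
  invisible(x)
}

#' Coerce a ratio specification to class probabilities
#'
#' Accepts an \code{expected_outcome}, a numeric probability (or weight)
#' vector, or a ratio string like "1:1", "7:1", "1:2:1".
#' @param ratio the specification.
#' @return numeric probabilities summing to 1
#' @export
as_ratio_probs <- function(ratio) {
  if (inherits(ratio, "expected_outcome")) return(ratio$probabilities)
  if (is.character(ratio)) {
    v <- suppressWarnings(
      as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]]))
    if (anyNA(v)) stop("cannot parse ratio '", ratio, "'")
    return(v / sum(v))
  }
  if (is.numeric(ratio)) return(ratio / sum(ratio))
  stop("unsupported ratio specification")
}

new_gof <- function(statistic, df, p_value, method) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 method = method), class = "uci_gof")
}

#' @export
print.uci_gof <- function(x, ...) {
  cat("<gof> method = ", x$method,
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' Pearson chi-square goodness-of-fit test for a segregation ratio
#'
#' Standard Pearson statistic sum((O - E)^2 / E) with df = classes - 1;
#' optional Yates continuity correction for the two-class case.
#'
#' @param obs \code{uci_counts}.
#' @param ratio expected ratio (see \code{\link{as_ratio_probs}}).
#' @param yates apply the continuity correction (df = 1 only).
#' @return \code{uci_gof}
#' @export
chi2_gof <- function(obs, ratio, yates = FALSE) {
  stopifnot(inherits(obs, "uci_counts"))
  p <- as_ratio_probs(ratio)
  if (length(p) != length(obs$counts))
    stop("ratio has ", length(p), " classes, counts have ",
         length(obs$counts))
  e <- obs$n * p
  if (any(e <= 0))
    stop("expected count of zero in some class; use exact_test()")
  d <- abs(obs$counts - e)
  if (yates) {
    if (length(p) != 2L) stop("Yates correction applies to 2 classes")
    d <- pmax(d - 0.5, 0)
  }
  stat <- sum(d^2 / e)
  df <- length(p) - 1L
  new_gof(stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
          if (yates) "pearson_yates" else "pearson")
}

# enumerate multinomial outcome probabilities (k classes, n trials)
multinom_outcome_probs <- function(n, p) {
  k <- length(p)
  combos <- utils::combn(n + k - 1, k - 1)  # stars and bars
  counts <- apply(combos, 2, function(cuts)
    diff(c(0, cuts, n + k)) - 1)
  probs <- apply(counts, 2, function(x) stats::dmultinom(x, prob = p))
  list(counts = t(counts), probs = probs)
}

#' Exact multinomial (binomial) goodness-of-fit test
#'
#' Two-sided p-value by the "at least as extreme in probability"
#' convention: the sum of probabilities of all outcomes whose null
#' probability does not exceed that of the observed table.  For two
#' classes this is the exact binomial test at any n; for more classes
#' the full multinomial sample space is enumerated subject to a budget.
#'
#' @param obs \code{uci_counts}.
#' @param ratio expected ratio.
#' @param budget maximum number of outcomes to enumerate (k > 2 only).
#' @return \code{uci_gof}
#' @export
exact_test <- function(obs, ratio, budget = 2e6) {
  stopifnot(inherits(obs, "uci_counts"))
  p <- as_ratio_probs(ratio)
  k <- length(p)
  if (k != length(obs$counts)) stop("class count mismatch")
  tol <- 1 + 1e-7
  if (k == 2L) {
    probs <- stats::dbinom(0:obs$n, obs$n, p[1])
    p_obs <- probs[obs$counts[1] + 1L]
    pv <- sum(probs[probs <= p_obs * tol])
    return(new_gof(statistic = p_obs, df = NA_integer_,
                   p_value = min(pv, 1), method = "exact_multinomial"))
  }
  n_outcomes <- choose(obs$n + k - 1, k - 1)
  if (n_outcomes > budget)
    stop("exact enumeration budget exceeded (", format(n_outcomes),
         " outcomes); use ratio_power(method = 'monte_carlo') or ",
         "chi2_gof()")
  space <- multinom_outcome_probs(obs$n, p)
  p_obs <- stats::dmultinom(obs$counts, prob = p)
  pv <- sum(space$probs[space$probs <= p_obs * tol])
  new_gof(statistic = p_obs, df = NA_integer_, p_value = min(pv, 1),
          method = "exact_multinomial")
}

#' Power to reject one segregation ratio when another is true
#'
#' Probability that the chosen goodness-of-fit test rejects
#' \code{null_ratio} at level \code{alpha} when counts are generated
#' under \code{true_ratio}.  For two classes,
#' \code{method = "exact_enumeration"} sums binomial masses over the
#' exact-test rejection region; \code{"monte_carlo"} simulates (needed
#' for k > 2).
#'
#' @param null_ratio,true_ratio ratio specifications.
#' @param n sample size.
#' @param alpha test level (default 0.05).
#' @param method "exact_enumeration" or "monte_carlo".
#' @param n_rep Monte Carlo replicates.
#' @param seed RNG seed (monte_carlo; recorded in the result).
#' @return list(null_ratio, true_ratio, n, alpha, power, method, seed)
#' @export
ratio_power <- function(null_ratio, true_ratio, n, alpha = 0.05,
                        method = c("exact_enumeration", "monte_carlo"),
                        n_rep = 2000, seed = NULL) {
  method <- match.arg(method)
  p0 <- as_ratio_probs(null_ratio)
  p1 <- as_ratio_probs(true_ratio)
  stopifnot(length(p0) == length(p1), n >= 1, alpha > 0, alpha < 1)
  if (method == "exact_enumeration") {
    if (length(p0) != 2L)
      stop("exact enumeration implemented for 2 classes; ",
           "use monte_carlo")
    probs0 <- stats::dbinom(0:n, n, p0[1])
    tol <- 1 + 1e-7
    ord <- order(probs0)
    cum <- cumsum(probs0[ord])
    pvals <- numeric(n + 1)
    # p-value of outcome k = total null mass of outcomes no more probable
    pvals[ord] <- vapply(seq_along(ord), function(i) {
      j <- max(which(probs0[ord] <= probs0[ord[i]] * tol))
      cum[j]
    }, numeric(1))
    reject <- pvals <= alpha
    pow <- sum(stats::dbinom(which(reject) - 1L, n, p1[1]))
  } else {
    if (is.null(seed)) seed <- 1L
    pow <- with_seed(seed, {
      rej <- vapply(seq_len(n_rep), function(i) {
        x <- as.integer(stats::rmultinom(1, n, p1))
        cd <- count_data("mc", paste0("c", seq_along(p1)), x)
        chi2_gof(cd, p0)$p_value <= alpha
      }, logical(1))
      mean(rej)
    })
  }
  structure(list(null_ratio = p0, true_ratio = p1, n = n, alpha = alpha,
                 power = pow, method = method,
                 seed = if (method == "monte_carlo") seed else NULL),
            class = "uci_power")
}

#' @export
print.uci_power <- function(x, ...) {
  cat("<power> n = ", x$n, ", alpha = ", x$alpha, ", power = ",
      signif(x$power, 4), " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Rank candidate segregation ratios by fit to observed counts
#'
#' Candidates are ranked by multinomial log-likelihood; each also gets a
#' Pearson test and an exact test.  Log-likelihood ties (within 1e-9)
#' are reported via the \code{tied} column, never broken silently.
#'
#' @param obs \code{uci_counts}.
#' @param candidates list of ratio specifications (named, optionally).
#' @param alpha rejection level for the \code{rejected} column.
#' @return data.frame sorted by decreasing log-likelihood.
#' @export
best_fit_ratio <- function(obs, candidates, alpha = 0.05) {
  if (!is.list(candidates)) candidates <- as.list(candidates)
  nm <- names(candidates)
  if (is.null(nm))
    nm <- vapply(candidates, function(r)
      paste(round(as_ratio_probs(r) /
                    min(as_ratio_probs(r)[as_ratio_probs(r) > 0]), 3),
            collapse = ":"), character(1))
  rows <- lapply(seq_along(candidates), function(i) {
    p <- as_ratio_probs(candidates[[i]])
    ll <- stats::dmultinom(obs$counts, prob = p, log = TRUE)
    g <- chi2_gof(obs, p)
    ex <- tryCatch(exact_test(obs, p), error = function(e) NULL)
    data.frame(candidate = nm[i], loglik = ll,
               statistic = g$statistic, p_value = g$p_value,
               exact_p = if (is.null(ex)) NA_real_ else ex$p_value,
               rejected = g$p_value <= alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$loglik), , drop = FALSE]
  out$tied <- c(FALSE, abs(diff(out$loglik)) < 1e-9)
  rownames(out) <- NULL
  out
}
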