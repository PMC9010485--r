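#' Write a table as TSV with a commented metadata header
#'
#' @param df data.frame.
#' @param path output path.
#' @param meta named list written as "# key: value" lines.
#' @return \code{path}, invisibly.
#' @export
write_tsv_report <- function(df, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(paste0("# ", k, ": ",
                      paste(unlist(meta[[k]]), collapse = " ")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by this package (or any '#'-commented TSV)
#'
#' @param path input path.
#' @return data.frame with attribute \code{meta} (parsed header lines).
#' @export
read_tsv_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 1L)
    stop("malformed TSV '", path, "': no header line", call. = FALSE)
  df <- tryCatch(
    utils::read.delim(text = paste(body, collapse = "\n"),
                      stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  attr(df, "meta") <- meta
  df
}

#' Read observed segregation counts from a TSV
#'
#' Expected columns: design_id, class, count.  Returns one
#' \code{uci_counts} per design, in file order.
#'
#' @param path TSV path; default: the bundled table of printed counts.
#' @return named list of \code{uci_counts}
#' @export
read_counts_tsv <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "observed_counts.tsv",
                        package = "ucicross", mustWork = TRUE)
  df <- read_tsv_report(path)
  need <- c("design_id", "class", "count")
  if (!all(need %in% names(df)))
    stop("malformed counts TSV '", path, "': need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  ids <- unique(df$design_id)
  out <- lapply(ids, function(id) {
    d <- df[df$design_id == id, ]
    count_data(id, d$class, d$count)
  })
  names(out) <- ids
  out
}

#' Write an expected outcome as a prediction TSV
#' @param eo \code{expected_outcome}.
#' @param path output path.
#' @return path, invisibly
#' @export
write_prediction_tsv <- function(eo, path) {
  df <- data.frame(design_id = eo$design_id, class = eo$classes,
                   probability = eo$probabilities,
                   ratio_string = eo$ratio_string,
                   stringsAsFactors = FALSE)
  write_tsv_report(df, path,
                   meta = c(list(design_id = eo$design_id),
                            if (!is.null(eo$note)) list(note = eo$note)))
}

#' Read and validate a run configuration (JSON)
#'
#' Recognized keys: \code{seed}, \code{male_mode}, \code{female_mode},
#' \code{female_dose_threshold}, \code{map_rate_cM_per_Mb},
#' \code{noise} (misclassification / contamination / genotyping_error),
#' \code{output_dir}.  Unknown keys are rejected (schema validation
#' before any run).
#'
#' @param path JSON path.
#' @return list(registry, noise, seed, output_dir, config)
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path, call. = FALSE)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- c("seed", "male_mode", "female_mode",
             "female_dose_threshold", "map_rate_cM_per_Mb", "noise",
             "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "),
         call. = FALSE)
  reg_args <- cfg[intersect(names(cfg),
                            c("male_mode", "female_mode",
                              "female_dose_threshold",
                              "map_rate_cM_per_Mb"))]
  registry <- do.call(ga2_registry, reg_args)
  noise <- if (is.null(cfg$noise)) noise_model()
           else do.call(noise_model, as.list(cfg$noise))
  list(registry = registry, noise = noise,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       output_dir = cfg$output_dir %||% ".", config = cfg)
}

#' One-shot reproduction report for all cataloged experiments
#'
#' Runs every catalog design through exact prediction, compares the
#' model's class distribution with the bundled printed counts (where
#' the original counts were published) via exact tests, and for the
#' sporophytic-female test additionally evaluates the reported 8:1
#' claim against the model's enumerated 7:1 together with their
#' discrimination power at the published sample size.
#'
#' @param seed RNG seed (used only for Monte Carlo fallbacks; the
#'   report itself is deterministic).
#' @param registry optional registry override.
#' @param alpha rejection level.
#' @return data.frame (one row per design x tested ratio) with
#'   attribute \code{power_7v8}.
#' @export
reproduce_paper <- function(seed = 1, registry = NULL, alpha = 0.05) {
  catalog <- design_catalog()
  observed <- read_counts_tsv()
  rows <- list()
  for (id in names(catalog)) {
    eo <- stats::predict(catalog[[id]], registry = registry)
    obs <- observed[[id]]
    row <- data.frame(design_id = id,
                      predicted = eo$ratio_string,
                      classes = paste(eo$classes, collapse = ":"),
                      observed = if (is.null(obs)) NA_character_
                                 else paste(obs$counts, collapse = ":"),
                      n = if (is.null(obs)) NA_integer_ else obs$n,
                      exact_p = NA_real_, conclusion = NA_character_,
                      stringsAsFactors = FALSE)
    if (!is.null(obs) && all(eo$probabilities > 0)) {
      et <- exact_test(obs, eo)
      row$exact_p <- et$p_value
      row$conclusion <- if (et$p_value > alpha)
        paste0("not rejected (P > ", alpha, ")") else "rejected"
    } else if (!is.null(obs)) {
      # degenerate prediction: consistent iff no mass in zero classes
      ok <- all(obs$counts[eo$probabilities == 0] == 0)
      row$exact_p <- if (ok) 1 else 0
      row$conclusion <- if (ok) "consistent (deterministic)"
                        else "contradicted"
    }
    rows[[length(rows) + 1L]] <- row
    if (id == "D7" && !is.null(obs)) {
      et8 <- exact_test(obs, "8:1")
      rows[[length(rows) + 1L]] <- data.frame(
        design_id = "D7 (reported claim)", predicted = "8:1",
        classes = paste(eo$classes, collapse = ":"),
        observed = paste(obs$counts, collapse = ":"), n = obs$n,
        exact_p = et8$p_value,
        conclusion = if (et8$p_value > alpha)
          paste0("not rejected (P > ", alpha, ")") else "rejected",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "power_7v8") <-
    ratio_power("8:1", "7:1", n = observed[["D7"]]$n, alpha = alpha)
  attr(out, "seed") <- seed
  out
}
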