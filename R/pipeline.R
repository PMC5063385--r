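#' Whole-percent share, as presented in summary tables
#' @param part,whole counts.
#' @return integer percent (rounded to whole percent).
#' @export
percent_of <- function(part, whole) {
  if (whole <= 0) stop("whole must be positive")
  round(100 * part / whole)
}

#' Mean events per tool, as presented in experiment summaries
#' @param total_events,n_tools counts.
#' @return mean rounded to 2 decimals.
#' @export
events_per_tool <- function(total_events, n_tools) {
  if (n_tools <= 0) stop("n_tools must be positive")
  round(total_events / n_tools, 2)
}

#' Pipeline run configuration
#'
#' @param input path: an S2-layout CSV, a directory of per-tool GeoJSON
#'   files, or an S3-layout distribution CSV, according to `format`.
#' @param format one of "s2", "geojson_dir", "s3".
#' @param candidates character vector of assemblage labels used as candidate
#'   process predictors.
#' @param responses labels to fit (default: all non-candidate labels with
#'   damage).
#' @param assemblage_column metadata column holding the grouping label.
#' @param class_filter optional damage classes to keep (GeoJSON input only).
#' @param alpha loess span in (0, 1].
#' @param seed integer seed recorded in the outputs.
#' @param out_dir output directory (created if needed); `NULL` disables file
#'   output.
#' @return an `edd_config`.
#' @export
run_config <- function(input, format = c("s2", "geojson_dir", "s3"),
                       candidates, responses = NULL,
                       assemblage_column = "assemblage",
                       class_filter = NULL, alpha = 0.15, seed = 1L,
                       out_dir = NULL) {
  format <- match.arg(format)
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  structure(list(input = input, format = format, candidates = candidates,
                 responses = responses, assemblage_column = assemblage_column,
                 class_filter = class_filter, alpha = alpha,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "edd_config")
}

load_grouped_vectors <- function(config) {
  if (config$format == "s2") {
    s2 <- read_s2_matrix(config$input)
    grp <- s2$metadata[[config$assemblage_column]]
    if (is.null(grp)) stop(sprintf("metadata column '%s' not found", config$assemblage_column))
    split_idx <- split(seq_len(nrow(s2$vectors)), grp)
    lapply(split_idx, function(i) s2$vectors[i, , drop = FALSE])
  } else { # geojson_dir
    files <- list.files(config$input, pattern = "\\.geojson$", full.names = TRUE)
    if (!length(files)) stop(sprintf("no .geojson files under '%s'", config$input))
    tools <- lapply(files, read_tool_geojson)
    vecs <- lapply(tools, build_damage_vector, class_filter = config$class_filter)
    mat <- do.call(rbind, lapply(vecs, as.integer))
    rownames(mat) <- vapply(tools, `[[`, "", "tool_id")
    grp <- vapply(tools, `[[`, "", "assemblage_label")
    lapply(split(seq_len(nrow(mat)), grp), function(i) mat[i, , drop = FALSE])
  }
}

#' Run the full assemblage edge-damage analysis
#'
#' Loads and groups damage vectors (or distributions), aggregates and smooths
#' each assemblage, then reports in order of increasing specificity: a
#' per-assemblage damage summary, the single best-fitting experimental
#' process for each response assemblage, and the full stepwise mixture model
#' with per-term variance contributions. Results are deterministic given the
#' inputs and seed.
#'
#' @param config an `edd_config`.
#' @return (invisibly) list with `summary`, `single_fits`, `stepwise_fits`
#'   data frames, the underlying `distributions` and `fits`, and the `log`
#'   lines. When `out_dir` is set, writes `summary.csv`, `single_fits.csv`,
#'   `stepwise_fits.csv`, `results.json` and `log.txt` there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "edd_config"))
  set.seed(config$seed)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  note("stage=load input=%s format=%s seed=%d", config$input, config$format, config$seed)

  if (config$format == "s3") {
    dists <- read_s3_distributions(config$input, alpha = config$alpha)
    summary_df <- data.frame(assemblage = names(dists),
                             n_tools = vapply(dists, function(d) as.integer(d$n_tools), 1L),
                             n_damaged = NA_integer_, percent_damaged = NA_integer_,
                             total_damage = vapply(dists, `[[`, 0, "total_damage"),
                             stringsAsFactors = FALSE)
  } else {
    groups <- load_grouped_vectors(config)
    if (!length(groups)) stop("no assemblages found in input")
    dists <- lapply(names(groups), function(lab)
      aggregate_vectors(groups[[lab]], label = lab, alpha = config$alpha))
    names(dists) <- names(groups)
    summary_df <- do.call(rbind, lapply(names(groups), function(lab) {
      v <- groups[[lab]]
      nd <- sum(rowSums(v) > 0)
      data.frame(assemblage = lab, n_tools = nrow(v), n_damaged = nd,
                 percent_damaged = percent_of(nd, nrow(v)),
                 total_damage = sum(v), stringsAsFactors = FALSE)
    }))
  }
  rownames(summary_df) <- NULL
  note("stage=aggregate assemblages=%d alpha=%g", length(dists), config$alpha)

  missing <- setdiff(config$candidates, names(dists))
  if (length(missing)) stop("candidate assemblage(s) not found: ", paste(missing, collapse = ", "))
  responses <- config$responses
  if (is.null(responses)) responses <- setdiff(names(dists), config$candidates)
  empty <- responses[vapply(dists[responses], `[[`, 0, "total_damage") == 0]
  for (lab in empty) note("stage=fit assemblage=%s skipped=zero_damage", lab)
  responses <- setdiff(responses, empty)

  fits <- list()
  single_rows <- list(); step_rows <- list()
  for (lab in responses) {
    cs <- candidates_from_distributions(dists[[lab]], dists[config$candidates])
    single <- fit_single_best(cs)
    step <- forward_stepwise(cs)
    fits[[lab]] <- list(single = single, stepwise = step)
    single_rows[[lab]] <- data.frame(
      assemblage = lab, best_fit = single$terms,
      aicc = single$aicc, r_squared = single$r_squared,
      f_ratio = single$f_ratio, p_value = single$p_value,
      stringsAsFactors = FALSE)
    model_str <- if (length(step$terms)) {
      paste0(step$terms, sprintf("(%.0f%%)", step$contributions[step$terms]),
             collapse = "+")
    } else "(intercept only)"
    step_rows[[lab]] <- data.frame(
      assemblage = lab, best_model = model_str, n_terms = length(step$terms),
      aicc = step$aicc, r_squared = step$r_squared, stringsAsFactors = FALSE)
    note("stage=fit assemblage=%s single=%s stepwise=%s", lab, single$terms, model_str)
  }
  single_df <- if (length(single_rows)) do.call(rbind, single_rows) else
    data.frame(assemblage = character(0))
  step_df <- if (length(step_rows)) do.call(rbind, step_rows) else
    data.frame(assemblage = character(0))
  rownames(single_df) <- rownames(step_df) <- NULL

  result <- list(summary = summary_df, single_fits = single_df,
                 stepwise_fits = step_df, distributions = dists, fits = fits,
                 excluded = empty, log = log_lines, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(single_df, file.path(config$out_dir, "single_fits.csv"), row.names = FALSE)
    utils::write.csv(step_df, file.path(config$out_dir, "stepwise_fits.csv"), row.names = FALSE)
    json <- list(seed = config$seed, alpha = config$alpha,
                 summary = summary_df, single_fits = single_df,
                 stepwise_fits = step_df,
                 stepwise_detail = lapply(fits, function(f) list(
                   terms = f$stepwise$terms,
                   coefficients = as.list(f$stepwise$coefficients),
                   contributions = as.list(f$stepwise$contributions),
                   r_squared = f$stepwise$r_squared,
                   aicc = f$stepwise$aicc)))
    jsonlite::write_json(json, file.path(config$out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  }
  invisible(result)
}
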