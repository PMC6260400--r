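# On-disk artifacts: results tables (TSV), truth and null summaries
# (JSON), simulator configs (YAML), gene-set files.  Numeric columns are
# written with 17 significant digits so round trips are exact.

results_columns <- c("gene_id", "selected_period", "p_value", "q_value",
                     "log2_half_amplitude", "peak_to_peak_fold",
                     "phase_hours", "mean_log2", "rhythmic", "group")

#' Write a per-gene rhythm results table as TSV
#'
#' @param calls A `rhythm_calls` object from [detect_transcriptome()] or
#'   its `results` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(calls, path) {
  res <- if (inherits(calls, "rhythm_calls")) calls$results else calls
  stopifnot(all(results_columns %in% names(res)))
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "none", sprintf("%.17g", v))
    else as.character(v)
  }
  out <- do.call(cbind, lapply(res[results_columns], fmt))
  writeLines(c(paste(results_columns, collapse = "\t"),
               apply(out, 1, paste, collapse = "\t")), path)
  invisible(path)
}

#' Read a rhythm results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A data.frame with the standard results columns;
#'   `selected_period` is `NA` for arrhythmic ("none") genes.
#' @export
read_results_table <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   na.strings = "none")
  missing <- setdiff(results_columns, names(df))
  if (length(missing))
    stop("results table lacks column(s): ", paste(missing, collapse = ", "))
  df$rhythmic <- as.logical(df$rhythmic)
  df$group <- as.integer(df$group)
  df
}

#' Write a synthetic truth table as JSON
#'
#' @param truth Truth data.frame from [simulate_transcriptome()].
#' @param path Output path.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(genes = truth,
                  group_centers = attr(truth, "group_centers"))
  jsonlite::write_json(payload, path, dataframe = "columns",
                       digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' Read a truth table written by [write_truth_json()]
#' @param path Path to the JSON file.
#' @return Truth data.frame with the `group_centers` attribute.
#' @export
read_truth_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- as.data.frame(payload$genes, stringsAsFactors = FALSE)
  for (col in c("group")) truth[[col]] <- as.integer(truth[[col]])
  for (col in c("mesor", "period_1", "amplitude_1", "phase_1",
                "period_2", "amplitude_2", "phase_2"))
    truth[[col]] <- as.numeric(truth[[col]])
  if (!is.null(payload$group_centers))
    attr(truth, "group_centers") <-
      as.data.frame(payload$group_centers, stringsAsFactors = FALSE)
  truth
}

#' Read a simulator configuration from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; unknown keys are
#' rejected rather than silently ignored.
#'
#' @param path Path to a YAML (or flat `key: value`) file.
#' @return A validated [sim_config()].
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config file must be a key-value mapping")
  allowed <- setdiff(names(formals(sim_config)), "")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(sim_config, raw)
}

#' Write a permutation null summary as JSON
#' @param null_summary A `null_summary` from [shuffle_null()].
#' @param path Output path.
#' @export
write_null_summary <- function(null_summary, path) {
  stopifnot(inherits(null_summary, "null_summary"))
  jsonlite::write_json(unclass(null_summary), path, digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read gene sets from a plain-text file
#'
#' One gene ID per line; lines of the form `# name: <set name>` start a
#' new named set.  A file without a header yields one set named after
#' the file.
#'
#' @param path Path to the gene-set file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  sets <- list()
  current <- sub("\\.[^.]*$", "", basename(path))
  for (ln in lines) {
    if (startsWith(ln, "#")) {
      m <- regmatches(ln, regexec("^#\\s*name:\\s*(.+)$", ln))[[1]]
      if (length(m) == 2) current <- m[2]
      next
    }
    sets[[current]] <- c(sets[[current]], ln)
  }
  if (!length(sets)) stop("no gene IDs found in ", path)
  sets
}
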