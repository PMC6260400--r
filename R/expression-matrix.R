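#' Construct an expression time-course matrix
#'
#' A lightweight container for a genes x time-points matrix of log2-scale
#' expression values with an explicit numeric time grid in hours.  This is
#' the input type of [detect_transcriptome()] and friends.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene IDs),
#'   time points in columns.
#' @param times Numeric vector of sampling times in hours, strictly
#'   increasing, one per column of `values`.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `times`.
#' @examples
#' em <- expression_matrix(matrix(rnorm(24), 2, 12,
#'                                dimnames = list(c("g1", "g2"), NULL)),
#'                         times = seq(0, 22, by = 2))
#' em
#' @export
expression_matrix <- function(values, times) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)))
    stop("`values` must have gene IDs as rownames")
  times <- as.numeric(times)
  if (length(times) != ncol(values))
    stop("length(times) must equal ncol(values)")
  if (length(times) < 4L)
    stop("an expression matrix needs at least 4 time points, got ",
         length(times))
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate gene ID(s): ", paste(unique(dup), collapse = ", "))
  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite expression value(s), first at gene '",
         rownames(values)[bad[1, 1]], "', time ", times[bad[1, 2]], " h")
  }
  structure(list(values = values, times = times),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d time points (%g-%g h)\n",
              nrow(x$values), length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read an expression matrix from a tab-separated file
#'
#' Expects a TSV whose first column holds gene IDs and whose header row
#' holds numeric sampling times in hours.  Values are validated to be
#' finite and rectangular; errors name the offending gene and time.
#'
#' @param path Path to the TSV file.
#' @param log2_transform If `TRUE`, values are transformed
#'   `v -> log2(v + pseudocount)` after reading (use for linear-scale
#'   input such as TPM-like arbitrary units).
#' @param pseudocount Pseudocount used by the log2 transform.
#' @return An [expression_matrix()].
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, log2_transform = FALSE,
                                   pseudocount = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV must have gene IDs plus values")
  times <- suppressWarnings(as.numeric(colnames(df)[-1]))
  if (anyNA(times))
    stop("non-numeric time header column(s): ",
         paste(colnames(df)[-1][is.na(times)], collapse = ", "))
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric expression values in ", path)
  rownames(vals) <- ids
  colnames(vals) <- NULL
  if (log2_transform) {
    if (any(vals + pseudocount <= 0, na.rm = TRUE))
      stop("log2 transform undefined: values + pseudocount <= 0")
    vals <- log2(vals + pseudocount)
  }
  expression_matrix(vals, times)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 17 significant digits so that a
#' write-then-read round trip reproduces the matrix exactly.
#'
#' @param x An [expression_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  header <- paste(c("gene_id", sprintf("%.17g", x$times)), collapse = "\t")
  body <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(rownames(x$values)[i], sprintf("%.17g", x$values[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Filter genes by mean expression on the linear scale
#'
#' Retains genes whose mean linear-scale (a.u.) expression exceeds
#' `min_mean`.  The default cutoff of 32 a.u. selects robustly expressed
#' genes; it is a heuristic and should be tuned to the input units.
#'
#' @param x An [expression_matrix()] of log2-scale values.
#' @param min_mean Cutoff on the linear-scale row mean (strictly
#'   greater-than); `0` retains everything.
#' @param values_are_log2 If `TRUE` (default) rows are exponentiated
#'   (`2^v`) before averaging; set `FALSE` when `x` already holds
#'   linear-scale values.
#' @return The filtered [expression_matrix()], gene order preserved.
#'   An empty result is returned with a warning.
#' @export
expression_filter <- function(x, min_mean = 32, values_are_log2 = TRUE) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!is.numeric(min_mean) || length(min_mean) != 1L || min_mean < 0)
    stop("`min_mean` must be a single non-negative number")
  lin <- if (values_are_log2) 2^x$values else x$values
  keep <- rowMeans(lin) > min_mean
  if (!any(keep)) {
    warning("expression_filter removed every gene (min_mean = ",
            min_mean, ")")
  }
  out <- x
  out$values <- x$values[keep, , drop = FALSE]
  out
}
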