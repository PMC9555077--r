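# Delimited-text matrix I/O and result serialization. Matrices circulate as
# plain CSV/TSV with an optional header row of region labels; comma is
# written, tab is accepted on read.

#' Read a numeric matrix from delimited text
#'
#' Reads a comma- or tab-separated numeric matrix, with an optional header
#' row of labels. Square-symmetric inputs (distances, adjacencies,
#' Laplacians) are validated for shape and symmetry with an absolute
#' tolerance; the offending entry is named on failure, as are ragged rows
#' and non-numeric cells.
#'
#' @param path file path.
#' @param expect `"square_symmetric"` for distance/adjacency/Laplacian
#'   matrices or `"rectangular"` for design matrices.
#' @param sym_tol absolute symmetry tolerance.
#' @return Numeric matrix; column names carry the labels when a header was
#'   present.
#' @export
read_matrix <- function(path, expect = c("square_symmetric", "rectangular"),
                        sym_tol = 1e-10) {
  expect <- match.arg(expect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  counts <- lengths(fields)
  if (length(unique(counts)) != 1) {
    bad <- which(counts != counts[1])[1]
    stop(sprintf("ragged input in %s: row %d has %d fields, expected %d",
                 path, bad, counts[bad], counts[1]), call. = FALSE)
  }
  first <- suppressWarnings(as.numeric(fields[[1]]))
  has_header <- anyNA(first)
  labels <- NULL
  if (has_header) {
    labels <- trimws(fields[[1]])
    fields <- fields[-1]
    if (!length(fields)) stop("header-only file: ", path, call. = FALSE)
  }
  m <- matrix(NA_real_, length(fields), counts[1])
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell at data row %d, column %d of %s: '%s'",
                   i, j, path, fields[[i]][j]), call. = FALSE)
    }
    m[i, ] <- v
  }
  if (!is.null(labels)) colnames(m) <- labels
  if (expect == "square_symmetric") {
    if (nrow(m) != ncol(m))
      stop(sprintf("%s: expected a square matrix, got %d x %d",
                   path, nrow(m), ncol(m)), call. = FALSE)
    dev <- abs(m - t(m))
    if (max(dev) > sym_tol) {
      idx <- sort(which(dev == max(dev), arr.ind = TRUE)[1, ])
      stop(sprintf("%s: asymmetric at entry (%d, %d): |%g - %g| = %.3g > %g",
                   path, idx[1], idx[2], m[idx[1], idx[2]], m[idx[2], idx[1]],
                   max(dev), sym_tol), call. = FALSE)
    }
    if (!is.null(labels)) rownames(m) <- labels
  }
  m
}

#' Write a numeric matrix as delimited text
#'
#' @param x numeric matrix; column names, if any, are written as a header
#'   row of labels.
#' @param path destination file.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(colnames(x)))
    writeLines(paste(colnames(x), collapse = ","), con)
  write.table(x, con, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Hash of a configuration object
#'
#' Canonical-JSON MD5 hash used to stamp output manifests; two configs hash
#' equal iff their serialized contents are identical.
#'
#' @param config any JSON-serializable list.
#' @return Hex digest string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = 15,
                           force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(json, tf)
  unname(tools::md5sum(tf))
}

#' Write a result object with a provenance manifest
#'
#' Serializes a fit, experiment or bootstrap result into a directory:
#' `result.json` with all numeric content, a `coefficients.csv` table where
#' the result has one, and `manifest.json` recording the package version,
#' timestamp, seed (when the result carries one) and a [config_hash()] of
#' the configuration.
#'
#' @param result a `dispeer_fit`, `dispeer_experiment` or `dispeer_boot`
#'   object (other lists are serialized as-is).
#' @param dir output directory (created if needed).
#' @param config optional configuration list recorded in the manifest; for
#'   experiments the stored config is used by default.
#' @return The manifest, invisibly.
#' @export
write_result <- function(result, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- unclass(result)
  # named numeric vectors must become JSON objects, not bare arrays
  if (!is.null(payload$lambdas) && !is.list(payload$lambdas))
    payload$lambdas <- as.list(payload$lambdas)
  if (!is.null(payload$medians)) payload$medians <- as.list(payload$medians)
  if (inherits(result, "dispeer_experiment") && is.null(config))
    config <- unclass(result$config)
  jsonlite::write_json(payload, file.path(dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  if (inherits(result, "dispeer_fit")) {
    tab <- data.frame(coefficient = c(paste0("beta", seq_along(result$beta_hat)),
                                      paste0("b", seq_along(result$b_hat))),
                      estimate = c(result$beta_hat, result$b_hat))
    write.table(tab, file.path(dir, "coefficients.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  if (inherits(result, "dispeer_boot")) {
    tab <- cbind(coefficient = rownames(result$table), result$table)
    write.table(tab, file.path(dir, "coefficients.csv"), sep = ",",
                row.names = FALSE, quote = FALSE)
  }
  manifest <- list(package = "dispeer",
                   version = as.character(utils::packageVersion("dispeer")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = result$seed %||% config$seed,
                   config_hash = if (!is.null(config)) config_hash(config))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
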