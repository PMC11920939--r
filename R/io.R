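#' Read a square interaction matrix from a delimited text file
#'
#' Accepts comma- or tab-delimited numeric tables, with or without a header
#' row; the delimiter and header are detected from the first line. The table
#' must be square.
#'
#' @param path Path to the file.
#' @return A numeric matrix.
#' @export
read_interaction_matrix <- function(path) {
  M <- as.matrix(read_numeric_table(path))
  if (nrow(M) != ncol(M))
    stop(sprintf("%s: expected a square matrix, got %d x %d",
                 path, nrow(M), ncol(M)), call. = FALSE)
  unname(M)
}

#' Read an abundance vector from a delimited text file
#'
#' One value per row (a single column), or a single row of values.
#' All entries must be strictly positive.
#'
#' @param path Path to the file.
#' @return A numeric vector.
#' @export
read_abundance_vector <- function(path) {
  M <- as.matrix(read_numeric_table(path))
  v <- as.numeric(if (ncol(M) == 1) M[, 1] else M[1, ])
  if (ncol(M) > 1 && nrow(M) > 1)
    stop(path, ": expected a single row or column of abundances", call. = FALSE)
  bad <- which(!(v > 0))
  if (length(bad) > 0)
    stop(sprintf("%s: abundances must be strictly positive (row %d is %g)",
                 path, bad[1], v[bad[1]]), call. = FALSE)
  v
}

read_numeric_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  sep <- if (grepl(",", first)) "," else "\t"
  if (!grepl("[,\t]", first)) sep <- ""   # single-column file
  fields <- strsplit(first, if (sep == "") "[[:space:]]+" else sep)[[1]]
  header <- anyNA(suppressWarnings(as.numeric(fields)))
  df <- utils::read.table(path, sep = sep, header = header)
  if (!all(vapply(df, is.numeric, logical(1))))
    stop(path, ": non-numeric entries found", call. = FALSE)
  df
}

#' Write sweep results as CSV tables plus a run manifest
#'
#' Writes the per-replicate records and the per-richness summary as two CSV
#' files (UTF-8, `.` decimal separator, full-precision floats that re-parse
#' losslessly) and a JSON manifest capturing the fully resolved
#' configuration, the richness grid, the root seed, the package version and
#' the output paths, sufficient to re-execute the run bit-identically.
#'
#' @param sweep A `glv_sweep` from [run_richness_sweep()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sweep_results <- function(sweep, dir, prefix = "sweep") {
  stopifnot(inherits(sweep, "glv_sweep"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    records = file.path(dir, paste0(prefix, "_records.csv")),
    summary = file.path(dir, paste0(prefix, "_summary.csv")),
    manifest = file.path(dir, paste0(prefix, "_manifest.json"))
  )
  readr::write_csv(sweep$records, paths[["records"]])
  readr::write_csv(sweep$summary, paths[["summary"]])
  manifest <- list(
    package = "glvsim",
    version = as.character(utils::packageVersion("glvsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(sweep$config),
    S_grid = sweep$S_grid,
    n_reps = nrow(sweep$records) / length(sweep$S_grid),
    outputs = as.list(paths[c("records", "summary")])
  )
  jsonlite::write_json(manifest, paths[["manifest"]],
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(paths)
}

#' Write a simulated trajectory as a delimited table
#'
#' One row per output checkpoint, columns `time, N1 ... NS`.
#'
#' @param sim A `glv_sim` produced with `keep_trajectory = TRUE`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  if (is.null(sim$trajectory))
    stop("simulation was run without keep_trajectory = TRUE", call. = FALSE)
  readr::write_csv(sim$trajectory, path)
  invisible(path)
}
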