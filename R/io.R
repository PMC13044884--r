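# Canonical CSV schemas tying the pipeline stages together. All files are
# comma-delimited UTF-8 with a header row, preceded by one comment line
# declaring the schema version, e.g. `# graphquant schema v1: measurements`.

.schema_version <- "v1"

.write_schema_csv <- function(tbl, path, schema) {
  con <- file(path, open = "w", encoding = "UTF-8")
  writeLines(sprintf("# graphquant schema %s: %s", .schema_version, schema),
             con)
  close(con)
  readr::write_csv(tibble::as_tibble(tbl), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

.read_schema_csv <- function(path, required) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Read and write pipeline CSV files
#'
#' Fixed schemas (all comma-delimited, UTF-8, header row, one `#` schema
#' comment line):
#' \describe{
#'   \item{measurements}{`sample_id, molecule_id, smiles,
#'     concentration_mg_per_kg, area, istd_area`}
#'   \item{molecules}{`molecule_id, smiles, target`}
#'   \item{beta}{`molecule_id, mean_alpha, beta, n_kept, n_flagged`}
#'   \item{predictions}{`molecule_id, target_true (optional), target_pred`}
#'   \item{estimates}{`molecule_id, s_bar, beta_pred,
#'     conc_estimate_mg_per_kg`}
#' }
#'
#' @param path File path.
#' @param tbl Tibble to write.
#' @return Readers return a tibble; writers return `path` invisibly.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_measurements <- function(path) {
  .read_schema_csv(path, c("sample_id", "molecule_id",
                           "concentration_mg_per_kg", "area", "istd_area"))
}

#' @rdname pipeline_io
#' @export
write_measurements <- function(tbl, path) {
  .write_schema_csv(tbl, path, "measurements")
}

#' @rdname pipeline_io
#' @export
read_molecules <- function(path) {
  .read_schema_csv(path, c("molecule_id", "smiles"))
}

#' @rdname pipeline_io
#' @export
write_molecules <- function(tbl, path) {
  .write_schema_csv(tbl, path, "molecules")
}

#' @rdname pipeline_io
#' @export
read_beta <- function(path) {
  .read_schema_csv(path, c("molecule_id", "mean_alpha", "beta"))
}

#' @rdname pipeline_io
#' @export
write_beta <- function(tbl, path) {
  .write_schema_csv(tbl, path, "beta")
}

#' @rdname pipeline_io
#' @export
read_predictions <- function(path) {
  .read_schema_csv(path, c("molecule_id", "target_pred"))
}

#' @rdname pipeline_io
#' @export
write_predictions <- function(tbl, path) {
  .write_schema_csv(tbl, path, "predictions")
}

#' @rdname pipeline_io
#' @export
write_estimates <- function(tbl, path) {
  .write_schema_csv(tbl, path, "estimates")
}

#' @rdname pipeline_io
#' @export
read_estimates <- function(path) {
  .read_schema_csv(path, c("molecule_id", "s_bar", "beta_pred",
                           "conc_estimate_mg_per_kg"))
}
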