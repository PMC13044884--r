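# Descriptor-table import (PaDEL export dialect) and impurity-based
# reduction to the main features.

#' Load a molecular descriptor table
#'
#' Parses a PaDEL-dialect CSV: a molecule-id column (named `Name` in PaDEL
#' exports, or `molecule_id`) followed by numeric descriptor columns with
#' their names in the header. Empty and NA cells are imputed with the column
#' median and recorded in the `imputed` attribute; constant-valued columns
#' are retained but listed in the `constant_columns` attribute.
#'
#' @param path Path to a delimited file.
#' @return A tibble: `molecule_id` plus one numeric column per descriptor.
#' @export
load_descriptor_table <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  idcol <- intersect(c("molecule_id", "Name", "name"), names(raw))[1]
  if (is.na(idcol)) stop("no molecule id column (molecule_id/Name) in ", path,
                         call. = FALSE)
  ids <- as.character(raw[[idcol]])
  if (anyDuplicated(ids)) {
    stop("duplicate molecule ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  vals <- raw[setdiff(names(raw), idcol)]
  for (j in names(vals)) {
    if (!is.numeric(vals[[j]])) {
      conv <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(!is.na(vals[[j]]) & is.na(conv) &
                     !vals[[j]] %in% c("NA", "", "Infinity", "-Infinity"))
      if (length(bad)) {
        stop("non-numeric cell at row ", bad[1], ", column '", j, "' of ",
             path, call. = FALSE)
      }
      vals[[j]] <- conv
    }
  }
  imputed <- tibble::tibble(molecule_id = character(0), descriptor = character(0))
  for (j in names(vals)) {
    na <- which(!is.finite(vals[[j]]))
    if (length(na)) {
      med <- stats::median(vals[[j]], na.rm = TRUE)
      if (!is.finite(med)) med <- 0
      vals[[j]][na] <- med
      imputed <- dplyr::bind_rows(imputed, tibble::tibble(
        molecule_id = ids[na], descriptor = j))
    }
  }
  const <- names(vals)[vapply(vals, function(v) length(unique(v)) == 1L, TRUE)]
  out <- dplyr::bind_cols(tibble::tibble(molecule_id = ids), vals)
  attr(out, "imputed") <- imputed
  attr(out, "constant_columns") <- const
  out
}

#' @rdname load_descriptor_table
#' @param table A descriptor tibble (`molecule_id` + numeric columns).
#' @export
write_descriptor_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' Select the main descriptors by random-forest impurity importance
#'
#' Fits the package's random-forest configuration (500 trees, depth 4) on
#' all descriptors and returns the `k` names with the largest mean impurity
#' decrease. Deterministic for a fixed seed; ties are broken by descriptor
#' name order.
#'
#' @param table Descriptor tibble (`molecule_id` + numeric columns).
#' @param targets Numeric targets aligned with the table rows.
#' @param k Number of descriptors to keep (default 11).
#' @param seed Integer seed for the forest.
#' @return Character vector of `k` descriptor names, most important first.
#' @export
select_main_features <- function(table, targets, k = 11L, seed = 1L) {
  tb <- tibble::as_tibble(table)
  feats <- setdiff(names(tb), "molecule_id")
  stopifnot(length(targets) == nrow(tb))
  if (k > length(feats)) {
    stop("k = ", k, " exceeds the ", length(feats), " available descriptors",
         call. = FALSE)
  }
  X <- as.data.frame(tb[feats])
  fit <- ranger::ranger(
    x = X, y = as.numeric(targets),
    num.trees = 500L, max.depth = 4L, importance = "impurity",
    seed = seed, num.threads = 1L)
  imp <- fit$variable.importance
  ord <- order(-imp, names(imp))
  names(imp)[ord][seq_len(k)]
}
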