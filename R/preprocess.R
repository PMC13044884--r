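# Signal preprocessing: raw spiked-sample measurements -> one beta value per
# molecule. ISTD correction, per-measurement response factors alpha = s_bar/c,
# averaging, and the single-pass +-0.5*mean relative-deviation outlier filter.

#' Internal-standard correction of a peak area
#'
#' `s_bar = s / s_ISTD`: the analyte area divided by the internal-standard
#' area of the same run, removing run-to-run technical variation.
#'
#' @param area Non-negative analyte peak area(s).
#' @param istd_area Positive internal-standard area(s).
#' @param sample_id Optional identifier(s) used in error messages.
#' @return The ISTD-corrected area(s).
#' @examples
#' istd_correct(100, 100)  # 1
#' @export
istd_correct <- function(area, istd_area, sample_id = NULL) {
  if (any(istd_area <= 0)) {
    bad <- which(istd_area <= 0)
    lab <- if (!is.null(sample_id)) paste(sample_id[bad], collapse = ", ")
           else paste(bad, collapse = ", ")
    stop("invalid measurement (istd_area <= 0): ", lab, call. = FALSE)
  }
  if (any(area < 0)) stop("negative peak area", call. = FALSE)
  area / istd_area
}

#' Per-molecule signal-to-concentration ratios
#'
#' Computes the per-measurement response factor `alpha = s_bar / c` for every
#' non-excluded row and groups them per molecule with their arithmetic mean.
#' Rows with a non-positive alpha (zero areas) and molecules named on the
#' exclusion list are dropped and reported in the `rejects` attribute with a
#' reason code, never silently.
#'
#' @param measurements A data frame with columns `sample_id`, `molecule_id`,
#'   `concentration_mg_per_kg`, `area`, `istd_area`.
#' @param exclusions Character vector of `sample_id` or `molecule_id` values
#'   to remove before computing anything (the audit trail for manual
#'   removals).
#' @return A tibble with one row per molecule: `molecule_id`, `alphas`
#'   (list-column of per-measurement values), `mean_alpha`, `n_kept`,
#'   `n_flagged` (0 until [flag_outliers()] runs). Attribute `rejects` is a
#'   tibble (`sample_id`, `molecule_id`, `reason`).
#' @export
compute_alpha <- function(measurements, exclusions = character(0)) {
  m <- tibble::as_tibble(measurements)
  need <- c("sample_id", "molecule_id", "concentration_mg_per_kg",
            "area", "istd_area")
  stopifnot(all(need %in% names(m)))
  if (any(m$concentration_mg_per_kg <= 0)) {
    stop("non-positive spiked concentration", call. = FALSE)
  }

  rejects <- tibble::tibble(sample_id = character(0),
                            molecule_id = character(0),
                            reason = character(0))
  excl <- m$sample_id %in% exclusions | m$molecule_id %in% exclusions
  if (any(excl)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      sample_id = m$sample_id[excl], molecule_id = m$molecule_id[excl],
      reason = "excluded"))
    m <- m[!excl, , drop = FALSE]
  }

  s_bar <- istd_correct(m$area, m$istd_area, m$sample_id)
  alpha <- s_bar / m$concentration_mg_per_kg
  nonpos <- alpha <= 0
  if (any(nonpos)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      sample_id = m$sample_id[nonpos], molecule_id = m$molecule_id[nonpos],
      reason = "nonpositive_alpha"))
    m <- m[!nonpos, , drop = FALSE]
    alpha <- alpha[!nonpos]
  }

  out <- tibble::tibble(molecule_id = m$molecule_id, alpha = alpha,
                        sample_id = m$sample_id) |>
    dplyr::group_by(.data$molecule_id) |>
    dplyr::summarise(
      alphas = list(stats::setNames(.data$alpha, .data$sample_id)),
      mean_alpha = mean(.data$alpha),
      n_kept = dplyr::n(),
      n_flagged = 0L,
      .groups = "drop")

  # molecules with nothing left, other than those excluded wholesale by name
  whole_mol_excl <- unique(measurements$molecule_id[
    measurements$molecule_id %in% exclusions])
  lost <- setdiff(unique(measurements$molecule_id),
                  c(out$molecule_id, whole_mol_excl))
  if (length(lost)) {
    rejects <- dplyr::bind_rows(rejects, tibble::tibble(
      sample_id = NA_character_, molecule_id = lost,
      reason = "no_usable_measurements"))
  }
  attr(out, "rejects") <- rejects
  out
}

#' Flag response-factor outliers by relative deviation from the mean
#'
#' Single pass: the mean over all values of a molecule is computed once,
#' every value deviating from it by more than `rel_threshold` times that mean
#' (strict inequality) is flagged and removed, and the mean is recomputed
#' over the kept values. If every value of a molecule would be flagged, all
#' are kept and a warning is emitted. Both the pre- and post-removal means
#' are returned (`mean_alpha_all`, `mean_alpha`); the post-removal mean is
#' canonical.
#'
#' @param alpha_records Output of [compute_alpha()].
#' @param rel_threshold Relative deviation threshold (default 0.5).
#' @return The records with `n_flagged`, recomputed `mean_alpha`,
#'   `mean_alpha_all`, and a `flagged` list-column of flagged sample ids.
#' @examples
#' rec <- compute_alpha(tibble::tibble(
#'   sample_id = as.character(1:3), molecule_id = "m",
#'   concentration_mg_per_kg = 1, area = c(10, 10, 22), istd_area = 1))
#' flag_outliers(rec)$mean_alpha  # 22 deviates by 8 > 7 -> flagged, mean 10
#' @export
flag_outliers <- function(alpha_records, rel_threshold = 0.5) {
  rec <- tibble::as_tibble(alpha_records)
  stopifnot(all(c("molecule_id", "alphas") %in% names(rec)))
  if (!nrow(rec)) stop("empty alpha record", call. = FALSE)

  res <- lapply(seq_len(nrow(rec)), function(i) {
    a <- rec$alphas[[i]]
    if (!length(a)) stop("empty alpha record for ", rec$molecule_id[i],
                         call. = FALSE)
    mu <- mean(a)
    flag <- abs(a - mu) > rel_threshold * mu
    if (all(flag)) {
      warning("all measurements of ", rec$molecule_id[i],
              " would be flagged; keeping all", call. = FALSE)
      flag[] <- FALSE
    }
    list(kept = a[!flag], flagged_ids = names(a)[flag], mean_all = mu)
  })
  rec$mean_alpha_all <- vapply(res, `[[`, 0, "mean_all")
  rec$mean_alpha <- vapply(res, function(r) mean(r$kept), 0)
  rec$n_flagged <- vapply(res, function(r) length(r$flagged_ids), 0L)
  rec$n_kept <- vapply(res, function(r) length(r$kept), 0L)
  rec$alphas <- lapply(res, `[[`, "kept")
  rec$flagged <- lapply(res, `[[`, "flagged_ids")
  attr(rec, "rejects") <- attr(alpha_records, "rejects")
  rec
}

#' Log-transform mean response factors into beta values
#'
#' `beta = ln(mean_alpha)`: the regression target learned from molecular
#' structure.
#'
#' @param alpha_records Output of [compute_alpha()] or [flag_outliers()].
#' @return A tibble: `molecule_id`, `mean_alpha`, `beta`, `n_kept`,
#'   `n_flagged`.
#' @export
compute_beta <- function(alpha_records) {
  rec <- tibble::as_tibble(alpha_records)
  if (any(rec$mean_alpha <= 0)) {
    stop("non-positive mean_alpha for ",
         paste(rec$molecule_id[rec$mean_alpha <= 0], collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(molecule_id = rec$molecule_id,
                        mean_alpha = rec$mean_alpha,
                        beta = log(rec$mean_alpha),
                        n_kept = rec$n_kept,
                        n_flagged = rec$n_flagged)
  attr(out, "rejects") <- attr(alpha_records, "rejects")
  out
}

#' Preprocess a measurement table into per-molecule beta values
#'
#' The full chain: exclusion list, ISTD correction, per-measurement alpha,
#' averaging, relative-deviation outlier filtering, log transform.
#'
#' @inheritParams compute_alpha
#' @inheritParams flag_outliers
#' @return The [compute_beta()] tibble; attributes `rejects` and `flagged`
#'   carry the audit trail.
#' @examples
#' \donttest{
#' study <- simulate_study(synthetic_spec(n_molecules = 4, signal_noise_cv = 0,
#'                                        beta_noise_sd = 0))
#' preprocess_measurements(study$measurements)
#' }
#' @export
preprocess_measurements <- function(measurements, exclusions = character(0),
                                    rel_threshold = 0.5) {
  rec <- compute_alpha(measurements, exclusions)
  rec <- flag_outliers(rec, rel_threshold)
  beta <- compute_beta(rec)
  attr(beta, "flagged") <- tibble::tibble(
    molecule_id = rep(rec$molecule_id, lengths(rec$flagged)),
    sample_id = unlist(rec$flagged, use.names = FALSE) %||% character(0))
  beta
}
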