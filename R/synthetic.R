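# Synthetic study generator: molecule sets from a small deterministic SMILES
# grammar, structure-dependent beta targets, and multi-level dilution-series
# measurement tables with controlled multiplicative noise and injectable
# outliers. Every downstream stage is testable against the ground truth this
# module records.

#' Specification of a synthetic spiked-blood study
#'
#' Defaults emulate the acquisition design the package targets: seven
#' concentration levels from a two-fold serial dilution spanning
#' 0.0015625-0.1 mg/kg, a fixed internal-standard area per sample, small
#' multiplicative signal noise, and a controllable fraction of one-sided
#' outlier rows whose relative offset exceeds the +-0.5 filter threshold so
#' that they are detectable by design.
#'
#' @param n_molecules Number of molecules.
#' @param concentration_levels Strictly positive, distinct spiking levels
#'   (mg/kg).
#' @param signal_noise_cv Coefficient of variation of the multiplicative
#'   signal noise.
#' @param beta_noise_sd SD of the Gaussian noise added to the structural
#'   beta rule.
#' @param outlier_fraction Fraction of measurement rows perturbed into
#'   outliers, in `[0, 1)`.
#' @param outlier_offset Relative one-sided perturbation of outlier rows;
#'   must exceed 0.5 so injected outliers violate the relative-deviation
#'   filter.
#' @param istd_area Internal-standard peak area used for every sample.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_molecules = 200L,
                           concentration_levels = 0.1 / 2^(0:6),
                           signal_noise_cv = 0.05,
                           beta_noise_sd = 0.1,
                           outlier_fraction = 0,
                           outlier_offset = 0.8,
                           istd_area = 1e4,
                           seed = 1L) {
  stopifnot(n_molecules >= 1,
            length(concentration_levels) >= 1,
            all(concentration_levels > 0),
            !anyDuplicated(concentration_levels),
            signal_noise_cv >= 0, beta_noise_sd >= 0,
            outlier_fraction >= 0, outlier_fraction < 1,
            outlier_offset > 0.5,
            istd_area > 0)
  structure(list(n_molecules = as.integer(n_molecules),
                 concentration_levels = as.numeric(concentration_levels),
                 signal_noise_cv = signal_noise_cv,
                 beta_noise_sd = beta_noise_sd,
                 outlier_fraction = outlier_fraction,
                 outlier_offset = outlier_offset,
                 istd_area = istd_area,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Deterministic SMILES grammar: scaffold x chain length x terminal group x
# halogen prefix. All strings are valid by construction and chemically
# drug-sized (1-16 heavy atoms).
.smiles_grammar <- function() {
  scaffolds <- c(chain = "", benzyl = "c1ccccc1", pyridyl = "c1ccncc1",
                 naphthyl = "c1ccc2ccccc2c1")
  chains <- 1:10
  terminals <- c(none = "", alcohol = "O", amine = "N")
  halos <- c(none = "", fluoro = "F", chloro = "Cl", bromo = "Br")
  out <- character(0)
  for (sc in names(scaffolds)) {
    for (n in chains) {
      for (tm in names(terminals)) {
        for (ha in names(halos)) {
          chain <- strrep("C", n)
          smi <- paste0(halos[[ha]], chain, terminals[[tm]])
          if (scaffolds[[sc]] != "") {
            # halogen on the chain start, scaffold fused at the end
            smi <- paste0(halos[[ha]], chain, scaffolds[[sc]])
            if (terminals[[tm]] != "") next  # keep aromatic variants simple
          }
          out <- c(out, smi)
        }
      }
    }
  }
  unique(out)
}

#' Generate synthetic molecules from a deterministic SMILES grammar
#'
#' Draws `n` distinct molecules from a fixed grammar of linear
#' alkanes/alcohols/amines, simple aromatics (benzene, pyridine, naphthalene
#' scaffolds with alkyl chains) and halogenated variants. Every generated
#' string parses in the featurization module.
#'
#' @param n Number of molecules (at most the grammar size, currently 240).
#' @param seed Integer seed; the same seed always yields the same list.
#' @return A tibble with `molecule_id` ("M001", ...) and `smiles`.
#' @examples
#' generate_molecules(5, seed = 7)
#' @export
generate_molecules <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  pool <- .smiles_grammar()
  if (n > length(pool)) {
    stop("grammar provides only ", length(pool), " distinct molecules; ",
         n, " requested", call. = FALSE)
  }
  smiles <- withr::with_seed(seed, sample(pool, n))
  tibble::tibble(
    molecule_id = sprintf("M%03d", seq_len(n)),
    smiles = smiles
  )
}

#' Assign structure-dependent beta targets
#'
#' The ground-truth rule is a fixed linear function of graph-computable
#' counts, `beta_true = 0.4 * n_heavy - 0.1 * n_aromatic + 0.8 *
#' has_nitrogen + eps`, `eps ~ N(0, noise_sd^2)`. The coefficients span
#' roughly three orders of magnitude in the response factor
#' `alpha = exp(beta)` over drug-sized molecules, and the deterministic part
#' is recoverable by both the descriptor baselines and the GAT.
#'
#' @param molecules A tibble with `molecule_id` and `smiles`.
#' @param noise_sd Non-negative SD of the Gaussian target noise.
#' @param seed Integer seed for the noise draw.
#' @return The tibble with a `beta_true` column appended.
#' @examples
#' \donttest{
#' assign_beta(tibble::tibble(molecule_id = "a", smiles = "CC"), noise_sd = 0)
#' }
#' @export
assign_beta <- function(molecules, noise_sd = 0.1, seed = 1L) {
  molecules <- tibble::as_tibble(molecules)
  stopifnot(noise_sd >= 0)
  cd <- count_descriptors(molecules)
  det <- 0.4 * cd$n_heavy - 0.1 * cd$n_aromatic + 0.8 * (cd$n_nitrogen > 0)
  eps <- withr::with_seed(seed, stats::rnorm(nrow(molecules), 0, noise_sd))
  molecules$beta_true <- det[match(molecules$molecule_id, cd$molecule_id)] + eps
  molecules
}

#' Generate a dilution-series measurement table
#'
#' For each molecule and each concentration level `c`, emits an analyte peak
#' area `s = exp(beta_true) * c * s_ISTD * (1 + delta)` with
#' `delta ~ N(0, signal_noise_cv^2)` and a fixed internal-standard area per
#' sample. A fraction `outlier_fraction` of rows (at most one per molecule,
#' so each injected outlier is detectable by the relative-deviation filter)
#' is additionally perturbed by the factor `(1 + outlier_offset)`.
#'
#' @param molecules_with_beta A tibble with `molecule_id`, `smiles`,
#'   `beta_true`.
#' @param spec A [synthetic_spec()].
#' @return A list: `measurements` (tibble: sample_id, molecule_id, smiles,
#'   concentration_mg_per_kg, area, istd_area), `ground_truth` (tibble:
#'   molecule_id, beta_true), `outliers` (tibble: sample_id, molecule_id —
#'   the injected rows).
#' @export
generate_measurements <- function(molecules_with_beta, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mols <- tibble::as_tibble(molecules_with_beta)
  if (!"beta_true" %in% names(mols)) {
    stop("beta targets must be assigned first (assign_beta())", call. = FALSE)
  }
  levels <- spec$concentration_levels
  if (!length(levels)) stop("empty concentration_levels", call. = FALSE)

  grid <- tidyr::expand_grid(
    molecule_id = mols$molecule_id,
    concentration_mg_per_kg = levels
  )
  grid <- dplyr::left_join(grid, mols[, c("molecule_id", "smiles", "beta_true")],
                           by = "molecule_id")
  n_rows <- nrow(grid)
  n_out <- round(spec$outlier_fraction * n_rows)
  if (n_out > nrow(mols)) {
    stop("outlier_fraction implies ", n_out, " outliers but only ",
         nrow(mols), " molecules are available for the one-per-molecule ",
         "layout", call. = FALSE)
  }

  withr::with_seed(spec$seed, {
    delta <- stats::rnorm(n_rows, 0, spec$signal_noise_cv)
    out_mols <- sample(mols$molecule_id, n_out)
  })
  area <- exp(grid$beta_true) * grid$concentration_mg_per_kg *
    spec$istd_area * (1 + delta)

  grid$sample_id <- sprintf("S%05d", seq_len(n_rows))
  is_outlier <- rep(FALSE, n_rows)
  if (n_out > 0) {
    # one randomly chosen row per selected molecule
    withr::with_seed(spec$seed + 1L, {
      for (m in out_mols) {
        rows <- which(grid$molecule_id == m)
        is_outlier[sample(rows, 1L)] <- TRUE
      }
    })
    area[is_outlier] <- area[is_outlier] * (1 + spec$outlier_offset)
  }

  measurements <- tibble::tibble(
    sample_id = grid$sample_id,
    molecule_id = grid$molecule_id,
    smiles = grid$smiles,
    concentration_mg_per_kg = grid$concentration_mg_per_kg,
    area = area,
    istd_area = spec$istd_area
  )
  list(
    measurements = measurements,
    ground_truth = tibble::tibble(molecule_id = mols$molecule_id,
                                  beta_true = mols$beta_true),
    outliers = tibble::tibble(sample_id = grid$sample_id[is_outlier],
                              molecule_id = grid$molecule_id[is_outlier])
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_molecules()], [assign_beta()] and
#' [generate_measurements()].
#'
#' @param spec A [synthetic_spec()].
#' @return The [generate_measurements()] list plus the `molecules` tibble.
#' @examples
#' \donttest{
#' study <- simulate_study(synthetic_spec(n_molecules = 5, seed = 3))
#' study$measurements
#' }
#' @export
simulate_study <- function(spec = synthetic_spec()) {
  mols <- generate_molecules(spec$n_molecules, seed = spec$seed)
  mols <- assign_beta(mols, noise_sd = spec$beta_noise_sd, seed = spec$seed + 1L)
  out <- generate_measurements(mols, spec)
  out$molecules <- mols
  out
}
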