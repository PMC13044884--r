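# Shared fixtures, built lazily and cached for the session: featurization
# calls out to OpenBabel, so the suite reuses one small featurized set.

.fixture_env <- new.env(parent = emptyenv())

# n featurized molecules with noiseless beta targets
fixture_molecules <- function(n = 16, seed = 11) {
  key <- paste0("mols_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    mols <- generate_molecules(n, seed = seed)
    mols <- featurize_molecules(mols)
    mols <- assign_beta(mols, noise_sd = 0, seed = seed)
    .fixture_env[[key]] <- mols
  }
  .fixture_env[[key]]
}

# hand-built graph with controllable features, bypassing chemistry
toy_graph <- function(n_nodes, edges, features, id = "toy") {
  g <- structure(
    list(molecule_id = id, smiles = NA_character_, n_nodes = n_nodes,
         edges = edges, elements = rep("C", n_nodes),
         node_order = seq_len(n_nodes), node_features = features),
    class = "mol_graph")
  g
}

# small measurement tibble from explicit alpha values, one molecule
measurements_from_alpha <- function(alpha, molecule_id = "m", conc = 1,
                                    istd = 1) {
  tibble::tibble(
    sample_id = paste0("s", seq_along(alpha)),
    molecule_id = molecule_id,
    concentration_mg_per_kg = conc,
    area = alpha * conc * istd,
    istd_area = istd)
}
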