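# SMILES -> molecular graph featurization for the GAT regressor and the
# descriptor baselines. Chemistry perception (SMILES parsing, aromaticity,
# SYBYL atom typing, 3D embedding) is delegated to OpenBabel through
# ChemmineOB; this file extracts fields from the MOL2 text it returns and
# derives the node-feature matrix.

# Element tables for the three scaled node features. vdW radii are Bondi's,
# covalent radii Cordero's, masses standard atomic weights. Scaling divides by
# a fixed constant: the maximum tabulated value over H-Rn (vdW 2.20 A for Rn,
# covalent 1.50 A for Rn, mass 222.0 for Rn), so all three columns lie in
# (0, 1] for any element this table knows.
.elements <- local({
  tb <- tibble::tribble(
    ~symbol, ~number, ~mass,    ~vdw,  ~covalent, ~valence_e, ~std_valence,
    "H",     1L,      1.008,    1.20,  0.31,      1L,         1L,
    "B",     5L,      10.81,    1.92,  0.84,      3L,         3L,
    "C",     6L,      12.011,   1.70,  0.76,      4L,         4L,
    "N",     7L,      14.007,   1.55,  0.71,      5L,         3L,
    "O",     8L,      15.999,   1.52,  0.66,      6L,         2L,
    "F",     9L,      18.998,   1.47,  0.57,      7L,         1L,
    "Si",    14L,     28.085,   2.10,  1.11,      4L,         4L,
    "P",     15L,     30.974,   1.80,  1.07,      5L,         3L,
    "S",     16L,     32.06,    1.80,  1.05,      6L,         2L,
    "Cl",    17L,     35.45,    1.75,  1.02,      7L,         1L,
    "Br",    35L,     79.904,   1.85,  1.20,      7L,         1L,
    "I",     53L,     126.904,  1.98,  1.39,      7L,         1L
  )
  tb$vdw_scaled <- tb$vdw / 2.20
  tb$covalent_scaled <- tb$covalent / 1.50
  tb$mass_scaled <- tb$mass / 222.0
  tb
})

#' Names of the 16 node-feature columns
#'
#' Twelve local atomic features in fixed order, then the four global shape
#' features copied onto every node.
#' @return Character vector of length 16.
#' @export
node_feature_names <- function() {
  c("atomic_number", "n_hydrogens", "n_valence_electrons",
    "n_radical_electrons", "formal_charge", "hybridization", "degree",
    "in_ring", "aromatic", "vdw_radius_scaled", "atomic_mass_scaled",
    "covalent_radius_scaled",
    "volume", "width", "length", "height")
}

# SYBYL atom type -> hybridization code.
# 0 unspecified, 1 sp, 2 sp2, 3 sp3, 4 sp3d, 5 sp3d2, 6 other.
.hybridization_code <- function(sybyl) {
  suffix <- sub("^[A-Za-z]+\\.?", "", sybyl)
  code <- dplyr::case_when(
    suffix == "1" ~ 1L,
    suffix %in% c("2", "ar", "am", "cat", "co2", "pl3") ~ 2L,
    suffix %in% c("3", "4", "spc", "t3p", "o", "o2", "th") ~ 3L,
    suffix == "" ~ 3L,   # bare halogen/metal types: single sigma framework
    TRUE ~ 6L
  )
  code
}

.obabel_convert <- function(smiles, ids, to = "MOL2", gen3d = FALSE, add_h = TRUE) {
  stopifnot(length(smiles) == length(ids), !anyDuplicated(ids))
  opts <- character(0)
  if (gen3d) opts <- c(opts, "gen3d")
  if (add_h) opts <- c(opts, "h")
  input <- paste(smiles, ids, sep = "\t", collapse = "\n")
  args <- if (length(opts)) {
    data.frame(names = opts, args = rep("", length(opts)))
  } else NULL
  out <- suppressWarnings(ChemmineOB::convertFormat("SMI", to, input, options = args))
  out
}

# Parse a multi-molecule MOL2 string into a named list of per-molecule
# records: atoms (symbol, x, y, z, sybyl), bonds (a1, a2, type), formal
# charges.
.parse_mol2 <- function(text) {
  blocks <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  out <- list()
  for (blk in blocks) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    name <- trimws(lines[which(nzchar(trimws(lines)))[1]])
    atom_at <- grep("^@<TRIPOS>ATOM", lines)
    bond_at <- grep("^@<TRIPOS>BOND", lines)
    attr_at <- grep("^@<TRIPOS>UNITY_ATOM_ATTR", lines)
    section_at <- grep("^@<TRIPOS>", lines)
    sec_end <- function(start) {
      nxt <- section_at[section_at > start]
      if (length(nxt)) nxt[1] - 1L else length(lines)
    }
    parse_rows <- function(start) {
      if (!length(start)) return(character(0))
      rows <- lines[(start + 1L):sec_end(start)]
      rows[nzchar(trimws(rows))]
    }
    atom_rows <- parse_rows(atom_at)
    atoms <- NULL
    if (length(atom_rows)) {
      f <- strsplit(trimws(atom_rows), "\\s+")
      atoms <- tibble::tibble(
        idx = as.integer(vapply(f, `[[`, "", 1L)),
        x = as.numeric(vapply(f, `[[`, "", 3L)),
        y = as.numeric(vapply(f, `[[`, "", 4L)),
        z = as.numeric(vapply(f, `[[`, "", 5L)),
        sybyl = vapply(f, `[[`, "", 6L)
      )
      atoms$symbol <- sub("\\..*$", "", atoms$sybyl)
      # MOL2 upcases two-letter symbols in the name column; the type column
      # keeps proper case ("Cl", "Br")
      atoms$symbol <- ifelse(atoms$symbol %in% .elements$symbol, atoms$symbol,
                             paste0(substr(atoms$symbol, 1, 1),
                                    tolower(substr(atoms$symbol, 2, 10))))
    }
    bond_rows <- parse_rows(bond_at)
    bonds <- tibble::tibble(a1 = integer(0), a2 = integer(0), type = character(0))
    if (length(bond_rows)) {
      f <- strsplit(trimws(bond_rows), "\\s+")
      bonds <- tibble::tibble(
        a1 = as.integer(vapply(f, `[[`, "", 2L)),
        a2 = as.integer(vapply(f, `[[`, "", 3L)),
        type = vapply(f, `[[`, "", 4L)
      )
    }
    charges <- numeric(nrow(atoms))
    if (length(attr_at)) {
      rows <- parse_rows(attr_at)
      i <- 1L
      while (i < length(rows)) {
        head <- as.integer(strsplit(trimws(rows[i]), "\\s+")[[1]])
        aid <- head[1]; nat <- head[2]
        for (j in seq_len(nat)) {
          kv <- strsplit(trimws(rows[i + j]), "\\s+")[[1]]
          if (identical(kv[1], "charge")) charges[aid] <- as.numeric(kv[2])
        }
        i <- i + 1L + nat
      }
    }
    out[[name]] <- list(atoms = atoms, bonds = bonds, formal_charge = charges)
  }
  out
}

.largest_fragment <- function(n_atoms, bonds) {
  g <- igraph::make_empty_graph(n = n_atoms, directed = FALSE)
  if (nrow(bonds)) g <- igraph::add_edges(g, rbind(bonds$a1, bonds$a2))
  comp <- igraph::components(g)
  if (comp$no <= 1L) return(list(keep = seq_len(n_atoms), dropped = 0L))
  main <- which.max(comp$csize)
  keep <- which(comp$membership == main)
  list(keep = keep, dropped = n_atoms - length(keep))
}

.new_mol_graph <- function(molecule_id, smiles, n_nodes, edges, elements,
                           node_features = NULL) {
  structure(
    list(molecule_id = molecule_id, smiles = smiles, n_nodes = n_nodes,
         edges = edges, elements = elements,
         node_order = seq_len(n_nodes), node_features = node_features),
    class = "mol_graph"
  )
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$molecule_id, ": ", x$n_nodes, " heavy atoms, ",
      nrow(x$edges), " bonds", sep = "")
  if (!is.null(x$node_features)) {
    cat(", ", ncol(x$node_features), "-column node features", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Convert a SMILES string to a heavy-atom molecular graph
#'
#' Atoms become nodes (hydrogens implicit), bonds become edges. Bond
#' multiplicity and aromaticity are deliberately not encoded on the edges:
#' the graph records only whether two heavy atoms are bound. Node indices are
#' 1-based and follow the SMILES parse order of the toolkit, which the
#' positional readout modes of the GAT rely on. Disconnected inputs (salts,
#' mixtures) are reduced to their largest fragment, recorded in the
#' `dropped_atoms` field.
#'
#' @param smiles A single SMILES string.
#' @param molecule_id Identifier attached to the graph (defaults to the
#'   SMILES itself).
#' @return A `mol_graph` object: `n_nodes`, two-column `edges` matrix of
#'   unordered 1-based node pairs, `elements`, `node_order`, and a
#'   `node_features` matrix once [atom_features()] / [assemble_node_matrix()]
#'   have run.
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_nodes   # 3
#' g$edges     # (1,2), (2,3)
#' @export
smiles_to_graph <- function(smiles, molecule_id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  parsed <- .featurize_batch_topology(smiles, molecule_id)
  parsed[[1]]
}

# Batch topology construction: one OpenBabel call for many molecules.
.featurize_batch_topology <- function(smiles, ids) {
  raw <- .obabel_convert(smiles, ids, gen3d = FALSE, add_h = TRUE)
  mols <- .parse_mol2(raw)
  missing <- setdiff(ids, names(mols))
  if (length(missing)) {
    bad <- smiles[match(missing, ids)]
    stop("unparseable SMILES for molecule(s) ", paste(missing, collapse = ", "),
         ": ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- vector("list", length(ids))
  names(out) <- ids
  for (i in seq_along(ids)) {
    m <- mols[[ids[i]]]
    heavy <- which(m$atoms$symbol != "H")
    frag <- .largest_fragment(nrow(m$atoms), m$bonds)
    keep_heavy <- intersect(heavy, frag$keep)
    if (!length(keep_heavy)) {
      stop("molecule ", ids[i], " has no heavy atoms", call. = FALSE)
    }
    hb <- m$bonds[m$bonds$a1 %in% keep_heavy & m$bonds$a2 %in% keep_heavy, , drop = FALSE]
    remap <- integer(nrow(m$atoms)); remap[keep_heavy] <- seq_along(keep_heavy)
    edges <- cbind(remap[hb$a1], remap[hb$a2])
    if (nrow(edges)) {
      edges <- t(apply(edges, 1L, sort))
      edges <- edges[!duplicated(edges) & edges[, 1] != edges[, 2], , drop = FALSE]
    }
    g <- .new_mol_graph(ids[i], smiles[i], length(keep_heavy), edges,
                        m$atoms$symbol[keep_heavy])
    g$dropped_atoms <- frag$dropped
    # carry the full parse for feature derivation
    g$.mol2 <- list(atoms = m$atoms, bonds = m$bonds,
                    formal_charge = m$formal_charge, keep_heavy = keep_heavy)
    out[[i]] <- g
  }
  out
}

#' Fill the 12 local atomic feature columns of a molecular graph
#'
#' Columns, in fixed order: atomic number, implicit+explicit hydrogen count,
#' valence-electron count of the element, radical-electron count, formal
#' charge, hybridization code (0 unspecified, 1 sp, 2 sp2, 3 sp3, 4 sp3d,
#' 5 sp3d2, 6 other), heavy-atom degree, in-ring flag, aromatic flag, and
#' scaled van der Waals radius, atomic mass and covalent radius (each divided
#' by its fixed H-Rn maximum: 2.20 A, 222.0 u, 1.50 A).
#'
#' @param graph A `mol_graph` from [smiles_to_graph()].
#' @return The graph with `node_features` holding the 12 local columns.
#' @export
atom_features <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  m <- graph$.mol2
  if (is.null(m)) stop("graph lacks its parse record; rebuild with smiles_to_graph()")
  heavy <- m$keep_heavy
  at <- m$atoms
  n <- length(heavy)

  el <- .elements[match(graph$elements, .elements$symbol), ]
  if (anyNA(el$number)) {
    bad <- unique(graph$elements[is.na(el$number)])
    stop("no tabulated radii for element(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # hydrogen count: explicit H neighbours (OpenBabel added all of them)
  h_idx <- which(at$symbol == "H")
  h_count <- integer(n)
  deg <- integer(n)
  if (nrow(m$bonds)) {
    for (k in seq_len(nrow(m$bonds))) {
      a <- m$bonds$a1[k]; b <- m$bonds$a2[k]
      ia <- match(a, heavy); ib <- match(b, heavy)
      if (!is.na(ia) && b %in% h_idx) h_count[ia] <- h_count[ia] + 1L
      if (!is.na(ib) && a %in% h_idx) h_count[ib] <- h_count[ib] + 1L
      if (!is.na(ia) && !is.na(ib)) { deg[ia] <- deg[ia] + 1L; deg[ib] <- deg[ib] + 1L }
    }
  }

  # ring membership: vertices of the 2-core of the heavy-atom graph lie on a
  # cycle; everything else does not (simple graphs)
  in_ring <- rep(0L, n)
  if (nrow(graph$edges)) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    g <- igraph::add_edges(g, t(graph$edges))
    in_ring <- as.integer(igraph::coreness(g) >= 2L)
  }

  # aromatic: in a ring and carrying at least one OpenBabel "ar" bond
  # (carboxylate O also gets "ar" bonds but is acyclic, hence the ring guard)
  has_ar <- rep(FALSE, nrow(at))
  arb <- m$bonds[m$bonds$type == "ar", , drop = FALSE]
  has_ar[unique(c(arb$a1, arb$a2))] <- TRUE
  aromatic <- as.integer(in_ring == 1L & has_ar[heavy])

  formal_charge <- m$formal_charge[heavy]

  # radical electrons via valence bookkeeping: unused valence of the element
  # after bonds, hydrogens and charge; 0 for closed-shell organics
  bond_order <- numeric(n)
  if (nrow(m$bonds)) {
    ord <- c(`1` = 1, `2` = 2, `3` = 3, am = 1, ar = 1.5, du = 1, un = 1)
    for (k in seq_len(nrow(m$bonds))) {
      o <- ord[[m$bonds$type[k]]] %||% 1
      ia <- match(m$bonds$a1[k], heavy); ib <- match(m$bonds$a2[k], heavy)
      if (!is.na(ia)) bond_order[ia] <- bond_order[ia] + o
      if (!is.na(ib)) bond_order[ib] <- bond_order[ib] + o
    }
  }
  radical <- pmax(0L, as.integer(round(el$std_valence + formal_charge - bond_order)))
  # aromatic ring closure rounds 1.5-bond sums up; treat within-0.5 as closed
  radical[abs(el$std_valence + formal_charge - bond_order) < 0.75] <- 0L

  hyb <- .hybridization_code(at$sybyl[heavy])

  feats <- cbind(
    atomic_number = el$number,
    n_hydrogens = h_count,
    n_valence_electrons = el$valence_e,
    n_radical_electrons = radical,
    formal_charge = formal_charge,
    hybridization = hyb,
    degree = deg,
    in_ring = in_ring,
    aromatic = aromatic,
    vdw_radius_scaled = el$vdw_scaled,
    atomic_mass_scaled = el$mass_scaled,
    covalent_radius_scaled = el$covalent_scaled
  )
  graph$node_features <- feats
  graph
}

#' Global 3D shape of a molecule
#'
#' Embeds one 3D conformer (OpenBabel distance-geometry `gen3d`, followed by
#' its force-field cleanup), then reports the molecule's extents along the
#' three principal axes of the heavy-atom coordinate cloud, sorted descending
#' into length >= width >= height, and its van der Waals volume. The volume is
#' the sum of atomic vdW spheres (explicit hydrogens included) minus the
#' pairwise sphere-sphere overlap lenses - a closed form that is exactly
#' invariant under rigid rotation and translation.
#'
#' @param smiles A single SMILES string.
#' @param conformer_seed Integer recorded with the result. The embedding
#'   protocol is deterministic, so the same SMILES always yields the same
#'   conformer; the seed is kept in the output for provenance.
#' @return A `global_shape` list: `volume` (A^3), `length`, `width`, `height`
#'   (A), `conformer_seed`.
#' @export
global_shape <- function(smiles, conformer_seed = 0L) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  raw <- .obabel_convert(smiles, "mol", gen3d = TRUE, add_h = TRUE)
  mols <- .parse_mol2(raw)
  if (!length(mols)) stop("3D embedding failed for SMILES: ", smiles, call. = FALSE)
  .shape_from_parsed(mols[[1]], conformer_seed, smiles)
}

.shape_from_parsed <- function(m, conformer_seed, label) {
  at <- m$atoms
  frag <- .largest_fragment(nrow(at), m$bonds)
  at <- at[frag$keep, , drop = FALSE]
  heavy <- at[at$symbol != "H", , drop = FALSE]
  xyz_h <- as.matrix(heavy[, c("x", "y", "z")])
  if (nrow(xyz_h) < 1L) stop("no heavy atoms in ", label, call. = FALSE)

  if (nrow(xyz_h) == 1L) {
    ext <- c(0, 0, 0)
  } else {
    cc <- sweep(xyz_h, 2L, colMeans(xyz_h))
    cv <- crossprod(cc) / nrow(cc)
    ax <- eigen(cv, symmetric = TRUE)$vectors
    proj <- cc %*% ax
    ext <- sort(apply(proj, 2L, function(p) diff(range(p))), decreasing = TRUE)
  }

  el <- .elements[match(at$symbol, .elements$symbol), ]
  if (anyNA(el$vdw)) {
    stop("no tabulated vdW radius for element(s): ",
         paste(unique(at$symbol[is.na(el$vdw)]), collapse = ", "), call. = FALSE)
  }
  r <- el$vdw
  vol <- sum(4 / 3 * pi * r^3)
  if (nrow(at) > 1L) {
    xyz <- as.matrix(at[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    for (i in seq_len(nrow(at) - 1L)) {
      for (j in (i + 1L):nrow(at)) {
        dij <- d[i, j]
        if (dij < r[i] + r[j]) {
          vol <- vol - .lens_volume(r[i], r[j], dij)
        }
      }
    }
  }
  structure(
    list(volume = vol, length = ext[1], width = ext[2], height = ext[3],
         conformer_seed = as.integer(conformer_seed)),
    class = "global_shape"
  )
}

# volume of the intersection of two spheres at centre distance d
.lens_volume <- function(r1, r2, d) {
  if (d <= abs(r1 - r2)) return(4 / 3 * pi * min(r1, r2)^3)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

#' Copy global shape features onto every node of a graph
#'
#' Appends columns 13-16 (volume, width, length, height), identical on every
#' row, to the 12 local columns: the GAT reads global molecular size directly
#' at each node instead of having to infer it through message passing.
#'
#' @param graph A `mol_graph` with its 12 local columns filled.
#' @param shape A `global_shape` for the same molecule.
#' @return The graph with a complete 16-column `node_features` matrix.
#' @export
assemble_node_matrix <- function(graph, shape) {
  stopifnot(inherits(graph, "mol_graph"), inherits(shape, "global_shape"))
  if (is.null(graph$node_features) || ncol(graph$node_features) < 12L) {
    stop("local atom features must be filled first (atom_features())")
  }
  glob <- matrix(rep(c(shape$volume, shape$width, shape$length, shape$height),
                     each = graph$n_nodes), nrow = graph$n_nodes)
  colnames(glob) <- c("volume", "width", "length", "height")
  graph$node_features <- cbind(graph$node_features[, 1:12, drop = FALSE], glob)
  graph$shape <- shape
  graph
}

#' Featurize a molecule table into GAT-ready graphs
#'
#' Runs [smiles_to_graph()], [atom_features()], [global_shape()] and
#' [assemble_node_matrix()] for every row, with a single batched OpenBabel
#' call for topology and one for 3D conformers.
#'
#' @param molecules A data frame with `molecule_id` and `smiles` columns.
#' @param conformer_seed Integer recorded with each conformer.
#' @return The input tibble with a `graph` list-column of `mol_graph` objects.
#' @examples
#' \donttest{
#' mols <- generate_molecules(5, seed = 1)
#' mols <- featurize_molecules(mols)
#' mols$graph[[1]]
#' }
#' @export
featurize_molecules <- function(molecules, conformer_seed = 0L) {
  molecules <- tibble::as_tibble(molecules)
  stopifnot(all(c("molecule_id", "smiles") %in% names(molecules)),
            !anyDuplicated(molecules$molecule_id))
  ids <- as.character(molecules$molecule_id)
  graphs <- .featurize_batch_topology(molecules$smiles, ids)
  graphs <- lapply(graphs, atom_features)

  raw3d <- .obabel_convert(molecules$smiles, ids, gen3d = TRUE, add_h = TRUE)
  mols3d <- .parse_mol2(raw3d)
  missing <- setdiff(ids, names(mols3d))
  if (length(missing)) {
    stop("3D embedding failed for molecule(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(ids)) {
    shape <- .shape_from_parsed(mols3d[[ids[i]]], conformer_seed, ids[i])
    g <- assemble_node_matrix(graphs[[ids[i]]], shape)
    g$.mol2 <- NULL  # drop the parse cache once features are final
    graphs[[ids[i]]] <- g
  }
  molecules$graph <- unname(graphs)
  molecules
}

#' Graph-derived count descriptors
#'
#' A small interpretable descriptor set computed from the heavy-atom graph
#' alone (no 3D, no external engine): heavy-atom count, aromatic-atom count,
#' per-element counts, ring-atom count, bond count and mean degree. Useful as
#' a transparent feature set for the non-graph baselines.
#'
#' @param molecules A tibble with a `graph` list-column
#'   (from [featurize_molecules()]) or `molecule_id` + `smiles` columns.
#' @return A tibble: `molecule_id` plus one numeric column per descriptor.
#' @export
count_descriptors <- function(molecules) {
  molecules <- tibble::as_tibble(molecules)
  if (!"graph" %in% names(molecules)) {
    graphs <- .featurize_batch_topology(molecules$smiles,
                                        as.character(molecules$molecule_id))
    graphs <- lapply(graphs, atom_features)
  } else {
    graphs <- molecules$graph
  }
  rows <- lapply(graphs, function(g) {
    f <- g$node_features
    tibble::tibble(
      molecule_id = g$molecule_id,
      n_heavy = g$n_nodes,
      n_aromatic = sum(f[, "aromatic"]),
      n_ring = sum(f[, "in_ring"]),
      n_carbon = sum(g$elements == "C"),
      n_nitrogen = sum(g$elements == "N"),
      n_oxygen = sum(g$elements == "O"),
      n_halogen = sum(g$elements %in% c("F", "Cl", "Br", "I")),
      n_bonds = nrow(g$edges),
      n_hydrogens = sum(f[, "n_hydrogens"]),
      mean_degree = mean(f[, "degree"])
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize a molecular graph to a JSON record
#'
#' Edges plus the row-major feature matrix, for caching featurization between
#' pipeline stages.
#' @param graph A `mol_graph`.
#' @return A JSON string.
#' @export
mol_graph_to_json <- function(graph) {
  jsonlite::toJSON(list(
    molecule_id = graph$molecule_id, smiles = graph$smiles,
    n_nodes = graph$n_nodes,
    edges = if (nrow(graph$edges)) unname(graph$edges) else matrix(0L, 0, 2),
    elements = graph$elements,
    feature_names = colnames(graph$node_features),
    node_features = if (is.null(graph$node_features)) NULL else
      unname(graph$node_features)
  ), auto_unbox = TRUE, digits = NA)
}

#' @rdname mol_graph_to_json
#' @param json A JSON string from [mol_graph_to_json()].
#' @export
mol_graph_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  feats <- NULL
  if (!is.null(x$node_features)) {
    feats <- matrix(unlist(x$node_features), nrow = x$n_nodes, byrow = FALSE)
    if (is.matrix(x$node_features)) feats <- x$node_features
    colnames(feats) <- x$feature_names
  }
  edges <- matrix(as.integer(unlist(x$edges)), ncol = 2)
  g <- .new_mol_graph(x$molecule_id, x$smiles, x$n_nodes, edges, x$elements, feats)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
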