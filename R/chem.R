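#' Atom feature schema for molecular graphs
#'
#' Describes, block by block, how heavy atoms are encoded as fixed-width
#' numeric feature vectors. Graphs featurized under different schema versions
#' are not interchangeable: every trained model carries the schema version it
#' was fit under and refuses graphs from another one.
#'
#' The default (and currently only) schema, `"bk-atom-v1"`, encodes each
#' heavy atom as a 30-dimensional vector:
#' element one-hot over C, N, O, S, F, Cl, Br, I, P, B, other (11);
#' heavy-atom degree one-hot 0-5 (6); formal charge as a scalar (1);
#' hybridization one-hot sp/sp2/sp3/other (4); aromaticity flag (1);
#' ring-membership flag (1); attached-hydrogen count one-hot 0-4 (5);
#' chirality flag (1). Hydrogens are implicit: graphs contain heavy atoms
#' only, with hydrogen counts folded into the node features.
#'
#' @param version Schema version tag. Only `"bk-atom-v1"` is defined.
#' @return A `feature_schema` object with fields `version`, `blocks`
#'   (a tibble of name/width/encoding), and `d_node` (total feature width).
#' @export
#' @examples
#' feature_schema()$d_node
feature_schema <- function(version = "bk-atom-v1") {
  if (!identical(version, "bk-atom-v1")) {
    stop_bk(sprintf("Unknown feature schema version '%s'.", version),
            "bkscore_schema_error")
  }
  blocks <- tibble(
    name = c("element", "degree", "formal_charge", "hybridization",
             "aromatic", "in_ring", "num_h", "chiral"),
    width = c(11L, 6L, 1L, 4L, 1L, 1L, 5L, 1L),
    encoding = c("one-hot C,N,O,S,F,Cl,Br,I,P,B,other", "one-hot 0-5",
                 "scalar", "one-hot sp,sp2,sp3,other", "flag", "flag",
                 "one-hot 0-4 (capped)", "flag")
  )
  structure(
    list(version = version, blocks = blocks, d_node = sum(blocks$width),
         elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "B")),
    class = "feature_schema"
  )
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema ", x$version, "> d_node = ", x$d_node, "\n", sep = "")
  print(x$blocks)
  invisible(x)
}

ob_convert <- function(from, to, text, add_h = FALSE) {
  if (add_h) {
    ChemmineOB::convertFormat(from, to, text,
                              options = data.frame(names = "h", args = ""))
  } else {
    ChemmineOB::convertFormat(from, to, text)
  }
}

# molfile atom-block charge codes (field 6) to formal charges
.molfile_charge <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0,
                     `5` = -1, `6` = -2, `7` = -3)

.elem_z <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11, Mg = 12,
             Si = 14, P = 15, S = 16, Cl = 17, K = 19, Ca = 20, Fe = 26,
             Cu = 29, Zn = 30, As = 33, Se = 34, Br = 35, I = 53)

atomic_number <- function(sym) {
  z <- unname(.elem_z[sym])
  z[is.na(z)] <- 110
  as.integer(z)
}

count_atoms_in_smiles <- function(s) {
  # rough heavy-atom count used only to pick the largest fragment of a salt
  s <- gsub("\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]", "", s)          # explicit hydrogens
  n_br <- stringr::str_count(s, "\\[[^]]+\\]")
  bare <- gsub("\\[[^]]+\\]", "", s)
  n_two <- stringr::str_count(bare, "Cl|Br")
  bare <- gsub("Cl|Br", "", bare)
  n_br + n_two + stringr::str_count(bare, "[BCNOPSFIbcnops]")
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to the unique OpenBabel canonical form, so that any two
#' valid spellings of the same molecule map to the same string. Multi-fragment
#' inputs (salts, counter-ions) are reduced to the largest covalent fragment
#' with a warning. Unparseable SMILES raise an error carrying the offending
#' string; they are never skipped silently.
#'
#' @param smiles Character vector of SMILES.
#' @param keep_largest_fragment Drop all but the largest covalent fragment of
#'   dot-disconnected inputs (default `TRUE`).
#' @return Character vector of canonical SMILES, same length as the input.
#' @export
#' @examples
#' canonicalize_smiles(c("OCC", "C(C)O"))  # both ethanol
canonicalize_smiles <- function(smiles, keep_largest_fragment = TRUE) {
  stopifnot(is.character(smiles))
  # fast path: one batched OpenBabel call; falls back to the per-molecule
  # path (which attributes errors to their SMILES) on any parse failure
  if (length(smiles) > 1L && !anyNA(smiles)) {
    out <- tryCatch(
      ob_convert("SMI", "CAN", paste0(paste(trimws(smiles),
                                            collapse = "\n"), "\n")),
      error = function(e) "")
    lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == length(smiles) &&
        !any(grepl(".", lines, fixed = TRUE))) {
      return(lines)
    }
  }
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) {
      stop_bk("Empty SMILES string.", "bkscore_invalid_molecule",
              smiles = s)
    }
    s <- trimws(s)
    can <- trimws(ob_convert("SMI", "CAN", paste0(s, "\n")))
    if (!nzchar(can)) {
      stop_bk(sprintf("SMILES '%s' could not be parsed.", s),
              "bkscore_invalid_molecule", smiles = s)
    }
    if (grepl(".", can, fixed = TRUE) && keep_largest_fragment) {
      frags <- strsplit(can, ".", fixed = TRUE)[[1]]
      sizes <- vapply(frags, count_atoms_in_smiles, numeric(1))
      warn(sprintf(
        "SMILES '%s' has %d fragments; keeping the largest (%s).",
        s, length(frags), frags[which.max(sizes)]))
      # re-canonicalize the kept fragment on its own
      can <- trimws(ob_convert("SMI", "CAN",
                               paste0(frags[which.max(sizes)], "\n")))
    }
    can
  }, character(1), USE.NAMES = FALSE)
}

# per-heavy-atom chirality and aromaticity flags, scanned from a canonical
# SMILES (atom order in the OpenBabel SDF follows the SMILES atom order;
# lowercase atoms carry OpenBabel's own aromaticity perception)
smiles_atom_flags <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  chiral <- logical(0); aromatic <- logical(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      tok <- paste0(chars[i:j], collapse = "")
      # bracketed hydrogen isotopes are not heavy atoms
      if (!grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", tok)) {
        chiral <- c(chiral, grepl("@", tok, fixed = TRUE))
        aromatic <- c(aromatic,
                      grepl("^\\[[0-9]*[a-z]", tok))
      }
      i <- j + 1L
    } else if (i < n && ch == "C" && chars[i + 1L] == "l") {
      chiral <- c(chiral, FALSE); aromatic <- c(aromatic, FALSE); i <- i + 2L
    } else if (i < n && ch == "B" && chars[i + 1L] == "r") {
      chiral <- c(chiral, FALSE); aromatic <- c(aromatic, FALSE); i <- i + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      chiral <- c(chiral, FALSE); aromatic <- c(aromatic, FALSE); i <- i + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      chiral <- c(chiral, FALSE); aromatic <- c(aromatic, TRUE); i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  list(chiral = chiral, aromatic = aromatic)
}

# parse one ChemmineR SDF molecule into a heavy-atom graph under a schema
sdf_to_graph <- function(sdf, canonical, schema) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  sym <- sub("_.*$", "", rownames(ab))
  heavy <- which(!sym %in% c("H", "D", "T"))
  n_heavy <- length(heavy)
  if (n_heavy < 1L) {
    stop_bk(sprintf("SMILES '%s' has no heavy atoms.", canonical),
            "bkscore_invalid_molecule", smiles = canonical)
  }
  remap <- integer(nrow(ab))
  remap[heavy] <- seq_len(n_heavy)

  if (is.null(dim(bb))) bb <- matrix(bb, nrow = length(bb) > 0, byrow = TRUE,
                                     dimnames = list(NULL, names(bb)))
  a1 <- if (nrow(bb)) as.integer(bb[, 1]) else integer(0)
  a2 <- if (nrow(bb)) as.integer(bb[, 2]) else integer(0)
  ord <- if (nrow(bb)) as.integer(bb[, 3]) else integer(0)

  n_h <- integer(n_heavy)
  deg <- integer(n_heavy)
  n_double <- integer(n_heavy)
  n_triple <- integer(n_heavy)
  src <- integer(0); dst <- integer(0)
  for (b in seq_along(a1)) {
    i <- a1[b]; j <- a2[b]
    hi <- i %in% heavy; hj <- j %in% heavy
    if (hi && hj) {
      ii <- remap[i]; jj <- remap[j]
      deg[ii] <- deg[ii] + 1L; deg[jj] <- deg[jj] + 1L
      if (ord[b] == 2L) { n_double[ii] <- n_double[ii] + 1L
                          n_double[jj] <- n_double[jj] + 1L }
      if (ord[b] == 3L) { n_triple[ii] <- n_triple[ii] + 1L
                          n_triple[jj] <- n_triple[jj] + 1L }
      src <- c(src, ii, jj); dst <- c(dst, jj, ii)
    } else if (hi && !hj) {
      n_h[remap[i]] <- n_h[remap[i]] + 1L
    } else if (hj && !hi) {
      n_h[remap[j]] <- n_h[remap[j]] + 1L
    }
  }

  charge_code <- if ("C6" %in% colnames(ab)) ab[heavy, "C6"] else rep(0, n_heavy)
  charge <- unname(.molfile_charge[as.character(charge_code)])
  charge[is.na(charge)] <- 0

  flags <- smiles_atom_flags(canonical)
  aromatic <- flags$aromatic
  chiral <- flags$chiral
  if (length(aromatic) != n_heavy) aromatic <- rep(FALSE, n_heavy)
  if (length(chiral) != n_heavy) chiral <- rep(FALSE, n_heavy)

  # an atom lies on a ring iff it is an endpoint of a non-bridge edge
  in_ring <- logical(n_heavy)
  bond_in_ring <- logical(length(src) / 2L)
  if (length(src)) {
    half <- seq(1L, length(src), by = 2L)
    el <- cbind(src[half], dst[half])
    ig <- igraph::graph_from_edgelist(el, directed = FALSE)
    br <- igraph::bridges(ig)
    bond_in_ring <- !(seq_len(nrow(el)) %in% as.integer(br))
    ring_atoms <- unique(as.vector(el[bond_in_ring, , drop = FALSE]))
    in_ring[ring_atoms] <- TRUE
  }

  hyb <- ifelse(n_triple > 0 | n_double >= 2, "sp",
         ifelse(aromatic | n_double == 1, "sp2", "sp3"))

  elems <- schema$elements
  sym_h <- sym[heavy]
  feat <- matrix(0, nrow = n_heavy, ncol = schema$d_node)
  one_hot <- function(value, levels) {
    m <- matrix(0, length(value), length(levels) + 1L)
    pos <- match(value, levels)
    pos[is.na(pos)] <- length(levels) + 1L
    m[cbind(seq_along(value), pos)] <- 1
    m
  }
  col <- 0L
  blk <- one_hot(sym_h, elems); feat[, col + seq_len(11)] <- blk; col <- col + 11L
  blk <- one_hot(pmin(deg, 5L), 0:4); feat[, col + seq_len(6)] <- blk; col <- col + 6L
  feat[, col + 1L] <- charge; col <- col + 1L
  blk <- one_hot(hyb, c("sp", "sp2", "sp3")); feat[, col + seq_len(4)] <- blk
  col <- col + 4L
  feat[, col + 1L] <- as.numeric(aromatic); col <- col + 1L
  feat[, col + 1L] <- as.numeric(in_ring); col <- col + 1L
  blk <- one_hot(pmin(n_h, 4L), 0:3); feat[, col + seq_len(5)] <- blk; col <- col + 5L
  feat[, col + 1L] <- as.numeric(chiral)

  # undirected heavy-atom bond list with effective order (4 = aromatic)
  bnd <- matrix(integer(0), ncol = 3,
                dimnames = list(NULL, c("i", "j", "order")))
  if (length(src)) {
    half <- seq(1, length(src), by = 2)
    bi <- src[half]; bj <- dst[half]
    bord <- rep(1L, length(bi))
    k <- 1L
    for (b in seq_along(a1)) {
      if (a1[b] %in% heavy && a2[b] %in% heavy) {
        bord[k] <- ord[b]
        if (bond_in_ring[k] && aromatic[remap[a1[b]]] &&
            aromatic[remap[a2[b]]]) bord[k] <- 4L
        k <- k + 1L
      }
    }
    bnd <- cbind(i = bi, j = bj, order = bord)
  }

  structure(
    list(node_features = feat,
         arcs = cbind(src = src, dst = dst),
         bonds = bnd,
         n_atoms = n_heavy,
         canonical_smiles = canonical,
         schema_version = schema$version,
         counts = list(n_heavy = n_heavy,
                       n_carbon = sum(sym_h == "C"),
                       n_hetero = sum(!sym_h %in% c("C", "H")),
                       n_rings = length(src) / 2L - n_heavy + 1L,
                       n_aromatic = sum(aromatic)),
         atom_invariants = cbind(z = atomic_number(sym_h),
                                 degree = deg, n_h = n_h, charge = charge,
                                 aromatic = as.integer(aromatic),
                                 in_ring = as.integer(in_ring))),
    class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$canonical_smiles, ": ", x$n_atoms, " atoms, ",
      nrow(x$arcs), " directed arcs, d_node = ", ncol(x$node_features),
      " (", x$schema_version, ")\n", sep = "")
  invisible(x)
}

featurize_smiles <- function(smiles, schema = feature_schema()) {
  can <- canonicalize_smiles(smiles)
  sdf_txt <- ob_convert("SMI", "SDF",
                        paste0(paste(can, collapse = "\n"), "\n"),
                        add_h = TRUE)
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_txt, tmp)
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  if (length(sdfs) != length(can)) {
    stop_bk("SMILES to SDF conversion dropped molecules.",
            "bkscore_invalid_molecule")
  }
  lapply(seq_along(can), function(i) sdf_to_graph(sdfs[[i]], can[i], schema))
}

#' Convert a SMILES string to a molecular graph
#'
#' Parses a SMILES string into a heavy-atom graph: one node per heavy atom
#' (hydrogens implicit) with schema-defined feature vectors, and every
#' chemical bond represented as two directed arcs. Node order follows the
#' canonical atom ranking, so any SMILES spelling of the same molecule yields
#' a bit-identical graph.
#'
#' @param smiles A single SMILES string.
#' @param schema A [feature_schema()].
#' @return A `molgraph` object: `node_features` (n_atoms x d_node matrix),
#'   `arcs` (two-column matrix of directed atom-index pairs), `n_atoms`,
#'   `canonical_smiles`, `schema_version`, and `counts` (heavy atoms, carbons,
#'   heteroatoms, rings, aromatic atoms).
#' @export
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms       # 3
#' nrow(g$arcs)    # 4 directed arcs (2 bonds)
smiles_to_graph <- function(smiles, schema = feature_schema()) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  featurize_smiles(smiles, schema)[[1]]
}

#' Featurize a table of molecules
#'
#' Data-frame-first wrapper around [smiles_to_graph()]: adds a
#' `canonical_smiles` column and a `graph` list-column to the input table.
#'
#' @param data A data frame with a SMILES column.
#' @param smiles_col Name of the SMILES column (default `"smiles"`).
#' @param schema A [feature_schema()].
#' @return The input as a tibble with `canonical_smiles` and `graph` added.
#' @export
featurize_molecules <- function(data, smiles_col = "smiles",
                                schema = feature_schema()) {
  stopifnot(is.data.frame(data), smiles_col %in% names(data))
  data <- as_tibble(data)
  graphs <- featurize_smiles(data[[smiles_col]], schema)
  data$canonical_smiles <- vapply(graphs, `[[`, "", "canonical_smiles")
  data$graph <- graphs
  data
}

# deterministic polynomial hash of an integer vector into [0, 2^28)
hash_ints <- function(ints) {
  h <- 17
  for (v in ints) h <- (h * 31 + (v %% 2^28)) %% 2^28
  h
}

# circular (Morgan/ECFP-style) identifiers of one molecular graph:
# iterative neighborhood hashing with duplicate-environment removal
morgan_identifiers <- function(graph, radius) {
  n <- graph$n_atoms
  inv <- apply(graph$atom_invariants, 1, hash_ints)
  ids <- inv
  if (radius == 0L || nrow(graph$bonds) == 0L) {
    # isolated-atom environments beyond radius 0 add nothing
    return(unique(ids))
  }
  bonds <- graph$bonds
  nbr <- lapply(seq_len(n), function(i) {
    sel <- which(bonds[, "i"] == i | bonds[, "j"] == i)
    other <- ifelse(bonds[sel, "i"] == i, bonds[sel, "j"], bonds[sel, "i"])
    cbind(bond = sel, atom = other, order = bonds[sel, "order"])
  })
  env_bonds <- lapply(seq_len(n), function(i) integer(0))
  seen_envs <- character(0)
  for (r in seq_len(radius)) {
    new_inv <- numeric(n)
    new_env <- vector("list", n)
    keep <- logical(n)
    for (i in seq_len(n)) {
      nb <- nbr[[i]]
      if (nrow(nb) == 0L) { new_inv[i] <- inv[i]; new_env[i] <- list(integer(0)); next }
      pairs <- cbind(nb[, "order"], inv[nb[, "atom"]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      new_inv[i] <- hash_ints(c(r, inv[i], t(pairs)))
      eb <- sort(unique(c(env_bonds[[i]], nb[, "bond"],
                          unlist(env_bonds[nb[, "atom"]]))))
      new_env[[i]] <- eb
      key <- paste(eb, collapse = ",")
      if (length(eb) && !key %in% seen_envs) {
        seen_envs <- c(seen_envs, key)
        keep[i] <- TRUE
      }
    }
    ids <- c(ids, new_inv[keep])
    inv <- new_inv
    env_bonds <- new_env
  }
  unique(ids)
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Hashed circular substructure fingerprint (ECFP family): atoms start from an
#' invariant hash (atomic number, heavy degree, attached hydrogens, formal
#' charge, aromaticity, ring membership) and are iteratively re-hashed with
#' their sorted (bond order, neighbor) environment up to the given radius.
#' Environments covering an identical bond set to one already enumerated are
#' discarded, so e.g. methane sets exactly one bit. Identifiers are folded to
#' `n_bits` by modulo; counts are folded to presence/absence bits.
#' Deterministic given the canonical molecule, radius and width.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighborhood radius (default 2, i.e. ECFP4).
#' @param n_bits Folded fingerprint length (default 2048).
#' @return A `fingerprint` object with `bits` (0/1 integer vector of length
#'   `n_bits`), `radius`, `n_bits` and `canonical_smiles`.
#' @export
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' sum(fp$bits)
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 2048L) {
  m <- morgan_matrix(tibble(smiles = smiles), radius = radius, n_bits = n_bits)
  structure(list(bits = m[1L, ], radius = as.integer(radius),
                 n_bits = as.integer(n_bits),
                 canonical_smiles = rownames(m)[1L]),
            class = "fingerprint")
}

#' Morgan fingerprint matrix for a table of molecules
#'
#' @param data Data frame with a SMILES column, or a character vector.
#' @param smiles_col Name of the SMILES column.
#' @inheritParams morgan_fingerprint
#' @return Integer 0/1 matrix, one row per molecule (rownames = canonical
#'   SMILES), `n_bits` columns.
#' @export
morgan_matrix <- function(data, smiles_col = "smiles", radius = 2L,
                          n_bits = 2048L) {
  if (is.character(data)) data <- tibble(smiles = data)
  stopifnot(smiles_col %in% names(data))
  if (!radius %in% 0:5) {
    stop_bk("`radius` must be an integer in 0..5.", "bkscore_config_error")
  }
  if (n_bits < 1L) stop_bk("`n_bits` must be positive.", "bkscore_config_error")
  graphs <- featurize_smiles(data[[smiles_col]])
  out <- matrix(0L, nrow = length(graphs), ncol = n_bits)
  for (i in seq_along(graphs)) {
    ids <- morgan_identifiers(graphs[[i]], as.integer(radius))
    out[i, unique(ids %% n_bits) + 1L] <- 1L
  }
  rownames(out) <- vapply(graphs, `[[`, "", "canonical_smiles")
  out
}
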