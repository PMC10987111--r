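# Fragment alphabet for the assembly generator. Every fragment contributes
# exactly six heavy atoms and is written so that plain concatenation of
# fragment SMILES yields a valid molecule (the last atom of one fragment
# bonds to the first atom of the next). Keeping the heavy-atom count fixed
# makes the ground-truth label a function of composition, which a
# permutation-invariant mean/max readout can represent.
.bk_fragments <- c(
  hexyl        = "CCCCCC",
  pentanol     = "CCCCCO",
  pentylamine  = "CCCCCN",
  diether      = "CCOCCO",
  aminoether   = "CCNCCO",
  isohexyl     = "CCCC(C)C",
  cyclohexane  = "C1CCCCC1",
  benzene      = "c1ccccc1",
  oxane        = "C1CCOCC1",
  piperidine   = "C1CCNCC1",
  pyridine     = "c1ccncc1",
  thiane       = "C1CCSCC1",
  morpholine   = "C1COCCN1",
  midether     = "CCCOCC",
  midamine     = "CCCNCC",
  fluoroalkyl  = "CCCC(F)C",
  branchol     = "CCC(C)CO",
  aminoether2  = "CCOCCN",
  thiol        = "CCCCCS",
  isoamylol    = "CC(C)CCO",
  secol        = "CCCC(C)O",
  mecyclopent  = "C1CC(C)CC1",
  methylfuran  = "c1ccoc1C",
  methylthioph = "c1ccsc1C"
)

.bk_scaffold <- "c1ccc2ncccc2c1"  # quinoline-like core, echoes a fused
                                  # camptothecin-type ring system
.bk_substituents <- c("C", "CC", "CCC", "CC(C)C", "CCCC", "C1CCC1",
                      "CCCCC", "C1CCCC1", "CC(C)(C)C", "C1CCCCC1")

#' Specification for synthetic molecule generation
#'
#' Defines a generator of valid small-molecule SMILES with a known,
#' graph-computable structure-to-label ground truth plus additive Gaussian
#' noise. It stands in for the (undeposited) permeability and potency
#' training tables so the whole pipeline is testable offline.
#'
#' Label functions (counts taken over the heavy-atom graph):
#' * `lipophilicity_proxy`: `c0 + c1 * n_carbon - c2 * n_hetero + c3 * n_rings`
#' * `ring_hetero_mix`:     `c0 + c1 * n_aromatic - c2 * n_hetero + c3 * n_rings`
#'
#' With the default coefficients `(c0, c1, c2, c3) = (0.5, 0.2, 0.3, 0.5)`
#' the noiseless labels land on a log10-permeability-like scale (roughly 1 to
#' 6), and the default `noise_sd = 0.26` puts the theoretical R-squared
#' ceiling near 0.9.
#'
#' @param n_molecules Number of molecules to generate (default 2000).
#' @param generator `"fragment_assembly"` (three six-atom fragments sampled
#'   from a fixed alphabet) or `"scaffold_series"` (one fixed fused-ring
#'   scaffold decorated with substituents of increasing alkyl bulk).
#' @param label_function `"lipophilicity_proxy"` or `"ring_hetero_mix"`.
#' @param coefficients Numeric vector `c(c0, c1, c2, c3)`.
#' @param noise_sd Standard deviation of additive Gaussian label noise
#'   (label units, >= 0).
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_molecules = 2000L,
                           generator = c("fragment_assembly",
                                         "scaffold_series"),
                           label_function = c("lipophilicity_proxy",
                                              "ring_hetero_mix"),
                           coefficients = c(c0 = 0.5, c1 = 0.2,
                                            c2 = 0.3, c3 = 0.5),
                           noise_sd = 0.26,
                           seed = 1L) {
  generator <- match.arg(generator)
  label_function <- match.arg(label_function)
  if (n_molecules < 1) {
    stop_bk("`n_molecules` must be positive.", "bkscore_config_error")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) {
    stop_bk("`noise_sd` must be >= 0.", "bkscore_config_error")
  }
  if (length(coefficients) != 4L || any(!is.finite(coefficients))) {
    stop_bk("`coefficients` must be 4 finite numbers.", "bkscore_config_error")
  }
  structure(list(n_molecules = as.integer(n_molecules), generator = generator,
                 label_function = label_function,
                 coefficients = setNames(as.numeric(coefficients),
                                         c("c0", "c1", "c2", "c3")),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Ground-truth label of molecules under a synthetic spec
#'
#' Evaluates the spec's noiseless structure-to-label function on graph-level
#' atom/ring counts.
#'
#' @param spec A [synthetic_spec()].
#' @param smiles Character vector of SMILES (any valid molecules).
#' @return Numeric vector of noiseless labels.
#' @export
ground_truth_label <- function(spec, smiles) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ground_truth_from_graphs(spec, featurize_smiles(smiles))
}

ground_truth_from_graphs <- function(spec, graphs) {
  co <- spec$coefficients
  vapply(graphs, function(g) {
    cts <- g$counts
    first <- switch(spec$label_function,
                    lipophilicity_proxy = cts$n_carbon,
                    ring_hetero_mix = cts$n_aromatic)
    co[["c0"]] + co[["c1"]] * first - co[["c2"]] * cts$n_hetero +
      co[["c3"]] * cts$n_rings
  }, numeric(1))
}

#' Generate a synthetic labeled dataset
#'
#' Composes molecules according to the spec's generator, evaluates the
#' ground-truth label function on each molecular graph, and adds seeded
#' Gaussian noise. Regenerating with the same spec reproduces molecules and
#' labels exactly.
#'
#' @param spec A [synthetic_spec()].
#' @return A [labeled_dataset()] (label_kind `"synthetic"`) with an extra
#'   `true_label` column; the spec is attached as attribute `synthetic_spec`.
#' @export
#' @examples
#' ds <- generate_dataset(synthetic_spec(n_molecules = 10))
#' ds[, c("canonical_smiles", "label", "true_label")]
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  smiles <- withr::with_seed(spec$seed, {
    if (spec$generator == "fragment_assembly") {
      nf <- length(.bk_fragments)
      n_space <- nf^3
      draw <- sample.int(n_space,
                         min(n_space, ceiling(1.3 * spec$n_molecules) + 50L))
      trip <- cbind((draw - 1L) %% nf,
                    ((draw - 1L) %/% nf) %% nf,
                    (draw - 1L) %/% (nf * nf)) + 1L
      # a fragment sequence and its reversal assemble the same molecule
      # whenever the fragments are symmetric; dedup on the orientation-free key
      key <- pmin(apply(trip, 1, paste, collapse = "."),
                  apply(trip[, 3:1, drop = FALSE], 1, paste, collapse = "."))
      trip <- trip[!duplicated(key), , drop = FALSE]
      trip <- trip[seq_len(min(nrow(trip), spec$n_molecules)), , drop = FALSE]
      apply(trip, 1, function(ix) paste0(.bk_fragments[ix], collapse = ""))
    } else {
      if (spec$n_molecules > length(.bk_substituents)) {
        stop_bk(sprintf(
          "scaffold_series defines %d molecules of increasing bulk; asked for %d.",
          length(.bk_substituents), spec$n_molecules), "bkscore_config_error")
      }
      paste0(.bk_substituents[seq_len(spec$n_molecules)], .bk_scaffold)
    }
  })
  graphs <- featurize_smiles(smiles)
  can <- vapply(graphs, `[[`, "", "canonical_smiles")
  truth <- ground_truth_from_graphs(spec, graphs)
  noise <- withr::with_seed(spec$seed + 1L,
                            rnorm(length(truth), 0, spec$noise_sd))
  ds <- labeled_dataset(
    tibble(smiles = can, label = truth + noise, true_label = truth),
    label_kind = "synthetic", assume_canonical = TRUE,
    provenance = sprintf("synthetic:%s/%s seed=%d", spec$generator,
                         spec$label_function, spec$seed))
  ds$graph <- graphs[match(ds$canonical_smiles, can)]
  attr(ds, "synthetic_spec") <- spec
  ds
}

#' Theoretical R-squared ceiling of a synthetic task
#'
#' The best squared correlation any regressor can reach against noisy labels:
#' `Var(f) / (Var(f) + noise_sd^2)`, with `Var(f)` the population variance of
#' the noiseless ground truth over the generated set.
#'
#' @param x A [synthetic_spec()] (the set is regenerated) or a dataset from
#'   [generate_dataset()] (its stored `true_label` column is used).
#' @return A single number in (0, 1].
#' @export
theoretical_r2_ceiling <- function(x) {
  if (inherits(x, "synthetic_spec")) x <- generate_dataset(x)
  spec <- attr(x, "synthetic_spec")
  if (is.null(spec) || !"true_label" %in% names(x)) {
    stop_bk("Need a synthetic_spec or a dataset from generate_dataset().",
            "bkscore_config_error")
  }
  vf <- mean((x$true_label - mean(x$true_label))^2)
  if (vf <= 0) {
    stop_bk("Ground-truth labels are constant; ceiling undefined.",
            "bkscore_degenerate_labels")
  }
  vf / (vf + spec$noise_sd^2)
}
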