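#' Construct a labeled molecule dataset
#'
#' Canonicalizes SMILES, drops rows whose SMILES fail to parse or whose labels
#' are non-finite (each rejection is reported, never silent), and collapses
#' duplicate canonical SMILES. The result is the tabular container every
#' downstream step (splitting, training, comparison) consumes.
#'
#' @param data Data frame with at least a SMILES column and a label column.
#' @param smiles_col,label_col Column names (defaults `"smiles"`, `"label"`).
#' @param label_kind One of `"permeability_log10_nm_s"` (B-score models),
#'   `"activity_pic50"` (K-score models) or `"synthetic"`.
#' @param dedup How to resolve duplicate canonical SMILES: keep the
#'   `"first"` occurrence (default) or `"average"` the labels.
#' @param provenance Free-text origin note stored on the dataset.
#' @param assume_canonical Skip canonicalization when the SMILES column is
#'   already in canonical form (used by generators whose molecules come out
#'   of the featurizer).
#' @return A `labeled_dataset`: a tibble with columns `id`,
#'   `canonical_smiles`, `label`, `weight` plus any extra input columns, and
#'   attributes `label_kind`, `provenance`, `rejects` (tibble of dropped rows
#'   with reasons) and `n_duplicates`.
#' @export
labeled_dataset <- function(data, smiles_col = "smiles", label_col = "label",
                            label_kind = c("synthetic",
                                           "permeability_log10_nm_s",
                                           "activity_pic50"),
                            dedup = c("first", "average"),
                            provenance = "in-memory",
                            assume_canonical = FALSE) {
  label_kind <- match.arg(label_kind)
  dedup <- match.arg(dedup)
  if (!is.data.frame(data)) {
    stop_bk("`data` must be a data frame.", "bkscore_schema_error")
  }
  missing_cols <- setdiff(c(smiles_col, label_col), names(data))
  if (length(missing_cols)) {
    stop_bk(sprintf("Missing column(s): %s.",
                    paste(missing_cols, collapse = ", ")),
            "bkscore_schema_error")
  }
  data <- as_tibble(data)
  raw_smiles <- as.character(data[[smiles_col]])
  label <- suppressWarnings(as.numeric(data[[label_col]]))

  reason <- rep(NA_character_, nrow(data))
  if (assume_canonical) {
    can <- raw_smiles
  } else {
    can <- rep(NA_character_, nrow(data))
    for (i in seq_len(nrow(data))) {
      can[i] <- tryCatch(canonicalize_smiles(raw_smiles[i]),
                         bkscore_invalid_molecule = function(e) NA_character_)
    }
  }
  reason[is.na(can)] <- "unparseable SMILES"
  reason[is.na(reason) & !is.finite(label)] <- "non-finite label"
  bad <- !is.na(reason)
  rejects <- tibble(row = which(bad), smiles = raw_smiles[bad],
                    reason = reason[bad])
  if (any(bad)) {
    inform(sprintf("Rejected %d row(s): %s.", sum(bad),
                   paste(unique(reason[bad]), collapse = "; ")))
  }

  keep <- which(!bad)
  out <- tibble(id = if ("id" %in% names(data)) as.character(data$id[keep])
                     else sprintf("mol%04d", keep),
                canonical_smiles = can[keep],
                label = label[keep],
                weight = 1)
  extra <- setdiff(names(data), c("id", smiles_col, label_col))
  for (nm in extra) out[[nm]] <- data[[nm]][keep]

  n_dup <- sum(duplicated(out$canonical_smiles))
  if (n_dup > 0) {
    inform(sprintf("Collapsed %d duplicate SMILES entr%s (%s).", n_dup,
                   if (n_dup == 1) "y" else "ies", dedup))
    if (dedup == "average") {
      means <- tapply(out$label, out$canonical_smiles, mean)
      out <- out[!duplicated(out$canonical_smiles), ]
      out$label <- unname(means[out$canonical_smiles])
    } else {
      out <- out[!duplicated(out$canonical_smiles), ]
    }
  }
  if (nrow(out) == 0L) {
    stop_bk("No valid records left after filtering.", "bkscore_empty_dataset")
  }
  structure(out, label_kind = label_kind, provenance = provenance,
            rejects = rejects, n_duplicates = n_dup,
            class = c("labeled_dataset", class(out)))
}

#' Load a labeled molecule table from CSV
#'
#' @param path CSV file (UTF-8, header row) with SMILES and numeric labels.
#' @inheritParams labeled_dataset
#' @return A `labeled_dataset` tibble; see [labeled_dataset()].
#' @export
load_labeled_csv <- function(path, smiles_col = "smiles",
                             label_col = "label",
                             label_kind = "permeability_log10_nm_s",
                             dedup = c("first", "average")) {
  if (!file.exists(path)) {
    stop_bk(sprintf("File '%s' does not exist.", path), "bkscore_io_error")
  }
  data <- readr::read_csv(path, show_col_types = FALSE,
                          progress = FALSE)
  labeled_dataset(data, smiles_col = smiles_col, label_col = label_col,
                  label_kind = label_kind, dedup = dedup,
                  provenance = path)
}

#' Seeded 8:1:1 random split
#'
#' Assigns every record to train/valid/test. Sizes follow the floor rule:
#' `floor(n * r_valid)` to valid, `floor(n * r_test)` to test, remainder to
#' train. The assignment is a deterministic function of the seed and of the
#' record order after deduplication, and does not disturb the caller's RNG
#' state.
#'
#' @param ds A `labeled_dataset` (or any data frame with an `id` column).
#' @param ratios Train/valid/test proportions, positive, summing to 1.
#' @param seed Integer seed.
#' @return A `split_assignment` tibble with columns `id` and `split`
#'   (factor train/valid/test), and attributes `seed` and `ratios`.
#' @export
random_split <- function(ds, ratios = c(0.8, 0.1, 0.1), seed = 0L) {
  n <- nrow(ds)
  if (is.null(n) || n < 3L) {
    stop_bk("Need at least 3 records to split.", "bkscore_split_error")
  }
  if (length(ratios) != 3L || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8) {
    stop_bk("`ratios` must be 3 positive numbers summing to 1.",
            "bkscore_config_error")
  }
  n_valid <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  split <- rep("train", n)
  split[perm[seq_len(n_valid)]] <- "valid"
  split[perm[n_valid + seq_len(n_test)]] <- "test"
  out <- tibble(id = as.character(ds$id),
                split = factor(split, levels = c("train", "valid", "test")))
  structure(out, seed = as.integer(seed), ratios = ratios,
            class = c("split_assignment", class(out)))
}

#' Fit an invertible label normalizer
#'
#' Standardizes labels to zero mean and unit spread using the population
#' (divide-by-n) standard deviation. Fit it on the training split only; the
#' fitted transform is frozen into the trained model so that predictions are
#' always de-normalized with training-time constants.
#'
#' @param train_labels Numeric vector of at least 2 finite training labels.
#' @return A `normalizer` with fields `mean` and `sd`.
#' @export
#' @examples
#' nz <- fit_normalizer(c(1, 2, 3))
#' normalizer_apply(nz, 1)           # (1 - 2) / sqrt(2/3)
#' normalizer_invert(nz, normalizer_apply(nz, 1.7))
fit_normalizer <- function(train_labels) {
  y <- train_labels
  if (length(y) < 2L || any(!is.finite(y))) {
    stop_bk("Need >= 2 finite training labels.", "bkscore_config_error")
  }
  mu <- mean(y)
  sd_pop <- sqrt(mean((y - mu)^2))
  if (sd_pop <= 0) {
    stop_bk("Training labels have zero variance; normalizer is degenerate.",
            "bkscore_degenerate_labels")
  }
  structure(list(mean = mu, sd = sd_pop), class = "normalizer")
}

#' @rdname fit_normalizer
#' @param nz A `normalizer`.
#' @param y Numeric vector of labels (original units).
#' @export
normalizer_apply <- function(nz, y) {
  stopifnot(inherits(nz, "normalizer"))
  (y - nz$mean) / nz$sd
}

#' @rdname fit_normalizer
#' @param z Numeric vector of normalized labels.
#' @export
normalizer_invert <- function(nz, z) {
  stopifnot(inherits(nz, "normalizer"))
  z * nz$sd + nz$mean
}

#' Export a split assignment for audit
#'
#' @param split A `split_assignment`.
#' @param path Output CSV path (two columns: id, split).
#' @export
write_split_csv <- function(split, path) {
  readr::write_csv(tibble(id = split$id, split = as.character(split$split)),
                   path)
  invisible(path)
}

split_indices <- function(ds, split, which) {
  stopifnot(nrow(ds) == nrow(split))
  which(as.character(split$split) == which)
}
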