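#' Convert a log10 permeability threshold from cm/s to nm/s
#'
#' The Caco-2 passive-diffusion criterion is usually quoted as
#' `log10 Papp > -5.5` with Papp in cm/s. On the nm/s scale used by the
#' B score this shifts by `log10(1e7) = 7`, so the same cut-off is
#' `-5.5 + 7 = 1.5` — the bystander-potential threshold.
#'
#' @param logpapp_cms log10 apparent permeability in cm/s.
#' @return log10 apparent permeability in nm/s.
#' @export
#' @examples
#' logpapp_cms_to_nms(-5.5)  # 1.5, the B-score criterion
logpapp_cms_to_nms <- function(logpapp_cms) logpapp_cms + 7

#' Scoring configuration for payload triage
#'
#' @param b_threshold Bystander cut on the absolute B score (log10 Papp in
#'   nm/s); default 1.5, i.e. [logpapp_cms_to_nms()] of -5.5. The comparison
#'   is inclusive (`>=`).
#' @param reference_smiles SMILES of the calibration reference payload
#'   (typically DXd); its scores define the (0, 0) origin of the calibrated
#'   delta scores.
#' @param combiner How B and K deltas combine into the B-K score: `"sum"`
#'   (equal-weight sum of calibrated deltas, the default) or
#'   `"weighted_sum"` with weights `w_b`, `w_k`.
#' @param w_b,w_k Weights for `"weighted_sum"`.
#' @return A `scoring_config`.
#' @export
scoring_config <- function(b_threshold = logpapp_cms_to_nms(-5.5),
                           reference_smiles = NULL,
                           combiner = c("sum", "weighted_sum"),
                           w_b = 1, w_k = 1) {
  combiner <- match.arg(combiner)
  check_scalar_number(b_threshold, "b_threshold")
  structure(list(b_threshold = b_threshold,
                 reference_smiles = reference_smiles,
                 combiner = combiner, w_b = w_b, w_k = w_k),
            class = "scoring_config")
}

#' Score molecules with a model or an oracle function
#'
#' Generic used by the scoring layer so that a trained [train_gat()] model,
#' a fitted baseline, or any plain `function(smiles) -> numeric` (e.g. a
#' ground-truth stub in tests) can serve as the B or K model.
#'
#' @param model Scorer.
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of scores.
#' @export
score_molecules <- function(model, smiles) {
  if (inherits(model, "gat_model") || inherits(model, "baseline_model")) {
    predict(model, smiles)
  } else if (is.function(model)) {
    model(smiles)
  } else {
    stop_bk("`model` must be a gat_model, baseline_model or function.",
            "bkscore_config_error")
  }
}

#' Score candidate payloads with the B and K models
#'
#' Applies the permeability (B) and potency (K) models to every candidate,
#' calibrates both scores against the reference payload so that the
#' reference sits exactly at (0, 0), combines the calibrated deltas into the
#' B-K score, and flags bystander potential on the absolute B score.
#' Candidates whose SMILES fail to parse are reported via a warning and the
#' `rejects` attribute, never dropped silently.
#'
#' @param b_model,k_model Scorers accepted by [score_molecules()].
#' @param candidates Character vector of SMILES or data frame with `smiles`
#'   (and optionally `id`).
#' @param config A [scoring_config()]; its `reference_smiles` must score.
#' @return A `payload_scores` tibble: `id`, `canonical_smiles`, `b_score`,
#'   `k_score`, `delta_b`, `delta_k`, `bk_score`, `bystander_flag`, plus
#'   attributes `reference` (its absolute scores) and `rejects`.
#' @export
score_candidates <- function(b_model, k_model, candidates,
                             config = scoring_config()) {
  stopifnot(inherits(config, "scoring_config"))
  if (is.character(candidates)) candidates <- tibble(smiles = candidates)
  if (!"id" %in% names(candidates)) {
    candidates$id <- sprintf("cand%03d", seq_len(nrow(candidates)))
  }
  if (is.null(config$reference_smiles)) {
    stop_bk("`config$reference_smiles` is required for calibration.",
            "bkscore_config_error")
  }
  ref_scores <- tryCatch(
    c(b = score_molecules(b_model, config$reference_smiles),
      k = score_molecules(k_model, config$reference_smiles)),
    error = function(e) {
      stop_bk(sprintf("Reference payload failed to score: %s",
                      conditionMessage(e)), "bkscore_config_error")
    })

  can <- rep(NA_character_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    can[i] <- tryCatch(canonicalize_smiles(candidates$smiles[i]),
                       bkscore_invalid_molecule = function(e) NA_character_)
  }
  bad <- is.na(can)
  rejects <- tibble(id = candidates$id[bad], smiles = candidates$smiles[bad])
  if (any(bad)) {
    warn(sprintf("%d candidate(s) had unparseable SMILES: %s.", sum(bad),
                 paste(candidates$id[bad], collapse = ", ")))
  }
  ok <- which(!bad)
  b <- score_molecules(b_model, can[ok])
  k <- score_molecules(k_model, can[ok])
  delta_b <- b - ref_scores[["b"]]
  delta_k <- k - ref_scores[["k"]]
  bk <- switch(config$combiner,
               sum = delta_b + delta_k,
               weighted_sum = config$w_b * delta_b + config$w_k * delta_k)
  out <- tibble(id = candidates$id[ok], canonical_smiles = can[ok],
                b_score = b, k_score = k, delta_b = delta_b,
                delta_k = delta_k, bk_score = bk,
                bystander_flag = b >= config$b_threshold)
  structure(out, reference = ref_scores, config = config, rejects = rejects,
            class = c("payload_scores", class(out)))
}

#' Rank scored candidates
#'
#' Descending by the chosen score; ties broken deterministically by
#' canonical SMILES (lexicographic).
#'
#' @param scores A `payload_scores` tibble from [score_candidates()].
#' @param key `"bk_score"`, `"b_score"` or `"k_score"`.
#' @return The reordered tibble with a `rank` column prepended.
#' @export
rank_candidates <- function(scores, key = c("bk_score", "b_score",
                                            "k_score")) {
  key <- match.arg(key)
  if (!nrow(scores)) stop_bk("No scores to rank.", "bkscore_empty_dataset")
  ord <- order(-scores[[key]], scores$canonical_smiles, method = "radix")
  out <- scores[ord, ]
  dplyr::bind_cols(tibble(rank = seq_len(nrow(out))), out)
}

#' Validate the bystander flag against a labeled payload panel
#'
#' Applies the B model and threshold to a panel of payloads with known
#' bystander annotations (e.g. payloads in clinic or development) and
#' reports the confusion matrix with accuracy, sensitivity and specificity.
#'
#' @param b_model Scorer accepted by [score_molecules()].
#' @param panel Data frame with columns `smiles` and `bystander_label`
#'   (logical).
#' @param config A [scoring_config()] (only `b_threshold` is used).
#' @return A `panel_validation` list: `counts` (tp/fn/tn/fp), `metrics`
#'   (one-row tibble: n, accuracy, sensitivity, specificity) and the
#'   per-payload table `details`.
#' @export
validate_panel <- function(b_model, panel, config = scoring_config()) {
  stopifnot(is.data.frame(panel),
            all(c("smiles", "bystander_label") %in% names(panel)))
  can <- rep(NA_character_, nrow(panel))
  for (i in seq_len(nrow(panel))) {
    can[i] <- tryCatch(canonicalize_smiles(panel$smiles[i]),
                       bkscore_invalid_molecule = function(e) NA_character_)
  }
  ok <- which(!is.na(can))
  if (!length(ok)) {
    stop_bk("No valid molecules in the panel.", "bkscore_empty_dataset")
  }
  b <- score_molecules(b_model, can[ok])
  pred <- b >= config$b_threshold
  obs <- as.logical(panel$bystander_label[ok])
  counts <- c(tp = sum(pred & obs), fn = sum(!pred & obs),
              tn = sum(!pred & !obs), fp = sum(pred & !obs))
  metrics <- tibble(
    n = length(ok),
    accuracy = (counts[["tp"]] + counts[["tn"]]) / length(ok),
    sensitivity = counts[["tp"]] / max(1L, counts[["tp"]] + counts[["fn"]]),
    specificity = counts[["tn"]] / max(1L, counts[["tn"]] + counts[["fp"]]))
  structure(list(counts = counts, metrics = metrics,
                 details = tibble(smiles = panel$smiles[ok],
                                  canonical_smiles = can[ok], b_score = b,
                                  predicted = pred, observed = obs)),
            class = "panel_validation")
}

#' @export
print.panel_validation <- function(x, ...) {
  cat("<panel_validation> n =", x$metrics$n, "\n")
  print(x$counts)
  print(x$metrics)
  invisible(x)
}

#' Long-format score table for heat-map display
#'
#' Pivots the scored candidates into a tidy candidate-by-metric table
#' (b_score, k_score, bk_score, and measured pIC50 when supplied) suitable
#' for tile plots. When measured potencies are given, a Spearman rank
#' correlation between the B-K score and pIC50 is attached as attribute
#' `rank_correlation`.
#'
#' @param scores A `payload_scores` tibble.
#' @param measured_pic50 Optional numeric vector aligned with `scores` rows.
#' @return Tibble with columns `id`, `metric`, `value`.
#' @export
score_heatmap_table <- function(scores, measured_pic50 = NULL) {
  if (!nrow(scores)) stop_bk("No scores given.", "bkscore_empty_dataset")
  tab <- tidyr::pivot_longer(
    scores[, c("id", "b_score", "k_score", "bk_score")],
    cols = -"id", names_to = "metric", values_to = "value")
  rho <- NULL
  if (!is.null(measured_pic50)) {
    stopifnot(length(measured_pic50) == nrow(scores))
    tab <- dplyr::bind_rows(tab, tibble(id = scores$id, metric = "pic50",
                                        value = measured_pic50))
    rho <- suppressWarnings(
      cor(scores$bk_score, measured_pic50, method = "spearman"))
  }
  tab$metric <- factor(tab$metric,
                       levels = c("b_score", "k_score", "bk_score", "pic50"))
  structure(tab, rank_correlation = rho,
            class = c("score_heatmap_table", class(tab)))
}
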