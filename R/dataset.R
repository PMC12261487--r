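# Synergy-score tables -> binary-labeled, symmetrized, de-duplicated
# (drug1, drug2, cell_line) samples.

SCORE_MODELS <- c("bliss", "loewe", "hsa", "zip")

#' Majority-vote binary synergy labels from reference-model scores
#'
#' Each available (non-missing) reference model votes positive when its score
#' exceeds zero; the label is the majority vote. A tied vote is broken by the
#' sign of the mean available score; a tie with mean exactly zero gives `NA`
#' (the sample is dropped downstream). Rows with no available score are an
#' error.
#'
#' @param scores Data frame or matrix with one numeric column per reference
#'   model (e.g. bliss, loewe, hsa, zip); `NA` marks a missing score.
#' @return Integer vector of labels in \{0, 1\} (or `NA` for dead ties).
#' @examples
#' vote_label(data.frame(bliss = 5.2, loewe = 1.1, hsa = -0.3, zip = 0.4))  # 1
#' vote_label(data.frame(bliss = 3, loewe = -1, hsa = 2, zip = -6))         # 0
#' @export
vote_label <- function(scores) {
  m <- as.matrix(scores)
  if (any(rowSums(!is.na(m)) == 0L)) {
    stop("sample with all reference-model scores missing", call. = FALSE)
  }
  pos <- rowSums(m > 0, na.rm = TRUE)
  neg <- rowSums(m <= 0 & !is.na(m), na.rm = TRUE)
  lab <- ifelse(pos > neg, 1L, ifelse(pos < neg, 0L, NA_integer_))
  ties <- which(is.na(lab))
  if (length(ties)) {
    mu <- rowMeans(m[ties, , drop = FALSE], na.rm = TRUE)
    lab[ties] <- ifelse(mu > 0, 1L, ifelse(mu < 0, 0L, NA_integer_))
  }
  lab
}

pair_key <- function(d1, d2) {
  paste(pmin(d1, d2), pmax(d1, d2), sep = "\r")
}

#' Symmetrize labeled samples over drug order
#'
#' Duplicate observations of the same unordered (drug pair, cell line) triple
#' are collapsed by majority vote over their labels (dead ties are dropped
#' with a message); each surviving triple is then expanded to both drug
#' orders, the observed order tagged `origin = "observed"` and its swap
#' `origin = "mirrored"`.
#'
#' @param samples Tibble with columns `drug1`, `drug2`, `cell_line`, `label`.
#' @return Tibble with both orders of every triple and an `origin` column.
#' @export
symmetrize_samples <- function(samples) {
  stopifnot(all(c("drug1", "drug2", "cell_line", "label") %in% names(samples)))
  samples <- dplyr::mutate(samples,
                           .key = paste(pair_key(.data$drug1, .data$drug2),
                                        .data$cell_line, sep = "\r"))
  resolved <- samples |>
    dplyr::summarise(
      drug1 = dplyr::first(.data$drug1),
      drug2 = dplyr::first(.data$drug2),
      cell_line = dplyr::first(.data$cell_line),
      n_pos = sum(.data$label == 1L),
      n_neg = sum(.data$label == 0L),
      .by = ".key"
    ) |>
    dplyr::mutate(label = dplyr::case_when(
      .data$n_pos > .data$n_neg ~ 1L,
      .data$n_pos < .data$n_neg ~ 0L,
      TRUE ~ NA_integer_
    ))
  n_tied <- sum(is.na(resolved$label))
  if (n_tied) {
    message("dropping ", n_tied,
            " duplicated triple(s) with tied conflicting labels")
    resolved <- dplyr::filter(resolved, !is.na(.data$label))
  }
  base <- dplyr::select(resolved, "drug1", "drug2", "cell_line", "label")
  mirrored <- base |>
    dplyr::filter(.data$drug1 != .data$drug2) |>
    dplyr::mutate(tmp = .data$drug1, drug1 = .data$drug2, drug2 = .data$tmp) |>
    dplyr::select(-"tmp")
  dplyr::bind_rows(
    dplyr::mutate(base, origin = "observed"),
    dplyr::mutate(mirrored, origin = "mirrored")
  )
}

#' Build a labeled, symmetrized synergy dataset
#'
#' Filters rows whose drugs or cell line cannot be resolved against the drug
#' table and expression matrix, votes a binary label per triple from the
#' reference-model score columns, optionally removes self-combinations,
#' collapses duplicates, and symmetrizes over drug order. Counts of every
#' stage are returned in a manifest.
#'
#' @param synergy Tibble with columns `drug1`, `drug2`, `cell_line` and one
#'   numeric column per reference model.
#' @param drug_tbl Tibble with a `drug_id` column.
#' @param expr Expression tibble with a `cell_line` column.
#' @param score_models Candidate reference-model column names to auto-detect.
#' @param keep_self Keep drug1 == drug2 combinations (default FALSE).
#' @return List with `samples` (tibble: drug1, drug2, cell_line, label,
#'   origin) and `manifest` (list of counts and the label rule).
#' @export
build_dataset <- function(synergy, drug_tbl, expr,
                          score_models = SCORE_MODELS, keep_self = FALSE) {
  stopifnot(all(c("drug1", "drug2", "cell_line") %in% names(synergy)))
  models <- intersect(score_models, names(synergy))
  if (!length(models)) stop("no reference-model score columns found", call. = FALSE)
  n_raw <- nrow(synergy)

  known_drugs <- drug_tbl$drug_id
  known_cells <- expr$cell_line
  ok <- synergy$drug1 %in% known_drugs & synergy$drug2 %in% known_drugs &
    synergy$cell_line %in% known_cells
  if (!keep_self) ok <- ok & synergy$drug1 != synergy$drug2
  filtered <- synergy[ok, , drop = FALSE]
  if (!nrow(filtered)) {
    stop("no resolvable samples: check that drug and cell-line identifiers ",
         "match the drug table and expression matrix", call. = FALSE)
  }

  has_score <- rowSums(!is.na(as.matrix(filtered[, models, drop = FALSE]))) > 0L
  filtered <- filtered[has_score, , drop = FALSE]
  labels <- vote_label(filtered[, models, drop = FALSE])
  labeled <- tibble::tibble(
    drug1 = filtered$drug1, drug2 = filtered$drug2,
    cell_line = filtered$cell_line, label = labels
  )
  n_dead_tie <- sum(is.na(labeled$label))
  labeled <- dplyr::filter(labeled, !is.na(.data$label))
  n_after_filtering <- nrow(labeled)

  samples <- symmetrize_samples(labeled)
  samples$sample_id <- seq_len(nrow(samples))

  manifest <- list(
    n_raw = n_raw,
    n_unresolvable = n_raw - nrow(filtered) - n_dead_tie,
    n_dead_tie_votes = n_dead_tie,
    n_after_filtering = n_after_filtering,
    n_after_symmetrization = nrow(samples),
    n_positive = sum(samples$label == 1L),
    n_negative = sum(samples$label == 0L),
    score_models = models,
    label_rule = "majority vote, score > 0 positive; ties by sign of mean"
  )
  list(samples = samples, manifest = manifest)
}
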