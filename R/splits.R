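# Five-fold 3:1:1 cross-validation in three scenarios, grouped so that
# mirrored twins always co-partition and leave-out folds hold entire drug
# pairs or cell lines away from training.

split_group_key <- function(samples, scenario) {
  switch(scenario,
    random = paste(pair_key(samples$drug1, samples$drug2),
                   samples$cell_line, sep = "\r"),
    leave_drug_pair_out = pair_key(samples$drug1, samples$drug2),
    leave_cell_line_out = samples$cell_line,
    stop("unknown scenario: ", scenario)
  )
}

make_split_manifests <- function(samples, scenario, n_folds, seed) {
  keys <- split_group_key(samples, scenario)
  groups <- unique(keys)
  if (length(groups) < n_folds) {
    stop("fewer ", switch(scenario,
                          random = "unordered triples",
                          leave_drug_pair_out = "drug pairs",
                          leave_cell_line_out = "cell lines"),
         " (", length(groups), ") than folds (", n_folds, ")", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample(groups))
  fold_of_group <- stats::setNames(rep_len(seq_len(n_folds), length(perm)), perm)
  fold <- unname(fold_of_group[keys])
  lapply(seq_len(n_folds) - 1L, function(k) {
    test_f <- k + 1L
    val_f <- (k + 1L) %% n_folds + 1L
    part <- ifelse(fold == test_f, "test",
                   ifelse(fold == val_f, "val", "train"))
    structure(
      list(
        scenario = scenario, fold_index = k, n_folds = n_folds, seed = seed,
        assignment = tibble::tibble(sample_id = samples$sample_id, part = part)
      ),
      class = "split_manifest"
    )
  })
}

#' @export
print.split_manifest <- function(x, ...) {
  tab <- table(x$assignment$part)
  cat("<split_manifest> ", x$scenario, " fold ", x$fold_index, "/",
      x$n_folds, " seed ", x$seed, " | train ", tab[["train"]],
      " val ", tab[["val"]], " test ", tab[["test"]], "\n", sep = "")
  invisible(x)
}

#' Random cross-validation splits over drug-drug-cell-line triples
#'
#' Unordered triples (so a sample and its mirrored twin always share a
#' partition) are shuffled into `n_folds` equal folds. For fold k the test
#' set is fold k, validation is fold k+1 (mod `n_folds`), and training the
#' remaining folds, giving the 3:1:1 ratio at five folds.
#'
#' @param samples Symmetrized sample tibble with `sample_id`.
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed controlling the shuffle.
#' @return List of `split_manifest` objects, one per fold.
#' @export
split_random <- function(samples, n_folds = 5L, seed = 1L) {
  make_split_manifests(samples, "random", n_folds, seed)
}

#' Leave-drug-pair-out cross-validation splits
#'
#' Folds over unordered drug pairs, so no drug pair in the validation or test
#' partition ever appears in training.
#'
#' @inheritParams split_random
#' @return List of `split_manifest` objects.
#' @export
split_leave_drug_pair_out <- function(samples, n_folds = 5L, seed = 1L) {
  make_split_manifests(samples, "leave_drug_pair_out", n_folds, seed)
}

#' Leave-cell-line-out cross-validation splits
#'
#' Folds over cell lines, so the model is evaluated on entirely unseen cell
#' lines.
#'
#' @inheritParams split_random
#' @return List of `split_manifest` objects.
#' @export
split_leave_cell_line_out <- function(samples, n_folds = 5L, seed = 1L) {
  make_split_manifests(samples, "leave_cell_line_out", n_folds, seed)
}

#' Make cross-validation splits for a named scenario
#'
#' @inheritParams split_random
#' @param scenario One of "random", "leave_drug_pair_out",
#'   "leave_cell_line_out".
#' @return List of `split_manifest` objects.
#' @export
make_splits <- function(samples,
                        scenario = c("random", "leave_drug_pair_out",
                                     "leave_cell_line_out"),
                        n_folds = 5L, seed = 1L) {
  scenario <- match.arg(scenario)
  make_split_manifests(samples, scenario, n_folds, seed)
}

split_part_ids <- function(samples, manifest, part) {
  manifest$assignment$sample_id[manifest$assignment$part == part]
}

split_part <- function(samples, manifest, part) {
  samples[samples$sample_id %in% split_part_ids(samples, manifest, part), ,
          drop = FALSE]
}
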