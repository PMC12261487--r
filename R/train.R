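# Training loop (minibatch Adam, early stopping on validation loss) and
# prediction for fitted models.

prepare_pre <- function(data, cfg, train_samples, expr_norm) {
  drug_ids <- data$drugs$drug_id
  cell_ids <- expr_norm$cell_line
  drug_index <- stats::setNames(seq_along(drug_ids), drug_ids)
  cell_index <- stats::setNames(seq_along(cell_ids), cell_ids)
  incidence <- build_incidence(train_samples, drug_ids, cell_ids,
                               mode = cfg$hyperedges)
  expr_mat <- expression_matrix(expr_norm)
  list(
    gb = build_graph_batch(data$graphs, drug_ids),
    expr_mat = expr_mat,
    M = as.matrix(hypergraph_propagation(incidence$H)),
    incidence = incidence,
    fp_cos = cosine_matrix(data$fingerprints[drug_ids, , drop = FALSE]),
    expr_cos = cosine_matrix(expr_mat),
    drug_index = drug_index,
    cell_index = cell_index,
    n_drugs = length(drug_ids),
    n_cells = length(cell_ids)
  )
}

index_samples <- function(pre, samples) {
  list(
    d1 = unname(pre$drug_index[samples$drug1]),
    d2 = unname(pre$drug_index[samples$drug2]),
    cell = unname(pre$cell_index[samples$cell_line]),
    labels = if ("label" %in% names(samples)) samples$label else
      rep(0L, nrow(samples))
  )
}

wrap_params <- function(params) lapply(params, ad_param)

#' Fit the dual-granularity synergy model
#'
#' Trains the full architecture — GIN/SAGPool drug encoder with jumping
#' knowledge, cell-line MLP, four-layer hypergraph convolution with a
#' residual connection, interaction-aware cross/self-attention, highway
#' fusion, and a two-layer classifier — with minibatch Adam on the weighted
#' sum of classification, similarity-reconstruction, and contrastive losses.
#' Hyperedges are built from the training partition only; validation loss
#' drives early stopping and the best-validation parameters are restored.
#'
#' @param data A [synergy_data()] bundle.
#' @param split A `split_manifest` (train/val/test assignment), or `NULL` to
#'   train on all samples with a random 10% validation carve-out.
#' @param config A [synergy_config()].
#' @return A `synergy_fit` object with elements `params`, `config`,
#'   `epoch_log` (tibble), `best_epoch`, `pre` (cached model inputs),
#'   `expr_norm`, `split`, and `data`.
#' @export
fit_synergy <- function(data, split = NULL, config = synergy_config()) {
  cfg <- config
  set.seed(cfg$seed)
  samples <- data$samples
  if (is.null(split)) {
    keys <- split_group_key(samples, "random")
    groups <- unique(keys)
    val_groups <- sample(groups, max(1L, round(0.1 * length(groups))))
    part <- ifelse(keys %in% val_groups, "val", "train")
    assignment <- tibble::tibble(sample_id = samples$sample_id, part = part)
  } else {
    assignment <- split$assignment
  }
  part_of <- assignment$part[match(samples$sample_id, assignment$sample_id)]
  train_rows <- which(part_of == "train")
  val_rows <- which(part_of == "val")
  stopifnot(length(train_rows) > 0L, length(val_rows) > 0L)

  train_cells <- unique(samples$cell_line[train_rows])
  expr_norm <- zscore_normalize(data$expression_raw, train_cells = train_cells)
  pre <- prepare_pre(data, cfg, samples[train_rows, ], expr_norm)
  idx <- index_samples(pre, samples)
  pre$d1 <- idx$d1; pre$d2 <- idx$d2; pre$cell <- idx$cell
  pre$labels <- idx$labels

  params <- init_params(cfg, n_genes = ncol(pre$expr_mat))
  state <- adam_state(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  log_rows <- vector("list", cfg$max_epochs)
  wait <- 0L

  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_rows)
    nb <- ceiling(length(ord) / cfg$batch_size)
    tr_losses <- matrix(0, nb, 4L)
    for (b in seq_len(nb)) {
      batch <- ord[((b - 1L) * cfg$batch_size + 1L):
                     min(b * cfg$batch_size, length(ord))]
      pn <- wrap_params(params)
      fwd <- model_forward(pn, cfg, pre, batch, train = TRUE)
      if (!is.finite(ad_value(fwd$total))) {
        stop("training diverged: non-finite loss at epoch ", epoch)
      }
      ad_backward(fwd$total)
      grads <- lapply(pn, function(n) n$grad)
      upd <- adam_step(params, grads, state, cfg$lr)
      params <- upd$params
      state <- upd$state
      tr_losses[b, ] <- c(ad_value(fwd$total), ad_value(fwd$cls),
                          ad_value(fwd$rec), ad_value(fwd$con))
    }
    vn <- wrap_params(params)
    vfwd <- model_forward(vn, cfg, pre, val_rows, train = FALSE)
    val_loss <- as.numeric(ad_value(vfwd$cls))
    val_auc <- suppressWarnings(auc_roc(vfwd$probs, vfwd$labels))
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch,
      loss_total = mean(tr_losses[, 1L]),
      loss_cls = mean(tr_losses[, 2L]),
      loss_rec = mean(tr_losses[, 3L]),
      loss_con = mean(tr_losses[, 4L]),
      val_loss = val_loss,
      val_auc = val_auc
    )
    if (cfg$verbose && (epoch %% 10L == 0L || epoch == 1L)) {
      message(sprintf("epoch %4d  train %.4f  val %.4f  val_auc %.3f",
                      epoch, mean(tr_losses[, 1L]), val_loss, val_auc))
    }
    if (val_loss < best$loss - cfg$min_delta) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }

  structure(
    list(
      params = best$params,
      config = cfg,
      epoch_log = dplyr::bind_rows(log_rows[!vapply(log_rows, is.null,
                                                    logical(1))]),
      best_epoch = best$epoch,
      best_val_loss = best$loss,
      pre = pre,
      expr_norm = expr_norm,
      assignment = assignment,
      split = split,
      data = data
    ),
    class = "synergy_fit"
  )
}

#' @export
print.synergy_fit <- function(x, ...) {
  cat("<synergy_fit> ", nrow(x$epoch_log), " epochs (best ", x$best_epoch,
      ", val loss ", signif(x$best_val_loss, 4), ")\n", sep = "")
  cat("  scenario: ",
      if (is.null(x$split)) "full-data" else x$split$scenario, "\n", sep = "")
  invisible(x)
}

#' Predict synergy probabilities
#'
#' @param object A `synergy_fit`.
#' @param newdata Tibble with `drug1`, `drug2`, `cell_line` (and optionally
#'   `label`); defaults to the fit's full sample table.
#' @param ... Unused.
#' @return `newdata` with an appended `.pred` column, the predicted
#'   probability that the combination is synergistic.
#' @export
predict.synergy_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$data$samples
  pre <- object$pre
  bad_d <- setdiff(unique(c(newdata$drug1, newdata$drug2)),
                   names(pre$drug_index))
  bad_c <- setdiff(unique(newdata$cell_line), names(pre$cell_index))
  if (length(bad_d) || length(bad_c)) {
    stop("unknown entities: ", paste(c(bad_d, bad_c), collapse = ", "))
  }
  idx <- index_samples(pre, newdata)
  loc <- pre
  loc$d1 <- idx$d1; loc$d2 <- idx$d2; loc$cell <- idx$cell
  loc$labels <- if ("label" %in% names(newdata)) newdata$label else
    rep(0L, nrow(newdata))
  pn <- wrap_params(object$params)
  fwd <- model_forward(pn, object$config, loc, seq_len(nrow(newdata)),
                       train = FALSE)
  dplyr::mutate(tibble::as_tibble(newdata), .pred = fwd$probs)
}

#' Evaluate a fitted model on one partition
#'
#' @param fit A `synergy_fit`.
#' @param part `"test"`, `"val"`, or `"train"`.
#' @return One-row metric tibble from [compute_metrics()].
#' @export
evaluate_fit <- function(fit, part = "test") {
  ids <- fit$assignment$sample_id[fit$assignment$part == part]
  rows <- fit$data$samples[fit$data$samples$sample_id %in% ids, , drop = FALSE]
  if (!nrow(rows)) stop("no samples in partition '", part, "'")
  preds <- predict(fit, rows)
  compute_metrics(preds$.pred, preds$label, threshold = fit$config$threshold)
}
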