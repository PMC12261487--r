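# Post-fit analyses: order independence, substructure importance, candidate
# screening, interaction bundles, embedding export, and the ablation harness.

#' Order-independence of predictions
#'
#' Predicts every sample under both drug input orders and returns the Pearson
#' correlation between the two probability vectors, plus the per-sample
#' scatter data.
#'
#' @param fit A `synergy_fit`.
#' @param samples Sample tibble; defaults to the fit's test partition if a
#'   split is present, otherwise all samples.
#' @return List with `pcc` and `scatter` (tibble: drug1, drug2, cell_line,
#'   prob_fwd, prob_rev).
#' @export
order_independence <- function(fit, samples = NULL) {
  if (is.null(samples)) {
    samples <- if (!is.null(fit$split)) {
      ids <- fit$assignment$sample_id[fit$assignment$part == "test"]
      fit$data$samples[fit$data$samples$sample_id %in% ids, , drop = FALSE]
    } else fit$data$samples
  }
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  fwd <- predict(fit, samples)
  swapped <- dplyr::mutate(samples, tmp = .data$drug1,
                           drug1 = .data$drug2, drug2 = .data$tmp)
  rev <- predict(fit, dplyr::select(swapped, -"tmp"))
  scatter <- tibble::tibble(
    drug1 = samples$drug1, drug2 = samples$drug2,
    cell_line = samples$cell_line,
    prob_fwd = fwd$.pred, prob_rev = rev$.pred
  )
  list(pcc = stats::cor(scatter$prob_fwd, scatter$prob_rev),
       scatter = scatter)
}

#' Per-layer atom importance for one drug
#'
#' Recovers the self-attention pooling scores of each encoder layer for the
#' given drug and min-max normalizes them to `[0, 1]` within each layer
#' (a layer whose scores are all equal, including a single surviving atom,
#' maps to 1). Deeper layers only score the atoms retained by earlier
#' pooling.
#'
#' @param fit A `synergy_fit` (with `pool = "sagpool"`).
#' @param drug_id Drug identifier.
#' @return Tibble with `layer`, `atom` (1-based index into the molecular
#'   graph), `score`, `retained`.
#' @export
explain_drug <- function(fit, drug_id) {
  pre <- fit$pre
  if (!drug_id %in% names(pre$drug_index)) stop("unknown drug: ", drug_id)
  if (fit$config$pool != "sagpool") {
    stop("atom importance requires pool = 'sagpool'")
  }
  pn <- wrap_params(fit$params)
  fwd <- model_forward(pn, fit$config, pre, 1L, train = FALSE, collect = TRUE)
  gid <- pre$drug_index[[drug_id]]
  offset <- pre$gb$offsets[gid]
  purrr::imap_dfr(fwd$layer_info, function(info, l) {
    sel <- info$graph == gid
    if (!any(sel)) return(NULL)
    sc <- info$scores[sel]
    rng <- range(sc)
    norm <- if (diff(rng) < 1e-12) rep(1, length(sc)) else
      (sc - rng[1]) / diff(rng)
    tibble::tibble(
      layer = l,
      atom = info$atoms[sel] - offset,
      score = norm,
      retained = info$atoms[sel] %in% info$kept
    )
  })
}

#' Rank novel drug-pair x cell-line candidates
#'
#' Enumerates all unordered drug pairs crossed with the cell lines, removes
#' every triple present in the training data, and ranks the rest by the
#' predicted synergy probability averaged over both input orders.
#'
#' @param fit A `synergy_fit`.
#' @param drugs,cell_lines Candidate identifiers; default to all known.
#' @return Tibble `drug1`, `drug2`, `cell_line`, `prob`, sorted descending.
#' @export
screen_combinations <- function(fit, drugs = NULL, cell_lines = NULL) {
  if (is.null(drugs)) drugs <- names(fit$pre$drug_index)
  if (is.null(cell_lines)) cell_lines <- names(fit$pre$cell_index)
  if (length(drugs) < 2L || !length(cell_lines)) {
    stop("empty candidate set")
  }
  pairs <- utils::combn(sort(drugs), 2L)
  cand <- tidyr::expand_grid(pair = seq_len(ncol(pairs)),
                             cell_line = cell_lines)
  cand$drug1 <- pairs[1L, cand$pair]
  cand$drug2 <- pairs[2L, cand$pair]
  known <- fit$data$samples
  known_keys <- unique(paste(pair_key(known$drug1, known$drug2),
                             known$cell_line))
  cand <- cand[!paste(pair_key(cand$drug1, cand$drug2), cand$cell_line) %in%
                 known_keys, , drop = FALSE]
  if (!nrow(cand)) stop("empty candidate set after removing known triples")
  fwd <- predict(fit, tibble::tibble(drug1 = cand$drug1, drug2 = cand$drug2,
                                     cell_line = cand$cell_line))
  rev <- predict(fit, tibble::tibble(drug1 = cand$drug2, drug2 = cand$drug1,
                                     cell_line = cand$cell_line))
  out <- tibble::tibble(
    drug1 = cand$drug1, drug2 = cand$drug2, cell_line = cand$cell_line,
    prob = (fwd$.pred + rev$.pred) / 2
  )
  dplyr::arrange(out, dplyr::desc(.data$prob))
}

#' Interaction bundle for a single triple
#'
#' Runs the fine-granularity module for one (drug1, drug2, cell line) input
#' and returns the six cross-attention interaction vectors (ordered A<-B,
#' B<-A, A<-cell, cell<-A, B<-cell, cell<-B), the fused fine embedding, and
#' all attention maps (row-stochastic within each query row).
#'
#' @param fit A `synergy_fit` with the fine module enabled.
#' @param drug1,drug2,cell_line Entity identifiers.
#' @return List with `vectors` (6 x token_dim matrix), `fine_embedding`,
#'   `attention_maps` (per mechanism, per head).
#' @export
fine_bundle <- function(fit, drug1, drug2, cell_line) {
  if (!fit$config$use_fine) stop("fine module disabled in this fit")
  pre <- fit$pre
  loc <- pre
  loc$d1 <- pre$drug_index[[drug1]]
  loc$d2 <- pre$drug_index[[drug2]]
  loc$cell <- pre$cell_index[[cell_line]]
  loc$labels <- 0L
  pn <- wrap_params(fit$params)
  fwd <- model_forward(pn, fit$config, loc, 1L, train = FALSE, collect = TRUE)
  dt <- fit$config$token_dim
  six <- matrix(ad_value(fwd$collect$six_raw), nrow = 6L, ncol = dt,
                byrow = TRUE)
  rownames(six) <- c("A<-B", "B<-A", "A<-cell", "cell<-A",
                     "B<-cell", "cell<-B")
  grab_maps <- function(maps, row) {
    lapply(maps, function(per_q) {
      do.call(rbind, lapply(per_q, function(A) ad_value(A)[row, ]))
    })
  }
  ct <- fwd$collect
  maps <- list(
    drug_drug = grab_maps(ct$cross_maps$AB,
                          which(ct$pair_tab[, 1L] == loc$d1 &
                                  ct$pair_tab[, 2L] == loc$d2)),
    drug_cell = grab_maps(ct$cross_maps$DC,
                          which(ct$combo_tab[, 1L] == loc$d1)[1L]),
    cell_drug = grab_maps(ct$cross_maps$CD,
                          which(ct$combo_tab[, 1L] == loc$d1)[1L]),
    self = grab_maps(ct$self_maps, 1L)
  )
  list(vectors = six,
       fine_embedding = as.vector(ad_value(fwd$fine_emb)),
       attention_maps = maps)
}

#' Export per-sample embeddings from each module
#'
#' Captures the representation of every requested sample after the
#' initialization module (concatenated drug and cell embeddings), the coarse
#' hypergraph module, the fine attention module, and the final fused layer —
#' the inputs one would hand to t-SNE or UMAP.
#'
#' @param fit A `synergy_fit`.
#' @param samples Sample tibble; defaults to all samples.
#' @return Tibble with sample keys, `label`, `stage` (init | coarse | fine |
#'   final), and an `embedding` list-column.
#' @export
export_embeddings <- function(fit, samples = NULL) {
  if (is.null(samples)) samples <- fit$data$samples
  pre <- fit$pre
  idx <- index_samples(pre, samples)
  loc <- pre
  loc$d1 <- idx$d1; loc$d2 <- idx$d2; loc$cell <- idx$cell
  loc$labels <- if ("label" %in% names(samples)) samples$label else
    rep(0L, nrow(samples))
  pn <- wrap_params(fit$params)
  fwd <- model_forward(pn, fit$config, loc, seq_len(nrow(samples)),
                       train = FALSE, collect = TRUE)
  mol <- ad_value(fwd$mol)
  cemb <- ad_value(fwd$cell_emb)
  stages <- list(
    init = cbind(mol[idx$d1, , drop = FALSE], mol[idx$d2, , drop = FALSE],
                 cemb[idx$cell, , drop = FALSE]),
    coarse = if (!is.null(fwd$coarse_s)) ad_value(fwd$coarse_s),
    fine = if (!is.null(fwd$fine_emb)) ad_value(fwd$fine_emb),
    final = ad_value(fwd$fused)
  )
  stages <- stages[!vapply(stages, is.null, logical(1))]
  purrr::imap_dfr(stages, function(m, nm) {
    tibble::tibble(
      drug1 = samples$drug1, drug2 = samples$drug2,
      cell_line = samples$cell_line,
      label = loc$labels[seq_len(nrow(samples))],
      stage = nm,
      embedding = lapply(seq_len(nrow(m)), function(i) m[i, ])
    )
  })
}

#' Ablation harness
#'
#' Refits the model with individual components disabled and reports the
#' test-set metric deltas against the full model: the coarse module, its
#' residual connection, the fine module, the highway fusion, and the
#' reconstruction/contrastive loss terms.
#'
#' @param data A [synergy_data()] bundle.
#' @param split A `split_manifest`.
#' @param config Base [synergy_config()].
#' @param components Character vector of ablations to run; any of
#'   `"coarse"`, `"residual"`, `"fine"`, `"highway"`, `"rec"`, `"con"`,
#'   `"rec+con"`.
#' @return Tibble with one metric row per model (full first) plus a `model`
#'   column; attribute `"deltas"` holds metric differences to the full model.
#' @export
run_ablation <- function(data, split, config = synergy_config("compact"),
                         components = c("rec+con")) {
  variants <- list(full = list())
  mods <- list(
    coarse = list(use_coarse = FALSE),
    residual = list(use_residual = FALSE),
    fine = list(use_fine = FALSE),
    highway = list(use_highway = FALSE),
    rec = list(loss_weights = c(cls = 1, rec = 0,
                                con = unname(config$loss_weights[["con"]]))),
    con = list(loss_weights = c(cls = 1,
                                rec = unname(config$loss_weights[["rec"]]),
                                con = 0)),
    `rec+con` = list(loss_weights = c(cls = 1, rec = 0, con = 0))
  )
  for (comp in components) {
    if (!comp %in% names(mods)) stop("unknown ablation component: ", comp)
    variants[[comp]] <- mods[[comp]]
  }
  rows <- purrr::imap(variants, function(override, nm) {
    cfg <- config
    cfg[names(override)] <- override
    fit <- fit_synergy(data, split, cfg)
    dplyr::mutate(evaluate_fit(fit, "test"), model = nm, .before = 1L)
  })
  out <- dplyr::bind_rows(rows)
  metric_cols <- c("auc_roc", "auc_pr", "acc", "bacc", "f1", "precision",
                   "recall", "kappa")
  deltas <- out[-1L, ]
  for (mc in metric_cols) deltas[[mc]] <- deltas[[mc]] - out[[mc]][1L]
  attr(out, "deltas") <- deltas
  out
}
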