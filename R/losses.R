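# Reference (plain-matrix) forms of the prediction head and the two
# auxiliary loss terms. Training runs the same formulas on the autodiff
# tape; the test suite asserts that both routes agree on live batches.

#' Highway fusion layer
#'
#' `y = T(x) * G(x) + (1 - T(x)) * x` with a sigmoid transformation gate
#' `T` and a ReLU transform `G`; the carry gate is `1 - T`.
#'
#' @param x Input matrix (rows = samples).
#' @param Wt,bt Gate weights (d x d) and bias (length d).
#' @param Wg,bg Transform weights and bias.
#' @return List with `output`, `gate` (the transformation gate values,
#'   strictly inside (0, 1)).
#' @export
highway_forward <- function(x, Wt, bt, Wg, bg) {
  x <- as.matrix(x)
  Tg <- 1 / (1 + exp(-sweep(x %*% Wt, 2L, as.vector(bt), "+")))
  G <- pmax(sweep(x %*% Wg, 2L, as.vector(bg), "+"), 0)
  list(output = Tg * G + (1 - Tg) * x, gate = Tg)
}

#' Similarity-reconstruction loss
#'
#' Mean squared difference between the cosine-similarity matrix of the
#' hypergraph node embeddings and the cosine-similarity matrix of the
#' original descriptors, computed separately for the drug block (ECFP6
#' fingerprints) and the cell block (expression rows) and summed; the two
#' blocks live in different descriptor spaces, so no cross-block target
#' exists. Zero-norm rows contribute zero cosine.
#'
#' @param node_embeddings Matrix of hypergraph node embeddings, drugs first.
#' @param fingerprints Drug fingerprint matrix (n_drugs rows).
#' @param expression Cell expression matrix (n_cells rows).
#' @return Scalar loss (>= 0).
#' @export
reconstruction_loss <- function(node_embeddings, fingerprints, expression) {
  nd <- nrow(fingerprints)
  nc <- nrow(expression)
  stopifnot(nrow(node_embeddings) == nd + nc)
  drug_emb <- node_embeddings[seq_len(nd), , drop = FALSE]
  cell_emb <- node_embeddings[nd + seq_len(nc), , drop = FALSE]
  mean((cosine_matrix(drug_emb) - cosine_matrix(fingerprints))^2) +
    mean((cosine_matrix(cell_emb) - cosine_matrix(expression))^2)
}

#' Margin contrastive loss over sample embeddings
#'
#' Pulls positive samples toward their (normalized) centroid and pushes each
#' positive's paired negative beyond a margin, in cosine distance
#' `d = 1 - cos`:
#' `mean_i d(p_i, centroid) + mean_i max(0, m - d(p_i, n_i))`.
#' Negatives are paired 1:1 with positives; by default they are taken by
#' cycling through the negative rows (the deterministic evaluation rule);
#' training samples them uniformly.
#'
#' @param embeddings Sample embedding matrix.
#' @param labels Binary labels.
#' @param margin Margin `m` on the cosine distance (default 0.5).
#' @param negatives Optional integer vector of negative row indices, one per
#'   positive.
#' @return Scalar loss, or `NA` (with a warning) for a single-class batch.
#' @export
contrastive_loss <- function(embeddings, labels, margin = 0.5,
                             negatives = NULL) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (!length(pos) || !length(neg)) {
    warning("contrastive loss skipped: single-class batch", call. = FALSE)
    return(NA_real_)
  }
  if (is.null(negatives)) {
    negatives <- neg[(seq_along(pos) - 1L) %% length(neg) + 1L]
  }
  stopifnot(length(negatives) == length(pos))
  unit <- function(m) {
    n <- pmax(sqrt(rowSums(m^2)), 1e-12)
    m / n
  }
  P <- unit(embeddings[pos, , drop = FALSE])
  Ng <- unit(embeddings[negatives, , drop = FALSE])
  centroid <- colMeans(P)
  centroid <- centroid / max(sqrt(sum(centroid^2)), 1e-12)
  pull <- mean(1 - P %*% centroid)
  push <- mean(pmax(0, margin - (1 - rowSums(P * Ng))))
  pull + push
}
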