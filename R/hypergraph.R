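# Coarse-granularity hypergraph: incidence construction over
# drugs + cell lines with one hyperedge per training triple, and the
# normalized hypergraph convolution.

#' Build the hypergraph incidence matrix
#'
#' Nodes are all drugs followed by all cell lines; each hyperedge connects the
#' two drugs and the cell line of one unique unordered training triple (so
#' every column sums to exactly 3). Mirrored duplicates collapse to one
#' hyperedge. With `mode = "positive_only"` only synergistic triples
#' contribute hyperedges.
#'
#' @param samples Training sample tibble (`drug1`, `drug2`, `cell_line`,
#'   `label`).
#' @param drug_ids,cell_ids Full entity vocabularies (row order of the node
#'   set).
#' @param mode `"all"` (default) or `"positive_only"`.
#' @return List with sparse binary `H` (n_nodes x n_edges), `node_index`,
#'   `node_degrees`, `edge_degrees`, `triples`, `n_isolated`.
#' @export
build_incidence <- function(samples, drug_ids, cell_ids,
                            mode = c("all", "positive_only")) {
  mode <- match.arg(mode)
  s <- if (mode == "positive_only") {
    samples[samples$label == 1L, , drop = FALSE]
  } else samples
  triples <- tibble::tibble(
    d_lo = pmin(s$drug1, s$drug2),
    d_hi = pmax(s$drug1, s$drug2),
    cell_line = s$cell_line
  )
  triples <- dplyr::distinct(triples)
  if (!nrow(triples)) stop("zero hyperedges", call. = FALSE)
  node_ids <- c(drug_ids, cell_ids)
  node_index <- stats::setNames(seq_along(node_ids), node_ids)
  n_nodes <- length(node_ids)
  n_edges <- nrow(triples)
  i <- c(node_index[triples$d_lo], node_index[triples$d_hi],
         node_index[triples$cell_line] )
  j <- rep(seq_len(n_edges), 3L)
  H <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n_nodes, n_edges))
  node_degrees <- as.integer(Matrix::rowSums(H))
  n_isolated <- sum(node_degrees == 0L)
  if (n_isolated) {
    message(n_isolated, " isolated node(s) in the hypergraph ",
            "(entities absent from training triples)")
  }
  list(H = H, node_index = node_index, node_degrees = node_degrees,
       edge_degrees = as.integer(Matrix::colSums(H)), triples = triples,
       n_isolated = n_isolated)
}

#' Normalized hypergraph propagation matrix
#'
#' Computes `M = Dv^{-1/2} H W De^{-1} H^T Dv^{-1/2}` with identity hyperedge
#' weights W. Isolated (zero-degree) nodes receive a degree-safe
#' self-propagation entry `M[v, v] = 1` so their features pass through
#' unchanged.
#'
#' @param H Binary incidence matrix (sparse or dense).
#' @return Sparse symmetric propagation matrix, n_nodes x n_nodes.
#' @export
hypergraph_propagation <- function(H) {
  H <- methods::as(methods::as(Matrix::Matrix(H, sparse = TRUE), "dMatrix"),
                   "generalMatrix")
  dv <- Matrix::rowSums(H)
  de <- Matrix::colSums(H)
  inv_sqrt_dv <- ifelse(dv > 0, 1 / sqrt(dv), 0)
  Dv <- Matrix::Diagonal(x = inv_sqrt_dv)
  De <- Matrix::Diagonal(x = 1 / de)
  M <- Dv %*% H %*% De %*% Matrix::t(H) %*% Dv
  iso <- which(dv == 0)
  if (length(iso)) {
    M <- M + Matrix::sparseMatrix(i = iso, j = iso, x = 1, dims = dim(M))
  }
  M
}

#' One hypergraph convolution layer
#'
#' `X' = act(M X Theta)` with `M` the normalized propagation matrix of
#' [hypergraph_propagation()].
#'
#' @param X Node feature matrix (n_nodes x d_in).
#' @param H Incidence matrix.
#' @param Theta Weight matrix (d_in x d_out).
#' @param act Elementwise activation (default identity).
#' @return Matrix n_nodes x d_out.
#' @export
hypergraph_conv <- function(X, H, Theta, act = identity) {
  stopifnot(nrow(X) == nrow(H), ncol(X) == nrow(Theta))
  M <- hypergraph_propagation(H)
  out <- act(as.matrix(M %*% X %*% Theta))
  if (any(!is.finite(out))) stop("non-finite hypergraph convolution output")
  out
}

#' Export the incidence as a sparse triplet table
#'
#' @param incidence Result of [build_incidence()].
#' @return Tibble with `node_id`, `hyperedge_id`.
#' @export
incidence_triplets <- function(incidence) {
  tr <- Matrix::mat2triplet(incidence$H)
  tibble::tibble(
    node_id = names(incidence$node_index)[tr$i],
    hyperedge_id = tr$j
  ) |> dplyr::arrange(.data$hyperedge_id, .data$node_id)
}
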