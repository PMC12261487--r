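# Multi-head scaled dot-product attention over fixed-size token sets, built
# from autodiff primitives and vectorized over groups (drug pairs or
# drug-cell combos): token t of group g occupies columns
# ((t-1)*d+1):(t*d) of a wide matrix with one row per group.

# Tq: node, g x (nq*d); Tk: node, g x (nk*d). Returns the attended token
# matrix (g x nq*d) and, when keep_maps, the per-head attention weights
# (lists of g x nk softmax values, one per query token). Forward and backward
# are fused into a single tape node; the backward closure replays the cached
# intermediates with the standard attention gradient identities
# (dS = (dA - rowSums(dA * A)) * A for the row softmax).
ad_mha <- function(Tq, Tk, nq, nk, Wq, Wk, Wv, Wo, heads, keep_maps = FALSE) {
  Wqv <- Wq$value; Wkv <- Wk$value; Wvv <- Wv$value; Wov <- Wo$value
  d <- ncol(Wqv)
  dh <- d / heads
  Tqv <- Tq$value; Tkv <- Tk$value
  g <- nrow(Tqv)
  tc <- function(t) ((t - 1L) * d + 1L):(t * d)
  hc <- function(h) ((h - 1L) * dh + 1L):(h * dh)
  inv_sqrt <- 1 / sqrt(dh)

  Qi <- lapply(seq_len(nq), function(t) Tqv[, tc(t), drop = FALSE] %*% Wqv)
  Kj <- lapply(seq_len(nk), function(t) Tkv[, tc(t), drop = FALSE] %*% Wkv)
  Vj <- lapply(seq_len(nk), function(t) Tkv[, tc(t), drop = FALSE] %*% Wvv)

  A <- vector("list", nq)       # A[[i]][[h]]: g x nk softmax weights
  Ci <- vector("list", nq)      # pre-output-mix attended features, g x d
  out <- matrix(0, g, nq * d)
  for (i in seq_len(nq)) {
    A[[i]] <- vector("list", heads)
    Cih <- matrix(0, g, d)
    for (h in seq_len(heads)) {
      cols <- hc(h)
      Qih <- Qi[[i]][, cols, drop = FALSE]
      S <- matrix(0, g, nk)
      for (j in seq_len(nk)) {
        S[, j] <- rowSums(Qih * Kj[[j]][, cols, drop = FALSE])
      }
      S <- S * inv_sqrt
      S <- S - apply(S, 1L, max)
      E <- exp(S)
      Ah <- E / rowSums(E)
      A[[i]][[h]] <- Ah
      acc <- matrix(0, g, dh)
      for (j in seq_len(nk)) {
        acc <- acc + Ah[, j] * Vj[[j]][, cols, drop = FALSE]
      }
      Cih[, cols] <- acc
    }
    Ci[[i]] <- Cih
    out[, tc(i)] <- Cih %*% Wov
  }

  node <- ad_node(out, list(Tq, Tk, Wq, Wk, Wv, Wo), function(gr) {
    dTq <- matrix(0, g, nq * d); dTk <- matrix(0, g, nk * d)
    dWq <- matrix(0, d, d); dWk <- matrix(0, d, d)
    dWv <- matrix(0, d, d); dWo <- matrix(0, d, d)
    dKj <- lapply(seq_len(nk), function(j) matrix(0, g, d))
    dVj <- lapply(seq_len(nk), function(j) matrix(0, g, d))
    for (i in seq_len(nq)) {
      dOi <- gr[, tc(i), drop = FALSE]
      dCi <- tcrossprod(dOi, Wov)
      dWo <- dWo + crossprod(Ci[[i]], dOi)
      dQi <- matrix(0, g, d)
      for (h in seq_len(heads)) {
        cols <- hc(h)
        dCih <- dCi[, cols, drop = FALSE]
        Ah <- A[[i]][[h]]
        dA <- matrix(0, g, nk)
        for (j in seq_len(nk)) {
          dA[, j] <- rowSums(dCih * Vj[[j]][, cols, drop = FALSE])
          dVj[[j]][, cols] <- dVj[[j]][, cols, drop = FALSE] + Ah[, j] * dCih
        }
        dS <- (dA - rowSums(dA * Ah)) * Ah * inv_sqrt
        Qih <- Qi[[i]][, cols, drop = FALSE]
        for (j in seq_len(nk)) {
          dQi[, cols] <- dQi[, cols, drop = FALSE] +
            dS[, j] * Kj[[j]][, cols, drop = FALSE]
          dKj[[j]][, cols] <- dKj[[j]][, cols, drop = FALSE] + dS[, j] * Qih
        }
      }
      Tqi <- Tqv[, tc(i), drop = FALSE]
      dTq[, tc(i)] <- dTq[, tc(i), drop = FALSE] + tcrossprod(dQi, Wqv)
      dWq <- dWq + crossprod(Tqi, dQi)
    }
    for (j in seq_len(nk)) {
      Tkj <- Tkv[, tc(j), drop = FALSE]
      dTk[, tc(j)] <- tcrossprod(dKj[[j]], Wkv) + tcrossprod(dVj[[j]], Wvv)
      dWk <- dWk + crossprod(Tkj, dKj[[j]])
      dWv <- dWv + crossprod(Tkj, dVj[[j]])
    }
    ad_acc(Tq, dTq); ad_acc(Tk, dTk)
    ad_acc(Wq, dWq); ad_acc(Wk, dWk); ad_acc(Wv, dWv); ad_acc(Wo, dWo)
  })
  maps <- NULL
  if (keep_maps) {
    maps <- lapply(seq_len(heads), function(h) {
      lapply(seq_len(nq), function(i) ad_const(A[[i]][[h]]))
    })
  }
  list(out = node, maps = maps)
}

# Cross-attention with mean pooling over query positions.
ad_cross_attend_pooled <- function(Tq, Tk, nq, nk, Wq, Wk, Wv, Wo, heads,
                                   keep_maps = FALSE) {
  r <- ad_mha(Tq, Tk, nq, nk, Wq, Wk, Wv, Wo, heads, keep_maps)
  list(pooled = ad_block_mean(r$out, nq), maps = r$maps)
}

#' Multi-head cross-attention over token sets (reference interface)
#'
#' Scaled dot-product attention of `queries` over `keys`, heads concatenated
#' and linearly mixed, then mean-pooled over query positions. This is the
#' plain-matrix entry point for a single token-set pair; training uses the
#' same computation batched over groups.
#'
#' @param queries,keys Token matrices (n_tokens x d).
#' @param params List with `Wq`, `Wk`, `Wv`, `Wo` (all d x d).
#' @param heads Number of attention heads; d must be divisible by it.
#' @return List with `pooled` (length-d vector), `attended`
#'   (n_query x d matrix), and `attention` (list per head of row-stochastic
#'   n_query x n_key matrices).
#' @export
cross_attend <- function(queries, keys, params, heads = 4L) {
  stopifnot(nrow(keys) >= 1L, nrow(queries) >= 1L,
            ncol(queries) == ncol(keys),
            ncol(queries) %% heads == 0L)
  nq <- nrow(queries)
  nk <- nrow(keys)
  Tq <- ad_const(matrix(t(queries), nrow = 1L))  # one group, tokens side by side
  Tk <- ad_const(matrix(t(keys), nrow = 1L))
  r <- ad_mha(Tq, Tk, nq, nk,
              ad_const(params$Wq), ad_const(params$Wk),
              ad_const(params$Wv), ad_const(params$Wo),
              heads, keep_maps = TRUE)
  d <- ncol(params$Wq)
  attended <- matrix(ad_value(r$out), nrow = nq, ncol = d, byrow = TRUE)
  attention <- lapply(r$maps, function(per_q) {
    do.call(rbind, lapply(per_q, function(A) as.vector(ad_value(A))))
  })
  list(pooled = colMeans(attended), attended = attended,
       attention = attention)
}
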