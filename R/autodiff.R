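# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every node is an environment holding a value (base matrix), an accumulated
# gradient, its parents, and a backward closure. The graph is rebuilt on each
# forward pass (dynamic tape), so data-dependent control flow (top-k pooling,
# per-batch index sets) needs no special casing. Gradient correctness is
# property-tested against central finite differences in the test suite.

.ad <- new.env(parent = emptyenv())
.ad$counter <- 0L

ad_node <- function(value, parents = list(), backward = NULL, req = NULL) {
  if (is.null(dim(value))) value <- matrix(value, nrow = 1L)
  if (is.null(req)) req <- any(vapply(parents, function(p) p$req, logical(1)))
  .ad$counter <- .ad$counter + 1L
  n <- new.env(parent = emptyenv())
  n$id <- .ad$counter
  n$value <- value
  n$grad <- NULL
  n$parents <- parents
  n$backward <- backward
  n$req <- req
  class(n) <- "ad_node"
  n
}

ad_const <- function(x) ad_node(x, req = FALSE)
ad_param <- function(x) ad_node(x, req = TRUE)

ad_value <- function(n) n$value

# accumulate gradient g into node n
ad_acc <- function(n, g) {
  if (!n$req) return(invisible(NULL))
  if (is.null(n$grad)) n$grad <- g else n$grad <- n$grad + g
  invisible(NULL)
}

# Backward pass from a scalar loss node. Topological order is creation order,
# which is valid because parents are always created before children.
ad_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- vector("list", 256L)
  k <- 0L
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]]) || !n$req) next
    seen[[key]] <- TRUE
    k <- k + 1L
    if (k > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[k]] <- n
    for (p in n$parents) if (p$req) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(k)]
  ord <- order(vapply(nodes, function(n) n$id, numeric(1)), decreasing = TRUE)
  loss$grad <- matrix(1, 1L, 1L)
  for (n in nodes[ord]) {
    if (!is.null(n$backward) && !is.null(n$grad)) n$backward(n$grad)
  }
  invisible(NULL)
}

# ---- core ops ---------------------------------------------------------------

# matrix product a %*% b, or a %*% t(b) when tb = TRUE
ad_mm <- function(a, b, tb = FALSE) {
  av <- a$value; bv <- b$value
  v <- if (tb) tcrossprod(av, bv) else av %*% bv
  ad_node(v, list(a, b), function(g) {
    if (tb) {
      # C = A B^T:  dA = G B,  dB = G^T A
      if (a$req) ad_acc(a, g %*% bv)
      if (b$req) ad_acc(b, crossprod(g, av))
    } else {
      # C = A B:    dA = G B^T, dB = A^T G
      if (a$req) ad_acc(a, tcrossprod(g, bv))
      if (b$req) ad_acc(b, crossprod(av, g))
    }
  })
}

ad_add <- function(a, b) {
  ad_node(a$value + b$value, list(a, b), function(g) {
    ad_acc(a, g); ad_acc(b, g)
  })
}

ad_sub <- function(a, b) {
  ad_node(a$value - b$value, list(a, b), function(g) {
    ad_acc(a, g); ad_acc(b, -g)
  })
}

ad_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) {
    ad_acc(a, g * bv); ad_acc(b, g * av)
  })
}

# add a 1 x k bias row to every row of a (g x k)
ad_addbias <- function(a, b) {
  ad_node(sweep(a$value, 2L, as.vector(b$value), "+"), list(a, b), function(g) {
    ad_acc(a, g)
    ad_acc(b, matrix(colSums(g), 1L))
  })
}

# multiply every column of a (g x k) by column vector w (g x 1)
ad_colmul <- function(a, w) {
  av <- a$value; wv <- as.vector(w$value)
  ad_node(av * wv, list(a, w), function(g) {
    ad_acc(a, g * wv)
    ad_acc(w, matrix(rowSums(g * av), ncol = 1L))
  })
}

ad_scale <- function(a, s) {
  ad_node(a$value * s, list(a), function(g) ad_acc(a, g * s))
}

ad_relu <- function(a) {
  m <- a$value > 0
  ad_node(a$value * m, list(a), function(g) ad_acc(a, g * m))
}

ad_leaky_relu <- function(a, slope = 0.2) {
  m <- ifelse(a$value > 0, 1, slope)
  ad_node(a$value * m, list(a), function(g) ad_acc(a, g * m))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(v, list(a), function(g) ad_acc(a, g * v * (1 - v)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) ad_acc(a, g * (1 - v^2)))
}

# inverted dropout; mask drawn from the active RNG stream
ad_dropout <- function(a, rate, train) {
  if (!train || rate <= 0) return(a)
  keep <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= rate) / (1 - rate)
  ad_node(a$value * keep, list(a), function(g) ad_acc(a, g * keep))
}

ad_rowsums <- function(a) {
  k <- ncol(a$value)
  ad_node(matrix(rowSums(a$value), ncol = 1L), list(a), function(g) {
    ad_acc(a, matrix(rep(as.vector(g), k), ncol = k))
  })
}

ad_mean <- function(a) {
  n <- length(a$value)
  ad_node(matrix(mean(a$value), 1L, 1L), list(a), function(g) {
    ad_acc(a, matrix(as.numeric(g) / n, nrow(a$value), ncol(a$value)))
  })
}

ad_sum <- function(a) {
  ad_node(matrix(sum(a$value), 1L, 1L), list(a), function(g) {
    ad_acc(a, matrix(as.numeric(g), nrow(a$value), ncol(a$value)))
  })
}

ad_cols <- function(a, idx) {
  nc <- ncol(a$value)
  ad_node(a$value[, idx, drop = FALSE], list(a), function(g) {
    ga <- matrix(0, nrow(a$value), nc)
    ga[, idx] <- g
    ad_acc(a, ga)
  })
}

# gather rows (with repetition); backward is scatter-add
ad_rows <- function(a, idx) {
  nr <- nrow(a$value)
  ad_node(a$value[idx, , drop = FALSE], list(a), function(g) {
    acc <- rowsum(g, group = idx)
    ga <- matrix(0, nr, ncol(a$value))
    ga[as.integer(rownames(acc)), ] <- acc
    ad_acc(a, ga)
  })
}

ad_cbind <- function(nodes) {
  widths <- vapply(nodes, function(n) ncol(n$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(do.call(cbind, lapply(nodes, ad_value)), nodes, function(g) {
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
    }
  })
}

ad_rbind <- function(nodes) {
  hs <- vapply(nodes, function(n) nrow(n$value), integer(1))
  ends <- cumsum(hs)
  starts <- ends - hs + 1L
  ad_node(do.call(rbind, lapply(nodes, ad_value)), nodes, function(g) {
    for (i in seq_along(nodes)) {
      ad_acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
    }
  })
}

# sparse-constant %*% dense
ad_spmm <- function(S, a) {
  ad_node(as.matrix(S %*% a$value), list(a), function(g) {
    ad_acc(a, as.matrix(Matrix::crossprod(S, g)))
  })
}

# per-group mean of rows; groups is an integer vector in 1..ngroups
ad_group_mean <- function(a, groups, ngroups) {
  cnt <- tabulate(groups, nbins = ngroups)
  sums <- rowsum(a$value, group = groups)
  out <- matrix(0, ngroups, ncol(a$value))
  out[sort(unique(groups)), ] <- sums
  out <- out / pmax(cnt, 1L)
  ad_node(out, list(a), function(g) {
    ad_acc(a, g[groups, , drop = FALSE] / cnt[groups])
  })
}

ad_group_sum <- function(a, groups, ngroups) {
  sums <- rowsum(a$value, group = groups)
  out <- matrix(0, ngroups, ncol(a$value))
  out[sort(unique(groups)), ] <- sums
  ad_node(out, list(a), function(g) {
    ad_acc(a, g[groups, , drop = FALSE])
  })
}

# per-group columnwise max; gradient routed to the argmax rows
ad_group_max <- function(a, groups, ngroups) {
  av <- a$value
  nc <- ncol(av)
  out <- matrix(-Inf, ngroups, nc)
  argr <- matrix(NA_integer_, ngroups, nc)
  for (r in seq_len(nrow(av))) {
    gvec <- groups[r]
    upd <- av[r, ] > out[gvec, ]
    out[gvec, upd] <- av[r, upd]
    argr[gvec, upd] <- r
  }
  ad_node(out, list(a), function(g) {
    ga <- matrix(0, nrow(av), nc)
    for (gr in seq_len(ngroups)) for (cc in seq_len(nc)) {
      r <- argr[gr, cc]
      if (!is.na(r)) ga[r, cc] <- ga[r, cc] + g[gr, cc]
    }
    ad_acc(a, ga)
  })
}

ad_rowsoftmax <- function(a) {
  av <- a$value
  m <- av - apply(av, 1L, max)
  e <- exp(m)
  v <- e / rowSums(e)
  ad_node(v, list(a), function(g) {
    ad_acc(a, (g - rowSums(g * v)) * v)
  })
}

# rows scaled to unit L2 norm; zero rows stay zero
ad_rownormalize <- function(a, eps = 1e-12) {
  av <- a$value
  nr <- sqrt(rowSums(av^2))
  nz <- pmax(nr, eps)
  v <- av / nz
  ad_node(v, list(a), function(g) {
    ad_acc(a, (g - v * rowSums(g * v)) / nz)
  })
}

# mean cross-entropy of 2-class logits against labels in {0,1}
ad_ce_softmax2 <- function(logits, labels) {
  lv <- logits$value
  m <- lv - apply(lv, 1L, max)
  e <- exp(m)
  p <- e / rowSums(e)
  n <- nrow(lv)
  y <- cbind(1 - labels, labels)
  loss <- -mean(rowSums(y * log(pmax(p, 1e-12))))
  node <- ad_node(matrix(loss, 1L, 1L), list(logits), function(g) {
    ad_acc(logits, as.numeric(g) * (p - y) / n)
  })
  attr(node, "probs") <- p[, 2L]
  node
}

# mean squared difference against a constant matrix
ad_mse <- function(a, C) {
  d <- a$value - C
  n <- length(d)
  ad_node(matrix(mean(d^2), 1L, 1L), list(a), function(g) {
    ad_acc(a, as.numeric(g) * 2 * d / n)
  })
}

# mean over blocks of width d in a wide matrix g x (ntok*d)
ad_block_mean <- function(a, ntok) {
  d <- ncol(a$value) / ntok
  stopifnot(d == round(d))
  v <- matrix(0, nrow(a$value), d)
  for (t in seq_len(ntok)) v <- v + a$value[, ((t - 1) * d + 1):(t * d), drop = FALSE]
  v <- v / ntok
  ad_node(v, list(a), function(g) {
    ga <- matrix(0, nrow(a$value), ncol(a$value))
    for (t in seq_len(ntok)) ga[, ((t - 1) * d + 1):(t * d)] <- g / ntok
    ad_acc(a, ga)
  })
}

# reshape wide (g x ntok*d) to tall (ntok*g x d); token t occupies rows
# ((t-1)*g+1):(t*g). Pure permutation, so backward is the inverse reshape.
ad_tokens_tall <- function(a, ntok) {
  g0 <- nrow(a$value)
  d <- ncol(a$value) / ntok
  stopifnot(d == round(d))
  v <- do.call(rbind, lapply(seq_len(ntok), function(t) {
    a$value[, ((t - 1) * d + 1):(t * d), drop = FALSE]
  }))
  ad_node(v, list(a), function(gr) {
    ga <- do.call(cbind, lapply(seq_len(ntok), function(t) {
      gr[((t - 1) * g0 + 1):(t * g0), , drop = FALSE]
    }))
    ad_acc(a, ga)
  })
}

ad_tokens_wide <- function(a, ntok) {
  g0 <- nrow(a$value) / ntok
  stopifnot(g0 == round(g0))
  v <- do.call(cbind, lapply(seq_len(ntok), function(t) {
    a$value[((t - 1) * g0 + 1):(t * g0), , drop = FALSE]
  }))
  d <- ncol(a$value)
  ad_node(v, list(a), function(gr) {
    ga <- do.call(rbind, lapply(seq_len(ntok), function(t) {
      gr[, ((t - 1) * d + 1):(t * d), drop = FALSE]
    }))
    ad_acc(a, ga)
  })
}

# elementwise addition of a constant matrix (used for attention masks)
ad_addconst <- function(a, C) {
  ad_node(a$value + C, list(a), function(g) ad_acc(a, g))
}

# ---- optimizer --------------------------------------------------------------

adam_state <- function(params) {
  list(
    m = lapply(params, function(p) array(0, dim(p))),
    v = lapply(params, function(p) array(0, dim(p))),
    t = 0L
  )
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# broadcast outer sum u 1^T + 1 v^T from column vectors u (n x 1), v (m x 1)
ad_outer_sum <- function(u, v) {
  uv <- as.vector(u$value); vv <- as.vector(v$value)
  ad_node(outer(uv, vv, "+"), list(u, v), function(g) {
    ad_acc(u, matrix(rowSums(g), ncol = 1L))
    ad_acc(v, matrix(colSums(g), ncol = 1L))
  })
}
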