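# Model assembly: input bundling, parameter initialization, and the full
# forward pass (drug encoder -> coarse hypergraph -> fine attention ->
# highway fusion -> three-term loss) on the autodiff tape.

#' Bundle the inputs of a synergy model
#'
#' Featurizes drugs (molecular graphs + ECFP6 fingerprints), optionally
#' restricts expression to a landmark gene list, and packages everything a
#' fit needs. Expression is kept raw here; normalization statistics are
#' computed at fit time from the training partition.
#'
#' @param samples Symmetrized sample tibble from [build_dataset()].
#' @param drug_tbl Tibble with `drug_id`, `smiles`.
#' @param expression Expression tibble (`cell_line` + gene columns).
#' @param landmark Optional character vector of landmark gene symbols.
#' @param fp_radius Fingerprint radius (see [compute_ecfp6()]).
#' @return A `synergy_data` list.
#' @export
synergy_data <- function(samples, drug_tbl, expression, landmark = NULL,
                         fp_radius = 3L) {
  if (!is.null(landmark)) {
    expression <- select_landmark_genes(expression, landmark)
  }
  used <- unique(c(samples$drug1, samples$drug2))
  missing_drugs <- setdiff(used, drug_tbl$drug_id)
  if (length(missing_drugs)) {
    stop("samples reference unknown drugs: ",
         paste(missing_drugs, collapse = ", "))
  }
  structure(
    list(
      samples = samples,
      drugs = drug_tbl,
      graphs = featurize_drugs(drug_tbl),
      fingerprints = compute_ecfp6(drug_tbl, fp_radius = fp_radius),
      expression_raw = expression
    ),
    class = "synergy_data"
  )
}

#' @export
print.synergy_data <- function(x, ...) {
  cat("<synergy_data> ", nrow(x$samples), " samples | ", nrow(x$drugs),
      " drugs | ", nrow(x$expression_raw), " cell lines | ",
      ncol(x$expression_raw) - 1L, " genes\n", sep = "")
  invisible(x)
}

# ---- static graph batch -----------------------------------------------------

# Concatenate all molecular graphs into one block structure.
build_graph_batch <- function(graphs, drug_ids) {
  graphs <- graphs[drug_ids]
  sizes <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  X0 <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  edges <- do.call(rbind, purrr::map2(graphs, offsets, function(g, off) {
    if (nrow(g$edges)) g$edges + off else matrix(integer(0), ncol = 2L)
  }))
  list(
    X0 = X0,
    edges = edges,
    graph_id = rep(seq_along(graphs), sizes),
    sizes = sizes,
    offsets = offsets
  )
}

# dense adjacency: molecular graphs here are small (tens of atoms), so plain
# base matrices beat sparse S4 dispatch
adjacency_dense <- function(edges, n, self_weight = 0) {
  A <- matrix(0, n, n)
  if (nrow(edges)) {
    A[edges] <- 1
    A[edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (self_weight != 0) diag(A) <- diag(A) + self_weight
  A
}

gcn_norm_dense <- function(edges, n) {
  A <- adjacency_dense(edges, n, self_weight = 1)
  d_inv <- 1 / sqrt(rowSums(A))
  A * outer(d_inv, d_inv)
}

# ---- parameter initialization -----------------------------------------------

glorot <- function(fin, fout) {
  s <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -s, s), fin, fout)
}

init_params <- function(cfg, n_genes, atom_dim = ATOM_FEATURE_DIM) {
  p <- list()
  din <- atom_dim
  for (l in seq_along(cfg$gin_hidden)) {
    d <- cfg$gin_hidden[l]
    if (cfg$encoder == "gin") {
      p[[paste0("enc_W1_", l)]] <- glorot(din, d)
      p[[paste0("enc_b1_", l)]] <- matrix(0, 1L, d)
      p[[paste0("enc_W2_", l)]] <- glorot(d, d)
      p[[paste0("enc_b2_", l)]] <- matrix(0, 1L, d)
    } else {
      p[[paste0("enc_W_", l)]] <- glorot(din, d)
      p[[paste0("enc_b_", l)]] <- matrix(0, 1L, d)
      if (cfg$encoder == "gat") {
        p[[paste0("enc_a1_", l)]] <- glorot(d, 1L)
        p[[paste0("enc_a2_", l)]] <- glorot(d, 1L)
      }
    }
    if (cfg$pool == "sagpool") {
      p[[paste0("pool_w_", l)]] <- glorot(d, 1L)
    }
    din <- d
  }
  p$jk_W <- glorot(sum(cfg$gin_hidden), cfg$mol_dim)
  p$cell_W1 <- glorot(n_genes, cfg$cell_mlp[1])
  p$cell_b1 <- matrix(0, 1L, cfg$cell_mlp[1])
  p$cell_W2 <- glorot(cfg$cell_mlp[1], cfg$cell_mlp[2])
  p$cell_b2 <- matrix(0, 1L, cfg$cell_mlp[2])

  fused_dim <- 0L
  if (cfg$use_coarse) {
    h <- cfg$hyper_dims
    p$proj_drug <- glorot(cfg$mol_dim, h[1])
    p$proj_drug_b <- matrix(0, 1L, h[1])
    p$proj_cell <- glorot(cfg$cell_mlp[2], h[1])
    p$proj_cell_b <- matrix(0, 1L, h[1])
    p$hg_W1 <- glorot(h[1], h[2])
    p$hg_W2 <- glorot(h[2], h[3])
    p$hg_W3 <- glorot(h[3], h[4])
    p$hg_W4 <- glorot(h[4], h[4])
    if (cfg$use_residual) p$res_W <- glorot(h[1], h[4])
    fused_dim <- fused_dim + 3L * h[4]
  }
  if (cfg$use_fine) {
    dt <- cfg$token_dim
    for (l in seq_along(cfg$gin_hidden)) {
      p[[paste0("tok_W_", l)]] <- glorot(cfg$gin_hidden[l], dt)
    }
    p$ctok_W <- glorot(cfg$cell_mlp[2], dt)
    for (nm in c("ca", "sa")) {
      p[[paste0(nm, "_Wq")]] <- glorot(dt, dt)
      p[[paste0(nm, "_Wk")]] <- glorot(dt, dt)
      p[[paste0(nm, "_Wv")]] <- glorot(dt, dt)
      p[[paste0(nm, "_Wo")]] <- glorot(dt, dt)
    }
    p$share_W <- glorot(dt, dt)
    p$share_b <- matrix(0, 1L, dt)
    fused_dim <- fused_dim + 6L * dt
  }
  if (fused_dim == 0L) stop("at least one of use_coarse/use_fine must be TRUE")
  if (cfg$use_highway) {
    p$hw_Wt <- glorot(fused_dim, fused_dim)
    p$hw_bt <- matrix(-1, 1L, fused_dim)  # carry-biased gate at init
    p$hw_Wg <- glorot(fused_dim, fused_dim)
    p$hw_bg <- matrix(0, 1L, fused_dim)
  }
  p$mlp_W1 <- glorot(fused_dim, cfg$mlp_hidden)
  p$mlp_b1 <- matrix(0, 1L, cfg$mlp_hidden)
  p$mlp_W2 <- glorot(cfg$mlp_hidden, 2L)
  p$mlp_b2 <- matrix(0, 1L, 2L)
  p
}

# ---- drug and cell encoders -------------------------------------------------

# Returns per-layer readout tokens (n_drugs x d_l), the molecular embedding,
# and per-layer pooling records for importance maps.
drug_encoder_forward <- function(pn, cfg, gb, train, collect = FALSE) {
  n_drugs <- length(gb$sizes)
  X <- ad_const(gb$X0)
  cur_edges <- gb$edges
  cur_graph <- gb$graph_id
  cur_global <- seq_len(nrow(gb$X0))
  tokens <- vector("list", length(cfg$gin_hidden))
  layer_info <- vector("list", length(cfg$gin_hidden))

  for (l in seq_along(cfg$gin_hidden)) {
    n_cur <- length(cur_graph)
    if (cfg$encoder == "gin") {
      S <- adjacency_dense(cur_edges, n_cur, self_weight = 1 + cfg$gin_eps)
      h <- ad_spmm(S, X)
      z <- ad_relu(ad_addbias(ad_mm(h, pn[[paste0("enc_W1_", l)]]),
                              pn[[paste0("enc_b1_", l)]]))
      z <- ad_relu(ad_addbias(ad_mm(z, pn[[paste0("enc_W2_", l)]]),
                              pn[[paste0("enc_b2_", l)]]))
    } else if (cfg$encoder == "gcn") {
      Ahat <- gcn_norm_dense(cur_edges, n_cur)
      z <- ad_relu(ad_addbias(ad_mm(ad_spmm(Ahat, X),
                                    pn[[paste0("enc_W_", l)]]),
                              pn[[paste0("enc_b_", l)]]))
    } else if (cfg$encoder == "gat") {
      d <- cfg$gin_hidden[l]
      heads <- cfg$gat_heads
      dh <- d %/% heads
      Xw <- ad_mm(X, pn[[paste0("enc_W_", l)]])
      mask <- adjacency_dense(cur_edges, n_cur, self_weight = 1) > 0
      mask_pen <- ifelse(mask, 0, -1e9)
      outs <- vector("list", heads)
      for (hh in seq_len(heads)) {
        cols <- ((hh - 1L) * dh + 1L):(hh * dh)
        Xwh <- ad_cols(Xw, cols)
        # attention logits from source/destination projections
        u <- ad_mm(Xwh, ad_rows(pn[[paste0("enc_a1_", l)]], cols))
        v <- ad_mm(Xwh, ad_rows(pn[[paste0("enc_a2_", l)]], cols))
        Sc <- ad_addconst(ad_leaky_relu(ad_outer_sum(u, v)), mask_pen)
        A <- ad_rowsoftmax(Sc)
        outs[[hh]] <- ad_mm(A, Xwh)
      }
      z <- ad_relu(ad_addbias(ad_cbind(outs), pn[[paste0("enc_b_", l)]]))
    } else stop("unknown encoder: ", cfg$encoder)
    z <- ad_dropout(z, cfg$dropout, train)

    if (cfg$pool == "sagpool") {
      Ahat <- gcn_norm_dense(cur_edges, n_cur)
      s <- ad_mm(ad_spmm(Ahat, z), pn[[paste0("pool_w_", l)]])
      sv <- as.vector(ad_value(s))
      keep <- integer(0)
      for (gid in seq_len(n_drugs)) {
        members <- which(cur_graph == gid)
        if (!length(members)) next
        k <- max(1L, ceiling(cfg$pool_ratio * length(members)))
        ord <- members[order(-sv[members], members)]  # ties: lower index first
        keep <- c(keep, ord[seq_len(k)])
      }
      keep <- sort(keep)
      gated <- ad_colmul(ad_rows(z, keep), ad_tanh(ad_rows(s, keep)))
      tokens[[l]] <- ad_group_mean(gated, cur_graph[keep], n_drugs)
      layer_info[[l]] <- list(
        atoms = cur_global, graph = cur_graph, scores = sv,
        kept = cur_global[keep]
      )
      # induce the retained subgraph for the next layer
      remap <- integer(n_cur)
      remap[keep] <- seq_along(keep)
      ek <- cur_edges[cur_edges[, 1L] %in% keep & cur_edges[, 2L] %in% keep, ,
                      drop = FALSE]
      cur_edges <- cbind(remap[ek[, 1L]], remap[ek[, 2L]])
      cur_graph <- cur_graph[keep]
      cur_global <- cur_global[keep]
      X <- gated
    } else {
      tokens[[l]] <- switch(cfg$pool,
        add = ad_group_sum(z, cur_graph, n_drugs),
        mean = ad_group_mean(z, cur_graph, n_drugs),
        max = ad_group_max(z, cur_graph, n_drugs),
        stop("unknown pool: ", cfg$pool)
      )
      layer_info[[l]] <- list(atoms = cur_global, graph = cur_graph,
                              scores = NULL, kept = cur_global)
      X <- z
    }
  }
  mol <- ad_mm(ad_cbind(tokens), pn$jk_W)
  out <- list(tokens = tokens, mol = mol)
  if (collect) out$layer_info <- layer_info
  out
}

cell_encoder_forward <- function(pn, cfg, expr_mat, train) {
  X <- ad_const(expr_mat)
  h <- ad_relu(ad_addbias(ad_mm(X, pn$cell_W1), pn$cell_b1))
  h <- ad_dropout(h, cfg$dropout, train)
  ad_relu(ad_addbias(ad_mm(h, pn$cell_W2), pn$cell_b2))
}

# ---- full forward pass ------------------------------------------------------

# pre: list(gb, expr_mat, M, fp_cos, expr_cos, d1, d2, cell, labels,
#           n_drugs, n_cells)
# batch: integer sample indices into pre$d1 etc.
model_forward <- function(pn, cfg, pre, batch, train = FALSE,
                          collect = FALSE) {
  w <- cfg$loss_weights
  n_drugs <- pre$n_drugs
  n_cells <- pre$n_cells
  enc <- drug_encoder_forward(pn, cfg, pre$gb, train, collect)
  cell_emb <- cell_encoder_forward(pn, cfg, pre$expr_mat, train)

  d1 <- pre$d1[batch]
  d2 <- pre$d2[batch]
  cl <- pre$cell[batch]
  labels <- pre$labels[batch]
  parts <- list()
  collectibles <- list()

  coarse_nodes <- NULL
  if (cfg$use_coarse) {
    drug_in <- ad_addbias(ad_mm(enc$mol, pn$proj_drug), pn$proj_drug_b)
    cell_in <- ad_addbias(ad_mm(cell_emb, pn$proj_cell), pn$proj_cell_b)
    X0n <- ad_rbind(list(drug_in, cell_in))
    X1 <- ad_dropout(ad_relu(ad_spmm(pre$M, ad_mm(X0n, pn$hg_W1))),
                     cfg$dropout, train)
    X2 <- ad_dropout(ad_relu(ad_spmm(pre$M, ad_mm(X1, pn$hg_W2))),
                     cfg$dropout, train)
    X3 <- ad_relu(ad_spmm(pre$M, ad_mm(X2, pn$hg_W3)))
    X4in <- if (cfg$use_residual) ad_add(ad_mm(X0n, pn$res_W), X3) else X3
    coarse_nodes <- ad_relu(ad_spmm(pre$M, ad_mm(X4in, pn$hg_W4)))
    coarse_s <- ad_cbind(list(
      ad_rows(coarse_nodes, d1),
      ad_rows(coarse_nodes, d2),
      ad_rows(coarse_nodes, n_drugs + cl)
    ))
    parts$coarse <- coarse_s
  }

  if (cfg$use_fine) {
    tok_proj <- lapply(seq_along(enc$tokens), function(l) {
      ad_mm(enc$tokens[[l]], pn[[paste0("tok_W_", l)]])
    })
    Td <- ad_cbind(tok_proj)                      # n_drugs x 3*dt
    Tc <- ad_mm(cell_emb, pn$ctok_W)              # n_cells x dt
    nl <- length(enc$tokens)

    pair_tab <- unique(rbind(cbind(d1, d2), cbind(d2, d1)))
    pair_of <- function(a, b) {
      match(paste(a, b), paste(pair_tab[, 1L], pair_tab[, 2L]))
    }
    ca <- list(pn$ca_Wq, pn$ca_Wk, pn$ca_Wv, pn$ca_Wo)
    AB <- ad_cross_attend_pooled(
      ad_rows(Td, pair_tab[, 1L]), ad_rows(Td, pair_tab[, 2L]),
      nl, nl, ca[[1]], ca[[2]], ca[[3]], ca[[4]], cfg$heads,
      keep_maps = collect
    )
    combo_tab <- unique(rbind(cbind(d1, cl), cbind(d2, cl)))
    combo_of <- function(a, b) {
      match(paste(a, b), paste(combo_tab[, 1L], combo_tab[, 2L]))
    }
    DC <- ad_cross_attend_pooled(
      ad_rows(Td, combo_tab[, 1L]), ad_rows(Tc, combo_tab[, 2L]),
      nl, 1L, ca[[1]], ca[[2]], ca[[3]], ca[[4]], cfg$heads,
      keep_maps = collect
    )
    CD <- ad_cross_attend_pooled(
      ad_rows(Tc, combo_tab[, 2L]), ad_rows(Td, combo_tab[, 1L]),
      1L, nl, ca[[1]], ca[[2]], ca[[3]], ca[[4]], cfg$heads,
      keep_maps = collect
    )
    # six interaction vectors per sample: A<-B, B<-A, A<-c, c<-A, B<-c, c<-B
    six <- list(
      ad_rows(AB$pooled, pair_of(d1, d2)),
      ad_rows(AB$pooled, pair_of(d2, d1)),
      ad_rows(DC$pooled, combo_of(d1, cl)),
      ad_rows(CD$pooled, combo_of(d1, cl)),
      ad_rows(DC$pooled, combo_of(d2, cl)),
      ad_rows(CD$pooled, combo_of(d2, cl))
    )
    S6 <- ad_cbind(six)
    sa <- ad_mha(S6, S6, 6L, 6L, pn$sa_Wq, pn$sa_Wk, pn$sa_Wv, pn$sa_Wo,
                 cfg$heads, keep_maps = collect)
    shared <- ad_tokens_wide(
      ad_addbias(ad_mm(ad_tokens_tall(sa$out, 6L), pn$share_W), pn$share_b),
      6L
    )
    parts$fine <- shared
    if (collect) {
      collectibles$six_raw <- S6
      collectibles$cross_maps <- list(AB = AB$maps, DC = DC$maps, CD = CD$maps)
      collectibles$self_maps <- sa$maps
      collectibles$pair_tab <- pair_tab
      collectibles$combo_tab <- combo_tab
    }
  }

  fused_in <- if (length(parts) > 1L) ad_cbind(unname(parts)) else parts[[1L]]
  if (cfg$use_highway) {
    Tg <- ad_sigmoid(ad_addbias(ad_mm(fused_in, pn$hw_Wt), pn$hw_bt))
    G <- ad_relu(ad_addbias(ad_mm(fused_in, pn$hw_Wg), pn$hw_bg))
    ones <- ad_const(matrix(1, nrow(ad_value(Tg)), ncol(ad_value(Tg))))
    fused <- ad_add(ad_mul(Tg, G), ad_mul(ad_sub(ones, Tg), fused_in))
  } else {
    fused <- fused_in
  }
  h <- ad_dropout(ad_relu(ad_addbias(ad_mm(fused, pn$mlp_W1), pn$mlp_b1)),
                  cfg$dropout, train)
  logits <- ad_addbias(ad_mm(h, pn$mlp_W2), pn$mlp_b2)
  cls <- ad_ce_softmax2(logits, labels)

  rec <- NULL
  if (cfg$use_coarse && w[["rec"]] > 0) {
    Nd <- ad_rownormalize(ad_rows(coarse_nodes, seq_len(n_drugs)))
    Nc <- ad_rownormalize(ad_rows(coarse_nodes,
                                  n_drugs + seq_len(n_cells)))
    rec <- ad_add(ad_mse(ad_mm(Nd, Nd, tb = TRUE), pre$fp_cos),
                  ad_mse(ad_mm(Nc, Nc, tb = TRUE), pre$expr_cos))
  }

  con <- NULL
  con_skipped <- FALSE
  if (cfg$use_coarse && w[["con"]] > 0) {
    pos <- which(labels == 1L)
    neg <- which(labels == 0L)
    if (length(pos) >= 1L && length(neg) >= 1L) {
      neg_s <- if (train) sample(neg, length(pos), replace = TRUE) else
        neg[(seq_along(pos) - 1L) %% length(neg) + 1L]
      P <- ad_rownormalize(ad_rows(parts$coarse, pos))
      Ngm <- ad_rownormalize(ad_rows(parts$coarse, neg_s))
      centroid <- ad_rownormalize(ad_group_mean(P, rep(1L, length(pos)), 1L))
      pos_cos <- ad_mm(P, centroid, tb = TRUE)           # p x 1
      neg_cos <- ad_rowsums(ad_mul(P, Ngm))              # p x 1
      ones_p <- ad_const(matrix(1, length(pos), 1L))
      pull <- ad_mean(ad_sub(ones_p, pos_cos))           # mean 1 - cos
      marg <- ad_const(matrix(cfg$contrastive_margin - 1, length(pos), 1L))
      # hinge on m - d(anchor, neg) = m - 1 + cos(anchor, neg)
      push <- ad_mean(ad_relu(ad_add(marg, neg_cos)))
      con <- ad_add(pull, push)
    } else {
      con_skipped <- TRUE
    }
  }

  zero <- ad_const(matrix(0, 1L, 1L))
  rec_n <- if (is.null(rec)) zero else rec
  con_n <- if (is.null(con)) zero else con
  total <- ad_add(ad_scale(cls, w[["cls"]]),
                  ad_add(ad_scale(rec_n, w[["rec"]]),
                         ad_scale(con_n, w[["con"]])))

  out <- list(
    total = total, cls = cls, rec = rec_n, con = con_n,
    probs = attr(cls, "probs"), labels = labels,
    con_skipped = con_skipped
  )
  if (collect) {
    out$mol = enc$mol
    out$tokens = enc$tokens
    out$layer_info = enc$layer_info
    out$cell_emb = cell_emb
    out$coarse_nodes = coarse_nodes
    out$coarse_s = parts$coarse
    out$fine_emb = parts$fine
    out$fused = fused
    out$collect = collectibles
  }
  out
}

cosine_matrix <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  mm <- m / n
  tcrossprod(mm)
}
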