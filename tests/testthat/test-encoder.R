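# Drug and cell encoders: GIN message passing, SAGPool top-k rules,
# jumping-knowledge readout, permutation invariance, and variant switches.

# a graph batch with arbitrary features (bypasses SMILES parsing)
fake_gb <- function(X, edges, sizes) {
  list(X0 = X, edges = edges, graph_id = rep(seq_along(sizes), sizes),
       sizes = sizes, offsets = cumsum(c(0L, sizes[-length(sizes)])))
}

test_that("a GIN layer with identity MLPs reduces to (A + I) X", {
  d <- 78L
  cfg <- synergy_config("compact", gin_hidden = rep(d, 3L), pool = "mean",
                        dropout = 0, use_fine = FALSE)
  set.seed(31)
  X <- matrix(abs(rnorm(4 * d)), 4, d)           # nonnegative: ReLU inert
  edges <- cbind(1:3, 2:4)                        # path graph on 4 nodes
  gb <- fake_gb(X, edges, sizes = 4L)
  params <- dgsynergy:::init_params(cfg, n_genes = 5L)
  for (l in 1:3) {
    params[[paste0("enc_W1_", l)]] <- diag(d)
    params[[paste0("enc_W2_", l)]] <- diag(d)
  }
  pn <- dgsynergy:::wrap_params(params)
  enc <- dgsynergy:::drug_encoder_forward(pn, cfg, gb, train = FALSE)
  A <- dgsynergy:::adjacency_dense(edges, 4L, self_weight = 1)
  expect_equal(dgsynergy:::ad_value(enc$tokens[[1]]),
               matrix(colMeans(A %*% X), 1L), tolerance = 1e-10)
  expect_equal(dgsynergy:::ad_value(enc$tokens[[2]]),
               matrix(colMeans(A %*% A %*% X), 1L), tolerance = 1e-10)
})

test_that("SAGPool retains ceil(ratio * n) nodes with stable tie-breaks", {
  d <- 16L
  X <- matrix(abs(rnorm(5 * d)), 5, d)
  gb <- fake_gb(X, cbind(1:4, 2:5), sizes = 5L)
  base <- synergy_config("compact", gin_hidden = rep(d, 3L), dropout = 0,
                         use_fine = FALSE)
  params <- dgsynergy:::init_params(base, n_genes = 5L, atom_dim = d)

  run <- function(ratio, pool_w = NULL) {
    cfg <- synergy_config("compact", gin_hidden = rep(d, 3L), dropout = 0,
                          use_fine = FALSE, pool_ratio = ratio)
    p2 <- params
    if (!is.null(pool_w)) for (l in 1:3) p2[[paste0("pool_w_", l)]] <- pool_w
    dgsynergy:::drug_encoder_forward(dgsynergy:::wrap_params(p2), cfg, gb,
                                     train = FALSE, collect = TRUE)
  }
  expect_length(run(1.0)$layer_info[[1]]$kept, 5L)
  expect_length(run(0.5)$layer_info[[1]]$kept, 3L)  # ceil(0.5 * 5)
  # all-equal scores: the lowest node indices win
  expect_equal(run(0.5, pool_w = matrix(0, d, 1L))$layer_info[[1]]$kept,
               1:3)
})

test_that("the molecular embedding is invariant to atom relabelling", {
  g <- parse_smiles("CCOc1ccncc1", "asym")
  n <- g$n_atoms
  set.seed(32)
  perm <- sample(n)
  inv <- order(perm)
  g_perm <- g
  g_perm$atom_features <- g$atom_features[perm, , drop = FALSE]
  e <- cbind(inv[g$edges[, 1]], inv[g$edges[, 2]])
  g_perm$edges <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))

  gb <- dgsynergy:::build_graph_batch(list(a = g, b = g_perm), c("a", "b"))
  cfg <- synergy_config("compact", dropout = 0)
  params <- dgsynergy:::init_params(cfg, n_genes = 5L)
  enc <- dgsynergy:::drug_encoder_forward(dgsynergy:::wrap_params(params),
                                          cfg, gb, train = FALSE)
  mol <- dgsynergy:::ad_value(enc$mol)
  expect_equal(mol[1, ], mol[2, ], tolerance = 1e-5)
  for (tok in enc$tokens) {
    tv <- dgsynergy:::ad_value(tok)
    expect_equal(tv[1, ], tv[2, ], tolerance = 1e-5)
  }
})

test_that("zero atom features give a zero molecular embedding", {
  d <- 8L
  gb <- fake_gb(matrix(0, 3, d), cbind(1:2, 2:3), sizes = 3L)
  cfg <- synergy_config("compact", gin_hidden = rep(d, 3L), dropout = 0,
                        use_fine = FALSE)
  params <- dgsynergy:::init_params(cfg, n_genes = 5L, atom_dim = d)
  enc <- dgsynergy:::drug_encoder_forward(dgsynergy:::wrap_params(params),
                                          cfg, gb, train = FALSE)
  expect_equal(dgsynergy:::ad_value(enc$mol), matrix(0, 1L, cfg$mol_dim))
})

test_that("the cell encoder has the configured width and is deterministic", {
  cfg <- synergy_config("reference")
  params <- dgsynergy:::init_params(cfg, n_genes = 20L)
  expr <- matrix(rnorm(60), 3, 20)
  expr[3, ] <- expr[1, ]
  out <- dgsynergy:::ad_value(dgsynergy:::cell_encoder_forward(
    dgsynergy:::wrap_params(params), cfg, expr, train = FALSE))
  expect_equal(ncol(out), 384L)
  expect_equal(out[1, ], out[3, ])
  zero <- dgsynergy:::ad_value(dgsynergy:::cell_encoder_forward(
    dgsynergy:::wrap_params(params), cfg, matrix(0, 1, 20), train = FALSE))
  expect_equal(zero, matrix(0, 1L, 384L))  # zero biases at initialization
})

test_that("encoder and readout variant switches all produce valid outputs", {
  b <- dg_bundle()
  samples <- b$ds$samples
  expr_norm <- zscore_normalize(b$dat$expression_raw)
  grid <- list(
    list(encoder = "gin", pool = "sagpool"),
    list(encoder = "gcn", pool = "sagpool"),
    list(encoder = "gat", pool = "sagpool", gat_heads = 1L),
    list(encoder = "gat", pool = "sagpool", gat_heads = 2L),
    list(encoder = "gat", pool = "sagpool", gat_heads = 4L),
    list(encoder = "gin", pool = "add"),
    list(encoder = "gin", pool = "max"),
    list(encoder = "gin", pool = "mean")
  )
  for (gcase in grid) {
    cfg <- do.call(synergy_config,
                   c(list(preset = "compact", seed = 1L), gcase))
    pre <- suppressMessages(
      dgsynergy:::prepare_pre(b$dat, cfg, samples, expr_norm))
    idx <- dgsynergy:::index_samples(pre, samples)
    pre$d1 <- idx$d1; pre$d2 <- idx$d2; pre$cell <- idx$cell
    pre$labels <- idx$labels
    set.seed(1)
    params <- dgsynergy:::init_params(cfg, n_genes = ncol(pre$expr_mat))
    fwd <- dgsynergy:::model_forward(dgsynergy:::wrap_params(params), cfg,
                                     pre, 1:20, train = FALSE)
    lbl <- paste(gcase$encoder, gcase$pool,
                 if (is.null(gcase$gat_heads)) "" else gcase$gat_heads)
    expect_true(all(is.finite(fwd$probs)), label = lbl)
    expect_true(all(fwd$probs >= 0 & fwd$probs <= 1), label = lbl)
    expect_true(is.finite(dgsynergy:::ad_value(fwd$total)), label = lbl)
  }
})
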