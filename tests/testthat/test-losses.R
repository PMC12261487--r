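# Prediction head and the three loss terms, including consistency between
# the plain reference formulas and the autodiff training path.

test_that("highway gates interpolate between carry and transform", {
  set.seed(51)
  d <- 6L
  x <- matrix(rnorm(12), 2, d)
  Wt <- matrix(rnorm(d * d) * 0.1, d, d)
  Wg <- matrix(rnorm(d * d) * 0.1, d, d)
  carry <- highway_forward(x, Wt, rep(-50, d), Wg, rep(0, d))
  expect_equal(carry$output, x, tolerance = 1e-8)
  transform <- highway_forward(x, Wt, rep(50, d), Wg, rep(0, d))
  expect_equal(transform$output,
               pmax(x %*% Wg, 0), tolerance = 1e-8)
  half <- highway_forward(x, matrix(0, d, d), rep(0, d),
                          matrix(0, d, d), rep(0, d))  # gate 0.5, G = 0
  expect_equal(half$output, x / 2, tolerance = 1e-12)
  expect_true(all(half$gate > 0 & half$gate < 1))
})

test_that("cross-entropy hits its closed-form anchor points", {
  ln2 <- dgsynergy:::ad_ce_softmax2(
    dgsynergy:::ad_const(matrix(0, 4, 2)), c(0, 1, 0, 1))
  expect_equal(as.numeric(dgsynergy:::ad_value(ln2)), log(2),
               tolerance = 1e-12)
  confident <- dgsynergy:::ad_ce_softmax2(
    dgsynergy:::ad_const(cbind(c(20, -20), c(-20, 20))), c(0, 1))
  expect_lt(as.numeric(dgsynergy:::ad_value(confident)), 1e-6)
  set.seed(52)
  rnd <- dgsynergy:::ad_ce_softmax2(
    dgsynergy:::ad_const(matrix(rnorm(20), 10, 2)),
    sample(0:1, 10, replace = TRUE))
  expect_gte(as.numeric(dgsynergy:::ad_value(rnd)), 0)
})

test_that("reconstruction loss matches its hand-computed example", {
  # embeddings whose cosine matrix equals the targets: loss 0 (a single
  # cell makes the cell block trivially exact)
  fp <- matrix(c(1, 1, 0, 0, 1, 1), 2, 3, byrow = TRUE)
  expr <- matrix(rnorm(4), 1, 4)
  emb0 <- rbind(fp, c(1, 1, 1))
  expect_equal(reconstruction_loss(emb0, fp, expr), 0, tolerance = 1e-12)
  # orthonormal embeddings vs identical originals (n = 2): drug block 0.5
  emb <- rbind(diag(2), matrix(1, 1, 2))
  fp_same <- matrix(1, 2, 3)
  expr_one <- matrix(c(1, 1), 1, 2)
  expect_equal(reconstruction_loss(emb, fp_same, expr_one), 0.5,
               tolerance = 1e-12)
  set.seed(53)
  rand <- reconstruction_loss(matrix(rnorm(15), 5, 3),
                              matrix(rbinom(12, 1, 0.5), 3, 4),
                              matrix(rnorm(8), 2, 4))
  expect_gte(rand, 0)
})

test_that("contrastive loss is a nonnegative margin penalty", {
  # positives collapsed, negatives opposite: both terms vanish
  emb <- rbind(matrix(c(1, 0), 3, 2, byrow = TRUE),
               matrix(c(-1, 0), 2, 2, byrow = TRUE))
  labels <- c(1, 1, 1, 0, 0)
  expect_equal(contrastive_loss(emb, labels, margin = 0.5), 0,
               tolerance = 1e-12)
  set.seed(54)
  emb_r <- matrix(rnorm(24), 8, 3)
  lab_r <- c(1, 1, 1, 1, 0, 0, 0, 0)
  l1 <- contrastive_loss(emb_r, lab_r, margin = 0.5)
  l2 <- contrastive_loss(emb_r, lab_r, margin = 1.0)
  expect_gte(l1, 0)
  expect_gte(l2, l1)  # monotone in the margin
  expect_warning(single <- contrastive_loss(emb_r, rep(1, 8)),
                 "single-class")
  expect_true(is.na(single))
})

test_that("the training tape reproduces the reference loss formulas", {
  b <- dg_bundle()
  cfg <- synergy_config("compact", seed = 2L, dropout = 0)
  expr_norm <- zscore_normalize(b$dat$expression_raw)
  pre <- suppressMessages(
    dgsynergy:::prepare_pre(b$dat, cfg, b$ds$samples, expr_norm))
  idx <- dgsynergy:::index_samples(pre, b$ds$samples)
  pre$d1 <- idx$d1; pre$d2 <- idx$d2; pre$cell <- idx$cell
  pre$labels <- idx$labels
  set.seed(2)
  params <- dgsynergy:::init_params(cfg, n_genes = ncol(pre$expr_mat))
  batch <- 1:60
  fwd <- dgsynergy:::model_forward(dgsynergy:::wrap_params(params), cfg, pre,
                                   batch, train = FALSE, collect = TRUE)
  # reconstruction: same value from the plain-matrix reference
  rec_ref <- reconstruction_loss(
    dgsynergy:::ad_value(fwd$coarse_nodes),
    b$dat$fingerprints[b$dat$drugs$drug_id, ],
    dgsynergy:::expression_matrix(expr_norm)
  )
  expect_equal(as.numeric(dgsynergy:::ad_value(fwd$rec)), rec_ref,
               tolerance = 1e-8)
  # contrastive: deterministic evaluation negatives
  con_ref <- contrastive_loss(dgsynergy:::ad_value(fwd$coarse_s),
                              pre$labels[batch],
                              margin = cfg$contrastive_margin)
  expect_equal(as.numeric(dgsynergy:::ad_value(fwd$con)), con_ref,
               tolerance = 1e-8)
  # additivity of the weighted sum
  w <- cfg$loss_weights
  expect_equal(
    as.numeric(dgsynergy:::ad_value(fwd$total)),
    w[["cls"]] * as.numeric(dgsynergy:::ad_value(fwd$cls)) +
      w[["rec"]] * rec_ref + w[["con"]] * con_ref,
    tolerance = 1e-6
  )
  expect_true(all(fwd$probs >= 0 & fwd$probs <= 1))
})

test_that("drug-swapped inputs yield a swapped six-vector bundle", {
  fit <- dg_fit_random()
  fb <- fine_bundle(fit, "D01", "D03", "CL02")
  fb_sw <- fine_bundle(fit, "D03", "D01", "CL02")
  reorder <- c(2, 1, 5, 6, 3, 4)  # A/B exchange permutes the six directions
  expect_equal(unname(fb_sw$vectors), unname(fb$vectors[reorder, ]),
               tolerance = 1e-8)
  # identical drugs with shared cross-attention weights: paired directions
  same <- fine_bundle(fit, "D05", "D05", "CL01")
  expect_equal(same$vectors["A<-B", ], same$vectors["B<-A", ],
               tolerance = 1e-8)
  expect_equal(same$vectors["A<-cell", ], same$vectors["B<-cell", ],
               tolerance = 1e-8)
  for (m in same$attention_maps$self) {
    expect_equal(rowSums(m), rep(1, 6), tolerance = 1e-5)
  }
})
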