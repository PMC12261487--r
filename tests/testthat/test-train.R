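# Training behaviour, prediction surfaces, and post-fit analyses.

test_that("training is reproducible given the seed", {
  b <- dg_bundle()
  sp <- split_random(b$ds$samples, seed = 7L)[[1]]
  cfg <- synergy_config("compact", max_epochs = 3L, seed = 13L)
  f1 <- suppressMessages(fit_synergy(b$dat, sp, cfg))
  f2 <- suppressMessages(fit_synergy(b$dat, sp, cfg))
  expect_equal(tidy(f1), tidy(f2), tolerance = 1e-12)
  expect_identical(f1$params, f2$params)
})

test_that("shuffled labels yield chance-level discrimination", {
  b <- dg_bundle()
  shuffled <- b$dat
  # permute labels at the unordered-triple level so twins stay consistent
  key <- paste(pmin(shuffled$samples$drug1, shuffled$samples$drug2),
               pmax(shuffled$samples$drug1, shuffled$samples$drug2),
               shuffled$samples$cell_line)
  uk <- unique(key)
  newlab <- withr::with_seed(99L, stats::setNames(
    sample(rep_len(0:1, length(uk))), uk))
  shuffled$samples$label <- unname(newlab[key])
  sp <- split_random(shuffled$samples, seed = 7L)[[1]]
  cfg <- synergy_config("compact", max_epochs = 30L, patience = 30L,
                        seed = 7L)
  fit <- suppressMessages(fit_synergy(shuffled, sp, cfg))
  m <- suppressWarnings(evaluate_fit(fit, "test"))
  expect_gt(m$auc_roc, 0.35)
  expect_lt(m$auc_roc, 0.65)
})

test_that("prediction returns calibrated-range probabilities per triple", {
  fit <- dg_fit_random()
  preds <- predict(fit, head(fit$data$samples, 50))
  expect_named(preds, c(names(fit$data$samples), ".pred"),
               ignore.order = TRUE)
  expect_true(all(preds$.pred >= 0 & preds$.pred <= 1))
  again <- predict(fit, head(fit$data$samples, 50))
  expect_identical(preds$.pred, again$.pred)  # eval mode is deterministic
  expect_error(predict(fit, tibble::tibble(drug1 = "nope", drug2 = "D01",
                                           cell_line = "CL01")),
               "unknown entities")
})

test_that("atom importance maps cover three layers on the unit interval", {
  fit <- dg_fit_random()
  imp <- explain_drug(fit, "D01")
  expect_setequal(unique(imp$layer), 1:3)
  expect_true(all(imp$score >= 0 & imp$score <= 1))
  n_atoms <- fit$data$graphs[["D01"]]$n_atoms
  expect_true(all(imp$atom >= 1 & imp$atom <= n_atoms))
  # layer 1 scores every atom; deeper layers only the retained subgraph
  expect_equal(sum(imp$layer == 1), n_atoms)
  expect_lte(sum(imp$layer == 2), n_atoms)
  # a layer reduced to a single atom degenerates to importance 1
  single <- dplyr::count(imp, layer)
  for (l in single$layer[single$n == 1]) {
    expect_equal(imp$score[imp$layer == l], 1)
  }
  # soft diagnostic: do motif atoms score above average? (logged, not asserted)
  l1 <- imp[imp$layer == 1, ]
  aromatic <- fit$data$graphs[["D01"]]$atom_features[l1$atom, 78] == 1
  message(sprintf("aromatic-atom layer-1 mean importance (diagnostic): %.2f",
                  mean(l1$score[aromatic])))
})

test_that("screening excludes training triples and ranks by probability", {
  fit <- dg_fit_random()
  ranked <- screen_combinations(fit)
  known <- fit$data$samples
  expect_length(intersect(
    paste(pmin(ranked$drug1, ranked$drug2),
          pmax(ranked$drug1, ranked$drug2), ranked$cell_line),
    paste(pmin(known$drug1, known$drug2),
          pmax(known$drug1, known$drug2), known$cell_line)), 0L)
  expect_false(is.unsorted(rev(ranked$prob)))
  # candidate count: all pairs x cell lines minus the known triples
  n_drugs <- nrow(fit$data$drugs)
  n_cells <- nrow(fit$data$expression_raw)
  n_known <- length(unique(paste(pmin(known$drug1, known$drug2),
                                 pmax(known$drug1, known$drug2),
                                 known$cell_line)))
  expect_equal(nrow(ranked),
               n_drugs * (n_drugs - 1) / 2 * n_cells - n_known)
})

test_that("embedding export covers the four module stages", {
  fit <- dg_fit_random()
  emb <- export_embeddings(fit, head(fit$data$samples, 8))
  expect_setequal(unique(emb$stage), c("init", "coarse", "fine", "final"))
  expect_equal(nrow(emb), 4L * 8L)
  widths <- tapply(lengths(emb$embedding), emb$stage, unique)
  cfg <- fit$config
  expect_equal(unname(widths[["coarse"]]), 3L * cfg$hyper_dims[4])
  expect_equal(unname(widths[["fine"]]), 6L * cfg$token_dim)
})

test_that("accessors and plots expose the fit the tidyverse way", {
  fit <- dg_fit_random()
  lg <- tidy(fit)
  expect_s3_class(lg, "tbl_df")
  expect_named(lg, c("epoch", "loss_total", "loss_cls", "loss_rec",
                     "loss_con", "val_loss", "val_auc"))
  g <- glance(fit)
  expect_equal(nrow(g), 1L)
  expect_equal(g$n_train + g$n_val + g$n_test, nrow(fit$data$samples))
  expect_s3_class(autoplot(fit), "ggplot")
  oi <- order_independence(fit)
  expect_s3_class(plot_order_independence(oi), "ggplot")
  expect_s3_class(plot_atom_importance(explain_drug(fit, "D02")), "ggplot")
})

test_that("hyperedges never grow at evaluation time", {
  fit <- dg_fit_random()
  H_before <- fit$pre$incidence$H
  invisible(predict(fit, fit$data$samples))
  expect_identical(fit$pre$incidence$H, H_before)
  # and the incidence only contains training triples
  train_ids <- fit$assignment$sample_id[fit$assignment$part == "train"]
  train <- fit$data$samples[fit$data$samples$sample_id %in% train_ids, ]
  expect_equal(ncol(H_before),
               length(unique(paste(pmin(train$drug1, train$drug2),
                                   pmax(train$drug1, train$drug2),
                                   train$cell_line))))
})
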