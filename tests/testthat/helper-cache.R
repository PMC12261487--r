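# Shared expensive objects, computed once per test session. The trained fits
# back both the behavioural tests and the acceptance suite.

.dg_cache <- new.env(parent = emptyenv())

dg_cached <- function(name, expr) {
  if (is.null(.dg_cache[[name]])) .dg_cache[[name]] <- force(expr)
  .dg_cache[[name]]
}

dg_bundle <- function() {
  dg_cached("bundle", {
    fx <- generate_fixture()
    ds <- suppressMessages(build_dataset(fx$synergy, fx$drugs, fx$expression))
    dat <- synergy_data(ds$samples, fx$drugs, fx$expression,
                        landmark = fx$landmark)
    list(fx = fx, ds = ds, dat = dat)
  })
}

dg_fit_random <- function() {
  dg_cached("fit_random", {
    b <- dg_bundle()
    sp <- split_random(b$ds$samples, seed = 7L)[[1]]
    suppressMessages(
      fit_synergy(b$dat, sp, synergy_config("compact", seed = 7L))
    )
  })
}

dg_fit_loco <- function() {
  dg_cached("fit_loco", {
    b <- dg_bundle()
    sp <- split_leave_cell_line_out(b$ds$samples, seed = 7L)[[1]]
    suppressMessages(
      fit_synergy(b$dat, sp, synergy_config("compact", seed = 7L))
    )
  })
}

dg_fit_noaux <- function() {
  dg_cached("fit_noaux", {
    b <- dg_bundle()
    sp <- split_random(b$ds$samples, seed = 7L)[[1]]
    suppressMessages(fit_synergy(
      b$dat, sp,
      synergy_config("compact", seed = 7L,
                     loss_weights = c(cls = 1, rec = 0, con = 0))
    ))
  })
}

# small random dataset for structural tests (no chemistry needed)
dg_toy_samples <- function(n_drugs = 8L, n_cells = 6L, n = 40L, seed = 3L) {
  withr::with_seed(seed, {
    base <- tibble::tibble(
      drug1 = sample(sprintf("D%02d", seq_len(n_drugs)), n, replace = TRUE),
      drug2 = sample(sprintf("D%02d", seq_len(n_drugs)), n, replace = TRUE),
      cell_line = sample(sprintf("C%02d", seq_len(n_cells)), n,
                         replace = TRUE),
      label = sample(0:1, n, replace = TRUE)
    )
    base <- base[base$drug1 != base$drug2, ]
    s <- suppressMessages(symmetrize_samples(base))
    s$sample_id <- seq_len(nrow(s))
    s
  })
}

# finite-difference gradient of scalar-valued f at x
dg_numgrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
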