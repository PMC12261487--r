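# Gradient correctness of the reverse-mode engine against central finite
# differences, including the fused multi-head attention.

ad <- function(x) dgsynergy:::ad_param(x)
adc <- function(x) dgsynergy:::ad_const(x)

test_that("elementary op gradients match finite differences", {
  set.seed(11)
  X <- matrix(rnorm(12), 3, 4)
  B <- matrix(rnorm(12), 3, 4)
  W <- matrix(rnorm(8), 4, 2)
  gidx <- c(1L, 2L, 1L)
  y <- c(1, 0, 1)
  S <- matrix(rnorm(9), 3, 3)

  cases <- list(
    mm_relu = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_relu(dgsynergy:::ad_mm(p, adc(W)))),
      ref = function(x) mean(pmax(x %*% W, 0))
    ),
    mm_transposed = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_mm(p, adc(B), tb = TRUE)),
      ref = function(x) mean(tcrossprod(x, B))
    ),
    softmax = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_mul(dgsynergy:::ad_rowsoftmax(p), adc(B))),
      ref = function(x) {
        e <- exp(x - apply(x, 1, max)); mean(e / rowSums(e) * B)
      }
    ),
    row_normalize = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_mul(dgsynergy:::ad_rownormalize(p), adc(B))),
      ref = function(x) mean(x / sqrt(rowSums(x^2)) * B)
    ),
    cross_entropy = list(
      ad = function(p) dgsynergy:::ad_ce_softmax2(
        dgsynergy:::ad_mm(p, adc(W)), y),
      ref = function(x) {
        l <- x %*% W
        e <- exp(l - apply(l, 1, max)); pr <- e / rowSums(e)
        -mean(log(ifelse(y == 1, pr[, 2], pr[, 1])))
      }
    ),
    group_mean = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_group_mean(p, gidx, 2L)),
      ref = function(x) mean(rowsum(x, gidx) / c(2, 1))
    ),
    group_max = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_group_max(p, gidx, 2L)),
      ref = function(x) mean(rbind(pmax(x[1, ], x[3, ]), x[2, ]))
    ),
    spmm = list(
      ad = function(p) dgsynergy:::ad_mean(dgsynergy:::ad_spmm(S, p)),
      ref = function(x) mean(S %*% x)
    ),
    gather_rows = list(
      ad = function(p) dgsynergy:::ad_mean(
        dgsynergy:::ad_rows(p, c(1L, 1L, 3L, 2L))),
      ref = function(x) mean(x[c(1, 1, 3, 2), ])
    ),
    mse = list(
      ad = function(p) dgsynergy:::ad_mse(p, B),
      ref = function(x) mean((x - B)^2)
    ),
    token_reshape = list(
      ad = function(p) dgsynergy:::ad_mean(dgsynergy:::ad_mul(
        dgsynergy:::ad_tokens_wide(dgsynergy:::ad_tokens_tall(p, 2L), 2L),
        adc(B))),
      ref = function(x) mean(x * B)
    ),
    outer_sum = list(
      ad = function(p) dgsynergy:::ad_mean(dgsynergy:::ad_outer_sum(
        dgsynergy:::ad_cols(p, 1L), dgsynergy:::ad_cols(p, 2L))),
      ref = function(x) mean(outer(x[, 1], x[, 2], "+"))
    )
  )
  for (nm in names(cases)) {
    p <- ad(X)
    loss <- cases[[nm]]$ad(p)
    dgsynergy:::ad_backward(loss)
    expect_equal(p$grad, dg_numgrad(cases[[nm]]$ref, X),
                 tolerance = 1e-6, ignore_attr = TRUE, label = nm)
  }
})

test_that("fused multi-head attention gradients match finite differences", {
  set.seed(12)
  d <- 8L; heads <- 4L; g0 <- 4L; nq <- 3L; nk <- 2L
  Tqv <- matrix(rnorm(g0 * nq * d), g0)
  Tkv <- matrix(rnorm(g0 * nk * d), g0)
  Ws <- lapply(1:4, function(i) matrix(rnorm(d * d) * 0.3, d, d))
  R <- matrix(rnorm(g0 * nq * d), g0)

  ref <- function(Tqv, Tkv, Ws, nq, nk) {
    dh <- d / heads
    out <- matrix(0, nrow(Tqv), nq * d)
    tc <- function(t) ((t - 1) * d + 1):(t * d)
    for (i in seq_len(nq)) {
      Qi <- Tqv[, tc(i)] %*% Ws[[1]]
      Cih <- matrix(0, nrow(Tqv), d)
      for (h in seq_len(heads)) {
        cols <- ((h - 1) * dh + 1):(h * dh)
        Sm <- sapply(seq_len(nk), function(j) {
          rowSums(Qi[, cols] * (Tkv[, tc(j)] %*% Ws[[2]])[, cols])
        }) / sqrt(dh)
        Sm <- matrix(Sm, ncol = nk)
        E <- exp(Sm - apply(Sm, 1, max)); A <- E / rowSums(E)
        acc <- matrix(0, nrow(Tqv), dh)
        for (j in seq_len(nk)) {
          acc <- acc + A[, j] * (Tkv[, tc(j)] %*% Ws[[3]])[, cols]
        }
        Cih[, cols] <- acc
      }
      out[, tc(i)] <- Cih %*% Ws[[4]]
    }
    out
  }

  Tq <- ad(Tqv); Tk <- ad(Tkv)
  Wn <- lapply(Ws, ad)
  r <- dgsynergy:::ad_mha(Tq, Tk, nq, nk, Wn[[1]], Wn[[2]], Wn[[3]], Wn[[4]],
                          heads)
  expect_equal(dgsynergy:::ad_value(r$out), ref(Tqv, Tkv, Ws, nq, nk),
               tolerance = 1e-10)
  loss <- dgsynergy:::ad_mean(dgsynergy:::ad_mul(r$out, adc(R)))
  dgsynergy:::ad_backward(loss)
  expect_equal(Tq$grad, dg_numgrad(function(x)
    mean(ref(x, Tkv, Ws, nq, nk) * R), Tqv), tolerance = 1e-6)
  expect_equal(Tk$grad, dg_numgrad(function(x)
    mean(ref(Tqv, x, Ws, nq, nk) * R), Tkv), tolerance = 1e-6)
  for (wi in 1:4) {
    expect_equal(Wn[[wi]]$grad, dg_numgrad(function(x) {
      W2 <- Ws; W2[[wi]] <- x
      mean(ref(Tqv, Tkv, W2, nq, nk) * R)
    }, Ws[[wi]]), tolerance = 1e-6, label = paste0("W", wi))
  }

  # self-attention: query and key nodes are the same tape node
  R2 <- matrix(rnorm(g0 * nq * d), g0)
  Tsv <- matrix(rnorm(g0 * nq * d), g0)
  Ts <- ad(Tsv)
  rs <- dgsynergy:::ad_mha(Ts, Ts, nq, nq, Wn[[1]], Wn[[2]], Wn[[3]],
                           Wn[[4]], heads)
  loss2 <- dgsynergy:::ad_mean(dgsynergy:::ad_mul(rs$out, adc(R2)))
  dgsynergy:::ad_backward(loss2)
  expect_equal(Ts$grad, dg_numgrad(function(x)
    mean(ref(x, x, Ws, nq, nq) * R2), Tsv), tolerance = 1e-6)
})
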