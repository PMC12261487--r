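# Model and training configuration.

#' Model and training configuration
#'
#' The `"reference"` preset is the method's full-scale hyperparameter set:
#' three GIN layers of 128 hidden units, a
#' `[512, 384]` cell-line MLP, a `[768, 384, 384, 384]` hypergraph stack,
#' 4 attention heads, dropout 0.3, Adam at learning rate 4e-4, and up to 2000
#' epochs with early stopping. The `"compact"` preset is a proportionally
#' narrower configuration (widths divided by four, shorter epoch budget,
#' higher learning rate) sized so that a full training run on the default
#' synthetic fixture finishes in a couple of minutes on one CPU; it is what
#' the package's tests and reproduction script use.
#'
#' @param preset `"reference"` or `"compact"`.
#' @param ... Named overrides of any configuration field.
#' @return A `synergy_config` list.
#' @export
synergy_config <- function(preset = c("reference", "compact"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    encoder = "gin",            # gin | gcn | gat
    gat_heads = 4L,
    gin_hidden = c(128L, 128L, 128L),
    gin_eps = 0,
    pool = "sagpool",           # sagpool | add | max | mean
    pool_ratio = 0.5,
    mol_dim = 384L,
    cell_mlp = c(512L, 384L),
    hyper_dims = c(768L, 384L, 384L, 384L),
    token_dim = 128L,
    heads = 4L,
    mlp_hidden = 512L,
    dropout = 0.3,
    lr = 4e-4,
    max_epochs = 2000L,
    patience = 50L,
    min_delta = 1e-4,
    batch_size = 256L,
    seed = 1L,
    loss_weights = c(cls = 1.0, rec = 0.1, con = 0.1),
    contrastive_margin = 0.5,
    hyperedges = "all",         # all | positive_only
    threshold = 0.5,
    use_coarse = TRUE,
    use_fine = TRUE,
    use_highway = TRUE,
    use_residual = TRUE,
    fp_radius = 3L,
    verbose = FALSE
  )
  if (preset == "compact") {
    cfg$gin_hidden <- c(32L, 32L, 32L)
    cfg$mol_dim <- 96L
    cfg$cell_mlp <- c(128L, 96L)
    cfg$hyper_dims <- c(192L, 96L, 96L, 96L)
    cfg$token_dim <- 32L
    cfg$mlp_hidden <- 128L
    cfg$dropout <- 0.2
    cfg$lr <- 2e-3
    cfg$max_epochs <- 150L
    cfg$patience <- 30L
    cfg$batch_size <- 1024L
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$token_dim %% cfg$heads != 0L) {
    stop("token_dim must be divisible by heads")
  }
  structure(cfg, class = "synergy_config")
}

#' @export
print.synergy_config <- function(x, ...) {
  cat("<synergy_config>\n")
  cat("  encoder:", x$encoder, " pool:", x$pool, " ratio:", x$pool_ratio, "\n")
  cat("  gin_hidden:", paste(x$gin_hidden, collapse = ","),
      " cell_mlp:", paste(x$cell_mlp, collapse = ","), "\n")
  cat("  hyper_dims:", paste(x$hyper_dims, collapse = ","),
      " token_dim:", x$token_dim, " heads:", x$heads, "\n")
  cat("  dropout:", x$dropout, " lr:", x$lr, " max_epochs:", x$max_epochs,
      " batch:", x$batch_size, "\n")
  cat("  loss_weights:", paste(names(x$loss_weights), x$loss_weights,
                               sep = "=", collapse = " "), "\n")
  invisible(x)
}
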