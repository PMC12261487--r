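# Cell-line expression preprocessing: landmark-gene restriction and per-gene
# z-score normalization.

#' Read a cell-line expression matrix
#'
#' @param path CSV or TSV file; first column is the cell-line identifier,
#'   remaining columns are gene symbols.
#' @return Tibble with a `cell_line` column followed by one column per gene.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1] <- "cell_line"
  tibble::as_tibble(df)
}

#' Restrict an expression matrix to a landmark gene set
#'
#' Keeps the intersection of the matrix's genes with the landmark list, in the
#' landmark list's order, and warns with a count of landmark genes absent from
#' the matrix.
#'
#' @param expr Tibble with `cell_line` plus gene columns.
#' @param landmark Character vector of gene symbols.
#' @return Tibble restricted to `cell_line` plus the intersecting genes.
#' @export
select_landmark_genes <- function(expr, landmark) {
  stopifnot(names(expr)[1] == "cell_line")
  present <- landmark[landmark %in% names(expr)[-1]]
  missing <- length(landmark) - length(present)
  if (length(present) == 0L) {
    stop("no landmark genes present in the expression matrix", call. = FALSE)
  }
  if (missing > 0L) {
    warning(missing, " landmark gene", if (missing > 1L) "s",
            " missing from the expression matrix", call. = FALSE)
  }
  dplyr::select(expr, "cell_line", dplyr::all_of(present))
}

#' Z-score normalize expression per gene
#'
#' Standardizes each gene column to mean 0, standard deviation 1, using the
#' population (1/n) standard deviation. When `train_cells` is supplied the
#' statistics are computed on those rows only and applied to all rows, so a
#' held-out partition never leaks into normalization. Zero-variance columns
#' are dropped with a message.
#'
#' @param expr Tibble with `cell_line` plus gene columns.
#' @param train_cells Optional character vector of cell lines whose rows
#'   define the normalization statistics.
#' @return Normalized tibble with attributes `norm_mean`, `norm_sd`,
#'   `dropped_genes`, and `norm_scope` ("train" or "all").
#' @export
zscore_normalize <- function(expr, train_cells = NULL) {
  stopifnot(names(expr)[1] == "cell_line")
  genes <- names(expr)[-1]
  m <- as.matrix(expr[, genes, drop = FALSE])
  if (anyNA(m)) stop("expression matrix contains missing values", call. = FALSE)
  scope_rows <- if (is.null(train_cells)) seq_len(nrow(m)) else {
    which(expr$cell_line %in% train_cells)
  }
  if (!length(scope_rows)) stop("no rows match train_cells", call. = FALSE)
  sub <- m[scope_rows, , drop = FALSE]
  mu <- colMeans(sub)
  sdv <- sqrt(colMeans(sweep(sub, 2L, mu)^2))  # population sd
  keep <- sdv > 1e-12
  dropped <- genes[!keep]
  if (length(dropped)) {
    message("dropping ", length(dropped), " zero-variance gene(s): ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ...")
  }
  z <- sweep(sweep(m[, keep, drop = FALSE], 2L, mu[keep]), 2L, sdv[keep], "/")
  out <- dplyr::bind_cols(
    tibble::tibble(cell_line = expr$cell_line),
    tibble::as_tibble(z)
  )
  attr(out, "norm_mean") <- mu[keep]
  attr(out, "norm_sd") <- sdv[keep]
  attr(out, "dropped_genes") <- dropped
  attr(out, "norm_scope") <- if (is.null(train_cells)) "all" else "train"
  out
}

expression_matrix <- function(expr) {
  m <- as.matrix(expr[, -1, drop = FALSE])
  rownames(m) <- expr$cell_line
  m
}
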