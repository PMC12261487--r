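# Self-contained synthetic toy universe: fragment-assembled drugs, clustered
# expression profiles, and synergy scores with a planted, learnable rule.
#
# Planted rule: a triple is synergistic iff BOTH drugs carry the active motif
# (a pyridine ring) AND the cell line belongs to a sensitive expression
# cluster. Reference-model scores share a latent magnitude |N(2,1)| signed by
# the rule, plus per-model N(0, 0.6) disagreement noise, so majority voting
# (including occasional 2-2 ties) is exercised.

#' Specification of a synthetic fixture
#'
#' @param n_drugs,n_cell_lines,n_genes,n_triples Universe sizes.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param positive_rate Target fraction of synergistic triples.
#' @param motif_fraction Fraction of drugs carrying the active pyridine motif.
#' @param n_clusters Latent expression clusters; the first
#'   `n_sensitive_clusters` are the synergy-sensitive ones.
#' @param n_sensitive_clusters Number of sensitive clusters.
#' @param n_landmark Genes listed in the landmark file (a subset of
#'   `n_genes`, exercising landmark restriction).
#' @param score_noise_sd Per-model disagreement noise standard deviation.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_drugs = 30L, n_cell_lines = 12L, n_genes = 64L,
                         n_triples = 600L, seed = 7L, positive_rate = 0.3,
                         motif_fraction = 2 / 3, n_clusters = 3L,
                         n_sensitive_clusters = 2L, n_landmark = 48L,
                         score_noise_sd = 0.6) {
  stopifnot(n_drugs >= 6L, n_cell_lines >= 5L, n_genes >= 4L,
            n_landmark <= n_genes, n_sensitive_clusters < n_clusters + 1L)
  structure(
    list(n_drugs = n_drugs, n_cell_lines = n_cell_lines, n_genes = n_genes,
         n_triples = n_triples, seed = seed, positive_rate = positive_rate,
         motif_fraction = motif_fraction, n_clusters = n_clusters,
         n_sensitive_clusters = n_sensitive_clusters, n_landmark = n_landmark,
         score_noise_sd = score_noise_sd),
    class = "fixture_spec"
  )
}

MOTIF_SMILES <- "c1ccncc1"

fixture_smiles_pool <- function(motif) {
  chains <- c("C", "CC", "CCC", "CCCC", "CC(C)C", "CCCCC")
  ring <- if (motif) "c1ccncc1" else "c1ccccc1"
  tails <- c("", "C(=O)N", "Cl", "F", "CC", "CCO", "C(=O)NC", "Br")
  bare <- if (motif) character(0) else c("CCO", "CCCO", "CC(=O)NC", "CCCC(=O)N",
                                         "CCCCCC", "CCNCC")
  combos <- as.vector(outer(chains, paste0(ring, tails), paste0))
  c(combos, bare)
}

#' Generate the synthetic drug table
#'
#' Valid SMILES are assembled from a small fragment library (alkyl chains,
#' benzene, pyridine, amide, halogens); the first
#' `ceil(motif_fraction * n_drugs)` drugs carry the pyridine motif. All
#' SMILES are unique after canonicalization.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble with `drug_id`, `smiles`, `has_motif`.
#' @export
generate_drugs <- function(spec) {
  n_motif <- ceiling(spec$motif_fraction * spec$n_drugs)
  withr::with_seed(spec$seed, {
    pick <- function(pool, k) {
      can <- canonicalize_smiles(pool)
      keep <- !duplicated(can)
      pool <- pool[keep]
      if (length(pool) < k) stop("fragment pool too small")
      sample(pool, k)
    }
    motif_smiles <- pick(fixture_smiles_pool(TRUE), n_motif)
    plain_smiles <- pick(fixture_smiles_pool(FALSE), spec$n_drugs - n_motif)
  })
  tibble::tibble(
    drug_id = sprintf("D%02d", seq_len(spec$n_drugs)),
    smiles = c(motif_smiles, plain_smiles),
    has_motif = rep(c(TRUE, FALSE), c(n_motif, spec$n_drugs - n_motif))
  )
}

#' Generate the synthetic expression matrix
#'
#' Cell lines are assigned round-robin to latent clusters; each gene's value
#' is the cluster mean (drawn N(0, 1) per cluster and gene) plus unit
#' Gaussian noise.
#'
#' @param spec A [fixture_spec()].
#' @return List with `expression` (tibble: cell_line + genes), `landmark`
#'   (character vector), `clusters` (named integer vector).
#' @export
generate_expression <- function(spec) {
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  cells <- sprintf("CL%02d", seq_len(spec$n_cell_lines))
  clusters <- rep_len(seq_len(spec$n_clusters), spec$n_cell_lines)
  vals <- withr::with_seed(spec$seed + 1L, {
    centers <- matrix(stats::rnorm(spec$n_clusters * spec$n_genes),
                      spec$n_clusters, spec$n_genes)
    centers[clusters, ] +
      matrix(stats::rnorm(spec$n_cell_lines * spec$n_genes),
             spec$n_cell_lines, spec$n_genes)
  })
  colnames(vals) <- genes
  expr <- dplyr::bind_cols(tibble::tibble(cell_line = cells),
                           tibble::as_tibble(vals))
  list(expression = expr,
       landmark = genes[seq_len(spec$n_landmark)],
       clusters = stats::setNames(clusters, cells))
}

#' Generate the synthetic synergy table
#'
#' Applies the planted rule to all candidate (unordered pair, cell line)
#' triples, then samples `n_triples` of them stratified by latent label so
#' the positive rate matches `positive_rate`. Scores for the four reference
#' models share a latent magnitude |N(2, 1)| signed by the rule plus
#' per-model Gaussian disagreement noise.
#'
#' @param spec A [fixture_spec()].
#' @param drugs Tibble from [generate_drugs()].
#' @param cells List from [generate_expression()].
#' @return Tibble with `drug1`, `drug2`, `cell_line`, `bliss`, `loewe`,
#'   `hsa`, `zip`, `latent_label`.
#' @export
generate_synergy <- function(spec, drugs, cells) {
  sensitive <- seq_len(spec$n_sensitive_clusters)
  pairs <- utils::combn(drugs$drug_id, 2L)
  cand <- tidyr::expand_grid(
    pair = seq_len(ncol(pairs)),
    cell_line = names(cells$clusters)
  )
  cand$drug1 <- pairs[1L, cand$pair]
  cand$drug2 <- pairs[2L, cand$pair]
  motif <- stats::setNames(drugs$has_motif, drugs$drug_id)
  cand$latent_label <- as.integer(
    motif[cand$drug1] & motif[cand$drug2] &
      cells$clusters[cand$cell_line] %in% sensitive
  )
  n_pos <- round(spec$positive_rate * spec$n_triples)
  n_neg <- spec$n_triples - n_pos
  withr::with_seed(spec$seed + 2L, {
    pos_rows <- sample(which(cand$latent_label == 1L), n_pos)
    neg_rows <- sample(which(cand$latent_label == 0L), n_neg)
    sel <- cand[sample(c(pos_rows, neg_rows)), , drop = FALSE]
    sgn <- ifelse(sel$latent_label == 1L, 1, -1)
    base <- abs(stats::rnorm(nrow(sel), mean = 2, sd = 1))
    scores <- vapply(SCORE_MODELS, function(m) {
      sgn * base + stats::rnorm(nrow(sel), sd = spec$score_noise_sd)
    }, numeric(nrow(sel)))
  })
  out <- tibble::tibble(
    drug1 = sel$drug1, drug2 = sel$drug2, cell_line = sel$cell_line
  )
  out[SCORE_MODELS] <- as.data.frame(scores)
  out$latent_label <- sel$latent_label
  out
}

#' Generate a complete synthetic fixture
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `drugs.csv`,
#'   `expression.csv`, `landmark.txt`, `synergy.csv`, `ground_truth.json`.
#' @return List with `drugs`, `expression`, `landmark`, `synergy`,
#'   `ground_truth`, and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  drugs <- generate_drugs(spec)
  ex <- generate_expression(spec)
  synergy <- generate_synergy(spec, drugs, ex)
  ground_truth <- list(
    motif_drugs = drugs$drug_id[drugs$has_motif],
    motif_smiles = MOTIF_SMILES,
    clusters = as.list(ex$clusters),
    sensitive_clusters = seq_len(spec$n_sensitive_clusters),
    positive_rate = mean(synergy$latent_label)
  )
  out <- list(drugs = drugs, expression = ex$expression,
              landmark = ex$landmark, synergy = synergy,
              ground_truth = ground_truth, spec = spec)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(drugs[c("drug_id", "smiles")],
                     file.path(dir, "drugs.csv"), row.names = FALSE)
    utils::write.csv(ex$expression, file.path(dir, "expression.csv"),
                     row.names = FALSE)
    writeLines(ex$landmark, file.path(dir, "landmark.txt"))
    utils::write.csv(
      synergy[c("drug1", "drug2", "cell_line", SCORE_MODELS)],
      file.path(dir, "synergy.csv"), row.names = FALSE
    )
    jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
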