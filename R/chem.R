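# SMILES featurization: molecular graphs with 78-dimensional atom features and
# folded ECFP6 fingerprints, via OpenBabel (ChemmineOB/ChemmineR).

# 43 named element symbols; anything else falls into the trailing "other"
# bucket, giving a 44-wide atom-type block and a 78-dimensional feature vector.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

ATOM_FEATURE_DIM <- 44L + 11L + 11L + 11L + 1L  # type, degree, H, valence, aromatic

one_hot <- function(idx, width) {
  v <- numeric(width)
  v[idx] <- 1
  v
}

# clamp a count in 0..Inf into the 11-wide one-hot over 0..10
count_hot <- function(k) one_hot(min(k, 10L) + 1L, 11L)

#' Canonicalize SMILES strings
#'
#' Converts each SMILES to its OpenBabel canonical form so that equivalent
#' writings of the same molecule unify before graph construction and
#' fingerprint hashing.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @export
canonicalize_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", s),
      error = function(e) ""
    )
    out <- strsplit(trimws(out), "[\t ]")[[1]][1]
    if (is.na(out) || !nzchar(out)) {
      stop("unparseable SMILES: '", s, "'", call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}

mol2_from_smiles <- function(smiles, add_h = TRUE) {
  opts <- if (add_h) data.frame(names = "h", args = "") else
    data.frame(names = character(0), args = character(0))
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", smiles, options = opts),
    error = function(e) ""
  )
  if (!nzchar(txt)) stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  txt
}

parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  tags <- grep("^@<TRIPOS>", lines)
  section <- function(name) {
    start <- which(lines == paste0("@<TRIPOS>", name))
    if (length(start) != 1L) return(character(0))
    stop_at <- tags[tags > start]
    end <- if (length(stop_at)) stop_at[1] - 1L else length(lines)
    if (end < start + 1L) return(character(0))
    out <- lines[(start + 1L):end]
    out[nzchar(trimws(out))]
  }
  atom_lines <- section("ATOM")
  bond_lines <- section("BOND")
  stopifnot(length(atom_lines) > 0L)
  atoms <- do.call(rbind, lapply(strsplit(trimws(atom_lines), "\\s+"), function(f) {
    data.frame(id = as.integer(f[1]), type = f[6], stringsAsFactors = FALSE)
  }))
  atoms$element <- sub("\\..*$", "", atoms$type)
  bonds <- if (length(bond_lines)) {
    do.call(rbind, lapply(strsplit(trimws(bond_lines), "\\s+"), function(f) {
      data.frame(a1 = as.integer(f[2]), a2 = as.integer(f[3]), type = f[4],
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), type = character(0))
  }
  list(atoms = atoms, bonds = bonds)
}

#' Parse a SMILES string into a featurized molecular graph
#'
#' Heavy atoms become nodes and bonds become edges. Each atom carries a
#' 78-dimensional binary feature vector made of four one-hot blocks (atom type
#' over 43 named elements plus an "other" bucket; degree 0-10; hydrogen count
#' 0-10; implicit valence 0-10, values above 10 clamped into the last bucket)
#' and a single aromaticity flag. Hydrogens are implicit: they contribute to
#' the hydrogen-count feature but are not nodes. The implicit valence equals
#' the implicit hydrogen count, the convention of the featurization this block
#' structure follows.
#'
#' @param smiles A single valid SMILES string.
#' @param drug_id Optional identifier stored on the result.
#' @return An object of class `molecular_graph`: a list with `drug_id`,
#'   `n_atoms`, `atom_features` (n_atoms x 78 binary matrix), `edges`
#'   (two-column integer matrix of 1-based atom indices, each bond once with
#'   i < j), and `smiles_canonical`.
#' @examples
#' g <- parse_smiles("c1ccccc1")
#' g$n_atoms            # 6
#' colSums(g$atom_features)[78]  # all six atoms aromatic
#' @export
parse_smiles <- function(smiles, drug_id = NA_character_) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonicalize_smiles(smiles)
  mol <- parse_mol2(mol2_from_smiles(can, add_h = TRUE))
  heavy <- mol$atoms$element != "H"
  if (!any(heavy)) stop("empty molecule: '", smiles, "'", call. = FALSE)
  idx_map <- integer(nrow(mol$atoms))
  idx_map[which(heavy)] <- seq_len(sum(heavy))
  n <- sum(heavy)

  deg <- integer(n)
  hcount <- integer(n)
  aromatic <- logical(n)
  edges <- matrix(integer(0), ncol = 2L)
  for (k in seq_len(nrow(mol$bonds))) {
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    h1 <- heavy[a1]; h2 <- heavy[a2]
    if (h1 && h2) {
      i <- idx_map[a1]; j <- idx_map[a2]
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
      edges <- rbind(edges, c(min(i, j), max(i, j)))
      if (mol$bonds$type[k] == "ar") {
        aromatic[i] <- TRUE
        aromatic[j] <- TRUE
      }
    } else if (h1 && !h2) {
      hcount[idx_map[a1]] <- hcount[idx_map[a1]] + 1L
    } else if (!h1 && h2) {
      hcount[idx_map[a2]] <- hcount[idx_map[a2]] + 1L
    }
  }
  if (nrow(edges)) edges <- unique(edges)
  elements <- mol$atoms$element[heavy]

  feats <- t(vapply(seq_len(n), function(i) {
    ti <- match(elements[i], ATOM_SYMBOLS)
    if (is.na(ti)) ti <- 44L
    c(one_hot(ti, 44L), count_hot(deg[i]), count_hot(hcount[i]),
      count_hot(hcount[i]), as.numeric(aromatic[i]))
  }, numeric(ATOM_FEATURE_DIM)))

  structure(
    list(drug_id = drug_id, n_atoms = n, atom_features = feats,
         edges = edges, smiles_canonical = can),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", x$drug_id, ": ", x$n_atoms, " atoms, ",
      nrow(x$edges), " bonds, ", x$smiles_canonical, "\n", sep = "")
  invisible(x)
}

#' Featurize a drug table into molecular graphs
#'
#' @param drug_tbl Data frame with columns `drug_id` and `smiles`.
#' @return Named list of `molecular_graph` objects, one per drug.
#' @export
featurize_drugs <- function(drug_tbl) {
  stopifnot(all(c("drug_id", "smiles") %in% names(drug_tbl)))
  graphs <- purrr::map2(drug_tbl$smiles, drug_tbl$drug_id, parse_smiles)
  stats::setNames(graphs, drug_tbl$drug_id)
}

#' Compute folded ECFP6 fingerprints
#'
#' Circular (extended-connectivity) fingerprints of diameter 6 bonds, i.e.
#' radius 3 — the conventional reading of "ECFP6"; `fp_radius` overrides the
#' radius for a literal reading. OpenBabel's 4096-bit ECFP output is folded by
#' bitwise OR to `n_bits`. SMILES are canonicalized first so equivalent
#' writings of a molecule hash identically.
#'
#' @param drug_tbl Data frame with columns `drug_id` and `smiles`.
#' @param n_bits Fingerprint length (default 1024).
#' @param fp_radius Circular radius in bonds (default 3 = diameter 6).
#' @return Binary integer matrix `n_drugs x n_bits` with drug_id rownames.
#' @export
compute_ecfp6 <- function(drug_tbl, n_bits = 1024L, fp_radius = 3L) {
  stopifnot(all(c("drug_id", "smiles") %in% names(drug_tbl)))
  can <- canonicalize_smiles(drug_tbl$smiles)
  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, drug_tbl$drug_id))
  fp_name <- paste0("ECFP", 2L * fp_radius)
  raw <- ChemmineR::fingerprintOB(sdf, fp_name)@fpma
  if (ncol(raw) %% n_bits != 0L) {
    stop("fingerprint width ", ncol(raw), " is not a multiple of n_bits")
  }
  folds <- ncol(raw) / n_bits
  out <- matrix(0L, nrow(raw), n_bits)
  for (f in seq_len(folds)) {
    out <- pmax(out, raw[, ((f - 1L) * n_bits + 1L):(f * n_bits), drop = FALSE])
  }
  storage.mode(out) <- "integer"
  rownames(out) <- drug_tbl$drug_id
  if (any(rowSums(out) == 0L)) {
    stop("fingerprint with no bits set for: ",
         paste(drug_tbl$drug_id[rowSums(out) == 0L], collapse = ", "))
  }
  out
}
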