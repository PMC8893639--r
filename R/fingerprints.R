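# Circular (Morgan/ECFP-style) substructure fingerprints.
#
# Each atom's neighborhood up to a radius is condensed into a 32-bit unsigned
# feature identifier by iterative neighborhood hashing. The unfolded count
# variant keeps the raw identifiers with the number of atoms rooting each
# environment; the folded bit variant maps identifiers into a fixed-length
# binary vector (index = id mod n_bits). Identifier collisions are accepted;
# ids are stored as R doubles because they exceed .Machine$integer.max.

.HASH_MOD <- 4294967296 # 2^32

# Order-sensitive polynomial hash over non-negative integers, exact in
# double precision (2^32 * 65599 < 2^53).
#' @noRd
.hash_ints <- function(xs) {
  h <- 17
  for (x in xs) h <- (h * 65599 + x) %% .HASH_MOD
  h
}

#' Fingerprint encoding parameters
#'
#' @param radius Maximum environment radius in bonds (default 3).
#' @param chiral Include tetrahedral chirality tags in atom invariants.
#' @param n_bits Length of the folded bit vector (ignored for the count
#'   variant). Default 1024.
#' @param variant `"count_unfolded"` (classifier encoding; default chiral in
#'   the trained pipeline) or `"bit_folded"` (clustering encoding).
#' @return An object of class `"npek_fp_params"`.
#' @export
fingerprint_params <- function(radius = 3L, chiral = FALSE, n_bits = 1024L,
                               variant = c("count_unfolded", "bit_folded")) {
  variant <- match.arg(variant)
  stopifnot(radius >= 0, n_bits >= 1)
  structure(
    list(radius = as.integer(radius), chiral = isTRUE(chiral),
         n_bits = as.integer(n_bits), variant = variant),
    class = "npek_fp_params"
  )
}

#' @export
print.npek_fp_params <- function(x, ...) {
  cat("<fingerprint params> ", x$variant, ", radius ", x$radius,
      if (x$chiral) ", chiral" else ", non-chiral",
      if (x$variant == "bit_folded") paste0(", ", x$n_bits, " bits"), "\n",
      sep = "")
  invisible(x)
}

#' @noRd
.params_match <- function(a, b) {
  a$radius == b$radius && a$chiral == b$chiral && a$variant == b$variant &&
    (a$variant == "count_unfolded" || a$n_bits == b$n_bits)
}

# Per-atom environment identifiers for radii 0..radius.
# Returns an n_atoms x (radius+1) matrix of ids (doubles).
#' @noRd
morgan_ids <- function(g, radius, chiral) {
  n <- g$n_atoms
  adj <- graph_adjacency(g)
  at <- g$atoms
  heavy_degree <- vapply(adj, function(a) length(a$nbr), 0L)
  inv <- vapply(seq_len(n), function(a) {
    parts <- c(at$z[a], heavy_degree[a], at$hcount[a], at$charge[a] + 16L,
               as.integer(at$in_ring[a]), as.integer(at$aromatic[a]))
    # stereocenters only: achiral molecules encode identically under both
    # chirality settings
    if (chiral && at$chiral[a] > 0L) parts <- c(parts, at$chiral[a])
    .hash_ints(parts)
  }, 0)
  ids <- matrix(0, nrow = n, ncol = radius + 1L)
  ids[, 1L] <- inv
  r <- 1L
  while (r <= radius) {
    new_inv <- vapply(seq_len(n), function(a) {
      nb <- adj[[a]]
      if (length(nb$nbr) == 0L) return(.hash_ints(c(r, inv[a])))
      code <- ifelse(nb$order == 1.5, 4, nb$order)
      o <- order(code, inv[nb$nbr])
      .hash_ints(c(r, inv[a], as.numeric(rbind(code[o], inv[nb$nbr][o]))))
    }, 0)
    inv <- new_inv
    ids[, r + 1L] <- inv
    r <- r + 1L
  }
  ids
}

#' @noRd
.resolve_graph <- function(m) {
  if (inherits(m, "npek_molecule_set")) {
    stopifnot(nrow(m) == 1L)
    parse_smiles_graph(m$smiles[1])
  } else if (is.character(m) && length(m) == 1L) {
    parse_smiles_graph(parse_smiles(m)$smiles)
  } else {
    npek_stop("expected a one-row molecule set or a SMILES string",
              "npek_config_error")
  }
}

#' Encode a molecule as an unfolded count fingerprint
#'
#' One entry per distinct atom-environment identifier up to `p$radius`; the
#' count is the number of atoms rooting that environment. Repetitive motifs
#' (e.g. long alkyl chains) yield high counts while leaving the feature
#' *support* unchanged — the property that separates count from bit
#' fingerprints.
#'
#' @param m A one-row molecule set or a SMILES string.
#' @param p Fingerprint parameters with `variant = "count_unfolded"`.
#' @return An object of class `"npek_count_fp"`: a named count vector
#'   (`counts`, names are decimal feature ids in ascending order) plus the
#'   parameters and the molecule id.
#' @examples
#' encode_count("CC", fingerprint_params(radius = 0))$counts  # one feature, count 2
#' @export
encode_count <- function(m, p = fingerprint_params(chiral = TRUE)) {
  stopifnot(inherits(p, "npek_fp_params"))
  if (p$variant != "count_unfolded")
    npek_stop("encode_count requires variant = 'count_unfolded'", "npek_config_error")
  g <- .resolve_graph(m)
  ids <- as.vector(morgan_ids(g, p$radius, p$chiral))
  tab <- table(ids)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  ord <- order(as.numeric(names(counts)))
  counts <- counts[ord]
  structure(
    list(counts = counts, params = p,
         mol_id = if (inherits(m, "npek_molecule_set")) m$mol_id[1] else NULL),
    class = "npek_count_fp"
  )
}

#' Encode a molecule as a folded bit fingerprint
#'
#' Sets the bit `feature_id mod n_bits` for every distinct environment
#' identifier; folding can only merge features, so the popcount never exceeds
#' the count-fingerprint support size.
#'
#' @inheritParams encode_count
#' @param p Fingerprint parameters with `variant = "bit_folded"`.
#' @return An object of class `"npek_bit_fp"` with a 0/1 integer vector
#'   `bits` of length `p$n_bits`.
#' @export
encode_folded_bits <- function(m, p = fingerprint_params(variant = "bit_folded")) {
  stopifnot(inherits(p, "npek_fp_params"))
  if (p$variant != "bit_folded")
    npek_stop("encode_folded_bits requires variant = 'bit_folded'", "npek_config_error")
  g <- .resolve_graph(m)
  ids <- unique(as.vector(morgan_ids(g, p$radius, p$chiral)))
  bits <- integer(p$n_bits)
  bits[(ids %% p$n_bits) + 1L] <- 1L
  structure(
    list(bits = bits, params = p,
         mol_id = if (inherits(m, "npek_molecule_set")) m$mol_id[1] else NULL),
    class = "npek_bit_fp"
  )
}

#' Folded bit fingerprint matrix for a molecule set
#'
#' @param ms A molecule set.
#' @param p Bit-folded fingerprint parameters.
#' @return An `nrow(ms)` x `n_bits` 0/1 integer matrix, rownames = `mol_id`.
#' @export
folded_bit_matrix <- function(ms, p = fingerprint_params(variant = "bit_folded")) {
  stopifnot(inherits(ms, "npek_molecule_set"))
  mat <- matrix(0L, nrow = nrow(ms), ncol = p$n_bits,
                dimnames = list(ms$mol_id, NULL))
  for (i in seq_len(nrow(ms))) {
    g <- parse_smiles_graph(ms$smiles[i])
    ids <- unique(as.vector(morgan_ids(g, p$radius, p$chiral)))
    mat[i, (ids %% p$n_bits) + 1L] <- 1L
  }
  mat
}

#' Count fingerprints for every molecule of a set
#'
#' @inheritParams folded_bit_matrix
#' @param p Count-unfolded fingerprint parameters.
#' @return A list of [encode_count()] fingerprints, named by `mol_id`.
#' @export
encode_count_set <- function(ms, p = fingerprint_params(chiral = TRUE)) {
  stopifnot(inherits(ms, "npek_molecule_set"))
  fps <- lapply(seq_len(nrow(ms)), function(i)
    encode_count(ms[i, , drop = FALSE], p))
  names(fps) <- ms$mol_id
  fps
}

#' Build a per-cluster feature matrix from count fingerprints
#'
#' Columns are the union of feature ids occurring (count >= 1) in at least
#' `min_occurrence` molecules, in ascending feature-id order; rows follow the
#' input order. Assay labels travel with the matrix so downstream filters can
#' resolve label conflicts.
#'
#' @param mols A molecule set (or a list of count fingerprints, in which case
#'   labels are absent).
#' @param p Count-unfolded fingerprint parameters.
#' @param min_occurrence Minimum number of supporting molecules per retained
#'   feature (default 10, the pipeline's trimming rule).
#' @return An object of class `"npek_feature_matrix"`: integer matrix
#'   `counts` (mol x feature), `mol_ids`, numeric `feature_ids`, `params`,
#'   label data.frame `labels`, the raw fingerprints `fps`, and a `history`
#'   of applied filters.
#' @export
build_feature_matrix <- function(mols, p = fingerprint_params(chiral = TRUE),
                                 min_occurrence = 10L) {
  stopifnot(min_occurrence >= 1L)
  if (inherits(mols, "npek_molecule_set")) {
    if (nrow(mols) == 0L)
      npek_stop("empty molecule set", "npek_config_error")
    fps <- encode_count_set(mols, p)
    labels <- data.frame(label_b = mols$label_b, label_t = mols$label_t)
    mol_ids <- mols$mol_id
  } else if (is.list(mols) && all(vapply(mols, inherits, TRUE, "npek_count_fp"))) {
    fps <- mols
    labels <- NULL
    mol_ids <- names(fps) %||% as.character(seq_along(fps))
  } else {
    npek_stop("mols must be a molecule set or a list of count fingerprints",
              "npek_config_error")
  }
  all_ids <- sort(unique(as.numeric(unlist(lapply(fps, function(f) names(f$counts))))))
  support <- integer(length(all_ids))
  names(support) <- sprintf("%.0f", all_ids)
  for (f in fps) {
    nm <- names(f$counts)
    support[nm] <- support[nm] + 1L
  }
  keep <- support >= min_occurrence
  if (!any(keep))
    npek_stop(paste0("no feature occurs in at least ", min_occurrence,
                     " molecules"), "npek_empty_features_error")
  kept_ids <- all_ids[keep]
  kept_names <- sprintf("%.0f", kept_ids)
  counts <- matrix(0L, nrow = length(fps), ncol = length(kept_ids),
                   dimnames = list(mol_ids, kept_names))
  for (i in seq_along(fps)) {
    nm <- intersect(names(fps[[i]]$counts), kept_names)
    counts[i, nm] <- fps[[i]]$counts[nm]
  }
  structure(
    list(counts = counts, mol_ids = mol_ids, feature_ids = kept_ids,
         params = p, labels = labels, fps = fps,
         history = list(min_occurrence = as.integer(min_occurrence),
                        pcc_threshold = NULL)),
    class = "npek_feature_matrix"
  )
}

#' @export
print.npek_feature_matrix <- function(x, ...) {
  cat("<npek feature matrix> ", nrow(x$counts), " molecules x ",
      ncol(x$counts), " features (radius ", x$params$radius,
      if (x$params$chiral) ", chiral" else ", non-chiral", ")\n", sep = "")
  cat("filters: min_occurrence = ", x$history$min_occurrence,
      if (!is.null(x$history$pcc_threshold))
        paste0(", |PCC| <= ", x$history$pcc_threshold), "\n", sep = "")
  invisible(x)
}

#' @export
dim.npek_feature_matrix <- function(x) dim(x$counts)

#' @noRd
.subset_features <- function(fm, idx) {
  fm$counts <- fm$counts[, idx, drop = FALSE]
  fm$feature_ids <- fm$feature_ids[idx]
  fm
}

#' Re-apply the minimum-occurrence trim to a feature matrix
#'
#' @param fm A feature matrix.
#' @param min_occurrence Minimum supporting-molecule count.
#' @return The trimmed feature matrix.
#' @export
trim_features <- function(fm, min_occurrence = 10L) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  support <- colSums(fm$counts >= 1L)
  keep <- support >= min_occurrence
  if (!any(keep))
    npek_stop(paste0("no feature occurs in at least ", min_occurrence,
                     " molecules"), "npek_empty_features_error")
  out <- .subset_features(fm, which(keep))
  out$history$min_occurrence <- as.integer(min_occurrence)
  out
}

#' Greedily drop features correlated with an already-kept feature
#'
#' Scans features in `ranking` order (default ascending feature id) and drops
#' a feature iff its absolute Pearson correlation with any already-kept
#' feature strictly exceeds `pcc_threshold`. Zero-variance columns have
#' undefined correlation; they are treated as uncorrelated (kept) with a
#' message.
#'
#' @param fm A feature matrix.
#' @param pcc_threshold Threshold in (0, 1); default 0.8.
#' @param ranking Optional vector of feature ids giving the scan order.
#' @return The decorrelated feature matrix (kept features in scan order).
#' @export
prune_correlated <- function(fm, pcc_threshold = 0.8, ranking = NULL) {
  stopifnot(inherits(fm, "npek_feature_matrix"),
            pcc_threshold > 0, pcc_threshold < 1)
  p <- ncol(fm$counts)
  scan <- if (is.null(ranking)) {
    order(fm$feature_ids)
  } else {
    idx <- match(ranking, fm$feature_ids)
    if (anyNA(idx))
      npek_stop("ranking contains feature ids absent from the matrix",
                "npek_config_error")
    idx
  }
  cm <- suppressWarnings(stats::cor(fm$counts))
  const <- apply(fm$counts, 2, function(v) stats::var(v) == 0)
  if (any(const))
    message(sum(const), " zero-variance feature column(s): correlation ",
            "undefined, treated as 0 and kept")
  cm[is.na(cm)] <- 0
  kept <- integer()
  for (j in scan) {
    if (length(kept) == 0L || all(abs(cm[j, kept]) <= pcc_threshold)) {
      kept <- c(kept, j)
    }
  }
  out <- .subset_features(fm, kept)
  out$history$pcc_threshold <- pcc_threshold
  out$history$pruned_features <- fm$feature_ids[setdiff(seq_len(p), kept)]
  out
}

#' Drop molecules with identical count fingerprints
#'
#' Among rows with identical count vectors the first is kept. If duplicates
#' carry conflicting assay labels the survivor is positive (a message records
#' the conflict).
#'
#' @param fm A feature matrix.
#' @return The feature matrix with unique rows.
#' @export
remove_identical_fingerprints <- function(fm) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  key <- apply(fm$counts, 1, paste, collapse = ",")
  grp <- match(key, unique(key))
  keep <- !duplicated(grp)
  if (all(keep)) return(fm)
  if (!is.null(fm$labels)) {
    lb <- as.logical(tapply(fm$labels$label_b, grp, any))
    lt <- as.logical(tapply(fm$labels$label_t, grp, any))
    conflict_b <- as.logical(tapply(fm$labels$label_b, grp, function(v) any(v) && !all(v)))
    conflict_t <- as.logical(tapply(fm$labels$label_t, grp, function(v) any(v) && !all(v)))
    n_conf <- sum(conflict_b | conflict_t)
    if (n_conf > 0L)
      message(n_conf, " identical-fingerprint group(s) had conflicting ",
              "labels; survivors marked positive")
    fm$labels <- data.frame(label_b = lb, label_t = lt)[grp[keep], , drop = FALSE]
    rownames(fm$labels) <- NULL
  }
  fm$counts <- fm$counts[keep, , drop = FALSE]
  fm$mol_ids <- fm$mol_ids[keep]
  fm$fps <- fm$fps[keep]
  fm$history$removed_identical <- sum(!keep)
  fm
}

#' Resolve a fingerprint feature to its substructure in a molecule
#'
#' Locates the atom environment (root atom plus all bonds within the
#' feature's radius) whose identifier equals `feature_id` and serializes it.
#' When several atoms root the environment, the smallest radius and then the
#' lowest atom index win.
#'
#' @param m A one-row molecule set or SMILES string.
#' @param feature_id Feature identifier (as produced by [encode_count()]).
#' @param p Fingerprint parameters the feature was generated under.
#' @return A list with `central_atom` (1-based index), `radius`, `bond_set`
#'   (bond row indices), `atoms` (atom indices) and `fragment_smiles`.
#' @export
feature_substructure <- function(m, feature_id,
                                 p = fingerprint_params(chiral = TRUE)) {
  g <- .resolve_graph(m)
  ids <- morgan_ids(g, p$radius, p$chiral)
  hit <- which(ids == as.numeric(feature_id), arr.ind = TRUE)
  if (nrow(hit) == 0L)
    npek_stop(paste0("feature ", sprintf("%.0f", as.numeric(feature_id)),
                     " does not occur in this molecule"), "npek_lookup_error")
  hit <- hit[order(hit[, 2], hit[, 1]), , drop = FALSE]
  root <- unname(hit[1, 1])
  radius <- unname(hit[1, 2]) - 1L
  # BFS bond distances from the root
  adj <- graph_adjacency(g)
  dist <- rep(Inf, g$n_atoms)
  dist[root] <- 0
  frontier <- root
  while (length(frontier) > 0L) {
    nxt <- integer()
    for (a in frontier) {
      for (b in adj[[a]]$nbr) {
        if (dist[b] > dist[a] + 1) {
          dist[b] <- dist[a] + 1
          nxt <- c(nxt, b)
        }
      }
    }
    frontier <- unique(nxt)
  }
  bs <- g$bonds
  in_env <- which(pmin(dist[bs$a1], dist[bs$a2]) <= radius - 1 &
                    pmax(dist[bs$a1], dist[bs$a2]) <= radius)
  atoms <- if (length(in_env)) sort(unique(c(bs$a1[in_env], bs$a2[in_env], root))) else root
  list(
    central_atom = root,
    radius = radius,
    bond_set = in_env,
    atoms = atoms,
    fragment_smiles = fragment_smiles(g, in_env, root)
  )
}
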