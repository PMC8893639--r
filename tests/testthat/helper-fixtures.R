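# Shared fixtures and oracle helpers. All data is built in code.

# Hand-construct a count fingerprint without going through a molecule.
fake_count_fp <- function(counts, params = fingerprint_params(chiral = TRUE),
                          mol_id = NULL) {
  counts <- counts[order(as.numeric(names(counts)))]
  structure(list(counts = counts, params = params, mol_id = mol_id),
            class = "npek_count_fp")
}

# Hand-construct a feature matrix from a plain counts matrix.
fake_feature_matrix <- function(counts, feature_ids = NULL, labels = NULL,
                                params = fingerprint_params(chiral = TRUE),
                                fps = NULL) {
  if (is.null(feature_ids)) feature_ids <- seq_len(ncol(counts))
  colnames(counts) <- sprintf("%.0f", feature_ids)
  if (is.null(rownames(counts))) rownames(counts) <- paste0("m", seq_len(nrow(counts)))
  if (is.null(fps)) {
    fps <- lapply(seq_len(nrow(counts)), function(i) {
      v <- counts[i, ]
      v <- v[v >= 1]
      fake_count_fp(stats::setNames(as.integer(v), names(v)), params,
                    mol_id = rownames(counts)[i])
    })
    names(fps) <- rownames(counts)
  }
  structure(
    list(counts = counts, mol_ids = rownames(counts),
         feature_ids = as.numeric(feature_ids), params = params,
         labels = labels, fps = fps,
         history = list(min_occurrence = 1L, pcc_threshold = NULL)),
    class = "npek_feature_matrix"
  )
}

# Brute-force ROC-AUC over all positive-negative pairs (ties count 1/2).
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# Independent chi-squared p-values from the count-sum formula.
oracle_chi2_p <- function(counts, labels) {
  n <- length(labels)
  vapply(seq_len(ncol(counts)), function(j) {
    o <- c(sum(counts[labels, j]), sum(counts[!labels, j]))
    tot <- sum(o)
    if (tot == 0) return(1)
    e <- tot * c(sum(labels), sum(!labels)) / n
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  }, 0)
}

# Naive Tanimoto over the union of feature names.
oracle_tanimoto <- function(a, b) {
  ids <- union(names(a), names(b))
  if (length(ids) == 0) return(0)
  av <- ifelse(ids %in% names(a), a[ids], 0)
  bv <- ifelse(ids %in% names(b), b[ids], 0)
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

# Literal simulation of the greedy correlation-pruning rule.
oracle_greedy_prune <- function(counts, threshold, scan = seq_len(ncol(counts))) {
  kept <- integer()
  for (j in scan) {
    ok <- TRUE
    for (k in kept) {
      r <- suppressWarnings(stats::cor(counts[, j], counts[, k]))
      if (!is.na(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, j)
  }
  kept
}

# Exhaustive best 2-partition inertia (n <= 12).
oracle_best_two_partition <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    for (g in list(grp, !grp)) {
      if (!any(g) || all(g)) { best <- Inf; break }
    }
    inertia <- 0
    for (g in list(grp, !grp)) {
      mu <- colMeans(x[g, , drop = FALSE])
      inertia <- inertia + sum(sweep(x[g, , drop = FALSE], 2, mu)^2)
    }
    best <- min(best, inertia)
  }
  best
}

# Molecule families for the two-cluster end-to-end scenario: an aliphatic
# family carrying all epitopes and a halogenated-aromatic family with none.
two_family_sets <- function(n_alkane = 25, n_haloarene = 25, n_epitope = 10) {
  bg <- molecule_set(
    mol_id = c(sprintf("alk_%02d", seq_len(n_alkane)),
               sprintf("har_%02d", seq_len(n_haloarene))),
    smiles = c(vapply(seq_len(n_alkane) + 2L, function(i) strrep("C", i), ""),
               vapply(seq_len(n_haloarene), function(i)
                 paste0("Clc1ccc(", strrep("C", i), ")cc1Cl"), "")),
    source = "background"
  )
  epi <- molecule_set(
    mol_id = sprintf("acid_%02d", seq_len(n_epitope)),
    smiles = vapply(seq_len(n_epitope) + 11L, function(i)
      paste0("O=C(O)", strrep("C", i)), ""),
    source = "epitope", label_b = FALSE, label_t = TRUE
  )
  list(background = bg, epitopes = epi)
}
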