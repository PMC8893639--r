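# The fitted two-step pipeline: cluster assignment over folded bit
# fingerprints, then per-cluster / per-assay epitope probability from
# random forests over trimmed, decorrelated count fingerprints, plus
# enrichment statistics and nearest known epitopes for interpretation.

.NPEK_FORMAT_VERSION <- 1L

#' Fit the clustered epitope-prediction pipeline
#'
#' Merges a deduplicated background with positive sets, clusters the merged
#' collection by k-means over folded bit fingerprints (non-chiral, fixed
#' encoding, independent of the classifier encoding), and trains one
#' random-forest classifier per cluster and assay on unfolded count
#' fingerprints after removal of identical fingerprints, low-occurrence
#' trimming and correlation pruning. Per cluster and assay a chi-squared
#' enrichment table is computed and the epitope fingerprints are stored for
#' nearest-neighbor reporting. Clusters without positives for an assay get
#' no model for it (probabilities are reported as `NA`).
#'
#' @param background,epitopes Molecule sets (deduplicated internally).
#' @param k Number of structural clusters (default 8; judge with
#'   [inertia_curve()] — there is no automatic elbow selection).
#' @param seed Integer run seed; all component seeds derive from it.
#' @param cluster_params Folded-bit encoding for clustering (default
#'   1024 bits, radius 3, non-chiral).
#' @param params Count encoding for classification (default radius 3,
#'   chiral).
#' @param min_occurrence,pcc_threshold Feature-matrix filters (defaults 10
#'   and 0.8).
#' @param n_trees Random-forest size (default 100).
#' @param n_init k-means restarts (default 10).
#' @return An object of class `"npek"`.
#' @seealso [predict.npek()], [evaluate_holdout()], [save_pipeline()]
#' @export
npek_fit <- function(background, epitopes, k = 8L, seed = 1L,
                     cluster_params = fingerprint_params(variant = "bit_folded"),
                     params = fingerprint_params(chiral = TRUE),
                     min_occurrence = 10L, pcc_threshold = 0.8,
                     n_trees = 100L, n_init = 10L) {
  stopifnot(inherits(background, "npek_molecule_set"),
            inherits(epitopes, "npek_molecule_set"))
  merged <- merge_background_positives(deduplicate(background),
                                       deduplicate(epitopes))
  bits <- folded_bit_matrix(merged, cluster_params)
  km <- fit_kmeans(bits, k = k, seed = seed, n_init = n_init,
                   params = cluster_params)
  pca <- project_pca(bits)

  clusters <- vector("list", k)
  for (c_id in 0:(k - 1L)) {
    mols_c <- merged[km$cluster == c_id, , drop = FALSE]
    class(mols_c) <- class(merged)
    entry <- list(cluster_id = c_id, n_molecules = nrow(mols_c),
                  feature_ids = numeric(), note = NULL)
    fm <- tryCatch({
      fm <- build_feature_matrix(mols_c, params, min_occurrence = 1L)
      fm <- remove_identical_fingerprints(fm)
      fm <- trim_features(fm, min_occurrence)
      prune_correlated(fm, pcc_threshold)
    }, npek_error = function(e) e)
    if (inherits(fm, "npek_error")) {
      entry$note <- conditionMessage(fm)
      clusters[[c_id + 1L]] <- entry
      next
    }
    entry$fm <- fm
    entry$feature_ids <- fm$feature_ids
    for (assay in c("b", "t")) {
      lbl <- if (assay == "b") fm$labels$label_b else fm$labels$label_t
      model <- NULL
      stats_tab <- NULL
      if (any(lbl) && !all(lbl)) {
        set.seed(seed + c_id + if (assay == "b") 100L else 200L)
        x <- fm$counts
        storage.mode(x) <- "double"
        model <- randomForest::randomForest(
          x = x, y = factor(lbl, levels = c(FALSE, TRUE)), ntree = n_trees
        )
        stats_tab <- feature_statistics(fm, lbl)
      }
      entry[[paste0("model_", assay)]] <- model
      entry[[paste0("stats_", assay)]] <- stats_tab
    }
    is_epi <- fm$labels$label_b | fm$labels$label_t
    entry$epitopes <- list(
      mol_ids = fm$mol_ids[is_epi],
      counts = fm$counts[is_epi, , drop = FALSE],
      fps = fm$fps[is_epi]
    )
    clusters[[c_id + 1L]] <- entry
  }

  structure(
    list(cluster_model = km, clusters = clusters, params = params,
         cluster_params = cluster_params, k = as.integer(k),
         min_occurrence = as.integer(min_occurrence),
         pcc_threshold = pcc_threshold, n_trees = as.integer(n_trees),
         seed = as.integer(seed),
         training = list(mol_ids = merged$mol_id, smiles = merged$smiles,
                         cluster = km$cluster,
                         label_b = merged$label_b, label_t = merged$label_t),
         pca = pca,
         format_version = .NPEK_FORMAT_VERSION,
         package_version = as.character(utils::packageVersion("npek")),
         date = format(Sys.Date()),
         call = match.call()),
    class = "npek"
  )
}

#' @export
print.npek <- function(x, ...) {
  cat("Clustered non-peptidic epitope predictor (npek)\n")
  cat("  ", length(x$training$mol_ids), " training molecules in ", x$k,
      " clusters; seed ", x$seed, "\n", sep = "")
  cat("  classifier encoding: radius ", x$params$radius,
      if (x$params$chiral) ", chiral" else ", non-chiral",
      " count fingerprints; filters: min occurrence ", x$min_occurrence,
      ", |PCC| <= ", x$pcc_threshold, "\n", sep = "")
  invisible(x)
}

#' @export
summary.npek <- function(object, ...) {
  rows <- lapply(object$clusters, function(cl) {
    has_fm <- !is.null(cl$fm)
    data.frame(
      cluster = cl$cluster_id,
      n_molecules = cl$n_molecules,
      b_positives = if (has_fm) sum(cl$fm$labels$label_b) else 0L,
      t_positives = if (has_fm) sum(cl$fm$labels$label_t) else 0L,
      n_features = length(cl$feature_ids),
      b_model = !is.null(cl$model_b),
      t_model = !is.null(cl$model_t)
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.npek", "data.frame")
  out
}

#' @export
print.summary.npek <- function(x, ...) {
  cat("Per-cluster summary (counts after identical-fingerprint removal):\n")
  print.data.frame(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
#' @method plot npek
plot.npek <- function(x, ...) {
  coords <- x$pca$coordinates
  cl <- x$training$cluster
  plot(coords[, 1], coords[, 2], col = cl + 1L, pch = 16, cex = 0.6,
       xlab = sprintf("PC1 (%.1f%% variance)", 100 * x$pca$explained_variance[1]),
       ylab = sprintf("PC2 (%.1f%% variance)", 100 * x$pca$explained_variance[2]),
       main = "Structural clusters (PCA of folded fingerprints)", ...)
  legend("topright", legend = paste("cluster", sort(unique(cl))),
         col = sort(unique(cl)) + 1L, pch = 16, cex = 0.7)
  invisible(x)
}

#' Nearest stored epitopes of a query fingerprint
#'
#' Ranks stored epitopes by Euclidean distance over the cluster's retained
#' feature counts (ties: higher full-fingerprint Tanimoto, then lower
#' mol_id) and reports the overall count-Tanimoto similarity computed on the
#' full unfolded fingerprints — two deliberately different spaces.
#'
#' @param query_fp The query's count fingerprint ([encode_count()]).
#' @param store A cluster's epitope store (fields `mol_ids`, `counts`,
#'   `fps`), as held by a fitted `"npek"` object.
#' @param n Number of neighbors (the full store if fewer).
#' @return A data.frame `mol_id`, `distance`, `tanimoto`, sorted ascending
#'   by distance.
#' @export
nearest_epitopes <- function(query_fp, store, n = 5L) {
  stopifnot(n >= 1L)
  if (length(store$mol_ids) == 0L)
    npek_stop("epitope store is empty", "npek_param_error")
  qv <- numeric(ncol(store$counts))
  names(qv) <- colnames(store$counts)
  common <- intersect(names(query_fp$counts), names(qv))
  qv[common] <- query_fp$counts[common]
  d <- sqrt(rowSums(sweep(store$counts, 2, qv)^2))
  tani <- vapply(store$fps, function(f) count_tanimoto(query_fp, f), 0)
  ord <- order(d, -tani, store$mol_ids)
  take <- utils::head(ord, n)
  data.frame(mol_id = store$mol_ids[take], distance = unname(d[take]),
             tanimoto = unname(tani[take]))
}

#' Predict epitope activity for query molecules
#'
#' The two-step analysis: the query is canonicalized, routed to its
#' structural cluster via the folded non-chiral encoding, and scored by that
#' cluster's B- and T-assay random forests on its count fingerprint
#' restricted to the cluster's feature registry (query features unseen in
#' training are dropped and counted). Each report also lists the significant
#' enriched features the query contains and its `n_neighbors` nearest stored
#' epitopes.
#'
#' @param object A fitted `"npek"` model.
#' @param newdata Character vector of SMILES.
#' @param n_neighbors Neighbors to report (default 5).
#' @param alpha Corrected-p cutoff for "significant" features (default
#'   0.05).
#' @param ... Unused.
#' @return An object of class `"npek_prediction"`: a list of per-query
#'   reports with fields `smiles` (canonical), `cluster_id`, `prob_b`,
#'   `prob_t` (`NA` when the cluster has no model for the assay),
#'   `n_features_dropped`, `significant_features` (per assay), `neighbors`,
#'   `note`.
#' @export
predict.npek <- function(object, newdata, n_neighbors = 5L, alpha = 0.05, ...) {
  stopifnot(is.character(newdata), length(newdata) >= 1L)
  reports <- lapply(newdata, function(smi) {
    q <- parse_smiles(smi)
    bit <- encode_folded_bits(q, object$cluster_params)
    c_id <- assign_cluster(object$cluster_model, bit)
    cl <- object$clusters[[c_id + 1L]]
    fp <- encode_count(q, object$params)
    report <- list(smiles = q$smiles[1], cluster_id = c_id,
                   prob_b = NA_real_, prob_t = NA_real_,
                   n_features_dropped = NA_integer_,
                   significant_features = list(b = NULL, t = NULL),
                   neighbors = NULL, note = cl$note)
    if (is.null(cl$fm)) {
      report$note <- cl$note %||% "cluster has no usable feature matrix"
      return(report)
    }
    reg <- sprintf("%.0f", cl$feature_ids)
    x <- matrix(0, nrow = 1, ncol = length(reg), dimnames = list(NULL, reg))
    common <- intersect(names(fp$counts), reg)
    x[1, common] <- fp$counts[common]
    report$n_features_dropped <- length(setdiff(names(fp$counts), reg))
    for (assay in c("b", "t")) {
      model <- cl[[paste0("model_", assay)]]
      if (!is.null(model)) {
        report[[paste0("prob_", assay)]] <-
          unname(stats::predict(model, x, type = "prob")[, "TRUE"])
        st <- cl[[paste0("stats_", assay)]]
        sig <- st[st$corrected_p < alpha, , drop = FALSE]
        present <- sig$feature_id %in% as.numeric(common)
        report$significant_features[[assay]] <- sig[present, , drop = FALSE]
      }
    }
    if (is.null(cl$model_b) && is.null(cl$model_t))
      report$note <- report$note %||%
        "no epitopes in this structural class: no models for either assay"
    if (length(cl$epitopes$mol_ids) > 0L)
      report$neighbors <- nearest_epitopes(fp, cl$epitopes, n = n_neighbors)
    report
  })
  structure(reports, class = "npek_prediction",
            single = length(newdata) == 1L)
}

#' @export
print.npek_prediction <- function(x, ...) {
  for (r in x) {
    cat("query:", r$smiles, "-> cluster", r$cluster_id, "\n")
    cat("  P(B-cell epitope) =",
        if (is.na(r$prob_b)) "NA (no model)" else round(r$prob_b, 3),
        "| P(T-cell epitope) =",
        if (is.na(r$prob_t)) "NA (no model)" else round(r$prob_t, 3), "\n")
    if (!is.null(r$note)) cat("  note:", r$note, "\n")
    if (!is.null(r$neighbors)) {
      cat("  nearest stored epitopes:\n")
      print.data.frame(r$neighbors, row.names = FALSE)
    }
  }
  invisible(x)
}

#' @export
as.data.frame.npek_prediction <- function(x, ...) {
  do.call(rbind, lapply(x, function(r) data.frame(
    smiles = r$smiles, cluster_id = r$cluster_id,
    prob_b = r$prob_b, prob_t = r$prob_t,
    n_features_dropped = r$n_features_dropped
  )))
}

#' Evaluate a fitted pipeline on an independent holdout set
#'
#' Molecules overlapping the training set (by canonical SMILES) are excluded
#' with a warning. Each remaining molecule is routed to its cluster and
#' scored by that cluster's model; ROC-AUC is reported per cluster and assay
#' (`NA` where positives or a model are missing) plus a pooled row over the
#' concatenated per-cluster scores.
#'
#' @param object A fitted `"npek"` model.
#' @param holdout A molecule set disjoint from training.
#' @return A data.frame with columns `cluster`, `assay`, `n`, `n_positive`,
#'   `auc`; cluster `"all"` rows hold the pooled result.
#' @export
evaluate_holdout <- function(object, holdout) {
  stopifnot(inherits(object, "npek"), inherits(holdout, "npek_molecule_set"))
  holdout <- deduplicate(holdout)
  overlap <- holdout$smiles %in% object$training$smiles
  if (any(overlap)) {
    warning(sum(overlap), " holdout molecule(s) overlap the training set ",
            "and are excluded: ",
            paste(utils::head(holdout$smiles[overlap], 5), collapse = ", "),
            if (sum(overlap) > 5) ", ...")
    holdout <- holdout[!overlap, , drop = FALSE]
    class(holdout) <- c("npek_molecule_set", "data.frame")
  }
  bits <- folded_bit_matrix(holdout, object$cluster_params)
  c_ids <- apply(bits, 1, function(v) assign_cluster(object$cluster_model, v))
  rows <- list()
  pooled <- list(b = list(scores = numeric(), labels = logical()),
                 t = list(scores = numeric(), labels = logical()))
  for (c_id in sort(unique(c_ids))) {
    sel <- c_ids == c_id
    mols_c <- holdout[sel, , drop = FALSE]
    cl <- object$clusters[[c_id + 1L]]
    reg <- sprintf("%.0f", cl$feature_ids)
    x <- matrix(0, nrow = nrow(mols_c), ncol = length(reg),
                dimnames = list(NULL, reg))
    if (length(reg) > 0L) {
      for (i in seq_len(nrow(mols_c))) {
        fp <- encode_count(mols_c[i, , drop = FALSE], object$params)
        common <- intersect(names(fp$counts), reg)
        x[i, common] <- fp$counts[common]
      }
    }
    for (assay in c("b", "t")) {
      lbl <- if (assay == "b") mols_c$label_b else mols_c$label_t
      model <- cl[[paste0("model_", assay)]]
      auc <- NA_real_
      if (!is.null(model)) {
        sc <- unname(stats::predict(model, x, type = "prob")[, "TRUE"])
        pooled[[assay]]$scores <- c(pooled[[assay]]$scores, sc)
        pooled[[assay]]$labels <- c(pooled[[assay]]$labels, lbl)
        if (any(lbl) && !all(lbl)) auc <- roc_auc(sc, lbl)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = as.character(c_id), assay = assay,
        n = nrow(mols_c), n_positive = sum(lbl), auc = auc
      )
    }
  }
  for (assay in c("b", "t")) {
    pl <- pooled[[assay]]
    auc <- if (length(pl$scores) && any(pl$labels) && !all(pl$labels))
      roc_auc(pl$scores, pl$labels) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = "all", assay = assay, n = length(pl$scores),
      n_positive = sum(pl$labels), auc = auc
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Persist a fitted pipeline to a directory
#'
#' Writes `metadata.json` (format version, package version, date, seed,
#' encoding parameters) next to the serialized model. [load_pipeline()]
#' refuses directories with a different format version.
#'
#' @param object A fitted `"npek"` model.
#' @param directory Target directory (created if needed).
#' @return `directory`, invisibly.
#' @export
save_pipeline <- function(object, directory) {
  stopifnot(inherits(object, "npek"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    format_version = object$format_version,
    package_version = object$package_version,
    date = object$date, seed = object$seed, k = object$k,
    radius = object$params$radius, chiral = object$params$chiral
  )
  jsonlite::write_json(meta, file.path(directory, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(object, file.path(directory, "pipeline.rds"))
  invisible(directory)
}

#' Load a pipeline saved by [save_pipeline()]
#'
#' @param directory Directory written by [save_pipeline()].
#' @return The fitted `"npek"` model; predictions after a save/load round
#'   trip are bit-identical to before.
#' @export
load_pipeline <- function(directory) {
  meta_path <- file.path(directory, "metadata.json")
  rds_path <- file.path(directory, "pipeline.rds")
  if (!file.exists(meta_path) || !file.exists(rds_path))
    npek_stop(paste0("no saved pipeline found in ", directory),
              "npek_not_found_error")
  meta <- jsonlite::read_json(meta_path)
  if (is.null(meta$format_version) ||
      meta$format_version != .NPEK_FORMAT_VERSION)
    npek_stop(paste0("incompatible pipeline format version: ",
                     meta$format_version %||% "missing"),
              "npek_version_error")
  readRDS(rds_path)
}
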