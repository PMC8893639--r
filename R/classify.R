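# Per-cluster, per-assay epitope classifiers and their benchmarks: random
# forest / k-NN / neural network / shuffled-label null models plus the
# maximum count-Tanimoto similarity baseline, all evaluated by repeated
# stratified cross-validation with ROC-AUC.

#' Classifier specification
#'
#' Hyperparameters mirror the usual library defaults so they are portable:
#' `rf` = 100 trees, unlimited depth, sqrt(p) candidate features per split,
#' probability = fraction of trees voting positive; `knn` = 5 neighbors;
#' `nn` = one hidden layer of 100 units, at most 200 epochs; `dummy_rf` = the
#' `rf` model trained on labels shuffled once per CV repeat; `similarity` =
#' maximum count-Tanimoto score against the training-fold positives.
#'
#' @param kind One of `"rf"`, `"knn"`, `"nn"`, `"dummy_rf"`, `"similarity"`.
#' @param seed Integer seed for the model's own randomness.
#' @param n_trees,k,size,maxit Hyperparameters for the respective kinds.
#' @return An object of class `"npek_model_spec"`.
#' @export
model_spec <- function(kind = c("rf", "knn", "nn", "dummy_rf", "similarity"),
                       seed = 1L, n_trees = 100L, k = 5L, size = 100L,
                       maxit = 200L) {
  kind <- match.arg(kind)
  hyper <- switch(kind,
    rf = , dummy_rf = list(n_trees = as.integer(n_trees)),
    knn = list(k = as.integer(k)),
    nn = list(size = as.integer(size), maxit = as.integer(maxit)),
    similarity = list()
  )
  structure(list(kind = kind, hyperparams = hyper, seed = as.integer(seed)),
            class = "npek_model_spec")
}

#' Cross-validation configuration
#'
#' @param n_repeats Number of repetitions (default 3).
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Integer seed for the fold splitter (and label shuffler of the
#'   dummy model); repeat r uses `seed + r - 1`.
#' @return An object of class `"npek_cv_config"`. Folds are always
#'   stratified: per-fold positive counts differ by at most one.
#' @export
cv_config <- function(n_repeats = 3L, n_folds = 5L, seed = 1L) {
  structure(list(n_repeats = as.integer(n_repeats),
                 n_folds = as.integer(n_folds),
                 stratified = TRUE, seed = as.integer(seed)),
            class = "npek_cv_config")
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counting one half.
#'
#' @param scores Numeric scores, larger = more positive.
#' @param labels Logical labels (both classes must be present).
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L)
    npek_stop("ROC-AUC undefined: both classes must be present",
              "npek_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

#' Shuffle a label vector (null-model labels)
#'
#' A uniform random permutation: the positive count (the cluster's epitope
#' fraction) is preserved exactly.
#'
#' @param labels Logical vector.
#' @param seed Integer seed.
#' @return The permuted label vector.
#' @export
make_dummy_labels <- function(labels, seed) {
  set.seed(as.integer(seed))
  sample(as.logical(labels))
}

#' Tanimoto similarity of two count fingerprints
#'
#' `sum_i min(a_i, b_i) / sum_i max(a_i, b_i)` over the union of features;
#' defined as 0 when both fingerprints are empty.
#'
#' @param a,b Count fingerprints with identical encoding parameters.
#' @return Similarity in \[0, 1\]; 1 iff the fingerprints are identical.
#' @export
count_tanimoto <- function(a, b) {
  stopifnot(inherits(a, "npek_count_fp"), inherits(b, "npek_count_fp"))
  if (!.params_match(a$params, b$params))
    npek_stop("fingerprint parameters differ", "npek_param_error")
  ids <- union(names(a$counts), names(b$counts))
  if (length(ids) == 0L) return(0)
  av <- bv <- numeric(length(ids))
  names(av) <- names(bv) <- ids
  av[names(a$counts)] <- a$counts
  bv[names(b$counts)] <- b$counts
  sum(pmin(av, bv)) / sum(pmax(av, bv))
}

#' Maximum-similarity scores against a reference epitope set
#'
#' Scores each query with its highest count-Tanimoto similarity over the
#' reference positives — the similarity-baseline classifier score.
#'
#' @param queries,reference_positives Lists of count fingerprints.
#' @param exclude_self If `TRUE`, a query is never scored against a reference
#'   with the same `mol_id` (cross-validation mode).
#' @return Numeric vector of scores in \[0, 1\].
#' @export
similarity_scores <- function(queries, reference_positives, exclude_self = FALSE) {
  if (length(reference_positives) == 0L)
    npek_stop("reference epitope set is empty", "npek_param_error")
  ref_ids <- vapply(reference_positives,
                    function(f) f$mol_id %||% NA_character_, "")
  vapply(queries, function(q) {
    refs <- reference_positives
    if (exclude_self && !is.null(q$mol_id)) {
      refs <- refs[is.na(ref_ids) | ref_ids != q$mol_id]
      if (length(refs) == 0L) return(0)
    }
    max(vapply(refs, function(r) count_tanimoto(q, r), 0))
  }, 0)
}

#' Stratified fold assignment
#'
#' @param labels Logical labels.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer fold ids in `1..n_folds`; per-fold class counts differ by
#'   at most one.
#' @export
stratified_folds <- function(labels, n_folds, seed) {
  labels <- as.logical(labels)
  if (sum(labels) < n_folds || sum(!labels) < n_folds)
    npek_stop(paste0("cannot stratify ", n_folds, "-fold CV with ",
                     sum(labels), " positives and ", sum(!labels),
                     " negatives"), "npek_cv_error")
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  folds
}

# Fit one model kind on a training matrix; returns a closure scoring new rows
# by positive-class probability (or similarity score).
#' @noRd
.fit_scorer <- function(spec, x_train, y_train, fps_train = NULL) {
  kind <- spec$kind
  if (kind %in% c("rf", "dummy_rf")) {
    set.seed(spec$seed)
    fit <- randomForest::randomForest(
      x = x_train, y = factor(y_train, levels = c(FALSE, TRUE)),
      ntree = spec$hyperparams$n_trees
    )
    function(x_new, fps_new = NULL)
      unname(stats::predict(fit, x_new, type = "prob")[, "TRUE"])
  } else if (kind == "knn") {
    k_use <- min(spec$hyperparams$k, nrow(x_train))
    function(x_new, fps_new = NULL) {
      set.seed(spec$seed)
      pred <- class::knn(train = x_train, test = x_new,
                         cl = factor(y_train, levels = c(FALSE, TRUE)),
                         k = k_use, prob = TRUE)
      pwin <- attr(pred, "prob")
      ifelse(pred == "TRUE", pwin, 1 - pwin)
    }
  } else if (kind == "nn") {
    set.seed(spec$seed)
    nw <- (ncol(x_train) + 1L) * spec$hyperparams$size + spec$hyperparams$size + 1L
    fit <- nnet::nnet(
      x = x_train, y = as.numeric(y_train), size = spec$hyperparams$size,
      maxit = spec$hyperparams$maxit, entropy = TRUE, trace = FALSE,
      MaxNWts = nw + 10L
    )
    function(x_new, fps_new = NULL) as.numeric(stats::predict(fit, x_new))
  } else if (kind == "similarity") {
    refs <- fps_train[y_train]
    function(x_new, fps_new = NULL) {
      if (length(refs) == 0L)
        npek_stop("no positive references in the training fold",
                  "npek_cv_error")
      similarity_scores(fps_new, refs, exclude_self = FALSE)
    }
  } else {
    npek_stop(paste0("unknown model kind: ", kind), "npek_config_error")
  }
}

#' Repeated stratified cross-validation of one classifier
#'
#' Machine-learning kinds are fit on the training folds and score the
#' held-out fold by positive-class probability. The similarity kind scores
#' held-out molecules against the *training-fold* positives only, so a
#' molecule is never its own reference. The dummy kind shuffles the labels
#' once per repeat (before splitting) and is evaluated against the shuffled
#' labels. When `select_k` is given, chi-squared feature selection is re-fit
#' inside each training fold (leakage-safe); set `selection_refit = FALSE`
#' to rank once on the full data instead.
#'
#' @param spec A [model_spec()].
#' @param fm A feature matrix ([build_feature_matrix()]).
#' @param labels Logical labels aligned with `fm` rows.
#' @param cv A [cv_config()].
#' @param select_k Optional number of top chi-squared features per fold.
#' @param selection_refit Re-rank features inside each training fold
#'   (default) or once on all data.
#' @param context Free-text tag (cluster/assay) used in error messages.
#' @return An object of class `"npek_cv_result"`: `per_fold_auc`
#'   (`n_repeats` x `n_folds`), `mean_auc`, `sd_auc`, `spec`, `cv`,
#'   `n_features_used`.
#' @export
cross_validate <- function(spec, fm, labels, cv = cv_config(),
                           select_k = NULL, selection_refit = TRUE,
                           context = NULL) {
  stopifnot(inherits(spec, "npek_model_spec"),
            inherits(fm, "npek_feature_matrix"),
            inherits(cv, "npek_cv_config"))
  labels <- as.logical(labels)
  stopifnot(length(labels) == nrow(fm$counts))
  if (sum(labels) < cv$n_folds || sum(!labels) < cv$n_folds)
    npek_stop(paste0("infeasible CV", if (!is.null(context)) paste0(" for ", context),
                     ": ", sum(labels), " positives / ", sum(!labels),
                     " negatives for ", cv$n_folds, " folds"),
              "npek_cv_error")
  x_all <- fm$counts
  storage.mode(x_all) <- "double"
  if (!is.null(select_k) && select_k >= ncol(x_all)) select_k <- NULL
  global_rank <- NULL
  if (!is.null(select_k) && !selection_refit) {
    global_rank <- .chi2_rank(x_all, labels)
  }
  aucs <- matrix(NA_real_, nrow = cv$n_repeats, ncol = cv$n_folds)
  n_feat <- if (is.null(select_k)) ncol(x_all) else min(select_k, ncol(x_all))
  for (r in seq_len(cv$n_repeats)) {
    seed_r <- cv$seed + r - 1L
    y <- labels
    # shuffler and splitter get distinct derived seeds so their streams
    # cannot couple
    if (spec$kind == "dummy_rf") y <- make_dummy_labels(labels, seed_r + 77003L)
    folds <- stratified_folds(y, cv$n_folds, seed_r)
    for (f in seq_len(cv$n_folds)) {
      tr <- folds != f
      cols <- seq_len(ncol(x_all))
      if (!is.null(select_k)) {
        rk <- if (selection_refit) .chi2_rank(x_all[tr, , drop = FALSE], y[tr])
              else global_rank
        cols <- rk[seq_len(min(select_k, length(rk)))]
      }
      scorer <- .fit_scorer(spec, x_all[tr, cols, drop = FALSE], y[tr],
                            fps_train = fm$fps[tr])
      sc <- scorer(x_all[!tr, cols, drop = FALSE], fps_new = fm$fps[!tr])
      aucs[r, f] <- roc_auc(sc, y[!tr])
    }
  }
  structure(
    list(per_fold_auc = aucs, mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
         spec = spec, cv = cv, n_features_used = n_feat),
    class = "npek_cv_result"
  )
}

#' @export
print.npek_cv_result <- function(x, ...) {
  cat("<npek CV result> ", x$spec$kind, ": mean ROC-AUC = ",
      round(x$mean_auc, 3), " (sd ", round(x$sd_auc, 3), ") over ",
      length(x$per_fold_auc), " folds, ", x$n_features_used,
      " features\n", sep = "")
  invisible(x)
}

# Feature ranking by descending chi-squared statistic, ties toward lower
# feature id; returns column indices.
#' @noRd
.chi2_rank <- function(counts, labels) {
  st <- .chi2_stats(counts, labels)$stat
  order(-st, seq_len(ncol(counts)))
}

#' Keep the k features most associated with the labels
#'
#' Ranks features by the chi-squared statistic of their class-wise count sums
#' (ties break toward the lower feature id) and keeps the top `k`, in ranking
#' order.
#'
#' @param fm A feature matrix.
#' @param labels Logical labels aligned with rows.
#' @param k Number of features to keep (`1 <= k <= n_features`).
#' @return The reduced feature matrix.
#' @export
select_top_features <- function(fm, labels, k) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  if (k < 1 || k > ncol(fm$counts))
    npek_stop(paste0("k must be in 1..", ncol(fm$counts)), "npek_param_error")
  rk <- .chi2_rank(fm$counts, as.logical(labels))
  .subset_features(fm, rk[seq_len(k)])
}

#' Benchmark classifiers across feature-set sizes
#'
#' One [cross_validate()] run per (model, k) with per-fold chi-squared
#' feature selection. The similarity baseline uses full fingerprints and is
#' therefore k-independent; it is repeated per k for plotting parity.
#'
#' @param fm A feature matrix.
#' @param labels Logical labels.
#' @param cv A [cv_config()].
#' @param specs List of [model_spec()] objects.
#' @param k_grid Ascending feature-set sizes; default powers of two capped at
#'   the feature count, plus the full feature count.
#' @return A data.frame with columns `kind`, `k`, `mean_auc`, `sd_auc`.
#' @export
feature_set_sweep <- function(fm, labels, cv = cv_config(), specs, k_grid = NULL) {
  stopifnot(inherits(fm, "npek_feature_matrix"))
  p <- ncol(fm$counts)
  if (is.null(k_grid)) {
    k_grid <- 2^(0:floor(log2(p)))
    k_grid <- sort(unique(c(k_grid[k_grid <= p], p)))
  }
  stopifnot(!is.unsorted(k_grid))
  rows <- list()
  for (spec in specs) {
    for (k in k_grid) {
      res <- cross_validate(spec, fm, labels, cv,
                            select_k = if (spec$kind == "similarity") NULL else k)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = spec$kind, k = as.integer(k),
        mean_auc = res$mean_auc, sd_auc = res$sd_auc
      )
    }
  }
  do.call(rbind, rows)
}

#' Benchmark fingerprint radius and chirality settings
#'
#' Runs the full per-cluster pipeline (encode, trim, prune, random-forest
#' cross-validation) for every (radius, chirality) combination.
#'
#' @param ms A molecule set (one cluster's molecules).
#' @param assay `"b"` or `"t"` — which assay labels to predict.
#' @param radii Integer vector of radii.
#' @param chiral Logical vector of chirality settings.
#' @param cv A [cv_config()].
#' @param min_occurrence,pcc_threshold Feature-matrix filters.
#' @param n_trees Random-forest size.
#' @param remove_identical Collapse identical fingerprints before training
#'   (the pipeline default). Disable to keep label conflicts visible when
#'   probing encodings that cannot tell molecules apart.
#' @return A data.frame with columns `radius`, `chiral`, `mean_auc`,
#'   `sd_auc`, `n_features`.
#' @export
radius_chirality_benchmark <- function(ms, assay = c("t", "b"), radii = 0:3,
                                       chiral = c(FALSE, TRUE),
                                       cv = cv_config(),
                                       min_occurrence = 10L,
                                       pcc_threshold = 0.8,
                                       n_trees = 100L,
                                       remove_identical = TRUE) {
  assay <- match.arg(assay)
  stopifnot(length(radii) > 0L)
  labels_all <- if (assay == "b") ms$label_b else ms$label_t
  rows <- list()
  for (r in radii) {
    for (ch in chiral) {
      p <- fingerprint_params(radius = r, chiral = ch)
      fm <- build_feature_matrix(ms, p, min_occurrence = 1L)
      if (remove_identical) fm <- remove_identical_fingerprints(fm)
      fm <- trim_features(fm, min_occurrence)
      fm <- prune_correlated(fm, pcc_threshold)
      labels <- if (assay == "b") fm$labels$label_b else fm$labels$label_t
      res <- cross_validate(model_spec("rf", seed = cv$seed, n_trees = n_trees),
                            fm, labels, cv,
                            context = paste0("radius ", r, ", assay ", assay))
      rows[[length(rows) + 1L]] <- data.frame(
        radius = as.integer(r), chiral = ch,
        mean_auc = res$mean_auc, sd_auc = res$sd_auc,
        n_features = ncol(fm$counts)
      )
    }
  }
  do.call(rbind, rows)
}
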