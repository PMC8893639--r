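test_that("roc_auc matches hand-derived values", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  # 3 of 4 positive-negative pairs concordant
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)), 0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), class = "npek_metric_error")
})

test_that("roc_auc equals brute-force pairwise concordance on all small inputs", {
  set.seed(31)
  for (trial in 1:150) {
    n <- sample(2:8, 1)
    labels <- logical(n)
    labels[sample(n, sample(n - 1, 1))] <- TRUE
    if (!any(labels) || all(labels)) next
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("roc_auc agrees with pROC and obeys the reversal identity", {
  set.seed(77)
  scores <- rnorm(60)
  labels <- runif(60) < 0.4
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              direction = "<"))))
  expect_equal(roc_auc(scores, labels) + roc_auc(-scores, labels), 1)
})

test_that("dummy labels are an exact permutation", {
  labels <- rep(c(TRUE, FALSE), c(5, 45))
  out <- make_dummy_labels(labels, seed = 8)
  expect_equal(sum(out), 5L)
  expect_identical(out, make_dummy_labels(labels, seed = 8))
  # over many seeds each index is positive with frequency ~ 5/50
  freqs <- rowMeans(vapply(1:400, function(s)
    make_dummy_labels(labels, seed = s), logical(50)))
  expect_true(all(abs(freqs - 0.1) < 0.06))
})

test_that("count Tanimoto matches the naive sum-min/sum-max formula", {
  p <- fingerprint_params(chiral = TRUE)
  a <- fake_count_fp(c("1" = 2L, "2" = 1L), p)
  b <- fake_count_fp(c("1" = 1L, "2" = 1L), p)
  expect_equal(count_tanimoto(a, b), 2 / 3)
  expect_equal(count_tanimoto(a, a), 1)
  d <- fake_count_fp(c("9" = 3L), p)
  expect_equal(count_tanimoto(a, d), 0)
  mism <- fake_count_fp(c("1" = 1L), fingerprint_params(radius = 2, chiral = TRUE))
  expect_error(count_tanimoto(a, mism), class = "npek_param_error")
  # random fingerprints: symmetry, bounds, identity-at-1, oracle agreement
  set.seed(12)
  for (t in 1:25) {
    ca <- stats::setNames(sample(1:5, 4, TRUE), sample(100, 4))
    cb <- stats::setNames(sample(1:5, 4, TRUE), sample(100, 4))
    fa <- fake_count_fp(ca, p); fb <- fake_count_fp(cb, p)
    s <- count_tanimoto(fa, fb)
    expect_equal(s, count_tanimoto(fb, fa))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, oracle_tanimoto(fa$counts, fb$counts))
    expect_equal(s == 1, identical(fa$counts[order(names(fa$counts))],
                                   fb$counts[order(names(fb$counts))]))
  }
})

test_that("similarity scores take the maximum over references", {
  p <- fingerprint_params(chiral = TRUE)
  q <- fake_count_fp(c("1" = 1L, "2" = 1L), p, mol_id = "q")
  refs <- list(
    fake_count_fp(c("1" = 1L, "2" = 1L, "3" = 8L), p, "r1"),  # 2/10
    fake_count_fp(c("1" = 1L, "2" = 1L, "3" = 2L), p, "r2"),  # 2/4
    fake_count_fp(c("1" = 1L, "2" = 1L, "3" = 3L), p, "r3")   # 2/5
  )
  pair <- vapply(refs, function(r) count_tanimoto(q, r), 0)
  expect_equal(similarity_scores(list(q), refs), max(pair))
  none <- fake_count_fp(c("99" = 1L), p)
  expect_equal(similarity_scores(list(none), refs), 0)
  expect_error(similarity_scores(list(q), list()), class = "npek_param_error")
  # self-exclusion by mol_id
  refs2 <- c(refs, list(q))
  expect_equal(similarity_scores(list(q), refs2), 1)
  expect_equal(similarity_scores(list(q), refs2, exclude_self = TRUE), max(pair))
})

test_that("stratified folds balance positives to within one", {
  for (seed in 1:8) {
    labels <- runif(47) < 0.3
    if (sum(labels) < 5 || sum(!labels) < 5) next
    folds <- stratified_folds(labels, 5, seed)
    pos_counts <- table(folds[labels])
    neg_counts <- table(folds[!labels])
    expect_lte(diff(range(pos_counts)), 1)
    expect_lte(diff(range(neg_counts)), 1)
    expect_true(all(table(factor(folds, 1:5)) > 0))
  }
  expect_error(stratified_folds(c(TRUE, rep(FALSE, 20)), 5, 1),
               class = "npek_cv_error")
})

test_that("cross-validation recovers a perfectly separating feature", {
  set.seed(10)
  n <- 60
  labels <- rep(c(TRUE, FALSE), c(15, 45))
  x <- cbind(signal = labels * 8L + rpois(n, 1),
             noise1 = rpois(n, 3), noise2 = rpois(n, 3))
  fm <- fake_feature_matrix(x)
  res <- cross_validate(model_spec("rf", seed = 3), fm, labels,
                        cv_config(seed = 3))
  expect_gt(res$mean_auc, 0.95)
  expect_equal(dim(res$per_fold_auc), c(3L, 5L))
  expect_equal(res$mean_auc, mean(res$per_fold_auc))
  expect_equal(res$sd_auc, sd(res$per_fold_auc))
  expect_error(
    cross_validate(model_spec("rf"), fm, rep(FALSE, n), cv_config()),
    class = "npek_cv_error"
  )
  # k-NN and NN run through the same harness
  res_knn <- cross_validate(model_spec("knn", seed = 3), fm, labels,
                            cv_config(n_repeats = 1L, seed = 3))
  expect_gt(res_knn$mean_auc, 0.9)
  res_nn <- cross_validate(model_spec("nn", seed = 3, size = 5L), fm, labels,
                           cv_config(n_repeats = 1L, seed = 3))
  expect_gt(res_nn$mean_auc, 0.9)
})

test_that("similarity CV never scores a molecule against itself", {
  # each positive has a private feature; negatives overlap every positive at
  # Tanimoto 0.5. With self-exclusion every held-out positive scores 0 and
  # every negative 0.5, so per-fold AUC is exactly 0; a leak would score the
  # positive 1.0 and flip the AUC to 1.
  p <- fingerprint_params(chiral = TRUE)
  fps <- c(
    lapply(1:5, function(i)
      fake_count_fp(stats::setNames(1L, i), p, paste0("pos", i))),
    lapply(1:5, function(i)
      fake_count_fp(stats::setNames(2L, i), p, paste0("neg", i)))
  )
  names(fps) <- vapply(fps, `[[`, "", "mol_id")
  counts <- matrix(0L, 10, 5, dimnames = list(names(fps), sprintf("%d", 1:5)))
  for (i in 1:5) { counts[i, i] <- 1L; counts[i + 5, i] <- 2L }
  fm <- fake_feature_matrix(counts, feature_ids = 1:5, fps = fps)
  labels <- rep(c(TRUE, FALSE), each = 5)
  res <- cross_validate(model_spec("similarity"), fm, labels,
                        cv_config(n_repeats = 2L, n_folds = 5L, seed = 1))
  expect_true(all(res$per_fold_auc == 0))
})

test_that("chi-squared feature selection ranks the planted column first", {
  set.seed(20)
  n <- 40
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x <- cbind(a = rpois(n, 3), b = labels * 6L + rpois(n, 1), c = rpois(n, 3))
  fm <- fake_feature_matrix(x)
  top1 <- select_top_features(fm, labels, 1)
  expect_equal(top1$feature_ids, 2)
  expect_setequal(select_top_features(fm, labels, 3)$feature_ids, fm$feature_ids)
  expect_error(select_top_features(fm, labels, 0), class = "npek_param_error")
  expect_error(select_top_features(fm, labels, 4), class = "npek_param_error")
  # k = 2 against an exhaustive chi-squared computation
  stat <- attr(chi2_feature_test(fm, labels), "statistic")
  want <- fm$feature_ids[order(-stat, fm$feature_ids)][1:2]
  expect_equal(select_top_features(fm, labels, 2)$feature_ids, want)
})

test_that("feature-set sweep covers the grid and matches the single run", {
  set.seed(41)
  n <- 50
  labels <- rep(c(TRUE, FALSE), c(15, 35))
  x <- cbind(s = labels * 5L + rpois(n, 1), n1 = rpois(n, 2),
             n2 = rpois(n, 2), n3 = rpois(n, 2))
  fm <- fake_feature_matrix(x)
  cv <- cv_config(n_repeats = 1L, seed = 6)
  tab <- feature_set_sweep(fm, labels, cv,
                           specs = list(model_spec("rf", seed = 6),
                                        model_spec("similarity", seed = 6)),
                           k_grid = c(1, 4))
  expect_equal(nrow(tab), 4L)
  single <- cross_validate(model_spec("rf", seed = 6), fm, labels, cv)
  expect_equal(tab$mean_auc[tab$kind == "rf" & tab$k == 4], single$mean_auc)
  # similarity baseline is k-independent
  sim <- tab[tab$kind == "similarity", ]
  expect_equal(sim$mean_auc[1], sim$mean_auc[2])
})

test_that("radius benchmark exposes signals invisible at radius zero", {
  # positional-isomer classes with identical radius-0 atom multisets:
  # ethers C^a-O-CC (positive) vs C^(a+1)-O-C (negative)
  a_rng <- 4:13
  ms <- molecule_set(
    mol_id = c(sprintf("p%02d", a_rng), sprintf("n%02d", a_rng)),
    smiles = c(paste0(strrep("C", a_rng), "OCC"),
               paste0(strrep("C", a_rng + 1), "OC")),
    source = rep(c("epitope", "background"), each = length(a_rng)),
    label_t = rep(c(TRUE, FALSE), each = length(a_rng))
  )
  tab <- radius_chirality_benchmark(
    ms, assay = "t", radii = c(0, 3), chiral = FALSE,
    cv = cv_config(n_repeats = 1L, n_folds = 2L, seed = 2),
    min_occurrence = 5L, remove_identical = FALSE
  )
  expect_equal(nrow(tab), 2L)
  auc0 <- tab$mean_auc[tab$radius == 0]
  auc3 <- tab$mean_auc[tab$radius == 3]
  expect_lt(auc0, 0.7)
  expect_gt(auc3, 0.9)
  # chirality toggle is a no-op for achiral molecule sets
  tab2 <- radius_chirality_benchmark(
    ms, assay = "t", radii = 3, chiral = c(FALSE, TRUE),
    cv = cv_config(n_repeats = 1L, n_folds = 2L, seed = 2),
    min_occurrence = 5L
  )
  expect_equal(tab2$mean_auc[1], tab2$mean_auc[2])
  expect_equal(tab2$n_features[1], tab2$n_features[2])
})
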