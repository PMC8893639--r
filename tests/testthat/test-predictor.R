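# One modest pipeline fitted once for the whole file: two structural
# families in the background (alkanes + dichloroarenes) and long-chain fatty
# acid epitopes, so one cluster carries every epitope and the other none.
sets <- two_family_sets()
fit <- npek_fit(sets$background, sets$epitopes, k = 2L, seed = 19,
                min_occurrence = 5L)

test_that("the pipeline summary reflects the engineered cluster structure", {
  sm <- summary(fit)
  expect_equal(nrow(sm), 2L)
  expect_equal(sum(sm$t_positives), 10L)
  # all epitopes in one cluster; the other has no T model
  expect_setequal(sm$t_model, c(TRUE, FALSE))
  expect_true(all(sm$n_molecules > 0))
  expect_output(print(fit), "npek")
})

test_that("a training epitope is its own nearest neighbor at distance zero", {
  query <- sets$epitopes$smiles[4]
  rep <- predict(fit, query)[[1]]
  expect_equal(rep$neighbors$mol_id[1], sets$epitopes$mol_id[4])
  expect_equal(rep$neighbors$distance[1], 0)
  expect_equal(rep$neighbors$tanimoto[1], 1)
  expect_false(is.na(rep$prob_t))
  expect_true(is.na(rep$prob_b))   # no B positives anywhere
  expect_true(all(rep$neighbors$tanimoto >= 0 & rep$neighbors$tanimoto <= 1))
  expect_true(all(rep$neighbors$distance >= 0))
  expect_true(!is.unsorted(rep$neighbors$distance))
})

test_that("queries routed to the epitope-free cluster get absent probabilities", {
  rep <- predict(fit, "Clc1ccc(CCC)cc1Cl")[[1]]
  other <- predict(fit, sets$epitopes$smiles[1])[[1]]
  expect_false(rep$cluster_id == other$cluster_id)
  expect_true(is.na(rep$prob_t))
  expect_true(is.na(rep$prob_b))
  expect_match(rep$note, "no epitopes|no models")
})

test_that("prediction is a pure function of the canonical SMILES", {
  q <- "O=C(O)CCCCCCCCCCCCC"
  r1 <- predict(fit, q)[[1]]
  r2 <- predict(fit, q)[[1]]
  expect_identical(r1$prob_t, r2$prob_t)
  expect_identical(r1$neighbors, r2$neighbors)
  # two spellings of the same structure predict identically
  r3 <- predict(fit, "OC(=O)CCCCCCCCCCCCC")[[1]]
  expect_identical(r1$prob_t, r3$prob_t)
  expect_error(predict(fit, "C1CC"), class = "npek_parse_error")
})

test_that("nearest epitopes rank by distance with the documented ties", {
  p <- fit$params
  store <- list(
    mol_ids = c("e1", "e2", "e3"),
    counts = matrix(c(5, 0,  2, 0,  7, 0), ncol = 2, byrow = TRUE,
                    dimnames = list(NULL, c("1", "2"))),
    fps = list(fake_count_fp(c("1" = 5L), p, "e1"),
               fake_count_fp(c("1" = 2L), p, "e2"),
               fake_count_fp(c("1" = 7L), p, "e3"))
  )
  q <- fake_count_fp(c("1" = 0L), p, "q")
  nn <- nearest_epitopes(q, store, n = 3)
  expect_equal(nn$mol_id, c("e2", "e1", "e3"))   # distances 2, 5, 7
  nn1 <- nearest_epitopes(store$fps[[1]], store, n = 1)
  expect_equal(nn1$mol_id, "e1")
  expect_equal(nn1$distance, 0)
  # n beyond the store size returns the whole ranked store
  expect_equal(nrow(nearest_epitopes(q, store, n = 10)), 3L)
  expect_error(nearest_epitopes(q, list(mol_ids = character()), n = 1),
               class = "npek_param_error")
})

test_that("save/load round trip reproduces predictions bit-identically", {
  dir <- withr::local_tempdir()
  save_pipeline(fit, dir)
  fit2 <- load_pipeline(dir)
  q <- sets$epitopes$smiles[2]
  expect_identical(predict(fit, q)[[1]]$prob_t, predict(fit2, q)[[1]]$prob_t)
  expect_identical(predict(fit, q)[[1]]$neighbors,
                   predict(fit2, q)[[1]]$neighbors)
  # tampered version metadata is refused
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"))
  meta$format_version <- 999
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE)
  expect_error(load_pipeline(dir), class = "npek_version_error")
  expect_error(load_pipeline(withr::local_tempdir()),
               class = "npek_not_found_error")
})

test_that("holdout evaluation scores new molecules per cluster and pooled", {
  hold_bg <- molecule_set(
    mol_id = sprintf("halk_%02d", 1:8),
    smiles = vapply(28:35, function(i) strrep("C", i), ""),
    source = "background")
  hold_pos <- molecule_set(
    mol_id = sprintf("hacid_%02d", 1:6),
    smiles = vapply(22:27, function(i) paste0("O=C(O)", strrep("C", i)), ""),
    source = "epitope", label_t = TRUE)
  holdout <- merge_background_positives(deduplicate(hold_bg),
                                        deduplicate(hold_pos))
  tab <- evaluate_holdout(fit, holdout)
  all_t <- tab[tab$cluster == "all" & tab$assay == "t", ]
  expect_equal(all_t$n_positive, 6L)
  expect_gt(all_t$auc, 0.9)
  # pooled row equals the AUC over concatenated per-cluster scores
  probs <- vapply(holdout$smiles, function(s) predict(fit, s)[[1]]$prob_t, 0)
  scored <- !is.na(probs)
  expect_equal(all_t$auc, roc_auc(probs[scored], holdout$label_t[scored]))
  # overlap with training is excluded with a warning
  overlap <- rbind(holdout, sets$epitopes[1, ])
  class(overlap) <- class(holdout)
  expect_warning(tab2 <- evaluate_holdout(fit, overlap), "overlap")
  expect_equal(tab2[tab2$cluster == "all" & tab2$assay == "t", "n_positive"], 6L)
})

test_that("holdout clusters without positives report missing AUC", {
  hold <- molecule_set(
    mol_id = sprintf("hha_%02d", 1:5),
    smiles = vapply(26:30, function(i)
      paste0("Clc1ccc(", strrep("C", i), ")cc1Cl"), ""),
    source = "background")
  tab <- evaluate_holdout(fit, hold)
  expect_true(all(is.na(tab$auc)))
})
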