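test_that("single-environment molecules encode with symmetry-aware counts", {
  p0 <- fingerprint_params(radius = 0L)
  methane <- encode_count("C", p0)
  expect_length(methane$counts, 1L)
  expect_equal(unname(methane$counts), 1L)
  ethane <- encode_count("CC", p0)  # symmetric atoms share one environment
  expect_length(ethane$counts, 1L)
  expect_equal(unname(ethane$counts), 2L)
})

test_that("chirality flag changes features only for chiral molecules", {
  pc <- fingerprint_params(radius = 2L, chiral = TRUE)
  pn <- fingerprint_params(radius = 2L, chiral = FALSE)
  chiral_mol <- "C[C@H](N)O"
  expect_false(identical(names(encode_count(chiral_mol, pc)$counts),
                         names(encode_count(chiral_mol, pn)$counts)))
  # enantiomers differ under the chiral encoding, agree under the non-chiral
  other <- "C[C@@H](N)O"
  expect_false(identical(names(encode_count(chiral_mol, pc)$counts),
                         names(encode_count(other, pc)$counts)))
  expect_identical(names(encode_count(chiral_mol, pn)$counts),
                   names(encode_count(other, pn)$counts))
  for (achiral in c("CCO", "c1ccccc1", "CC(C)C")) {
    expect_identical(names(encode_count(achiral, pc)$counts),
                     names(encode_count(achiral, pn)$counts))
  }
})

test_that("distinct-feature count is non-decreasing in radius", {
  mols <- c("CCCCCCCC", "c1ccccc1O", "OC1OC(CCCC)C(O)C(O)C1O",
            "OP(=O)(OCC)O", "CC(=O)NCC")
  for (smi in mols) for (ch in c(FALSE, TRUE)) {
    sizes <- vapply(0:4, function(r)
      length(encode_count(smi, fingerprint_params(radius = r, chiral = ch))$counts), 0L)
    expect_true(all(diff(sizes) >= 0), info = smi)
  }
})

test_that("encoding is deterministic across calls", {
  p <- fingerprint_params(radius = 3L, chiral = TRUE)
  a <- encode_count("OC1OC(CCCCCCCC)C(O)C(O)C1O", p)
  b <- encode_count("OC1OC(CCCCCCCC)C(O)C(O)C1O", p)
  expect_identical(a$counts, b$counts)
})

test_that("folding merges but never invents features", {
  pb <- fingerprint_params(variant = "bit_folded")
  pcnt <- fingerprint_params(chiral = FALSE)
  for (smi in c("C", "CCCCCCCCCC", "c1ccccc1O", "OC1OC(C)C(O)C(O)C1O")) {
    bits <- encode_folded_bits(smi, pb)
    expect_length(bits$bits, 1024L)
    expect_true(all(bits$bits %in% 0:1))
    support <- length(encode_count(smi, pcnt)$counts)
    expect_lte(sum(bits$bits), support)
  }
  m <- encode_folded_bits("C", fingerprint_params(radius = 0, variant = "bit_folded"))
  expect_equal(sum(m$bits), 1L)
  # folding is exactly (id mod n_bits) of the count support
  smi <- "CC(=O)OCC"
  ids <- as.numeric(names(encode_count(smi, pcnt)$counts))
  bits <- encode_folded_bits(smi, pb)
  expect_setequal(which(bits$bits == 1L) - 1L, unique(ids %% 1024))
})

test_that("feature matrix trimming respects the occurrence boundary", {
  p <- fingerprint_params(chiral = TRUE)
  # feature 101 in 10 molecules, feature 202 in 9, feature 303 in all 12
  fps <- lapply(1:12, function(i) {
    counts <- c("303" = 1L)
    if (i <= 10) counts <- c(counts, "101" = 2L)
    if (i <= 9) counts <- c(counts, "202" = 1L)
    fake_count_fp(counts, p, mol_id = paste0("m", i))
  })
  fm <- build_feature_matrix(fps, p, min_occurrence = 10L)
  expect_setequal(fm$feature_ids, c(101, 303))   # 202 dropped at the boundary
  fm_all <- build_feature_matrix(fps, p, min_occurrence = 1L)
  expect_setequal(fm_all$feature_ids, c(101, 202, 303))
  expect_equal(fm_all$feature_ids, sort(fm_all$feature_ids))
  expect_error(build_feature_matrix(fps, p, min_occurrence = 13L),
               class = "npek_empty_features_error")
})

test_that("greedy correlation pruning follows the stated rule", {
  # duplicated column: exactly one copy survives
  x <- cbind(a = c(1, 2, 3, 4, 5, 6), b = c(1, 2, 3, 4, 5, 6),
             c = c(6, 1, 4, 2, 5, 3))
  fm <- fake_feature_matrix(x)
  pruned <- prune_correlated(fm, 0.8)
  expect_equal(ncol(pruned$counts), 2L)
  expect_equal(pruned$feature_ids[1], 1)

  # orthogonal columns all survive
  set.seed(4)
  xo <- matrix(rnorm(60), ncol = 3) %*% diag(3)
  xo <- qr.Q(qr(xo)) * 5
  pr <- prune_correlated(fake_feature_matrix(round(xo + 10, 3)), 0.8)
  expect_equal(ncol(pr$counts), 3L)

  # chain a-b high, b-c high, a-c low: greedy keeps {a, c}, drops b
  set.seed(11)
  S <- rbind(c(1, 0.9, 0.66), c(0.9, 1, 0.9), c(0.66, 0.9, 1))
  X <- matrix(rnorm(1200), ncol = 3) %*% chol(S)
  stopifnot(abs(cor(X[, 1], X[, 2])) > 0.8, abs(cor(X[, 2], X[, 3])) > 0.8,
            abs(cor(X[, 1], X[, 3])) < 0.8)
  pruned <- prune_correlated(fake_feature_matrix(X), 0.8)
  expect_equal(pruned$feature_ids, c(1, 3))
})

test_that("greedy pruning matches an exhaustive simulation on small matrices", {
  set.seed(99)
  for (trial in 1:20) {
    p <- sample(2:5, 1)
    n <- 30
    base <- matrix(rpois(n * p, 4), ncol = p)
    # inject correlation pairs at random
    if (p >= 2 && runif(1) < 0.7) {
      j <- sample(p, 2)
      base[, j[2]] <- base[, j[1]] + rpois(n, 1)
    }
    fm <- fake_feature_matrix(base)
    thr <- runif(1, 0.5, 0.95)
    scan <- sample(p)
    got <- prune_correlated(fm, thr, ranking = scan)
    want <- oracle_greedy_prune(base, thr, scan)
    expect_equal(sort(got$feature_ids), sort(want), info = paste("trial", trial))
  }
})

test_that("zero-variance columns are kept with a message", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(2, 2, 2, 2))
  expect_message(pr <- prune_correlated(fake_feature_matrix(x), 0.8),
                 "zero-variance")
  expect_equal(ncol(pr$counts), 2L)
})

test_that("pruned matrices satisfy the decorrelation invariant", {
  set.seed(5)
  x <- matrix(rpois(40 * 12, 3), ncol = 12)
  x[, 5] <- x[, 1] * 2 + rpois(40, 1)
  pr <- prune_correlated(fake_feature_matrix(x), 0.8)
  cm <- abs(suppressWarnings(cor(pr$counts)))
  diag(cm) <- 0
  expect_true(all(cm[!is.na(cm)] <= 0.8 + 1e-12))
})

test_that("identical fingerprints collapse with positive-wins labels", {
  x <- rbind(c(1, 2), c(1, 2), c(3, 1))
  fm <- fake_feature_matrix(x, labels = data.frame(
    label_b = c(FALSE, TRUE, FALSE), label_t = c(FALSE, FALSE, FALSE)))
  expect_message(rr <- remove_identical_fingerprints(fm), "conflicting")
  expect_equal(nrow(rr$counts), 2L)
  expect_equal(rr$mol_ids, c("m1", "m3"))
  expect_true(rr$labels$label_b[1])   # survivor positive

  distinct <- fake_feature_matrix(rbind(c(1, 0), c(0, 1)))
  expect_identical(remove_identical_fingerprints(distinct)$counts,
                   distinct$counts)
})

test_that("feature substructures resolve to the rooted environment", {
  p1 <- fingerprint_params(radius = 1L)
  hexane <- "CCCCCC"
  fp <- encode_count(hexane, p1)
  # the radius-1 environment of an interior CH2 is a three-carbon chain
  mid_id <- names(fp$counts)[fp$counts == max(fp$counts)]
  fs <- feature_substructure(hexane, as.numeric(mid_id[length(mid_id)]), p1)
  expect_lte(fs$radius, 1L)
  g <- npek:::parse_smiles_graph(parse_smiles(hexane)$smiles)
  # oracle: atoms within `radius` bonds of the root by brute-force BFS
  bfs <- function(g, root, r) {
    d <- rep(Inf, g$n_atoms); d[root] <- 0
    for (step in seq_len(r)) {
      for (k in seq_len(nrow(g$bonds))) {
        a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
        if (d[a] + 1 < d[b]) d[b] <- d[a] + 1
        if (d[b] + 1 < d[a]) d[a] <- d[b] + 1
      }
    }
    which(d <= r)
  }
  expect_setequal(fs$atoms, bfs(g, fs$central_atom, fs$radius))
  # radius-0 features are single atoms
  p0 <- fingerprint_params(radius = 0L)
  f0 <- encode_count("CCO", p0)
  s0 <- feature_substructure("CCO", as.numeric(names(f0$counts)[1]), p0)
  expect_equal(s0$radius, 0L)
  expect_length(s0$atoms, 1L)
  expect_error(feature_substructure("CCO", 123456, p0),
               class = "npek_lookup_error")
})

test_that("environment atom sets match brute-force BFS across features", {
  p <- fingerprint_params(radius = 2L)
  smi <- "OC1OC(CC)C(O)C(O)C1O"
  fp <- encode_count(smi, p)
  g <- npek:::parse_smiles_graph(parse_smiles(smi)$smiles)
  dmat <- matrix(Inf, g$n_atoms, g$n_atoms)
  diag(dmat) <- 0
  for (step in seq_len(g$n_atoms)) {
    for (k in seq_len(nrow(g$bonds))) {
      a <- g$bonds$a1[k]; b <- g$bonds$a2[k]
      dmat[, a] <- pmin(dmat[, a], dmat[, b] + 1)
      dmat[, b] <- pmin(dmat[, b], dmat[, a] + 1)
    }
  }
  for (id in names(fp$counts)[seq(1, length(fp$counts), by = 4)]) {
    fs <- feature_substructure(smi, as.numeric(id), p)
    expect_setequal(fs$atoms, which(dmat[, fs$central_atom] <= fs$radius))
  }
})
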