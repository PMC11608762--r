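test_that("GLCM features behave on degenerate and random images", {
  const <- matrix(120L, 32, 32)
  f <- glcm_features(const)
  expect_equal(unname(f["glcm_energy"]), 1)
  expect_equal(unname(f["glcm_contrast"]), 0)
  # against the naive per-pixel oracle, one offset at a time
  img <- withr::with_seed(2, matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
  for (d in list(c(0, 1), c(2, 0))) {
    ours <- glcm_features(img, offsets = list(d))
    orc <- oracle_glcm(img, d[1], d[2])
    expect_equal(unname(ours), unname(orc), tolerance = 1e-12)
  }
})

test_that("morphology and skeleton features match simple geometry", {
  mask <- matrix(FALSE, 40, 40)
  mask[10:19, 5:16] <- TRUE              # one 10x12 rectangle
  m <- morphology_features(mask)
  expect_equal(unname(m["morph_area_mean"]), 120)
  expect_equal(unname(m["morph_perimeter_mean"]), 2 * (10 + 12) - 4)
  expect_equal(unname(m["morph_area_sd"]), 0)
  expect_gt(unname(m["morph_solidity_mean"]), 0.9)
  # a straight line: one branch, no junctions
  line <- matrix(FALSE, 30, 30)
  line[5:25, 14] <- TRUE
  s <- skeleton_features(line)
  expect_equal(unname(s["skel_n_branches"]), 1)
  expect_equal(unname(s["skel_n_junctions"]), 0)
  expect_equal(unname(s["skel_total_len"]), 21)
})

test_that("PCA embedding is anchored to the training set", {
  tr <- as.data.frame(withr::with_seed(5, matrix(rnorm(60), 20, 3)))
  emb <- pca_embed(tr, tr, n_components = 2)
  expect_identical(emb$train_emb, emb$gen_emb)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  # against a direct eigen-decomposition on a tiny table
  tr3 <- data.frame(a = c(1, 2, 4), b = c(2, 1, 7))
  emb3 <- pca_embed(tr3, tr3, n_components = 2)
  z <- scale(as.matrix(tr3))
  ev <- eigen(cov(z))
  oracle_scores <- z %*% ev$vectors
  # principal axes are defined up to sign
  for (j in 1:2) {
    expect_equal(abs(emb3$train_emb[, j]), abs(oracle_scores[, j]),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("cosine similarity samples have the defining properties", {
  # identical vectors: similarity exactly 1
  same <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  s <- cosine_similarity_samples(same, same, n_pairs = 50, seed = 1)
  expect_equal(s$sims_tt, rep(1, 50))
  expect_equal(s$sims_tg, rep(1, 50))
  # orthogonal train/gen vectors: similarity exactly 0
  tr <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE) * c(1, 2)
  tr <- rbind(c(1, 0), c(2, 0))
  ge <- rbind(c(0, 1), c(0, 3))
  s2 <- cosine_similarity_samples(tr, ge, n_pairs = 40, seed = 2)
  expect_equal(s2$sims_tg, rep(0, 40))
  expect_true(all(abs(s2$sims_tt) <= 1))
  expect_error(cosine_similarity_samples(tr[1, , drop = FALSE], ge, 10, 1),
               "two training rows")
  # reproducible given the seed
  big <- withr::with_seed(3, matrix(rnorm(200), 20, 10))
  a <- cosine_similarity_samples(big, big, 100, seed = 7)
  b <- cosine_similarity_samples(big, big, 100, seed = 7)
  expect_identical(a, b)
})

test_that("KS statistic equals the ECDF enumeration oracle", {
  expect_equal(ks_statistic(1:5, 1:5), 0)
  expect_equal(ks_statistic(1:5, 11:15), 1)
  expect_equal(ks_statistic(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  withr::with_seed(11, for (i in 1:20) {
    a <- rnorm(sample(5:30, 1))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    expect_equal(ks_statistic(a, b), oracle_ks(a, b))
    expect_equal(ks_statistic(a, b), ks_statistic(b, a))
    expect_equal(ks_statistic(a, b),
                 unname(suppressWarnings(ks.test(a, b)$statistic)))
  })
})

test_that("coverage and density match brute-force ball enumeration", {
  real <- withr::with_seed(4, matrix(rnorm(10), 5, 2))
  gen <- withr::with_seed(5, matrix(rnorm(6), 3, 2))
  ours <- coverage_density(real, gen, k = 2)
  orc <- oracle_coverage_density(real, gen, k = 2)
  expect_equal(ours$coverage, orc$coverage)
  expect_equal(ours$density, orc$density)
  # duplicated set: full coverage
  expect_equal(coverage_density(real, real, k = 2)$coverage, 1)
  # distant generated set: nothing covered
  far <- coverage_density(real, gen + 100, k = 2)
  expect_equal(far$coverage, 0)
  expect_equal(far$density, 0)
  expect_error(coverage_density(real[1:2, ], gen, k = 2), "more than k")
})

test_that("class prevalence sums to 100 with faithful rounding", {
  labels <- rep(c("a", "b", "c", "d"), times = c(10, 40, 40, 10))
  p <- class_prevalence_summary(labels)
  expect_equal(unname(p), c(10, 40, 40, 10))
  expect_equal(unname(class_prevalence_summary(rep("x", 7))), 100)
  expect_error(class_prevalence_summary(character(0)), "empty")
  # binomial concentration for uniform labels
  big <- withr::with_seed(6, sample(1:4, 10000, replace = TRUE))
  expect_true(all(abs(class_prevalence_summary(big) - 25) < 2))
  # largest-remainder integers preserve the total
  expect_equal(sum(round_percent(c(33.4, 33.3, 33.3))), 100)
})

test_that("feature extraction flags uncomputable families", {
  ph <- generate_phantom("dense", seed = 77, size = 256)
  no_lig <- ph$masks
  no_lig$ligament <- matrix(FALSE, 256, 256)
  feats <- extract_feature_families(list(ph$image, ph$image),
                                    list(ph$masks, no_lig))
  flagged <- attr(feats, "flagged")
  expect_false(flagged[1, "skeleton"])
  expect_true(flagged[2, "skeleton"])
  expect_false(anyNA(feats[1, ]))
  fam <- attr(feats, "families")
  expect_setequal(unique(fam),
                  c("texture", "morphology", "skeleton", "fg_ratio"))
})
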