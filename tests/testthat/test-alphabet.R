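test_that("glyph set is deterministic, distinct, and unambiguous", {
  g <- build_glyph_set()
  expect_length(g, 8)
  expect_setequal(names(g), c("H", "K", "L", "V", "W", "X", "Y", "Z"))
  for (b in g) {
    expect_equal(dim(b), c(32, 32))
    expect_true(all(b %in% c(0L, 255L)))
  }
  # identity score is exactly 1; all 28 distinct pairs stay below 0.8
  expect_equal(ncc_score(g$H, g$H), 1.0)
  pairs <- utils::combn(8, 2)
  ccs <- apply(pairs, 2, function(p) ncc_score(g[[p[1]]], g[[p[2]]]))
  expect_length(ccs, 28)
  expect_lt(max(ccs), 0.8)
  expect_identical(g, build_glyph_set())
})

test_that("sampled layouts satisfy the multiset and pair constraints", {
  seeds <- 1:300
  layouts <- lapply(seeds, sample_letter_layout)
  ok <- vapply(layouts, oracle_validate_layout, logical(1))
  expect_true(all(ok))
  # distinct seeds give distinct layouts
  keys <- vapply(layouts, function(l) paste(l, collapse = ""), character(1))
  expect_gt(length(unique(keys)), 299 * 0.99)
})

test_that("rendering stamps glyphs tile-exactly", {
  glyphs <- build_glyph_set()
  all_h <- matrix("H", 8, 8)
  img <- render_realization(all_h, glyphs)
  for (r in c(1, 5, 8)) for (c in c(1, 3, 8)) {
    expect_equal(img[(r - 1) * 32 + 1:32, (c - 1) * 32 + 1:32], glyphs$H)
  }
  # pixel sum equals sum over letters of count x glyph pixel sum
  lay <- sample_letter_layout(17)
  img <- render_realization(lay, glyphs)
  counts <- table(c(lay))
  expected_sum <- sum(vapply(names(counts), function(l) {
    counts[[l]] * sum(glyphs[[l]])
  }, numeric(1)))
  expect_equal(sum(img), expected_sum)
})

test_that("template matching inverts rendering and localizes degradation", {
  glyphs <- build_glyph_set()
  for (s in c(3, 14, 159)) {
    lay <- sample_letter_layout(s)
    rec <- recover_layout(render_realization(lay, glyphs), glyphs)
    expect_identical(rec$layout, matrix(as.character(lay), 8, 8))
    expect_true(rec$recognizable)
    expect_equal(min(rec$scores), 1.0)
  }
  # one tile of uniform noise: not recognizable, exactly one tile below 0.9
  lay <- sample_letter_layout(5)
  img <- render_realization(lay, glyphs)
  img[33:64, 65:96] <- withr::with_seed(1, matrix(sample(0:255, 1024,
                                                         replace = TRUE), 32))
  rec <- recover_layout(img, glyphs, threshold = 0.9)
  expect_false(rec$recognizable)
  expect_equal(sum(rec$scores < 0.9), 1)
  expect_lt(rec$scores[2, 3], 0.9)
  expect_error(recover_layout(img[1:128, ]), "must be")
})

test_that("letter prevalence goodness of fit matches the hand formula", {
  b <- alphabet_multiset()
  g0 <- letter_prevalence_gof(b)
  expect_equal(g0$chi2, 0)
  expect_true(g0$pass)
  expect_true(g0$exact)
  # one H replaced by one L: chi2 = 1/24 + 1/16
  b1 <- b; b1["H"] <- 23L; b1["L"] <- 17L
  g1 <- letter_prevalence_gof(b1)
  expect_equal(g1$chi2, 1 / 24 + 1 / 16, tolerance = 1e-12)
  expect_true(g1$pass)
  expect_false(g1$exact)
  expect_equal(g1$critical, qchisq(0.95, df = 7))
  expect_error(letter_prevalence_gof(c(H = 10)), "sum to 64")
})

test_that("pair prevalence counts adjacencies and flags orphans", {
  lay <- sample_letter_layout(23)
  pp <- pair_prevalence(lay)
  expect_equal(unname(pp$counts), c(8L, 2L, 1L, 1L))
  expect_equal(pp$n_orphans, 0)
  expect_true(pp$ok)
  # reverse one X-Y: count drops to 7 and both letters orphaned
  xs <- which(matrix(lay == "X", 8, 8), arr.ind = TRUE)[1, ]
  swapped <- matrix(as.character(lay), 8, 8)
  swapped[xs[1], xs[2]] <- "Y"; swapped[xs[1], xs[2] + 1] <- "X"
  pp2 <- pair_prevalence(swapped)
  expect_equal(unname(pp2$counts["XY"]), 7L)
  expect_equal(pp2$n_orphans, 2)
  expect_false(pp2$ok)
  # letters that never pair give zero counts and no orphans
  pp3 <- pair_prevalence(matrix("H", 8, 8))
  expect_equal(unname(pp3$counts), c(0L, 0L, 0L, 0L))
  expect_equal(pp3$n_orphans, 0)
})
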