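test_that("class templates satisfy the 80/176/24 constraints", {
  A <- build_class_templates(1)
  expect_equal(dim(A), c(256L, 8L))
  expect_true(all(colSums(A) == 80))
  expect_true(all(colSums(1 - A) == 176))
  expect_length(forbidden_tiles(A), 24)
  # columns pairwise distinct
  expect_equal(anyDuplicated(t(A)), 0L)
  expect_identical(A, build_class_templates(1))
  # the shipped fixture is the seed-1 construction
  fixture <- read_templates(system.file("extdata",
                                        "flag_templates_default.txt",
                                        package = "scmbench"))
  expect_true(all(fixture == A))
})

test_that("tile sampling respects the scaled-Beta supports and means", {
  for (s in 1:25) {
    fg <- sample_tile(TRUE, seed = s)
    bg <- sample_tile(FALSE, seed = s + 100)
    expect_true(all(fg >= 96 & fg <= 248))
    expect_true(all(bg >= 8 & bg <= 200))
  }
  means <- withr::with_seed(3, replicate(2000, mean(sample_tile(TRUE))))
  expect_equal(mean(means), 152 * 4 / 6 + 96, tolerance = 1e-3)
})

test_that("rendering is deterministic and recovery inverts it", {
  A <- build_class_templates(1)
  f1 <- render_flag(4, A, seed = 9)
  f2 <- render_flag(4, A, seed = 9)
  expect_identical(f1$image, f2$image)
  for (cl in 1:8) {
    fl <- render_flag(cl, A, seed = 20 + cl)
    pat <- recover_foreground_pattern(fl$image)
    expect_identical(pat, unname(A[, cl]))
    expect_equal(sum(pat), 80)
  }
  # an all-background image recovers an all-zero pattern
  bg_img <- matrix(0L, 256, 256)
  withr::with_seed(1, for (k in 1:256) {
    r <- (k - 1) %% 16; c <- (k - 1) %/% 16
    bg_img[r * 16 + 1:16, c * 16 + 1:16] <- sample_tile(FALSE)
  })
  expect_equal(sum(recover_foreground_pattern(bg_img)), 0)
})

test_that("RMAE classification identifies class, ties and violations", {
  A <- build_class_templates(1)
  for (cl in c(1, 5, 8)) {
    res <- classify_by_rmae(A[, cl], A)
    expect_equal(res$class_id, cl)
    expect_equal(unname(res$rmae[cl]), 0)
    expect_false(res$forbidden_violation)
    expect_length(res$error_tiles, 0)
  }
  # move one foreground tile to a forbidden index: violation plus 2 error tiles
  forb <- forbidden_tiles(A)
  pat <- A[, 2]
  pat[which(pat == 1L)[1]] <- 0L
  pat[forb[1]] <- 1L
  res <- classify_by_rmae(pat, A)
  expect_true(res$forbidden_violation)
  expect_equal(res$class_id, 2L)
  expect_length(res$error_tiles, 2)
  # an all-zero pattern is equidistant from all classes: lowest id wins
  expect_equal(classify_by_rmae(integer(256), A)$class_id, 1L)
})

test_that("Moran's I matches its definition and null expectation", {
  # maximal negative autocorrelation: checkerboard
  cb <- outer(1:16, 1:16, function(i, j) (i + j) %% 2)
  expect_equal(morans_i(cb)$I, -1, tolerance = 1e-12)
  # strong positive autocorrelation: sorted gradient
  grad <- matrix(rep(1:16, each = 16), 16, 16)
  expect_gt(morans_i(grad)$I, 0.5)
  # constant tile is undefined
  expect_false(morans_i(matrix(5, 16, 16))$defined)
  expect_equal(morans_i(cb)$expected, -1 / 255)
  # textbook double-sum oracle on random tiles
  for (s in 1:5) {
    tile <- sample_tile(s %% 2 == 0, seed = s)
    expect_equal(morans_i(tile)$I, oracle_morans_i(tile), tolerance = 1e-10)
  }
})

test_that("Moran's I null band captures iid texture", {
  nb <- morans_null_band(n_tiles = 2000, seed = 4)
  expect_lt(abs(nb$mean - (-1 / 255)), 0.003)
  vals <- withr::with_seed(9, replicate(300, morans_i(sample_tile(TRUE))$I))
  inside <- mean(vals >= nb$band[1] & vals <= nb$band[2])
  expect_gte(inside, 0.97)
})

test_that("intensity goodness of fit accepts clean and rejects wrong laws", {
  A <- build_class_templates(1)
  null_q <- flag_intensity_null()
  clean_ok <- vapply(1:30, function(i) {
    fl <- render_flag((i - 1) %% 8 + 1, A, seed = 3000 + i)
    intensity_gof(fl$image, fl$pattern, null_q)$acceptable
  }, logical(1))
  expect_gte(mean(clean_ok), 0.9)
  # foreground replaced by uniform draws on the same support
  fl <- render_flag(2, A, seed = 41)
  img <- fl$image
  withr::with_seed(6, for (k in which(fl$pattern == 1L)) {
    r <- (k - 1) %% 16; c <- (k - 1) %/% 16
    img[r * 16 + 1:16, c * 16 + 1:16] <- sample(96:248, 256, replace = TRUE)
  })
  expect_false(intensity_gof(img, fl$pattern, null_q)$acceptable)
  expect_error(intensity_gof(fl$image, integer(256), null_q), "foreground")
})

test_that("generated flag images carry a constant foreground pixel count", {
  A <- build_class_templates(1)
  for (cl in c(1, 8)) {
    fl <- render_flag(cl, A, seed = cl)
    n_fg <- sum(recover_foreground_pattern(fl$image)) * 256
    expect_equal(n_fg, 80 * 256)
  }
})
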