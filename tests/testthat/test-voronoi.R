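test_that("palette has 128 distinct 8-bit values in [1, 254]", {
  p <- voronoi_palette()
  expect_length(p, 128)
  expect_false(anyDuplicated(p) > 0)
  expect_true(all(p >= 1 & p <= 254))
  expect_identical(p, sort(p))
})

test_that("center sampling respects count and minimum separation", {
  for (n in c(16, 64)) {
    pts <- sample_centers(n, seed = n + 3)
    expect_equal(nrow(pts), n)
    d <- as.matrix(dist(pts))
    diag(d) <- Inf
    expect_gte(min(d), 8)
  }
})

test_that("rasterized labels agree with an exhaustive nearest-center scan", {
  for (s in 1:5) {
    centers <- sample_centers(6, seed = s * 11, size = 64)
    part <- rasterize_partition(centers, size = 64)
    oracle <- oracle_nearest_scan(centers, 64)
    inner <- part$label_map > 0
    expect_true(all(part$label_map[inner] == oracle[inner]))
  }
})

test_that("degenerate partitions behave as defined", {
  # one center: a single region, no edges
  one <- rasterize_partition(cbind(32, 32), size = 64)
  expect_false(any(one$edge_mask))
  expect_true(all(one$label_map == 1L))
  # two centers mirrored about the vertical midline: the edge is one column
  two <- rasterize_partition(rbind(c(32.5, 16.5), c(32.5, 48.5)), size = 64)
  edge_cols <- unique(which(two$edge_mask, arr.ind = TRUE)[, 2])
  expect_length(edge_cols, 1)
  expect_equal(sum(two$edge_mask), 64)
})

test_that("intensity assignment achieves exact rank correlation", {
  v <- generate_voronoi(48, seed = 31)
  expect_equal(area_gray_correlation(v$regions), 1.0)
  # two regions: the smaller area carries the smaller gray
  v2 <- generate_voronoi(2, seed = 5)
  ord <- order(v2$regions$area)
  expect_lt(v2$regions$gray[ord[1]], v2$regions$gray[ord[2]])
  # random permutation of intensities destroys the correlation
  rhos <- withr::with_seed(8, replicate(50, {
    g <- sample(v$regions$gray)
    cor(v$regions$area, g, method = "spearman")
  }))
  expect_lt(abs(mean(rhos)), 0.2)
  expect_error(assign_region_intensities(matrix(1L, 4, 4) * 0L +
                                           rep(1:2, each = 8)),
               "distinct")
})

test_that("edge pixels and region areas tile the image exactly", {
  for (s in c(2, 9)) {
    v <- generate_voronoi(32, seed = s)
    expect_equal(sum(v$edge_mask) + sum(v$regions$area), 256^2)
    expect_true(all(v$image[v$edge_mask] == 0))
    # all pixels of a region share one gray
    for (i in c(1, 16, 32)) {
      expect_length(unique(v$image[v$label_map == i]), 1)
    }
  }
})

test_that("region recovery inverts generation within tolerance", {
  errs <- c(); rhos <- c()
  for (cl in c(16, 64)) for (s in 1:3) {
    v <- generate_voronoi(cl, seed = 100 * s + cl)
    r <- recover_regions(v$image)
    errs <- c(errs, abs(r$n_regions - cl))
    rhos <- c(rhos, area_gray_correlation(r$regions))
  }
  expect_true(all(errs <= 2))
  expect_true(all(rhos >= 0.9))
  # degenerate inputs
  expect_equal(recover_regions(matrix(0L, 64, 64))$n_regions, 0)
  expect_equal(recover_regions(matrix(200L, 64, 64))$n_regions, 1)
})

test_that("implicit-context statistics describe the edge graph", {
  # two mirrored regions: one straight edge, no junctions
  part <- rasterize_partition(rbind(c(128.5, 64.5), c(128.5, 192.5)),
                              size = 256)
  regions <- data.frame(id = 1:2, area = tabulate(part$label_map[
    part$label_map > 0], 2), gray = c(100L, 200L))
  x <- list(edge_mask = part$edge_mask, regions = regions)
  st <- implicit_context_stats(x)
  expect_equal(unname(st["n_junctions"]), 0)
  expect_equal(unname(st["n_regions"]), 2)
  expect_gt(unname(st["mean_edge_len"]), 250)
  # conservation: mean area x count ~ non-edge pixels
  v <- generate_voronoi(32, seed = 4)
  st2 <- implicit_context_stats(v)
  expect_equal(st2[["mean_region_area"]] * st2[["n_regions"]],
               256^2 - sum(v$edge_mask))
  # denser classes have smaller regions
  a16 <- median(vapply(1:3, function(s)
    implicit_context_stats(generate_voronoi(16, s))[["mean_region_area"]],
    numeric(1)))
  a64 <- median(vapply(1:3, function(s)
    implicit_context_stats(generate_voronoi(64, s))[["mean_region_area"]],
    numeric(1)))
  expect_lt(a64, a16)
})

test_that("region counts map to exactly one class status", {
  expect_equal(classify_by_region_count(64),
               list(class = 64L, status = "in-class"))
  expect_equal(classify_by_region_count(40),
               list(class = 32L, status = "interpolated"))
  expect_equal(classify_by_region_count(80),
               list(class = 64L, status = "extrapolated"))
  expect_equal(classify_by_region_count(3)$status, "extrapolated")
  statuses <- vapply(1:100, function(n)
    classify_by_region_count(n)$status, character(1))
  expect_true(all(statuses %in% c("in-class", "interpolated", "extrapolated")))
  expect_equal(sum(statuses == "in-class"), 4)
})
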