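# Low-level raster operations shared by the model analyzers.
#
# Connected-component labeling is delegated to EBImage::bwlabel (4-connected);
# skeleton-graph connectivity to igraph. Sauvola thresholding, morphological
# thinning and gray-level co-occurrence summaries are implemented here.

# result[r, c] = m[r + dr, c + dc], out-of-range cells take `fill`
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

# Windowed sums with border clamping, via 2-d cumulative sums.
local_sums <- function(m, w) {
  r <- (w - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed cumulative table
  cs <- t(cs)
  pad <- matrix(0, nr + 1L, nc + 1L)
  pad[-1, -1] <- cs
  r1 <- pmax(1L, seq_len(nr) - r); r2 <- pmin(nr, seq_len(nr) + r)
  c1 <- pmax(1L, seq_len(nc) - r); c2 <- pmin(nc, seq_len(nc) + r)
  sums <- pad[r2 + 1L, c2 + 1L, drop = FALSE] - pad[r1, c2 + 1L, drop = FALSE] -
    pad[r2 + 1L, c1, drop = FALSE] + pad[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  list(sum = sums, count = counts)
}

#' Sauvola local threshold mask
#'
#' Flags pixels darker than the Sauvola adaptive threshold
#' `t = m (1 + k (s / R - 1))`, where `m` and `s` are the local mean and
#' standard deviation in a square window and `R` is the assumed dynamic range
#' of the standard deviation. Used to isolate the near-zero edge network of a
#' Voronoi realization against its brighter constant-intensity regions.
#'
#' @param image numeric matrix of 8-bit intensities.
#' @param window odd window side in pixels.
#' @param k sensitivity parameter.
#' @param R dynamic range of the standard deviation (128 for 8-bit data).
#' @return logical matrix, `TRUE` where the pixel is below its local threshold.
#' @export
sauvola_mask <- function(image, window = 15, k = 0.2, R = 128) {
  s1 <- local_sums(image, window)
  s2 <- local_sums(image^2, window)
  mu <- s1$sum / s1$count
  va <- pmax(0, s2$sum / s2$count - mu^2)
  thr <- mu * (1 + k * (sqrt(va) / R - 1))
  image < thr
}

#' Morphological thinning (skeletonization)
#'
#' Guo-Hall parallel thinning of a binary mask down to a one-pixel-wide,
#' 8-connected skeleton; connectivity and holes of the mask are preserved.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety cap on thinning iterations.
#' @return logical skeleton matrix.
#' @export
thin_mask <- function(mask, max_iter = 500) {
  gh_thin_cpp(matrix(mask != 0, nrow(mask), ncol(mask)), max_iter)
}

# 4-connected component labels of a binary mask (0 = background).
label_components <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)))
  matrix(as.integer(lab), nrow(mask), ncol(mask))
}

# bounding box of a mask's TRUE pixels, padded by one pixel
.mask_bbox <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  list(rows = max(1L, min(px[, 1]) - 1L):min(nrow(mask), max(px[, 1]) + 1L),
       cols = max(1L, min(px[, 2]) - 1L):min(ncol(mask), max(px[, 2]) + 1L))
}

# 8-connected component membership for sparse pixel sets (skeleton pieces).
# Returns an integer matrix of labels, 0 = background.
label8 <- function(mask) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  bb <- .mask_bbox(mask)
  full <- matrix(0L, nrow(mask), ncol(mask))
  full[bb$rows, bb$cols] <- .label8_core(mask[bb$rows, bb$cols, drop = FALSE])
  full
}

.label8_core <- function(mask) {
  idx <- which(mask)
  out <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask)
  id <- matrix(0L, nrow(mask), ncol(mask))
  id[idx] <- seq_along(idx)
  edges <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    nb <- shift_mat(id, d[1], d[2], fill = 0L)
    both <- which(mask & nb > 0L)
    if (length(both)) edges <- c(edges, rbind(id[both], nb[both]))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  out[idx] <- as.integer(comp[seq_along(idx)])
  out
}

# Count of 8-neighbors for every pixel of a binary mask.
neighbor_count <- function(mask) {
  acc <- matrix(0L, nrow(mask), ncol(mask))
  if (!any(mask != 0)) return(acc)
  bb <- .mask_bbox(mask != 0)
  p <- matrix(as.integer(mask[bb$rows, bb$cols] != 0),
              length(bb$rows), length(bb$cols))
  sub <- matrix(0L, nrow(p), ncol(p))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sub <- sub + shift_mat(p, dr, dc)
  }
  acc[bb$rows, bb$cols] <- sub
  acc
}

#' Skeleton graph statistics
#'
#' Decomposes a one-pixel-wide skeleton into junctions (pixels with three or
#' more 8-neighbors, merged into clusters) and branches (8-connected runs of
#' the remaining skeleton pixels), and summarizes branch lengths.
#'
#' @param skeleton logical skeleton matrix (e.g. from [thin_mask()]).
#' @return list with `n_branches`, `n_junctions`, `n_endpoints`,
#'   `branch_lengths` (pixel counts per branch), `total_length`, and
#'   `endpoint_pixels` (two-column matrix of endpoint coordinates).
#' @export
skeleton_stats <- function(skeleton) {
  skeleton <- skeleton != 0
  npx <- sum(skeleton)
  if (npx == 0) {
    return(list(n_branches = 0L, n_junctions = 0L, n_endpoints = 0L,
                branch_lengths = numeric(0), total_length = 0,
                endpoint_pixels = matrix(0, 0, 2)))
  }
  nb <- neighbor_count(skeleton)
  junction_px <- skeleton & nb >= 3
  endpoint_px <- skeleton & nb <= 1
  jlab <- label8(junction_px)
  n_junctions <- max(jlab)
  blab <- label8(skeleton & !junction_px)
  lens <- if (max(blab) > 0) as.numeric(tabulate(blab[blab > 0])) else numeric(0)
  list(n_branches = length(lens),
       n_junctions = as.integer(n_junctions),
       n_endpoints = as.integer(sum(endpoint_px)),
       branch_lengths = lens,
       total_length = npx,
       endpoint_pixels = which(endpoint_px, arr.ind = TRUE))
}

# Iterated box blur (separable mean filter); approximates a Gaussian.
box_blur <- function(m, radius = 8, passes = 3) {
  w <- 2L * radius + 1L
  for (i in seq_len(passes)) {
    s <- local_sums(m, w)
    m <- s$sum / s$count
  }
  m
}

#' Gray-level co-occurrence texture summary
#'
#' Quantizes an 8-bit image to `levels` gray bins, accumulates symmetric
#' co-occurrence matrices at the given pixel offsets, and returns the mean
#' over offsets of the standard contrast, homogeneity, energy and correlation
#' summaries.
#'
#' @param image numeric matrix of 8-bit intensities.
#' @param mask optional logical matrix; only pixel pairs fully inside the mask
#'   are counted.
#' @param levels number of gray levels after quantization.
#' @param offsets list of `c(dr, dc)` displacement vectors.
#' @return named numeric vector
#'   `(glcm_contrast, glcm_homogeneity, glcm_energy, glcm_correlation)`.
#' @export
glcm_features <- function(image, mask = NULL, levels = 32,
                          offsets = list(c(0, 1), c(0, 2), c(0, 4),
                                         c(1, 0), c(2, 0), c(4, 0))) {
  q <- matrix(pmin(levels, floor(image / (256 / levels)) + 1L),
              nrow(image), ncol(image))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  feats <- sapply(offsets, function(d) {
    a <- q; b <- shift_mat(q, d[1], d[2], fill = 0L)
    ok <- mask & shift_mat(mask, d[1], d[2], fill = FALSE) & b > 0L
    if (!any(ok)) return(c(NA, NA, NA, NA))
    code <- (a[ok] - 1L) * levels + b[ok]
    cmat <- matrix(tabulate(code, nbins = levels^2), levels, levels, byrow = TRUE)
    cmat <- cmat + t(cmat)
    p <- cmat / sum(cmat)
    i <- row(p); j <- col(p)
    mu <- sum(p * i)                        # symmetric: row and col means equal
    sg <- sqrt(sum(p * (i - mu)^2))
    corr <- if (sg > 0) sum(p * (i - mu) * (j - mu)) / sg^2 else NA_real_
    c(contrast = sum(p * (i - j)^2),
      homogeneity = sum(p / (1 + (i - j)^2)),
      energy = sum(p^2),
      correlation = corr)
  })
  out <- rowMeans(feats, na.rm = TRUE)
  names(out) <- c("glcm_contrast", "glcm_homogeneity", "glcm_energy",
                  "glcm_correlation")
  out
}
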