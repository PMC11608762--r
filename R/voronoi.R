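# Voronoi SCM: a 256x256 realization partitions the image into c Voronoi
# regions (c in {16, 32, 48, 64} defines the class) around spatially random
# centers. Region boundaries are rasterized as one-pixel-wide zero-intensity
# edges; each region receives a constant gray level from a 128-value palette
# such that the Spearman rank correlation between region area and gray level
# is exactly 1. Recovery isolates the dark edge network with a Sauvola local
# threshold, thins it, and reads regions off the 4-connected complement.

VORONOI_CLASSES <- c(16L, 32L, 48L, 64L)

#' Default gray-level palette of the Voronoi model
#'
#' 128 distinct 8-bit values evenly spaced over `[1, 254]` (linear spacing,
#' rounded). Wide spacing keeps modal-gray recovery unambiguous.
#'
#' @return sorted integer vector of length 128.
#' @export
voronoi_palette <- function() {
  unique(as.integer(round(seq(1, 254, length.out = 128))))
}

#' Sample spatially random region centers
#'
#' Centers are uniform over the image with a minimum pairwise separation
#' `d_min`, enforced by rejection; the whole draw restarts under a derived
#' seed if the rejection cap is hit.
#'
#' @param n_centers number of centers (the class label for in-class values).
#' @param seed integer seed.
#' @param size image side in pixels.
#' @param d_min minimum pairwise center distance in pixels.
#' @return two-column matrix of `(row, col)` coordinates.
#' @export
sample_centers <- function(n_centers, seed, size = 256, d_min = 8) {
  stopifnot(n_centers >= 1)
  with_seed(seed, {
    for (restart in 1:100) {
      pts <- matrix(numeric(0), 0, 2)
      fails <- 0L
      while (nrow(pts) < n_centers && fails < 5000L) {
        p <- runif(2, 0.5, size + 0.5)
        if (nrow(pts) == 0 ||
            min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2) >= d_min^2) {
          pts <- rbind(pts, p)
        } else fails <- fails + 1L
      }
      if (nrow(pts) == n_centers) {
        colnames(pts) <- c("row", "col")
        rownames(pts) <- NULL
        return(pts)
      }
    }
    stop("center sampling exhausted rejection budget", call. = FALSE)
  })
}

#' Rasterize the Voronoi partition of a set of centers
#'
#' Labels every pixel by its nearest center (Euclidean distance to the pixel
#' center), then marks a one-pixel boundary: a pixel is an edge pixel when its
#' label differs from that of its right or bottom 4-neighbor. Edge pixels are
#' set to label 0 in the returned label map.
#'
#' @param centers two-column matrix of `(row, col)` coordinates.
#' @param size image side in pixels.
#' @return list with `label_map` (integer matrix, 0 on edges) and `edge_mask`
#'   (logical matrix).
#' @export
rasterize_partition <- function(centers, size = 256) {
  stopifnot(nrow(centers) >= 1)
  nearest <- nearest_center_cpp(centers, size)
  edge <- (nearest != cbind(nearest[, -1], nearest[, size])) |
    (nearest != rbind(nearest[-1, ], nearest[size, ]))
  label_map <- nearest
  label_map[edge] <- 0L
  list(label_map = label_map, edge_mask = edge)
}

#' Assign rank-correlated region intensities
#'
#' Draws a random subset of the palette (one value per region) and assigns
#' values so that the region with the i-th smallest area receives the i-th
#' smallest gray level, making the Spearman correlation between area and gray
#' exactly 1. Region areas must be pairwise distinct.
#'
#' @param label_map integer label matrix from [rasterize_partition()].
#' @param palette sorted vector of available gray values.
#' @param seed integer seed for the palette subset draw.
#' @return data frame with columns `id`, `area`, `gray`.
#' @export
assign_region_intensities <- function(label_map, palette = voronoi_palette(),
                                      seed = 1) {
  n <- max(label_map)
  areas <- tabulate(label_map[label_map > 0], nbins = n)
  if (anyDuplicated(areas)) {
    stop("region areas must be pairwise distinct", call. = FALSE)
  }
  if (n > length(palette)) stop("palette smaller than region count", call. = FALSE)
  grays <- with_seed(seed, sort(sample(palette, n)))
  data.frame(id = seq_len(n), area = areas,
             gray = grays[rank(areas)])
}

#' Generate one Voronoi realization
#'
#' Samples centers (resampling under derived seeds until all region areas are
#' pairwise distinct), rasterizes the partition, assigns rank-correlated
#' intensities and renders the 8-bit image with zero-intensity edges.
#'
#' @param n_regions region count; in-class values are 16, 32, 48, 64 but any
#'   positive count is accepted (used to synthesize interpolated and
#'   extrapolated fixtures).
#' @param seed integer seed.
#' @param size image side in pixels.
#' @param max_resample resampling cap for the distinct-area requirement.
#' @return list with `image`, `centers`, `label_map`, `edge_mask`, `regions`
#'   (data frame id/area/gray), `n_regions`, `seed`.
#' @export
generate_voronoi <- function(n_regions, seed, size = 256, max_resample = 100) {
  for (k in seq_len(max_resample)) {
    s <- derive_seed(seed, (k - 1L) * 7919L)
    centers <- sample_centers(n_regions, s, size = size)
    part <- rasterize_partition(centers, size = size)
    areas <- tabulate(part$label_map[part$label_map > 0], nbins = n_regions)
    if (length(areas) == n_regions && all(areas > 0) && !anyDuplicated(areas)) {
      regions <- assign_region_intensities(part$label_map, seed = s)
      image <- matrix(0L, size, size)
      pos <- part$label_map > 0
      image[pos] <- regions$gray[part$label_map[pos]]
      return(list(image = image, centers = centers,
                  label_map = part$label_map, edge_mask = part$edge_mask,
                  regions = regions, n_regions = n_regions,
                  seed = as.integer(seed)))
    }
  }
  stop("could not realize pairwise distinct region areas", call. = FALSE)
}

#' Recover Voronoi regions from an image
#'
#' Isolates the dark edge network with a Sauvola local threshold, thins it to
#' a one-pixel skeleton, and reads regions off the 4-connected components of
#' the complement. Components smaller than `min_area` pixels are treated as
#' thresholding debris and dropped. Per-region gray is the modal intensity,
#' per-region area the component pixel count.
#'
#' @param image 8-bit numeric matrix.
#' @param window,k Sauvola parameters (see [sauvola_mask()]).
#' @param min_area smallest component kept as a region.
#' @return list with `label_map`, `regions` (data frame id/area/gray),
#'   `n_regions` and `edge_skeleton`.
#' @export
recover_regions <- function(image, window = 9, k = 0.2, min_area = 24) {
  assert_image(image)
  if (all(image == 0)) {
    return(list(label_map = matrix(0L, nrow(image), ncol(image)),
                regions = data.frame(id = integer(0), area = integer(0),
                                     gray = integer(0)),
                n_regions = 0L,
                edge_skeleton = matrix(FALSE, nrow(image), ncol(image))))
  }
  dark <- sauvola_mask(image, window = window, k = k)
  # Pad with a foreground frame before thinning: walls that terminate on the
  # image border connect to the frame ring, so their separations survive as
  # holes (thinning would otherwise retract thick border-touching walls).
  pad <- 2L
  padded <- matrix(TRUE, nrow(dark) + 2L * pad, ncol(dark) + 2L * pad)
  padded[pad + seq_len(nrow(dark)), pad + seq_len(ncol(dark))] <- dark
  skel_p <- thin_mask(padded)
  skel <- skel_p[pad + seq_len(nrow(dark)), pad + seq_len(ncol(dark))]
  lab <- label_components(!skel)
  n0 <- max(lab)
  areas <- tabulate(lab[lab > 0], nbins = n0)
  keep <- which(areas >= min_area)
  remap <- integer(n0)
  remap[keep] <- seq_along(keep)
  label_map <- matrix(0L, nrow(image), ncol(image))
  pos <- lab > 0 & areas[pmax(lab, 1L)] >= min_area
  label_map[pos] <- remap[lab[pos]]
  n <- length(keep)
  pos <- label_map > 0
  grays <- vapply(split(as.integer(image[pos]), label_map[pos]),
                  modal_value, integer(1))
  regions <- data.frame(id = seq_len(n), area = areas[keep],
                        gray = unname(grays))
  list(label_map = label_map, regions = regions, n_regions = n,
       edge_skeleton = skel)
}

#' Spearman correlation between region area and gray level
#'
#' @param regions data frame with `area` and `gray` columns.
#' @return Spearman rho, or `NA` for fewer than 2 regions.
#' @export
area_gray_correlation <- function(regions) {
  if (nrow(regions) < 2) return(NA_real_)
  cor(regions$area, regions$gray, method = "spearman")
}

#' Implicit-context statistics of a Voronoi realization
#'
#' Seven statistics of the edge graph and region geometry that emerge from the
#' construction without being prescribed: region count, junction count,
#' junction density (junctions per pixel), mean and standard deviation of edge
#' (branch) lengths, and mean and standard deviation of region areas. Edges
#' and junctions are read from the skeletonized edge network (a junction is a
#' cluster of skeleton pixels with three or more neighbors; an edge is a
#' skeleton branch between junctions or endpoints).
#'
#' @param x result of [generate_voronoi()] (ground truth) or
#'   [recover_regions()] (recovered).
#' @return named numeric 7-vector.
#' @export
implicit_context_stats <- function(x) {
  skel <- if (!is.null(x$edge_skeleton)) x$edge_skeleton else thin_mask(x$edge_mask)
  ss <- skeleton_stats(skel)
  areas <- x$regions$area
  npx <- prod(dim(skel))
  c(n_regions = as.numeric(nrow(x$regions)),
    n_junctions = as.numeric(ss$n_junctions),
    junction_density = ss$n_junctions / npx,
    mean_edge_len = if (ss$n_branches) mean(ss$branch_lengths) else 0,
    sd_edge_len = if (ss$n_branches > 1) sd(ss$branch_lengths) else 0,
    mean_region_area = if (length(areas)) mean(areas) else 0,
    sd_region_area = if (length(areas) > 1) sd(areas) else 0)
}

#' Classify a region count against the model classes
#'
#' @param n_regions positive integer region count.
#' @return list with `class` (nearest of 16, 32, 48, 64; ties go to the lower
#'   class) and `status`: `"in-class"` when the count is a class,
#'   `"interpolated"` when strictly between 16 and 64, `"extrapolated"`
#'   otherwise.
#' @export
classify_by_region_count <- function(n_regions) {
  stopifnot(n_regions >= 1)
  d <- abs(VORONOI_CLASSES - n_regions)
  nearest <- VORONOI_CLASSES[which.min(d)]  # which.min takes the lower on ties
  status <- if (n_regions %in% VORONOI_CLASSES) "in-class"
  else if (n_regions > 16 && n_regions < 64) "interpolated"
  else "extrapolated"
  list(class = nearest, status = status)
}

#' Voronoi error detectors
#'
#' Image-level detectors matched to the catalogued error modes.
#'
#' `detect_rank_violation()` flags a realization whose recovered area-gray
#' Spearman correlation falls below `threshold` (0.9 in the standard
#' analysis).
#'
#' `detect_disjoint_edge()` flags the signature of a locally erased edge.
#' Two effects can occur, depending on the gray contrast of the two regions
#' the erased edge separated: (i) the regions merge in recovery, leaving a
#' recovered region whose nonzero pixels carry a substantial second gray
#' level (generated regions are constant-intensity); or (ii) the bare
#' intensity step between dissimilar regions is re-detected as a boundary by
#' the local threshold, leaving a recovered edge segment with no zero-valued
#' pixel nearby (every clean edge is zero-valued). Either signature flags the
#' image.
#'
#' `detect_off_class()` flags a region count farther than `tol` from every
#' class in {16, 32, 48, 64}; the tolerance absorbs the small recovery error
#' on clean realizations.
#'
#' @param recovery result of [recover_regions()].
#' @param threshold Spearman rho threshold.
#' @return logical flag.
#' @export
detect_rank_violation <- function(recovery, threshold = 0.9) {
  rho <- area_gray_correlation(recovery$regions)
  !is.na(rho) && rho < threshold
}

#' @rdname detect_rank_violation
#' @param image the analyzed image (for per-region intensity histograms).
#' @param second_gray_min second-gray pixel mass that indicates a merge
#'   (clean recovery leaks only thin slivers across thinned halos).
#' @param zero_dist recovered edge pixels farther than this from any
#'   zero-valued pixel indicate a re-detected bare intensity step.
#' @param min_run number of far-from-zero edge pixels required.
#' @export
detect_disjoint_edge <- function(image, recovery, second_gray_min = 400,
                                 zero_dist = 10, min_run = 3) {
  lm <- recovery$label_map
  for (i in recovery$regions$id) {
    px <- image[lm == i]
    px <- px[px > 0]
    if (length(px) < second_gray_min) next
    tb <- sort(tabulate(px), decreasing = TRUE)
    if (length(tb) >= 2 && tb[2] >= second_gray_min) return(TRUE)
  }
  sk <- recovery$edge_skeleton
  if (!any(sk)) return(FALSE)
  dm <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(matrix(as.numeric(image != 0), nrow(image), ncol(image)))))
  sum(dm[sk] > zero_dist) >= min_run
}

#' @rdname detect_rank_violation
#' @param n_regions recovered region count.
#' @param tol in-class tolerance in regions.
#' @export
detect_off_class <- function(n_regions, tol = 2) {
  min(abs(VORONOI_CLASSES - n_regions)) > tol
}

#' Generate an ensemble of Voronoi realizations
#'
#' @param classes vector of region-count classes to draw from, cycled.
#' @param per_class images per class.
#' @param seed ensemble seed.
#' @return list with `images`, `realizations` and a `manifest` data frame.
#' @export
generate_voronoi_ensemble <- function(classes = VORONOI_CLASSES, per_class = 1,
                                      seed = 1) {
  cls <- rep(classes, each = per_class)
  seeds <- vapply(seq_along(cls), function(i) derive_seed(seed, i), integer(1))
  reals <- Map(function(cl, s) generate_voronoi(cl, s), cls, seeds)
  manifest <- data.frame(
    filename = sprintf("voronoi_%05d.png", seq_along(cls)),
    model = "voronoi", class = cls, seed = seeds,
    n_regions = cls, stringsAsFactors = FALSE
  )
  list(images = lapply(reals, `[[`, "image"), realizations = reals,
       manifest = manifest)
}
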