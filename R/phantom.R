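# Synthetic breast-slice phantom: a 512x512 stand-in for an anatomy-derived
# stochastic object model, reproducing only the properties the evaluation
# pipeline needs: a zero-valued background, a compact breast-like region, two
# tissue intensity bands separable by global thresholding, a thin bright
# ligament web, and a fatty/glandular pixel ratio that determines one of four
# density classes allocated 1:4:4:1 across an ensemble.
#
# Default intensity bands (8-bit, pairwise disjoint):
#   background 0, glandular [60, 120], fatty [150, 200], ligament [230, 255].
# Default class F/G-ratio intervals (disjoint, ordered):
#   fatty [3, 5), scattered [1.5, 3), heterogeneous [0.5, 1.5),
#   dense [0.1, 0.5).

PHANTOM_CLASSES <- c("fatty", "scattered", "heterogeneous", "dense")
PHANTOM_PREVALENCE <- c(fatty = 1, scattered = 4, heterogeneous = 4, dense = 1)

#' Default tissue intensity bands of the phantom
#' @return named list of `c(lo, hi)` 8-bit intervals plus `background = 0`.
#' @export
phantom_bands <- function() {
  list(background = c(0, 0),
       glandular = c(60, 120),
       fatty = c(150, 200),
       ligament = c(230, 255))
}

#' Default class intervals of the fatty-to-glandular ratio
#' @return named list of `c(lo, hi)` half-open intervals.
#' @export
phantom_class_ranges <- function() {
  list(fatty = c(3, 5), scattered = c(1.5, 3),
       heterogeneous = c(0.5, 1.5), dense = c(0.1, 0.5))
}

# Elliptical breast-like region mask with a low-frequency radial modulation.
.phantom_region <- function(size) {
  cy <- size / 2 + runif(1, -size / 40, size / 40)
  cx <- size / 2 + runif(1, -size / 40, size / 40)
  a <- runif(1, 0.33, 0.40) * size
  b <- runif(1, 0.28, 0.37) * size
  th <- runif(1, 0, pi)
  k <- sample(2:4, 1)
  amp <- runif(1, 0.02, 0.06)
  ph <- runif(1, 0, 2 * pi)
  rr <- matrix(seq_len(size), size, size) - cy
  cc <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- rr * cos(th) + cc * sin(th)
  v <- -rr * sin(th) + cc * cos(th)
  ang <- atan2(v, u)
  (u / a)^2 + (v / b)^2 <= (1 + amp * cos(k * ang + ph))^2
}

#' Generate one phantom realization
#'
#' The breast region is a randomly placed, slightly modulated ellipse on a
#' zero background. A ligament web is drawn as the one-pixel Voronoi ridge
#' network of random interior seed points, clipped to the region. The
#' remaining tissue pixels are split into fatty and glandular by thresholding
#' a smoothed noise field at the quantile that realizes the class's target
#' F/G ratio, and each tissue receives uniform intensities within its band.
#'
#' @param class_label one of `"fatty"`, `"scattered"`, `"heterogeneous"`,
#'   `"dense"`.
#' @param seed integer seed.
#' @param size image side in pixels.
#' @param bands tissue intensity bands as in [phantom_bands()].
#' @param class_ranges class F/G intervals as in [phantom_class_ranges()].
#' @return list with `image`, `masks` (background/fatty/glandular/ligament),
#'   `class_label`, `target_ratio`, `seed`.
#' @export
generate_phantom <- function(class_label, seed, size = 512,
                             bands = phantom_bands(),
                             class_ranges = phantom_class_ranges()) {
  class_label <- match.arg(class_label, PHANTOM_CLASSES)
  with_seed(seed, {
    region <- .phantom_region(size)
    # ligament web: one-sided Voronoi ridges of random seeds, clipped
    n_seeds <- sample(30:45, 1)
    centers <- cbind(runif(n_seeds, 1, size), runif(n_seeds, 1, size))
    part <- rasterize_partition(centers, size = size)
    ligament <- part$edge_mask & region
    rng <- class_ranges[[class_label]]
    target_ratio <- runif(1, rng[1], rng[2])
    tissue <- region & !ligament
    field <- box_blur(matrix(runif(size^2), size, size), radius = 8, passes = 3)
    fvals <- field[tissue]
    gland_frac <- 1 / (1 + target_ratio)
    thr <- quantile(fvals, gland_frac, names = FALSE)
    glandular <- tissue & field <= thr
    fatty <- tissue & field > thr
    image <- matrix(0L, size, size)
    image[glandular] <- as.integer(sample(bands$glandular[1]:bands$glandular[2],
                                          sum(glandular), replace = TRUE))
    image[fatty] <- as.integer(sample(bands$fatty[1]:bands$fatty[2],
                                      sum(fatty), replace = TRUE))
    image[ligament] <- as.integer(sample(bands$ligament[1]:bands$ligament[2],
                                         sum(ligament), replace = TRUE))
    list(image = image,
         masks = list(background = !region, fatty = fatty,
                      glandular = glandular, ligament = ligament),
         class_label = class_label, target_ratio = target_ratio,
         seed = as.integer(seed))
  })
}

#' Generate a phantom ensemble with 1:4:4:1 class prevalence
#'
#' Class labels are allocated deterministically in proportions 1:4:4:1
#' (largest-remainder rounding) and shuffled; per-image seeds derive from the
#' ensemble seed.
#'
#' @param n ensemble size (at least 4).
#' @param seed ensemble seed.
#' @param size image side in pixels.
#' @return list with `images`, `realizations` and `manifest` (filename, class,
#'   target F/G, seed, broken flag).
#' @export
generate_phantom_ensemble <- function(n, seed, size = 512) {
  stopifnot(n >= 4)
  alloc <- largest_remainder(n, PHANTOM_PREVALENCE)
  labels <- rep(PHANTOM_CLASSES, times = alloc)
  labels <- with_seed(derive_seed(seed, 0), sample(labels))
  reals <- lapply(seq_len(n), function(i) {
    generate_phantom(labels[i], derive_seed(seed, i), size = size)
  })
  manifest <- data.frame(
    filename = sprintf("phantom_%05d.png", seq_len(n)),
    model = "phantom", class = labels,
    target_fg_ratio = vapply(reals, `[[`, numeric(1), "target_ratio"),
    seed = vapply(reals, `[[`, integer(1), "seed"),
    broken = FALSE, stringsAsFactors = FALSE
  )
  list(images = lapply(reals, `[[`, "image"), realizations = reals,
       manifest = manifest)
}

#' Segment tissues by global thresholding
#'
#' Exact on clean phantoms because the intensity bands are disjoint by
#' construction.
#'
#' @param image 8-bit numeric matrix.
#' @param bands named band list; intervals must be pairwise disjoint.
#' @return named list of logical masks (background, glandular, fatty,
#'   ligament) forming a partition of the image.
#' @export
segment_tissues <- function(image, bands = phantom_bands()) {
  iv <- do.call(rbind, bands)
  o <- order(iv[, 1])
  if (any(iv[o, 1][-1] <= iv[o, 2][-nrow(iv)])) {
    stop("intensity bands must be pairwise disjoint", call. = FALSE)
  }
  masks <- lapply(bands, function(b) image >= b[1] & image <= b[2])
  # pixels falling between bands (none on clean phantoms) count as background
  assigned <- Reduce(`|`, masks)
  masks$background <- masks$background | !assigned
  masks
}

#' Fatty-to-glandular pixel ratio
#'
#' @param masks mask list with `fatty` and `glandular` entries.
#' @return ratio of fatty to glandular pixel counts; `NA` (with a warning)
#'   when the glandular mask is empty.
#' @export
fg_ratio <- function(masks) {
  gl <- sum(masks$glandular)
  if (gl == 0) {
    warning("empty glandular mask; F/G ratio undefined")
    return(NA_real_)
  }
  sum(masks$fatty) / gl
}

#' Break a ligament segment
#'
#' Erases the ligament pixels inside a disc around a random interior ligament
#' pixel, replacing them with intensities of the locally dominant surrounding
#' tissue. The injected break creates new skeleton endpoints away from the
#' region boundary, which is what the break detector keys on.
#'
#' @param image 8-bit phantom image.
#' @param seed integer seed.
#' @param radius break disc radius in pixels.
#' @param n_breaks number of separate break sites (1 emulates an isolated
#'   major break; larger values emulate badly formed ligament webs).
#' @param bands tissue intensity bands.
#' @return list with `image` (corrupted) and `site` `(row, col)` of the first
#'   break.
#' @export
break_ligament <- function(image, seed, radius = 7, n_breaks = 1,
                           bands = phantom_bands()) {
  masks <- segment_tissues(image, bands)
  lig <- which(masks$ligament, arr.ind = TRUE)
  if (nrow(lig) == 0) stop("no ligament pixels to break", call. = FALSE)
  rr0 <- matrix(seq_len(nrow(image)), nrow(image), ncol(image))
  cc0 <- matrix(seq_len(ncol(image)), nrow(image), ncol(image), byrow = TRUE)
  with_seed(seed, {
    # prefer interior sites: ligament pixels far from the background
    bg_dist_ok <- function(p) {
      r <- p[1]; c <- p[2]; w <- 12
      rs <- max(1, r - w):min(nrow(image), r + w)
      cs <- max(1, c - w):min(ncol(image), c + w)
      !any(masks$background[rs, cs])
    }
    out <- image
    first_site <- NULL
    for (b in seq_len(n_breaks)) {
      for (try in 1:50) {
        site <- lig[sample.int(nrow(lig), 1), ]
        if (bg_dist_ok(site)) break
      }
      if (is.null(first_site)) first_site <- unname(site)
      disc <- (rr0 - site[1])^2 + (cc0 - site[2])^2 <= radius^2
      erase <- disc & masks$ligament
      n_fat <- sum(disc & masks$fatty)
      n_gla <- sum(disc & masks$glandular)
      fill_band <- if (n_fat >= n_gla) bands$fatty else bands$glandular
      out[erase] <- as.integer(sample(fill_band[1]:fill_band[2], sum(erase),
                                      replace = TRUE))
    }
    list(image = out, site = first_site)
  })
}

#' Break ligaments across an ensemble
#'
#' Affects exactly `round(break_rate * n)` images (chosen at random) with one
#' ligament break each; the manifest records which.
#'
#' @param ensemble result of [generate_phantom_ensemble()].
#' @param break_rate fraction of images affected, in `[0, 1]`.
#' @param seed integer seed.
#' @param n_breaks break sites per affected image.
#' @return the ensemble with corrupted `images`, updated `manifest$broken`,
#'   and a `truth` data frame (filename, affected, site).
#' @export
break_ligaments <- function(ensemble, break_rate, seed, n_breaks = 1) {
  stopifnot(break_rate >= 0, break_rate <= 1)
  n <- length(ensemble$images)
  n_aff <- round(break_rate * n)
  affected <- with_seed(derive_seed(seed, 0),
                        sort(sample.int(n, n_aff)))
  sites <- vector("list", n)
  for (i in affected) {
    br <- break_ligament(ensemble$images[[i]], derive_seed(seed, i),
                         n_breaks = n_breaks)
    ensemble$images[[i]] <- br$image
    sites[[i]] <- br$site
  }
  ensemble$manifest$broken <- seq_len(n) %in% affected
  ensemble$truth <- data.frame(
    filename = ensemble$manifest$filename,
    affected = ensemble$manifest$broken,
    site_row = vapply(sites, function(s) if (is.null(s)) NA_real_ else s[1],
                      numeric(1)),
    site_col = vapply(sites, function(s) if (is.null(s)) NA_real_ else s[2],
                      numeric(1)),
    stringsAsFactors = FALSE
  )
  ensemble
}

#' Detect a broken ligament
#'
#' Prunes short spurs from the thinned ligament skeleton and flags the image
#' when any remaining skeleton endpoint lies well inside the breast region
#' (clean Voronoi-ridge webs only terminate at the region boundary).
#'
#' @param image 8-bit phantom image.
#' @param bands tissue intensity bands.
#' @param margin minimum distance (pixels, Chebyshev) from the background for
#'   an endpoint to count as interior.
#' @param spur_len spur branches up to this length are pruned first.
#' @return logical: break detected.
#' @export
detect_ligament_break <- function(image, bands = phantom_bands(), margin = 8,
                                  spur_len = 4) {
  masks <- segment_tissues(image, bands)
  skel <- thin_mask(masks$ligament)
  ss <- skeleton_stats(skel)
  if (ss$total_length == 0) return(FALSE)
  # prune short terminal branches (thinning debris)
  nb <- neighbor_count(skel)
  blab <- label8(skel & nb <= 2)
  if (max(blab) > 0) {
    lens <- tabulate(blab[blab > 0])
    has_end <- vapply(seq_along(lens), function(b) {
      any(nb[blab == b] <= 1)
    }, logical(1))
    drop <- which(lens <= spur_len & has_end)
    skel[blab %in% drop] <- FALSE
    ss <- skeleton_stats(skel)
  }
  ep <- ss$endpoint_pixels
  if (nrow(ep) == 0) return(FALSE)
  not_bg <- !masks$background
  interior <- vapply(seq_len(nrow(ep)), function(i) {
    r <- ep[i, 1]; c <- ep[i, 2]
    rs <- max(1, r - margin):min(nrow(image), r + margin)
    cs <- max(1, c - margin):min(ncol(image), c + margin)
    all(not_bg[rs, cs])
  }, logical(1))
  any(interior)
}
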