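# Ensemble-level evaluation framework: per-image feature families (texture,
# morphology, skeleton, fatty/glandular ratio), a PCA embedding fit on the
# training set, paired cosine-similarity distributions summarized by the
# two-sample Kolmogorov-Smirnov statistic, k-NN coverage/density in the top-2
# principal-component space, and class prevalence.

FEATURE_FAMILIES <- c("texture", "morphology", "skeleton", "fg_ratio")

# Morphology summaries of the 4-connected regions of a binary mask:
# mean/sd of area, perimeter, eccentricity and solidity. Shape and moment
# descriptors come from EBImage; solidity is region area over convex-hull
# area (convex hull via grDevices::chull).
morphology_features <- function(mask, min_region = 9) {
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0) return(setNames(rep(NA_real_, 8), .morph_names))
  areas <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(areas >= min_region)
  if (length(keep) == 0) return(setNames(rep(NA_real_, 8), .morph_names))
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  pos <- which(lab > 0, arr.ind = TRUE)
  coords <- split.data.frame(pos, lab[lab > 0])
  sol <- vapply(keep, function(i) {
    px <- as.matrix(coords[[as.character(i)]])
    if (nrow(px) < 3) return(1)
    h <- grDevices::chull(px)
    hp <- px[h, , drop = FALSE]
    # shoelace area of the hull polygon plus a half-perimeter correction so a
    # convex pixel set has solidity close to 1
    xs <- hp[, 1]; ys <- hp[, 2]
    a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
    hull_area <- a + nrow(hp) / 2 + 1
    min(1, areas[i] / hull_area)
  }, numeric(1))
  vals <- cbind(area = sh[keep, "s.area"],
                perimeter = sh[keep, "s.perimeter"],
                eccentricity = mo[keep, "m.eccentricity"],
                solidity = sol)
  out <- c(apply(vals, 2, mean), apply(vals, 2, function(x) {
    if (length(x) > 1) sd(x) else 0
  }))
  setNames(out, .morph_names)
}

.morph_names <- c("morph_area_mean", "morph_perimeter_mean",
                  "morph_eccentricity_mean", "morph_solidity_mean",
                  "morph_area_sd", "morph_perimeter_sd",
                  "morph_eccentricity_sd", "morph_solidity_sd")

# Skeleton-statistics family of a ligament (or edge) mask.
skeleton_features <- function(mask) {
  nm <- c("skel_n_branches", "skel_n_junctions", "skel_branch_len_mean",
          "skel_branch_len_sd", "skel_total_len")
  if (sum(mask) == 0) return(setNames(rep(NA_real_, 5), nm))
  ss <- skeleton_stats(thin_mask(mask))
  setNames(c(ss$n_branches, ss$n_junctions,
             if (ss$n_branches) mean(ss$branch_lengths) else NA_real_,
             if (ss$n_branches > 1) sd(ss$branch_lengths) else 0,
             ss$total_length), nm)
}

#' Extract per-image feature families
#'
#' Computes, for every image, the four feature families of the evaluation
#' framework: gray-level co-occurrence texture summaries, region morphology
#' summaries, skeleton statistics, and the fatty-to-glandular pixel ratio.
#' Masks are supplied per image as a named list (as produced by
#' [segment_tissues()] for phantoms): `texture` uses the union of tissue
#' masks, `morphology` the glandular mask, `skeleton` the ligament mask.
#' Images where a family is uncomputable (e.g. an empty skeleton) carry `NA`
#' in that family and are flagged.
#'
#' @param images list of 8-bit image matrices.
#' @param masks list (one element per image) of named logical-mask lists with
#'   entries `fatty`, `glandular`, `ligament`; or `NULL` to compute texture on
#'   the full image and skip the other families.
#' @param families subset of families to extract.
#' @return data frame of features; attribute `families` maps each column to
#'   its family, attribute `flagged` is a logical matrix image x family.
#' @export
extract_feature_families <- function(images, masks = NULL,
                                     families = FEATURE_FAMILIES) {
  families <- match.arg(families, FEATURE_FAMILIES, several.ok = TRUE)
  if (is.null(masks)) families <- intersect(families, "texture")
  rows <- lapply(seq_along(images), function(i) {
    img <- images[[i]]
    out <- numeric(0)
    if ("texture" %in% families) {
      tmask <- if (is.null(masks)) NULL else
        (masks[[i]]$fatty | masks[[i]]$glandular | masks[[i]]$ligament)
      out <- c(out, glcm_features(img, tmask))
    }
    if ("morphology" %in% families) {
      out <- c(out, morphology_features(masks[[i]]$glandular))
    }
    if ("skeleton" %in% families) {
      out <- c(out, skeleton_features(masks[[i]]$ligament))
    }
    if ("fg_ratio" %in% families) {
      gl <- sum(masks[[i]]$glandular)
      out <- c(out, fg_ratio = if (gl > 0) sum(masks[[i]]$fatty) / gl else NA_real_)
    }
    out
  })
  feats <- as.data.frame(do.call(rbind, rows))
  fam_of <- function(nm) {
    if (startsWith(nm, "glcm_")) "texture"
    else if (startsWith(nm, "morph_")) "morphology"
    else if (startsWith(nm, "skel_")) "skeleton"
    else "fg_ratio"
  }
  fam <- vapply(names(feats), fam_of, character(1))
  flagged <- t(vapply(seq_len(nrow(feats)), function(i) {
    vapply(unique(fam), function(f) {
      anyNA(feats[i, fam == f, drop = FALSE])
    }, logical(1))
  }, logical(length(unique(fam)))))
  colnames(flagged) <- unique(fam)
  attr(feats, "families") <- fam
  attr(feats, "flagged") <- flagged
  feats
}

#' PCA embedding fit on training features
#'
#' Columns are z-scored using training means and standard deviations
#' (zero-variance columns are dropped); principal components are fit on the
#' training rows only and both tables are projected onto the leading
#' components.
#'
#' @param train_features,gen_features data frames with identical columns.
#' @param n_components components to retain (10 for the similarity framework,
#'   2 for coverage/density); capped at the number of usable features.
#' @return list with `train_emb`, `gen_emb` (matrices), `explained_variance`.
#' @export
pca_embed <- function(train_features, gen_features, n_components = 10) {
  stopifnot(identical(names(train_features), names(gen_features)))
  tr <- as.matrix(train_features)
  ge <- as.matrix(gen_features)
  keep <- colSums(is.na(tr)) == 0 & apply(tr, 2, sd) > 0
  tr <- tr[, keep, drop = FALSE]
  ge <- ge[, keep, drop = FALSE]
  mu <- colMeans(tr)
  sg <- apply(tr, 2, sd)
  trz <- scale(tr, center = mu, scale = sg)
  gez <- scale(ge, center = mu, scale = sg)
  k <- min(n_components, ncol(trz), nrow(trz) - 1)
  pc <- prcomp(trz, center = FALSE, scale. = FALSE)
  list(train_emb = trz %*% pc$rotation[, seq_len(k), drop = FALSE],
       gen_emb = gez %*% pc$rotation[, seq_len(k), drop = FALSE],
       explained_variance = pc$sdev^2)
}

#' Paired cosine-similarity samples
#'
#' Draws `n_pairs` random training-training pairs (distinct indices) and
#' `n_pairs` random training-generated pairs, both with replacement across
#' pairs, and returns the two cosine-similarity samples.
#'
#' @param train_emb,gen_emb embedding matrices with identical column count.
#' @param n_pairs pairs per sample.
#' @param seed integer seed.
#' @return list with `sims_tt` and `sims_tg`, each of length `n_pairs`.
#' @export
cosine_similarity_samples <- function(train_emb, gen_emb, n_pairs = 10000,
                                      seed = 1) {
  nt <- nrow(train_emb); ng <- nrow(gen_emb)
  if (nt < 2) stop("need at least two training rows", call. = FALSE)
  cossim <- function(a, b) {
    rowSums(a * b) / (sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)))
  }
  with_seed(seed, {
    i <- sample.int(nt, n_pairs, replace = TRUE)
    j <- sample.int(nt - 1L, n_pairs, replace = TRUE)
    j <- j + (j >= i)                       # distinct partner, uniform
    sims_tt <- cossim(train_emb[i, , drop = FALSE], train_emb[j, , drop = FALSE])
    a <- sample.int(nt, n_pairs, replace = TRUE)
    b <- sample.int(ng, n_pairs, replace = TRUE)
    sims_tg <- cossim(train_emb[a, , drop = FALSE], gen_emb[b, , drop = FALSE])
    list(sims_tt = sims_tt, sims_tg = sims_tg)
  })
}

#' Two-sample Kolmogorov-Smirnov statistic
#'
#' The supremum distance between the two empirical CDFs; 0 iff the empirical
#' distributions coincide, 1 for fully separated supports.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return D in `[0, 1]`.
#' @export
ks_statistic <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) > 0, length(sample_b) > 0)
  grid <- sort(unique(c(sample_a, sample_b)))
  ea <- vapply(grid, function(g) mean(sample_a <= g), numeric(1))
  eb <- vapply(grid, function(g) mean(sample_b <= g), numeric(1))
  max(abs(ea - eb))
}

#' k-NN coverage and density
#'
#' For each real sample, the k-NN ball is centered on it with radius equal to
#' the distance to its k-th nearest real neighbor (the point itself excluded
#' from the neighbor search). Coverage is the fraction of real balls
#' containing at least one generated sample; density is
#' `1 / (k M) * sum_j #\{real balls containing generated sample j\}` over the
#' M generated samples.
#'
#' @param real_emb,gen_emb embedding matrices (top-2 principal components in
#'   the standard analysis).
#' @param k neighborhood size.
#' @return list with `coverage` and `density`.
#' @export
coverage_density <- function(real_emb, gen_emb, k = 5) {
  n <- nrow(real_emb); m <- nrow(gen_emb)
  if (n < k + 1) stop("need more than k real samples", call. = FALSE)
  dd <- as.matrix(dist(real_emb))
  diag(dd) <- Inf
  radius <- apply(dd, 1, function(r) sort(r)[k])
  dg <- matrix(0, n, m)
  for (d in seq_len(ncol(real_emb))) {
    dg <- dg + outer(real_emb[, d], gen_emb[, d], `-`)^2
  }
  dg <- sqrt(dg)
  inside <- dg <= radius                      # radius recycles over columns
  list(coverage = mean(apply(inside, 1, any)),
       density = sum(inside) / (k * m))
}

#' Class prevalence summary
#'
#' @param labels vector of class labels (factor, character or integer).
#' @param classes optional class ordering for the output.
#' @return named numeric vector of percentages summing to 100.
#' @export
class_prevalence_summary <- function(labels, classes = NULL) {
  if (length(labels) == 0) stop("empty label set", call. = FALSE)
  if (is.null(classes)) classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  setNames(100 * counts / length(labels), as.character(classes))
}

#' Round percentages to integers preserving the total
#'
#' Largest-remainder rounding so the reported integers sum to 100.
#'
#' @param pct numeric percentage vector.
#' @return integer vector summing to 100.
#' @export
round_percent <- function(pct) {
  setNames(largest_remainder(100L, pct), names(pct))
}

#' Full similarity summary of a generated ensemble against training
#'
#' Runs the framework end to end: per-family and all-feature PCA embeddings
#' (10 components), paired cosine-similarity samples, and the KS statistic
#' per family and overall.
#'
#' @param train_features,gen_features feature tables from
#'   [extract_feature_families()].
#' @param n_pairs cosine pairs per comparison.
#' @param seed integer seed.
#' @return list with `ks_per_family`, `ks_overall`, `n_pairs`, `seed`.
#' @export
similarity_summary <- function(train_features, gen_features, n_pairs = 10000,
                               seed = 1) {
  fam <- attr(train_features, "families")
  run <- function(cols) {
    tr <- train_features[, cols, drop = FALSE]
    ge <- gen_features[, cols, drop = FALSE]
    ok_tr <- stats::complete.cases(tr)
    ok_ge <- stats::complete.cases(ge)
    emb <- pca_embed(tr[ok_tr, , drop = FALSE], ge[ok_ge, , drop = FALSE], 10)
    s <- cosine_similarity_samples(emb$train_emb, emb$gen_emb, n_pairs, seed)
    ks_statistic(s$sims_tt, s$sims_tg)
  }
  fams <- unique(fam)
  ks_fam <- vapply(fams, function(f) {
    cols <- which(fam == f)
    if (length(cols) == 1) {
      # scalar family (F/G ratio): cosine similarity is degenerate, compare
      # the feature distributions directly
      a <- train_features[[cols]]; b <- gen_features[[cols]]
      return(ks_statistic(a[!is.na(a)], b[!is.na(b)]))
    }
    run(cols)
  }, numeric(1))
  list(ks_per_family = ks_fam,
       ks_overall = run(seq_along(fam)),
       n_pairs = n_pairs, seed = as.integer(seed))
}
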