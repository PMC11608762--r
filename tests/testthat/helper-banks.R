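# Memoized clean-ensemble banks shared across test files, so expensive
# generation and recovery run once per test session. Phantom banks keep
# images only (tissue masks are exactly recomputable by global thresholding),
# which keeps hundreds of 512x512 realizations within memory.

.banks <- new.env(parent = emptyenv())

.memo <- function(key, builder) {
  if (!exists(key, envir = .banks)) assign(key, builder(), envir = .banks)
  get(key, envir = .banks)
}

alphabet_bank <- function(n, seed = 9001) {
  .memo(sprintf("alpha_%d_%d", n, seed),
        function() generate_alphabet_ensemble(n, seed))
}

# recovered layouts for the alphabet bank (index-aligned)
alphabet_bank_recovered <- function(n, seed = 9001) {
  .memo(sprintf("alpha_rec_%d_%d", n, seed), function() {
    ens <- alphabet_bank(n, seed)
    glyphs <- build_glyph_set()
    lapply(ens$images, function(img) recover_layout(img, glyphs)$layout)
  })
}

voronoi_bank <- function(per_class, seed = 9002) {
  .memo(sprintf("vor_%d_%d", per_class, seed),
        function() generate_voronoi_ensemble(per_class = per_class,
                                             seed = seed))
}

voronoi_bank_recovered <- function(per_class, seed = 9002) {
  .memo(sprintf("vor_rec_%d_%d", per_class, seed), function() {
    ens <- voronoi_bank(per_class, seed)
    lapply(ens$images, recover_regions)
  })
}

# per-image clean detector verdicts for the voronoi bank (memory-lean)
voronoi_bank_flags <- function(per_class, seed = 9002) {
  .memo(sprintf("vor_flag_%d_%d", per_class, seed), function() {
    ens <- voronoi_bank(per_class, seed)
    t(vapply(ens$images, voronoi_detector_verdicts, logical(3)))
  })
}

# run all three matched voronoi detectors on one image
voronoi_detector_verdicts <- function(img) {
  rec <- recover_regions(img)
  c(rank = detect_rank_violation(rec),
    disjoint = detect_disjoint_edge(img, rec),
    off_class = detect_off_class(rec$n_regions))
}

flag_bank <- function(per_class, seed = 9003) {
  .memo(sprintf("flag_%d_%d", per_class, seed),
        function() generate_flag_ensemble(per_class = per_class, seed = seed))
}

flag_intensity_null <- function() {
  .memo("flag_null", function() {
    build_intensity_null(build_class_templates(), n_images = 500, seed = 77)
  })
}

# run all three matched flag detectors on one image
flag_detector_verdicts <- function(img, templates, null_q) {
  pat <- recover_foreground_pattern(img)
  cls <- classify_by_rmae(pat, templates)
  c(pattern_error = length(cls$error_tiles) > 0,
    forbidden = cls$forbidden_violation,
    bad_intensity = !intensity_gof(img, pat, null_q)$acceptable)
}

flag_bank_flags <- function(per_class, seed = 9003) {
  .memo(sprintf("flag_flag_%d_%d", per_class, seed), function() {
    ens <- flag_bank(per_class, seed)
    null_q <- flag_intensity_null()
    t(vapply(ens$images, flag_detector_verdicts, logical(3),
             templates = ens$templates, null_q = null_q))
  })
}

# images-only phantom bank with the 1:4:4:1 class allocation
phantom_bank <- function(n, seed = 9004) {
  .memo(sprintf("ph_%d_%d", n, seed), function() {
    alloc <- scmbench:::largest_remainder(n, c(1, 4, 4, 1))
    labels <- rep(c("fatty", "scattered", "heterogeneous", "dense"),
                  times = alloc)
    labels <- withr::with_seed(scmbench:::derive_seed(seed, 0), sample(labels))
    images <- vector("list", n)
    target <- numeric(n)
    for (i in seq_len(n)) {
      ph <- generate_phantom(labels[i], scmbench:::derive_seed(seed, i))
      images[[i]] <- ph$image
      target[i] <- ph$target_ratio
    }
    list(images = images,
         manifest = data.frame(filename = sprintf("phantom_%05d.png",
                                                  seq_len(n)),
                               model = "phantom", class = labels,
                               target_fg_ratio = target,
                               seed = vapply(seq_len(n), function(i)
                                 scmbench:::derive_seed(seed, i), integer(1)),
                               broken = FALSE, stringsAsFactors = FALSE))
  })
}

# feature table for a phantom bank, one image at a time (masks recomputed)
phantom_bank_features <- function(n, seed = 9004) {
  .memo(sprintf("ph_feat_%d_%d", n, seed), function() {
    ens <- phantom_bank(n, seed)
    phantom_features(ens$images)
  })
}

phantom_features <- function(images) {
  rows <- lapply(images, function(img) {
    extract_feature_families(list(img), list(segment_tissues(img)))
  })
  out <- do.call(rbind, rows)
  attr(out, "families") <- attr(rows[[1]], "families")
  out
}

# clean break-detector verdicts for a phantom bank
phantom_bank_detected <- function(n, seed = 9004) {
  .memo(sprintf("ph_det_%d_%d", n, seed), function() {
    vapply(phantom_bank(n, seed)$images, detect_ligament_break, logical(1))
  })
}

# clean break-detector verdicts for the first 200 images of the 500 bank
phantom_bank_detected_first200 <- function() {
  .memo("ph_det_first200", function() {
    vapply(phantom_bank(500)$images[1:200], detect_ligament_break, logical(1))
  })
}
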