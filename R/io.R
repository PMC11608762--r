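# Ensemble I/O and report assembly. Images are 8-bit grayscale PNG; the
# manifest travels alongside as CSV; evaluation reports are JSON with full
# provenance (config echo, seeds, package version).

#' Write an image ensemble to a directory
#'
#' @param images list of 8-bit integer matrices.
#' @param manifest data frame with at least a `filename` column.
#' @param dir output directory (created if missing).
#' @return invisible vector of written paths.
#' @export
write_ensemble <- function(images, manifest, dir) {
  stopifnot(length(images) == nrow(manifest))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, manifest$filename)
  for (i in seq_along(images)) {
    assert_image(images[[i]])
    png::writePNG(images[[i]] / 255, paths[i])
  }
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(paths)
}

#' Read an image ensemble from a directory
#'
#' Restores pixel matrices bitwise (8-bit round trip). A missing manifest is
#' inferred from the PNG listing with a warning.
#'
#' @param dir ensemble directory.
#' @return list with `images` (integer matrices) and `manifest`.
#' @export
read_ensemble <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (file.exists(mpath)) {
    manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  } else {
    warning("no manifest.csv; inferring from directory listing")
    manifest <- data.frame(filename = sort(list.files(dir, "\\.png$")),
                           stringsAsFactors = FALSE)
  }
  missing <- !file.exists(file.path(dir, manifest$filename))
  if (any(missing)) {
    stop("missing files: ", paste(manifest$filename[missing], collapse = ", "),
         call. = FALSE)
  }
  images <- lapply(file.path(dir, manifest$filename), function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3) m <- m[, , 1]
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
  })
  list(images = images, manifest = manifest)
}

#' Evaluate an alphabet ensemble
#'
#' Template-matching recovery, per-image letter-prevalence goodness of fit
#' and letter-pair audit, with ensemble summaries.
#'
#' @param images list of 256x256 images.
#' @param threshold recognition threshold for template matching.
#' @return list of per-image records and ensemble summary.
#' @export
evaluate_alphabet_ensemble <- function(images, threshold = 0.9) {
  glyphs <- build_glyph_set()
  per_image <- lapply(images, function(img) {
    rec <- recover_layout(img, glyphs, threshold)
    counts <- table(factor(rec$layout, levels = ALPHABET_LETTERS))
    gof <- letter_prevalence_gof(counts)
    pp <- pair_prevalence(rec$layout)
    list(recognizable = rec$recognizable, min_score = min(rec$scores),
         chi2 = gof$chi2, prevalence_pass = gof$pass,
         prevalence_exact = gof$exact,
         pair_counts = as.integer(pp$counts), n_orphans = pp$n_orphans,
         pairs_ok = pp$ok)
  })
  list(per_image = per_image, summary = list(
    n = length(images),
    pct_recognizable = 100 * mean(vapply(per_image, `[[`, logical(1),
                                         "recognizable")),
    pct_prevalence_pass = 100 * mean(vapply(per_image, `[[`, logical(1),
                                            "prevalence_pass")),
    pct_prevalence_exact = 100 * mean(vapply(per_image, `[[`, logical(1),
                                             "prevalence_exact")),
    pct_pairs_ok = 100 * mean(vapply(per_image, `[[`, logical(1), "pairs_ok"))
  ))
}

#' Evaluate a Voronoi ensemble
#'
#' Region recovery, area-gray rank correlation, merged-region and off-class
#' flags, implicit-context statistics, and a region-count histogram.
#'
#' @param images list of images.
#' @return list of per-image records and ensemble summary.
#' @export
evaluate_voronoi_ensemble <- function(images) {
  per_image <- lapply(images, function(img) {
    rec <- recover_regions(img)
    cls <- classify_by_region_count(max(1L, rec$n_regions))
    list(n_regions = rec$n_regions,
         rho = area_gray_correlation(rec$regions),
         rank_violation = detect_rank_violation(rec),
         disjoint_edge = detect_disjoint_edge(img, rec),
         off_class = detect_off_class(rec$n_regions),
         nearest_class = cls$class, status = cls$status,
         implicit = implicit_context_stats(rec))
  })
  counts <- vapply(per_image, `[[`, integer(1), "n_regions")
  list(per_image = per_image, summary = list(
    n = length(images),
    pct_rho_below_0.9 = 100 * mean(vapply(per_image, `[[`, logical(1),
                                          "rank_violation")),
    pct_disjoint_edge = 100 * mean(vapply(per_image, `[[`, logical(1),
                                          "disjoint_edge")),
    pct_off_class = 100 * mean(vapply(per_image, `[[`, logical(1),
                                      "off_class")),
    region_count_histogram = table(counts)
  ))
}

#' Evaluate a flag ensemble
#'
#' Foreground-pattern recovery, RMAE classification, forbidden-tile audit,
#' per-tile Moran's I texture check, and intensity goodness of fit; the
#' report mirrors the percent-acceptable-per-constraint layout.
#'
#' @param images list of images.
#' @param templates template matrix.
#' @param intensity_null length-2 chi-squared null thresholds (built via
#'   [build_intensity_null()] when `NULL`).
#' @param moran_band length-2 Moran's I random-texture band (built via
#'   [morans_null_band()] when `NULL`).
#' @param seed seed for null construction.
#' @return list of per-image records and ensemble summary.
#' @export
evaluate_flag_ensemble <- function(images, templates = build_class_templates(),
                                   intensity_null = NULL, moran_band = NULL,
                                   seed = 1) {
  if (is.null(intensity_null)) {
    intensity_null <- build_intensity_null(templates, n_images = 100,
                                           seed = seed)
  }
  if (is.null(moran_band)) {
    moran_band <- morans_null_band(n_tiles = 2000, seed = seed)$band
  }
  per_image <- lapply(images, function(img) {
    pat <- recover_foreground_pattern(img)
    cls <- classify_by_rmae(pat, templates)
    gof <- intensity_gof(img, pat, intensity_null)
    mi <- vapply(seq_len(FLAG_N_TILES), function(k) {
      r <- (k - 1L) %% FLAG_GRID
      c <- (k - 1L) %/% FLAG_GRID
      morans_i(img[r * FLAG_TILE + 1:16, c * FLAG_TILE + 1:16])$I
    }, numeric(1))
    texture_ok <- mean(!is.na(mi) & mi >= moran_band[1] & mi <= moran_band[2])
    list(class_id = cls$class_id, rmae_best = min(cls$rmae),
         n_error_tiles = length(cls$error_tiles),
         forbidden_violation = cls$forbidden_violation,
         chi2_fg = gof$chi2_fg, chi2_bg = gof$chi2_bg,
         intensity_acceptable = gof$acceptable,
         pct_tiles_random_texture = 100 * texture_ok)
  })
  list(per_image = per_image, summary = list(
    n = length(images),
    pct_pattern_exact = 100 * mean(vapply(per_image, function(p)
      p$n_error_tiles == 0, logical(1))),
    pct_forbidden_violation = 100 * mean(vapply(per_image, `[[`, logical(1),
                                                "forbidden_violation")),
    pct_intensity_acceptable = 100 * mean(vapply(per_image, `[[`, logical(1),
                                                 "intensity_acceptable")),
    mean_pct_random_texture = mean(vapply(per_image, `[[`, numeric(1),
                                          "pct_tiles_random_texture"))
  ))
}

#' Evaluate a phantom ensemble
#'
#' Tissue segmentation, F/G ratio and class assignment, and ligament-break
#' detection.
#'
#' @param images list of 512x512 images.
#' @return list of per-image records and ensemble summary.
#' @export
evaluate_phantom_ensemble <- function(images) {
  ranges <- phantom_class_ranges()
  per_image <- lapply(images, function(img) {
    masks <- segment_tissues(img)
    r <- fg_ratio(masks)
    cls <- NA_character_
    if (!is.na(r)) {
      for (nm in names(ranges)) {
        if (r >= ranges[[nm]][1] && r < ranges[[nm]][2]) cls <- nm
      }
    }
    list(fg_ratio = r, class_label = cls,
         ligament_break = detect_ligament_break(img))
  })
  labels <- vapply(per_image, `[[`, character(1), "class_label")
  list(per_image = per_image, summary = list(
    n = length(images),
    prevalence = class_prevalence_summary(labels[!is.na(labels)],
                                          PHANTOM_CLASSES),
    pct_breaks = 100 * mean(vapply(per_image, `[[`, logical(1),
                                   "ligament_break")),
    pct_unclassified = 100 * mean(is.na(labels))
  ))
}

#' Run a full evaluation report
#'
#' Dispatches on `config$model` (alphabet, voronoi, flags, phantom), reads
#' the ensemble from `config$dir`, evaluates it, and writes a JSON report
#' with provenance. `config` may be a list or the path to a YAML file.
#'
#' @param config list or YAML path with fields `model`, `dir`, `report`, and
#'   optional model-specific settings (`threshold`, `templates`, `seed`).
#' @return the report list, invisibly; written to `config$report` if set.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$model), !is.null(config$dir))
  ens <- read_ensemble(config$dir)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  res <- switch(config$model,
    alphabet = evaluate_alphabet_ensemble(
      ens$images,
      threshold = if (is.null(config$threshold)) 0.9 else config$threshold),
    voronoi = evaluate_voronoi_ensemble(ens$images),
    flags = evaluate_flag_ensemble(
      ens$images,
      templates = if (is.null(config$templates)) build_class_templates()
                  else read_templates(config$templates),
      seed = seed),
    phantom = evaluate_phantom_ensemble(ens$images),
    stop("unknown model: ", config$model, call. = FALSE)
  )
  report <- list(config = config,
                 package_version = as.character(utils::packageVersion("scmbench")),
                 seed = seed,
                 summary = res$summary,
                 per_image = res$per_image)
  if (!is.null(config$report)) {
    jsonlite::write_json(report, config$report, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(report)
}
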